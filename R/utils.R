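# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

# Single internal missing marker: "" from CSV and XPT missing both become NA.
normalize_missing <- function(x) {
  x <- as.character(x)
  x[!is.na(x) & trimws(x) == ""] <- NA_character_
  x
}

# Numeric coercion that never warns; non-numeric text becomes NA.
as_num <- function(x) suppressWarnings(as.numeric(x))

# Character rendering of numerics that round-trips cleanly through CSV/XPT.
num_chr <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) NA_character_ else format(v, scientific = FALSE, trim = TRUE, digits = 15)
  }, character(1))
  out
}

abort_if <- function(cond, msg) {
  if (isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(NULL)
}

# File path with deterministic, filesystem-safe subject stem.
sanitize_stem <- function(x) gsub("[^A-Za-z0-9._-]", "_", x)

round1 <- function(x) round(x + 1e-12, 1)
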
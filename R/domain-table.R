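#' Construct a clinical domain table
#'
#' A domain table is the package's long-format container for one clinical
#' domain (one row = one record). It is an ordinary tibble of character
#' columns carrying three attributes: the two-letter domain code, a named
#' vector of human-readable variable labels, and the name of the unique
#' subject identifier variable (default `USUBJID`).
#'
#' All values are stored as text; empty strings are normalized to `NA`, the
#' single internal missing marker, so that missing values read from CSV and
#' from SAS transport compare equal. Numeric interpretation happens at use
#' sites (summaries, derivations), never at the storage layer, which keeps
#' partial dates and decimal text verbatim.
#'
#' @param data A data frame of records.
#' @param domain_code Two-letter uppercase domain code, e.g. `"AE"`.
#' @param variable_labels Named character vector mapping variable name to
#'   label. Unlabelled variables fall back to their own name on display.
#' @param subject_id_var Name of the subject identifier variable; every
#'   record must carry a non-missing value for it.
#' @param allow_empty Permit a zero-record table (a structurally valid,
#'   legitimately empty domain, e.g. no adverse events yet); file readers
#'   never allow this.
#' @return A tibble of class `domain_table`.
#' @examples
#' dm <- domain_table(
#'   tibble::tibble(USUBJID = c("S1", "S2"), SEX = c("F", "M")),
#'   domain_code = "DM"
#' )
#' domain_code(dm)
#' @export
domain_table <- function(data, domain_code, variable_labels = character(),
                         subject_id_var = "USUBJID", allow_empty = FALSE) {
  abort_if(!grepl("^[A-Z]{2}$", domain_code),
           "domain_code must be a 2-letter uppercase code")
  data <- tibble::as_tibble(data)
  abort_if(nrow(data) == 0L && !allow_empty,
           sprintf("%s: no records", domain_code))
  abort_if(anyDuplicated(names(data)) > 0L,
           sprintf("%s: duplicate column names", domain_code))
  abort_if(!subject_id_var %in% names(data),
           sprintf("%s: subject identifier variable '%s' not present",
                   domain_code, subject_id_var))
  data <- dplyr::mutate(data, dplyr::across(dplyr::everything(), normalize_missing))
  abort_if(anyNA(data[[subject_id_var]]),
           sprintf("%s: record with missing %s", domain_code, subject_id_var))
  structure(data,
            class = c("domain_table", class(tibble::tibble()))[!duplicated(
              c("domain_table", class(tibble::tibble())))],
            domain_code = domain_code,
            variable_labels = variable_labels,
            subject_id_var = subject_id_var)
}

#' @rdname domain_table
#' @param x A `domain_table`.
#' @export
domain_code <- function(x) attr(x, "domain_code")

#' @rdname domain_table
#' @export
variable_labels <- function(x) attr(x, "variable_labels") %||% character()

#' @rdname domain_table
#' @export
subject_id_var <- function(x) attr(x, "subject_id_var") %||% "USUBJID"

#' @export
print.domain_table <- function(x, ...) {
  cat(sprintf("<domain_table %s: %d records x %d variables, subjects by %s>\n",
              domain_code(x), nrow(x), ncol(x), subject_id_var(x)))
  NextMethod()
}

#' Read one clinical domain from file
#'
#' Reads a domain table from CSV (RFC 4180, header row required, UTF-8) or
#' SAS transport version 5. For CSV, an optional sidecar file
#' `<stem>-labels.csv` with columns `variable,label` populates variable
#' labels; for XPT the labels come from the transport metadata.
#'
#' @param path Path to the data file.
#' @param format `"csv"` or `"xpt"`.
#' @param domain_code Two-letter domain code the file is configured as.
#' @param subject_id_var Subject identifier variable name.
#' @return A [domain_table()] with records in file order.
#' @export
read_domain <- function(path, format = c("csv", "xpt"), domain_code,
                        subject_id_var = "USUBJID") {
  format <- match.arg(format)
  abort_if(!file.exists(path), sprintf("cannot read '%s': no such file", path))
  if (format == "csv") {
    data <- tryCatch(
      readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                      progress = FALSE, show_col_types = FALSE,
                      name_repair = "minimal", locale = readr::locale(encoding = "UTF-8")),
      error = function(e) stop(sprintf("cannot read '%s': %s", path, conditionMessage(e)),
                               call. = FALSE))
    labels <- read_label_sidecar(path)
  } else {
    data <- tryCatch(haven::read_xpt(path),
                     error = function(e) stop(sprintf("cannot read '%s': %s", path,
                                                      conditionMessage(e)), call. = FALSE))
    labels <- vapply(data, function(col) attr(col, "label") %||% NA_character_, character(1))
    labels <- labels[!is.na(labels)]
    data <- dplyr::mutate(data, dplyr::across(
      dplyr::where(is.numeric), num_chr))
    data <- dplyr::mutate(data, dplyr::across(dplyr::everything(), as.character))
  }
  abort_if(nrow(data) == 0L, sprintf("%s: no records in '%s'", domain_code, path))
  domain_table(data, domain_code = domain_code, variable_labels = labels,
               subject_id_var = subject_id_var)
}

read_label_sidecar <- function(path) {
  stem <- sub("\\.csv$", "", path, ignore.case = TRUE)
  sidecar <- paste0(stem, "-labels.csv")
  if (!file.exists(sidecar)) return(character())
  lab <- readr::read_csv(sidecar, col_types = "cc", progress = FALSE,
                         show_col_types = FALSE)
  stats::setNames(lab$label, lab$variable)
}

#' Write a domain table to CSV
#'
#' Inverse of [read_domain()] for the CSV format: records and variable order
#' are preserved exactly on a read-write-read round trip. Variable labels,
#' when present, go to the `<stem>-labels.csv` sidecar.
#'
#' @param table A `domain_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_domain_csv <- function(table, path) {
  readr::write_csv(tibble::as_tibble(table), path, na = "", progress = FALSE)
  labs <- variable_labels(table)
  if (length(labs)) {
    sidecar <- paste0(sub("\\.csv$", "", path, ignore.case = TRUE), "-labels.csv")
    readr::write_csv(tibble::tibble(variable = names(labs), label = unname(labs)),
                     sidecar, progress = FALSE)
  }
  invisible(path)
}

#' Check required variables exist in a domain table
#'
#' Existence checks are the first line of defence against a snapshot that
#' drifts from its expected structure: the check reports, it never raises,
#' so that a report build can surface every problem at once.
#'
#' @param table A `domain_table`.
#' @param required Non-empty character vector of required variable names.
#' @return A one-row tibble with columns `domain_code`, `missing_required`
#'   (list column), `present` (list column) and `passed` (`TRUE` iff nothing
#'   is missing).
#' @export
check_required_variables <- function(table, required) {
  abort_if(length(required) == 0L, "required must be a non-empty character vector")
  missing_req <- setdiff(required, names(table))
  tibble::tibble(
    domain_code = domain_code(table),
    missing_required = list(missing_req),
    present = list(intersect(required, names(table))),
    passed = length(missing_req) == 0L
  )
}

#' Packaged default required variables per domain
#'
#' The defaults ship as configuration, not code constants; override per
#' study by supplying your own `required` vectors to
#' [check_required_variables()].
#'
#' @return Named list: domain code -> character vector of variable names.
#' @export
default_required_variables <- function() {
  yaml::read_yaml(system.file("config", "required-variables.yml",
                              package = "safetyreview"))
}

#' Run existence checks across a whole batch
#'
#' @param batch A `study_batch`.
#' @param required Named list domain -> required variables; defaults to
#'   [default_required_variables()]. Domains without an entry are skipped.
#' @return Tibble with one row per checked domain.
#' @export
check_batch <- function(batch, required = default_required_variables()) {
  codes <- intersect(names(batch$domains), names(required))
  req <- required
  if (batch$blinded) {
    trt <- attr(batch, "masked_treatment_var")
    req <- lapply(req, setdiff, y = trt %||% character())
  }
  dplyr::bind_rows(lapply(codes, function(code)
    check_required_variables(batch$domains[[code]], req[[code]])))
}

#' Assemble a study batch from a directory of domain files
#'
#' A batch is one dated snapshot of the accumulating trial database. The
#' manifest (usually a fragment of the report YAML) lists the domain files,
#' the cutoff date and the blinding status. When the batch is blinded the
#' treatment variable named in the manifest is dropped from every table
#' before the batch is returned, so no downstream computation can see it.
#'
#' @param dir Directory holding the domain files.
#' @param manifest A list with elements `batch_id`, `cutoff_date`, `blinded`
#'   (logical), `treatment_var` (variable name), `subject_id_var` (optional,
#'   default `USUBJID`) and `domains`: a named list mapping domain code to
#'   either a file name or a list `list(file =, format =)`.
#' @return A `study_batch`: list with `batch_id`, `cutoff_date`, `domains`
#'   (named list of `domain_table`), `blinded`, and `treatment_var` (absent
#'   when blinded).
#' @export
load_batch <- function(dir, manifest) {
  blinded <- isTRUE(manifest$blinded)
  sid <- manifest$subject_id_var %||% "USUBJID"
  trt <- manifest$treatment_var
  domains <- purrr::imap(manifest$domains, function(spec, code) {
    if (is.character(spec)) spec <- list(file = spec)
    fmt <- spec$format %||% (if (grepl("\\.xpt$", spec$file, ignore.case = TRUE)) "xpt" else "csv")
    path <- file.path(dir, spec$file)
    abort_if(!file.exists(path), sprintf("%s: file not found ('%s')", code, path))
    tab <- read_domain(path, format = fmt, domain_code = code, subject_id_var = sid)
    if (blinded && !is.null(trt) && trt %in% names(tab)) {
      keep <- setdiff(names(tab), trt)
      tab <- domain_table(tab[keep], domain_code = code,
                          variable_labels = variable_labels(tab)[
                            intersect(names(variable_labels(tab)), keep)],
                          subject_id_var = sid)
    }
    tab
  })
  batch <- study_batch(batch_id = manifest$batch_id %||% basename(dir),
                       cutoff_date = manifest$cutoff_date %||% NA_character_,
                       domains = domains, blinded = blinded,
                       treatment_var = if (blinded) NULL else trt)
  if (blinded) attr(batch, "masked_treatment_var") <- trt
  batch
}

#' @rdname load_batch
#' @export
load_batch_dir <- function(dir) {
  manifest_path <- file.path(dir, "manifest.yml")
  abort_if(!file.exists(manifest_path),
           sprintf("no manifest.yml in '%s'", dir))
  load_batch(dir, yaml::read_yaml(manifest_path))
}

#' @rdname load_batch
#' @param batch_id Text label for the snapshot.
#' @param cutoff_date ISO-8601 date of the data cut.
#' @param domains Named list of `domain_table`s.
#' @param blinded Logical; when `TRUE`, `treatment_var` must be `NULL`.
#' @param treatment_var Treatment variable name, or `NULL` when blinded.
#' @export
study_batch <- function(batch_id, cutoff_date, domains, blinded = FALSE,
                        treatment_var = NULL) {
  abort_if(blinded && !is.null(treatment_var),
           "a blinded batch cannot carry a treatment variable")
  structure(list(batch_id = batch_id, cutoff_date = cutoff_date,
                 domains = domains, blinded = blinded,
                 treatment_var = treatment_var),
            class = "study_batch")
}

#' @export
print.study_batch <- function(x, ...) {
  cat(sprintf("<study_batch '%s' cutoff %s, %s>\n", x$batch_id, x$cutoff_date,
              if (x$blinded) "blinded" else sprintf("unblinded (arm: %s)",
                                                    x$treatment_var %||% "?")))
  for (code in names(x$domains))
    cat(sprintf("  %s: %d records\n", code, nrow(x$domains[[code]])))
  invisible(x)
}
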
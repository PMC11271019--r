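# Export surfaces for summary tables and listings: interactive payload
# (JSON embedded in chapter HTML), flat CSV, and a plain paginated document.

flatten_summary <- function(table) {
  row_vars <- attr(table, "row_vars")
  df <- tibble::as_tibble(table)
  present <- intersect(row_vars, names(df))
  indent <- function(i, lab) paste0(strrep("  ", i), lab)
  lab <- rep("", nrow(df))
  depth <- rep(0L, nrow(df))
  for (i in seq_along(present)) {
    v <- df[[present[i]]]
    fill <- !is.na(v) & v != ""
    lab[fill] <- v[fill]
    depth[fill] <- i - 1L
  }
  df$row <- mapply(indent, depth, lab)
  stat_cols <- intersect(c("n_subjects", "pct", "n_events", "n", "n_missing",
                           "mean", "sd", "median", "min", "max",
                           "prev_n_subjects", "prev_pct", "prev_n_events",
                           "prev_n", "prev_mean", "prev_sd", "prev_median",
                           "prev_min", "prev_max"), names(df))
  out <- df[, c("row", "group", stat_cols), drop = FALSE]
  if ("pct" %in% names(out)) out$pct <- round1(out$pct)
  if ("prev_pct" %in% names(out)) out$prev_pct <- round1(out$prev_pct)
  for (col in intersect(c("mean", "sd", "median", "prev_mean", "prev_sd",
                          "prev_median"), names(out)))
    out[[col]] <- signif(out[[col]], 6)
  if ("subjects" %in% names(df))
    out$subjects <- purrr::map_chr(df$subjects, paste, collapse = ";")
  out
}

#' Export a summary table
#'
#' Three contracts: `"interactive_html_data"` serializes rows, hierarchy,
#' per-cell subject ids and their profile link targets as the JSON payload
#' the in-report table widget consumes; `"csv"` flattens the row hierarchy
#' into an indented label column; `"static_doc"` writes a plain paginated
#' document table. Stored statistics are unrounded; exports round
#' percentages to one decimal.
#'
#' @param table A `summary_table` (or plain tibble for listings).
#' @param format One of `"interactive_html_data"`, `"csv"`, `"static_doc"`.
#' @param path Output file path.
#' @param link_index Optional named character vector mapping subject id to
#'   profile path, used to annotate cell subjects with link targets.
#' @param page_rows Rows per page for the static document (default 40).
#' @return `path`, invisibly.
#' @export
export_table <- function(table, format, path, link_index = NULL, page_rows = 40) {
  supported <- c("interactive_html_data", "csv", "static_doc")
  abort_if(!format %in% supported,
           sprintf("unknown format '%s'; supported: %s", format,
                   paste(supported, collapse = ", ")))
  is_summary <- inherits(table, "summary_table")
  flat <- if (is_summary) flatten_summary(table) else tibble::as_tibble(table)
  if (format == "csv") {
    readr::write_csv(flat, path, na = "", progress = FALSE)
  } else if (format == "interactive_html_data") {
    payload <- summary_payload(table, link_index)
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null")
  } else {
    writeLines(paginate_doc(flat, page_rows), path)
  }
  invisible(path)
}

summary_payload <- function(table, link_index = NULL) {
  is_summary <- inherits(table, "summary_table")
  df <- tibble::as_tibble(table)
  subj_links <- NULL
  if ("subjects" %in% names(df)) {
    subj_links <- purrr::map(df$subjects, function(s) {
      lapply(s, function(id) list(
        subject_id = id,
        profile = if (!is.null(link_index) && id %in% names(link_index))
          unname(link_index[[id]]) else NULL))
    })
    df$subjects <- NULL
  }
  rows <- purrr::transpose(lapply(df, function(col) {
    if (is.list(col)) purrr::map(col, identity) else col
  }))
  list(
    kind = "summary_table",
    table_type = if (is_summary) attr(table, "table_type") else "listing",
    row_hierarchy = if (is_summary) as.list(attr(table, "row_vars")) else list(),
    columns = as.list(names(df)),
    denominators = if (is_summary) attr(table, "denominators") else NULL,
    previous_batch = attr(table, "previous_batch_id"),
    rows = rows,
    cell_subjects = subj_links
  )
}

paginate_doc <- function(flat, page_rows = 40) {
  flat <- dplyr::mutate(flat, dplyr::across(dplyr::everything(), function(x) {
    x <- if (is.numeric(x)) formatC(x, format = "g", digits = 6) else as.character(x)
    ifelse(is.na(x) | x == "NA", "", x)
  }))
  widths <- pmax(nchar(names(flat)),
                 purrr::map_int(flat, ~ max(nchar(.x), 0L)))
  fmt_row <- function(vals) paste(mapply(formatC, vals, width = widths,
                                         MoreArgs = list(flag = "-")), collapse = "  ")
  header <- fmt_row(names(flat))
  rule <- strrep("-", nchar(header))
  body <- purrr::map_chr(seq_len(nrow(flat)), function(i) fmt_row(unlist(flat[i, ])))
  pages <- split(body, ceiling(seq_along(body) / page_rows))
  if (length(pages) == 0L) pages <- list(character())
  out <- purrr::imap(pages, function(rows, i) {
    c(sprintf("Page %s of %d", i, length(pages)), header, rule, rows)
  })
  unlist(purrr::map(out, ~ c(.x, "\f")))
}
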
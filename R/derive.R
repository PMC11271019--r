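# Light analysis-dataset derivations: study day, partial-date flags,
# severity ranks, categorization, visit-window averaging, QTcF.

#' Study day relative to a reference date
#'
#' Signed day count with no day zero: the reference date itself is day 1,
#' the day before it is day -1 (the SDTM `--DY` convention).
#'
#' @param date ISO-8601 complete date(s), `"YYYY-MM-DD"`.
#' @param reference_date ISO-8601 complete reference date(s) (recycled).
#' @return Integer vector of study days; never 0, `NA` for missing dates.
#' @examples
#' derive_study_day("2023-01-10", "2023-01-10")  # 1
#' derive_study_day("2023-01-09", "2023-01-10")  # -1
#' @export
derive_study_day <- function(date, reference_date) {
  chk <- function(x) {
    bad <- !is.na(x) & !grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
    abort_if(any(bad), sprintf("derive_study_day requires complete dates (got '%s')",
                               x[bad][1]))
  }
  date <- normalize_missing(date); reference_date <- normalize_missing(reference_date)
  chk(date); chk(reference_date)
  d <- as.integer(as.Date(date) - as.Date(reference_date))
  as.integer(ifelse(is.na(d), NA_integer_, ifelse(d >= 0L, d + 1L, d)))
}

#' Classify a possibly-partial ISO date
#'
#' Clinical start dates are often only known to the month or year. The
#' status records which components are missing; the imputed date fills the
#' missing day and/or month with 01 (the earliest date consistent with the
#' recorded text), so that imputed timelines never start later than the
#' truth. Downstream displays carry the `imputed` flag.
#'
#' @param text Character vector of `"YYYY"`, `"YYYY-MM"`, `"YYYY-MM-DD"` or
#'   empty/`NA`.
#' @return Tibble with columns `text`, `status` (`complete`, `missing_day`,
#'   `missing_month_day`, `missing_all`), `imputed_date` (ISO date or `NA`)
#'   and `imputed` (`TRUE` iff partial and an imputed date exists).
#' @export
classify_partial_date <- function(text) {
  text <- normalize_missing(text)
  safe_date <- function(x) tryCatch(as.Date(x), error = function(e) as.Date(NA))
  one <- function(x) {
    if (is.na(x)) return(list(status = "missing_all", imputed_date = NA_character_))
    if (grepl("^\\d{4}-\\d{2}-\\d{2}$", x)) {
      abort_if(is.na(safe_date(x)), sprintf("unparseable date '%s'", x))
      return(list(status = "complete", imputed_date = x))
    }
    if (grepl("^\\d{4}-\\d{2}$", x)) {
      imp <- paste0(x, "-01")
      abort_if(is.na(safe_date(imp)), sprintf("unparseable date '%s'", x))
      return(list(status = "missing_day", imputed_date = imp))
    }
    if (grepl("^\\d{4}$", x)) {
      return(list(status = "missing_month_day", imputed_date = paste0(x, "-01-01")))
    }
    stop(sprintf("unparseable date '%s'", x), call. = FALSE)
  }
  parts <- purrr::map(text, one)
  status <- purrr::map_chr(parts, "status")
  imputed_date <- purrr::map_chr(parts, "imputed_date")
  tibble::tibble(
    text = text, status = status,
    imputed_date = ifelse(status == "complete", imputed_date,
                          ifelse(status == "missing_all", NA_character_, imputed_date)),
    imputed = status != "complete" & status != "missing_all"
  )
}

#' Numeric rank for an ordered categorical level
#'
#' Gives adverse-event severities (or CTCAE grades) a numeric ordering
#' variable for sorting and worst-case logic. Matching is case-insensitive;
#' an unknown or missing level ranks after every known level so it sorts
#' last rather than silently dropping.
#'
#' @param level Character vector of levels to rank.
#' @param ordered_levels Non-empty ordered character vector, mildest first.
#' @return Integer ranks, 1-based; `length(ordered_levels) + 1` for unknown
#'   or missing levels.
#' @export
rank_severity <- function(level, ordered_levels = c("MILD", "MODERATE", "SEVERE")) {
  abort_if(length(ordered_levels) == 0L, "ordered_levels must be non-empty")
  idx <- match(toupper(trimws(as.character(level))), toupper(ordered_levels))
  as.integer(ifelse(is.na(idx), length(ordered_levels) + 1L, idx))
}

#' Categorize a continuous value against ascending cut points
#'
#' Intervals are left-closed, right-open, except the last which is closed
#' above; a value equal to a break therefore falls in the upper interval
#' (age 65 with break 65 is ">=65").
#'
#' @param value Numeric (or numeric-text) vector.
#' @param breaks Strictly ascending cut points.
#' @param labels Labels; `length(labels) == length(breaks) + 1`.
#' @return Character labels; `NA` for non-numeric values.
#' @export
categorize_numeric <- function(value, breaks, labels) {
  abort_if(length(labels) != length(breaks) + 1L,
           "need length(breaks) + 1 labels")
  abort_if(is.unsorted(breaks, strictly = TRUE), "breaks must be strictly ascending")
  v <- as_num(value)
  idx <- findInterval(v, breaks) + 1L
  ifelse(is.na(v), NA_character_, labels[idx])
}

#' Average repeated measurements within a visit window
#'
#' ECG and vital-sign snapshots often carry several measurements for the
#' same subject, parameter and visit (e.g. triplicate ECGs). Measurements
#' whose study day lies within `window_days` of the visit's nominal day are
#' averaged into one record; records outside the window pass through
#' unaveraged. The output record keeps the earliest in-window timestamp and
#' is flagged `averaged_flag = TRUE` when more than one record contributed.
#'
#' @param records Tibble of measurement records for one subject, parameter
#'   and visit, with columns `study_day`, `value` (numeric or numeric text)
#'   and optionally `timestamp` (sortable text).
#' @param nominal_day Nominal study day of the visit.
#' @param window_days Half-width of the window in days (default 3).
#' @return Tibble: one averaged in-window record (or a missing-value record
#'   when no numeric in-window results exist) plus any out-of-window records
#'   unchanged, each with `averaged_flag`.
#' @export
average_visit_window <- function(records, nominal_day, window_days = 3) {
  records <- tibble::as_tibble(records)
  if (!"timestamp" %in% names(records)) records$timestamp <- NA_character_
  records$value <- as_num(records$value)
  inw <- !is.na(records$study_day) &
    abs(records$study_day - nominal_day) <= window_days
  outside <- records[!inw, , drop = FALSE]
  if (nrow(outside)) outside$averaged_flag <- FALSE
  win <- records[inw, , drop = FALSE]
  vals <- win$value[!is.na(win$value)]
  if (nrow(win) == 0L) return(outside)
  avg <- win[1L, , drop = FALSE]
  ord <- order(win$timestamp, win$study_day, na.last = TRUE)
  avg$timestamp <- win$timestamp[ord][1L]
  avg$study_day <- win$study_day[ord][1L]
  if (length(vals) == 0L) {
    avg$value <- NA_real_
    avg$averaged_flag <- FALSE
  } else {
    avg$value <- mean(vals)
    avg$averaged_flag <- length(vals) > 1L
  }
  dplyr::bind_rows(avg, outside)
}

#' QT interval corrected for heart rate (Fridericia)
#'
#' QTcF = QT / RR^(1/3) with RR in seconds. When RR is not recorded it is
#' derived from heart rate as 60 / HR; a recorded RR takes precedence. When
#' neither constituent exists no value is derived.
#'
#' @param qt_ms QT interval in milliseconds, positive.
#' @param rr_s RR interval in seconds, or `NA`.
#' @param hr_bpm Heart rate in beats per minute, or `NA`.
#' @return QTcF in milliseconds; `NA` where underivable.
#' @examples
#' derive_qtcf(400, rr_s = 1)    # 400
#' derive_qtcf(400, hr_bpm = 120)  # 400 / 0.5^(1/3)
#' @export
derive_qtcf <- function(qt_ms, rr_s = NA_real_, hr_bpm = NA_real_) {
  n <- max(length(qt_ms), length(rr_s), length(hr_bpm))
  qt_ms <- rep_len(as_num(qt_ms), n)
  rr_s <- rep_len(as_num(rr_s), n)
  hr_bpm <- rep_len(as_num(hr_bpm), n)
  rr <- ifelse(!is.na(rr_s), rr_s, 60 / hr_bpm)
  out <- ifelse(is.na(qt_ms) | qt_ms <= 0 | is.na(rr) | rr <= 0,
                NA_real_, qt_ms / rr^(1/3))
  out
}

#' Append a study-day column derived from a date variable
#'
#' Joins each record's subject to its reference start date (usually DM's
#' `RFSTDTC`) and derives the SDTM-convention study day from the record's
#' (possibly partial, earliest-imputed) date. Adds `<day_var>` plus an
#' `<day_var>_IMPUTED` flag column.
#'
#' @param table A `domain_table` with a date variable.
#' @param reference_dates Tibble `subject_id`/`reference_date`, or a DM
#'   `domain_table` with an `RFSTDTC` column.
#' @param date_var Name of the date variable in `table`.
#' @param day_var Name of the study-day column to create.
#' @return `table` with the two columns appended.
#' @export
add_study_day <- function(table, reference_dates, date_var,
                          day_var = paste0(domain_code(table), "DY")) {
  if (inherits(reference_dates, "domain_table")) {
    reference_dates <- tibble::tibble(
      subject_id = reference_dates[[subject_id_var(reference_dates)]],
      reference_date = reference_dates$RFSTDTC)
  }
  sid <- subject_id_var(table)
  ref <- reference_dates$reference_date[
    match(table[[sid]], reference_dates$subject_id)]
  cls <- classify_partial_date(table[[date_var]])
  table[[day_var]] <- derive_study_day(cls$imputed_date, ref)
  table[[paste0(day_var, "_IMPUTED")]] <- cls$imputed
  table
}

#' Evaluate generic analysis-flag rules
#'
#' Config-driven boolean flags of the form (variable, operator, value),
#' e.g. `AESER == "Y"`. Supported operators: `==`, `!=`, `<`, `<=`, `>`,
#' `>=`, `in`. Comparisons are numeric when both sides coerce, else text.
#'
#' @param table A `domain_table` or data frame.
#' @param rules List of lists with elements `flag`, `variable`, `operator`,
#'   `value`.
#' @return `table` with one logical column per rule appended.
#' @export
apply_flag_rules <- function(table, rules) {
  for (rule in rules) {
    abort_if(!rule$variable %in% names(table),
             sprintf("flag rule '%s': variable '%s' absent", rule$flag, rule$variable))
    x <- table[[rule$variable]]
    v <- rule$value
    num <- !anyNA(as_num(x[!is.na(x)])) && !anyNA(as_num(unlist(v)))
    if (num && rule$operator != "in") {
      xs <- as_num(x); vs <- as_num(v)
    } else {
      xs <- as.character(x); vs <- as.character(unlist(v))
    }
    res <- switch(rule$operator,
      "==" = xs == vs, "!=" = xs != vs,
      "<" = xs < vs, "<=" = xs <= vs,
      ">" = xs > vs, ">=" = xs >= vs,
      "in" = xs %in% vs,
      stop(sprintf("unknown operator '%s'", rule$operator), call. = FALSE))
    table[[rule$flag]] <- !is.na(res) & res
  }
  table
}
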
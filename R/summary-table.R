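# Descriptive and incidence summary tables with per-cell subject links.
#
# A summary_table is a tidy tibble: one row per (row-hierarchy, group) cell,
# with the hierarchy columns named in attr "row_vars", a `group` column, the
# statistics for that cell, and a `subjects` list column feeding the
# patient-profile links. Percentages are stored unrounded; rounding to one
# decimal happens at export time only.

new_summary_table <- function(data, table_type, row_vars, denominators,
                              listing = NULL) {
  structure(tibble::as_tibble(data),
            class = c("summary_table", class(tibble::tibble()))[!duplicated(
              c("summary_table", class(tibble::tibble())))],
            table_type = table_type, row_vars = row_vars,
            denominators = denominators, listing = listing)
}

#' Analysis population with group assignment
#'
#' Builds the subject-to-arm mapping every summary groups by. With a
#' treatment variable the groups are the arms; without one (blinded data)
#' all subjects fall in a single pooled `"All"` column. Denominators for
#' percentages are the population counts per group, not the subjects with
#' records in any particular domain.
#'
#' @param dm The demographics `domain_table`.
#' @param treatment_var Arm variable name, or `NULL` for a pooled column.
#' @return Tibble with columns `subject_id` and `group`.
#' @export
analysis_population <- function(dm, treatment_var = NULL) {
  sid <- subject_id_var(dm)
  pop <- tibble::tibble(subject_id = dm[[sid]])
  if (!is.null(treatment_var)) {
    abort_if(!treatment_var %in% names(dm),
             sprintf("treatment variable '%s' absent from DM", treatment_var))
    pop$group <- dm[[treatment_var]]
  } else {
    pop$group <- "All"
  }
  dplyr::distinct(pop, .data$subject_id, .keep_all = TRUE)
}

as_population <- function(population) {
  if (is.character(population))
    population <- tibble::tibble(subject_id = population, group = "All")
  abort_if(nrow(population) == 0L, "population must be non-empty")
  abort_if(!all(c("subject_id", "group") %in% names(population)),
           "population needs columns subject_id and group")
  population
}

pop_denominators <- function(population) {
  dplyr::summarise(dplyr::group_by(population, .data$group),
                   denominator = dplyr::n_distinct(.data$subject_id),
                   .groups = "drop")
}

#' Summary table of a categorical variable
#'
#' Distinct-subject counts and percentages per group and level, the core of
#' demographic baseline tables. A `"Missing"` row appears when (and only
#' when) some population subject has a missing value.
#'
#' @param table A `domain_table` holding the variable (usually DM).
#' @param var Variable to summarize.
#' @param population Tibble `subject_id`/`group` from
#'   [analysis_population()], or a character vector of subject ids (pooled).
#' @param level_order `"given"` (order of `levels`), `"frequency"` or
#'   `"alphabetic"`.
#' @param levels Explicit level order when `level_order = "given"`.
#' @return A `summary_table` with row vars `variable`, `level` and per-cell
#'   `n_subjects`, `pct`, `subjects`.
#' @export
summarize_categorical <- function(table, var, population,
                                  level_order = c("alphabetic", "given", "frequency"),
                                  levels = NULL) {
  level_order <- match.arg(level_order)
  chk <- check_required_variables(table, var)
  abort_if(!chk$passed, sprintf("%s: missing required variable(s): %s",
                                domain_code(table), paste(chk$missing_required[[1]], collapse = ", ")))
  population <- as_population(population)
  sid <- subject_id_var(table)
  den <- pop_denominators(population)

  recs <- tibble::tibble(subject_id = table[[sid]], level = table[[var]])
  recs <- dplyr::distinct(dplyr::inner_join(population, recs, by = "subject_id"))
  # subjects in the population with no record at all count as missing too
  seen <- unique(recs$subject_id)
  unseen <- dplyr::filter(population, !.data$subject_id %in% seen)
  if (nrow(unseen)) recs <- dplyr::bind_rows(recs, dplyr::mutate(unseen, level = NA_character_))

  cells <- dplyr::summarise(
    dplyr::group_by(recs, .data$group, .data$level),
    n_subjects = dplyr::n_distinct(.data$subject_id),
    subjects = list(sort(unique(.data$subject_id))), .groups = "drop")

  lvl <- cells$level[!is.na(cells$level)]
  ord <- switch(level_order,
    given = { abort_if(is.null(levels), "level_order 'given' needs levels"); levels },
    frequency = {
      tot <- dplyr::count(dplyr::filter(cells, !is.na(.data$level)),
                          .data$level, wt = .data$n_subjects, sort = TRUE)
      tot$level
    },
    alphabetic = sort(unique(lvl)))
  has_missing <- anyNA(cells$level)

  grid <- tidyr::expand_grid(group = den$group,
                             level = c(ord, if (has_missing) NA_character_))
  out <- dplyr::left_join(grid, cells, by = c("group", "level"))
  out$n_subjects[is.na(out$n_subjects)] <- 0L
  out$subjects <- purrr::map(out$subjects, ~ .x %||% character())
  out <- dplyr::left_join(out, den, by = "group")
  out$pct <- 100 * out$n_subjects / out$denominator
  out$variable <- var
  out$level_label <- ifelse(is.na(out$level), "Missing", out$level)
  out <- dplyr::select(out, "variable", "level", "level_label", "group",
                       "n_subjects", "pct", "subjects")
  new_summary_table(out, "categorical", c("variable", "level_label"), den)
}

#' Summary table of a continuous variable
#'
#' Per-group n, mean, sample standard deviation (n - 1 denominator), median,
#' min and max. Values that do not coerce to numeric are excluded from the
#' statistics and counted in `n_missing`.
#'
#' @inheritParams summarize_categorical
#' @return A `summary_table` with row var `variable`.
#' @export
summarize_continuous <- function(table, var, population) {
  chk <- check_required_variables(table, var)
  abort_if(!chk$passed, sprintf("%s: missing required variable(s): %s",
                                domain_code(table), paste(chk$missing_required[[1]], collapse = ", ")))
  population <- as_population(population)
  sid <- subject_id_var(table)
  den <- pop_denominators(population)

  recs <- tibble::tibble(subject_id = table[[sid]], value = as_num(table[[var]]),
                         raw = table[[var]])
  recs <- dplyr::inner_join(population, recs, by = "subject_id")
  stat_or_na <- function(v, f, min_n = 1L) {
    v <- v[!is.na(v)]
    if (length(v) < min_n) NA_real_ else f(v)
  }
  out <- dplyr::summarise(
    dplyr::group_by(recs, .data$group),
    n = sum(!is.na(.data$value)),
    n_missing = sum(is.na(.data$value)),
    mean = stat_or_na(.data$value, mean),
    sd = stat_or_na(.data$value, stats::sd, min_n = 2L),
    median = stat_or_na(.data$value, stats::median),
    min = stat_or_na(.data$value, min),
    max = stat_or_na(.data$value, max),
    subjects = list(sort(unique(.data$subject_id[!is.na(.data$value)]))),
    .groups = "drop")
  out <- dplyr::right_join(out, dplyr::select(den, "group"), by = "group")
  out$n[is.na(out$n)] <- 0L
  out$n_missing[is.na(out$n_missing)] <- 0L
  out$subjects <- purrr::map(out$subjects, ~ .x %||% character())
  out$variable <- var
  out <- dplyr::select(out, "variable", "group", "n", "n_missing", "mean",
                       "sd", "median", "min", "max", "subjects")
  new_summary_table(out, "continuous", "variable", den)
}

#' Flag treatment-emergent adverse events
#'
#' An adverse event is treatment-emergent when its (imputed) onset lies
#' between the subject's first dose and last dose plus `lag_days`. Events
#' with a fully missing onset are included conservatively and flagged as
#' imputed; subjects absent from the exposure table get `FALSE` with a
#' warning.
#'
#' @param ae The AE `domain_table` with an onset date variable.
#' @param exposure The EX `domain_table` with dosing interval dates.
#' @param lag_days Days after last dose still counted as on-treatment
#'   (default 30).
#' @param start_var,ex_start_var,ex_end_var Date variable names.
#' @return `ae` with logical `teae` and `onset_imputed` columns appended.
#' @export
flag_treatment_emergent <- function(ae, exposure, lag_days = 30,
                                    start_var = "AESTDTC",
                                    ex_start_var = "EXSTDTC",
                                    ex_end_var = "EXENDTC") {
  sid <- subject_id_var(ae)
  exs <- tibble::tibble(subject_id = exposure[[subject_id_var(exposure)]],
                        st = exposure[[ex_start_var]],
                        en = exposure[[ex_end_var]])
  dosing <- dplyr::summarise(
    dplyr::group_by(exs, .data$subject_id),
    first_dose = suppressWarnings(min(as.Date(.data$st), na.rm = TRUE)),
    last_dose = suppressWarnings(max(as.Date(ifelse(is.na(.data$en), .data$st, .data$en)),
                                     na.rm = TRUE)),
    .groups = "drop")
  onset <- classify_partial_date(ae[[start_var]])
  res <- tibble::tibble(subject_id = ae[[sid]],
                        onset_date = as.Date(onset$imputed_date),
                        onset_missing = onset$status == "missing_all",
                        onset_imputed = onset$imputed | onset$status == "missing_all")
  res <- dplyr::left_join(res, dosing, by = "subject_id")
  unknown <- is.na(res$first_dose)
  if (any(unknown))
    warning(sprintf("%d AE record(s) for subject(s) without exposure: %s",
                    sum(unknown),
                    paste(unique(res$subject_id[unknown]), collapse = ", ")),
            call. = FALSE)
  teae <- !unknown & (res$onset_missing |
    (!is.na(res$onset_date) &
       res$onset_date >= res$first_dose &
       res$onset_date <= res$last_dose + lag_days))
  ae$teae <- teae
  ae$onset_imputed <- res$onset_imputed
  ae
}

#' Adverse-event incidence table at worst severity
#'
#' Rows are an "Any event" total, then System Organ Class, Preferred Term
#' and a severity breakdown under each term. In every row each subject is
#' counted once, at their worst severity within that row, so the severity
#' children of a term partition the term's subjects. Percentages use the
#' analysis-population denominator per group; `n_events` counts records.
#' Rows are ordered by descending total subject count, ties alphabetical.
#'
#' @param ae AE `domain_table`, already filtered (e.g. to treatment-emergent
#'   records).
#' @param population Population tibble from [analysis_population()].
#' @param severity_order Ordered severity levels, mildest first.
#' @param soc_var,pt_var,sev_var AE hierarchy and severity variable names.
#' @return A `summary_table` with row vars `soc`, `pt`, `severity`.
#' @export
summarize_ae <- function(ae, population,
                         severity_order = c("MILD", "MODERATE", "SEVERE"),
                         soc_var = "AEBODSYS", pt_var = "AEDECOD",
                         sev_var = "AESEV") {
  population <- as_population(population)
  den <- pop_denominators(population)
  empty_row <- function() {
    out <- dplyr::mutate(dplyr::select(den, "group"),
                         soc = "Any event", pt = NA_character_,
                         severity = NA_character_, n_subjects = 0L, pct = 0,
                         n_events = 0L, subjects = list(character()))
    dplyr::select(out, "soc", "pt", "severity", "group", "n_subjects",
                  "pct", "n_events", "subjects")
  }
  if (nrow(ae) == 0L)
    return(new_summary_table(empty_row(), "ae", c("soc", "pt", "severity"), den))

  sid <- subject_id_var(ae)
  recs <- tibble::tibble(subject_id = ae[[sid]], soc = ae[[soc_var]],
                         pt = ae[[pt_var]], severity = ae[[sev_var]])
  recs$sev_rank <- rank_severity(recs$severity, severity_order)
  recs <- dplyr::inner_join(population, recs, by = "subject_id")
  if (nrow(recs) == 0L)
    return(new_summary_table(empty_row(), "ae", c("soc", "pt", "severity"), den))

  sev_label <- function(rank) {
    ifelse(rank > length(severity_order), "Unknown", severity_order[pmin(rank, length(severity_order))])
  }
  cell <- function(d) {
    dplyr::summarise(dplyr::group_by(d, .data$group),
                     n_subjects = dplyr::n_distinct(.data$subject_id),
                     n_events = dplyr::n(),
                     subjects = list(sort(unique(.data$subject_id))),
                     .groups = "drop")
  }
  any_row <- dplyr::mutate(cell(recs), soc = "Any event", pt = NA_character_,
                           severity = NA_character_)
  soc_rows <- dplyr::mutate(
    dplyr::summarise(dplyr::group_by(recs, .data$soc, .data$group),
                     n_subjects = dplyr::n_distinct(.data$subject_id),
                     n_events = dplyr::n(),
                     subjects = list(sort(unique(.data$subject_id))),
                     .groups = "drop"),
    pt = NA_character_, severity = NA_character_)
  pt_rows <- dplyr::mutate(
    dplyr::summarise(dplyr::group_by(recs, .data$soc, .data$pt, .data$group),
                     n_subjects = dplyr::n_distinct(.data$subject_id),
                     n_events = dplyr::n(),
                     subjects = list(sort(unique(.data$subject_id))),
                     .groups = "drop"),
    severity = NA_character_)
  # worst severity per subject within each PT: subjects partition by worst rank
  worst <- dplyr::summarise(
    dplyr::group_by(recs, .data$soc, .data$pt, .data$group, .data$subject_id),
    worst_rank = max(.data$sev_rank), n_events_subj = dplyr::n(), .groups = "drop")
  ev_by_sev <- dplyr::summarise(
    dplyr::group_by(recs, .data$soc, .data$pt, .data$group, .data$sev_rank),
    n_events = dplyr::n(), .groups = "drop")
  sev_rows <- dplyr::summarise(
    dplyr::group_by(worst, .data$soc, .data$pt, .data$group, .data$worst_rank),
    n_subjects = dplyr::n_distinct(.data$subject_id),
    subjects = list(sort(unique(.data$subject_id))), .groups = "drop")
  sev_rows <- dplyr::left_join(
    sev_rows, ev_by_sev,
    by = c("soc", "pt", "group", worst_rank = "sev_rank"))
  sev_rows$n_events[is.na(sev_rows$n_events)] <- 0L
  sev_rows$severity <- sev_label(sev_rows$worst_rank)
  sev_rows$worst_rank <- NULL

  out <- dplyr::bind_rows(any_row, soc_rows, pt_rows, sev_rows)
  out <- dplyr::left_join(out, den, by = "group")
  out$pct <- 100 * out$n_subjects / out$denominator
  out$denominator <- NULL

  # row ordering: "Any event" first, then SOCs by descending total subjects,
  # PTs within SOC likewise, severity rows in severity order
  totals <- dplyr::summarise(dplyr::group_by(recs, .data$soc),
                             tot = dplyr::n_distinct(.data$subject_id), .groups = "drop")
  pt_totals <- dplyr::summarise(dplyr::group_by(recs, .data$soc, .data$pt),
                                tot = dplyr::n_distinct(.data$subject_id), .groups = "drop")
  out <- dplyr::left_join(out, stats::setNames(totals, c("soc", "soc_tot")), by = "soc")
  out <- dplyr::left_join(out, stats::setNames(pt_totals, c("soc", "pt", "pt_tot")),
                          by = c("soc", "pt"))
  out$sev_ord <- rank_severity(out$severity, severity_order)
  out <- dplyr::arrange(out,
                        .data$soc != "Any event",
                        dplyr::desc(dplyr::coalesce(.data$soc_tot, Inf)), .data$soc,
                        !is.na(.data$pt),
                        dplyr::desc(dplyr::coalesce(.data$pt_tot, Inf)), .data$pt,
                        !is.na(.data$severity), .data$sev_ord, .data$group)
  out <- dplyr::select(out, "soc", "pt", "severity", "group", "n_subjects",
                       "pct", "n_events", "subjects")
  new_summary_table(out, "ae", c("soc", "pt", "severity"), den)
}

#' Disposition summary and discontinuation listing
#'
#' Counts and percentages of completed versus discontinued subjects per
#' group, with a companion listing of each discontinuation's subject, reason
#' and study day; every listing row links to the subject's patient profile.
#'
#' @param ds DS `domain_table` with disposition status and reason variables.
#' @param population Population tibble from [analysis_population()].
#' @param status_var,reason_var,date_var DS variable names.
#' @param completed_values Status values counted as completed.
#' @param reference_dates Optional tibble `subject_id`/`reference_date` for
#'   study-day derivation in the listing.
#' @return A `summary_table` with row var `status`; the listing is in
#'   `attr(, "listing")`.
#' @export
summarize_disposition <- function(ds, population, status_var = "DSDECOD",
                                  reason_var = "DSTERM", date_var = "DSSTDTC",
                                  completed_values = "COMPLETED",
                                  reference_dates = NULL) {
  population <- as_population(population)
  den <- pop_denominators(population)
  sid <- subject_id_var(ds)
  recs <- tibble::tibble(subject_id = ds[[sid]], status = ds[[status_var]],
                         reason = ds[[reason_var]],
                         date = if (date_var %in% names(ds)) ds[[date_var]] else NA_character_)
  recs <- dplyr::inner_join(population, recs, by = "subject_id")
  recs$disposition <- ifelse(toupper(recs$status) %in% toupper(completed_values),
                             "Completed", "Discontinued")
  # one disposition per subject: discontinuation wins if both recorded
  per_subj <- dplyr::slice_max(
    dplyr::group_by(recs, .data$subject_id),
    order_by = .data$disposition == "Discontinued", n = 1, with_ties = FALSE)
  per_subj <- dplyr::ungroup(per_subj)
  # subjects with no DS record are ongoing; they appear in neither row
  grid <- tidyr::expand_grid(group = den$group,
                             disposition = c("Completed", "Discontinued"))
  cells <- dplyr::summarise(
    dplyr::group_by(per_subj, .data$group, .data$disposition),
    n_subjects = dplyr::n_distinct(.data$subject_id),
    subjects = list(sort(unique(.data$subject_id))), .groups = "drop")
  out <- dplyr::left_join(grid, cells, by = c("group", "disposition"))
  out$n_subjects[is.na(out$n_subjects)] <- 0L
  out$subjects <- purrr::map(out$subjects, ~ .x %||% character())
  out <- dplyr::left_join(out, den, by = "group")
  out$pct <- 100 * out$n_subjects / out$denominator
  out <- dplyr::select(out, status = "disposition", "group", "n_subjects",
                       "pct", "subjects")

  disc <- dplyr::filter(per_subj, .data$disposition == "Discontinued")
  listing <- tibble::tibble(subject_id = disc$subject_id, group = disc$group,
                            reason = disc$reason, date = disc$date,
                            study_day = NA_integer_)
  if (!is.null(reference_dates) && nrow(listing)) {
    listing <- dplyr::left_join(dplyr::select(listing, -"study_day"),
                                reference_dates, by = "subject_id")
    cls <- classify_partial_date(listing$date)
    listing$study_day <- derive_study_day(cls$imputed_date, listing$reference_date)
    listing$reference_date <- NULL
  }
  listing <- dplyr::arrange(listing, .data$subject_id)
  new_summary_table(out, "disposition", "status", den, listing = listing)
}

#' Attach a previous batch's statistics as a comparison column
#'
#' Re-runs the identical summary computation on the previous batch and joins
#' the result cell-for-cell as `prev_*` columns, the side-by-side view used
#' to answer "what changed since the last review". Rows absent in the
#' previous batch get empty previous cells; if the previous batch cannot
#' support the computation (e.g. the domain is absent) the previous column
#' is marked unavailable and the current table is returned intact.
#'
#' @param table A `summary_table` computed on the current batch.
#' @param previous The previous `study_batch`.
#' @param compute Function `study_batch -> summary_table` encoding the same
#'   computation that produced `table`.
#' @return `table` with `prev_*` statistic columns and attributes
#'   `previous_batch_id` and `previous_available`.
#' @export
attach_previous_batch <- function(table, previous, compute) {
  prev_tab <- tryCatch(compute(previous), error = function(e) e)
  if (inherits(prev_tab, "error")) {
    attr(table, "previous_batch_id") <- previous$batch_id
    attr(table, "previous_available") <- FALSE
    return(table)
  }
  row_vars <- attr(table, "row_vars")
  keys <- intersect(c(setdiff(names(table), c("subjects")), row_vars),
                    names(prev_tab))
  stat_cols <- intersect(c("n_subjects", "pct", "n_events", "n", "n_missing",
                           "mean", "sd", "median", "min", "max"), names(prev_tab))
  keys <- setdiff(keys, stat_cols)
  prev_sel <- dplyr::select(tibble::as_tibble(prev_tab),
                            dplyr::all_of(c(keys, stat_cols)))
  names(prev_sel)[names(prev_sel) %in% stat_cols] <-
    paste0("prev_", stat_cols)
  out <- dplyr::left_join(tibble::as_tibble(table), prev_sel, by = keys)
  out <- new_summary_table(out, attr(table, "table_type"), row_vars,
                           attr(table, "denominators"), attr(table, "listing"))
  attr(out, "previous_batch_id") <- previous$batch_id
  attr(out, "previous_available") <- TRUE
  out
}

#' @export
print.summary_table <- function(x, ...) {
  cat(sprintf("<summary_table (%s): %d cells, groups: %s>\n",
              attr(x, "table_type"), nrow(x),
              paste(attr(x, "denominators")$group, collapse = ", ")))
  NextMethod()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy summary_table
#' @export
tidy.summary_table <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$subjects <- NULL
  out
}

#' @method glance summary_table
#' @export
glance.summary_table <- function(x, ...) {
  den <- attr(x, "denominators")
  tibble::tibble(table_type = attr(x, "table_type"), n_cells = nrow(x),
                 n_groups = nrow(den), n_population = sum(den$denominator),
                 previous_batch = attr(x, "previous_batch_id") %||% NA_character_)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @method autoplot summary_table
#' @export
autoplot.summary_table <- function(object, ...) {
  type <- attr(object, "table_type")
  df <- tidy(object)
  if (type == "categorical") {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$level_label, y = .data$pct,
                                     fill = .data$group)) +
      ggplot2::geom_col(position = "dodge") +
      ggplot2::labs(x = df$variable[1], y = "% of subjects", fill = NULL) +
      ggplot2::theme_minimal()
  } else if (type == "ae") {
    top <- dplyr::filter(df, !is.na(.data$pt), is.na(.data$severity))
    ggplot2::ggplot(top, ggplot2::aes(x = stats::reorder(.data$pt, .data$pct),
                                      y = .data$pct, fill = .data$group)) +
      ggplot2::geom_col(position = "dodge") + ggplot2::coord_flip() +
      ggplot2::labs(x = NULL, y = "% of subjects with event", fill = NULL) +
      ggplot2::theme_minimal()
  } else {
    xvar <- attr(object, "row_vars")[1]
    yvar <- if ("n_subjects" %in% names(df)) "n_subjects" else "n"
    ggplot2::ggplot(df, ggplot2::aes(x = .data[[xvar]], y = .data[[yvar]],
                                     fill = .data$group)) +
      ggplot2::geom_col(position = "dodge") +
      ggplot2::labs(x = NULL, y = "subjects", fill = NULL) +
      ggplot2::theme_minimal()
  }
}
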
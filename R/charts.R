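# Data products behind the interactive figures. Every payload carries the
# flat backing table the coupled interactive table displays, and per-point
# subject link annotations; the series must be reconstructible from the
# backing table alone.

new_chart_payload <- function(kind, series, backing_table, links, params = list()) {
  structure(list(kind = kind, series = tibble::as_tibble(series),
                 backing_table = tibble::as_tibble(backing_table),
                 links = links, params = params),
            class = "chart_payload")
}

#' @export
print.chart_payload <- function(x, ...) {
  cat(sprintf("<chart_payload %s: %d series rows, %d backing records>\n",
              x$kind, nrow(x$series), nrow(x$backing_table)))
  invisible(x)
}

#' @method tidy chart_payload
#' @export
tidy.chart_payload <- function(x, ...) x$series

#' @method glance chart_payload
#' @export
glance.chart_payload <- function(x, ...) {
  tibble::tibble(kind = x$kind, n_series = nrow(x$series),
                 n_backing = nrow(x$backing_table),
                 n_subjects = length(unique(x$backing_table$subject_id %||%
                                              character())))
}

chart_links <- function(subject_ids, link_index = NULL) {
  ids <- sort(unique(subject_ids))
  tibble::tibble(subject_id = ids,
                 profile = if (is.null(link_index)) NA_character_
                 else unname(link_index[ids]))
}

#' Subjects attending each visit, by arm
#'
#' The study snapshot bar chart: distinct subjects with a visit record, per
#' visit and treatment arm, visits in protocol order. Shows how much data
#' exist at later visits relative to the number randomized.
#'
#' @param sv SV `domain_table` with visit label and visit order variables.
#' @param population Population tibble from [analysis_population()].
#' @param visit_var,visitnum_var Visit label and numeric order variables.
#' @param link_index Optional subject-to-profile-path map.
#' @return A `chart_payload` of kind `visit_bar`; series columns `visit`,
#'   `visitnum`, `group`, `n_subjects`.
#' @export
visit_attendance <- function(sv, population, visit_var = "VISIT",
                             visitnum_var = "VISITNUM", link_index = NULL) {
  population <- as_population(population)
  sid <- subject_id_var(sv)
  recs <- tibble::tibble(subject_id = sv[[sid]], visit = sv[[visit_var]],
                         visitnum = as_num(sv[[visitnum_var]]))
  recs <- dplyr::inner_join(population, recs, by = "subject_id")
  series <- dplyr::summarise(
    dplyr::group_by(recs, .data$visit, .data$visitnum, .data$group),
    n_subjects = dplyr::n_distinct(.data$subject_id), .groups = "drop")
  series <- dplyr::arrange(series, .data$visitnum, .data$group)
  backing <- dplyr::distinct(dplyr::arrange(recs, .data$visitnum, .data$group,
                                            .data$subject_id))
  new_chart_payload("visit_bar", series, backing,
                    chart_links(recs$subject_id, link_index))
}

#' Adverse-event hierarchy for treemap and sunburst charts
#'
#' One node per Preferred Term and one aggregate node per System Organ
#' Class. A SOC node's subject count is the size of the union of its terms'
#' subject sets (a subject with two different terms in one SOC counts once);
#' event counts are conserved (PT events sum to the SOC, SOCs to the total).
#' Node shading is driven by the worst severity rank among the node's
#' events.
#'
#' @param ae AE `domain_table`, filtered as configured.
#' @param population Population tibble (defines denominators for `pct`).
#' @param severity_order Ordered severity levels.
#' @param soc_var,pt_var,sev_var AE variable names.
#' @param link_index Optional subject-to-profile-path map.
#' @return A `chart_payload` of kind `treemap` whose series is the node
#'   table: `level` (SOC/PT), `label`, `parent`, `n_subjects`, `pct`,
#'   `n_events`, `worst_severity_rank`.
#' @export
ae_hierarchy <- function(ae, population,
                         severity_order = c("MILD", "MODERATE", "SEVERE"),
                         soc_var = "AEBODSYS", pt_var = "AEDECOD",
                         sev_var = "AESEV", link_index = NULL) {
  population <- as_population(population)
  den <- sum(pop_denominators(population)$denominator)
  sid <- subject_id_var(ae)
  if (nrow(ae) == 0L) {
    empty <- tibble::tibble(level = character(), label = character(),
                            parent = character(), n_subjects = integer(),
                            pct = numeric(), n_events = integer(),
                            worst_severity_rank = integer())
    return(new_chart_payload("treemap", empty, empty, chart_links(character(), link_index)))
  }
  recs <- tibble::tibble(subject_id = ae[[sid]], soc = ae[[soc_var]],
                         pt = ae[[pt_var]], severity = ae[[sev_var]])
  recs <- dplyr::inner_join(population, recs, by = "subject_id")
  recs$sev_rank <- rank_severity(recs$severity, severity_order)
  pt_nodes <- dplyr::summarise(
    dplyr::group_by(recs, .data$soc, .data$pt),
    n_subjects = dplyr::n_distinct(.data$subject_id),
    n_events = dplyr::n(),
    worst_severity_rank = max(.data$sev_rank),
    subjects = list(sort(unique(.data$subject_id))), .groups = "drop")
  soc_nodes <- dplyr::summarise(
    dplyr::group_by(recs, .data$soc),
    n_subjects = dplyr::n_distinct(.data$subject_id),
    n_events = dplyr::n(),
    worst_severity_rank = max(.data$sev_rank),
    subjects = list(sort(unique(.data$subject_id))), .groups = "drop")
  nodes <- dplyr::bind_rows(
    dplyr::mutate(soc_nodes, level = "SOC", label = .data$soc,
                  parent = NA_character_),
    dplyr::mutate(pt_nodes, level = "PT", label = .data$pt,
                  parent = .data$soc))
  nodes$pct <- 100 * nodes$n_subjects / den
  nodes <- dplyr::arrange(nodes, .data$level != "SOC",
                          dplyr::desc(.data$n_subjects), .data$label)
  series <- dplyr::select(nodes, "level", "label", "parent", "n_subjects",
                          "pct", "n_events", "worst_severity_rank", "subjects")
  new_chart_payload("treemap", series, recs,
                    chart_links(recs$subject_id, link_index))
}

#' eDish hepatotoxicity scatter data
#'
#' Per subject, the peak post-baseline alanine aminotransferase and total
#' bilirubin expressed as multiples of their upper limits of normal
#' (independent per-parameter maxima). Reference lines at 3 x ULN (ALT) and
#' 2 x ULN (bilirubin) define the quadrants; the high/high quadrant is the
#' Hy's-law region. The backing table carries all visit-level points so a
#' selected subject's whole trajectory can be highlighted.
#'
#' @param lb LB `domain_table` with test code, result, and study-day (or
#'   date) variables.
#' @param population Population tibble.
#' @param alt_code,bili_code Test codes for ALT and total bilirubin.
#' @param uln Named numeric vector of upper limits of normal per test code,
#'   used when the record-level `hi_var` is missing.
#' @param test_var,result_var,day_var,hi_var LB variable names.
#' @param baseline_day Records with study day greater than this count as
#'   post-baseline (default 1).
#' @param alt_threshold,bili_threshold Quadrant reference lines in ULN
#'   multiples (defaults 3 and 2).
#' @param link_index Optional subject-to-profile-path map.
#' @return A `chart_payload` of kind `edish`; series columns `subject_id`,
#'   `group`, `alt_uln`, `bili_uln`, `quadrant`.
#' @export
edish <- function(lb, population, alt_code = "ALT", bili_code = "BILI",
                  uln = NULL, test_var = "LBTESTCD", result_var = "LBORRES",
                  day_var = "LBDY", hi_var = "LBORNRHI", baseline_day = 1,
                  alt_threshold = 3, bili_threshold = 2, link_index = NULL) {
  population <- as_population(population)
  sid <- subject_id_var(lb)
  recs <- tibble::tibble(
    subject_id = lb[[sid]], test = lb[[test_var]],
    value = as_num(lb[[result_var]]),
    day = as_num(lb[[day_var]]),
    hi = if (hi_var %in% names(lb)) as_num(lb[[hi_var]]) else NA_real_)
  recs$hi <- ifelse(is.na(recs$hi) & recs$test %in% names(uln),
                    uln[recs$test], recs$hi)
  recs <- dplyr::inner_join(population, recs, by = "subject_id")
  recs <- dplyr::filter(recs, .data$test %in% c(alt_code, bili_code),
                        !is.na(.data$value), !is.na(.data$hi), .data$hi > 0,
                        !is.na(.data$day), .data$day > baseline_day)
  recs$uln_mult <- recs$value / recs$hi
  peaks <- dplyr::summarise(
    dplyr::group_by(recs, .data$subject_id, .data$group, .data$test),
    peak = max(.data$uln_mult), .groups = "drop")
  wide <- tidyr::pivot_wider(peaks, names_from = "test", values_from = "peak")
  have_alt <- alt_code %in% names(wide); have_bili <- bili_code %in% names(wide)
  wide$alt_uln <- if (have_alt) wide[[alt_code]] else NA_real_
  wide$bili_uln <- if (have_bili) wide[[bili_code]] else NA_real_
  dropped <- dplyr::filter(wide, is.na(.data$alt_uln) & is.na(.data$bili_uln))
  if (nrow(dropped))
    warning(sprintf("eDish: %d subject(s) lack both parameters and were excluded",
                    nrow(dropped)), call. = FALSE)
  series <- dplyr::filter(wide, !(is.na(.data$alt_uln) & is.na(.data$bili_uln)))
  series$quadrant <- dplyr::case_when(
    series$alt_uln >= alt_threshold & series$bili_uln >= bili_threshold ~ "hys_law",
    series$alt_uln >= alt_threshold ~ "temple_corollary",
    series$bili_uln >= bili_threshold ~ "hyperbilirubinemia",
    TRUE ~ "normal")
  series <- dplyr::select(series, "subject_id", "group", "alt_uln",
                          "bili_uln", "quadrant")
  series <- dplyr::arrange(series, .data$subject_id)
  new_chart_payload("edish", series, recs,
                    chart_links(series$subject_id, link_index),
                    params = list(alt_threshold = alt_threshold,
                                  bili_threshold = bili_threshold,
                                  log_axes = TRUE))
}

#' Spaghetti-plot data for a laboratory parameter
#'
#' One (study day, value) polyline per subject, with optional per-arm
#' per-visit mean and standard-deviation aggregate lines and abnormality
#' threshold lines. A subset rule such as "subjects with at least one
#' abnormal value" filters subjects before emission.
#'
#' @param lb LB `domain_table`.
#' @param parameter Test code of the parameter.
#' @param population Population tibble.
#' @param test_var,result_var,day_var,visit_var,lo_var,hi_var LB variables.
#' @param thresholds Optional numeric vector of horizontal reference lines.
#' @param subset_rule `"all"` or `"abnormal"` (keep only subjects with at
#'   least one value outside the reference range).
#' @param aggregate Emit per-arm per-visit mean and sd lines.
#' @param link_index Optional subject-to-profile-path map.
#' @return A `chart_payload` of kind `spaghetti`; series columns
#'   `subject_id`, `group`, `day`, `value`, `abnormal`; aggregate lines (if
#'   requested) in `$params$aggregate`.
#' @export
spaghetti_data <- function(lb, parameter, population, test_var = "LBTESTCD",
                           result_var = "LBORRES", day_var = "LBDY",
                           visit_var = "VISIT", lo_var = "LBORNRLO",
                           hi_var = "LBORNRHI", thresholds = NULL,
                           subset_rule = c("all", "abnormal"),
                           aggregate = TRUE, link_index = NULL) {
  subset_rule <- match.arg(subset_rule)
  population <- as_population(population)
  sid <- subject_id_var(lb)
  recs <- tibble::tibble(
    subject_id = lb[[sid]], test = lb[[test_var]],
    value = as_num(lb[[result_var]]), day = as_num(lb[[day_var]]),
    visit = if (visit_var %in% names(lb)) lb[[visit_var]] else NA_character_,
    lo = if (lo_var %in% names(lb)) as_num(lb[[lo_var]]) else NA_real_,
    hi = if (hi_var %in% names(lb)) as_num(lb[[hi_var]]) else NA_real_)
  recs <- dplyr::inner_join(population, recs, by = "subject_id")
  recs <- dplyr::filter(recs, .data$test == parameter, !is.na(.data$value),
                        !is.na(.data$day))
  recs$abnormal <- (!is.na(recs$lo) & recs$value < recs$lo) |
    (!is.na(recs$hi) & recs$value > recs$hi)
  if (subset_rule == "abnormal") {
    keep <- unique(recs$subject_id[recs$abnormal])
    recs <- dplyr::filter(recs, .data$subject_id %in% keep)
  }
  series <- dplyr::arrange(
    dplyr::select(recs, "subject_id", "group", "day", "value", "abnormal"),
    .data$subject_id, .data$day)
  agg <- NULL
  if (aggregate && nrow(recs)) {
    agg <- dplyr::summarise(
      dplyr::group_by(recs, .data$group, .data$visit, .data$day),
      n = sum(!is.na(.data$value)), mean = mean(.data$value),
      sd = ifelse(sum(!is.na(.data$value)) > 1, stats::sd(.data$value), NA_real_),
      .groups = "drop")
    agg <- dplyr::arrange(agg, .data$group, .data$day)
  }
  new_chart_payload("spaghetti", series, recs,
                    chart_links(series$subject_id, link_index),
                    params = list(parameter = parameter,
                                  thresholds = thresholds, aggregate = agg))
}

#' Shift-table data: baseline versus worst post-baseline category
#'
#' Classifies each value low/normal/high against its reference range,
#' takes the last non-missing value on or before day 1 as baseline and the
#' worst post-baseline classification (high beats low beats normal), and
#' cross-tabulates per arm. Subjects with no baseline record land in a
#' `"no baseline"` margin.
#'
#' @inheritParams spaghetti_data
#' @param baseline_day Baseline is the last record with day <= this value.
#' @return A `chart_payload` of kind `shift`; series is the per-arm
#'   cross-tab (`group`, `baseline`, `post`, `n_subjects`); the per-subject
#'   classification is the backing table.
#' @export
shift_data <- function(lb, parameter, population, test_var = "LBTESTCD",
                       result_var = "LBORRES", day_var = "LBDY",
                       lo_var = "LBORNRLO", hi_var = "LBORNRHI",
                       baseline_day = 1, link_index = NULL) {
  population <- as_population(population)
  sid <- subject_id_var(lb)
  recs <- tibble::tibble(
    subject_id = lb[[sid]], test = lb[[test_var]],
    value = as_num(lb[[result_var]]), day = as_num(lb[[day_var]]),
    lo = if (lo_var %in% names(lb)) as_num(lb[[lo_var]]) else NA_real_,
    hi = if (hi_var %in% names(lb)) as_num(lb[[hi_var]]) else NA_real_)
  recs <- dplyr::inner_join(population, recs, by = "subject_id")
  recs <- dplyr::filter(recs, .data$test == parameter, !is.na(.data$value),
                        !is.na(.data$day))
  classify <- function(value, lo, hi) {
    dplyr::case_when(!is.na(hi) & value > hi ~ "high",
                     !is.na(lo) & value < lo ~ "low",
                     TRUE ~ "normal")
  }
  recs$category <- classify(recs$value, recs$lo, recs$hi)
  sev <- c(normal = 0L, low = 1L, high = 2L)
  baseline_cat <- function(day, category) {
    b <- day <= baseline_day
    if (!any(b)) "no baseline" else category[b][which.max(day[b])]
  }
  worst_post_cat <- function(day, category) {
    p <- day > baseline_day
    if (!any(p)) "no post-baseline"
    else names(sev)[match(max(sev[category[p]]), sev)]
  }
  per_subj <- dplyr::summarise(
    dplyr::group_by(recs, .data$subject_id, .data$group),
    baseline = baseline_cat(.data$day, .data$category),
    post = worst_post_cat(.data$day, .data$category),
    .groups = "drop")
  series <- dplyr::count(per_subj, .data$group, .data$baseline, .data$post,
                         name = "n_subjects")
  new_chart_payload("shift", series, per_subj,
                    chart_links(per_subj$subject_id, link_index),
                    params = list(parameter = parameter))
}

#' Recompute a chart's series from its backing table
#'
#' The coupled-table contract: every chart series must be reconstructible
#' from the flat backing table its interactive table displays. Used by the
#' test-suite and available for report self-checks.
#'
#' @param payload A `chart_payload`.
#' @return The series recomputed from `payload$backing_table`.
#' @export
series_from_backing <- function(payload) {
  bt <- payload$backing_table
  switch(payload$kind,
    visit_bar = dplyr::arrange(dplyr::summarise(
      dplyr::group_by(bt, .data$visit, .data$visitnum, .data$group),
      n_subjects = dplyr::n_distinct(.data$subject_id), .groups = "drop"),
      .data$visitnum, .data$group),
    treemap = {
      pt_nodes <- dplyr::summarise(
        dplyr::group_by(bt, .data$soc, .data$pt),
        n_subjects = dplyr::n_distinct(.data$subject_id),
        n_events = dplyr::n(), worst_severity_rank = max(.data$sev_rank),
        subjects = list(sort(unique(.data$subject_id))), .groups = "drop")
      soc_nodes <- dplyr::summarise(
        dplyr::group_by(bt, .data$soc),
        n_subjects = dplyr::n_distinct(.data$subject_id),
        n_events = dplyr::n(), worst_severity_rank = max(.data$sev_rank),
        subjects = list(sort(unique(.data$subject_id))), .groups = "drop")
      nodes <- dplyr::bind_rows(
        dplyr::mutate(soc_nodes, level = "SOC", label = .data$soc,
                      parent = NA_character_),
        dplyr::mutate(pt_nodes, level = "PT", label = .data$pt,
                      parent = .data$soc))
      nodes
    },
    edish = {
      peaks <- dplyr::summarise(
        dplyr::group_by(bt, .data$subject_id, .data$group, .data$test),
        peak = max(.data$uln_mult), .groups = "drop")
      tidyr::pivot_wider(peaks, names_from = "test", values_from = "peak")
    },
    spaghetti = dplyr::arrange(
      dplyr::select(bt, "subject_id", "group", "day", "value", "abnormal"),
      .data$subject_id, .data$day),
    shift = dplyr::count(bt, .data$group, .data$baseline, .data$post,
                         name = "n_subjects"),
    stop(sprintf("unknown chart kind '%s'", payload$kind), call. = FALSE))
}

#' @method autoplot chart_payload
#' @export
autoplot.chart_payload <- function(object, ...) {
  s <- object$series
  switch(object$kind,
    visit_bar = ggplot2::ggplot(s, ggplot2::aes(
      x = stats::reorder(.data$visit, .data$visitnum), y = .data$n_subjects,
      fill = .data$group)) +
      ggplot2::geom_col(position = "dodge") +
      ggplot2::labs(x = NULL, y = "subjects attending", fill = NULL) +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1)),
    edish = {
      p <- ggplot2::ggplot(s, ggplot2::aes(x = .data$alt_uln, y = .data$bili_uln,
                                           colour = .data$quadrant)) +
        ggplot2::geom_point() +
        ggplot2::geom_vline(xintercept = object$params$alt_threshold,
                            linetype = "dashed") +
        ggplot2::geom_hline(yintercept = object$params$bili_threshold,
                            linetype = "dashed") +
        ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
        ggplot2::labs(x = "peak ALT (x ULN)", y = "peak bilirubin (x ULN)") +
        ggplot2::theme_minimal()
      p
    },
    spaghetti = ggplot2::ggplot(s, ggplot2::aes(x = .data$day, y = .data$value,
                                                group = .data$subject_id,
                                                colour = .data$group)) +
      ggplot2::geom_line(alpha = 0.6) + ggplot2::geom_point(size = 0.8) +
      ggplot2::labs(x = "study day", y = object$params$parameter, colour = NULL) +
      ggplot2::theme_minimal(),
    shift = ggplot2::ggplot(s, ggplot2::aes(x = .data$baseline, y = .data$post,
                                            size = .data$n_subjects,
                                            colour = .data$group)) +
      ggplot2::geom_point() +
      ggplot2::labs(x = "baseline", y = "worst post-baseline") +
      ggplot2::theme_minimal(),
    treemap = ggplot2::ggplot(
      dplyr::filter(s, .data$level == "PT"),
      ggplot2::aes(x = stats::reorder(.data$label, .data$n_subjects),
                   y = .data$n_subjects, fill = .data$parent)) +
      ggplot2::geom_col() + ggplot2::coord_flip() +
      ggplot2::labs(x = NULL, y = "subjects", fill = "SOC") +
      ggplot2::theme_minimal(),
    stop("no autoplot for this chart kind", call. = FALSE))
}
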
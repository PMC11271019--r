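# Per-subject patient profiles: ordered stacks of text / event / interval /
# line modules on a shared study-day axis, paginated greedily and rendered
# as deterministic paginated SVG documents (vector, self-contained,
# byte-reproducible), one file per subject plus a JSON link index.

#' Build one profile module for a subject
#'
#' Module kinds: `text` (label-value pairs, e.g. demography), `event`
#' (point-in-time markers such as disposition milestones), `interval`
#' (bars with start/end days, e.g. adverse events or dosing; a missing end
#' renders open-ended) and `line` (parameter course with reference band).
#' Study days come from [derive_study_day()] via earliest-imputed partial
#' dates, and imputed days carry a flag that renders as a distinct glyph.
#'
#' @param config List naming `kind`, `domain`, `title`, and the variable
#'   mapping: `vars` (text), `label_var`/`date_var` (event),
#'   `label_var`/`start_var`/`end_var` (interval),
#'   `test_var`/`value_var`/`date_var`/`lo_var`/`hi_var` and `parameter`
#'   (line).
#' @param batch A `study_batch` containing the domain and DM (for the
#'   reference start date).
#' @param subject_id Subject to extract.
#' @return A `profile_module`: list with `kind`, `title`, `domain_code`,
#'   `data` (tibble), `empty`, and `height_units`.
#' @export
build_module <- function(config, batch, subject_id) {
  kind <- config$kind
  abort_if(!kind %in% c("text", "event", "interval", "line"),
           sprintf("unknown module kind '%s'", kind))
  dom <- config$domain
  abort_if(!dom %in% names(batch$domains),
           sprintf("%s: domain absent from batch", dom))
  tab <- batch$domains[[dom]]
  sid <- subject_id_var(tab)
  need <- switch(kind,
    text = unlist(config$vars),
    event = c(config$label_var, config$date_var),
    interval = c(config$label_var, config$start_var, config$end_var),
    line = c(config$test_var, config$value_var, config$date_var))
  for (v in need)
    abort_if(!v %in% names(tab),
             sprintf("%s: variable '%s' absent", dom, v))
  rows <- tab[tab[[sid]] == subject_id, , drop = FALSE]
  ref <- ref_dates(batch)
  refdate <- ref$reference_date[match(subject_id, ref$subject_id)]
  day_of <- function(txt) {
    cls <- classify_partial_date(txt)
    list(day = derive_study_day(cls$imputed_date, rep(refdate, length(txt))),
         imputed = cls$imputed | cls$status == "missing_all")
  }
  data <- switch(kind,
    text = {
      vars <- config$vars
      labs <- if (!is.null(names(vars)) && any(names(vars) != ""))
        names(vars) else unlist(vars)
      vals <- if (nrow(rows)) vapply(unlist(vars), function(v)
        rows[[v]][1] %||% NA_character_, character(1)) else
        rep(NA_character_, length(vars))
      tibble::tibble(label = labs, value = unname(vals))
    },
    event = {
      d <- day_of(rows[[config$date_var]])
      tibble::tibble(label = rows[[config$label_var]], study_day = d$day,
                     imputed = d$imputed)
    },
    interval = {
      s <- day_of(rows[[config$start_var]])
      e <- day_of(rows[[config$end_var]])
      tibble::tibble(label = rows[[config$label_var]],
                     start_day = s$day, end_day = e$day,
                     start_imputed = s$imputed,
                     end_missing = is.na(e$day))
    },
    line = {
      sel <- rows[!is.na(rows[[config$test_var]]) &
                    rows[[config$test_var]] == config$parameter, , drop = FALSE]
      d <- day_of(sel[[config$date_var]])
      tibble::tibble(
        parameter = config$parameter,
        study_day = d$day, imputed = d$imputed,
        value = as_num(sel[[config$value_var]]),
        reference_low = if (!is.null(config$lo_var) && config$lo_var %in% names(sel))
          as_num(sel[[config$lo_var]]) else NA_real_,
        reference_high = if (!is.null(config$hi_var) && config$hi_var %in% names(sel))
          as_num(sel[[config$hi_var]]) else NA_real_)
    })
  if (kind == "interval" && nrow(data)) {
    bad <- !is.na(data$start_day) & !data$end_missing &
      data$end_day < data$start_day
    data$end_day[bad] <- data$start_day[bad]
  }
  empty <- if (kind == "text") all(is.na(data$value)) else nrow(data) == 0L
  height <- switch(kind,
    text = 1 + 0.35 * nrow(data),
    event = 1 + 0.3 * max(nrow(data), 1L),
    interval = 1 + 0.3 * max(nrow(data), 1L),
    line = 3)
  structure(list(kind = kind, title = config$title %||% dom,
                 domain_code = dom, data = data, empty = empty,
                 height_units = height),
            class = "profile_module")
}

ref_dates <- function(batch) {
  dm <- batch$domains$DM
  abort_if(is.null(dm), "batch has no DM domain for reference dates")
  tibble::tibble(subject_id = dm[[subject_id_var(dm)]],
                 reference_date = if ("RFSTDTC" %in% names(dm))
                   dm$RFSTDTC else NA_character_)
}

module_days <- function(m) {
  d <- switch(m$kind,
    text = numeric(),
    event = m$data$study_day,
    interval = c(m$data$start_day, m$data$end_day),
    line = m$data$study_day)
  d[!is.na(d)]
}

#' Compose a paginated patient profile
#'
#' Stacks modules in the configured order on a shared study-day axis and
#' paginates greedily: a module that would exceed the remaining page height
#' moves whole to the next page (modules are never split).
#'
#' @param modules List of `profile_module`s (at least one).
#' @param subject_id Subject identifier.
#' @param page_height_units Page capacity in module height units
#'   (default 10).
#' @return A `patient_profile`: list with `subject_id`, `modules`,
#'   `time_range`, `pages` (list of module index vectors) and `file_name`
#'   (deterministic stem).
#' @export
compose_profile <- function(modules, subject_id, page_height_units = 10) {
  abort_if(length(modules) == 0L, "need at least one module")
  days <- unlist(lapply(modules, module_days))
  time_range <- if (length(days)) range(days) else c(1, 1)
  pages <- list(); cur <- integer(); remaining <- page_height_units
  for (i in seq_along(modules)) {
    h <- min(modules[[i]]$height_units, page_height_units)
    if (h > remaining && length(cur)) {
      pages[[length(pages) + 1L]] <- cur
      cur <- integer(); remaining <- page_height_units
    }
    cur <- c(cur, i); remaining <- remaining - h
  }
  if (length(cur)) pages[[length(pages) + 1L]] <- cur
  structure(list(subject_id = subject_id, modules = modules,
                 time_range = time_range, pages = pages,
                 file_name = sanitize_stem(subject_id)),
            class = "patient_profile")
}

#' @export
print.patient_profile <- function(x, ...) {
  cat(sprintf("<patient_profile %s: %d modules over %d page(s), days %g..%g>\n",
              x$subject_id, length(x$modules), length(x$pages),
              x$time_range[1], x$time_range[2]))
  invisible(x)
}

# -- SVG rendering ----------------------------------------------------------

svg_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  ifelse(is.na(x), "", x)
}

fmt_num <- function(x) formatC(x, format = "g", digits = 6)

profile_svg <- function(profile, width = 800, unit_px = 40,
                        page_height_units = 10) {
  tr <- profile$time_range
  span <- max(tr[2] - tr[1], 1)
  x_of <- function(day) 140 + (day - tr[1]) / span * (width - 180)
  page_px <- page_height_units * unit_px + 60
  n_pages <- length(profile$pages)
  out <- c(sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" width="%d" ',
                          'height="%d" font-family="monospace" font-size="11">'),
                   width, page_px * n_pages))
  for (p in seq_len(n_pages)) {
    y0 <- (p - 1) * page_px
    out <- c(out, sprintf('<g class="page" data-page="%d">', p),
             sprintf('<text x="10" y="%g" font-size="13">Patient profile: %s (page %d of %d)</text>',
                     y0 + 20, svg_escape(profile$subject_id), p, n_pages))
    y <- y0 + 40
    for (mi in profile$pages[[p]]) {
      m <- profile$modules[[mi]]
      mh <- min(m$height_units, page_height_units) * unit_px
      out <- c(out, sprintf('<text x="10" y="%g" font-weight="bold">%s</text>',
                            y + 12, svg_escape(m$title)))
      if (m$empty) {
        out <- c(out, sprintf('<text x="140" y="%g" fill="grey">no data</text>', y + 12))
      } else if (m$kind == "text") {
        yy <- y + 14
        for (i in seq_len(nrow(m$data))) {
          out <- c(out, sprintf('<text x="140" y="%g">%s: %s</text>', yy,
                                svg_escape(m$data$label[i]),
                                svg_escape(m$data$value[i])))
          yy <- yy + 14
        }
      } else if (m$kind == "event") {
        yy <- y + 14
        for (i in seq_len(nrow(m$data))) {
          if (!is.na(m$data$study_day[i])) {
            glyph <- if (m$data$imputed[i]) "imputed-event" else "event"
            out <- c(out, sprintf(
              '<circle cx="%g" cy="%g" r="4" class="%s" fill="%s"/>',
              x_of(m$data$study_day[i]), yy, glyph,
              if (m$data$imputed[i]) "orange" else "black"))
          }
          out <- c(out, sprintf('<text x="10" y="%g" font-size="9">%s (day %s)</text>',
                                yy + 3, svg_escape(m$data$label[i]),
                                ifelse(is.na(m$data$study_day[i]), "?",
                                       fmt_num(m$data$study_day[i]))))
          yy <- yy + 12
        }
      } else if (m$kind == "interval") {
        yy <- y + 14
        for (i in seq_len(nrow(m$data))) {
          s <- m$data$start_day[i]
          e <- if (m$data$end_missing[i]) tr[2] else m$data$end_day[i]
          if (!is.na(s)) {
            out <- c(out, sprintf(
              '<rect x="%g" y="%g" width="%g" height="6" fill="%s"/>',
              x_of(s), yy - 4, max(x_of(e) - x_of(s), 2),
              if (m$data$start_imputed[i]) "orange" else "steelblue"))
            if (m$data$end_missing[i])
              out <- c(out, sprintf(
                '<text x="%g" y="%g" class="ongoing" font-size="9">&#8594;</text>',
                x_of(e) + 2, yy + 2))
          }
          out <- c(out, sprintf('<text x="10" y="%g" font-size="9">%s</text>',
                                yy + 2, svg_escape(m$data$label[i])))
          yy <- yy + 12
        }
      } else if (m$kind == "line") {
        d <- m$data[!is.na(m$data$study_day) & !is.na(m$data$value), , drop = FALSE]
        d <- d[order(d$study_day), , drop = FALSE]
        if (nrow(d)) {
          vr <- range(c(d$value, d$reference_low, d$reference_high), na.rm = TRUE)
          if (vr[1] == vr[2]) vr <- vr + c(-1, 1)
          y_of <- function(v) y + mh - 20 - (v - vr[1]) / (vr[2] - vr[1]) * (mh - 40)
          lo <- d$reference_low[1]; hi <- d$reference_high[1]
          if (!is.na(lo) && !is.na(hi))
            out <- c(out, sprintf(
              '<rect x="140" y="%g" width="%g" height="%g" fill="lightgreen" opacity="0.3"/>',
              y_of(hi), width - 180, abs(y_of(lo) - y_of(hi))))
          pts <- paste(sprintf("%g,%g", x_of(d$study_day), y_of(d$value)),
                       collapse = " ")
          out <- c(out, sprintf(
            '<polyline points="%s" fill="none" stroke="black"/>', pts))
          for (i in seq_len(nrow(d)))
            out <- c(out, sprintf(
              '<circle cx="%g" cy="%g" r="3" fill="%s"/>',
              x_of(d$study_day[i]), y_of(d$value[i]),
              if (d$imputed[i]) "orange" else "black"))
        }
      }
      y <- y + mh
    }
    # shared study-day axis at the bottom of each page
    axis_y <- y0 + page_px - 18
    out <- c(out, sprintf('<line x1="140" y1="%g" x2="%g" y2="%g" stroke="black"/>',
                          axis_y, width - 40, axis_y))
    for (t in pretty(tr, n = 5)) {
      if (t >= tr[1] && t <= tr[2])
        out <- c(out, sprintf('<text x="%g" y="%g" font-size="9">%s</text>',
                              x_of(t), axis_y + 12, fmt_num(t)))
    }
    out <- c(out, sprintf('<text x="10" y="%g" font-size="9">study day</text>',
                          axis_y + 12), '</g>')
  }
  c(out, '</svg>')
}

#' Render patient profiles for a batch
#'
#' One self-contained SVG document per subject (deterministic bytes for a
#' given batch and configuration), plus a JSON link index mapping subject id
#' to relative profile path; the index is what summary tables and chart
#' payloads use to annotate subject links. Rendering is independent per
#' subject and parallelizable.
#'
#' @param batch A `study_batch` (DM required).
#' @param config List with `modules`: list of module configs for
#'   [build_module()], and optional `page_height_units`.
#' @param out_dir Output directory (created if needed); profiles go to
#'   `out_dir/profiles/`.
#' @param subjects `"all"` or a character vector of subject ids (ids absent
#'   from DM are skipped with a warning).
#' @param jobs Number of parallel workers (forked; serial when 1).
#' @return Named character vector: subject id -> relative profile path; the
#'   same mapping is written to `out_dir/profiles/index.json`.
#' @export
render_profiles <- function(batch, config, out_dir, subjects = "all", jobs = 1) {
  dm <- batch$domains$DM
  abort_if(is.null(dm), "batch has no DM domain")
  all_ids <- unique(dm[[subject_id_var(dm)]])
  if (identical(subjects, "all")) {
    ids <- all_ids
  } else {
    missing_ids <- setdiff(subjects, all_ids)
    if (length(missing_ids))
      warning(sprintf("subject(s) not in DM, skipped: %s",
                      paste(missing_ids, collapse = ", ")), call. = FALSE)
    ids <- intersect(subjects, all_ids)
  }
  dir.create(file.path(out_dir, "profiles"), recursive = TRUE, showWarnings = FALSE)
  phu <- config$page_height_units %||% 10
  render_one <- function(id) {
    mods <- lapply(config$modules, build_module, batch = batch, subject_id = id)
    prof <- compose_profile(mods, id, page_height_units = phu)
    rel <- file.path("profiles", paste0(prof$file_name, ".svg"))
    writeLines(profile_svg(prof, page_height_units = phu),
               file.path(out_dir, rel))
    rel
  }
  rels <- if (jobs > 1) {
    unlist(parallel::mclapply(ids, render_one, mc.cores = jobs))
  } else {
    vapply(ids, render_one, character(1))
  }
  index <- stats::setNames(as.character(rels), ids)
  jsonlite::write_json(as.list(index), file.path(out_dir, "profiles", "index.json"),
                       auto_unbox = TRUE)
  index
}
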
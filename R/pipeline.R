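# Report pipeline: YAML config -> validated chapters -> standalone HTML
# pages -> assembled report with a deterministic identifier.

known_top_keys <- c("study", "settings", "data", "previous_data", "chapters",
                    "profiles")

#' Load and merge a report configuration
#'
#' Reads the YAML configuration, checks top-level keys strictly (typos are
#' fatal: the tool targets minimally-technical users and a silently ignored
#' key is worse than an error), and merges the packaged default
#' configuration for the declared blinding mode underneath the user's
#' values.
#'
#' @param path YAML configuration file.
#' @return A `report_config` list with elements `study`, `settings`, `data`,
#'   `chapters`, `profiles`.
#' @export
load_config <- function(path) {
  user <- tryCatch(yaml::read_yaml(path),
                   error = function(e) stop(sprintf("YAML error in '%s': %s", path,
                                                    conditionMessage(e)), call. = FALSE))
  unknown <- setdiff(names(user), known_top_keys)
  abort_if(length(unknown) > 0,
           sprintf("unknown configuration key(s): %s (known: %s)",
                   paste(unknown, collapse = ", "),
                   paste(known_top_keys, collapse = ", ")))
  blinded <- isTRUE(user$settings$blinded)
  default_file <- system.file("config",
                              if (blinded) "default-blinded.yml" else "default-unblinded.yml",
                              package = "safetyreview")
  defaults <- yaml::read_yaml(default_file)
  cfg <- utils::modifyList(defaults, user, keep.null = TRUE)
  # chapters are replaced wholesale, not merged element-wise
  if (!is.null(user$chapters)) cfg$chapters <- user$chapters
  abort_if(is.null(cfg$study$study_id), "config must set study: study_id")
  ids <- vapply(cfg$chapters, function(ch) ch$output %||% ch$template, character(1))
  abort_if(anyDuplicated(ids) > 0,
           sprintf("duplicate chapter output id: %s", ids[duplicated(ids)][1]))
  for (ch in cfg$chapters)
    abort_if(!(ch$template %in% list_templates()),
             sprintf("chapter template '%s' is not registered (known: %s)",
                     ch$template, paste(list_templates(), collapse = ", ")))
  if (blinded) cfg$settings$treatment_var <- NULL
  structure(cfg, class = "report_config")
}

batch_digest <- function(batch) {
  digest::digest(lapply(batch$domains, function(tab)
    list(names(tab), as.list(tibble::as_tibble(tab)))), algo = "xxhash64")
}

config_digest <- function(config) {
  digest::digest(unclass(config), algo = "xxhash64")
}

# -- HTML primitives --------------------------------------------------------

html_escape <- function(x) {
  x <- gsub("&", "&amp;", as.character(x), fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  ifelse(is.na(x), "", x)
}

html_page <- function(title, body, report_digest) {
  c("<!DOCTYPE html>",
    "<html lang=\"en\"><head><meta charset=\"utf-8\">",
    sprintf("<title>%s</title>", html_escape(title)),
    "<style>body{font-family:sans-serif;margin:2em;}table{border-collapse:collapse;}",
    "td,th{border:1px solid #999;padding:3px 8px;font-size:13px;}",
    "th{background:#eee;}details{margin:2px 0;}.badge{padding:1px 6px;border-radius:4px;font-size:11px;}",
    ".addition{background:#cfc;}.removal{background:#fcc;}.change{background:#ffc;}</style>",
    "</head><body>",
    sprintf("<p class=\"report-id\">Report id: %s</p>", html_escape(report_digest)),
    sprintf("<h1>%s</h1>", html_escape(title)),
    body,
    "</body></html>")
}

subject_links_html <- function(subjects, link_index) {
  if (length(subjects) == 0L) return("")
  items <- vapply(subjects, function(id) {
    if (!is.null(link_index) && id %in% names(link_index))
      sprintf("<a href=\"%s\">%s</a>", html_escape(link_index[[id]]),
              html_escape(id))
    else html_escape(id)
  }, character(1))
  sprintf("<details><summary>%d subject(s)</summary>%s</details>",
          length(subjects), paste(items, collapse = ", "))
}

html_table <- function(df, link_index = NULL) {
  subjects <- NULL
  if ("subjects" %in% names(df)) {
    subjects <- df$subjects
    df$subjects <- NULL
  }
  fmt <- function(x) {
    if (is.numeric(x)) ifelse(is.na(x), "", formatC(x, format = "g", digits = 6))
    else html_escape(x)
  }
  header <- paste0("<tr>", paste0("<th>", html_escape(names(df)), "</th>",
                                  collapse = ""),
                   if (!is.null(subjects)) "<th>subjects</th>", "</tr>")
  rows <- vapply(seq_len(nrow(df)), function(i) {
    cells <- vapply(df, function(col) paste0("<td>", fmt(col[i])[1], "</td>"),
                    character(1))
    subj_cell <- if (!is.null(subjects))
      paste0("<td>", subject_links_html(subjects[[i]], link_index), "</td>") else ""
    paste0("<tr>", paste(cells, collapse = ""), subj_cell, "</tr>")
  }, character(1))
  c("<table>", header, rows, "</table>")
}

embed_payload <- function(id, payload) {
  c(sprintf("<script type=\"application/json\" id=\"%s\">", id),
    jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, null = "null",
                     na = "null"),
    "</script>")
}

chart_payload_json <- function(payload, link_index = NULL) {
  series <- payload$series
  if ("subjects" %in% names(series))
    series$subjects <- purrr::map(series$subjects, as.list)
  list(kind = payload$kind, series = series,
       backing_table = payload$backing_table,
       links = payload$links,
       params = payload$params[setdiff(names(payload$params), "aggregate")])
}

# -- chapter computation ----------------------------------------------------

chapter_population <- function(batch, settings) {
  dm <- batch$domains$DM
  abort_if(is.null(dm), "DM domain required for the analysis population")
  analysis_population(dm, if (batch$blinded) NULL else settings$treatment_var)
}

compute_chapter <- function(spec, batch, previous_batch, link_index, settings) {
  params <- spec$params %||% list()
  template <- spec$template
  pop <- chapter_population(batch, settings)
  dm <- batch$domains$DM
  sections <- list()
  add <- function(title, table = NULL, payload = NULL) {
    sections[[length(sections) + 1L]] <<- list(title = title, table = table,
                                               payload = payload)
  }
  sev_order <- unlist(settings$severity_order %||% c("MILD", "MODERATE", "SEVERE"))
  prev_compute <- function(f) {
    function(prev) {
      prev_pop <- chapter_population(prev, settings)
      f(prev, prev_pop)
    }
  }
  get_domain <- function(b, code) {
    abort_if(!code %in% names(b$domains),
             sprintf("%s: domain absent from batch '%s'", code, b$batch_id))
    b$domains[[code]]
  }

  if (template == "demographics") {
    ds <- get_domain(batch, params$dataset %||% "DM")
    for (v in unlist(params$categorical_vars %||% character())) {
      tab <- summarize_categorical(ds, v, pop)
      if (!is.null(previous_batch))
        tab <- attach_previous_batch(tab, previous_batch, prev_compute(
          function(b, p) summarize_categorical(get_domain(b, params$dataset %||% "DM"), v, p)))
      add(sprintf("Demographics: %s", v), table = tab)
    }
    for (v in unlist(params$continuous_vars %||% character())) {
      tab <- summarize_continuous(ds, v, pop)
      if (!is.null(previous_batch))
        tab <- attach_previous_batch(tab, previous_batch, prev_compute(
          function(b, p) summarize_continuous(get_domain(b, params$dataset %||% "DM"), v, p)))
      add(sprintf("Demographics: %s", v), table = tab)
    }
  } else if (template == "disposition") {
    ds <- get_domain(batch, params$dataset %||% "DS")
    ref <- tibble::tibble(subject_id = dm[[subject_id_var(dm)]],
                          reference_date = dm$RFSTDTC)
    tab <- summarize_disposition(ds, pop,
                                 status_var = params$status_var %||% "DSDECOD",
                                 reason_var = params$reason_var %||% "DSTERM",
                                 reference_dates = ref)
    add("Subject disposition", table = tab)
    add("Discontinuation listing", table = attr(tab, "listing"))
    if ((params$visit_dataset %||% "SV") %in% names(batch$domains)) {
      sv <- batch$domains[[params$visit_dataset %||% "SV"]]
      add("Subjects by visit",
          payload = visit_attendance(sv, pop, link_index = link_index))
    }
  } else if (template == "adverse_events") {
    ae <- get_domain(batch, params$dataset %||% "AE")
    if (isTRUE(params$teae_only %||% TRUE) &&
        (params$exposure_dataset %||% "EX") %in% names(batch$domains)) {
      ae_flagged <- flag_treatment_emergent(
        ae, batch$domains[[params$exposure_dataset %||% "EX"]],
        lag_days = params$lag_days %||% 30)
      ae <- ae_flagged[ae_flagged$teae, , drop = FALSE]
    }
    tab <- summarize_ae(ae, pop, severity_order = sev_order)
    if (!is.null(previous_batch))
      tab <- attach_previous_batch(tab, previous_batch, prev_compute(
        function(b, p) {
          pae <- get_domain(b, params$dataset %||% "AE")
          if (isTRUE(params$teae_only %||% TRUE) &&
              (params$exposure_dataset %||% "EX") %in% names(b$domains)) {
            pf <- flag_treatment_emergent(
              pae, b$domains[[params$exposure_dataset %||% "EX"]],
              lag_days = params$lag_days %||% 30)
            pae <- pf[pf$teae, , drop = FALSE]
          }
          summarize_ae(pae, p, severity_order = sev_order)
        }))
    add("Treatment-emergent adverse events", table = tab)
    add("Adverse-event hierarchy (treemap/sunburst)",
        payload = ae_hierarchy(ae, pop, severity_order = sev_order,
                               link_index = link_index))
  } else if (template == "labs") {
    lb <- get_domain(batch, params$dataset %||% "LB")
    if (!"LBDY" %in% names(lb))
      lb <- add_study_day(lb, dm, params$date_var %||% "LBDTC", "LBDY")
    if (isTRUE(params$edish %||% FALSE)) {
      add("eDish (peak ALT vs peak bilirubin, x ULN)",
          payload = edish(lb, pop, alt_code = params$alt_code %||% "ALT",
                          bili_code = params$bili_code %||% "BILI",
                          link_index = link_index))
    }
    for (prm in unlist(params$parameters %||% character())) {
      add(sprintf("Time course: %s", prm),
          payload = spaghetti_data(lb, prm, pop,
                                   subset_rule = params$subset_rule %||% "all",
                                   link_index = link_index))
      add(sprintf("Shift table: %s", prm),
          payload = shift_data(lb, prm, pop, link_index = link_index))
    }
  } else if (template == "batch_comparison") {
    abort_if(is.null(previous_batch),
             "batch_comparison chapter needs a previous batch")
    code <- params$dataset %||% "AE"
    keys <- unlist(params$keys %||% default_diff_keys(code))
    dd <- diff_batches(get_domain(previous_batch, code),
                       get_domain(batch, code), keys = keys)
    add(sprintf("Changes since batch '%s' (%s domain)",
                previous_batch$batch_id, code),
        table = diff_listing(dd, label_vars = unlist(params$label_vars %||% character())))
    add("Diff summary", table = tibble::tibble(
      status = names(dd$summary), n = as.integer(dd$summary)))
  } else if (template == "patient_profiles") {
    idx <- tibble::tibble(subject_id = names(link_index),
                          profile = unname(link_index),
                          subjects = purrr::map(names(link_index), identity))
    add("Patient profiles", table = idx)
  } else {
    stop(sprintf("unknown template '%s'", template), call. = FALSE)
  }
  sections
}

default_diff_keys <- function(domain_code) {
  keys <- yaml::read_yaml(system.file("config", "diff-keys.yml",
                                      package = "safetyreview"))
  unlist(keys[[domain_code]] %||% keys[["default"]])
}

#' Render one report chapter to a standalone HTML file
#'
#' Validates the chapter's parameters against its template schema, computes
#' the chapter's tables and chart payloads, and writes one self-contained
#' HTML page (all data embedded as JSON, no external assets). A failing
#' chapter is contained: it produces an error page and a `"failed"` status,
#' and sibling chapters are unaffected.
#'
#' @param spec Chapter spec: list with `template`, `output`, `params`.
#' @param batch Current `study_batch`.
#' @param previous_batch Previous `study_batch` or `NULL`.
#' @param link_index Subject-to-profile-path map from [render_profiles()].
#' @param out_dir Report output directory.
#' @param report_digest Deterministic report digest shown on the page.
#' @param settings Global settings list from the config.
#' @return One-row tibble: `id`, `template`, `file`, `status`, `error`.
#' @export
render_chapter <- function(spec, batch, previous_batch = NULL,
                           link_index = NULL, out_dir, report_digest = "",
                           settings = list()) {
  id <- spec$output %||% spec$template
  file <- paste0(sanitize_stem(id), ".html")
  result <- tryCatch({
    schema <- read_template_schema(spec$template)
    vrep <- validate_chapter_params(spec$params %||% list(), schema)
    if (!attr(vrep, "valid")) {
      msgs <- vrep$message[!vrep$passed]
      stop(sprintf("parameter validation failed: %s",
                   paste(msgs, collapse = "; ")), call. = FALSE)
    }
    sections <- compute_chapter(spec, batch, previous_batch, link_index,
                                settings)
    body <- unlist(purrr::imap(sections, function(sec, i) {
      frag <- sprintf("<h2>%s</h2>", html_escape(sec$title))
      if (!is.null(sec$table)) {
        flat <- if (inherits(sec$table, "summary_table")) {
          f <- flatten_summary(sec$table)
          f$subjects <- NULL
          df <- tibble::as_tibble(sec$table)
          if ("subjects" %in% names(df)) f$subjects <- df$subjects
          f
        } else tibble::as_tibble(sec$table)
        frag <- c(frag, html_table(flat, link_index),
                  embed_payload(sprintf("table-%d", i),
                                summary_payload(sec$table, link_index)))
      }
      if (!is.null(sec$payload)) {
        frag <- c(frag,
                  sprintf("<p>%d series rows; data payload embedded.</p>",
                          nrow(sec$payload$series)),
                  embed_payload(sprintf("chart-%d", i),
                                chart_payload_json(sec$payload, link_index)))
      }
      frag
    }))
    writeLines(html_page(sprintf("%s - %s", id, batch$batch_id), body,
                         report_digest),
               file.path(out_dir, file))
    tibble::tibble(id = id, template = spec$template, file = file,
                   status = "ok", error = NA_character_)
  }, error = function(e) {
    writeLines(html_page(sprintf("%s - FAILED", id),
                         sprintf("<p class=\"error\">Chapter failed: %s</p>",
                                 html_escape(conditionMessage(e))),
                         report_digest),
               file.path(out_dir, file))
    tibble::tibble(id = id, template = spec$template, file = file,
                   status = "failed", error = conditionMessage(e))
  })
  result
}

#' Assemble the chapter pages into a navigable report
#'
#' Writes the index page with a table of contents linking every chapter
#' (failed chapters are marked), and the JSON manifest carrying the report
#' identifier. The identifier's digest component is a pure function of the
#' configuration and data; the timestamp lives only in the manifest so
#' rebuilt artifacts stay byte-identical.
#'
#' @param chapters Tibble of chapter results from [render_chapter()].
#' @param config The `report_config`.
#' @param batch Current `study_batch`.
#' @param out_dir Output directory.
#' @param report_digest Deterministic digest component of the report id.
#' @param previous_batch Previous batch or `NULL`.
#' @return The manifest (list), invisibly; written to `manifest.json`.
#' @export
assemble_report <- function(chapters, config, batch, out_dir, report_digest,
                            previous_batch = NULL) {
  abort_if(nrow(chapters) == 0L, "no chapters rendered")
  toc <- vapply(seq_len(nrow(chapters)), function(i) {
    ch <- chapters[i, ]
    if (ch$status == "ok")
      sprintf("<li><a href=\"%s\">%s</a></li>", ch$file, html_escape(ch$id))
    else
      sprintf("<li><a href=\"%s\">%s</a> <span class=\"badge removal\">failed</span></li>",
              ch$file, html_escape(ch$id))
  }, character(1))
  body <- c(sprintf("<p>Study %s, batch %s (cutoff %s), %s.</p>",
                    html_escape(config$study$study_id),
                    html_escape(batch$batch_id),
                    html_escape(batch$cutoff_date),
                    if (batch$blinded) "blinded" else "unblinded"),
            "<h2>Table of contents</h2>", "<ul>", toc, "</ul>",
            "<p><a href=\"profiles/index.json\">Patient profile index</a></p>")
  writeLines(html_page(sprintf("Safety review report: %s",
                               config$study$study_id),
                       body, report_digest),
             file.path(out_dir, "index.html"))
  manifest <- list(
    report_id = paste0(report_digest, "-", format(Sys.time(), "%Y%m%dT%H%M%S")),
    digest = report_digest,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    study_id = config$study$study_id,
    batch_id = batch$batch_id,
    previous_batch_id = previous_batch$batch_id %||% NULL,
    blinded = batch$blinded,
    chapters = purrr::map(seq_len(nrow(chapters)), function(i)
      as.list(chapters[i, c("id", "template", "file", "status")])))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, null = "null", na = "null")
  invisible(manifest)
}

#' Build a full report from a configuration and data directory
#'
#' Loads the batch (and optionally a previous batch), renders every patient
#' profile and chapter (parallelizable across subjects and chapters), and
#' assembles the navigable report. Chapter failures are contained; the
#' returned manifest records per-chapter status, and `attr(, "ok")` is
#' `FALSE` when any chapter failed.
#'
#' @param config A `report_config` from [load_config()], or a path to a
#'   YAML config.
#' @param data_dir Directory with the current batch's domain files.
#' @param out_dir Output directory for the report.
#' @param previous_data_dir Optional directory with the previous batch.
#' @param jobs Parallel workers for profiles and chapters (default 1).
#' @return The report manifest, invisibly.
#' @export
run_report <- function(config, data_dir, out_dir, previous_data_dir = NULL,
                       jobs = 1) {
  if (is.character(config)) config <- load_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest_cfg <- c(config$data,
                    list(blinded = isTRUE(config$settings$blinded),
                         treatment_var = config$settings$treatment_var %||%
                           config$data$treatment_var,
                         subject_id_var = config$settings$subject_id_var %||% "USUBJID"))
  batch <- load_batch(data_dir, manifest_cfg)
  previous_batch <- NULL
  if (!is.null(previous_data_dir)) {
    prev_cfg <- manifest_cfg
    prev_cfg$batch_id <- config$previous_data$batch_id %||%
      basename(previous_data_dir)
    prev_cfg$cutoff_date <- config$previous_data$cutoff_date %||% NA_character_
    previous_batch <- load_batch(previous_data_dir, prev_cfg)
  }
  report_digest <- digest::digest(
    list(config = unclass(config), batch_id = batch$batch_id,
         data = batch_digest(batch),
         previous = if (!is.null(previous_batch)) batch_digest(previous_batch)),
    algo = "xxhash64")

  link_index <- render_profiles(batch, config$profiles, out_dir,
                                subjects = config$profiles$subjects %||% "all",
                                jobs = jobs)

  render_one <- function(spec) {
    render_chapter(spec, batch, previous_batch, link_index, out_dir,
                   report_digest, config$settings)
  }
  chapters <- if (jobs > 1) {
    dplyr::bind_rows(parallel::mclapply(config$chapters, render_one,
                                        mc.cores = jobs))
  } else {
    dplyr::bind_rows(lapply(config$chapters, render_one))
  }
  manifest <- assemble_report(chapters, config, batch, out_dir, report_digest,
                              previous_batch)
  if (isTRUE(config$settings$blinded) && !is.null(config$data$treatment_var))
    assert_no_treatment_leak(out_dir, config$data$treatment_var)
  attr(manifest, "ok") <- all(chapters$status == "ok")
  invisible(manifest)
}

assert_no_treatment_leak <- function(out_dir, treatment_var) {
  files <- list.files(out_dir, pattern = "\\.(html|svg)$", full.names = TRUE,
                      recursive = TRUE)
  for (f in files) {
    txt <- readLines(f, warn = FALSE)
    abort_if(any(grepl(paste0("\\b", treatment_var, "\\b"), txt)),
             sprintf("blinding violation: treatment variable '%s' appears in %s",
                     treatment_var, basename(f)))
  }
  invisible(TRUE)
}

#' Build the blinded and unblinded reports side by side
#'
#' The two runs differ only by the inclusion of the treatment variable: the
#' blinded run drops it everywhere and pools all subjects into a single
#' column; the unblinded run groups by it. Everything else — populations,
#' filters, derivations — is identical.
#'
#' @param config A `report_config` (unblinded; must name the treatment
#'   variable in `data$treatment_var` or `settings$treatment_var`).
#' @param data_dir Data directory for the batch.
#' @param out_dir Parent output directory; reports go to `blinded/` and
#'   `unblinded/` beneath it.
#' @param jobs Parallel workers.
#' @return List with elements `blinded` and `unblinded` (manifests).
#' @export
run_blinded_vs_unblinded <- function(config, data_dir, out_dir, jobs = 1) {
  if (is.character(config)) config <- load_config(config)
  trt <- config$settings$treatment_var %||% config$data$treatment_var
  abort_if(is.null(trt), "config must name the treatment variable")
  unblinded_cfg <- config
  unblinded_cfg$settings$blinded <- FALSE
  unblinded_cfg$settings$treatment_var <- trt
  blinded_cfg <- config
  blinded_cfg$settings$blinded <- TRUE
  blinded_cfg$settings$treatment_var <- NULL
  blinded_cfg$data$treatment_var <- trt  # so load_batch knows what to drop
  list(
    blinded = run_report(blinded_cfg, data_dir, file.path(out_dir, "blinded"),
                         jobs = jobs),
    unblinded = run_report(unblinded_cfg, data_dir,
                           file.path(out_dir, "unblinded"), jobs = jobs))
}
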
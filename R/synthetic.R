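# Seeded SDTM-like synthetic study generator: a consistent set of domain
# tables (DM, EX, SV, AE, LB, EG, VS, DS) plus ground truth for every
# injected feature, and a second-batch generator with known differences.
# Targets structural realism (variables, keys, partial dates, reference
# ranges), not pharmacological realism.

ae_term_pool <- tibble::tibble(
  pt = c("HEADACHE", "NAUSEA", "DIZZINESS", "FATIGUE", "RASH",
         "PRURITUS", "DIARRHOEA", "VOMITING", "INSOMNIA", "ARTHRALGIA"),
  soc = c("NERVOUS SYSTEM DISORDERS", "GASTROINTESTINAL DISORDERS",
          "NERVOUS SYSTEM DISORDERS", "GENERAL DISORDERS",
          "SKIN AND SUBCUTANEOUS TISSUE DISORDERS",
          "SKIN AND SUBCUTANEOUS TISSUE DISORDERS",
          "GASTROINTESTINAL DISORDERS", "GASTROINTESTINAL DISORDERS",
          "PSYCHIATRIC DISORDERS", "MUSCULOSKELETAL DISORDERS"))

default_labs <- list(
  ALT = list(mid = 22, sd = 6, lo = 7, hi = 40, drift = 1.5, unit = "U/L"),
  BILI = list(mid = 0.6, sd = 0.15, lo = 0.2, hi = 1.2, drift = 0, unit = "mg/dL"),
  CREAT = list(mid = 0.9, sd = 0.15, lo = 0.6, hi = 1.3, drift = 0, unit = "mg/dL"))

#' Recipe for a synthetic SDTM-like study
#'
#' The recipe fixes the study conditions: cohort size, arms, visit schedule,
#' adverse-event rate and severity mix, per-visit dropout hazard, laboratory
#' parameters with reference ranges and per-arm drift, and the rate of
#' partial onset dates. A fixed seed fixes all randomness.
#'
#' @param n_subjects Number of subjects (default 50).
#' @param arms Arm labels (default Placebo / Active).
#' @param n_visits Number of scheduled visits (default 6).
#' @param visit_spacing_days Days between visits (default 14).
#' @param ae_rate Probability of a new adverse event per subject-visit
#'   (default 0.3).
#' @param severity_dist Named probabilities over the ordered severity levels
#'   (default MILD 0.5, MODERATE 0.35, SEVERE 0.15).
#' @param dropout_hazard Per-visit discontinuation probability after visit 1
#'   (default 0.05).
#' @param labs Named list of lab parameters: each `list(mid, sd, lo, hi,
#'   drift, unit)`; `drift` shifts the non-reference arms' mean per visit.
#' @param partial_date_rate Fraction of AE onset dates truncated to
#'   year-month (default 0.05).
#' @param pre_treatment_ae_rate Fraction of subjects given one AE starting
#'   before first dose (known non-treatment-emergent; default 0.1).
#' @param seed Integer seed fixing all randomness.
#' @return A `study_recipe` list.
#' @export
study_recipe <- function(n_subjects = 50, arms = c("Placebo", "Active"),
                         n_visits = 6, visit_spacing_days = 14,
                         ae_rate = 0.3,
                         severity_dist = c(MILD = 0.5, MODERATE = 0.35,
                                           SEVERE = 0.15),
                         dropout_hazard = 0.05, labs = default_labs,
                         partial_date_rate = 0.05,
                         pre_treatment_ae_rate = 0.1, seed = 20240101) {
  probs <- c(ae_rate, dropout_hazard, partial_date_rate, pre_treatment_ae_rate,
             severity_dist)
  abort_if(any(probs < 0 | probs > 1), "probabilities must lie in [0, 1]")
  abort_if(abs(sum(severity_dist) - 1) > 1e-9, "severity_dist must sum to 1")
  abort_if(n_subjects < 1, "need at least one subject")
  abort_if(n_visits < 1 && length(labs) > 0,
           "labs requested but no visits scheduled")
  structure(list(n_subjects = n_subjects, arms = arms, n_visits = n_visits,
                 visit_spacing_days = visit_spacing_days, ae_rate = ae_rate,
                 severity_dist = severity_dist,
                 dropout_hazard = dropout_hazard, labs = labs,
                 partial_date_rate = partial_date_rate,
                 pre_treatment_ae_rate = pre_treatment_ae_rate, seed = seed),
            class = "study_recipe")
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  force(code)
}

iso <- function(d) format(d, "%Y-%m-%d")

#' Generate a synthetic study batch with ground truth
#'
#' Produces a consistent `study_batch` (adverse-event onsets inside the
#' study window, visit records consistent with dropout, one lab/ECG/vitals
#' record per attended visit and parameter, ECG includes QT and HR so QTcF
#' is derivable) together with the generator's ground truth: per-record
#' treatment-emergent status, attendance per visit, discontinuation reasons,
#' and abnormal-lab subject sets.
#'
#' @param recipe A [study_recipe()].
#' @param batch_id,cutoff_date Batch labelling.
#' @return List with elements `batch` (a `study_batch`) and `truth` (list).
#' @export
generate_study <- function(recipe, batch_id = "batch1",
                           cutoff_date = "2025-06-30") {
  abort_if(!inherits(recipe, "study_recipe"), "recipe must be a study_recipe")
  with_seed(recipe$seed, {
    n <- recipe$n_subjects
    ids <- sprintf("SYN01-%03d", seq_len(n))
    arm <- sample(recipe$arms, n, replace = TRUE)
    start <- as.Date("2025-01-06") + sample(0:59, n, replace = TRUE)
    age <- pmin(pmax(round(stats::rnorm(n, 52, 12)), 18), 85)
    sex <- sample(c("F", "M"), n, replace = TRUE)
    race <- sample(c("WHITE", "BLACK OR AFRICAN AMERICAN", "ASIAN", "OTHER"),
                   n, replace = TRUE, prob = c(0.6, 0.15, 0.18, 0.07))

    # dropout: first visit always attended; geometric thereafter
    dropout_visit <- rep(NA_integer_, n)
    attended_last <- integer(n)
    for (i in seq_len(n)) {
      v <- 1L
      while (v < recipe$n_visits &&
             stats::runif(1) >= recipe$dropout_hazard) v <- v + 1L
      attended_last[i] <- v
      if (v < recipe$n_visits) dropout_visit[i] <- v + 1L
    }
    visit_day <- function(v) 1L + (v - 1L) * recipe$visit_spacing_days
    visit_name <- function(v) sprintf("VISIT %d", v)

    dm <- tibble::tibble(
      USUBJID = ids, SUBJID = sprintf("%03d", seq_len(n)),
      AGE = as.character(age), SEX = sex, RACE = race, ARM = arm,
      COUNTRY = "BEL",
      RFSTDTC = iso(start),
      RFENDTC = iso(start + visit_day(attended_last) - 1L))

    sv <- purrr::map_dfr(seq_len(n), function(i) {
      vs <- seq_len(attended_last[i])
      tibble::tibble(USUBJID = ids[i], VISITNUM = as.character(vs),
                     VISIT = visit_name(vs),
                     SVSTDTC = iso(start[i] + visit_day(vs) - 1L))
    })

    ex <- tibble::tibble(
      USUBJID = ids, EXTRT = ifelse(arm == recipe$arms[1], "PLACEBO", "DRUG X"),
      EXDOSE = ifelse(arm == recipe$arms[1], "0", "50"), EXDOSU = "mg",
      EXSTDTC = iso(start), EXENDTC = iso(start + visit_day(attended_last) - 1L))

    # adverse events: per attended visit; some subjects get a pre-dose AE
    sev_levels <- names(recipe$severity_dist)
    ae_rows <- list()
    truth_ae <- list()
    for (i in seq_len(n)) {
      seq_no <- 0L
      emit <- function(pt, soc, sev, onset, end, teae, partial = FALSE) {
        seq_no <<- seq_no + 1L
        st_txt <- if (partial) format(onset, "%Y-%m") else iso(onset)
        ae_rows[[length(ae_rows) + 1L]] <<- tibble::tibble(
          USUBJID = ids[i], AESEQ = as.character(seq_no), AEDECOD = pt,
          AEBODSYS = soc, AESEV = sev,
          AESER = ifelse(sev == "SEVERE" && stats::runif(1) < 0.3, "Y", "N"),
          AESTDTC = st_txt,
          AEENDTC = if (is.na(end)) NA_character_ else iso(end))
        # ground-truth TEAE on the earliest-imputed onset (generator's own
        # arithmetic, same imputation convention the pipeline documents)
        imp <- if (partial) as.Date(paste0(format(onset, "%Y-%m"), "-01")) else onset
        truth_ae[[length(truth_ae) + 1L]] <<- tibble::tibble(
          USUBJID = ids[i], AESEQ = as.character(seq_no), pt = pt, soc = soc,
          severity = sev,
          teae = imp >= start[i] &
            imp <= start[i] + visit_day(attended_last[i]) - 1L + 30L)
      }
      if (stats::runif(1) < recipe$pre_treatment_ae_rate) {
        k <- sample(nrow(ae_term_pool), 1)
        onset <- start[i] - sample(5:20, 1)
        emit(ae_term_pool$pt[k], ae_term_pool$soc[k],
             sample(sev_levels, 1, prob = recipe$severity_dist),
             onset, onset + sample(1:10, 1), teae = FALSE)
      }
      for (v in seq_len(attended_last[i])) {
        if (stats::runif(1) < recipe$ae_rate) {
          k <- sample(nrow(ae_term_pool), 1)
          onset <- start[i] + visit_day(v) - 1L + sample(0:6, 1)
          end <- if (stats::runif(1) < 0.8) onset + sample(1:14, 1) else as.Date(NA)
          partial <- stats::runif(1) < recipe$partial_date_rate
          emit(ae_term_pool$pt[k], ae_term_pool$soc[k],
               sample(sev_levels, 1, prob = recipe$severity_dist),
               onset, end, teae = NA, partial = partial)
        }
      }
    }
    ae <- if (length(ae_rows)) dplyr::bind_rows(ae_rows) else
      tibble::tibble(USUBJID = character(), AESEQ = character(),
                     AEDECOD = character(), AEBODSYS = character(),
                     AESEV = character(), AESER = character(),
                     AESTDTC = character(), AEENDTC = character())
    truth_ae_tbl <- if (length(truth_ae)) dplyr::bind_rows(truth_ae) else
      tibble::tibble(USUBJID = character(), AESEQ = character(),
                     pt = character(), soc = character(),
                     severity = character(), teae = logical())

    # labs: one record per attended visit and parameter; values capped below
    # 2 x ULN so hepatotoxicity quadrants stay empty unless injected
    lab_rows <- list()
    for (i in seq_len(n)) {
      for (v in seq_len(attended_last[i])) {
        for (pname in names(recipe$labs)) {
          p <- recipe$labs[[pname]]
          drift <- if (arm[i] != recipe$arms[1]) p$drift * (v - 1L) else 0
          val <- stats::rnorm(1, p$mid + drift, p$sd)
          val <- min(max(val, p$lo * 0.5), p$hi * 1.9)
          lab_rows[[length(lab_rows) + 1L]] <- tibble::tibble(
            USUBJID = ids[i], LBSEQ = NA_character_, LBTESTCD = pname,
            LBTEST = pname, LBORRES = sprintf("%.2f", val),
            LBORRESU = p$unit, LBORNRLO = num_chr(p$lo),
            LBORNRHI = num_chr(p$hi),
            VISITNUM = as.character(v), VISIT = visit_name(v),
            LBDTC = iso(start[i] + visit_day(v) - 1L))
        }
      }
    }
    lb <- dplyr::bind_rows(lab_rows)
    lb$LBSEQ <- as.character(seq_len(nrow(lb)))

    eg_rows <- list()
    for (i in seq_len(n)) {
      for (v in seq_len(attended_last[i])) {
        qt <- stats::rnorm(1, 400, 15)
        hr <- stats::rnorm(1, 72, 9)
        for (tc in c("QT", "HR")) {
          eg_rows[[length(eg_rows) + 1L]] <- tibble::tibble(
            USUBJID = ids[i], EGSEQ = NA_character_, EGTESTCD = tc,
            EGORRES = sprintf("%.1f", if (tc == "QT") qt else hr),
            EGORRESU = if (tc == "QT") "ms" else "beats/min",
            VISITNUM = as.character(v), VISIT = visit_name(v),
            EGDTC = iso(start[i] + visit_day(v) - 1L))
        }
      }
    }
    eg <- dplyr::bind_rows(eg_rows)
    eg$EGSEQ <- as.character(seq_len(nrow(eg)))

    vs_rows <- list()
    vs_params <- list(SYSBP = c(122, 11, "mmHg"), DIABP = c(78, 8, "mmHg"),
                      PULSE = c(72, 8, "beats/min"))
    for (i in seq_len(n)) {
      for (v in seq_len(attended_last[i])) {
        for (pn in names(vs_params)) {
          pp <- vs_params[[pn]]
          vs_rows[[length(vs_rows) + 1L]] <- tibble::tibble(
            USUBJID = ids[i], VSSEQ = NA_character_, VSTESTCD = pn,
            VSORRES = sprintf("%.0f", stats::rnorm(1, as.numeric(pp[1]),
                                                   as.numeric(pp[2]))),
            VSORRESU = pp[3],
            VISITNUM = as.character(v), VISIT = visit_name(v),
            VSDTC = iso(start[i] + visit_day(v) - 1L))
        }
      }
    }
    vs <- dplyr::bind_rows(vs_rows)
    vs$VSSEQ <- as.character(seq_len(nrow(vs)))

    reasons <- c("ADVERSE EVENT", "WITHDRAWAL BY SUBJECT", "LOST TO FOLLOW-UP")
    completed <- is.na(dropout_visit)
    ds_reason <- ifelse(completed, "COMPLETED",
                        sample(reasons, n, replace = TRUE))
    ds <- tibble::tibble(
      USUBJID = ids, DSCAT = "DISPOSITION EVENT",
      DSDECOD = ifelse(completed, "COMPLETED", ds_reason),
      DSTERM = ifelse(completed, "COMPLETED", ds_reason),
      DSSTDTC = iso(start + visit_day(attended_last) - 1L))

    labels <- list(
      DM = c(USUBJID = "Unique Subject Identifier", AGE = "Age", SEX = "Sex",
             RACE = "Race", ARM = "Description of Planned Arm",
             RFSTDTC = "Subject Reference Start Date/Time"),
      AE = c(AEDECOD = "Dictionary-Derived Term",
             AEBODSYS = "Body System or Organ Class",
             AESEV = "Severity/Intensity"),
      LB = c(LBTESTCD = "Lab Test Short Name", LBORRES = "Result or Finding",
             LBORNRLO = "Reference Range Lower Limit",
             LBORNRHI = "Reference Range Upper Limit"))

    mk <- function(df, code) domain_table(
      df, code, variable_labels = labels[[code]] %||% character(),
      allow_empty = TRUE)
    batch <- study_batch(
      batch_id = batch_id, cutoff_date = cutoff_date,
      domains = list(DM = mk(dm, "DM"), EX = mk(ex, "EX"), SV = mk(sv, "SV"),
                     AE = mk(ae, "AE"), LB = mk(lb, "LB"), EG = mk(eg, "EG"),
                     VS = mk(vs, "VS"), DS = mk(ds, "DS")),
      blinded = FALSE, treatment_var = "ARM")

    attendance <- purrr::map_dfr(seq_len(recipe$n_visits), function(v)
      tibble::tibble(visit = visit_name(v), visitnum = v,
                     subjects = list(ids[attended_last >= v]),
                     n_subjects = sum(attended_last >= v)))
    abnormal <- purrr::map(names(recipe$labs), function(pname) {
      p <- recipe$labs[[pname]]
      sub <- lb[lb$LBTESTCD == pname, ]
      v <- as.numeric(sub$LBORRES)
      sort(unique(sub$USUBJID[v < p$lo | v > p$hi]))
    })
    names(abnormal) <- names(recipe$labs)

    truth <- list(
      arm = stats::setNames(arm, ids),
      reference_start = stats::setNames(iso(start), ids),
      attended_last = stats::setNames(attended_last, ids),
      dropout_visit = stats::setNames(dropout_visit, ids),
      attendance = attendance,
      disposition = tibble::tibble(
        USUBJID = ids,
        status = ifelse(completed, "Completed", "Discontinued"),
        reason = ds_reason,
        last_day = visit_day(attended_last)),
      ae = truth_ae_tbl,
      abnormal_lab_subjects = abnormal)
    list(batch = batch, truth = truth)
  })
}

#' Generate a consecutive batch with known injected differences
#'
#' Returns a new batch differing from the input by exactly the requested
#' counts per domain, plus the exact expected diff (keys, statuses and
#' changed-variable sets) as ground truth. Changes never touch key
#' variables; additions clone an existing record under a fresh key;
#' removals drop whole records.
#'
#' @param batch A `study_batch`.
#' @param delta List: per domain code, `list(additions =, removals =,
#'   changes =, change_var =)`; plus `seed`.
#' @return List with `batch` (the new `study_batch`) and `truth`: per
#'   domain, a list with `keys`, `summary` (addition/removal/change counts)
#'   and `entries` (tibble of key values, status, changed_vars).
#' @export
generate_next_batch <- function(batch, delta) {
  seed <- delta$seed %||% 1L
  doms <- setdiff(names(delta), "seed")
  with_seed(seed, {
    new_domains <- batch$domains
    truth <- list()
    for (code in doms) {
      d <- delta[[code]]
      abort_if(!code %in% names(batch$domains),
               sprintf("%s: domain absent from batch", code))
      tab <- tibble::as_tibble(batch$domains[[code]])
      keys <- default_diff_keys(code)
      keys <- intersect(keys, names(tab))
      n_add <- d$additions %||% 0L
      n_rem <- d$removals %||% 0L
      n_chg <- d$changes %||% 0L
      abort_if(n_rem + n_chg > nrow(tab),
               sprintf("%s: delta exceeds table size", code))
      idx <- sample(nrow(tab), n_rem + n_chg)
      rem_idx <- idx[seq_len(n_rem)]
      chg_idx <- setdiff(idx, rem_idx)
      change_var <- d$change_var %||% setdiff(names(tab), keys)[1]
      abort_if(change_var %in% keys, "change_var must not be a key variable")

      new_tab <- tab
      entries <- list()
      # changes
      for (j in chg_idx) {
        old_val <- new_tab[[change_var]][j]
        new_val <- perturb_value(old_val, change_var)
        new_tab[[change_var]][j] <- new_val
        entries[[length(entries) + 1L]] <- c(
          as.list(tab[j, keys, drop = FALSE]),
          list(status = "change", changed_vars = list(change_var)))
      }
      # removals
      for (j in rem_idx)
        entries[[length(entries) + 1L]] <- c(
          as.list(tab[j, keys, drop = FALSE]),
          list(status = "removal", changed_vars = list(character())))
      if (n_rem) new_tab <- new_tab[-rem_idx, , drop = FALSE]
      # additions: clone a template record under a fresh key
      seq_key <- grep("SEQ$", keys, value = TRUE)[1]
      for (a in seq_len(n_add)) {
        src <- new_tab[sample(nrow(new_tab), 1), , drop = FALSE]
        if (!is.na(seq_key)) {
          src[[seq_key]] <- as.character(
            max(as_num(new_tab[[seq_key]]), na.rm = TRUE) + a)
        } else {
          src[[keys[length(keys)]]] <- paste0(src[[keys[length(keys)]]],
                                              "-NEW", a)
        }
        new_tab <- dplyr::bind_rows(new_tab, src)
        entries[[length(entries) + 1L]] <- c(
          as.list(src[, keys, drop = FALSE]),
          list(status = "addition", changed_vars = list(character())))
      }
      old_dt <- batch$domains[[code]]
      new_domains[[code]] <- domain_table(
        new_tab, code, variable_labels = variable_labels(old_dt),
        subject_id_var = subject_id_var(old_dt))
      truth[[code]] <- list(
        keys = keys,
        summary = c(addition = n_add, removal = n_rem, change = n_chg),
        entries = if (length(entries))
          dplyr::bind_rows(lapply(entries, tibble::as_tibble))
        else tibble::tibble())
    }
    new_batch <- batch
    new_batch$domains <- new_domains
    new_batch$batch_id <- paste0(batch$batch_id, "+1")
    list(batch = new_batch, truth = truth)
  })
}

perturb_value <- function(x, var) {
  sev <- c("MILD", "MODERATE", "SEVERE")
  if (!is.na(x) && toupper(x) %in% sev) {
    return(sev[(match(toupper(x), sev)) %% 3L + 1L])
  }
  v <- as_num(x)
  if (!is.na(v)) return(num_chr(v + 1))
  if (is.na(x)) return("UPDATED")
  paste0(x, " (corrected)")
}

#' Inject a named clinical scenario into a batch
#'
#' Modifies one subject's records to realize a scenario with a known
#' downstream classification: `hys_law` (one subject's post-baseline ALT to
#' 5 x ULN and bilirubin to 3 x ULN), `severe_teae` (a SEVERE plus a MILD
#' event of the same term, on treatment), or `partial_onset` (one onset
#' date truncated to year-month).
#'
#' @param batch A `study_batch` (unblinded, with DM/LB or AE as needed).
#' @param case `"hys_law"`, `"severe_teae"` or `"partial_onset"`.
#' @param subject_id Target subject; default picks the first eligible one.
#' @return List with `batch` (modified) and `descriptor` (list naming the
#'   subject and the expected downstream classification).
#' @export
inject_case <- function(batch, case = c("hys_law", "severe_teae", "partial_onset"),
                        subject_id = NULL) {
  case <- match.arg(case)
  dm <- batch$domains$DM
  sid <- subject_id_var(dm)
  if (case == "hys_law") {
    lb <- tibble::as_tibble(batch$domains$LB)
    ref <- stats::setNames(dm$RFSTDTC, dm[[sid]])
    lb_day <- as.integer(as.Date(lb$LBDTC) - as.Date(ref[lb$USUBJID])) + 1L
    eligible <- unique(lb$USUBJID[!is.na(lb_day) & lb_day > 1 &
                                    lb$LBTESTCD %in% c("ALT", "BILI")])
    subject_id <- subject_id %||% sort(eligible)[1]
    abort_if(is.na(subject_id), "no subject with post-baseline ALT/BILI records")
    for (tc in c("ALT", "BILI")) {
      rows <- which(lb$USUBJID == subject_id & lb$LBTESTCD == tc & lb_day > 1)
      abort_if(length(rows) == 0L,
               sprintf("subject %s has no post-baseline %s", subject_id, tc))
      r <- rows[length(rows)]
      mult <- if (tc == "ALT") 5 else 3
      lb$LBORRES[r] <- sprintf("%.2f", as.numeric(lb$LBORNRHI[r]) * mult)
    }
    batch$domains$LB <- domain_table(lb, "LB",
                                     variable_labels = variable_labels(batch$domains$LB))
    descriptor <- list(case = case, subject_id = subject_id,
                       expected = "unique subject in the eDish Hy's-law quadrant")
  } else if (case == "severe_teae") {
    ae <- tibble::as_tibble(batch$domains$AE)
    ex <- tibble::as_tibble(batch$domains$EX)
    subject_id <- subject_id %||% sort(unique(ex$USUBJID))[1]
    onset <- iso(as.Date(ex$EXSTDTC[match(subject_id, ex$USUBJID)]) + 3L)
    next_seq <- function() {
      cur <- as_num(ae$AESEQ[ae$USUBJID == subject_id])
      if (length(cur) == 0L || all(is.na(cur))) 1L else max(cur, na.rm = TRUE) + 1L
    }
    tmpl <- list(USUBJID = subject_id, AEDECOD = "HEPATOTOXICITY",
                 AEBODSYS = "HEPATOBILIARY DISORDERS", AESER = "N",
                 AESTDTC = onset, AEENDTC = NA_character_)
    for (sev in c("MILD", "SEVERE")) {
      rec <- tibble::as_tibble(c(tmpl, list(AESEV = sev,
                                            AESEQ = as.character(next_seq()))))
      ae <- dplyr::bind_rows(ae, rec[names(ae)])
    }
    batch$domains$AE <- domain_table(ae, "AE",
                                     variable_labels = variable_labels(batch$domains$AE))
    descriptor <- list(case = case, subject_id = subject_id, pt = "HEPATOTOXICITY",
                       expected = "counted once, under SEVERE, in the AE summary")
  } else {
    ae <- tibble::as_tibble(batch$domains$AE)
    abort_if(nrow(ae) == 0L, "batch has no adverse events")
    subject_id <- subject_id %||% ae$USUBJID[1]
    r <- which(ae$USUBJID == subject_id &
                 grepl("^\\d{4}-\\d{2}-\\d{2}$", ae$AESTDTC))[1]
    abort_if(is.na(r), "subject has no complete onset date to truncate")
    ae$AESTDTC[r] <- substr(ae$AESTDTC[r], 1, 7)
    batch$domains$AE <- domain_table(ae, "AE",
                                     variable_labels = variable_labels(batch$domains$AE))
    descriptor <- list(case = case, subject_id = subject_id,
                       aeseq = ae$AESEQ[r],
                       expected = "onset flagged imputed in listings and profiles")
  }
  list(batch = batch, descriptor = descriptor)
}

#' Write a study batch to a directory
#'
#' Writes each domain in the folder layout [load_batch()] consumes, as CSV
#' (with label sidecars) or SAS transport v5, and returns the manifest
#' fragment describing the batch.
#'
#' @param batch A `study_batch`.
#' @param dir Output directory (created if needed).
#' @param format `"csv"` or `"xpt"`.
#' @return The manifest list (batch id, cutoff date, domain file map),
#'   invisibly; also written to `dir/manifest.yml`.
#' @export
write_batch <- function(batch, dir, format = c("csv", "xpt")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- purrr::imap(batch$domains, function(tab, code) {
    fname <- paste0(tolower(code), ".", format)
    if (format == "csv") {
      write_domain_csv(tab, file.path(dir, fname))
    } else {
      df <- tibble::as_tibble(tab)
      labs <- variable_labels(tab)
      for (v in intersect(names(labs), names(df)))
        attr(df[[v]], "label") <- unname(labs[[v]])
      haven::write_xpt(df, file.path(dir, fname), version = 5,
                       name = code)
    }
    fname
  })
  manifest <- list(batch_id = batch$batch_id, cutoff_date = batch$cutoff_date,
                   blinded = batch$blinded,
                   treatment_var = batch$treatment_var,
                   domains = files)
  yaml::write_yaml(manifest, file.path(dir, "manifest.yml"))
  invisible(manifest)
}
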
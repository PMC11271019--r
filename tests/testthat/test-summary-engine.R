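# Summary engine: categorical/continuous descriptives, TEAE flagging,
# worst-severity AE incidence, disposition, batch comparison columns,
# exports.

test_that("categorical summaries count distinct subjects with percentages", {
  dm <- tiny_dm()
  pop <- analysis_population(dm, NULL)  # single pooled column
  tab <- summarize_categorical(dm, "SEX", pop)
  m <- tab[tab$level == "M", ]
  f <- tab[tab$level == "F", ]
  expect_equal(m$n_subjects, 2); expect_equal(m$pct, 50)
  expect_equal(f$n_subjects, 2); expect_equal(f$pct, 50)

  solo <- summarize_categorical(dm, "SEX",
                                tibble::tibble(subject_id = "S1", group = "All"))
  expect_equal(solo$n_subjects[solo$level == "M"], 1)
  expect_equal(solo$pct[solo$level == "M"], 100)
  expect_error(summarize_categorical(dm, "NOPE", pop), "missing required")
})

test_that("categorical summaries equal brute-force distinct counts on a 200-subject study", {
  g <- generate_study(study_recipe(n_subjects = 200, seed = 77))
  dm <- g$batch$domains$DM
  pop <- analysis_population(dm, "ARM")
  for (v in c("SEX", "RACE")) {
    tab <- summarize_categorical(dm, v, pop)
    oracle <- brute_count_distinct(dm$USUBJID, dm[[v]], dm$ARM)
    for (i in seq_len(nrow(tab))) {
      if (is.na(tab$level[i])) next
      o <- oracle$Freq[oracle$level == tab$level[i] &
                         oracle$group == tab$group[i]]
      expect_equal(tab$n_subjects[i], if (length(o)) o else 0)
      den <- sum(dm$ARM == tab$group[i])
      expect_equal(tab$pct[i], 100 * tab$n_subjects[i] / den)
    }
  }
})

test_that("percentages per group sum to 100 including any missing row", {
  set.seed(5)
  for (i in 1:10) {
    n <- sample(20:60, 1)
    dm <- domain_table(tibble::tibble(
      USUBJID = sprintf("S%03d", 1:n),
      SEX = sample(c("M", "F", NA), n, replace = TRUE),
      ARM = sample(c("A", "B"), n, replace = TRUE)), "DM")
    tab <- summarize_categorical(dm, "SEX", analysis_population(dm, "ARM"))
    sums <- tapply(tab$pct, tab$group, sum)
    expect_equal(as.numeric(sums), rep(100, length(sums)), tolerance = 1e-9)
  }
})

test_that("continuous summaries compute sample statistics and degenerate cases", {
  dm <- domain_table(tibble::tibble(
    USUBJID = c("S1", "S2", "S3"), AGE = c("1", "2", "3")), "DM")
  tab <- summarize_continuous(dm, "AGE", analysis_population(dm, NULL))
  expect_equal(tab$n, 3); expect_equal(tab$mean, 2); expect_equal(tab$sd, 1)
  expect_equal(tab$median, 2); expect_equal(tab$min, 1); expect_equal(tab$max, 3)

  one <- domain_table(tibble::tibble(USUBJID = "S1", AGE = "5"), "DM")
  t1 <- summarize_continuous(one, "AGE", analysis_population(one, NULL))
  expect_equal(t1$n, 1); expect_equal(t1$mean, 5); expect_true(is.na(t1$sd))

  allmiss <- domain_table(tibble::tibble(USUBJID = c("S1", "S2"),
                                         AGE = c("x", NA)), "DM")
  t0 <- summarize_continuous(allmiss, "AGE", analysis_population(allmiss, NULL))
  expect_equal(t0$n, 0)
  expect_true(is.na(t0$mean))
})

test_that("continuous summaries match an independent two-pass computation on 500 lab values", {
  g <- generate_study(study_recipe(n_subjects = 40, seed = 55))
  lb <- g$batch$domains$LB
  pop <- analysis_population(g$batch$domains$DM, "ARM")
  tab <- summarize_continuous(lb, "LBORRES", pop)
  arm <- g$truth$arm
  vals <- as.numeric(lb$LBORRES)
  for (i in seq_len(nrow(tab))) {
    v <- vals[arm[lb$USUBJID] == tab$group[i]]
    # two-pass: mean first, then squared deviations
    m <- sum(v) / length(v)
    s <- sqrt(sum((v - m)^2) / (length(v) - 1))
    expect_equal(tab$mean[i], m, tolerance = 1e-12)
    expect_equal(tab$sd[i], s, tolerance = 1e-12)
    expect_equal(tab$n[i], length(v))
  }
  expect_gt(sum(tab$n), 500)
})

test_that("treatment-emergent flagging uses the dosing window inclusively", {
  ex <- domain_table(tibble::tibble(
    USUBJID = c("S1", "S2"),
    EXTRT = "DRUG", EXSTDTC = c("2025-01-10", "2025-01-12"),
    EXENDTC = c("2025-02-10", "2025-02-12")), "EX")
  ae <- domain_table(tibble::tibble(
    USUBJID = c("S1", "S1", "S1", "S2", "S3"),
    AESEQ = as.character(1:5),
    AEDECOD = "X", AEBODSYS = "Y", AESEV = "MILD",
    AESTDTC = c("2025-01-10",   # = first dose -> TRUE
                "2025-01-09",   # day before  -> FALSE
                "2025-03-20",   # beyond last dose + 30 -> FALSE
                "",             # missing -> conservative TRUE
                "2025-01-15"),  # no exposure -> FALSE + warning
    AEENDTC = NA_character_), "AE")
  expect_warning(out <- flag_treatment_emergent(ae, ex, lag_days = 30),
                 "without exposure")
  expect_equal(out$teae, c(TRUE, FALSE, FALSE, TRUE, FALSE))
  expect_true(out$onset_imputed[4])
})

test_that("treatment-emergent flags equal generator ground truth", {
  g <- generate_study(study_recipe(n_subjects = 60, seed = 31,
                                   pre_treatment_ae_rate = 0.3))
  out <- flag_treatment_emergent(g$batch$domains$AE, g$batch$domains$EX)
  truth <- g$truth$ae
  key <- paste(out$USUBJID, out$AESEQ)
  tkey <- paste(truth$USUBJID, truth$AESEQ)
  expect_setequal(key, tkey)
  expect_equal(out$teae, truth$teae[match(key, tkey)])
  expect_gt(sum(!truth$teae), 0)  # the scenario includes pre-dose AEs
})

test_that("AE summary counts each subject once at worst severity", {
  ae <- tiny_ae()  # S1 has MILD and SEVERE HEADACHE
  pop <- tiny_pop(grouped = FALSE)
  tab <- summarize_ae(ae, pop)
  ht <- tab[!is.na(tab$pt) & tab$pt == "HEADACHE" & is.na(tab$severity), ]
  expect_equal(ht$n_subjects, 1)
  expect_equal(ht$n_events, 2)
  sev <- tab[!is.na(tab$pt) & tab$pt == "HEADACHE" & !is.na(tab$severity), ]
  expect_equal(sev$severity[sev$n_subjects > 0], "SEVERE")

  # two subjects, disjoint PTs, same SOC
  ae2 <- domain_table(tibble::tibble(
    USUBJID = c("S1", "S2"), AESEQ = c("1", "1"),
    AEDECOD = c("HEADACHE", "DIZZINESS"), AEBODSYS = "NERVOUS",
    AESEV = c("MILD", "MILD"), AESTDTC = NA_character_), "AE")
  t2 <- summarize_ae(ae2, pop)
  soc <- t2[t2$soc == "NERVOUS" & is.na(t2$pt), ]
  expect_equal(soc$n_subjects, 2)

  # empty filtered table -> zero-count "Any event" row
  t0 <- summarize_ae(ae[0, ], pop)
  expect_equal(t0$soc, "Any event")
  expect_equal(t0$n_subjects, 0)
})

test_that("AE summary equals brute-force per-subject max-severity tabulation", {
  g <- generate_study(study_recipe(n_subjects = 50, seed = 99, ae_rate = 0.5))
  ae <- g$batch$domains$AE
  pop <- analysis_population(g$batch$domains$DM, "ARM")
  tab <- summarize_ae(ae, pop)
  arm <- g$truth$arm
  sevrank <- c(MILD = 1, MODERATE = 2, SEVERE = 3)
  df <- data.frame(subj = ae$USUBJID, soc = ae$AEBODSYS, pt = ae$AEDECOD,
                   sev = ae$AESEV, grp = arm[ae$USUBJID],
                   stringsAsFactors = FALSE)
  for (i in seq_len(nrow(tab))) {
    r <- tab[i, ]
    sub <- df[df$grp == r$group, ]
    if (r$soc != "Any event") sub <- sub[sub$soc == r$soc, ]
    if (!is.na(r$pt)) sub <- sub[sub$pt == r$pt, ]
    if (!is.na(r$severity)) {
      worst <- tapply(sevrank[sub$sev], sub$subj, max)
      expect_equal(r$n_subjects,
                   sum(worst == sevrank[r$severity]), info = paste(r, collapse = "/"))
      expect_equal(r$n_events, sum(sub$sev == r$severity))
    } else {
      expect_equal(r$n_subjects, length(unique(sub$subj)))
      expect_equal(r$n_events, nrow(sub))
      expect_equal(r$pct, 100 * r$n_subjects / sum(arm == r$group))
    }
    expect_setequal(r$subjects[[1]],
                    if (!is.na(r$severity)) {
                      worst <- tapply(sevrank[sub$sev], sub$subj, max)
                      names(worst)[worst == sevrank[r$severity]]
                    } else unique(sub$subj))
  }
})

test_that("'Any event' equals the subject-set union and children sum to parents", {
  set.seed(2024)
  for (trial in 1:25) {
    n_ae <- sample(5:40, 1)
    subj <- sprintf("S%02d", sample(1:15, n_ae, replace = TRUE))
    ae <- domain_table(tibble::tibble(
      USUBJID = subj, AESEQ = as.character(seq_len(n_ae)),
      AEDECOD = sample(c("P1", "P2", "P3", "P4"), n_ae, replace = TRUE),
      AEBODSYS = NA_character_, AESEV = sample(c("MILD", "MODERATE", "SEVERE"),
                                               n_ae, replace = TRUE),
      AESTDTC = NA_character_), "AE")
    ae$AEBODSYS <- ifelse(ae$AEDECOD %in% c("P1", "P2"), "SOC1", "SOC2")
    pop <- tibble::tibble(subject_id = sprintf("S%02d", 1:15), group = "All")
    tab <- summarize_ae(ae, pop)
    any_row <- tab[tab$soc == "Any event", ]
    expect_equal(any_row$n_subjects, length(unique(subj)))
    # SOC rows equal PT subject-set unions
    for (soc in unique(ae$AEBODSYS)) {
      soc_row <- tab[tab$soc == soc & is.na(tab$pt), ]
      pts <- tab[tab$soc == soc & !is.na(tab$pt) & is.na(tab$severity), ]
      expect_equal(soc_row$n_subjects,
                   length(unique(unlist(pts$subjects))))
      # severity children partition each PT's subjects
      for (pt in unique(pts$pt)) {
        parent <- tab[!is.na(tab$pt) & tab$pt == pt & is.na(tab$severity), ]
        kids <- tab[!is.na(tab$pt) & tab$pt == pt & !is.na(tab$severity), ]
        expect_equal(sum(kids$n_subjects), parent$n_subjects)
      }
    }
  }
})

test_that("disposition summary counts discontinuations with a linked listing", {
  ds <- domain_table(tibble::tibble(
    USUBJID = sprintf("S%02d", 1:10),
    DSDECOD = c(rep("COMPLETED", 8), "ADVERSE EVENT", "WITHDRAWAL BY SUBJECT"),
    DSTERM = c(rep("COMPLETED", 8), "ADVERSE EVENT", "WITHDRAWAL BY SUBJECT"),
    DSSTDTC = "2025-03-01"), "DS")
  pop <- tibble::tibble(subject_id = sprintf("S%02d", 1:10), group = "All")
  tab <- summarize_disposition(ds, pop)
  disc <- tab[tab$status == "Discontinued", ]
  expect_equal(disc$n_subjects, 2)
  expect_equal(disc$pct, 20)
  listing <- attr(tab, "listing")
  expect_equal(nrow(listing), 2)
  expect_setequal(listing$reason, c("ADVERSE EVENT", "WITHDRAWAL BY SUBJECT"))

  none <- domain_table(tibble::tibble(
    USUBJID = c("S1", "S2"), DSDECOD = "COMPLETED", DSTERM = "COMPLETED",
    DSSTDTC = NA_character_), "DS")
  t0 <- summarize_disposition(none, tibble::tibble(subject_id = c("S1", "S2"),
                                                   group = "All"))
  expect_equal(t0$n_subjects[t0$status == "Discontinued"], 0)
  expect_equal(t0$pct[t0$status == "Discontinued"], 0)
  expect_equal(nrow(attr(t0, "listing")), 0)
})

test_that("disposition listing equals generator ground truth", {
  g <- generate_study(study_recipe(n_subjects = 50, seed = 13,
                                   dropout_hazard = 0.15))
  pop <- analysis_population(g$batch$domains$DM, "ARM")
  ref <- tibble::tibble(subject_id = g$batch$domains$DM$USUBJID,
                        reference_date = g$batch$domains$DM$RFSTDTC)
  tab <- summarize_disposition(g$batch$domains$DS, pop, reference_dates = ref)
  listing <- attr(tab, "listing")
  truth <- g$truth$disposition[g$truth$disposition$status == "Discontinued", ]
  expect_setequal(listing$subject_id, truth$USUBJID)
  expect_equal(listing$reason,
               truth$reason[match(listing$subject_id, truth$USUBJID)])
  expect_equal(listing$study_day,
               truth$last_day[match(listing$subject_id, truth$USUBJID)])
})

test_that("previous-batch columns are the identical computation on the old batch", {
  g <- generate_study(study_recipe(n_subjects = 20, seed = 41))
  dm <- g$batch$domains$DM
  pop <- analysis_population(dm, "ARM")
  cur <- summarize_ae(g$batch$domains$AE, pop)
  compute <- function(b) summarize_ae(b$domains$AE,
                                      analysis_population(b$domains$DM, "ARM"))
  same <- attach_previous_batch(cur, g$batch, compute)
  expect_equal(same$prev_n_subjects, same$n_subjects)
  expect_equal(same$prev_n_events, same$n_events)
  expect_equal(same$prev_pct, same$pct)

  # previous batch lacking one PT -> empty previous cells for that row
  prev <- g$batch
  ae_df <- tibble::as_tibble(prev$domains$AE)
  drop_pt <- ae_df$AEDECOD[1]
  prev$domains$AE <- domain_table(ae_df[ae_df$AEDECOD != drop_pt, ], "AE")
  with_prev <- attach_previous_batch(cur, prev, compute)
  gone <- with_prev[!is.na(with_prev$pt) & with_prev$pt == drop_pt &
                      is.na(with_prev$severity) & with_prev$n_subjects > 0, ]
  expect_true(all(is.na(gone$prev_n_subjects)))

  # previous batch missing the domain entirely -> current intact, marked
  prev2 <- g$batch
  prev2$domains$AE <- NULL
  unav <- attach_previous_batch(cur, prev2, compute)
  expect_false(attr(unav, "previous_available"))
  expect_equal(unav$n_subjects, cur$n_subjects)
})

test_that("exports round-trip values, reject unknown formats, and link subjects", {
  dm <- tiny_dm()
  tab <- summarize_categorical(dm, "SEX", tiny_pop())
  td <- withr::local_tempdir()
  csv <- file.path(td, "t.csv")
  export_table(tab, "csv", csv)
  back <- readr::read_csv(csv, show_col_types = FALSE)
  expect_equal(nrow(back), nrow(tab))
  expect_equal(back$n_subjects, tab$n_subjects)
  expect_equal(back$pct, round(tab$pct, 1))

  expect_error(export_table(tab, "xlsx", file.path(td, "t.x")),
               "supported")

  # header-only export for an empty listing
  empty <- tibble::tibble(subject_id = character(), reason = character())
  export_table(empty, "csv", file.path(td, "e.csv"))
  expect_equal(nrow(readr::read_csv(file.path(td, "e.csv"),
                                    show_col_types = FALSE)), 0)

  # interactive payload carries one link target per cell subject
  idx <- setNames(paste0("profiles/", dm$USUBJID, ".svg"), dm$USUBJID)
  json <- file.path(td, "t.json")
  export_table(tab, "interactive_html_data", json, link_index = idx)
  payload <- jsonlite::read_json(json)
  n_links <- sum(lengths(payload$cell_subjects))
  expect_equal(n_links, sum(lengths(tab$subjects)))
  first <- payload$cell_subjects[[1]][[1]]
  expect_equal(first$profile, unname(idx[first$subject_id]))

  # static document paginates with a repeated header
  doc <- file.path(td, "t.txt")
  export_table(tab, "static_doc", doc, page_rows = 2)
  lines <- readLines(doc)
  expect_gte(sum(grepl("^Page ", lines)), 2)
})

test_that("pooling unblinded arm counts reproduces the blinded single column", {
  g <- generate_study(study_recipe(n_subjects = 40, seed = 17))
  dm <- g$batch$domains$DM
  unb <- summarize_ae(g$batch$domains$AE, analysis_population(dm, "ARM"))
  bl <- summarize_ae(g$batch$domains$AE, analysis_population(dm, NULL))
  pooled <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(unb), .data$soc, .data$pt, .data$severity),
    n_subjects = sum(.data$n_subjects), n_events = sum(.data$n_events),
    .groups = "drop")
  merged <- dplyr::inner_join(
    pooled, tibble::as_tibble(bl)[, c("soc", "pt", "severity", "n_subjects",
                                      "n_events")],
    by = c("soc", "pt", "severity"), suffix = c("_pooled", "_blinded"))
  expect_equal(nrow(merged), nrow(bl))
  expect_equal(merged$n_subjects_pooled, merged$n_subjects_blinded)
  expect_equal(merged$n_events_pooled, merged$n_events_blinded)
})
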
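# Chart data products and the coupled-table contract.

test_that("visit attendance counts distinct subjects per visit and arm", {
  sv <- domain_table(tibble::tibble(
    USUBJID = c("S1", "S2", "S3", "S4", "S1", "S1"),
    VISITNUM = c("1", "1", "1", "1", "2", "2"),
    VISIT = c(rep("VISIT 1", 4), "VISIT 2", "VISIT 2"),
    SVSTDTC = NA_character_), "SV")
  pop <- tiny_pop(grouped = FALSE)
  p <- visit_attendance(sv, pop)
  v1 <- p$series[p$series$visit == "VISIT 1", ]
  expect_equal(v1$n_subjects, 4)
  # duplicate SV rows at a visit count once
  v2 <- p$series[p$series$visit == "VISIT 2", ]
  expect_equal(v2$n_subjects, 1)
})

test_that("visit attendance equals the generator's dropout schedule", {
  g <- generate_study(study_recipe(n_subjects = 80, seed = 19,
                                   dropout_hazard = 0.2))
  pop <- analysis_population(g$batch$domains$DM, NULL)
  p <- visit_attendance(g$batch$domains$SV, pop)
  truth <- g$truth$attendance
  got <- setNames(p$series$n_subjects, p$series$visit)
  for (i in seq_len(nrow(truth))) {
    if (truth$n_subjects[i] > 0)
      expect_equal(unname(got[truth$visit[i]]), truth$n_subjects[i])
  }
  # zero dropout: everyone attends every visit
  g0 <- generate_study(study_recipe(n_subjects = 15, seed = 20,
                                    dropout_hazard = 0))
  p0 <- visit_attendance(g0$batch$domains$SV,
                         analysis_population(g0$batch$domains$DM, NULL))
  expect_true(all(p0$series$n_subjects == 15))
})

test_that("AE hierarchy nodes follow the union and conservation rules", {
  pop <- tibble::tibble(subject_id = c("S1", "S2"), group = "All")
  one <- domain_table(tibble::tibble(
    USUBJID = "S1", AESEQ = "1", AEDECOD = "HEADACHE",
    AEBODSYS = "NERVOUS", AESEV = "MILD", AESTDTC = NA_character_), "AE")
  h1 <- ae_hierarchy(one, pop)
  expect_equal(nrow(h1$series), 2)  # one SOC + one PT
  expect_true(all(h1$series$n_subjects == 1))
  expect_true(all(h1$series$worst_severity_rank == 1))

  two <- domain_table(tibble::tibble(
    USUBJID = c("S1", "S1"), AESEQ = c("1", "2"),
    AEDECOD = c("HEADACHE", "DIZZINESS"), AEBODSYS = "NERVOUS",
    AESEV = c("MILD", "SEVERE"), AESTDTC = NA_character_), "AE")
  h2 <- ae_hierarchy(two, pop)
  soc <- h2$series[h2$series$level == "SOC", ]
  expect_equal(soc$n_subjects, 1)   # same subject counted once
  expect_equal(soc$n_events, 2)
  expect_equal(soc$worst_severity_rank, 3)
})

test_that("AE hierarchy equals brute-force set computation on a 50-subject study", {
  g <- generate_study(study_recipe(n_subjects = 50, seed = 23, ae_rate = 0.5))
  ae <- g$batch$domains$AE
  pop <- analysis_population(g$batch$domains$DM, NULL)
  h <- ae_hierarchy(ae, pop)
  sevrank <- c(MILD = 1, MODERATE = 2, SEVERE = 3)
  for (i in seq_len(nrow(h$series))) {
    node <- h$series[i, ]
    sel <- if (node$level == "SOC") ae$AEBODSYS == node$label else
      ae$AEDECOD == node$label & ae$AEBODSYS == node$parent
    expect_equal(node$n_subjects, length(unique(ae$USUBJID[sel])))
    expect_equal(node$n_events, sum(sel))
    expect_equal(node$worst_severity_rank, max(sevrank[ae$AESEV[sel]]))
    expect_equal(node$pct, 100 * node$n_subjects / 50)
  }
  # conservation: total event count equals filtered AE record count
  expect_equal(sum(h$series$n_events[h$series$level == "SOC"]), nrow(ae))
  expect_equal(sum(h$series$n_events[h$series$level == "PT"]), nrow(ae))
  # SOC subject unions
  for (soc in unique(ae$AEBODSYS)) {
    socn <- h$series[h$series$level == "SOC" & h$series$label == soc, ]
    pts <- h$series[h$series$level == "PT" & h$series$parent == soc, ]
    expect_equal(socn$n_subjects, length(unique(unlist(pts$subjects))))
  }
})

test_that("eDish places subjects by peak post-baseline ULN multiples", {
  pop <- tibble::tibble(subject_id = c("S1", "S2"), group = "All")
  lb <- domain_table(tibble::tibble(
    USUBJID = rep(c("S1", "S2"), each = 4),
    LBTESTCD = rep(c("ALT", "ALT", "BILI", "BILI"), 2),
    LBORRES = c("40", "35", "1.2", "1.0",   # S1 peaks at exactly ULN
                "160", "100", "3.6", "2.0"),  # S2: 4 x ULN ALT, 3 x ULN BILI
    LBORNRHI = rep(c("40", "40", "1.2", "1.2"), 2),
    LBDY = as.character(rep(c(15, 29), 4))), "LB")
  p <- edish(lb, pop)
  s1 <- p$series[p$series$subject_id == "S1", ]
  expect_equal(s1$alt_uln, 1); expect_equal(s1$bili_uln, 1)
  expect_equal(s1$quadrant, "normal")
  s2 <- p$series[p$series$subject_id == "S2", ]
  expect_equal(s2$alt_uln, 4); expect_equal(s2$bili_uln, 3)
  expect_equal(s2$quadrant, "hys_law")
})

test_that("eDish is invariant to record order and recovers the injected case", {
  g <- generate_study(study_recipe(n_subjects = 40, seed = 37))
  inj <- inject_case(g$batch, "hys_law")
  lb <- add_study_day(inj$batch$domains$LB, g$batch$domains$DM, "LBDTC", "LBDY")
  pop <- analysis_population(g$batch$domains$DM, NULL)
  p <- edish(lb, pop)
  hys <- p$series[p$series$quadrant == "hys_law", ]
  expect_equal(hys$subject_id, inj$descriptor$subject_id)

  shuffled <- lb[sample(nrow(lb)), ]
  p2 <- edish(shuffled, pop)
  expect_equal(p2$series, p$series)
})

test_that("spaghetti data emits per-subject polylines with subset filtering", {
  pop <- tibble::tibble(subject_id = "S1", group = "All")
  lb <- domain_table(tibble::tibble(
    USUBJID = "S1", LBTESTCD = "ALT",
    LBORRES = c("20", "25", "30"), LBORNRLO = "7", LBORNRHI = "40",
    LBDY = c("1", "15", "29")), "LB")
  p <- spaghetti_data(lb, "ALT", pop)
  expect_equal(nrow(p$series), 3)
  expect_equal(p$series$day, c(1, 15, 29))

  # no abnormal values -> empty payload under the abnormal subset rule
  p2 <- spaghetti_data(lb, "ALT", pop, subset_rule = "abnormal")
  expect_equal(nrow(p2$series), 0)
})

test_that("aggregated spaghetti means equal per-visit continuous summaries", {
  g <- generate_study(study_recipe(n_subjects = 30, seed = 47))
  dm <- g$batch$domains$DM
  lb <- add_study_day(g$batch$domains$LB, dm, "LBDTC", "LBDY")
  pop <- analysis_population(dm, "ARM")
  p <- spaghetti_data(lb, "ALT", pop)
  agg <- p$params$aggregate
  for (i in sample(nrow(agg), 8)) {
    sub <- lb[lb$LBTESTCD == "ALT" & lb$VISIT == agg$visit[i], ]
    grp_pop <- pop[pop$group == agg$group[i], ]
    cs <- summarize_continuous(sub, "LBORRES", grp_pop)
    cs <- cs[cs$group == agg$group[i], ]
    expect_equal(agg$mean[i], cs$mean, tolerance = 1e-12)
    expect_equal(agg$n[i], cs$n)
  }
})

test_that("shift data classifies baseline vs worst post-baseline", {
  pop <- tibble::tibble(subject_id = c("S1", "S2"), group = "All")
  lb <- domain_table(tibble::tibble(
    USUBJID = c("S1", "S1", "S1", "S2", "S2"),
    LBTESTCD = "ALT",
    LBORRES = c("20", "22", "25",   # S1: all normal
                "20", "55"),        # S2: normal baseline, high post
    LBORNRLO = "7", LBORNRHI = "40",
    LBDY = c("1", "15", "29", "1", "15")), "LB")
  p <- shift_data(lb, "ALT", pop)
  tab <- p$series
  expect_equal(tab$n_subjects[tab$baseline == "normal" & tab$post == "normal"], 1)
  expect_equal(tab$n_subjects[tab$baseline == "normal" & tab$post == "high"], 1)

  # no baseline record -> margin
  lb2 <- domain_table(tibble::tibble(
    USUBJID = "S1", LBTESTCD = "ALT", LBORRES = "20",
    LBORNRLO = "7", LBORNRHI = "40", LBDY = "15"), "LB")
  p2 <- shift_data(lb2, "ALT", tibble::tibble(subject_id = "S1", group = "All"))
  expect_equal(p2$series$baseline, "no baseline")
})

test_that("shift cross-tabs equal brute-force classification on a synthetic cohort", {
  g <- generate_study(study_recipe(n_subjects = 40, seed = 53))
  dm <- g$batch$domains$DM
  lb <- add_study_day(g$batch$domains$LB, dm, "LBDTC", "LBDY")
  pop <- analysis_population(dm, "ARM")
  p <- shift_data(lb, "ALT", pop)
  # brute force in base R
  sub <- lb[lb$LBTESTCD == "ALT", ]
  df <- data.frame(s = sub$USUBJID, d = as.numeric(sub$LBDY),
                   v = as.numeric(sub$LBORRES),
                   lo = as.numeric(sub$LBORNRLO), hi = as.numeric(sub$LBORNRHI))
  cls <- function(v, lo, hi) ifelse(v > hi, "high", ifelse(v < lo, "low", "normal"))
  per <- lapply(split(df, df$s), function(x) {
    b <- x[x$d <= 1, ]; pz <- x[x$d > 1, ]
    bl <- if (nrow(b) == 0) "no baseline" else cls(b$v, b$lo, b$hi)[which.max(b$d)]
    rank <- c(normal = 0, low = 1, high = 2)
    po <- if (nrow(pz) == 0) "no post-baseline" else
      names(rank)[match(max(rank[cls(pz$v, pz$lo, pz$hi)]), rank)]
    c(bl, po)
  })
  arm <- g$truth$arm
  oracle <- table(group = arm[names(per)],
                  baseline = vapply(per, `[`, "", 1),
                  post = vapply(per, `[`, "", 2))
  for (i in seq_len(nrow(p$series))) {
    r <- p$series[i, ]
    expect_equal(r$n_subjects,
                 unname(oracle[r$group, r$baseline, r$post]))
  }
  expect_equal(sum(p$series$n_subjects), sum(oracle))
})

test_that("every chart series is reconstructible from its backing table", {
  g <- generate_study(study_recipe(n_subjects = 25, seed = 71))
  dm <- g$batch$domains$DM
  lb <- add_study_day(g$batch$domains$LB, dm, "LBDTC", "LBDY")
  pop <- analysis_population(dm, "ARM")
  payloads <- list(
    visit_attendance(g$batch$domains$SV, pop),
    ae_hierarchy(g$batch$domains$AE, pop),
    edish(lb, pop),
    spaghetti_data(lb, "ALT", pop),
    shift_data(lb, "ALT", pop))
  for (p in payloads) {
    re <- series_from_backing(p)
    shared <- intersect(names(p$series), names(re))
    a <- dplyr::arrange(p$series[shared], dplyr::across(dplyr::everything()))
    b <- dplyr::arrange(re[shared], dplyr::across(dplyr::everything()))
    expect_equal(as.data.frame(a), as.data.frame(b), info = p$kind)
  }
})
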
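# Config loading, schema validation, chapter rendering, assembly,
# blinded-vs-unblinded identity.

test_that("configs load with defaults merged and strict key checking", {
  td <- withr::local_tempdir()
  cfg <- load_config(minimal_config_file(file.path(td, "c.yml")))
  expect_s3_class(cfg, "report_config")
  expect_equal(cfg$study$study_id, "SYN01")
  expect_gt(length(cfg$chapters), 0)  # defaults filled in
  expect_false(isTRUE(cfg$settings$blinded))

  # typo'd top-level key is fatal and named
  writeLines(c("study:", "  study_id: X", "chapterz: []"),
             file.path(td, "typo.yml"))
  expect_error(load_config(file.path(td, "typo.yml")), "chapterz")

  # YAML syntax error reports the file
  writeLines(c("study:", "  study_id: [unclosed"), file.path(td, "bad.yml"))
  expect_error(load_config(file.path(td, "bad.yml")), "YAML error")

  # packaged blinded default loads with no treatment variable in settings
  writeLines(c("study:", "  study_id: X", "settings:", "  blinded: true"),
             file.path(td, "bl.yml"))
  bl <- load_config(file.path(td, "bl.yml"))
  expect_true(bl$settings$blinded)
  expect_null(bl$settings$treatment_var)
})

test_that("chapter parameters validate for presence and type with named failures", {
  schema <- read_template_schema("demographics")
  ok <- validate_chapter_params(list(dataset = "DM",
                                     categorical_vars = list("SEX")), schema)
  expect_true(attr(ok, "valid"))

  missing <- validate_chapter_params(list(categorical_vars = list("SEX")),
                                     schema)
  expect_false(attr(missing, "valid"))
  expect_match(missing$message[!missing$passed], "dataset")

  wrong <- validate_chapter_params(list(dataset = 5), schema)
  expect_false(attr(wrong, "valid"))
  bad <- wrong[!wrong$passed, ]
  expect_match(bad$message, "dataset")
  expect_match(bad$message, "string")

  en <- validate_chapter_params(list(dataset = "LB", parameters = list("ALT"),
                                     subset_rule = "everything"),
                                read_template_schema("labs"))
  expect_false(attr(en, "valid"))
  expect_match(en$message[!en$passed], "subset_rule")
})

test_that("the validator agrees with an independent checker on fuzzed parameter maps", {
  # independent brute-force checker for the draft-07 subset used here
  indep_check <- function(params, schema) {
    for (r in unlist(schema$required))
      if (is.null(params[[r]])) return(FALSE)
    for (p in names(schema$properties)) {
      if (is.null(params[[p]])) next
      v <- params[[p]]; sch <- schema$properties[[p]]
      t <- sch$type
      ok <- switch(t,
        string = is.character(v) && length(v) == 1,
        boolean = is.logical(v) && length(v) == 1,
        integer = is.numeric(v) && length(v) == 1 && v == floor(v),
        number = is.numeric(v) && length(v) == 1,
        # a YAML scalar is indistinguishable from a one-element sequence, so
        # an array accepts a scalar whose type matches the items schema
        array = is.list(v) || length(v) > 1 ||
          (length(v) == 1 && identical(sch$items$type, "string") &&
             is.character(v)),
        TRUE)
      if (!ok) return(FALSE)
      if (!is.null(sch$enum) && length(v) == 1 && !is.list(v) &&
          !(as.character(v) %in% unlist(sch$enum))) return(FALSE)
    }
    TRUE
  }
  schema <- read_template_schema("labs")
  pool <- list("DM", "LB", 5L, 2.5, TRUE, list("ALT", "BILI"), "abnormal",
               "everything", list())
  set.seed(11)
  for (i in 1:100) {
    params <- list()
    for (p in c("dataset", "parameters", "edish", "subset_rule", "alt_code")) {
      if (runif(1) < 0.7) params[[p]] <- pool[[sample(length(pool), 1)]]
    }
    got <- attr(validate_chapter_params(params, schema), "valid")
    expect_equal(got, indep_check(params, schema),
                 info = paste(deparse(params), collapse = ""))
  }
})

make_report_fixture <- function(td, n = 8, seed = 101) {
  g <- generate_study(study_recipe(n_subjects = n, seed = seed))
  write_batch(g$batch, file.path(td, "data"))
  cfg <- load_config(minimal_config_file(file.path(td, "c.yml")))
  list(g = g, cfg = cfg, data_dir = file.path(td, "data"))
}

test_that("chapters render standalone HTML with embedded payloads", {
  td <- withr::local_tempdir()
  fx <- make_report_fixture(td)
  out <- file.path(td, "report")
  m <- run_report(fx$cfg, fx$data_dir, out)
  expect_true(attr(m, "ok"))
  html <- readLines(file.path(out, "demographics.html"))
  expect_true(any(grepl("application/json", html)))
  expect_true(any(grepl("SEX", html)))
  expect_true(any(grepl(m$digest, html)))  # report id visible on the page
  # standalone: no external asset references
  expect_false(any(grepl("src=\"http|href=\"http", html)))
})

test_that("a failing chapter is contained and siblings still render", {
  td <- withr::local_tempdir()
  fx <- make_report_fixture(td)
  cfg <- fx$cfg
  cfg$chapters <- c(cfg$chapters, list(list(
    template = "labs", output = "broken",
    params = list(dataset = "ZZ", parameters = list("ALT")))))
  m <- run_report(cfg, fx$data_dir, file.path(td, "rep"))
  expect_false(attr(m, "ok"))
  st <- vapply(m$chapters, function(ch) ch$status, character(1))
  ids <- vapply(m$chapters, function(ch) ch$id, character(1))
  expect_equal(st[ids == "broken"], "failed")
  expect_true(all(st[ids != "broken"] == "ok"))
  err_page <- readLines(file.path(td, "rep", "broken.html"))
  expect_true(any(grepl("Chapter failed", err_page)))
  idx <- readLines(file.path(td, "rep", "index.html"))
  expect_true(any(grepl("failed", idx)))
})

test_that("schema violations abort the chapter with a named-parameter error", {
  td <- withr::local_tempdir()
  fx <- make_report_fixture(td)
  cfg <- fx$cfg
  cfg$chapters <- list(list(template = "demographics", output = "demog",
                            params = list(dataset = 5)))
  m <- run_report(cfg, fx$data_dir, file.path(td, "rep"))
  expect_false(attr(m, "ok"))
  page <- readLines(file.path(td, "rep", "demog.html"))
  expect_true(any(grepl("dataset", page)))
  expect_true(any(grepl("string", page)))
})

test_that("every intra-report hyperlink resolves on disk", {
  td <- withr::local_tempdir()
  fx <- make_report_fixture(td)
  out <- file.path(td, "report")
  run_report(fx$cfg, fx$data_dir, out)
  for (f in list.files(out, pattern = "\\.html$", full.names = TRUE)) {
    html <- paste(readLines(f), collapse = "\n")
    hrefs <- regmatches(html, gregexpr('href="[^"]+"', html))[[1]]
    hrefs <- sub('^href="', "", sub('"$', "", hrefs))
    hrefs <- hrefs[!grepl("^(http|#|mailto)", hrefs)]
    for (h in hrefs)
      expect_true(file.exists(file.path(out, h)),
                  info = sprintf("%s -> %s", basename(f), h))
  }
})

test_that("rebuilds from identical inputs give identical artifacts; digest is input-determined", {
  td <- withr::local_tempdir()
  fx <- make_report_fixture(td, n = 5, seed = 103)
  o1 <- file.path(td, "r1"); o2 <- file.path(td, "r2")
  m1 <- run_report(fx$cfg, fx$data_dir, o1)
  m2 <- run_report(fx$cfg, fx$data_dir, o2)
  expect_equal(m1$digest, m2$digest)
  arts <- setdiff(list.files(o1, recursive = TRUE), "manifest.json")
  expect_setequal(arts, setdiff(list.files(o2, recursive = TRUE), "manifest.json"))
  for (a in arts)
    expect_identical(readLines(file.path(o1, a), warn = FALSE),
                     readLines(file.path(o2, a), warn = FALSE), info = a)
})

test_that("blinded and unblinded runs differ only by the treatment split", {
  td <- withr::local_tempdir()
  fx <- make_report_fixture(td, n = 12, seed = 107)
  res <- run_blinded_vs_unblinded(fx$cfg, fx$data_dir, file.path(td, "rep"))
  expect_true(attr(res$blinded, "ok"))
  expect_true(attr(res$unblinded, "ok"))

  # demography table: unblinded has one column per arm, blinded exactly one
  read_payloads <- function(dir, file) {
    html <- paste(readLines(file.path(dir, file), warn = FALSE), collapse = "\n")
    m <- regmatches(html, gregexpr(
      '<script type="application/json"[^>]*>.*?</script>', html))[[1]]
    lapply(m, function(s) jsonlite::fromJSON(
      sub("</script>$", "", sub('^<script[^>]*>', "", s)),
      simplifyVector = FALSE))
  }
  pb <- read_payloads(file.path(td, "rep", "blinded"), "demographics.html")
  pu <- read_payloads(file.path(td, "rep", "unblinded"), "demographics.html")
  groups_of <- function(p) unique(vapply(p$rows, function(r) r$group, character(1)))
  expect_equal(groups_of(pb[[1]]), "All")
  expect_equal(sort(groups_of(pu[[1]])), c("Active", "Placebo"))

  # pooled unblinded counts equal the blinded single column
  cnt <- function(p) {
    out <- list()
    for (r in p$rows)
      out[[paste(r$level_label)]] <- (out[[paste(r$level_label)]] %||% 0) +
        r$n_subjects
    out
  }
  `%||%` <- function(x, y) if (is.null(x)) y else x
  expect_equal(cnt(pu[[1]]), cnt(pb[[1]]))

  # treatment variable appears nowhere in the blinded output
  files <- list.files(file.path(td, "rep", "blinded"), recursive = TRUE,
                      full.names = TRUE)
  files <- files[grepl("\\.(html|svg|json)$", files)]
  for (f in files)
    expect_false(any(grepl("\\bARM\\b", readLines(f, warn = FALSE))), info = f)
})
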
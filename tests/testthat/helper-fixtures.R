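# Shared fixtures built in code.

tiny_dm <- function() {
  domain_table(tibble::tibble(
    USUBJID = c("S1", "S2", "S3", "S4"),
    AGE = c("34", "51", "67", "45"),
    SEX = c("M", "M", "F", "F"),
    ARM = c("A", "B", "A", "B"),
    RFSTDTC = c("2025-01-10", "2025-01-12", "2025-01-15", "2025-01-20")),
    "DM")
}

tiny_ae <- function() {
  domain_table(tibble::tibble(
    USUBJID = c("S1", "S1", "S2", "S3"),
    AESEQ = c("1", "2", "1", "1"),
    AEDECOD = c("HEADACHE", "HEADACHE", "NAUSEA", "RASH"),
    AEBODSYS = c("NERVOUS", "NERVOUS", "GI", "SKIN"),
    AESEV = c("MILD", "SEVERE", "MODERATE", "MILD"),
    AESTDTC = c("2025-01-12", "2025-01-20", "2025-01-13", "2025-01-16"),
    AEENDTC = c("2025-01-14", NA, NA, "2025-01-18")),
    "AE")
}

tiny_pop <- function(grouped = TRUE) {
  dm <- tiny_dm()
  analysis_population(dm, if (grouped) "ARM" else NULL)
}

fixture_dir <- function(batch = "batch2025q1") {
  system.file("extdata", "fixture01", batch, package = "safetyreview")
}

minimal_config_file <- function(path, extra = character()) {
  writeLines(c("study:", "  study_id: SYN01", extra), path)
  path
}

# independent tabulation helpers used as oracles (base R only, no package code)
brute_count_distinct <- function(subject, level, group) {
  df <- unique(data.frame(subject, level, group, stringsAsFactors = FALSE))
  as.data.frame(table(level = df$level, group = df$group),
                stringsAsFactors = FALSE)
}
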
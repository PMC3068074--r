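test_that("parse_tnm handles full, partial and malformed stage strings", {
  full <- parse_tnm("T2cN0M0")
  expect_s3_class(full, "clinical_stage")
  expect_equal(full$t_category, "T2c")
  expect_equal(full$n_category, "N0")
  expect_equal(full$m_category, "M0")

  bare <- parse_tnm("T1c")
  expect_equal(bare$t_category, "T1c")
  expect_equal(bare$n_category, "NX")
  expect_equal(bare$m_category, "MX")

  expect_equal(parse_tnm("t2bn1mx")$t_category, "T2b")  # case-insensitive

  for (bad in c("T9N0M0", "T2x", "T1cN2M0", "T1cN0M3", "N0M0", "stageII")) {
    expect_error(parse_tnm(bad), class = "psakit_data_error")
  }
  expect_error(parse_tnm(""), class = "psakit_data_error")
})

test_that("parse_tnm is total over the enumerated T/N/M grid", {
  t_cats <- c("T1a", "T1b", "T1c", "T2a", "T2b", "T2c", "T3a", "T3b", "T4")
  for (t in t_cats) for (n in c("N0", "N1", "NX")) for (m in c("M0", "M1", "MX")) {
    parsed <- parse_tnm(paste0(t, n, m))
    expect_identical(unlist(unclass(parsed), use.names = FALSE), c(t, n, m))
  }
})

test_that("parse_gleason covers pattern pairs, bare sums and ranges", {
  g <- parse_gleason("4+3")
  expect_equal(g$primary, 4L)
  expect_equal(g$secondary, 3L)
  expect_equal(g$sum_set, 7L)

  r <- parse_gleason("5-6")
  expect_true(is.na(r$primary))
  expect_equal(r$sum_set, c(5L, 6L))

  expect_equal(parse_gleason("5+5")$sum_set, 10L)
  expect_equal(parse_gleason("7")$sum_set, 7L)

  # exhaustive: all pattern pairs land on the pair sum
  for (a in 1:5) for (b in 1:5) {
    expect_equal(parse_gleason(paste0(a, "+", b))$sum_set, a + b)
  }

  for (bad in c("0+3", "6+1", "4+6", "1", "11", "1-1", "9-11", "7-5", "abc")) {
    expect_error(parse_gleason(bad), class = "psakit_data_error")
  }
})

test_that("Gleason pattern pairs span sums 2..10 exactly", {
  sums <- unique(c(outer(1:5, 1:5, `+`)))
  expect_setequal(sums, 2:10)
})

test_that("read_cohort joins files by patient id and sorts measurements", {
  dir <- write_cohort_csvs(
    tempfile(),
    psa_lines = c("P2,2010-07-01,5.2",
                  "P1,2011-01-01,6.0",
                  "P1,2010-01-01,4.0",
                  "P2,2010-01-01,4.8",
                  "P1,2010-07-01,5.0"),
    staging_lines = c("P1,T2aN0M0,3+4,35,18", "P2,T1c,5-6,,"),
    treatment_lines = "P1,surgery,2011-02-01,6.0")
  cohort <- read_cohort(file.path(dir, "psa.csv"),
                        file.path(dir, "staging.csv"),
                        file.path(dir, "treatments.csv"))
  expect_length(cohort, 2)
  p1 <- cohort[[which(vapply(cohort, `[[`, "", "patient_id") == "P1")]]
  expect_equal(p1$psa_series$measurements$psa, c(4.0, 5.0, 6.0))
  expect_true(!is.unsorted(p1$psa_series$measurements$date))
  expect_equal(p1$stage$t_category, "T2a")
  expect_equal(p1$gleason$sum_set, 7L)
  expect_equal(p1$prostate_volume, 35)
  expect_equal(p1$life_expectancy, 18)
  expect_length(p1$treatments, 1)
  expect_equal(p1$treatments[[1]]$modality, "surgery")

  p2 <- cohort[[which(vapply(cohort, `[[`, "", "patient_id") == "P2")]]
  expect_equal(p2$stage$n_category, "NX")
  expect_true(is.na(p2$prostate_volume))
  expect_length(p2$treatments, 0)
})

test_that("read_cohort rejects duplicates, unknown columns and bad dates", {
  dir <- write_cohort_csvs(tempfile(),
                           psa_lines = c("P1,2010-01-01,4.0",
                                         "P1,2010-01-01,5.0"))
  expect_error(read_cohort(file.path(dir, "psa.csv")),
               "duplicate", class = "psakit_data_error")

  dir2 <- tempfile(); dir.create(dir2)
  writeLines(c("patient_id,date,psa_ng_ml,extra", "P1,2010-01-01,4,1"),
             file.path(dir2, "psa.csv"))
  expect_error(read_cohort(file.path(dir2, "psa.csv")),
               "unknown column", class = "psakit_data_error")

  dir3 <- write_cohort_csvs(tempfile(),
                            psa_lines = "P1,01/02/2010,4.0")
  expect_error(read_cohort(file.path(dir3, "psa.csv")),
               "unparseable", class = "psakit_data_error")
})

test_that("an empty PSA file yields an empty cohort", {
  dir <- write_cohort_csvs(tempfile(), psa_lines = character(0))
  cohort <- read_cohort(file.path(dir, "psa.csv"))
  expect_length(cohort, 0)
})

test_that("write_cohort then read_cohort is the identity on valid cohorts", {
  sim <- simulate_cohort(sim_params(n_patients = 10, seed = 7))
  dir <- tempfile()
  paths <- write_cohort(sim$cohort, dir)
  back <- read_cohort(paths[1], paths[2], paths[3])
  expect_length(back, 10)
  for (i in seq_along(back)) {
    a <- sim$cohort[[i]]; b <- back[[i]]
    expect_identical(b$patient_id, a$patient_id)
    expect_equal(b$psa_series$measurements$date, a$psa_series$measurements$date)
    expect_equal(b$psa_series$measurements$psa, a$psa_series$measurements$psa)
    expect_identical(unclass(b$stage), unclass(a$stage))
    expect_equal(b$gleason$sum_set, a$gleason$sum_set)
    expect_equal(b$prostate_volume, a$prostate_volume)
    expect_equal(b$life_expectancy, a$life_expectancy)
    expect_equal(length(b$treatments), length(a$treatments))
    expect_equal(b$treatments[[1]]$date, a$treatments[[1]]$date)
    expect_equal(b$treatments[[1]]$pre_treatment_psa,
                 a$treatments[[1]]$pre_treatment_psa)
  }
})

test_that("absent staging fields round-trip to absent", {
  series <- psa_series("P9", c("2010-01-01", "2010-06-01"), c(4, 5))
  rec <- patient_record("P9", series)   # no stage/gleason/volume
  dir <- tempfile()
  paths <- write_cohort(structure(list(rec), class = "psa_cohort"), dir)
  back <- read_cohort(paths[1], paths[2], paths[3])[[1]]
  expect_null(back$stage)
  expect_null(back$gleason)
  expect_true(is.na(back$prostate_volume))
  expect_true(is.na(back$life_expectancy))
})
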
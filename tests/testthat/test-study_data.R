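test_that("embedded evidence table has the published shape and values", {
  fix <- table2_fixture()
  expect_named(fix, c("diabetes", "hypertension", "cardiovascular_disease",
                      "respiratory_disease", "chronic_kidney_disease"))
  ks <- vapply(fix, function(d) nrow(d$studies), integer(1))
  expect_equal(unname(ks), c(9L, 8L, 6L, 6L, 5L))

  dia <- fix$diabetes$studies
  expect_equal(dia$y[1], 3.63)                  # Bhaskaran, mortality
  expect_equal(dia$vi[2], 0.04)                 # Boulle printed variance
  expect_equal(fix$respiratory_disease$studies$vi[2], 0.22)  # Dandachi
  expect_equal(fix$chronic_kidney_disease$studies$y[5], 0.22)  # Meyerowitz

  for (d in fix) {
    expect_true(all(d$studies$sigma > 0))
    expect_gte(nrow(d$studies), 1)
    expect_equal(anyDuplicated(d$studies$study_label), 0)
  }
})

test_that("printed variance column is consistent with the printed CIs", {
  # ((ci_high - ci_low) / (2 * 1.96))^2 must reproduce the printed variance
  # for every one of the 34 rows -- identifying the column as a variance, and
  # the CIs as y +/- 1.96 * sigma within rounding
  for (d in table2_fixture()) {
    st <- d$studies
    se_ci <- se_from_ci(st$ci_low, st$ci_high)
    expect_lt(max(abs(se_ci - st$sigma)), 0.02)
    # and the CIs are centred on y (within 2-decimal rounding of the bounds)
    expect_lt(max(abs((st$ci_low + st$ci_high) / 2 - st$y)), 0.011)
  }
})

test_that("CSV round-trip is lossless and readers validate input", {
  fix <- table2_fixture()
  path <- withr::local_tempfile(fileext = ".csv")
  write_studies(fix, path, schema = "effects")
  back <- read_studies(path, schema = "effects")
  expect_named(back, names(fix))
  for (nm in names(fix)) {
    expect_identical(back[[nm]]$studies$study_label,
                     fix[[nm]]$studies$study_label)
    expect_identical(back[[nm]]$studies$y, fix[[nm]]$studies$y)
    expect_identical(back[[nm]]$studies$sigma, fix[[nm]]$studies$sigma)
  }

  # a 2-row effects CSV parses into one dataset with two studies
  p2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("comorbidity,study_label,year,country,sample_size,outcome_type,log_or,se",
               "diabetes,A,2020,X,100,mortality,0.5,0.2",
               "diabetes,B,2021,Y,50,hospitalization,0.1,0.4"), p2)
  ds <- read_studies(p2, schema = "effects")
  expect_length(ds, 1)
  expect_equal(nrow(ds$diabetes$studies), 2)

  # missing column is named in the error; sigma = 0 is rejected with its row
  p3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("comorbidity,study_label,year,country,sample_size,outcome_type,log_or",
               "diabetes,A,2020,X,100,mortality,0.5"), p3)
  expect_error(read_studies(p3, schema = "effects"), "se")
  p4 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("comorbidity,study_label,year,country,sample_size,outcome_type,log_or,se",
               "diabetes,A,2020,X,100,mortality,0.5,0.2",
               "diabetes,B,2021,Y,50,hospitalization,0.1,0"), p4)
  expect_error(read_studies(p4, schema = "effects"), "row.*2")
})

test_that("counts schema recomputes effects and round-trips", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(paste("comorbidity,study_label,events_exposed,nonevents_exposed,",
                     "events_comparator,nonevents_comparator", sep = ""),
               "sim,A,20,80,10,90",
               "sim,B,5,45,8,42"), p)
  ds <- read_studies(p, schema = "counts")
  st <- ds$sim$studies
  expect_equal(st$y[1], log(20 * 90 / (80 * 10)))
  expect_equal(st$sigma[1], sqrt(1/20 + 1/80 + 1/10 + 1/90))
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_studies(ds, p2, schema = "counts")
  back <- read_studies(p2, schema = "counts")
  expect_equal(back$sim$studies$y, st$y)
})

test_that("study_effects enforces its invariants", {
  expect_error(study_effects(c("A", "A"), c(0, 1), c(0.1, 0.2)), "unique")
  expect_error(study_effects("A", 0, 0), "sigma")
  expect_error(study_effects("A", 0, 0.5, outcome_type = "icu"), "outcome_type")
  # counts must agree with y/sigma to 1e-12
  lor <- log_odds_ratio(20, 80, 10, 90)
  expect_silent(study_effects("A", lor$y, lor$sigma,
                              a = 20, b = 80, c = 10, d = 90))
  expect_error(study_effects("A", lor$y + 1e-6, lor$sigma,
                             a = 20, b = 80, c = 10, d = 90), "counts")
})
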
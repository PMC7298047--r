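test_that("cohort summaries count patients once per drug with a strict age cutoff", {
  rec <- data.frame(
    patient_id = c("p1", "p2", "p3", "p3"),
    age = c(35, 50, 70, 70),
    drug = c("D", "D", "D", "D"),
    glaucoma = c(0, 1, 0, 0), stringsAsFactors = FALSE)
  co <- summarize_cohorts(rec, "D")
  expect_equal(unlist(co[, -1]),
               c(n_total = 3, g_total = 1, n_over40 = 2, g_over40 = 1))
  # drug never prescribed: all-zero cohort
  co0 <- summarize_cohorts(rec, c("D", "absent"))
  expect_equal(unlist(co0[2, -1]),
               c(n_total = 0, g_total = 0, n_over40 = 0, g_over40 = 0))
  # age exactly at the cutoff is excluded
  rec40 <- data.frame(patient_id = "p9", age = 40, drug = "D", glaucoma = 0)
  expect_equal(summarize_cohorts(rec40, "D")$n_over40, 0L)
  # inconsistent glaucoma flags are an error naming the patient
  bad <- data.frame(patient_id = c("p1", "p1"), age = c(50, 50),
                    drug = c("D", "E"), glaucoma = c(0, 1))
  expect_error(summarize_cohorts(bad, "D"), "p1")
})

test_that("prevalence reproduces the published cohort proportions", {
  expect_equal(signif(prevalence(5, 4594), 3), 1.09e-3)
  expect_equal(signif(prevalence(16, 5358), 3), 2.99e-3)
  expect_equal(prevalence(0, 435), 0)
  expect_equal(prevalence(0, 0), 0)
  expect_error(prevalence(5, 4), "exceeds")
})

test_that("small cohorts rescale to the assumed comparison size", {
  bg <- background_model()
  expect_equal(adjust_cohort(242, 0, bg)[c("adjusted_n", "adjusted_g", "scaled")],
               list(adjusted_n = 1000, adjusted_g = 0, scaled = TRUE))
  expect_equal(adjust_cohort(4397, 5, bg)[c("adjusted_n", "adjusted_g", "scaled")],
               list(adjusted_n = 4397, adjusted_g = 5, scaled = FALSE))
  a <- adjust_cohort(564, 2, bg)
  expect_equal(a$adjusted_g, 2 * 1000 / 564, tolerance = 1e-12)
  expect_true(a$scaled)
  # empty cohort scales to zero events
  z <- adjust_cohort(0, 0, bg)
  expect_equal(z$adjusted_g, 0)
  expect_true(z$zero_event)
  # identity at or above the assumed size (scaling invariance)
  expect_false(adjust_cohort(1000, 3, bg)$scaled)
})

test_that("screening a cohort reproduces the published P and odds ratio", {
  celecoxib <- list(drug = "celecoxib", n_total = 1719, g_total = 1,
                    n_over40 = 1488, g_over40 = 1)
  r <- screen_drug(celecoxib)
  expect_equal(r$p_value, 1.74e-3, tolerance = 0.01)
  expect_equal(signif(r$odds_ratio, 2), 0.067)
  theo <- list(drug = "theophylline", n_total = 4594, g_total = 5,
               n_over40 = 4397, g_over40 = 5)
  expect_equal(signif(screen_drug(theo)$odds_ratio, 3), 0.113)
  # zero events: OR 0 with the zero_event flag
  cyt <- list(drug = "cytarabine", n_total = 435, g_total = 0,
              n_over40 = 242, g_over40 = 0)
  rc <- screen_drug(cyt)
  expect_equal(rc$odds_ratio, 0)
  expect_match(rc$flags, "zero_event")
  expect_match(rc$flags, "scaled")
  # all-event cohort: OR undefined
  ru <- screen_drug(list(drug = "x", n_total = 5, g_total = 5,
                         n_over40 = 5, g_over40 = 5))
  expect_true(is.na(ru$odds_ratio))
  expect_match(ru$flags, "or_undefined")
  # empty over-40 stratum: p from the scaled all-zero cohort
  r0 <- screen_drug(list(drug = "caffeine", n_total = 3, g_total = 0,
                         n_over40 = 0, g_over40 = 0))
  expect_equal(r0$p_value, chi_squared(c(0, 1000, 10, 990))$p.value)
  expect_match(r0$flags, "zero_event")
})

test_that("odds ratio rises with events and matches the over-40 prevalence", {
  bg <- background_model()
  ors <- vapply(0:19, function(g)
    screen_drug(list(drug = "d", n_total = 2000, g_total = g,
                     n_over40 = 2000, g_over40 = g), bg)$odds_ratio,
    numeric(1))
  expect_true(all(diff(ors) > 0))
  r <- screen_drug(list(drug = "d", n_total = 2500, g_total = 9,
                        n_over40 = 2000, g_over40 = 7), bg)
  expect_equal(r$prevalence_over40, 7 / 2000)
})

test_that("screening all drugs composes cohorts and sorts by p-value", {
  emr <- nine_drug_cohort_fixture()
  res <- screen_all(emr, sort(unique(emr$drug)))
  expect_equal(nrow(res), 9L)
  expect_false(is.unsorted(res$p_value))
  expect_equal(res$drug[1], "theophylline")
  one <- screen_all(emr, "aspirin")
  expect_equal(nrow(one), 1L)
  expect_equal(one$g_over40, 13)
  expect_equal(nrow(screen_all(emr, character())), 0L)
  # duplicate exposure rows do not change counts
  res2 <- screen_all(rbind(emr, emr[1:50, ]), sort(unique(emr$drug)))
  expect_equal(res2, res)
})

test_that("EMR reader validates the schema and flags", {
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(nine_drug_cohort_fixture()[1:20, ], f, row.names = FALSE)
  rec <- read_emr(f)
  expect_named(rec, c("patient_id", "age", "drug", "glaucoma"))
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("patient_id,age,drug,glaucoma", "p1,50,D,2"), bad)
  expect_error(read_emr(bad), "0 or 1")
})
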
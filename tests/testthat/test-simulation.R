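test_that("NPE is the exact sum of absolute benefits and doubles on duplication", {
  pop <- fixture_population(size = 100, seed = 6)
  res <- run_effect_model(pop, disease_params(), therapy_config())
  expect_identical(res$npe, sum(res$outcomes$ab))
  expect_identical(res$outcomes$ab, res$outcomes$rc - res$outcomes$rt)

  pop2 <- rbind(pop, transform(pop, subject_id = subject_id + 100L))
  class(pop2) <- class(pop)
  res2 <- run_effect_model(pop2, disease_params(), therapy_config())
  expect_identical(res2$npe, 2 * res$npe)
})

test_that("harm splits the population into harmed low-risk and helped high-risk", {
  pop <- fixture_population(size = 300, seed = 12)
  res <- run_effect_model(pop, disease_params(),
                          therapy_config(harm = 0.04))
  o <- res$outcomes
  expect_gt(sum(o$ab < 0), 0)
  expect_gt(sum(o$ab > 0), 0)
  # net harm concentrates at low untreated risk
  expect_lt(median(o$rc[o$ab < 0]), median(o$rc[o$ab > 0]))
  # rt never exceeds 1 even with harm added
  expect_true(all(o$rt <= 1))
})

test_that("effect curve bins means correctly and validates input", {
  o <- data.frame(rc = seq(0.1, 0.9, length.out = 100))
  o$rt <- 0.5 * o$rc + 0.02
  curve <- effect_curve(o, n_bins = 10)
  expect_true(all(abs(curve$mean_rt - (0.5 * curve$rc_mid + 0.02)) <
                    0.5 * diff(range(o$rc)) / 10))
  same <- data.frame(rc = rep(0.3, 5), rt = rep(0.1, 5))
  expect_equal(nrow(effect_curve(same, 10)), 1L)
  expect_error(effect_curve(o, 1), "n_bins")
})

test_that("shape classifier labels the five canonical shapes", {
  rc <- seq(0.05, 0.9, length.out = 30)
  # generated from the published one-year antiarrhythmic line
  lin_thr <- data.frame(rc = rc, rt = 0.56 * rc + 0.053)
  expect_equal(classify_shape(lin_thr), "linear_with_threshold")

  origin <- data.frame(rc = rc, rt = 0.7 * rc)
  expect_equal(classify_shape(origin), "linear_through_origin")

  curv <- data.frame(rc = rc, rt = closed_form_rt(rc, 1.5))
  expect_equal(classify_shape(curv), "curvilinear")

  lower <- data.frame(rc = rc, rt = closed_form_rt(rc, 1.0) + 0.05)
  expect_equal(classify_shape(lower), "curvilinear_lower_threshold")

  rc2 <- seq(0.02, 0.98, length.out = 30)
  both <- data.frame(rc = rc2, rt = rc2 + 0.025 - 0.5 * rc2 * (1 - rc2))
  expect_equal(classify_shape(both), "curvilinear_both_thresholds")
})

test_that("shape classifier is invariant to shuffling and on-curve points", {
  rc <- seq(0.05, 0.9, length.out = 30)
  curv <- data.frame(rc = rc, rt = closed_form_rt(rc, 1.0) + 0.05)
  base <- classify_shape(curv)
  set.seed(3)
  shuffled <- curv[sample(nrow(curv)), ]
  expect_equal(classify_shape(shuffled), base)
  extra_rc <- runif(10, 0.05, 0.9)
  augmented <- rbind(curv, data.frame(rc = extra_rc,
                                      rt = closed_form_rt(extra_rc, 1.0) +
                                        0.05))
  expect_equal(classify_shape(augmented), base)
})

test_that("shape classifier enforces its preconditions", {
  few <- data.frame(rc = c(0.1, 0.5, 0.9), rt = c(0.1, 0.4, 0.8))
  expect_error(classify_shape(few), "at least 5")
  narrow <- data.frame(rc = seq(0.4, 0.5, length.out = 10),
                       rt = seq(0.3, 0.4, length.out = 10))
  expect_error(classify_shape(narrow), "range")
})

test_that("bootstrap NPE interval is seeded, reproducible and sane", {
  pop <- fixture_population(size = 150, seed = 9)
  dis <- disease_params()
  th <- therapy_config()
  i1 <- npe_prediction_interval(pop, dis, th, n_resamples = 500, seed = 11)
  i2 <- npe_prediction_interval(pop, dis, th, n_resamples = 500, seed = 11)
  expect_identical(i1, i2)
  expect_lt(i1[1], attr(i1, "npe"))
  expect_gt(i1[2], attr(i1, "npe"))
  expect_error(npe_prediction_interval(pop, dis, th, n_resamples = 50),
               ">= 100")
})

test_that("a population of identical subjects gives a zero-width interval", {
  one <- unit_subject()
  clones <- one[rep(1, 30), ]
  clones$subject_id <- 1:30
  iv <- npe_prediction_interval(clones, disease_params(), therapy_config(),
                                n_resamples = 200, seed = 5)
  expect_equal(iv[1], iv[2], tolerance = 1e-12)
  expect_equal(iv[1], attr(iv, "npe"), tolerance = 1e-12)
})

test_that("result writers export consistent CSV and JSON artifacts", {
  pop <- fixture_population(size = 60, seed = 10)
  res <- run_effect_model(pop, disease_params(), therapy_config())
  res$npe_interval <- npe_prediction_interval(pop, disease_params(),
                                              therapy_config(),
                                              n_resamples = 200, seed = 2)
  dir <- withr::local_tempdir()
  write_outcomes(res, file.path(dir, "out.csv"))
  write_effect_curve(res, file.path(dir, "curve.csv"))
  write_result_summary(res, file.path(dir, "sum.json"), seed = 2)
  out <- utils::read.csv(file.path(dir, "out.csv"))
  expect_equal(nrow(out), 60L)
  expect_equal(sum(out$ab), res$npe, tolerance = 1e-10)
  js <- jsonlite::read_json(file.path(dir, "sum.json"), simplifyVector = TRUE)
  expect_equal(js$npe, res$npe, tolerance = 1e-12)
  expect_equal(js$seed, 2)
  expect_length(js$npe_interval, 2L)
})
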
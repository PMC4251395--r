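test_that("noise-free collinear data are recovered exactly", {
  for (w in list(collinear_pairs(),
                 transform(collinear_pairs(), weight = c(2, 5, 9)))) {
    fit <- fit_effect_model(w)
    expect_equal(unname(coef(fit)), c(0.5, 0.05), tolerance = 1e-12)
    expect_lt(fit$residual_ss, 1e-20)
  }
})

test_that("fitting preconditions are enforced", {
  expect_error(fit_effect_model(collinear_pairs()[1:2, ]), "3 trials")
  flat <- data.frame(rc = rep(0.2, 4), rt = c(0.1, 0.12, 0.11, 0.13))
  expect_error(fit_effect_model(flat), "degenerate")
})

test_that("estimates recover known truth within 2 SE on simulated trials", {
  set.seed(11)
  fit <- fit_effect_model(simulate_trials(40, a = 0.56, b = 0.053,
                                          n_per_arm = 1000))
  expect_lt(abs(coef(fit)["a"] - 0.56), 2 * fit$se["se_a"] + 0.02)
  expect_lt(abs(coef(fit)["b"] - 0.053), 2 * fit$se["se_b"] + 0.005)
})

test_that("natural threshold is b/(1-a) with documented edge cases", {
  expect_equal(natural_threshold(0.56, 0.053), 0.053 / 0.44)
  expect_equal(natural_threshold(0.5, 0), 0)
  expect_equal(natural_threshold(0.5, -0.01), 0)
  expect_true(is.na(natural_threshold(1, 0.02)))
  expect_equal(natural_threshold(1, 0), 0)
  expect_true(is.na(natural_threshold(0.9, 0.5)))  # crossing beyond 1
})

test_that("threshold is the fixed point of the prediction rule", {
  fit <- fit_effect_model(collinear_pairs())
  s <- natural_threshold(fit)
  expect_equal(unname(predict(fit, s)), s, tolerance = 1e-12)
  # fitted line from the one-year antiarrhythmic estimates
  expect_equal(0.56 * 0.053 / 0.44 + 0.053, 0.053 / 0.44, tolerance = 1e-12)
})

test_that("predictions are clipped to [0,1] and reject bad rc", {
  fit <- fit_effect_model(collinear_pairs())
  expect_equal(unname(predict(fit, 0)), 0.05)
  expect_true(all(predict(fit, c(0, 0.5, 1)) >= 0 &
                    predict(fit, c(0, 0.5, 1)) <= 1))
  expect_error(predict(fit, 1.2), "\\[0, 1\\]")
  expect_error(predict(fit, -0.1), "\\[0, 1\\]")
})

test_that("leave-one-out sensitivity brackets the truth and needs >= 4", {
  pairs4 <- data.frame(rc = c(0.1, 0.2, 0.3, 0.4),
                       rt = 0.5 * c(0.1, 0.2, 0.3, 0.4) + 0.05, weight = 1)
  loo <- loo_sensitivity(pairs4)
  expect_equal(loo$a_range, c(0.5, 0.5), tolerance = 1e-10)
  expect_equal(loo$b_range, c(0.05, 0.05), tolerance = 1e-10)
  expect_error(loo_sensitivity(collinear_pairs()), "at least 4")

  set.seed(5)
  loo_sim <- loo_sensitivity(simulate_trials(40))
  expect_true(loo_sim$a_range[1] <= 0.56 + 0.05 &&
                loo_sim$a_range[2] >= 0.56 - 0.05)
})

test_that("polynomial comparison picks the generating complexity", {
  set.seed(21)
  rc <- runif(60, 0.05, 0.9)
  lin <- data.frame(rc = rc, rt = 0.5 * rc + 0.05 + rnorm(60, 0, 0.005),
                    weight = 1)
  expect_equal(compare_polynomial_fits(lin, 3)$best_degree, 1L)

  curv <- data.frame(rc = rc,
                     rt = closed_form_rt(rc, 1.0) + rnorm(60, 0, 0.005),
                     weight = 1)
  expect_gte(compare_polynomial_fits(curv, 3)$best_degree, 2L)

  one <- compare_polynomial_fits(lin, 1)
  expect_equal(one$best_degree, 1L)
  expect_equal(nrow(one$scores), 1L)
})

test_that("polynomial degrees beyond the design are skipped with warning", {
  pairs <- data.frame(rc = c(0.1, 0.2, 0.3, 0.1, 0.2, 0.3),
                      rt = c(0.1, 0.15, 0.2, 0.11, 0.14, 0.21), weight = 1)
  expect_warning(out <- compare_polynomial_fits(pairs, 4), "skipped")
  expect_true(any(out$scores$skipped))
})

test_that("parameter recovery and interval coverage over replicates", {
  # 200 replicate meta-analyses of 40 trials at 1000/arm, truth (0.56, 0.053)
  set.seed(1)
  n_rep <- 200
  est <- matrix(NA_real_, n_rep, 2)
  covered <- matrix(NA, n_rep, 2)
  for (i in seq_len(n_rep)) {
    fit <- fit_effect_model(simulate_trials(40, 0.56, 0.053, 1000))
    est[i, ] <- coef(fit)
    ci <- confint(fit)
    covered[i, ] <- c(ci["a", 1] <= 0.56 & 0.56 <= ci["a", 2],
                      ci["b", 1] <= 0.053 & 0.053 <= ci["b", 2])
  }
  expect_lt(abs(mean(est[, 1]) - 0.56), 0.02)
  expect_lt(abs(mean(est[, 2]) - 0.053), 0.005)
  expect_gte(mean(covered), 0.90)
  expect_lte(mean(covered), 0.99)
})

test_that("small trials attenuate the slope more than large trials", {
  # regression-to-the-mean: same generating model, 50/arm vs 5000/arm
  set.seed(7)
  n_rep <- 60
  bias <- function(n_arm) {
    mean(vapply(seq_len(n_rep), function(i) {
      coef(fit_effect_model(simulate_trials(40, 0.56, 0.053, n_arm)))[["a"]]
    }, numeric(1))) - 0.56
  }
  expect_gt(abs(bias(50)), abs(bias(5000)))
})

test_that("fit report JSON carries estimates, threshold and diagnostics", {
  trials <- read_trial_summaries(fixture_trials_path())
  fit <- fit_effect_model(trials)
  loo <- loo_sensitivity(trials)
  poly <- compare_polynomial_fits(trials, 2)
  tmp <- withr::local_tempfile(fileext = ".json")
  fit_report(fit, tmp, loo = loo, poly = poly)
  rep <- jsonlite::read_json(tmp, simplifyVector = TRUE)
  expect_equal(rep$a, unname(coef(fit)["a"]), tolerance = 1e-12)
  expect_equal(rep$threshold, natural_threshold(fit), tolerance = 1e-12)
  expect_length(rep$loo_ranges$a, 2L)
  expect_true(all(c("degree", "score") %in% names(rep$polynomial_scores)))
})
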
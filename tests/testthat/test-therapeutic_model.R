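test_that("single-dose concentration starts at zero and washes out", {
  pk <- pkpd_params(dose = 100, bioavailability_f0 = 0.8, ka = 1, ke0 = 0.1,
                    volume = 50)
  sub <- unit_subject()
  expect_equal(concentration(pk, sub, 0), 0)
  t_half <- log(2) / 0.1
  peak <- max(concentration(pk, sub, seq(0, 24, by = 0.1)))
  expect_lt(concentration(pk, sub, 50 * t_half), 1e-6 * peak)
  expect_error(concentration(pk, sub, -1), ">= 0")
})

test_that("closed-form concentration matches a numerical ODE oracle", {
  # independent route: integrate the gut/central two-state system
  pk <- pkpd_params(dose = 100, bioavailability_f0 = 0.8, ka = 1, ke0 = 0.1,
                    volume = 50)
  sub <- unit_subject(x_age = 50)  # age scaling = 1, ke = 0.1
  times <- seq(0.5, 30, length.out = 20)
  ode_fit <- deSolve::ode(
    y = c(gut = 0.8 * 100, central = 0),
    times = c(0, times),
    func = function(t, y, p) {
      list(c(-p$ka * y["gut"], p$ka * y["gut"] - p$ke * y["central"]))
    },
    parms = list(ka = 1, ke = 0.1),
    rtol = 1e-10, atol = 1e-12
  )
  oracle <- ode_fit[-1, "central"] / 50
  closed <- concentration(pk, sub, times)
  expect_equal(closed, unname(oracle), tolerance = 1e-6)
})

test_that("the ka = ke removable singularity uses the analytic limit", {
  sub <- unit_subject(x_age = 50)
  pk_eq <- pkpd_params(ka = 0.1, ke0 = 0.1)
  pk_near <- pkpd_params(ka = 0.1 * (1 + 1e-12), ke0 = 0.1)
  t <- c(1, 5, 20)
  expect_equal(concentration(pk_eq, sub, t), concentration(pk_near, sub, t),
               tolerance = 1e-9)
  expected <- 0.8 * 100 / 50 * 0.1 * t * exp(-0.1 * t)
  expect_equal(concentration(pk_eq, sub, t), expected, tolerance = 1e-9)
})

test_that("Hill stimulus hits its landmarks", {
  pk <- pkpd_params(gamma = 1, ec50_0 = 2, smax_0 = 1)
  sub <- unit_subject()
  expect_equal(receptor_stimulus(pk, sub, 0), 0)
  expect_equal(receptor_stimulus(pk, sub, 2), 0.5)      # C = EC50
  expect_equal(receptor_stimulus(pk, sub, 6), 0.75)     # C = 3 EC50
  # effective EC50 scales with the binding-gene descriptor
  sub2 <- unit_subject(); sub2$x_binding_genes <- 3
  expect_equal(receptor_stimulus(pk, sub2, 6), 0.5)
  # saturation below the effective maximum
  expect_lt(receptor_stimulus(pk, sub, 1e6), 1)
})

test_that("transduction and feedback behave as documented", {
  sub <- unit_subject()
  pk_off <- pkpd_params(feedback_h = 0, transduction_gain = 1)
  expect_equal(net_effect(pk_off, sub, 1.7), 1.7)
  expect_equal(net_effect(pk_off, sub, 0), 0)
  pk_fb <- pkpd_params(feedback_h = 0.5, transduction_gain = 1)
  expect_equal(net_effect(pk_fb, sub, 2), 2 / (1 + 0.5 * 2))  # = 1
})

test_that("logistic event probability evaluates exactly", {
  sub <- unit_subject(y_biomarker = 1, y_risk_factor = 0)
  dis <- disease_params(beta0 = -2, beta_biomarker = 1, beta_risk_factor = 0)
  expect_equal(event_probability(dis, sub, 0), 1 / (1 + exp(1)))
  dis0 <- disease_params(beta0 = 0, beta_biomarker = 0, beta_risk_factor = 0)
  expect_equal(event_probability(dis0, unit_subject(), 0), 0.5)
  # any positive effect lowers the risk
  expect_lt(event_probability(dis, sub, 0.5), event_probability(dis, sub, 0))
  expect_error(event_probability(dis, sub, -0.1), ">= 0")
})

test_that("closed-form effect model hits its landmarks and bounds", {
  expect_equal(closed_form_rt(0.37, 0), 0.37)
  expect_equal(closed_form_rt(0.5, log(2)), 1 / 3)
  expect_equal(closed_form_rt(0.2, log(2)), 1 / 9)
  expect_equal(closed_form_rt(c(0, 1), 2), c(0, 1))
  rc <- seq(0.01, 0.99, by = 0.01)
  expect_true(all(closed_form_rt(rc, 1) < rc))      # pure benefit
  expect_true(all(diff(closed_form_rt(rc, 1)) > 0)) # increasing in rc
  effs <- seq(0.1, 3, by = 0.1)
  expect_true(all(diff(closed_form_rt(0.3, effs)) < 0)) # decreasing in E
})

test_that("zero dose collapses the whole chain to Rt = Rc", {
  pop <- fixture_population(size = 200, seed = 1)
  dis <- disease_params()
  th0 <- therapy_config(pkpd = pkpd_params(dose = 0))
  res <- run_effect_model(pop, dis, th0)
  expect_identical(res$outcomes$rt, res$outcomes$rc)
  expect_identical(res$outcomes$ab, rep(0, 200))
  expect_identical(res$npe, 0)
})

test_that("chain equals the closed form when feedback is off, unit gain", {
  pop <- fixture_population(size = 50, seed = 4)
  pop$x_transduction <- 1
  dis <- disease_params()
  doses <- seq(5, 400, length.out = 50)
  for (d in doses[c(1, 10, 25, 50)]) {
    pk <- pkpd_params(dose = d, feedback_h = 0, transduction_gain = 1)
    eff <- subject_effect(pk, pop, 24)
    rc <- event_probability(dis, pop, 0)
    rt <- event_probability(dis, pop, eff)
    expect_equal(rt, closed_form_rt(rc, eff), tolerance = 1e-12)
  }
})

test_that("treated risk is nonincreasing in dose for a fixed subject", {
  sub <- unit_subject(y_biomarker = 0.5, y_risk_factor = 0.5)
  dis <- disease_params()
  doses <- seq(0, 500, by = 10)
  rts <- vapply(doses, function(d) {
    th <- therapy_config(pkpd = pkpd_params(dose = d))
    run_effect_model(sub, dis, th)$outcomes$rt
  }, numeric(1))
  expect_true(all(diff(rts) <= 1e-14))
})
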
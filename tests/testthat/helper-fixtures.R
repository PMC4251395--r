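# Shared fixtures, built in code at test time.

fixture_trials_path <- function() {
  system.file("extdata", "synthetic_trials.csv", package = "effectmodel")
}

fixture_config_path <- function() {
  system.file("extdata", "default_config.yaml", package = "effectmodel")
}

fixture_population <- function(size = 200, seed = 1) {
  sample_population(default_population_spec(size = size, seed = seed))
}

# A hand-built subject with every multiplicative descriptor at its
# reference value (useful for exact-arithmetic checks).
unit_subject <- function(x_age = 50, y_biomarker = 0, y_risk_factor = 0,
                         x_sympathetic = 1) {
  data.frame(subject_id = 1L, x_absorption = 1, x_age = x_age,
             x_emax_genes = 1, x_binding_genes = 1, x_transduction = 1,
             x_sympathetic = x_sympathetic, y_biomarker = y_biomarker,
             y_risk_factor = y_risk_factor)
}

# Exactly collinear risk pairs on rt = 0.5 rc + 0.05.
collinear_pairs <- function() {
  data.frame(rc = c(0.10, 0.20, 0.30), rt = c(0.10, 0.15, 0.20), weight = 1)
}

# Mean slope/intercept over replicate simulated meta-analyses with known
# generating parameters (the parameter-recovery harness).
recover_mean_coefs <- function(n_rep, n_trials = 40, a = 0.56, b = 0.053,
                               n_per_arm = 1000,
                               weighting = "inverse_variance") {
  est <- vapply(seq_len(n_rep), function(i) {
    coef(fit_effect_model(simulate_trials(n_trials, a = a, b = b,
                                          n_per_arm = n_per_arm),
                          weighting = weighting))
  }, numeric(2))
  rowMeans(est)
}
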
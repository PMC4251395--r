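#' Pharmacokinetic-pharmacodynamic chain parameters
#'
#' Parameters of the six-step therapeutic chain (absorption, distribution,
#' drug-receptor interaction, transduction, homeostatic feedback, clinical
#' transduction) for one drug. Reference values are scaled per subject by
#' the X descriptors: absorption by `x_absorption`, elimination by age,
#' maximal stimulus by `x_emax_genes`, binding (EC50) by `x_binding_genes`,
#' transduction gain by `x_transduction` and feedback strength by
#' `x_sympathetic`.
#'
#' @param dose Administered dose (mass units, e.g. mg); 0 switches the drug
#'   off entirely.
#' @param bioavailability_f0 Reference oral bioavailability in (0, 1].
#' @param ka First-order absorption rate constant (1/h).
#' @param ke0 Reference elimination rate constant (1/h); a subject's
#'   elimination is `ke0 * clamp(x_age / 50, 0.5, 2)`.
#' @param volume Apparent distribution volume (L); one-compartment model.
#' @param gamma Hill coefficient (> 0) of the concentration-stimulus curve.
#' @param ec50_0 Reference half-effect concentration (> 0); the effective
#'   EC50 is `ec50_0 * x_binding_genes`.
#' @param smax_0 Reference maximal stimulus (> 0); effective maximum is
#'   `smax_0 * x_emax_genes`.
#' @param transduction_gain Gain of post-receptor signal transduction (> 0).
#' @param feedback_h Homeostatic feedback strength (>= 0); 0 disables the
#'   feedback loop.
#' @return A list of class `"pkpd_params"`.
#' @export
pkpd_params <- function(dose = 100, bioavailability_f0 = 0.8, ka = 1.0,
                        ke0 = 0.1, volume = 50, gamma = 1.5, ec50_0 = 0.5,
                        smax_0 = 2, transduction_gain = 1, feedback_h = 0.2) {
  p <- list(dose = dose, bioavailability_f0 = bioavailability_f0, ka = ka,
            ke0 = ke0, volume = volume, gamma = gamma, ec50_0 = ec50_0,
            smax_0 = smax_0, transduction_gain = transduction_gain,
            feedback_h = feedback_h)
  for (nm in c("ka", "ke0", "volume", "gamma", "ec50_0", "smax_0",
               "transduction_gain")) {
    if (!is_num1(p[[nm]]) || p[[nm]] <= 0) stop_user(nm, " must be > 0")
  }
  if (!is_num1(p$dose) || p$dose < 0) stop_user("dose must be >= 0")
  if (!is_num1(p$bioavailability_f0) || p$bioavailability_f0 <= 0 ||
      p$bioavailability_f0 > 1) {
    stop_user("bioavailability_f0 must lie in (0, 1]")
  }
  if (!is_num1(p$feedback_h) || p$feedback_h < 0) {
    stop_user("feedback_h must be >= 0")
  }
  structure(p, class = "pkpd_params")
}

#' Logistic disease-model parameters
#'
#' The untreated event probability over the follow-up is
#' `Rc = plogis(beta0 + beta_biomarker * y_biomarker +
#' beta_risk_factor * y_risk_factor)`. The drug lowers the linear predictor
#' by its net pharmacological effect, which yields the treated probability
#' Rt for the same subject.
#'
#' @param beta0 Logistic intercept (baseline log-odds of the event).
#' @param beta_biomarker Coefficient on `y_biomarker`, the disease variable
#'   whose effect on risk the drug modifies.
#' @param beta_risk_factor Coefficient on `y_risk_factor`, untouched by the
#'   drug.
#' @return A list of class `"disease_params"`.
#' @export
disease_params <- function(beta0 = -2, beta_biomarker = 0.8,
                           beta_risk_factor = 0.6) {
  for (v in list(beta0, beta_biomarker, beta_risk_factor)) {
    if (!is_num1(v)) stop_user("disease parameters must be finite numbers")
  }
  structure(list(beta0 = beta0, beta_biomarker = beta_biomarker,
                 beta_risk_factor = beta_risk_factor),
            class = "disease_params")
}

# Elimination scaling with age: proportional to age/50, clamped to [0.5, 2].
age_scaling <- function(age) pmin(pmax(age / 50, 0.5), 2)

#' Plasma concentration of the one-compartment oral model
#'
#' Closed-form concentration after a single oral dose with first-order
#' absorption and elimination:
#' `C(t) = F0 x_abs D ka / (V (ka - ke)) * (exp(-ke t) - exp(-ka t))`
#' with `ke = ke0 * clamp(x_age/50, 0.5, 2)`. The removable singularity at
#' `ka = ke` is evaluated by its analytic limit
#' `C(t) = (F0 x_abs D ka t / V) exp(-ka t)` when `|ka - ke| < 1e-9 ka`.
#'
#' @param params A [pkpd_params()] object.
#' @param subject One subject (a one-row `data.frame` slice of a
#'   [sample_population()] result) or a whole population; descriptor
#'   columns are recycled against `time`.
#' @param time Time since dosing (h), `>= 0`; vectorized.
#' @return Concentration(s), nonnegative.
#' @export
concentration <- function(params, subject, time) {
  if (any(time < 0)) stop_user("time must be >= 0")
  ke <- params$ke0 * age_scaling(subject$x_age)
  fabs <- params$bioavailability_f0 * subject$x_absorption * params$dose /
    params$volume
  ka <- params$ka
  n <- max(length(time), length(ke), length(fabs))
  time <- rep_len(time, n)
  ke <- rep_len(ke, n)
  fabs <- rep_len(fabs, n)
  near <- abs(ka - ke) < 1e-9 * ka
  out <- ifelse(near,
                fabs * ka * time * exp(-ka * time),
                fabs * ka / (ka - ke) * (exp(-ke * time) - exp(-ka * time)))
  pmax(out, 0)
}

#' Average steady-state concentration over one dosing interval
#'
#' For repeated dosing every `tau` hours the mean steady-state concentration
#' is `F0 x_abs D / (V ke tau)`, the standard time-average of the
#' one-compartment model. This is the summary exposure used when computing
#' follow-up risks, which makes Rc and Rt time-free given the regimen.
#'
#' @inheritParams concentration
#' @param tau Dosing interval (h), `> 0`.
#' @return Average concentration(s).
#' @export
steady_state_concentration <- function(params, subject, tau) {
  if (!is_num1(tau) || tau <= 0) stop_user("tau must be > 0")
  ke <- params$ke0 * age_scaling(subject$x_age)
  params$bioavailability_f0 * subject$x_absorption * params$dose /
    (params$volume * ke * tau)
}

#' Receptor stimulus from drug concentration (Hill model)
#'
#' `S = Smax_eff * C^gamma / (EC50_eff^gamma + C^gamma)` with
#' `Smax_eff = smax_0 * x_emax_genes` and
#' `EC50_eff = ec50_0 * x_binding_genes`. `S` is 0 at zero concentration,
#' half of `Smax_eff` at the effective EC50, and saturates below `Smax_eff`.
#'
#' @inheritParams concentration
#' @param conc Drug concentration(s), `>= 0`.
#' @return Stimulus value(s) in `[0, Smax_eff)`.
#' @export
receptor_stimulus <- function(params, subject, conc) {
  if (any(conc < 0)) stop_user("conc must be >= 0")
  smax <- params$smax_0 * subject$x_emax_genes
  ec50 <- params$ec50_0 * subject$x_binding_genes
  cg <- conc^params$gamma
  ifelse(conc == 0, 0, smax * cg / (ec50^params$gamma + cg))
}

#' Net pharmacological effect after transduction and feedback
#'
#' The receptor stimulus is amplified by post-receptor transduction,
#' `Z = transduction_gain * x_transduction * S`, then damped by the
#' homeostatic (sympathetic-drive) feedback loop:
#' `E = Z / (1 + feedback_h * x_sympathetic * Z)`. With the feedback off
#' (`feedback_h = 0`) the effect equals the transduced signal.
#'
#' @inheritParams concentration
#' @param stimulus Receptor stimulus value(s), `>= 0`.
#' @return Net effect(s) `E` with `0 <= E <= Z`.
#' @export
net_effect <- function(params, subject, stimulus) {
  if (any(stimulus < 0)) stop_user("stimulus must be >= 0")
  z <- params$transduction_gain * subject$x_transduction * stimulus
  z / (1 + params$feedback_h * subject$x_sympathetic * z)
}

#' Event probability under the logistic disease model
#'
#' Clinical transduction: the event probability over the follow-up is the
#' logistic of the disease linear predictor minus the drug's net effect,
#' `plogis(beta0 + beta_biomarker * y_biomarker +
#' beta_risk_factor * y_risk_factor - effect)`. `effect = 0` gives the
#' untreated risk Rc, `effect > 0` the treated risk Rt (always below Rc for
#' the same subject).
#'
#' @param disease A [disease_params()] object.
#' @inheritParams concentration
#' @param effect Net pharmacological effect(s), `>= 0`.
#' @return Event probability(ies) in `(0, 1)`.
#' @export
event_probability <- function(disease, subject, effect) {
  if (any(effect < 0)) stop_user("effect must be >= 0")
  lp <- disease$beta0 + disease$beta_biomarker * subject$y_biomarker +
    disease$beta_risk_factor * subject$y_risk_factor
  stats::plogis(lp - effect)
}

#' Run the full chain for each subject at a summary exposure
#'
#' Convenience composition: steady-state average concentration, Hill
#' stimulus, transduction and feedback. Vectorized over the rows of
#' `subject`.
#'
#' @inheritParams concentration
#' @param tau Dosing interval (h).
#' @return Net effect per subject.
#' @export
subject_effect <- function(params, subject, tau) {
  cbar <- steady_state_concentration(params, subject, tau)
  s <- receptor_stimulus(params, subject, cbar)
  net_effect(params, subject, s)
}

#' Closed-form treated risk from untreated risk and net effect
#'
#' The analytic effect model implied by a logistic event probability whose
#' linear predictor is reduced by the Hill-derived effect `E`: multiplying
#' the event odds by `exp(-E)` gives
#' `Rt = Rc / (Rc + (1 - Rc) * exp(E))`.
#' The curve is curvilinear in Rc, fixes the endpoints 0 and 1, is strictly
#' increasing in `Rc` and strictly decreasing in `E`, and lies strictly
#' below the diagonal for `Rc` in (0, 1) and `E > 0` (a pure-benefit model
#' never crosses into net harm; crossing requires an added iatrogenic term).
#' It serves as the exact oracle for the simulated chain when the feedback
#' is off and transduction is unit-gain.
#'
#' @param rc Untreated risk(s) in `[0, 1]`; the boundary values 0 and 1 are
#'   returned unchanged (fixed points).
#' @param effect Net effect(s), `>= 0`.
#' @return Treated risk(s) in `[0, 1]`.
#' @examples
#' closed_form_rt(0.5, log(2))  # odds halved: 1/3
#' @export
closed_form_rt <- function(rc, effect) {
  if (any(rc < 0 | rc > 1)) stop_user("rc must lie in [0, 1]")
  if (any(effect < 0)) stop_user("effect must be >= 0")
  ifelse(rc == 0 | rc == 1, rc, rc / (rc + (1 - rc) * exp(effect)))
}
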
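#' Number needed to treat
#'
#' The reciprocal of the absolute benefit: how many similar patients must
#' be treated over the follow-up to prevent one event. A negative value is
#' a number needed to harm (one extra event caused per `|1/ab|` patients
#' treated). Because AB varies across patients, the NNT inferred from a
#' trial average is not characteristic of a therapy; prefer per-patient AB.
#'
#' @param ab Absolute benefit(s) `Rc - Rt`; must be nonzero.
#' @return `1 / ab`, vectorized.
#' @export
nnt <- function(ab) {
  if (!is.numeric(ab) || any(!is.finite(ab))) {
    stop_user("ab must be finite numeric")
  }
  if (any(ab == 0)) {
    stop_user("NNT is undefined at ab = 0 (no expected benefit or harm)")
  }
  1 / ab
}

#' Compare competing treatments for one patient
#'
#' Predicts the absolute benefit of each candidate therapy for a single
#' subject via the mechanistic chain (all therapies act on the same disease
#' model — one disease/event pair, several treatments) and recommends the
#' treatment with the largest predicted AB, provided it exceeds the
#' decision threshold.
#'
#' @param subject A one-row subject `data.frame` (a slice of a
#'   [sample_population()] result).
#' @param disease A [disease_params()] object shared by all therapies.
#' @param therapies A nonempty list of [therapy_config()] objects; their
#'   follow-up durations must agree, otherwise the ABs are not comparable
#'   and an error is raised.
#' @param threshold Minimum AB required to treat (default 0). Callers can
#'   supply an individually tailored value (e.g. reflecting side-effect
#'   burden scored on the same scale as the outcome).
#' @return A list of class `"decision_report"`: `subject_id`,
#'   `ab_by_treatment` (named numeric), `best_treatment` (label, or
#'   `"none"` when no therapy clears the threshold), `treat` (logical),
#'   `threshold_used` and `tie` (TRUE when the best AB is shared by several
#'   therapies; ties break by label order).
#' @export
compare_treatments <- function(subject, disease, therapies, threshold = 0) {
  if (!is.data.frame(subject) || nrow(subject) != 1L) {
    stop_user("subject must be a single-row data.frame")
  }
  if (!is.list(therapies) || length(therapies) == 0L) {
    stop_user("supply at least one therapy_config")
  }
  if (inherits(therapies, "therapy_config")) therapies <- list(therapies)
  ok <- vapply(therapies, inherits, logical(1), "therapy_config")
  if (!all(ok)) stop_user("therapies must be therapy_config objects")
  fu <- vapply(therapies, `[[`, numeric(1), "followup")
  if (length(unique(fu)) > 1L) {
    stop_user("therapies have different follow-up durations; ",
              "absolute benefits are not comparable")
  }
  labels <- vapply(therapies, `[[`, character(1), "label")
  if (anyDuplicated(labels)) stop_user("therapy labels must be unique")
  ab <- vapply(therapies, function(th) {
    res <- run_effect_model(subject, disease, th, n_bins = 2)
    res$outcomes$ab[1L]
  }, numeric(1))
  names(ab) <- labels
  ord <- order(-ab, labels)
  best_ab <- ab[ord[1L]]
  tie <- sum(abs(ab - best_ab) < 1e-12) > 1L
  treat <- best_ab > threshold
  structure(list(subject_id = subject$subject_id %||% NA_integer_,
                 ab_by_treatment = ab,
                 best_treatment = if (treat) labels[ord[1L]] else "none",
                 treat = treat,
                 threshold_used = threshold,
                 tie = tie),
            class = "decision_report")
}

#' @export
print.decision_report <- function(x, digits = 4, ...) {
  cat(sprintf("Treatment decision for subject %s\n",
              format(x$subject_id)))
  for (lab in names(x$ab_by_treatment)) {
    cat(sprintf("  %-12s AB = %+.*f  (NNT %s)\n", lab, digits,
                x$ab_by_treatment[[lab]],
                if (x$ab_by_treatment[[lab]] == 0) "undefined"
                else format(round(1 / x$ab_by_treatment[[lab]], 1))))
  }
  cat(sprintf("  decision: %s (threshold %.4g)%s\n",
              if (x$treat) paste("treat with", x$best_treatment)
              else "do not treat",
              x$threshold_used,
              if (x$tie) "  [tie broken by label order]" else ""))
  invisible(x)
}

#' Treat/no-treat rule at the natural threshold of a linear effect model
#'
#' Under a linear effect model with `0 < a < 1` and `b > 0`, treatment has
#' positive net efficacy only for patients whose untreated risk exceeds the
#' natural threshold `s = b / (1 - a)`; the rule is strict (a patient
#' exactly at the threshold gains nothing and is not treated).
#'
#' @param subject_rc Untreated risk(s) in `[0, 1]`.
#' @param model A fitted `effect_model` with a diagonal crossing.
#' @return Logical: treat (`TRUE`) iff `subject_rc > s`.
#' @export
natural_threshold_decision <- function(subject_rc, model) {
  if (any(subject_rc < 0 | subject_rc > 1)) {
    stop_user("subject_rc must lie in [0, 1]")
  }
  s <- natural_threshold(model)
  if (is.na(s)) {
    stop_user("the model has no natural threshold in (0, 1); ",
              "use an absolute-benefit rule instead")
  }
  subject_rc > s
}

#' Allocate a fixed treatment budget by predicted absolute benefit
#'
#' With a uniform cost per treated patient, the population benefit under a
#' budget cap is maximized by treating patients in decreasing order of
#' predicted AB until the budget is exhausted — never treating anyone with
#' nonpositive AB, however slack the budget (treatment must beat the
#' zero-benefit floor). The AB of the last patient treated is the
#' operational, externally imposed decision threshold.
#'
#' @param outcomes An `effect_model_result` or its `outcomes` `data.frame`
#'   (`subject_id`, `ab`).
#' @param budget Total budget (currency), `>= 0`.
#' @param unit_cost Cost per treated patient, `> 0`.
#' @return A list of class `"budget_allocation"`: `treated_ids` (ordered by
#'   decreasing AB), `n_treated`, `total_ab`, `marginal_ab` (AB of the last
#'   treated patient, `Inf` when nobody is treated), `budget`, `unit_cost`,
#'   `spend`.
#' @export
allocate_budget <- function(outcomes, budget, unit_cost) {
  if (inherits(outcomes, "effect_model_result")) outcomes <- outcomes$outcomes
  if (!is.data.frame(outcomes) || !all(c("subject_id", "ab") %in%
                                       names(outcomes))) {
    stop_user("outcomes must have subject_id and ab columns")
  }
  if (!is_num1(budget) || budget < 0) stop_user("budget must be >= 0")
  if (!is_num1(unit_cost) || unit_cost <= 0) stop_user("unit_cost must be > 0")
  affordable <- floor(budget / unit_cost)
  ord <- order(-outcomes$ab, outcomes$subject_id)
  ranked <- outcomes[ord, , drop = FALSE]
  eligible <- ranked[ranked$ab > 0, , drop = FALSE]
  n_treated <- min(nrow(eligible), affordable)
  treated <- eligible[seq_len(n_treated), , drop = FALSE]
  structure(list(treated_ids = treated$subject_id,
                 n_treated = n_treated,
                 total_ab = sum(treated$ab),
                 marginal_ab = if (n_treated == 0L) Inf
                   else treated$ab[n_treated],
                 budget = budget, unit_cost = unit_cost,
                 spend = n_treated * unit_cost),
            class = "budget_allocation")
}

#' @export
print.budget_allocation <- function(x, digits = 4, ...) {
  cat(sprintf("Budget allocation: %d patient(s) treated (spend %.4g of %.4g)\n",
              x$n_treated, x$spend, x$budget))
  cat(sprintf("  total expected prevented events: %.*f\n", digits, x$total_ab))
  cat(sprintf("  marginal AB (operational threshold): %s\n",
              if (is.infinite(x$marginal_ab)) "none treated"
              else format(round(x$marginal_ab, digits))))
  invisible(x)
}

#' Export budget-allocation and decision tables
#'
#' @param allocation A `"budget_allocation"`.
#' @param outcomes The outcomes table the allocation was computed from.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_allocation <- function(allocation, outcomes, path) {
  if (inherits(outcomes, "effect_model_result")) outcomes <- outcomes$outcomes
  out <- outcomes[order(-outcomes$ab, outcomes$subject_id), ,
                  drop = FALSE]
  out$treated <- out$subject_id %in% allocation$treated_ids
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
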
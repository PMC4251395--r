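#' Configure one therapy of a disease/event/treatment triplet
#'
#' Bundles the PK-PD chain parameters with the dosing regimen, follow-up
#' duration and an optional constant iatrogenic risk. The harm term is an
#' additive event risk independent of Rc — the mechanistic counterpart of
#' the intercept `b` of the linear effect model — and is applied on top of
#' the pure-benefit chain: `Rt = min(1, Rt_mechanistic + harm)`.
#'
#' @param label Treatment label (the T of the triplet).
#' @param pkpd A [pkpd_params()] object.
#' @param dosing_interval Dosing interval tau (h), `> 0`.
#' @param followup Follow-up duration t (years), `> 0`. Risks are
#'   probabilities over this fixed window; absolute benefits are only
#'   comparable across therapies sharing the same follow-up.
#' @param harm Constant additive event risk in `[0, 1)` caused by the
#'   treatment itself (default 0).
#' @return A list of class `"therapy_config"`.
#' @export
therapy_config <- function(label = "drug", pkpd = pkpd_params(),
                           dosing_interval = 24, followup = 1, harm = 0) {
  if (!inherits(pkpd, "pkpd_params")) stop_user("pkpd must be pkpd_params()")
  if (!is_num1(dosing_interval) || dosing_interval <= 0) {
    stop_user("dosing_interval must be > 0")
  }
  if (!is_num1(followup) || followup <= 0) stop_user("followup must be > 0")
  if (!is_num1(harm) || harm < 0 || harm >= 1) {
    stop_user("harm must lie in [0, 1)")
  }
  structure(list(label = as.character(label), pkpd = pkpd,
                 dosing_interval = dosing_interval, followup = followup,
                 harm = harm),
            class = "therapy_config")
}

#' Simulate the effect model over a virtual population
#'
#' Submits every subject in turn to the disease model alone (untreated risk
#' Rc) and to the therapeutic model (treated risk Rt, including any constant
#' harm term), yielding one `(Rc, Rt, AB)` point per subject on the L'Abbe
#' plane. Both models are deterministic given the subject's descriptors, so
#' all variability in the scatter comes from the population. The number of
#' prevented events is the sum of per-subject absolute benefits; the shape
#' of the binned mean curve is classified into the five canonical
#' representations.
#'
#' @param population A `virtual_population` (see [sample_population()]).
#' @param disease A [disease_params()] object.
#' @param therapy A [therapy_config()] object.
#' @param n_bins Bins for the summary effect curve (default 20).
#' @return An object of class `"effect_model_result"`: a list with
#'   `outcomes` (`subject_id`, `rc`, `rt`, `ab = rc - rt`), `npe`,
#'   `curve` (binned means), `shape`, `natural_threshold` (lowest diagonal
#'   crossing of the binned curve, or `NA`), `therapy` and `disease`.
#' @examples
#' pop <- sample_population(default_population_spec(size = 100, seed = 3))
#' res <- run_effect_model(pop, disease_params(), therapy_config())
#' summary(res)
#' @export
run_effect_model <- function(population, disease, therapy, n_bins = 20) {
  if (!is.data.frame(population) || nrow(population) == 0L) {
    stop_user("population must be a nonempty data.frame of subjects")
  }
  if (!inherits(disease, "disease_params")) {
    stop_user("disease must be disease_params()")
  }
  if (!inherits(therapy, "therapy_config")) {
    stop_user("therapy must be therapy_config()")
  }
  eff <- subject_effect(therapy$pkpd, population, therapy$dosing_interval)
  rc <- event_probability(disease, population, 0)
  rt_mech <- event_probability(disease, population, eff)
  rt <- pmin(1, rt_mech + therapy$harm)
  outcomes <- data.frame(subject_id = population$subject_id,
                         rc = rc, rt = rt, ab = rc - rt)
  curve <- effect_curve(outcomes, n_bins = n_bins)
  shape <- tryCatch(classify_shape(curve),
                    error = function(e) NA_character_)
  structure(list(outcomes = outcomes,
                 npe = sum(outcomes$ab),
                 curve = curve,
                 shape = shape,
                 natural_threshold = diagonal_crossing(curve),
                 npe_interval = NULL,
                 therapy = therapy,
                 disease = disease,
                 n = nrow(outcomes)),
            class = "effect_model_result")
}

#' @export
print.effect_model_result <- function(x, digits = 4, ...) {
  cat(sprintf("Effect model for treatment '%s' over %d subjects\n",
              x$therapy$label, x$n))
  cat(sprintf("  number of prevented events (NPE): %.*f\n", digits, x$npe))
  cat(sprintf("  mean absolute benefit: %.*f\n", digits, x$npe / x$n))
  cat(sprintf("  shape: %s\n", if (is.na(x$shape)) "<not classified>" else
    x$shape))
  if (!is.na(x$natural_threshold)) {
    cat(sprintf("  natural threshold (diagonal crossing): %.*f\n", digits,
                x$natural_threshold))
  }
  if (!is.null(x$npe_interval)) {
    cat(sprintf("  NPE %d%% interval: [%.*f, %.*f]\n",
                round(100 * attr(x$npe_interval, "level")),
                digits, x$npe_interval[1L], digits, x$npe_interval[2L]))
  }
  invisible(x)
}

#' @export
summary.effect_model_result <- function(object, ...) {
  o <- object$outcomes
  structure(list(
    label = object$therapy$label,
    n = object$n,
    npe = object$npe,
    shape = object$shape,
    natural_threshold = object$natural_threshold,
    npe_interval = object$npe_interval,
    rc = stats::quantile(o$rc, c(0, 0.25, 0.5, 0.75, 1)),
    rt = stats::quantile(o$rt, c(0, 0.25, 0.5, 0.75, 1)),
    ab = stats::quantile(o$ab, c(0, 0.25, 0.5, 0.75, 1)),
    n_harmed = sum(o$ab < 0)
  ), class = "summary.effect_model_result")
}

#' @export
print.summary.effect_model_result <- function(x, digits = 4, ...) {
  cat(sprintf("Effect model '%s': %d subjects, NPE = %.*f, shape = %s\n",
              x$label, x$n, digits, x$npe,
              if (is.na(x$shape)) "<not classified>" else x$shape))
  if (x$n_harmed > 0) {
    cat(sprintf("  %d subject(s) with negative absolute benefit (net harm)\n",
                x$n_harmed))
  }
  tab <- rbind(Rc = x$rc, Rt = x$rt, AB = x$ab)
  print(round(tab, digits))
  invisible(x)
}

#' Plot a simulated effect model on the L'Abbe plane
#'
#' @param x An `effect_model_result`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.effect_model_result <- function(x, ...) {
  o <- x$outcomes
  graphics::plot(o$rc, o$rt, xlim = c(0, 1), ylim = c(0, 1), pch = 16,
                 cex = 0.5, col = "steelblue",
                 xlab = "Rc (untreated probability)",
                 ylab = "Rt (treated probability)", ...)
  graphics::abline(0, 1, lty = 2, col = "grey40")
  graphics::lines(x$curve$rc_mid, x$curve$mean_rt, col = "firebrick", lwd = 2)
  invisible(x)
}

#' Binned mean effect curve
#'
#' Averages Rt within equal-width Rc bins over the observed Rc range — the
#' "average value of Rt for each Rc" summary used to read off the shape of
#' an effect model from a subject-level scatter.
#'
#' @param outcomes An `effect_model_result` or its `outcomes` `data.frame`
#'   (columns `rc`, `rt`).
#' @param n_bins Number of equal-width bins (`>= 2`).
#' @return A `data.frame` with `rc_mid`, `mean_rt` and `n` per occupied
#'   bin; empty bins are omitted.
#' @export
effect_curve <- function(outcomes, n_bins = 20) {
  if (inherits(outcomes, "effect_model_result")) outcomes <- outcomes$outcomes
  if (!is.data.frame(outcomes) || nrow(outcomes) == 0L) {
    stop_user("outcomes must be a nonempty data.frame")
  }
  if (!is_count(n_bins) || n_bins < 2) stop_user("n_bins must be >= 2")
  rc <- outcomes$rc
  rng <- range(rc)
  if (diff(rng) == 0) {
    return(data.frame(rc_mid = rng[1L], mean_rt = mean(outcomes$rt),
                      n = nrow(outcomes)))
  }
  breaks <- seq(rng[1L], rng[2L], length.out = n_bins + 1L)
  idx <- findInterval(rc, breaks, rightmost.closed = TRUE)
  mids <- (breaks[-1L] + breaks[-length(breaks)]) / 2
  agg <- tapply(outcomes$rt, idx, mean)
  cnt <- tapply(outcomes$rt, idx, length)
  occupied <- as.integer(names(agg))
  data.frame(rc_mid = mids[occupied], mean_rt = as.numeric(agg),
             n = as.integer(cnt))
}

# Lowest diagonal crossing (rt = rc) of a binned curve, by linear
# interpolation between sign changes of rt - rc; NA when no crossing.
diagonal_crossing <- function(curve) {
  cr <- all_diagonal_crossings(curve)
  if (length(cr) == 0L) NA_real_ else cr[1L]
}

all_diagonal_crossings <- function(curve) {
  rc <- curve[[1L]]
  rt <- curve[[2L]]
  ord <- order(rc)
  rc <- rc[ord]; rt <- rt[ord]
  d <- rt - rc
  out <- numeric(0)
  for (i in seq_len(length(d) - 1L)) {
    if (d[i] == 0) out <- c(out, rc[i])
    if (d[i] * d[i + 1L] < 0) {
      out <- c(out, rc[i] + (rc[i + 1L] - rc[i]) * d[i] / (d[i] - d[i + 1L]))
    }
  }
  if (length(d) > 0L && d[length(d)] == 0) out <- c(out, rc[length(d)])
  unique(out)
}

#' Classify the shape of an effect-model curve
#'
#' Assigns one of the five canonical representations of an effect model:
#' a straight line through the origin, a straight line with a threshold
#' (positive intercept), a curvilinear relationship, or a curvilinear
#' relationship crossing the no-effect diagonal near the lower end or at
#' both ends of the observed Rc range.
#'
#' A weighted line is fitted to the curve points; if the relative RMS
#' residual (RMS residual divided by the Rt range) is below `tol_linear`
#' the curve is called linear, and through the origin when the fitted
#' intercept is below `tol_zero` in absolute value. Otherwise diagonal
#' crossings are located by sign changes of `rt - rc` with linear
#' interpolation; a crossing in the bottom third of the observed Rc range
#' flags a lower threshold and one in the top third an upper threshold.
#'
#' @param curve A `data.frame` of curve points, first two columns Rc and Rt
#'   (e.g. the output of [effect_curve()]); at least 5 points spanning an
#'   Rc range of at least 0.3.
#' @param tol_linear Relative RMS tolerance for calling the curve linear
#'   (default 0.02).
#' @param tol_zero Absolute intercept tolerance, in risk units, for calling
#'   a line "through the origin" (default 0.005).
#' @return One of `"linear_through_origin"`, `"linear_with_threshold"`,
#'   `"curvilinear"`, `"curvilinear_lower_threshold"`,
#'   `"curvilinear_both_thresholds"`.
#' @export
classify_shape <- function(curve, tol_linear = 0.02, tol_zero = 0.005) {
  if (!is.data.frame(curve) || nrow(curve) < 5L) {
    stop_user("curve must have at least 5 points")
  }
  rc <- curve[[1L]]
  rt <- curve[[2L]]
  if (diff(range(rc)) < 0.3) {
    stop_user("curve must span an rc range of at least 0.3")
  }
  w <- if ("n" %in% names(curve)) curve$n else rep(1, nrow(curve))
  fit <- stats::lm(rt ~ rc, weights = w)
  rms <- sqrt(stats::weighted.mean(stats::residuals(fit)^2, w))
  rel <- rms / max(diff(range(rt)), .Machine$double.eps)
  if (rel < tol_linear) {
    b <- unname(stats::coef(fit)[1L])
    return(if (abs(b) < tol_zero) "linear_through_origin"
           else "linear_with_threshold")
  }
  crossings <- all_diagonal_crossings(curve)
  rng <- range(rc)
  third <- diff(rng) / 3
  lower <- any(crossings <= rng[1L] + third)
  upper <- any(crossings >= rng[2L] - third)
  if (lower && upper) "curvilinear_both_thresholds"
  else if (lower) "curvilinear_lower_threshold"
  else "curvilinear"
}

#' Bootstrap prediction interval for the number of prevented events
#'
#' Resamples subjects with replacement, recomputes the number of prevented
#' events for each resampled population (the models being deterministic per
#' subject), and returns a percentile interval. This quantifies the
#' population-sampling uncertainty of the NPE prediction.
#'
#' @inheritParams run_effect_model
#' @param n_resamples Number of bootstrap resamples (`>= 100`).
#' @param level Interval coverage level (default 0.95).
#' @param seed RNG seed for the resampling; same seed, same interval.
#' @return Length-2 numeric `c(low, high)` with attributes `npe` (the
#'   plug-in value), `level` and `n_resamples`.
#' @export
npe_prediction_interval <- function(population, disease, therapy,
                                    n_resamples = 1000, level = 0.95,
                                    seed = 1) {
  if (!is_count(n_resamples) || n_resamples < 100) {
    stop_user("n_resamples must be an integer >= 100")
  }
  if (!is_num1(level) || level <= 0 || level >= 1) {
    stop_user("level must lie in (0, 1)")
  }
  res <- run_effect_model(population, disease, therapy)
  ab <- res$outcomes$ab
  n <- length(ab)
  stat <- with_seed(seed, {
    vapply(seq_len(n_resamples),
           function(i) sum(ab[sample.int(n, n, replace = TRUE)]),
           numeric(1))
  })
  alpha <- (1 - level) / 2
  out <- unname(stats::quantile(stat, c(alpha, 1 - alpha)))
  attributes(out) <- list(npe = res$npe, level = level,
                          n_resamples = n_resamples)
  out
}

#' Write per-subject outcomes, the binned curve, and a summary report
#'
#' `write_outcomes()` exports the per-subject `(rc, rt, ab)` table,
#' `write_effect_curve()` the binned curve for L'Abbe plotting, and
#' `write_result_summary()` a JSON summary (NPE, interval, shape, threshold,
#' seed).
#'
#' @param result An `effect_model_result`.
#' @param path Output path.
#' @param seed Seed to record in the summary (reproducibility metadata).
#' @return The path, invisibly.
#' @export
write_outcomes <- function(result, path) {
  utils::write.csv(result$outcomes, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_outcomes
#' @export
write_effect_curve <- function(result, path) {
  utils::write.csv(result$curve, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_outcomes
#' @export
write_result_summary <- function(result, path, seed = NULL) {
  out <- list(label = result$therapy$label,
              n_subjects = result$n,
              npe = result$npe,
              mean_ab = result$npe / result$n,
              shape = if (is.na(result$shape)) NULL else result$shape,
              natural_threshold = if (is.na(result$natural_threshold)) NULL
                else result$natural_threshold,
              harm = result$therapy$harm,
              dose = result$therapy$pkpd$dose,
              followup = result$therapy$followup)
  if (!is.null(result$npe_interval)) {
    out$npe_interval <- as.numeric(result$npe_interval)
    out$npe_interval_level <- attr(result$npe_interval, "level")
  }
  if (!is.null(seed)) out$seed <- seed
  writeLines(jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}
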
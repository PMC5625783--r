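#' Decision thresholds for interim and final analyses
#'
#' The success/futility criteria used in the design evaluation. Effects are
#' placebo-adjusted improvements (placebo mean minus dose mean, positive =
#' better). At an interim, with p = Pr(effect at ED90 > 0): success when
#' p > `interim_success_prob`, futility when p < `interim_futility_prob`,
#' otherwise continue. At the final analysis of an adaptive design, success
#' requires all of Pr(effect at ED90 > `final_csd`) > `final_success_prob`,
#' Pr(effect at dmax > 0) > `dmax_prob` and Pr(effect at ED90 > 0) >
#' `interim_success_prob`; the fixed design declares success when
#' Pr(effect at ED90 > 0) >= `fixed_final_prob`.
#'
#' @param interim_success_prob Posterior-probability bar for interim success
#'   (default 0.95).
#' @param interim_futility_prob Bar below which the trial stops for futility
#'   (default 0.20, strict inequality).
#' @param final_csd Clinically significant difference: the placebo-adjusted
#'   DAS28 improvement required at the final analysis (default 0.95 points).
#' @param final_success_prob Posterior-probability bar for beating the CSD at
#'   the final analysis (default 0.70).
#' @param dmax_prob Bar for the dose with maximal posterior-mean effect
#'   beating placebo (default 0.95).
#' @param fixed_final_prob Bar for the fixed design's final rule
#'   (default 0.95).
#' @param interim_success_criterion How the trial engine stops early for
#'   success: `"full"` (default) stops only when the complete final-success
#'   conjunction already holds at the interim — the reading under which
#'   early stopping for success is essentially impossible under a flat
#'   truth — while `"effect_only"` stops as soon as
#'   Pr(effect at ED90 > 0) > `interim_success_prob`. Futility stopping
#'   always uses the Pr(effect at ED90 > 0) < `interim_futility_prob` rule.
#' @param final_success_criterion The final-analysis success rule for the
#'   adaptive scenarios: `"effect_only"` (default) requires
#'   Pr(effect at ED90 > 0) >= `fixed_final_prob`, the same bar as the
#'   fixed design — the rule under which the type-I error of the final
#'   analysis is essentially design-independent; `"full"` requires the CSD
#'   conjunction instead.
#' @return An object of class `decision_thresholds`.
#' @export
decision_thresholds <- function(interim_success_prob = 0.95,
                                interim_futility_prob = 0.20,
                                final_csd = 0.95,
                                final_success_prob = 0.70,
                                dmax_prob = 0.95,
                                fixed_final_prob = 0.95,
                                interim_success_criterion = c("full",
                                                              "effect_only"),
                                final_success_criterion = c("effect_only",
                                                            "full")) {
  interim_success_criterion <- match.arg(interim_success_criterion)
  final_success_criterion <- match.arg(final_success_criterion)
  probs <- c(interim_success_prob, interim_futility_prob,
             final_success_prob, dmax_prob, fixed_final_prob)
  if (any(!is.finite(probs)))
    stop("thresholds must be finite")
  if (final_csd <= 0) stop("`final_csd` must be positive")
  structure(list(interim_success_prob = interim_success_prob,
                 interim_futility_prob = interim_futility_prob,
                 final_csd = final_csd,
                 final_success_prob = final_success_prob,
                 dmax_prob = dmax_prob,
                 fixed_final_prob = fixed_final_prob,
                 interim_success_criterion = interim_success_criterion,
                 final_success_criterion = final_success_criterion),
            class = "decision_thresholds")
}

#' Per-draw placebo-adjusted effects
#'
#' For each retained MCMC draw and each active dose, the effect versus
#' control: fitted mean at placebo minus fitted mean at the dose, so that a
#' positive effect is an improvement (a larger DAS28 decrease than placebo).
#'
#' @param posterior A `model_posterior` whose grid includes placebo.
#' @return An object of class `effect_draws`: a numeric matrix with one row
#'   per draw and one column per active dose (named by dose), carrying the
#'   active doses as attribute `doses`.
#' @export
effect_draws <- function(posterior) {
  stopifnot(inherits(posterior, "model_posterior"))
  doses <- posterior$grid$doses
  if (doses[1] != 0) stop("the posterior grid must include placebo")
  dm <- posterior$dose_means
  eff <- dm[, 1] - dm[, -1, drop = FALSE]
  colnames(eff) <- as.character(doses[-1])
  structure(eff, doses = doses[-1], class = c("effect_draws", "matrix",
                                              "array"))
}

#' ED90 estimate and its posterior distribution over the dose grid
#'
#' Applies the 90%-of-maximum-effect, lowest-qualifying-dose rule to each
#' draw's effect vector. The ED90 posterior is the relative frequency with
#' which each active dose is selected among draws with a positive maximum
#' effect; the point estimate is the posterior modal dose, ties broken to
#' the lower dose. Because selection is over the nominal grid, the estimate
#' can never exceed the maximum planned dose (30 mg/kg on the default grid).
#' When no draw shows any positive effect the sentinel `NA` is returned and
#' the highest dose is carried as `ed90_for_decision` (flagged), so that
#' decision rules can still be evaluated.
#'
#' @param effects An [effect_draws()] matrix.
#' @param grid The [dose_grid()] the effects were computed on.
#' @return An object of class `ed90_estimate`: a list with elements `ed90`
#'   (modal dose or `NA`), `posterior` (named selection frequencies over the
#'   active doses), `prop_no_effect` (fraction of draws with no positive
#'   effect), `no_effective_dose` (flag) and `ed90_for_decision`.
#' @export
estimate_ed90 <- function(effects, grid = dose_grid()) {
  stopifnot(inherits(effects, "effect_draws"), inherits(grid, "dose_grid"))
  active <- grid$doses[-1]
  if (!identical(as.character(active), colnames(effects)))
    stop("`effects` columns do not match the active doses of `grid`")
  eff <- unclass(effects)
  # row maxima without apply(): pmax over the (few) dose columns
  rmax <- do.call(pmax, lapply(seq_len(ncol(eff)), function(j) eff[, j]))
  ok <- rmax > 0
  sel <- rep(NA_integer_, nrow(eff))
  if (any(ok)) {
    qual <- eff[ok, , drop = FALSE] >= 0.9 * rmax[ok]
    sel[ok] <- max.col(qual, ties.method = "first")
  }
  counts <- tabulate(sel, nbins = length(active))
  n_ok <- sum(ok)
  post <- if (n_ok > 0) counts / n_ok else rep(NA_real_, length(active))
  names(post) <- as.character(active)
  if (n_ok == 0) {
    out <- list(ed90 = NA_real_, posterior = post, prop_no_effect = 1,
                no_effective_dose = TRUE,
                ed90_for_decision = active[length(active)])
  } else {
    mode_idx <- which(counts == max(counts))[1] # ties -> lower dose
    out <- list(ed90 = active[mode_idx], posterior = post,
                prop_no_effect = 1 - n_ok / nrow(eff),
                no_effective_dose = FALSE,
                ed90_for_decision = active[mode_idx])
  }
  structure(out, class = "ed90_estimate")
}

#' @export
print.ed90_estimate <- function(x, ...) {
  cat("ED90 estimate:",
      if (is.na(x$ed90)) "none (no effective dose)" else
        paste0(x$ed90, " mg/kg"), "\n")
  cat("Selection posterior over active doses:\n")
  print(round(x$posterior, 3))
  invisible(x)
}

.effect_at <- function(effects, dose) {
  col <- match(as.character(dose), colnames(effects))
  if (is.na(col)) stop("dose ", dose, " is not an active dose of `effects`")
  unclass(effects)[, col]
}

#' Dose with maximal posterior-mean effect
#'
#' @param effects An [effect_draws()] matrix.
#' @return The active dose whose posterior mean placebo-adjusted effect is
#'   largest (ties to the lower dose).
#' @export
dmax_dose <- function(effects) {
  stopifnot(inherits(effects, "effect_draws"))
  m <- colMeans(unclass(effects))
  attr(effects, "doses")[which.max(m)]
}

.decision_outcome <- function(stage, verdict, posterior_probs, ed90) {
  structure(list(stage = stage, verdict = verdict,
                 posterior_probs = posterior_probs, ed90 = ed90),
            class = "decision_outcome")
}

#' @export
print.decision_outcome <- function(x, ...) {
  cat(sprintf("%s analysis: %s (ED90 = %s mg/kg)\n", x$stage, x$verdict,
              format(x$ed90)))
  print(round(unlist(x$posterior_probs), 4))
  invisible(x)
}

#' Interim decision
#'
#' Evaluates Pr(effect at ED90 > 0) against the interim success and futility
#' bars: success above `interim_success_prob`, futility strictly below
#' `interim_futility_prob`, otherwise continue.
#'
#' @param effects An [effect_draws()] matrix.
#' @param ed90 The active dose used as ED90 at this analysis.
#' @param thresholds A [decision_thresholds()].
#' @return A `decision_outcome` with verdict `success`, `futility` or
#'   `continue`.
#' @export
evaluate_interim <- function(effects, ed90, thresholds = decision_thresholds()) {
  stopifnot(inherits(thresholds, "decision_thresholds"))
  p <- mean(.effect_at(effects, ed90) > 0)
  verdict <- if (p > thresholds$interim_success_prob) "success"
  else if (p < thresholds$interim_futility_prob) "futility"
  else "continue"
  .decision_outcome("interim", verdict, list(p_effect_gt0 = p), ed90)
}

#' Final decision
#'
#' For the fixed design, success requires Pr(effect at ED90 > 0) >=
#' `fixed_final_prob`. For the adaptive designs the rule follows the
#' thresholds' `final_success_criterion`: with `"effect_only"` (the
#' default) success requires Pr(effect at ED90 > 0) >= `fixed_final_prob`,
#' the same bar as the fixed design; with `"full"` it is the conjunction
#' Pr(effect at ED90 > `final_csd`) > `final_success_prob` and
#' Pr(effect at dmax > 0) > `dmax_prob` and
#' Pr(effect at ED90 > 0) > `interim_success_prob`. Anything else is
#' futility. All three probabilities are reported regardless of the rule so
#' that decision-threshold sweeps (ROC curves) can be recomputed without
#' refitting.
#'
#' @param effects An [effect_draws()] matrix.
#' @param ed90 The active dose used as ED90.
#' @param dmax The dose with maximal posterior-mean effect (see
#'   [dmax_dose()]); defaults to computing it from `effects`.
#' @param thresholds A [decision_thresholds()].
#' @param design `"adaptive"` or `"fixed"`.
#' @return A `decision_outcome` with verdict `success` or `futility`.
#' @export
evaluate_final <- function(effects, ed90, dmax = dmax_dose(effects),
                           thresholds = decision_thresholds(),
                           design = c("adaptive", "fixed")) {
  stopifnot(inherits(thresholds, "decision_thresholds"))
  design <- match.arg(design)
  e_ed90 <- .effect_at(effects, ed90)
  p0 <- mean(e_ed90 > 0)
  p_csd <- mean(e_ed90 > thresholds$final_csd)
  p_dmax <- mean(.effect_at(effects, dmax) > 0)
  success <- if (design == "fixed" ||
                 !isTRUE(thresholds$final_success_criterion == "full")) {
    p0 >= thresholds$fixed_final_prob
  } else {
    p_csd > thresholds$final_success_prob &&
      p_dmax > thresholds$dmax_prob &&
      p0 > thresholds$interim_success_prob
  }
  .decision_outcome("final", if (success) "success" else "futility",
                    list(p_effect_gt0 = p0, p_effect_gt_csd = p_csd,
                         p_dmax_gt0 = p_dmax),
                    ed90)
}
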
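#' Operating-characteristic summary of a batch of simulated trials
#'
#' Empirical early/final success and futility rates (which sum to 1: every
#' trial has exactly one terminal outcome), the total success rate
#' (early + final) and the mean number of subjects at stop.
#'
#' @param trials A `trial_study` or list of `trial_record`s sharing one
#'   (scenario, profile, model) combination.
#' @return A one-row data frame of class `oc_table`.
#' @export
summarize_oc <- function(trials) {
  stopifnot(length(trials) > 0)
  key <- vapply(trials, function(tr)
    paste(tr$scenario, tr$profile, tr$model), character(1))
  if (length(unique(key)) != 1)
    stop("all trials must share the same scenario, profile and model")
  stages <- vapply(trials, function(tr) tr$stop_stage, character(1))
  n <- length(trials)
  rate <- function(s) sum(stages == s) / n
  out <- data.frame(
    scenario = trials[[1]]$scenario, profile = trials[[1]]$profile,
    model = trials[[1]]$model, n_trials = n,
    early_success_rate = rate("early_success"),
    early_futility_rate = rate("early_futility"),
    final_success_rate = rate("final_success"),
    final_futility_rate = rate("final_futility"),
    mean_subjects = mean(vapply(trials, function(tr) tr$n_enrolled,
                                numeric(1))))
  out$total_success_rate <- out$early_success_rate + out$final_success_rate
  class(out) <- c("oc_table", "data.frame")
  out
}

#' ED90 selection table
#'
#' The empirical distribution of the final ED90 over the active doses, with
#' trials whose fit identified no effective dose counted as `missing`
#' (the sentinel used when the maximum effect was not estimated as
#' positive). Proportions including the missing mass sum to 1.
#'
#' @param trials A `trial_study` or list of `trial_record`s.
#' @param grid The [dose_grid()] the trials used.
#' @return A data frame with columns `dose` (active doses, then `NA` for
#'   missing) and `proportion`.
#' @export
ed90_selection <- function(trials, grid = dose_grid()) {
  stopifnot(length(trials) > 0, inherits(grid, "dose_grid"))
  active <- grid$doses[-1]
  ed <- vapply(trials, function(tr) tr$final_ed90, numeric(1))
  counts <- vapply(active, function(d) sum(!is.na(ed) & ed == d), numeric(1))
  data.frame(dose = c(active, NA_real_),
             proportion = c(counts, sum(is.na(ed))) / length(ed))
}

#' Per-dose bias of the final fitted curve
#'
#' For each grid dose, the mean over trials of (final posterior-mean fitted
#' response) minus (true profile mean): the statistical bias of the analysis
#' model under the assumed truth. The fitted curve is the one from the last
#' analysis performed, i.e. the analysis at which the trial stopped.
#'
#' @param trials A `trial_study` or list of `trial_record`s.
#' @param profile The [true_profile()] the trials were generated from.
#' @param grid The [dose_grid()] the trials used.
#' @return A data frame with columns `dose` and `bias` (DAS28 points).
#' @export
compute_bias <- function(trials, profile, grid = dose_grid()) {
  stopifnot(length(trials) > 0, inherits(profile, "true_profile"))
  fitted <- t(vapply(trials, function(tr) tr$final_dose_means,
                     numeric(length(grid$doses))))
  truth <- true_mean(profile, grid$doses)
  data.frame(dose = grid$doses,
             bias = colMeans(fitted) - truth)
}

#' Re-apply the final decision rule under new success thresholds
#'
#' Re-decides the final analysis of each trial from its stored posterior
#' probabilities, sweeping the success bar while holding the interim rules
#' fixed: trials that stopped early keep their outcome (their interim
#' thresholds are not part of the sweep), trials that reached the final
#' analysis are re-classified. For fixed-design records the rule is
#' Pr(effect at ED90 > 0) >= `prob`; for adaptive records `prob` replaces
#' `final_success_prob` in the final conjunction (the CSD, dmax and
#' Pr(effect > 0) bars keep their original values). No model is refitted.
#'
#' @param trials A `trial_study` or list of `trial_record`s.
#' @param prob The swept success-probability threshold.
#' @return Character vector of stop stages under the new threshold.
#' @export
redecide_final <- function(trials, prob) {
  vapply(trials, function(tr) {
    if (tr$stop_stage %in% c("early_success", "early_futility"))
      return(tr$stop_stage)
    p <- tr$final_probs
    full_rule <- tr$design_rule != "fixed" &&
      isTRUE(tr$thresholds$final_success_criterion == "full")
    success <- if (!full_rule) {
      p$p_effect_gt0 >= prob
    } else {
      thr <- tr$thresholds
      p$p_effect_gt_csd > prob &&
        p$p_dmax_gt0 > thr$dmax_prob &&
        p$p_effect_gt0 > thr$interim_success_prob
    }
    if (success) "final_success" else "final_futility"
  }, character(1))
}

.total_success <- function(stages)
  mean(stages %in% c("early_success", "final_success"))

#' ROC curve over a decision-threshold sweep
#'
#' One (false-positive rate, true-positive rate) point per threshold, where
#' the rate is the total (early or final) success rate: the FPR from trials
#' generated under the flat (null) profile, the TPR from trials under an
#' effect profile. The degenerate limiting points (0, 0) and (1, 1) are
#' appended and the curve is returned sorted by FPR.
#'
#' @param null_trials_by_threshold Named list (names = threshold values) of
#'   trial batches simulated/re-decided under the flat profile.
#' @param alt_trials_by_threshold The matching list under the effect
#'   profile; the same thresholds must be used.
#' @return A data frame of class `roc_curve` with columns `threshold`,
#'   `fpr`, `tpr`, sorted by `fpr`.
#' @export
compute_roc <- function(null_trials_by_threshold, alt_trials_by_threshold) {
  thr_n <- names(null_trials_by_threshold)
  thr_a <- names(alt_trials_by_threshold)
  if (is.null(thr_n) || !identical(thr_n, thr_a))
    stop("the same named threshold sweep must be applied to both batches")
  stage_of <- function(batch)
    if (is.character(batch)) batch
    else vapply(batch, function(tr) tr$stop_stage, character(1))
  fpr <- vapply(null_trials_by_threshold,
                function(b) .total_success(stage_of(b)), numeric(1))
  tpr <- vapply(alt_trials_by_threshold,
                function(b) .total_success(stage_of(b)), numeric(1))
  out <- data.frame(threshold = as.numeric(thr_n), fpr = fpr, tpr = tpr,
                    row.names = NULL)
  out <- rbind(out, data.frame(threshold = c(Inf, -Inf), fpr = c(0, 1),
                               tpr = c(0, 1)))
  out <- out[order(out$fpr, out$tpr), ]
  rownames(out) <- NULL
  class(out) <- c("roc_curve", "data.frame")
  out
}

#' Sweep the final-success threshold of two matched trial batches
#'
#' Convenience wrapper around [redecide_final()] and [compute_roc()]: the
#' final-success probability bar is swept over a grid and every point is
#' recomputed from the stored posterior probabilities, with no refitting.
#'
#' @param null_trials Trials generated under the flat profile.
#' @param alt_trials Trials generated under an effect profile.
#' @param thresholds Numeric grid of success-probability thresholds.
#' @return A `roc_curve` data frame.
#' @export
roc_sweep <- function(null_trials, alt_trials,
                      thresholds = seq(0.5, 1, by = 0.01)) {
  nm <- as.character(thresholds)
  compute_roc(
    stats::setNames(lapply(thresholds, function(p)
      redecide_final(null_trials, p)), nm),
    stats::setNames(lapply(thresholds, function(p)
      redecide_final(alt_trials, p)), nm))
}

#' Write operating-characteristic tables to disk
#'
#' Writes each table as CSV plus a JSON manifest (file list with MD5 hashes
#' and any metadata such as seed and number of simulations). Output is
#' byte-stable given identical inputs.
#'
#' @param tables Named list of non-empty data frames.
#' @param path Output directory (created if needed).
#' @param meta Named list of metadata stored in the manifest.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(tables, path, meta = list()) {
  if (!is.list(tables) || length(tables) == 0 || is.null(names(tables)) ||
      any(names(tables) == ""))
    stop("`tables` must be a non-empty named list of data frames")
  for (nm in names(tables)) {
    if (!is.data.frame(tables[[nm]]) || nrow(tables[[nm]]) == 0)
      stop("table `", nm, "` is empty")
  }
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (nm in names(tables)) {
    f <- file.path(path, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], f, row.names = FALSE)
    files <- c(files, f)
  }
  manifest <- list(files = lapply(files, function(f)
    list(name = basename(f), md5 = unname(tools::md5sum(f)))),
    meta = meta)
  mf <- file.path(path, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(files, mf))
}
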
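#' Design scenarios for the simulated phase 2a trial
#'
#' Four designs with a total target sample size of 64 on the 7-level dose
#' grid:
#' \describe{
#'   \item{S1_fixed}{all subjects allocated up front (16 placebo, 8 per
#'     active dose); a single final analysis with the fixed-design rule.}
#'   \item{S2_no_adaptive}{8 cohorts of 8 (2 placebo + 6 active, one per
#'     active dose) giving the overall 2:1:1:1:1:1:1 ratio; interim analyses
#'     at 8, 16, 24, 32, 40 and 48 completers.}
#'   \item{S3_half_adaptive}{the first 50% of subjects (4 cohorts) use the
#'     fixed cohort pattern; afterwards each subject is randomised to
#'     placebo with probability 0.25 (subject to the overall 25% placebo
#'     budget) or to an active dose drawn from the current ED90 posterior;
#'     interims at 32, 40 and 48.}
#'   \item{S4_adaptive}{cohort 1 uses the fixed pattern, all later cohorts
#'     are ED90-targeted as in S3; interims at 8 through 48.}
#' }
#' Early stopping at an interim truncates enrolment, which is what drives
#' the mean sample size below 64 in the operating characteristics.
#'
#' @param name Scenario name.
#' @param total_n Target sample size (default 64).
#' @param cohort_size Cohort size for S2-S4 (default 8).
#' @param placebo_fraction Fraction of subjects on placebo (default 0.25);
#'   must be consistent with the cohort composition.
#' @param grid A [dose_grid()].
#' @param interim_schedule Optional override of the completer counts that
#'   trigger interim analyses.
#' @return An object of class `design_scenario`.
#' @export
design_scenario <- function(name = c("S1_fixed", "S2_no_adaptive",
                                     "S3_half_adaptive", "S4_adaptive"),
                            total_n = 64, cohort_size = 8,
                            placebo_fraction = 0.25, grid = dose_grid(),
                            interim_schedule = NULL) {
  name <- match.arg(name)
  stopifnot(inherits(grid, "dose_grid"), total_n >= 8)
  n_active <- length(grid$doses) - 1
  placebo_budget <- as.integer(round(placebo_fraction * total_n))

  if (name == "S1_fixed") {
    u <- total_n / (n_active + 2)
    if (u != round(u))
      stop("S1 needs total_n divisible by (number of active doses + 2)")
    fixed_allocation <- c(2 * u, rep(u, n_active))
    if (is.null(interim_schedule)) interim_schedule <- integer(0)
    if (length(interim_schedule) > 0)
      stop("the fixed design has no interim analyses")
    cohort_pattern <- NULL
    n_fixed_cohorts <- 0L
    n_cohorts <- 1L
    allocation_rule <- "fixed"
  } else {
    if (total_n %% cohort_size != 0)
      stop("total_n must be a multiple of cohort_size")
    n_cohorts <- total_n %/% cohort_size
    pl_per_cohort <- cohort_size * placebo_fraction
    if (pl_per_cohort != round(pl_per_cohort) ||
        cohort_size - pl_per_cohort != n_active)
      stop("inconsistent placebo_fraction vs cohort composition: each ",
           "cohort must hold cohort_size * placebo_fraction placebo ",
           "subjects plus one subject per active dose")
    cohort_pattern <- c(rep(0, pl_per_cohort), grid$doses[-1])
    fixed_allocation <- NULL
    n_fixed_cohorts <- switch(name,
      S2_no_adaptive = n_cohorts,
      S3_half_adaptive = {
        if ((total_n / 2) %% cohort_size != 0)
          stop("S3 needs total_n/2 to be a whole number of cohorts")
        as.integer(total_n / 2 / cohort_size)
      },
      S4_adaptive = 1L)
    allocation_rule <- if (name == "S2_no_adaptive") "fixed"
                       else "ed90_posterior"
    if (is.null(interim_schedule)) {
      interim_schedule <- switch(name,
        S2_no_adaptive = ,
        S4_adaptive = seq(cohort_size, total_n - 2 * cohort_size,
                          by = cohort_size),
        S3_half_adaptive = seq(total_n / 2, total_n - 2 * cohort_size,
                               by = cohort_size))
    }
    interim_schedule <- as.integer(interim_schedule)
    if (any(diff(interim_schedule) <= 0) ||
        any(interim_schedule >= total_n) || any(interim_schedule <= 0))
      stop("interim schedule must be strictly increasing and below total_n")
  }

  structure(list(name = name, total_n = as.integer(total_n),
                 cohort_size = as.integer(cohort_size),
                 placebo_fraction = placebo_fraction,
                 placebo_budget = placebo_budget,
                 grid = grid, interim_schedule = interim_schedule,
                 fixed_allocation = fixed_allocation,
                 cohort_pattern = cohort_pattern,
                 n_fixed_cohorts = n_fixed_cohorts,
                 n_cohorts = as.integer(n_cohorts),
                 allocation_rule = allocation_rule),
            class = "design_scenario")
}

#' @export
print.design_scenario <- function(x, ...) {
  cat(sprintf("Design scenario %s: n = %d, allocation %s\n", x$name,
              x$total_n, x$allocation_rule))
  if (length(x$interim_schedule))
    cat("Interim analyses at:", paste(x$interim_schedule, collapse = ", "),
        "completers\n")
  invisible(x)
}

#' ED90-targeted allocation of the next subject
#'
#' With probability `placebo_fraction` the subject receives placebo, subject
#' to the overall placebo budget; otherwise an active dose is drawn from the
#' current ED90 selection posterior over the grid (uniform over the active
#' doses when no posterior is available, e.g. before any fit or when no draw
#' showed a positive effect).
#'
#' @param scenario A [design_scenario()] with ED90-posterior allocation.
#' @param ed90_posterior Named selection probabilities over the active doses
#'   (see [estimate_ed90()]), or `NULL`.
#' @param n_so_far Subjects enrolled so far (unused by the default rule but
#'   part of the allocation interface).
#' @param n_placebo_so_far Placebo subjects enrolled so far.
#' @return The assigned dose (mg/kg; 0 = placebo).
#' @export
allocate_next <- function(scenario, ed90_posterior, n_so_far,
                          n_placebo_so_far) {
  stopifnot(inherits(scenario, "design_scenario"))
  if (n_placebo_so_far < scenario$placebo_budget &&
      stats::runif(1) < scenario$placebo_fraction)
    return(0)
  active <- scenario$grid$doses[-1]
  prob <- ed90_posterior
  if (is.null(prob) || anyNA(prob) || sum(prob) <= 0)
    prob <- rep(1, length(active))
  active[sample.int(length(active), 1, prob = prob)]
}

.default_response_fn <- function(profile) {
  force(profile)
  function(doses)
    true_mean(profile, doses) +
      stats::rnorm(length(doses), sd = sqrt(profile$residual_variance))
}

.fit_model <- function(model, data, prior, mcmc, grid) {
  switch(model,
         emax = fit_emax(data, prior = prior, mcmc = mcmc, grid = grid),
         ndlm = fit_ndlm(data, grid = grid, prior = prior, mcmc = mcmc))
}

.trial_record <- function(scenario, profile, model, subjects, analyses,
                          stop_stage, final_ed90, final_ed90_missing,
                          final_dose_means, final_probs, design_rule,
                          thresholds) {
  structure(list(scenario = scenario$name, profile = profile$name,
                 model = model, subjects = subjects, analyses = analyses,
                 stop_stage = stop_stage, n_enrolled = nrow(subjects),
                 final_ed90 = final_ed90,
                 final_ed90_missing = final_ed90_missing,
                 final_dose_means = final_dose_means,
                 final_probs = final_probs, design_rule = design_rule,
                 thresholds = thresholds),
            class = "trial_record")
}

#' @export
print.trial_record <- function(x, ...) {
  cat(sprintf("Simulated trial (%s, %s truth, %s model): %s after %d subjects",
              x$scenario, x$profile, x$model, x$stop_stage, x$n_enrolled),
      sprintf("\nFinal ED90: %s mg/kg\n",
              if (is.na(x$final_ed90)) "none" else format(x$final_ed90)))
  invisible(x)
}

#' Run one simulated trial
#'
#' Simulates enrolment, interim analyses, ED90-targeted allocation and early
#' stopping for a single trial under a design scenario and a true
#' dose-response profile, analysing with either the Bayesian Emax model or
#' the NDLM. The model is refitted on all accumulated data at every
#' scheduled interim; an interim verdict of success or futility stops the
#' trial (recording the fit at stop), otherwise the final analysis refits on
#' the full sample and applies the final rule (fixed-design rule for S1, the
#' adaptive conjunction otherwise).
#'
#' @param scenario A [design_scenario()].
#' @param profile A [true_profile()].
#' @param model `"emax"` or `"ndlm"`.
#' @param prior An [emax_prior()] or [ndlm_prior()] matching `model`
#'   (defaults to the model's vague prior).
#' @param thresholds A [decision_thresholds()].
#' @param mcmc An [mcmc_control()].
#' @param seed Optional integer seed; a seeded trial is fully reproducible
#'   (data, sampler and allocation all draw from the one stream).
#' @param response_fn Optional generator `function(doses)` returning one
#'   response per assigned dose, replacing the profile's Normal sampler
#'   (used for what-if analyses and design diagnostics with injected data).
#' @return A `trial_record`: subjects, the sequence of `decision_outcome`s,
#'   the stop stage (`early_success`, `early_futility`, `final_success`,
#'   `final_futility`), the final ED90 and the final fitted per-dose means.
#' @export
run_trial <- function(scenario, profile, model = c("emax", "ndlm"),
                      prior = NULL, thresholds = decision_thresholds(),
                      mcmc = mcmc_control(), seed = NULL,
                      response_fn = NULL) {
  stopifnot(inherits(scenario, "design_scenario"),
            inherits(profile, "true_profile"))
  model <- match.arg(model)
  if (is.null(prior))
    prior <- if (model == "emax") emax_prior() else ndlm_prior()
  if (!is.null(seed)) set.seed(seed)
  if (is.null(response_fn)) response_fn <- .default_response_fn(profile)
  grid <- scenario$grid

  new_subjects <- function(doses, cohort, start_id) {
    data.frame(subject_id = seq.int(start_id, length.out = length(doses)),
               cohort = rep.int(as.integer(cohort), length(doses)),
               dose = as.numeric(doses), response = response_fn(doses))
  }

  if (scenario$name == "S1_fixed") {
    doses <- rep(grid$doses, times = scenario$fixed_allocation)
    subjects <- new_subjects(doses, 1L, 1L)
    post <- .fit_model(model, subjects, prior, mcmc, grid)
    eff <- effect_draws(post)
    ed <- estimate_ed90(eff, grid)
    out <- evaluate_final(eff, ed$ed90_for_decision,
                          thresholds = thresholds, design = "fixed")
    attr(out, "n") <- nrow(subjects)
    return(.trial_record(scenario, profile, model, subjects, list(out),
                         paste0("final_", out$verdict),
                         ed$ed90, ed$no_effective_dose,
                         colMeans(post$dose_means), out$posterior_probs,
                         "fixed", thresholds))
  }

  subjects <- NULL
  analyses <- list()
  alloc_post <- NULL
  last_ed <- NULL
  last_dose_means <- NULL
  n_placebo <- 0L

  for (k in seq_len(scenario$n_cohorts)) {
    if (k <= scenario$n_fixed_cohorts) {
      doses_k <- scenario$cohort_pattern
      n_placebo <- n_placebo + sum(doses_k == 0)
    } else {
      doses_k <- numeric(scenario$cohort_size)
      n_now <- if (is.null(subjects)) 0L else nrow(subjects)
      for (i in seq_len(scenario$cohort_size)) {
        d <- allocate_next(scenario, alloc_post, n_now + i - 1L, n_placebo)
        if (d == 0) n_placebo <- n_placebo + 1L
        doses_k[i] <- d
      }
    }
    start_id <- if (is.null(subjects)) 1L else nrow(subjects) + 1L
    subjects <- rbind(subjects, new_subjects(doses_k, k, start_id))

    if (nrow(subjects) %in% scenario$interim_schedule) {
      post <- .fit_model(model, subjects, prior, mcmc, grid)
      eff <- effect_draws(post)
      ed <- estimate_ed90(eff, grid)
      out <- evaluate_interim(eff, ed$ed90_for_decision, thresholds)
      if (thresholds$interim_success_criterion == "full") {
        # stop for success only once the full CSD conjunction holds
        thr_full <- thresholds
        thr_full$final_success_criterion <- "full"
        fin <- evaluate_final(eff, ed$ed90_for_decision, dmax_dose(eff),
                              thr_full, design = "adaptive")
        verdict <- if (fin$verdict == "success") "success"
                   else if (out$verdict == "futility") "futility"
                   else "continue"
        out <- .decision_outcome("interim", verdict, fin$posterior_probs,
                                 ed$ed90_for_decision)
      }
      attr(out, "n") <- nrow(subjects)
      analyses <- c(analyses, list(out))
      alloc_post <- if (ed$no_effective_dose) NULL else ed$posterior
      last_ed <- ed
      last_dose_means <- colMeans(post$dose_means)
      if (out$verdict != "continue") {
        return(.trial_record(scenario, profile, model, subjects, analyses,
                             paste0("early_", out$verdict),
                             ed$ed90, ed$no_effective_dose, last_dose_means,
                             NULL, "adaptive", thresholds))
      }
    }
  }

  post <- .fit_model(model, subjects, prior, mcmc, grid)
  eff <- effect_draws(post)
  ed <- estimate_ed90(eff, grid)
  out <- evaluate_final(eff, ed$ed90_for_decision, dmax_dose(eff),
                        thresholds, design = "adaptive")
  attr(out, "n") <- nrow(subjects)
  analyses <- c(analyses, list(out))
  .trial_record(scenario, profile, model, subjects, analyses,
                paste0("final_", out$verdict), ed$ed90,
                ed$no_effective_dose, colMeans(post$dose_means),
                out$posterior_probs, "adaptive", thresholds)
}

#' Run a simulation study
#'
#' Runs `n_sims` independent trials under one (scenario, profile, model)
#' combination. Per-trial seeds are spawned from the root seed, so studies
#' are reproducible and individual trials can be re-run in isolation.
#'
#' @param scenario,profile,model,prior,thresholds,mcmc As [run_trial()].
#' @param n_sims Number of simulated trials.
#' @param root_seed Integer root seed.
#' @return An object of class `trial_study`: a list of `trial_record`s with
#'   the study settings attached as attributes.
#' @export
run_study <- function(scenario, profile, model = c("emax", "ndlm"),
                      n_sims = 100, root_seed = 1, prior = NULL,
                      thresholds = decision_thresholds(),
                      mcmc = mcmc_control()) {
  stopifnot(n_sims >= 1)
  model <- match.arg(model)
  set.seed(root_seed)
  seeds <- sample.int(2147483646L, n_sims)
  records <- lapply(seeds, function(s)
    run_trial(scenario, profile, model, prior = prior,
              thresholds = thresholds, mcmc = mcmc, seed = s))
  structure(records, class = "trial_study", scenario = scenario$name,
            profile = profile$name, model = model, root_seed = root_seed,
            seeds = seeds)
}

#' @export
print.trial_study <- function(x, ...) {
  cat(sprintf("Simulation study: %d trials (%s, %s truth, %s model)\n",
              length(x), attr(x, "scenario"), attr(x, "profile"),
              attr(x, "model")))
  print(summarize_oc(x))
  invisible(x)
}

#' Per-trial summary table
#'
#' @param trials A `trial_study` or list of `trial_record`s.
#' @return A data frame with one row per trial: scenario, profile, model,
#'   stop stage, subjects enrolled, number of analyses and final ED90
#'   (`NA` when no effective dose was identified).
#' @export
trial_summary <- function(trials) {
  stopifnot(length(trials) > 0)
  do.call(rbind, lapply(seq_along(trials), function(i) {
    tr <- trials[[i]]
    data.frame(trial = i, scenario = tr$scenario, profile = tr$profile,
               model = tr$model, stop_stage = tr$stop_stage,
               n_enrolled = tr$n_enrolled,
               n_analyses = length(tr$analyses),
               final_ed90 = tr$final_ed90)
  }))
}
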
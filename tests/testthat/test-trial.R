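fast_mcmc <- function(seed = NULL) mcmc_control(n_burnin = 100,
                                                n_retained = 400,
                                                seed = seed)

test_that("design scenarios carry the study's allocation structure", {
  s1 <- design_scenario("S1_fixed")
  expect_equal(s1$fixed_allocation, c(16, rep(8, 6)))
  expect_length(s1$interim_schedule, 0)
  s2 <- design_scenario("S2_no_adaptive")
  expect_equal(s2$interim_schedule, c(8L, 16L, 24L, 32L, 40L, 48L))
  expect_equal(s2$cohort_pattern, c(0, 0, 0.03, 0.3, 3, 10, 20, 30))
  expect_equal(s2$n_fixed_cohorts, 8L)
  s3 <- design_scenario("S3_half_adaptive")
  expect_equal(s3$interim_schedule, c(32L, 40L, 48L))
  expect_equal(s3$n_fixed_cohorts, 4L)
  s4 <- design_scenario("S4_adaptive")
  expect_equal(s4$interim_schedule, c(8L, 16L, 24L, 32L, 40L, 48L))
  expect_equal(s4$n_fixed_cohorts, 1L)
  expect_equal(s4$placebo_budget, 16L)
  # inconsistent placebo fraction vs cohort composition is a config error
  expect_error(design_scenario("S2_no_adaptive", placebo_fraction = 0.3),
               "inconsistent placebo_fraction")
  expect_error(design_scenario("S2_no_adaptive",
                               interim_schedule = c(8, 72)),
               "below total_n")
})

test_that("the fixed design enrols everyone, has no interims and uses the final rule", {
  tr <- run_trial(design_scenario("S1_fixed"), true_profile("flat"), "emax",
                  mcmc = fast_mcmc(), seed = 41)
  expect_equal(tr$n_enrolled, 64)
  expect_equal(sum(tr$subjects$dose == 0), 16)
  for (d in dose_grid()$doses[-1])
    expect_equal(sum(tr$subjects$dose == d), 8)
  expect_length(tr$analyses, 1)
  expect_equal(tr$analyses[[1]]$stage, "final")
  expect_true(tr$stop_stage %in% c("final_success", "final_futility"))
})

test_that("a trivially passable interim bar stops S2 at the first cohort", {
  thr <- decision_thresholds(interim_success_prob = 1e-9,
                             interim_success_criterion = "effect_only")
  tr <- run_trial(design_scenario("S2_no_adaptive"), true_profile("emax"),
                  "emax", thresholds = thr, mcmc = fast_mcmc(), seed = 42)
  expect_equal(tr$stop_stage, "early_success")
  expect_equal(tr$n_enrolled, 8)
  expect_length(tr$analyses, 1)
  expect_equal(attr(tr$analyses[[1]], "n"), 8)
})

test_that("with unreachable interim bars S2 reduces to the fixed design on matched data", {
  pool <- local({
    set.seed(43)
    doses <- dose_grid()$doses
    stats::setNames(lapply(doses, function(d)
      true_mean(true_profile("emax"), rep(d, 16)) + rnorm(16, sd = 1.2)),
      as.character(doses))
  })
  thr <- decision_thresholds(interim_success_prob = 2,
                             interim_futility_prob = -1,
                             interim_success_criterion = "effect_only")
  t1 <- run_trial(design_scenario("S1_fixed"), true_profile("emax"), "emax",
                  thresholds = thr, mcmc = fast_mcmc(seed = 77), seed = 44,
                  response_fn = pooled_response_fn(pool))
  t2 <- run_trial(design_scenario("S2_no_adaptive"), true_profile("emax"),
                  "emax", thresholds = thr, mcmc = fast_mcmc(seed = 77),
                  seed = 44, response_fn = pooled_response_fn(pool))
  expect_equal(t2$n_enrolled, 64)
  expect_true(all(vapply(t2$analyses[-length(t2$analyses)],
                         function(a) a$verdict, character(1)) == "continue"))
  # identical per-dose allocation and identical per-dose response multisets
  for (d in dose_grid()$doses) {
    expect_equal(sort(t1$subjects$response[t1$subjects$dose == d]),
                 sort(t2$subjects$response[t2$subjects$dose == d]))
  }
  # same data and sampler seed: the final analyses agree
  expect_equal(t1$final_probs$p_effect_gt0, t2$final_probs$p_effect_gt0,
               tolerance = 5e-3)
  expect_equal(t1$stop_stage, t2$stop_stage)
  expect_equal(t1$final_dose_means, t2$final_dose_means, tolerance = 1e-6)
})

test_that("allocate_next follows the ED90 posterior and the placebo budget", {
  s3 <- design_scenario("S3_half_adaptive")
  active <- dose_grid()$doses[-1]
  degen <- stats::setNames(c(0, 0, 1, 0, 0, 0), as.character(active))
  set.seed(45)
  d <- replicate(200, allocate_next(s3, degen, 40, 8))
  expect_true(all(d %in% c(0, 3)))
  expect_true(all(d[d > 0] == 3))
  # exhausted placebo budget: never placebo
  d2 <- replicate(200, allocate_next(s3, degen, 60, 16))
  expect_true(all(d2 == 3))
  # uniform posterior: active assignments roughly uniform
  set.seed(46)
  u <- replicate(3000, allocate_next(s3, NULL, 40, 16))
  tab <- table(factor(u, levels = active))
  expect_gt(stats::chisq.test(tab)$p.value, 0.001)
  # placebo frequency tracks placebo_fraction when the budget is open
  set.seed(47)
  p <- mean(replicate(2000, allocate_next(s3, NULL, 10, 0)) == 0)
  expect_lt(abs(p - 0.25), 0.04)
})

test_that("adaptive scenarios respect the placebo budget and total n", {
  for (name in c("S3_half_adaptive", "S4_adaptive")) {
    for (seed in 48:50) {
      tr <- run_trial(design_scenario(name), true_profile("ushape"), "ndlm",
                      mcmc = fast_mcmc(), seed = seed)
      expect_lte(tr$n_enrolled, 64)
      expect_lte(sum(tr$subjects$dose == 0), 16)
      expect_true(all(tr$subjects$dose %in% dose_grid()$doses))
      expect_equal(tr$n_enrolled, nrow(tr$subjects))
      # early stopping truncates at a scheduled analysis
      if (startsWith(tr$stop_stage, "early"))
        expect_true(tr$n_enrolled %in%
                      design_scenario(name)$interim_schedule)
    }
  }
})

test_that("studies are reproducible from the root seed", {
  s <- design_scenario("S2_no_adaptive")
  a <- run_study(s, true_profile("flat"), "ndlm", n_sims = 3, root_seed = 51,
                 mcmc = fast_mcmc())
  b <- run_study(s, true_profile("flat"), "ndlm", n_sims = 3, root_seed = 51,
                 mcmc = fast_mcmc())
  expect_identical(trial_summary(a), trial_summary(b))
  expect_identical(a[[2]]$subjects, b[[2]]$subjects)
  expect_identical(a[[2]]$final_dose_means, b[[2]]$final_dose_means)
})

test_that("early success is monotone in the interim success bar on matched seeds", {
  s2 <- design_scenario("S2_no_adaptive")
  early <- function(bar) {
    thr <- decision_thresholds(interim_success_prob = bar,
                               interim_futility_prob = -1,
                               interim_success_criterion = "effect_only")
    vapply(1:12, function(i)
      run_trial(s2, true_profile("ushape"), "ndlm", thresholds = thr,
                mcmc = fast_mcmc(), seed = 500 + i)$stop_stage ==
        "early_success", logical(1))
  }
  lo <- early(0.80)
  hi <- early(0.95)
  expect_true(all(which(hi) %in% which(lo)))
  expect_gte(sum(lo), sum(hi))
})
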
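test_that("FFBS draws match the brute-force joint-Normal smoother", {
  set.seed(21)
  grid <- dose_grid()
  subj <- simulate_responses(true_profile("ushape"),
                             rep(grid$doses, each = 3))
  ybar <- tapply(subj$response, subj$dose, mean)[as.character(grid$doses)]
  s2 <- 1.0; sth2 <- 0.5; sde2 <- 0.3
  fit <- fit_ndlm(subj,
                  mcmc = mcmc_control(n_burnin = 50, n_retained = 6000,
                                      seed = 9),
                  fix_variances = list(sigma2 = s2, sigma_theta2 = sth2,
                                       sigma_delta2 = sde2))
  or <- oracle_smoother(as.numeric(ybar), rep(3, 7), s2, sth2, sde2)
  th_mean <- colMeans(fit$state_draws$theta)
  th_sd <- apply(fit$state_draws$theta, 2, stats::sd)
  or_mean <- or$mean[or$theta_idx]
  or_sd <- sqrt(diag(or$cov)[or$theta_idx])
  # draws are iid here, so Monte-Carlo error of the mean is sd/sqrt(n)
  mc <- or_sd / sqrt(nrow(fit$state_draws$theta))
  expect_true(all(abs(th_mean - or_mean) < 5 * mc))
  expect_equal(th_sd, or_sd, tolerance = 0.05, ignore_attr = TRUE)
  # a couple of smoothing covariances, not just marginals
  emp_cov <- stats::cov(fit$state_draws$theta[, c(3, 4)])[1, 2]
  or_cov <- or$cov[or$theta_idx[3], or$theta_idx[4]]
  expect_equal(emp_cov, or_cov, tolerance = 0.05)
})

test_that("doses with no observations are treated as pure evolution steps", {
  set.seed(22)
  grid <- dose_grid()
  # leave doses 0.3 and 20 unobserved
  alloc <- rep(c(0, 0.03, 3, 10, 30), each = 4)
  subj <- simulate_responses(true_profile("loglinear"), alloc)
  fit <- fit_ndlm(subj,
                  mcmc = mcmc_control(n_burnin = 50, n_retained = 4000,
                                      seed = 10),
                  fix_variances = list(sigma2 = 1.44, sigma_theta2 = 0.4,
                                       sigma_delta2 = 0.2))
  nobs <- vapply(grid$doses, function(d) sum(subj$dose == d), numeric(1))
  ybar <- vapply(grid$doses, function(d)
    if (any(subj$dose == d)) mean(subj$response[subj$dose == d]) else NA_real_,
    numeric(1))
  yb <- ybar; yb[is.na(yb)] <- 0 # ignored by the oracle where nobs = 0
  or <- oracle_smoother(yb, nobs, 1.44, 0.4, 0.2)
  or_mean <- or$mean[or$theta_idx]
  or_sd <- sqrt(diag(or$cov)[or$theta_idx])
  th_mean <- colMeans(fit$state_draws$theta)
  mc <- or_sd / sqrt(nrow(fit$state_draws$theta))
  expect_true(all(abs(th_mean - or_mean) < 5 * mc))
  # unobserved doses carry visibly more posterior spread than observed ones
  th_sd <- apply(fit$state_draws$theta, 2, stats::sd)
  expect_gt(th_sd[3], max(th_sd[c(2, 4)]))
})

test_that("fit_ndlm is deterministic under a fixed seed and validates input", {
  dat <- fixed_design_data(true_profile("ushape"), seed = 13)
  m <- mcmc_control(n_burnin = 50, n_retained = 200, seed = 14)
  f1 <- fit_ndlm(dat, mcmc = m)
  f2 <- fit_ndlm(dat, mcmc = m)
  expect_identical(f1$state_draws, f2$state_draws)
  expect_identical(f1$variance_draws, f2$variance_draws)
  off <- dat
  off$dose[3] <- 5
  expect_error(fit_ndlm(off), "on the dose grid")
  expect_error(fit_ndlm(dat[0, ]), "empty")
})

test_that("a linear trend in dose index is recovered from noiseless data", {
  grid <- dose_grid()
  line <- -0.4 - 0.25 * (grid$index - 1)
  prof <- true_profile("custom",
                       mean_fn = function(d)
                         line[match(d, grid$doses)],
                       residual_variance = 0)
  dat <- fixed_design_data(prof, n_per_active = 20, seed = 15)
  fit <- fit_ndlm(dat, mcmc = mcmc_control(n_burnin = 500,
                                           n_retained = 2000, seed = 16))
  cv <- ndlm_fitted_curve(fit)
  sds <- apply(fit$state_draws$theta, 2, stats::sd)
  expect_true(all(abs(cv$mean - line) < 3 * pmax(sds, 1e-4)))
})

test_that("the NDLM recovers the tabulated U-shape and fits non-monotonically", {
  truth <- c(-0.5, -0.7, -1.6, -1.8, -1.2, -1, -0.6)
  prof <- true_profile("ushape", residual_variance = 0)
  dat <- fixed_design_data(prof, n_per_active = 30, seed = 17)
  fit <- fit_ndlm(dat, mcmc = mcmc_control(n_burnin = 500,
                                           n_retained = 2500, seed = 18))
  cv <- ndlm_fitted_curve(fit)
  sds <- apply(fit$state_draws$theta, 2, stats::sd)
  expect_true(all(abs(cv$mean - truth) < 3 * pmax(sds, 1e-4)))
  # rises after the trough at 3 mg/kg: non-monotone fitted mean curve
  expect_lt(cv$mean[4], cv$mean[1])
  expect_lt(cv$mean[4], cv$mean[7])
  expect_gt(cv$mean[7], cv$mean[5])
})

test_that("flat data give near-common fitted means across doses", {
  dat <- fixed_design_data(true_profile("flat"), n_per_active = 25,
                           seed = 19)
  fit <- fit_ndlm(dat, mcmc = mcmc_control(n_burnin = 300,
                                           n_retained = 1500, seed = 20))
  cv <- ndlm_fitted_curve(fit)
  sds <- apply(fit$state_draws$theta, 2, stats::sd)
  expect_true(all(abs(cv$mean - mean(dat$response)) < 3 * sds))
})

test_that("fitted-curve summaries collapse correctly on a single draw", {
  curve <- c(-0.5, -0.7, -1.6, -1.8, -1.2, -1, -0.6)
  post <- degenerate_posterior(curve, n_draws = 1)
  cv <- ndlm_fitted_curve(post)
  expect_equal(cv$mean, curve)
  expect_equal(cv$lower, curve)
  expect_equal(cv$upper, curve)
})

test_that("NDLM DIC: degenerate p_D is zero, regular p_D is bounded", {
  dat <- fixed_design_data(true_profile("ushape"), seed = 23)
  fit <- fit_ndlm(dat, mcmc = mcmc_control(n_burnin = 200,
                                           n_retained = 1000, seed = 24))
  deg <- fit
  deg$state_draws$theta <- matrix(colMeans(fit$state_draws$theta), 50, 7,
                                  byrow = TRUE,
                                  dimnames = list(NULL,
                                                  colnames(fit$dose_means)))
  deg$variance_draws <- as.data.frame(lapply(fit$variance_draws, function(x)
    rep(mean(x), 50)))
  expect_equal(dic_ndlm(deg, dat)$p_d, 0, tolerance = 1e-8)
  d <- dic_ndlm(fit, dat)
  expect_gt(d$p_d, 0)
  expect_lt(d$p_d, 7 + 3) # latent levels + variance parameters
  expect_true(is.finite(d$dic))
})

test_that("DIC is comparable across the two models on one adaptive dataset", {
  set.seed(25)
  tr <- run_trial(design_scenario("S3_half_adaptive"), true_profile("ushape"),
                  "ndlm", mcmc = mcmc_control(n_burnin = 100,
                                              n_retained = 400),
                  seed = 26)
  dat <- tr$subjects
  m <- mcmc_control(n_burnin = 200, n_retained = 800, seed = 27)
  dic_n <- dic_ndlm(fit_ndlm(dat, mcmc = m), dat)
  dic_e <- dic_emax(fit_emax(dat, mcmc = m), dat)
  expect_true(is.finite(dic_n$dic))
  expect_true(is.finite(dic_e$dic))
  expect_lt(abs(dic_n$dic - dic_e$dic), 100)
})
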
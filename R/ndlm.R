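#' Prior for the Bayesian second-order NDLM
#'
#' The normal dynamic linear model places a locally linear trend on the
#' per-dose mean response over the equally-spaced dose index: the level
#' theta_j evolves as theta_{j-1} + delta_{j-1} + omega_j and the slope as
#' delta_j = delta_{j-1} + v_j. The initial state (theta_1, delta_1) has
#' independent Normal priors; the observation variance sigma2 and the two
#' evolution variances carry inverse-gamma (shape/scale) priors.
#'
#' Defaults: theta_1, delta_1 ~ N(0, 1e4); the evolution variances have the
#' vague IG(0.5, 72) prior, which implies almost no smoothing across doses;
#' sigma2 has the same weak IG(0.5, 0.7) prior as the Emax model's residual
#' variance, so that the residual variance is learned from the data rather
#' than dominated by the prior scale. Informative alternatives explored for
#' the evolution variances are IG(0.5, 0.5) and IG(2, 4).
#'
#' @param theta1_mean,theta1_var Normal prior on the placebo-level state.
#' @param delta1_mean,delta1_var Normal prior on the initial slope.
#' @param sigma2_shape,sigma2_scale IG prior on the observation variance.
#' @param sigma_theta2_shape,sigma_theta2_scale IG prior on the level
#'   evolution variance.
#' @param sigma_delta2_shape,sigma_delta2_scale IG prior on the slope
#'   evolution variance.
#' @return An object of class `ndlm_prior`.
#' @export
ndlm_prior <- function(theta1_mean = 0, theta1_var = 1e4,
                       delta1_mean = 0, delta1_var = 1e4,
                       sigma2_shape = 0.5, sigma2_scale = 0.7,
                       sigma_theta2_shape = 0.5, sigma_theta2_scale = 72,
                       sigma_delta2_shape = 0.5, sigma_delta2_scale = 72) {
  ig <- c(sigma2_shape, sigma2_scale, sigma_theta2_shape, sigma_theta2_scale,
          sigma_delta2_shape, sigma_delta2_scale)
  if (any(ig <= 0) || theta1_var <= 0 || delta1_var <= 0)
    stop("prior variances and inverse-gamma parameters must be positive")
  structure(list(theta1_mean = theta1_mean, theta1_var = theta1_var,
                 delta1_mean = delta1_mean, delta1_var = delta1_var,
                 sigma2_shape = sigma2_shape, sigma2_scale = sigma2_scale,
                 sigma_theta2_shape = sigma_theta2_shape,
                 sigma_theta2_scale = sigma_theta2_scale,
                 sigma_delta2_shape = sigma_delta2_shape,
                 sigma_delta2_scale = sigma_delta2_scale),
            class = "ndlm_prior")
}

#' Fit the Bayesian NDLM by Gibbs sampling with FFBS
#'
#' Each Gibbs cycle draws the joint state sequence (theta_1..theta_J,
#' delta_1..delta_J) from its exact Gaussian full conditional by
#' forward-filtering backward-sampling, then updates the observation and the
#' two evolution variances by their exact conjugate inverse-gamma steps.
#' Subjects at the same dose enter as repeated scalar observations of
#' theta_j; dose indices with no observations are handled as pure evolution
#' steps. The dose axis is the integer index 1..J (the nominal doses are
#' treated as equally spaced), so the fitted curve is free to rise and fall:
#' no monotonicity is imposed.
#'
#' @param data Data frame of subject records with columns `dose` and
#'   `response`; every dose must be on `grid`.
#' @param grid A [dose_grid()].
#' @param prior An [ndlm_prior()].
#' @param mcmc An [mcmc_control()].
#' @param fix_variances Optional named list with elements `sigma2`,
#'   `sigma_theta2`, `sigma_delta2`: hold all three variances fixed (no
#'   inverse-gamma step). With fixed variances the retained states are exact
#'   draws from the Gaussian smoothing distribution, which is what the
#'   brute-force smoother diagnostics check.
#' @return An object of class `c("ndlm_posterior", "model_posterior")` with
#'   elements `state_draws` (list of matrices `theta`, `delta`),
#'   `variance_draws` (data frame `sigma2`, `sigma_theta2`, `sigma_delta2`),
#'   `dose_means` (the theta draws, one column per grid dose), `grid`,
#'   `n_burnin`, `n_retained`.
#' @export
fit_ndlm <- function(data, grid = dose_grid(), prior = ndlm_prior(),
                     mcmc = mcmc_control(), fix_variances = NULL) {
  .check_subjects(data)
  stopifnot(inherits(grid, "dose_grid"), inherits(prior, "ndlm_prior"),
            inherits(mcmc, "mcmc_control"))
  idx <- match(data$dose, grid$doses)
  if (anyNA(idx)) stop("all subject doses must be on the dose grid")
  if (!is.null(mcmc$seed)) set.seed(mcmc$seed)

  s2 <- stats::var(data$response)
  if (!is.finite(s2) || s2 <= 0) s2 <- 1
  fixed <- !is.null(fix_variances)
  if (fixed) {
    stopifnot(all(c("sigma2", "sigma_theta2", "sigma_delta2") %in%
                    names(fix_variances)))
    init <- unlist(fix_variances[c("sigma2", "sigma_theta2",
                                   "sigma_delta2")])
    stopifnot(all(init > 0))
  } else {
    init <- c(s2, 1, 1)
  }

  res <- .ndlm_mcmc_cpp(
    as.numeric(data$response), as.integer(idx), length(grid$doses),
    prior$theta1_mean, prior$theta1_var,
    prior$delta1_mean, prior$delta1_var,
    prior$sigma2_shape, prior$sigma2_scale,
    prior$sigma_theta2_shape, prior$sigma_theta2_scale,
    prior$sigma_delta2_shape, prior$sigma_delta2_scale,
    mcmc$n_burnin, mcmc$n_retained,
    init[1], init[2], init[3], fixed)

  theta <- res$theta
  colnames(theta) <- as.character(grid$doses)
  delta <- res$delta
  colnames(delta) <- paste0("delta_", seq_along(grid$doses))
  vars <- as.data.frame(res$variances)
  names(vars) <- c("sigma2", "sigma_theta2", "sigma_delta2")
  structure(list(state_draws = list(theta = theta, delta = delta),
                 variance_draws = vars,
                 dose_means = theta, grid = grid,
                 n_burnin = mcmc$n_burnin, n_retained = mcmc$n_retained,
                 diagnostics = list()),
            class = c("ndlm_posterior", "model_posterior"))
}

#' Posterior summary of the NDLM fitted curve
#'
#' @param posterior An `ndlm_posterior` (or any `model_posterior`).
#' @param level Central credible-interval level.
#' @return A data frame with one row per grid dose: `dose`, `mean`, `lower`,
#'   `upper`.
#' @export
ndlm_fitted_curve <- function(posterior, level = 0.95) {
  stopifnot(inherits(posterior, "model_posterior"), level > 0, level < 1)
  dm <- posterior$dose_means
  a <- (1 - level) / 2
  qs <- apply(dm, 2, stats::quantile, probs = c(a, 1 - a), names = FALSE)
  data.frame(dose = posterior$grid$doses,
             mean = colMeans(dm), lower = qs[1, ], upper = qs[2, ],
             row.names = NULL)
}

#' Deviance information criterion for an NDLM fit
#'
#' As [dic_emax()], with the per-subject mean given by the state theta at
#' the subject's dose index; the effective number of parameters p_D counts
#' the latent states through the difference between the mean deviance and
#' the deviance at the posterior means.
#'
#' @param posterior An `ndlm_posterior` from [fit_ndlm()].
#' @param data The subject records the model was fitted to.
#' @return A list with elements `dic`, `p_d` and `mean_deviance`.
#' @export
dic_ndlm <- function(posterior, data) {
  stopifnot(inherits(posterior, "ndlm_posterior"))
  .check_subjects(data)
  idx <- match(data$dose, posterior$grid$doses)
  if (anyNA(idx)) stop("all subject doses must be on the fitted grid")
  th <- posterior$state_draws$theta
  s2 <- posterior$variance_draws$sigma2
  dev <- vapply(seq_len(nrow(th)), function(k) {
    .normal_deviance(data$response, th[k, idx], s2[k])
  }, numeric(1))
  th_hat <- colMeans(th)
  dev_hat <- .normal_deviance(data$response, th_hat[idx], mean(s2))
  mean_dev <- mean(dev)
  list(dic = 2 * mean_dev - dev_hat, p_d = mean_dev - dev_hat,
       mean_deviance = mean_dev)
}
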
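# Independent oracles used across the suite. These deliberately avoid the
# package's samplers: the smoother oracle conditions the joint Gaussian prior
# of the full state sequence on all observations at once by brute-force
# linear algebra, and the conjugate oracle is the textbook Normal
# linear-model posterior.

# Brute-force smoothing distribution of the locally-linear-trend DLM:
# state alpha_j = (theta_j, delta_j), transition [[1,1],[0,1]], evolution
# covariance diag(sth2, sde2), observations ybar_j ~ N(theta_j, s2/n_j).
oracle_smoother <- function(ybar, nobs, s2, sth2, sde2,
                            m1 = c(0, 0), V1 = diag(c(1e4, 1e4))) {
  J <- length(ybar)
  Tm <- matrix(c(1, 0, 1, 1), 2) # [[1,1],[0,1]]
  W <- diag(c(sth2, sde2))
  powT <- function(k) {
    M <- diag(2)
    for (i in seq_len(k)) M <- M %*% Tm
    M
  }
  mu <- numeric(2 * J)
  mu[1:2] <- m1
  P <- vector("list", J)
  P[[1]] <- V1
  for (j in 2:J) {
    P[[j]] <- Tm %*% P[[j - 1]] %*% t(Tm) + W
    mu[(2 * j - 1):(2 * j)] <- Tm %*% mu[(2 * (j - 1) - 1):(2 * (j - 1))]
  }
  Sig <- matrix(0, 2 * J, 2 * J)
  for (j in 1:J) for (k in j:J) {
    C <- P[[j]] %*% t(powT(k - j))
    Sig[(2 * j - 1):(2 * j), (2 * k - 1):(2 * k)] <- C
    Sig[(2 * k - 1):(2 * k), (2 * j - 1):(2 * j)] <- t(C)
  }
  obs <- which(nobs > 0)
  H <- matrix(0, length(obs), 2 * J)
  for (i in seq_along(obs)) H[i, 2 * obs[i] - 1] <- 1
  Rv <- diag(s2 / nobs[obs], length(obs))
  S <- H %*% Sig %*% t(H) + Rv
  K <- Sig %*% t(H) %*% solve(S)
  list(mean = drop(mu + K %*% (ybar[obs] - H %*% mu)),
       cov = Sig - K %*% H %*% Sig,
       theta_idx = seq(1, 2 * J, by = 2))
}

# Closed-form posterior of (E0, Emax) in the Emax model with ED50 and sigma2
# known: a conjugate Normal linear model with design [1, d/(ed50+d)].
oracle_emax_conjugate <- function(y, dose, ed50, sigma2,
                                  prior_mean = c(0, 0),
                                  prior_var = c(1e4, 1e4)) {
  X <- cbind(1, dose / (ed50 + dose))
  Prec <- diag(1 / prior_var) + crossprod(X) / sigma2
  b <- prior_mean / prior_var + crossprod(X, y) / sigma2
  V <- solve(Prec)
  list(mean = drop(V %*% b), cov = V)
}

# A degenerate model posterior whose every draw is the same curve.
degenerate_posterior <- function(curve, grid = dose_grid(), n_draws = 4) {
  as_model_posterior(matrix(curve, nrow = n_draws, ncol = length(curve),
                            byrow = TRUE), grid)
}

# Response generator that pays out pre-drawn per-dose queues, so two designs
# with the same per-dose allocation receive identical data regardless of
# enrolment order.
pooled_response_fn <- function(pool) {
  used <- stats::setNames(integer(length(pool)), names(pool))
  function(doses) {
    vapply(doses, function(d) {
      key <- as.character(d)
      used[[key]] <<- used[[key]] + 1L
      pool[[key]][used[[key]]]
    }, numeric(1))
  }
}

# Small fixed-design subject sample used by several fitter tests.
fixed_design_data <- function(profile, n_per_active = 8, seed = 1) {
  doses <- dose_grid()$doses
  simulate_responses(profile,
                     rep(doses, times = c(2 * n_per_active,
                                          rep(n_per_active, 6))),
                     seed = seed)
}
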
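#' Nominal dose grid
#'
#' The set of doses a trial can assign, placebo first. The default is the
#' seven-level grid used throughout the simulation study:
#' 0 (placebo), 0.03, 0.3, 3, 10, 20 and 30 mg/kg. Doses are half-log spaced
#' at the design stage (with the exception of 20 mg/kg) and 30 mg/kg is the
#' maximum tolerated dose. The grid also carries the integer index 1..J used
#' as the NDLM's equally-spaced dose axis.
#'
#' @param doses Numeric vector of dose levels in mg/kg, strictly increasing,
#'   with placebo (exactly 0) first.
#' @return An object of class `dose_grid`: a list with elements `doses` and
#'   `index`.
#' @examples
#' dose_grid()
#' @export
dose_grid <- function(doses = c(0, 0.03, 0.3, 3, 10, 20, 30)) {
  if (!is.numeric(doses) || length(doses) < 2 || anyNA(doses))
    stop("`doses` must be a numeric vector with at least two levels")
  if (doses[1] != 0)
    stop("the first dose must be placebo (exactly 0)")
  if (any(diff(doses) <= 0))
    stop("doses must be strictly increasing")
  structure(list(doses = as.numeric(doses), index = seq_along(doses)),
            class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  cat("Dose grid (mg/kg):", paste(x$doses, collapse = ", "), "\n")
  invisible(x)
}

# means of the tabulated U-shaped profile at the default grid
.ushape_doses <- c(0, 0.03, 0.3, 3, 10, 20, 30)
.ushape_means <- c(-0.5, -0.7, -1.6, -1.8, -1.2, -1, -0.6)

#' True dose-response profiles
#'
#' The four data-generating truths used to evaluate the designs, expressed as
#' mean change from baseline in DAS28 at day 56 (negative = improvement).
#' The placebo effect is -0.5 DAS28 points in all profiles:
#' \describe{
#'   \item{flat}{-0.5 at every dose (null effect); residual variance 0.25.}
#'   \item{emax}{-0.5 - 1.7 d / (2.5 + d): a monotone Emax curve with
#'     ED50 = 2.5 mg/kg; residual variance 1.44.}
#'   \item{loglinear}{-0.5 - log(d + 1); residual variance 1.44.}
#'   \item{ushape}{the tabulated non-monotone curve
#'     (-0.5, -0.7, -1.6, -1.8, -1.2, -1, -0.6) at doses
#'     0, 0.03, 0.3, 3, 10, 20, 30 mg/kg, with its peak effect at 3 mg/kg;
#'     residual variance 1.44. Defined only at these nominal doses.}
#' }
#' A `custom` profile can be supplied through `mean_fn` for what-if analyses.
#'
#' @param name One of `"flat"`, `"emax"`, `"loglinear"`, `"ushape"`,
#'   `"custom"`.
#' @param residual_variance Optional override of the residual variance of the
#'   subject-level Normal error (DAS28 points squared).
#' @param mean_fn For `name = "custom"` only: a vectorised function
#'   dose -> mean response.
#' @return An object of class `true_profile` with elements `name`, `mean_fn`
#'   and `residual_variance`.
#' @examples
#' true_mean(true_profile("emax"), 2.5) # half of the maximal effect
#' @export
true_profile <- function(name = c("flat", "emax", "loglinear", "ushape",
                                  "custom"),
                         residual_variance = NULL, mean_fn = NULL) {
  name <- match.arg(name)
  fn <- switch(name,
    flat = function(dose) rep(-0.5, length(dose)),
    emax = function(dose) -0.5 - 1.7 * dose / (2.5 + dose),
    loglinear = function(dose) -0.5 - log(dose + 1),
    ushape = function(dose) {
      i <- vapply(dose, function(d) {
        k <- which(abs(.ushape_doses - d) < 1e-9)
        if (length(k) != 1)
          stop("the ushape profile is defined only at the nominal doses ",
               paste(.ushape_doses, collapse = ", "))
        k
      }, integer(1))
      .ushape_means[i]
    },
    custom = {
      if (!is.function(mean_fn))
        stop("a custom profile requires `mean_fn`")
      mean_fn
    })
  if (is.null(residual_variance))
    residual_variance <- if (name == "flat") 0.25 else 1.44
  if (name == "custom" && is.null(residual_variance))
    stop("a custom profile requires `residual_variance`")
  if (!is.numeric(residual_variance) || residual_variance < 0)
    stop("`residual_variance` must be a non-negative number")
  structure(list(name = name, mean_fn = fn,
                 residual_variance = as.numeric(residual_variance)),
            class = "true_profile")
}

#' @export
print.true_profile <- function(x, ...) {
  cat("True dose-response profile:", x$name,
      sprintf("(residual variance %.3g)\n", x$residual_variance))
  invisible(x)
}

#' Deterministic mean response of a true profile
#'
#' @param profile A [true_profile()].
#' @param dose Numeric vector of doses (mg/kg, non-negative). The `ushape`
#'   profile is tabulated and may only be queried at its nominal doses.
#' @return Mean change in DAS28 at day 56 for each dose (no noise).
#' @export
true_mean <- function(profile, dose) {
  stopifnot(inherits(profile, "true_profile"))
  if (any(dose < 0)) stop("doses must be non-negative")
  profile$mean_fn(dose)
}

#' Simulate subject-level DAS28 change scores
#'
#' Draws one day-56 change-from-baseline response per allocated subject:
#' the profile's true mean at the assigned dose plus independent Normal noise
#' with the profile's residual variance.
#'
#' @param profile A [true_profile()].
#' @param allocation Numeric vector of assigned doses, one per subject, in
#'   enrolment order.
#' @param seed Optional integer seed (responses are reproducible given the
#'   seed; with `seed = NULL` the ambient RNG stream is used).
#' @param cohort Integer cohort labels, recycled over subjects (default 1).
#' @param start_id First subject id (useful when appending cohorts).
#' @return A data frame of subject records with columns `subject_id`,
#'   `cohort`, `dose`, `response`.
#' @examples
#' simulate_responses(true_profile("emax"), c(0, 0, 3, 30), seed = 1)
#' @export
simulate_responses <- function(profile, allocation, seed = NULL,
                               cohort = 1L, start_id = 1L) {
  stopifnot(inherits(profile, "true_profile"))
  if (length(allocation) == 0) stop("`allocation` must be non-empty")
  if (!is.null(seed)) set.seed(seed)
  mu <- true_mean(profile, allocation)
  resp <- mu + stats::rnorm(length(allocation),
                            sd = sqrt(profile$residual_variance))
  data.frame(subject_id = seq.int(start_id, length.out = length(allocation)),
             cohort = rep_len(as.integer(cohort), length(allocation)),
             dose = as.numeric(allocation),
             response = resp)
}

# 90%-of-maximum-effect rule shared by the true-curve and posterior-draw ED90:
# effects are placebo-minus-dose differences over the active doses, in grid
# order. Returns the lowest active dose whose effect reaches 90% of the
# maximum effect, or NA_real_ when no dose beats placebo.
.ed90_rule <- function(effects, active_doses) {
  m <- max(effects)
  if (!is.finite(m) || m <= 0) return(NA_real_)
  active_doses[which(effects >= 0.9 * m)[1]]
}

#' True ED90 of a profile on a dose grid
#'
#' The ED90 is the lowest nominal dose achieving at least 90% of the maximum
#' placebo-adjusted effect over the grid, with effect defined as
#' mean(placebo) - mean(dose) so that positive values indicate improvement.
#' When no active dose beats placebo the sentinel `NA` is returned
#' ("no effective dose").
#'
#' @param profile A [true_profile()].
#' @param grid A [dose_grid()].
#' @return The ED90 dose in mg/kg, or `NA_real_` when the maximum effect is
#'   not positive.
#' @examples
#' true_ed90(true_profile("emax"))   # 20
#' true_ed90(true_profile("ushape")) # 3
#' @export
true_ed90 <- function(profile, grid = dose_grid()) {
  stopifnot(inherits(profile, "true_profile"), inherits(grid, "dose_grid"))
  mu <- true_mean(profile, grid$doses)
  effects <- mu[1] - mu[-1]
  .ed90_rule(effects, grid$doses[-1])
}
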
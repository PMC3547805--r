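# Poisson trend model for annual death counts with a log person-time offset:
# a restricted cubic spline in calendar year captures the smooth trend and a
# step indicator for the first year under the new cause-of-death coding
# policy captures the sudden level change. The exponentiated step coefficient
# is the multiplication factor by which pre-change rates must be multiplied
# to be comparable with post-change rates.

#' Restricted cubic spline basis (truncated-power form)
#'
#' Harrell's restricted cubic spline: for k knots, one linear column plus
#' k-2 nonlinear columns built from truncated cubes and scaled by the
#' squared knot range, constrained so the function is linear beyond the
#' boundary knots.
#'
#' @param x Evaluation points (calendar years).
#' @param knots Strictly increasing knot vector, length >= 3 (default 1990,
#'   1995, 2000, 2004).
#' @return Numeric matrix with `length(knots) - 1` columns (`lin`,
#'   `rcs1`, ...), knots kept in an attribute.
#' @export
rcs_basis <- function(x, knots = c(1990, 1995, 2000, 2004)) {
  k <- length(knots)
  if (k < 3) stop("at least 3 knots are required")
  if (is.unsorted(knots, strictly = TRUE))
    stop("knots must be strictly increasing")
  km1 <- knots[k - 1]; kk <- knots[k]
  scale2 <- (kk - knots[1])^2
  p3 <- function(u) pmax(u, 0)^3
  nl <- vapply(seq_len(k - 2), function(j) {
    (p3(x - knots[j]) -
       p3(x - km1) * (kk - knots[j]) / (kk - km1) +
       p3(x - kk) * (km1 - knots[j]) / (kk - km1)) / scale2
  }, numeric(length(x)))
  b <- cbind(lin = x, matrix(nl, nrow = length(x),
                             dimnames = list(NULL,
                                             paste0("rcs", seq_len(k - 2)))))
  attr(b, "knots") <- knots
  b
}

#' Trend model specification
#'
#' @param step_year First calendar year under the new coding regime (the step
#'   indicator is `1(year >= step_year)`); `NULL` for a model without a step.
#' @param knots Spline knots; `NULL` for an intercept-only (degenerate)
#'   model.
#' @param cause,sex,age_group Optional labels describing the stratum being
#'   modelled (carried through to output).
#' @return List of class `trend_model_spec`.
#' @export
trend_model_spec <- function(step_year = 1995L,
                             knots = c(1990, 1995, 2000, 2004),
                             cause = NULL, sex = NULL, age_group = NULL) {
  structure(list(step_year = step_year, knots = knots, cause = cause,
                 sex = sex, age_group = age_group),
            class = "trend_model_spec")
}

#' Fit the Poisson trend model with a coding-change step
#'
#' Maximum-likelihood Poisson regression of annual death counts with design
#' `[intercept | rcs(year) | 1(year >= step_year)]` and offset
#' `log(person_years)`. Fitting iterates to a relative deviance change below
#' 1e-11 (at most 100 iterations); non-convergence and separation (a regime
#' with no events, which makes the step unidentifiable) are flagged, not
#' silently accepted.
#'
#' @param data data.frame with columns `year`, `deaths`, `person_years`
#'   (one row per stratum-year; multiple rows per year are allowed and
#'   treated as independent Poisson observations).
#' @param spec A [trend_model_spec()].
#' @return Object of class `poisson_trend_fit`: coefficients, covariance,
#'   log-likelihood, convergence/separation flags, and the data and spec for
#'   prediction.
#' @export
fit_poisson_trend <- function(data, spec = trend_model_spec()) {
  d <- as.data.table(data)
  stopifnot(all(c("year", "deaths", "person_years") %in% names(d)))
  d <- d[person_years > 0]
  if (nrow(d) == 0) stop("no stratum-year with positive person-time")
  if (sum(d$deaths) == 0)
    stop("all counts are zero; the model is unidentifiable")
  X <- matrix(numeric(0), nrow = nrow(d), ncol = 0)
  if (!is.null(spec$knots)) X <- rcs_basis(d$year, spec$knots)
  separation <- FALSE
  if (!is.null(spec$step_year)) {
    post <- as.numeric(d$year >= spec$step_year)
    if (all(post == 0) || all(post == 1))
      stop("years must span both coding regimes to identify the step")
    X <- cbind(X, step = post)
    if (sum(d$deaths[post == 0]) == 0 || sum(d$deaths[post == 1]) == 0)
      separation <- TRUE
  }
  off <- log(d$person_years)
  fit <- if (ncol(X)) {
    glm(d$deaths ~ X, family = poisson(), offset = off,
        control = glm.control(epsilon = 1e-11, maxit = 100))
  } else {
    glm(d$deaths ~ 1, family = poisson(), offset = off,
        control = glm.control(epsilon = 1e-11, maxit = 100))
  }
  cf <- coef(fit)
  names(cf) <- sub("^X", "", names(cf))
  V <- vcov(fit)
  dimnames(V) <- list(names(cf), names(cf))
  if (separation) warning("one coding regime has no events; ",
                          "the step coefficient is not identifiable")
  structure(list(
    coefficients = cf, vcov = V,
    loglik = as.numeric(logLik(fit)),
    converged = fit$converged && !separation,
    separation = separation,
    n_strata = nrow(d), data = d, spec = spec,
    glm = fit), class = "poisson_trend_fit")
}

#' @export
print.poisson_trend_fit <- function(x, ...) {
  lbl <- paste(c(x$spec$cause, x$spec$sex, x$spec$age_group), collapse = " ")
  cat("Poisson trend model", if (nzchar(lbl)) paste0("(", lbl, ")"), "\n")
  cat("  stratum-years:", x$n_strata, " log-likelihood:",
      format(x$loglik, digits = 6), "\n")
  print(round(x$coefficients, 4))
  if (!x$converged) cat("  WARNING: fit did not converge cleanly\n")
  invisible(x)
}

#' Multiplication factor for the coding-policy change
#'
#' The exponentiated step coefficient with its Wald 95% confidence interval:
#' the factor by which rates computed under the old coding policy must be
#' multiplied to be comparable with the new policy. The percent reduction is
#' `100 * (1 - factor)` rounded half away from zero to the integer.
#'
#' @param fit A converged [fit_poisson_trend()] result.
#' @return Object of class `multiplication_factor`.
#' @export
multiplication_factor <- function(fit) {
  stopifnot(inherits(fit, "poisson_trend_fit"))
  if (!fit$converged) stop("fit did not converge; no factor reported")
  if (!"step" %in% names(fit$coefficients))
    stop("the model has no step term")
  g <- fit$coefficients[["step"]]
  se <- sqrt(fit$vcov["step", "step"])
  as_multiplication_factor(exp(g), exp(g - 1.96 * se), exp(g + 1.96 * se),
                           se_log = se)
}

#' @rdname multiplication_factor
#' @param point,ci_low,ci_high A factor and its 95% CI (e.g. printed values
#'   from a published table), to be converted to percent reductions.
#' @param se_log Optional standard error of the log factor.
#' @export
as_multiplication_factor <- function(point, ci_low, ci_high, se_log = NA) {
  if (!(ci_low <= point && point <= ci_high) || any(c(point, ci_low,
                                                      ci_high) <= 0))
    stop("need 0 < ci_low <= point <= ci_high")
  structure(list(point = point, ci_low = ci_low, ci_high = ci_high,
                 se_log = se_log,
                 percent_reduction = percent_reduction(point),
                 percent_reduction_ci = c(percent_reduction(ci_high),
                                          percent_reduction(ci_low))),
            class = "multiplication_factor")
}

#' Percent reduction implied by a multiplication factor
#'
#' `100 * (1 - x)` rounded half away from zero to the nearest integer
#' (a factor of 0.843 is a 16% reduction).
#'
#' @param x Multiplication factor(s).
#' @return Integer percent reduction(s).
#' @export
percent_reduction <- function(x) as.integer(round_half_away(100 * (1 - x)))

#' @export
print.multiplication_factor <- function(x, ...) {
  cat(sprintf("Multiplication factor %.3f (95%% CI %.3f - %.3f)\n",
              x$point, x$ci_low, x$ci_high))
  cat(sprintf("  i.e. a %d%% change (95%% CI %d%% - %d%%) in rate at the switch\n",
              x$percent_reduction, x$percent_reduction_ci[1],
              x$percent_reduction_ci[2]))
  invisible(x)
}

#' Fitted and coding-adjusted rate series
#'
#' Fitted rates per 100,000 person-years by calendar year, with 95%
#' confidence intervals from the delta method on the linear predictor, plus
#' the adjusted series in which the step term is forced to its post-change
#' value for all years: the rates as if the new coding policy had applied
#' throughout. For years at or after the step year the two series coincide.
#'
#' @param fit A converged [fit_poisson_trend()] result.
#' @param years Years at which to evaluate (default: observed years).
#' @return data.table `(year, fitted_rate, fitted_lo, fitted_hi,
#'   adjusted_rate, adjusted_lo, adjusted_hi)`.
#' @export
adjusted_rate_series <- function(fit, years = NULL) {
  stopifnot(inherits(fit, "poisson_trend_fit"))
  if (!fit$converged) stop("fit did not converge")
  if (is.null(years)) years <- sort(unique(fit$data$year))
  X <- cbind(`(Intercept)` = 1,
             if (!is.null(fit$spec$knots)) rcs_basis(years, fit$spec$knots))
  if (!is.null(fit$spec$step_year)) {
    Xo <- cbind(X, step = as.numeric(years >= fit$spec$step_year))
    Xa <- cbind(X, step = 1)
  } else {
    Xo <- Xa <- X
  }
  Xo <- Xo[, names(fit$coefficients), drop = FALSE]
  Xa <- Xa[, names(fit$coefficients), drop = FALSE]
  band <- function(M) {
    lp <- drop(M %*% fit$coefficients)
    se <- sqrt(rowSums((M %*% fit$vcov) * M))
    list(rate = exp(lp) * 1e5, lo = exp(lp - 1.96 * se) * 1e5,
         hi = exp(lp + 1.96 * se) * 1e5)
  }
  f <- band(Xo); a <- band(Xa)
  data.table(year = years, fitted_rate = f$rate, fitted_lo = f$lo,
             fitted_hi = f$hi, adjusted_rate = a$rate, adjusted_lo = a$lo,
             adjusted_hi = a$hi)
}
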
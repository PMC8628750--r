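#' Damped cosine parameter set
#'
#' Container for the six parameters of the damped cosine model with a
#' linear baseline,
#' \deqn{y(t) = A e^{-\lambda t} \cos\!\big(2\pi (t - \theta)/\tau\big) + m t + b,}
#' where `A` is the amplitude (relative-expression units), `lambda` the
#' damping rate in 1/h (positive values damp the oscillation, negative
#' values grow it), `theta` the phase in hours, `tau` the intrinsic period
#' in hours, `m` the baseline slope (1/h) and `b` the y-intercept.
#'
#' @param A amplitude, must be >= 0 (a sign flip is absorbed into the phase).
#' @param lambda damping rate (1/h). Conventionally constrained to
#'   \[-0.05, 0.05\]; the constructor only warns outside that range so that
#'   generators can explore it.
#' @param theta phase (h).
#' @param tau intrinsic period (h), must be > 0.
#' @param m baseline slope (1/h).
#' @param b y-intercept (relative-expression units).
#'
#' @return An object of class `damped_cosine_params` (a named list).
#' @examples
#' p <- damped_cosine_params(A = 1, lambda = 0, theta = 6, tau = 24, m = 0, b = 0)
#' eval_damped_cosine(p, c(6, 12))
#' @export
damped_cosine_params <- function(A, lambda, theta, tau, m, b) {
  stopifnot(is.numeric(A), is.numeric(lambda), is.numeric(theta),
            is.numeric(tau), is.numeric(m), is.numeric(b))
  if (tau <= 0) stop("'tau' (period) must be > 0")
  if (A < 0) {
    # canonicalize: -A cos(x) = A cos(x + pi), i.e. shift phase by tau/2
    A <- -A
    theta <- theta + tau / 2
  }
  structure(list(A = A, lambda = lambda, theta = theta, tau = tau,
                 m = m, b = b),
            class = "damped_cosine_params")
}

#' @export
print.damped_cosine_params <- function(x, ...) {
  cat("Damped cosine with linear baseline\n")
  cat(sprintf("  A = %.4g  lambda = %.4g /h  theta = %.4g h  tau = %.4g h\n",
              x$A, x$lambda, x$theta, x$tau))
  cat(sprintf("  m = %.4g /h  b = %.4g\n", x$m, x$b))
  invisible(x)
}

as_damped_cosine_params <- function(p) {
  if (inherits(p, "damped_cosine_params")) return(p)
  p <- as.list(p)
  nm <- names(p)
  if (!all(c("A", "lambda", "theta", "tau", "m", "b") %in% nm))
    stop("parameters must contain A, lambda, theta, tau, m, b")
  damped_cosine_params(p$A, p$lambda, p$theta, p$tau, p$m, p$b)
}

#' Evaluate the damped cosine model
#'
#' @param params a [damped_cosine_params()] object (or a named list/vector
#'   with elements A, lambda, theta, tau, m, b).
#' @param times numeric vector of times (h).
#' @return Numeric vector of model values at `times`.
#' @export
eval_damped_cosine <- function(params, times) {
  p <- as_damped_cosine_params(params)
  stopifnot(is.numeric(times))
  p$A * exp(-p$lambda * times) * cos(2 * pi * (times - p$theta) / p$tau) +
    p$m * times + p$b
}

#' Peak times of the oscillatory component
#'
#' Peaks of the cosine factor, ignoring the damping envelope and the
#' linear baseline: the first peak falls at `theta mod tau` and subsequent
#' peaks every `tau` hours. This is the conventional "peak time into each
#' cycle" arithmetic used when reporting circadian phase.
#'
#' @param params a [damped_cosine_params()] object.
#' @param horizon report peaks in `[0, horizon]` hours (default 48).
#' @return Numeric vector of peak times (possibly empty when `A = 0`).
#' @examples
#' peak_times(damped_cosine_params(1, 0, 11.402, 26.546, 0, 0))
#' @export
peak_times <- function(params, horizon = 48) {
  p <- as_damped_cosine_params(params)
  if (p$A == 0) return(numeric(0))
  first <- p$theta %% p$tau
  if (first > horizon) return(numeric(0))
  seq(first, horizon, by = p$tau)
}

#' Derived circadian metrics
#'
#' Baseline change over the experiment (`m * horizon`) and the exponential
#' growth rate of the oscillation envelope. With the sign convention
#' `lambda > 0` damping / `lambda < 0` growing, the growth rate is
#' `-lambda` for growing oscillations and 0 (with a `"damping"` label
#' carrying `|lambda|`) otherwise.
#'
#' @inheritParams peak_times
#' @param horizon hours over which the baseline change is accumulated
#'   (default 48, the span of the standard design).
#' @return A list with `baseline_change`, `growth_rate`, `envelope`
#'   (`"growing"`, `"damping"` or `"flat"`) and `damping_rate`
#'   (`|lambda|` when damping, else 0).
#' @export
derived_metrics <- function(params, horizon = 48) {
  p <- as_damped_cosine_params(params)
  if (p$lambda < 0) {
    list(baseline_change = p$m * horizon, growth_rate = -p$lambda,
         envelope = "growing", damping_rate = 0)
  } else {
    list(baseline_change = p$m * horizon, growth_rate = 0,
         envelope = if (p$lambda > 0) "damping" else "flat",
         damping_rate = abs(p$lambda))
  }
}

#' Phase relationship between two fitted oscillations
#'
#' Circular distance between the first peak times of two converged fits,
#' measured on a circle whose circumference is the mean of the two
#' periods. The anti-phase flag is set when the offset lies within
#' `tolerance` (fraction) of half the mean period.
#'
#' @param fit_a,fit_b [cosinor_fit] objects (see [fit_damped_cosine()]) or
#'   `damped_cosine_params` objects.
#' @param tolerance relative tolerance on tau/2 for the anti-phase call
#'   (default 0.2, i.e. within 20 percent of half a period).
#' @return A list with `offset` (hours, in `[0, tau_bar/2]`), `antiphase`
#'   (logical) and `mean_period`.
#' @export
phase_relationship <- function(fit_a, fit_b, tolerance = 0.2) {
  pa <- extract_params(fit_a)
  pb <- extract_params(fit_b)
  tau_bar <- (pa$tau + pb$tau) / 2
  peak_a <- pa$theta %% pa$tau
  peak_b <- pb$theta %% pb$tau
  d <- (peak_a - peak_b) %% tau_bar
  offset <- min(d, tau_bar - d)
  half <- tau_bar / 2
  list(offset = offset,
       antiphase = abs(offset - half) <= tolerance * half,
       mean_period = tau_bar)
}

extract_params <- function(x) {
  if (inherits(x, "cosinor_fit")) {
    if (!isTRUE(x$converged)) stop("fit did not converge; no parameters available")
    return(x$params)
  }
  as_damped_cosine_params(x)
}
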
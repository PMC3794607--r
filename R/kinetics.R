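#' Fit a first-order mRNA decay constant
#'
#' Normalizes a decay time course to its t = 0 value and fits the
#' single-parameter exponential model \eqn{m(t) = e^{-k t}} by nonlinear least
#' squares ([stats::nls()]). Points flagged invalid (`NA`) are excluded. The
#' standard error of the estimate comes from the local curvature of the
#' least-squares objective (the `nls` linearization).
#'
#' @param decay Tibble with columns `time_min` and `value` (one series;
#'   replicates should be fitted separately or averaged beforehand). Must
#'   contain a t = 0 point and at least 3 valid points.
#' @return An object of class `decay_fit` with elements `k_deg` (1/min),
#'   `half_life` (min, `log(2)/k_deg`), `stderr_k`, `rss`, `n_points`.
#' @export
fit_degradation <- function(decay) {
  stopifnot_cols(decay, c("time_min", "value"), "decay series")
  d <- decay %>% filter(is.finite(.data$value)) %>% arrange(.data$time_min)
  if (any(duplicated(d$time_min))) abort("duplicate time points in decay series")
  if (nrow(d) < 3) abort("need at least 3 valid points to fit a decay constant")
  i0 <- which(d$time_min == 0)
  if (length(i0) != 1) abort("decay series must contain a t = 0 point")
  if (d$value[i0] <= 0) abort("t = 0 value must be positive for normalization")
  m <- d$value / d$value[i0]
  t <- d$time_min

  # log-linear start value through the positive points
  pos <- m > 0 & t > 0
  k0 <- if (sum(pos) >= 2) {
    max(1e-4, -stats::coef(stats::lm(log(m[pos]) ~ 0 + t[pos]))[[1]])
  } else 0.05

  fit <- tryCatch(
    # scaleOffset makes the convergence test sound for zero-residual
    # (noiseless) problems
    nls(m ~ exp(-k * t), start = list(k = k0),
        control = stats::nls.control(maxiter = 200, scaleOffset = 1,
                                     warnOnly = TRUE)),
    error = function(e) abort(paste0("decay fit failed: ", conditionMessage(e)))
  )
  k <- stats::coef(fit)[["k"]]
  if (k <= 0) {
    abort(sprintf(
      "data are not decaying: least-squares optimum at k = %.4g <= 0", k
    ))
  }
  smry <- summary(fit)
  structure(
    list(
      k_deg = k,
      half_life = log(2) / k,
      stderr_k = smry$coefficients["k", "Std. Error"],
      rss = sum(stats::residuals(fit)^2),
      n_points = length(m),
      data = tibble(time_min = t, value = m)
    ),
    class = "decay_fit"
  )
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf(
    "First-order decay fit: k_deg = %.4g /min (se %.2g), half-life = %.3g min, rss = %.3g (%d points)\n",
    x$k_deg, x$stderr_k, x$half_life, x$rss, x$n_points
  ))
  invisible(x)
}

#' @export
tidy.decay_fit <- function(x, ...) {
  tibble(
    term = "k_deg",
    estimate = x$k_deg,
    std.error = x$stderr_k,
    half_life_min = x$half_life
  )
}

#' @export
glance.decay_fit <- function(x, ...) {
  tibble(rss = x$rss, n_points = x$n_points, half_life_min = x$half_life)
}

#' Per-point derivative of a trace on a nonuniform grid
#'
#' At interior points the slope is the weighted average of the secant slopes of
#' the two adjacent segments, weighted by the *opposite* interval lengths:
#' \deqn{m'(t_i) \approx \frac{\Delta t_{after} s_{before} + \Delta t_{before} s_{after}}
#'   {\Delta t_{before} + \Delta t_{after}}}
#' which is the second-order-accurate nonuniform central difference (exact for
#' quadratics). Endpoints use the one-sided secant slope.
#'
#' @param trace Tibble with columns `time_min` (strictly increasing, >= 2
#'   points) and `value` (a replicate-mean trace).
#' @return Tibble with columns `time_min` and `slope` (units/min).
#' @export
derivative_weighted <- function(trace) {
  stopifnot_cols(trace, c("time_min", "value"), "trace")
  trace <- arrange(trace, .data$time_min)
  t <- trace$time_min
  m <- trace$value
  n <- length(t)
  if (n < 2) abort("need at least 2 points for a derivative")
  if (any(diff(t) <= 0)) abort("duplicate or non-increasing time points")
  sec <- diff(m) / diff(t) # secant slope of each segment
  slope <- numeric(n)
  slope[1] <- sec[1]
  slope[n] <- sec[n - 1]
  if (n > 2) {
    i <- 2:(n - 1)
    dt_before <- t[i] - t[i - 1]
    dt_after <- t[i + 1] - t[i]
    slope[i] <- (dt_after * sec[i - 1] + dt_before * sec[i]) /
      (dt_before + dt_after)
  }
  tibble(time_min = t, slope = slope)
}

#' Deconvolve the mRNA synthesis rate from an abundance trace
#'
#' Adds first-order degradation back onto the time derivative of mRNA
#' abundance, yielding a promoter-activity proxy at each sampled time point:
#' \deqn{S(t_i) = \frac{dm}{dt}(t_i) + K_{deg}\, m(t_i)}
#' with the derivative from [derivative_weighted()]. Values may be negative at
#' noisy points.
#'
#' @param trace Tibble with columns `time_min`, `value` (replicate-mean trace).
#' @param k_deg First-order degradation constant, 1/min (> 0).
#' @return Tibble with columns `time_min`, `synthesis` (expression units/min).
#' @export
synthesis_rate <- function(trace, k_deg) {
  if (!is.finite(k_deg) || k_deg <= 0) abort("k_deg must be > 0")
  d <- derivative_weighted(trace)
  trace <- arrange(trace, .data$time_min)
  tibble(time_min = d$time_min, synthesis = d$slope + k_deg * trace$value)
}
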
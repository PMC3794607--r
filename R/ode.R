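#' Calibrate the binding-driven expression ODE at its steady states
#'
#' The model is the reconstructed two-parameter production--degradation
#' balance
#' \deqn{\frac{dm}{dt} = K_{basal} + K_{eff}\,B(t)^n - K_{deg}\, m}
#' where `B(t)` is promoter fold enrichment (1 = no binding) and the Hill
#' coefficient `n` is +1 for activation or -1 for repression. Setting the right
#' hand side to zero at the pre- and post-perturbation steady states -- the
#' means of the first three and last three points of the expression and binding
#' time courses -- gives a 2x2 linear system that is solved exactly for
#' `K_basal` and `K_eff`.
#'
#' A negative solved `K_basal` is biologically suspect but not an error; the
#' returned object carries a `negative_basal` flag.
#'
#' @param expr Replicate-mean expression trace for one gene in the parent
#'   strain: tibble with columns `time_min`, `value` (>= 3 points on each side
#'   of the perturbation).
#' @param binding Binding curve tibble with columns `time_min`, `enrichment`.
#' @param n Hill coefficient sign, +1 (activation) or -1 (repression).
#' @param k_deg First-order mRNA degradation constant, 1/min.
#' @return An object of class `ode_params`: list with `k_basal`, `k_eff`, `n`,
#'   `k_deg`, `negative_basal`.
#' @export
calibrate_ode <- function(expr, binding, n, k_deg) {
  if (!n %in% c(-1, 1)) abort("Hill coefficient n must be +1 or -1")
  if (!is.finite(k_deg) || k_deg <= 0) abort("k_deg must be > 0")
  stopifnot_cols(expr, c("time_min", "value"), "expression trace")
  stopifnot_cols(binding, c("time_min", "enrichment"), "binding curve")
  expr <- arrange(expr, .data$time_min)
  binding <- arrange(binding, .data$time_min)
  if (nrow(expr) < 6 || nrow(binding) < 6) {
    abort("need at least 3 points on each side of the perturbation in both curves")
  }
  m_pre <- mean(head(expr$value, 3), na.rm = TRUE)
  m_post <- mean(tail(expr$value, 3), na.rm = TRUE)
  b_pre <- mean(head(binding$enrichment, 3))^n
  b_post <- mean(tail(binding$enrichment, 3))^n
  if (abs(b_pre - b_post) <= 1e-12 * max(abs(b_pre), abs(b_post))) {
    abort("binding indistinct across states: B_pre^n = B_post^n gives a singular system")
  }
  k_eff <- k_deg * (m_pre - m_post) / (b_pre - b_post)
  k_basal <- k_deg * m_pre - k_eff * b_pre
  negative_basal <- k_basal < 0
  if (negative_basal) {
    warn(sprintf("calibrated K_basal is negative (%.4g)", k_basal))
  }
  structure(
    list(k_basal = k_basal, k_eff = k_eff, n = n, k_deg = k_deg,
         negative_basal = negative_basal),
    class = "ode_params"
  )
}

#' @export
print.ode_params <- function(x, ...) {
  cat(sprintf(
    "ODE parameters: K_basal = %.4g, K_eff = %.4g, n = %+d, K_deg = %.4g /min%s\n",
    x$k_basal, x$k_eff, x$n, x$k_deg,
    if (isTRUE(x$negative_basal)) " [negative basal]" else ""
  ))
  invisible(x)
}

#' @export
tidy.ode_params <- function(x, ...) {
  tibble(
    term = c("k_basal", "k_eff", "n", "k_deg"),
    estimate = c(x$k_basal, x$k_eff, x$n, x$k_deg)
  )
}

# Forward-Euler integration of dm/dt = k_basal + k_eff * b(t)^n - k_deg * m.
# `b_fun` maps a vector of times to fold enrichment. m is floored at 0.
euler_expression <- function(params, b_fun, m0, t0, t1, dt) {
  n_steps <- ceiling(round((t1 - t0) / dt, 9))
  times <- t0 + (0:n_steps) * dt
  b <- b_fun(times)
  m <- numeric(length(times))
  m[1] <- m0
  syn <- params$k_basal + params$k_eff * b^params$n
  for (i in seq_len(length(times) - 1)) {
    m[i + 1] <- max(0, m[i] + dt * (syn[i] - params$k_deg * m[i]))
  }
  list(times = times, m = m)
}

#' Predict an expression trajectory from calibrated parameters
#'
#' Integrates the calibrated ODE forward with an explicit Euler scheme at a
#' 1-minute step (the scheme is part of the method: expression changes are
#' computed "every minute"). Binding is linearly interpolated between its
#' samples and held constant before the first and after the last sample.
#' Predicted abundance is floored at zero.
#'
#' @param params An `ode_params` object from [calibrate_ode()].
#' @param binding Binding curve tibble (`time_min`, `enrichment`).
#' @param m0 Initial expression level (> 0) at the first output time.
#' @param grid_out Times (minutes) at which to report the trajectory; the
#'   integration runs over `range(grid_out)`.
#' @param dt Euler step in minutes (default 1).
#' @return Tibble with columns `time_min`, `value`.
#' @export
predict_expression <- function(params, binding, m0, grid_out, dt = 1) {
  if (!inherits(params, "ode_params")) abort("params must be an 'ode_params' object")
  if (!is.finite(m0) || m0 <= 0) abort("m0 must be > 0")
  if (dt <= 0) abort("dt must be > 0")
  grid_out <- sort(as.numeric(grid_out))
  b_fun <- function(tt) interp_flat(binding$time_min, binding$enrichment, tt)
  sol <- euler_expression(params, b_fun, m0, min(grid_out), max(grid_out), dt)
  if (min(grid_out) < sol$times[1] || max(grid_out) > sol$times[length(sol$times)]) {
    abort("grid_out lies outside the integration span")
  }
  tibble(
    time_min = grid_out,
    value = stats::approx(sol$times, sol$m, xout = grid_out)$y
  )
}

#' Predict the knockout-strain trajectory (no binding)
#'
#' As [predict_expression()] but with the regulator deleted: fold enrichment is
#' the no-binding baseline `B(t) == 1`, so the trajectory is a monotone
#' first-order relaxation to the steady state `(K_basal + K_eff) / K_deg`.
#'
#' @inheritParams predict_expression
#' @return Tibble with columns `time_min`, `value`.
#' @export
predict_knockout <- function(params, m0, grid_out, dt = 1) {
  flat <- tibble(time_min = range(grid_out), enrichment = c(1, 1))
  predict_expression(params, flat, m0, grid_out, dt = dt)
}

#' Synthesis-rate residual traces for one gene
#'
#' Implements the residual diagnostic used to detect regulation the
#' binding-driven model cannot explain. The gene's replicate-mean traces are
#' jointly scaled to a maximum of 1 (one max per gene across both strains so
#' parent-calibrated parameters remain on the knockout's scale), the model is
#' recalibrated on the scaled parent trace, and at each design time point the
#' residual is the actual synthesis rate (from [synthesis_rate()]) minus the
#' model's instantaneous synthesis \eqn{K_{basal} + K_{eff} B(t)^n}
#' (with `B == 1` for the knockout strain).
#'
#' @param traces Mean-trace tibble for one gene with columns `strain`,
#'   `time_min`, `value`; must contain the parent strain, and optionally the
#'   knockout.
#' @param binding Binding curve tibble.
#' @param n Hill coefficient sign (+1 activation, -1 repression).
#' @param k_deg Degradation constant, 1/min.
#' @return Tibble with columns `strain`, `time_min`, `actual`, `predicted`,
#'   `residual` (normalized units/min), carrying the recalibrated parameters in
#'   attribute `"params"`.
#' @export
residual_trace <- function(traces, binding, n, k_deg) {
  stopifnot_cols(traces, c("strain", "time_min", "value"), "mean traces")
  if (!"parent" %in% traces$strain) abort("traces must include the parent strain")
  peak <- max(traces$value, na.rm = TRUE)
  if (!is.finite(peak) || peak <= 0) abort("traces must contain positive values")
  scaled <- traces %>% mutate(value = .data$value / peak)
  parent <- scaled %>% filter(.data$strain == "parent") %>% arrange(.data$time_min)
  params <- calibrate_ode(parent, binding, n = n, k_deg = k_deg)
  out <- scaled %>%
    group_by(.data$strain) %>%
    group_modify(function(d, key) {
      d <- arrange(d, .data$time_min)
      s <- synthesis_rate(d, k_deg)
      b <- if (key$strain == "parent") {
        interp_flat(binding$time_min, binding$enrichment, d$time_min)
      } else {
        rep(1, nrow(d))
      }
      pred <- params$k_basal + params$k_eff * b^params$n
      tibble(time_min = d$time_min, actual = s$synthesis, predicted = pred,
             residual = s$synthesis - pred)
    }) %>%
    ungroup()
  attr(out, "params") <- params
  out
}

#' Residual traces for every gene in a panel
#'
#' Applies [residual_trace()] gene by gene: replicate-mean traces are computed,
#' each gene is scaled to a joint maximum of 1, the model is calibrated on the
#' parent trace with the gene's degradation constant and regulatory sign, and
#' synthesis-rate residuals are returned for both strains.
#'
#' @param panel Long time-course tibble (both strains).
#' @param binding Binding curve tibble.
#' @param deg_table Tibble with columns `gene`, `k_deg`.
#' @param signs Optional tibble with columns `gene`, `n` giving the regulatory
#'   sign per gene; genes absent from it default to `default_n`.
#' @param default_n Sign used when a gene has no entry in `signs` (default +1).
#' @return Tibble with columns `gene`, `strain`, `time_min`, `actual`,
#'   `predicted`, `residual`.
#' @export
panel_residuals <- function(panel, binding, deg_table, signs = NULL,
                            default_n = 1) {
  stopifnot_cols(deg_table, c("gene", "k_deg"), "degradation table")
  traces <- mean_trace(panel)
  genes <- unique(traces$gene)
  missing_k <- setdiff(genes, deg_table$gene)
  if (length(missing_k) > 0) {
    abort(sprintf("no degradation constant for gene(s): %s",
                  paste(head(missing_k, 5), collapse = ", ")))
  }
  k_map <- setNames(deg_table$k_deg, deg_table$gene)
  n_map <- setNames(rep(default_n, length(genes)), genes)
  if (!is.null(signs)) {
    stopifnot_cols(signs, c("gene", "n"), "sign table")
    n_map[signs$gene] <- signs$n
  }
  purrr::map_dfr(genes, function(g) {
    res <- residual_trace(
      traces %>% filter(.data$gene == g) %>% select(-"gene"),
      binding, n = n_map[[g]], k_deg = k_map[[g]]
    )
    mutate(res, gene = g, .before = 1)
  })
}
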
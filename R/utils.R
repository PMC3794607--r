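# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random state.
with_seed_ <- function(seed, code) {
  withr::with_seed(seed, code)
}

# Piecewise-linear interpolation held constant outside the sampled range.
interp_flat <- function(x, y, xout) {
  stats::approx(x, y, xout = xout, method = "linear", rule = 2)$y
}

stopifnot_cols <- function(data, cols, what = "input table") {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(data)
}

# Average replicates at each (gene, strain, time) point; NA values are
# excluded pairwise (explicit validity flags, never silently dropped rows).
#' Average replicate series into one mean trace per gene and strain
#'
#' @param panel Long time-course tibble with columns `gene`, `strain`,
#'   `replicate`, `time_min`, `value`. Missing measurements are `NA` and are
#'   excluded pairwise from the mean.
#' @return Tibble with columns `gene`, `strain`, `time_min`, `value` sorted by
#'   gene, strain, time.
#' @export
mean_trace <- function(panel) {
  stopifnot_cols(panel, c("gene", "strain", "time_min", "value"), "panel")
  panel %>%
    group_by(.data$gene, .data$strain, .data$time_min) %>%
    summarise(value = mean(.data$value, na.rm = TRUE), .groups = "drop") %>%
    arrange(.data$gene, .data$strain, .data$time_min)
}

# Lognormal multiplicative noise with mean 1 and coefficient of variation cv.
lnorm_noise <- function(n, cv) {
  if (cv < 0) abort("noise cv must be >= 0")
  if (cv == 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
}
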
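#' One-sided Welch test against a fold-change threshold
#'
#' Tests whether the post-perturbation mean exceeds `fold` times the
#' pre-perturbation mean (direction `"up"`), or falls below `1/fold` times it
#' (direction `"down"`), using the one-sided Welch two-sample t statistic with
#' Welch-Satterthwaite degrees of freedom. The threshold is built into the
#' null by scaling the pre-group (`fold * pre` for up, `pre / fold` for down)
#' so that the boundary case "post equals exactly the fold-scaled pre" gives
#' t = 0 and p = 0.5. In the reference design the pre-group holds the first
#' three time points of a biological replicate's time course and the
#' post-group the last two; replicates are tested separately.
#'
#' @param pre Numeric vector of pre-perturbation values (>= 2, positive).
#' @param post Numeric vector of post-perturbation values (>= 2, positive).
#' @param fold Fold-change threshold (default 1.5).
#' @param direction `"up"` (post > fold * pre) or `"down"` (post < pre / fold).
#' @param log_scale If `TRUE`, the test is performed on log values with the
#'   log-fold offset (an alternative reading of "a 1.5-fold difference in
#'   means"); the default operates on the linear scale.
#' @return One-row tibble: `statistic`, `df`, `p_value`, `fold`, `direction`,
#'   `mean_pre`, `mean_post`.
#' @export
#' @examples
#' fold_change_test(c(10, 11, 9), c(30, 32), fold = 1.5, direction = "up")
fold_change_test <- function(pre, post, fold = 1.5,
                             direction = c("up", "down"), log_scale = FALSE) {
  direction <- match.arg(direction)
  pre <- as.numeric(pre)
  post <- as.numeric(post)
  if (length(pre) < 2 || length(post) < 2) {
    abort("need at least 2 values per group")
  }
  if (any(pre <= 0) || any(post <= 0)) abort("values must be positive")
  if (fold <= 0) abort("fold must be > 0")
  if (sd(pre) == 0 && sd(post) == 0) {
    abort("zero variance in both groups: p-value undefined")
  }
  if (log_scale) {
    x <- log(post)
    y <- if (direction == "up") log(pre) + log(fold) else log(pre) - log(fold)
  } else {
    x <- post
    y <- if (direction == "up") fold * pre else pre / fold
  }
  alternative <- if (direction == "up") "greater" else "less"
  ht <- t.test(x, y, alternative = alternative, var.equal = FALSE)
  tibble(
    statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = ht$p.value,
    fold = fold,
    direction = direction,
    mean_pre = mean(pre),
    mean_post = mean(post)
  )
}
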
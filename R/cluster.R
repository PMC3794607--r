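# Distance from each row of x to each centroid (rows of cent).
kmeans_dist <- function(x, cent, metric) {
  if (metric == "euclidean") {
    # squared Euclidean distance, the Lloyd objective
    d2 <- outer(rowSums(x^2), rep(1, nrow(cent))) +
      outer(rep(1, nrow(x)), rowSums(cent^2)) - 2 * x %*% t(cent)
    pmax(d2, 0)
  } else {
    1 - cor(t(x), t(cent))
  }
}

row_standardize <- function(x) {
  mu <- rowMeans(x)
  s <- apply(x, 1, sd)
  (x - mu) / s
}

lloyd_once <- function(x, k, metric, max_iter = 300) {
  n <- nrow(x)
  cent <- x[sample.int(n, k), , drop = FALSE]
  assign_old <- rep(0L, n)
  obj_trace <- numeric(0)
  for (iter in seq_len(max_iter)) {
    d <- kmeans_dist(x, cent, metric)
    assign_new <- max.col(-d, ties.method = "first")
    # re-seed empty clusters at the point farthest from its centroid until
    # every cluster has a member (at most k passes)
    for (pass in seq_len(k)) {
      empties <- which(tabulate(assign_new, k) == 0)
      if (length(empties) == 0) break
      for (j in empties) {
        far <- which.max(d[cbind(seq_len(n), assign_new)])
        cent[j, ] <- x[far, ]
      }
      d <- kmeans_dist(x, cent, metric)
      assign_new <- max.col(-d, ties.method = "first")
    }
    obj_trace <- c(obj_trace, sum(d[cbind(seq_len(n), assign_new)]))
    if (all(assign_new == assign_old)) break
    assign_old <- assign_new
    for (j in seq_len(k)) {
      members <- which(assign_new == j)
      if (length(members) == 0) next # keep previous centroid
      mu <- colMeans(x[members, , drop = FALSE])
      if (metric == "pearson") {
        if (sd(mu) == 0) mu <- x[members[1], ] # degenerate mean trace
        mu <- (mu - mean(mu)) / sd(mu)
      }
      cent[j, ] <- mu
    }
  }
  d <- kmeans_dist(x, cent, metric)
  list(
    assignments = assign_new,
    centroids = cent,
    inertia = sum(d[cbind(seq_len(n), assign_new)]),
    obj_trace = obj_trace,
    iterations = iter
  )
}

#' K-means clustering of expression or residual profiles
#'
#' Lloyd's algorithm with either squared Euclidean distance (used for model
#' residual traces, k = 5 in the reference analysis) or Pearson correlation
#' distance `d = 1 - r` (used for standardized expression profiles, k = 8).
#' Under the correlation metric each centroid is the arithmetic mean of its
#' member traces re-standardized to mean 0 / sd 1 after every update, so the
#' correlation to a centroid is well defined. Clusters that empty during an
#' iteration are re-seeded at the point farthest from its current centroid.
#' The best of `restarts` seeded random initializations (by total
#' within-cluster distance) is returned; results are deterministic given
#' `seed`.
#'
#' @param profiles Long tibble with columns `gene`, `time_min`, `value`; every
#'   gene must be sampled on the same grid. For the Pearson metric, constant
#'   traces are an error (standardize and exclude them first, see
#'   [standardize_profiles()]).
#' @param k Number of clusters (< number of profiles).
#' @param metric `"pearson"` or `"euclidean"`.
#' @param seed Integer seed for the restarts.
#' @param restarts Number of random initializations (default 25).
#' @param max_iter Lloyd iteration cap per restart.
#' @return An object of class `cluster_result`: `assignments` (tibble `gene`,
#'   `cluster`), `centroids` (tibble `cluster`, `time_min`, `value`), `k`,
#'   `metric`, `inertia`, `seed`, `restarts`, `obj_trace` (objective per
#'   iteration of the winning restart).
#' @export
cluster_profiles <- function(profiles, k, metric = c("pearson", "euclidean"),
                             seed = 1, restarts = 25, max_iter = 300) {
  metric <- match.arg(metric)
  stopifnot_cols(profiles, c("gene", "time_min", "value"), "profiles")
  wide <- profiles %>%
    arrange(.data$gene, .data$time_min) %>%
    tidyr::pivot_wider(names_from = "time_min", values_from = "value")
  genes <- wide$gene
  x <- as.matrix(wide[, -1])
  if (anyNA(x)) abort("all profiles must be sampled on the same time grid")
  if (k >= nrow(x)) abort("k must be smaller than the number of profiles")
  if (metric == "pearson") {
    if (any(apply(x, 1, sd) == 0)) {
      abort("constant trace under the Pearson metric; standardize and exclude constant genes first")
    }
    x <- row_standardize(x)
  }

  runs <- with_seed_(seed, {
    lapply(seq_len(restarts), function(r) lloyd_once(x, k, metric, max_iter))
  })
  best <- runs[[which.min(purrr::map_dbl(runs, "inertia"))]]

  times <- as.numeric(colnames(wide)[-1])
  centroids <- purrr::map_dfr(seq_len(k), function(j) {
    tibble(cluster = j, time_min = times, value = best$centroids[j, ])
  })
  structure(
    list(
      assignments = tibble(gene = genes, cluster = best$assignments),
      centroids = centroids,
      k = k, metric = metric, inertia = best$inertia, seed = seed,
      restarts = restarts, obj_trace = best$obj_trace,
      iterations = best$iterations,
      profiles = tibble(gene = genes) %>%
        dplyr::bind_cols(as_tibble(x, .name_repair = "minimal"))
    ),
    class = "cluster_result"
  )
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf(
    "k-means (%s distance), k = %d, %d profiles, inertia = %.4g (%d restarts)\n",
    x$metric, x$k, nrow(x$assignments), x$inertia, x$restarts
  ))
  print(table(cluster = x$assignments$cluster))
  invisible(x)
}

#' @export
tidy.cluster_result <- function(x, ...) {
  x$assignments
}

#' @export
glance.cluster_result <- function(x, ...) {
  tibble(k = x$k, metric = x$metric, inertia = x$inertia,
         n_profiles = nrow(x$assignments), iterations = x$iterations)
}

#' @export
autoplot.cluster_result <- function(object, ...) {
  times <- object$centroids$time_min[object$centroids$cluster == 1]
  prof_long <- object$profiles %>%
    tidyr::pivot_longer(-"gene", names_to = "idx", values_to = "value") %>%
    mutate(time_min = rep(times, times = nrow(object$profiles))) %>%
    left_join(object$assignments, by = "gene")
  ggplot2::ggplot(prof_long,
                  ggplot2::aes(x = .data$time_min, y = .data$value,
                               group = .data$gene)) +
    ggplot2::geom_line(alpha = 0.3) +
    ggplot2::geom_line(
      data = object$centroids,
      ggplot2::aes(x = .data$time_min, y = .data$value, group = NULL),
      colour = "red", linewidth = 1
    ) +
    ggplot2::facet_wrap(~cluster) +
    ggplot2::labs(x = "time (min)", y = "profile",
                  title = sprintf("k-means (%s), k = %d", object$metric,
                                  object$k))
}
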
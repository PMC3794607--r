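#' Hypergeometric functional-category enrichment of clusters
#'
#' For every (cluster, category) pair, tests over-representation of the
#' category among the cluster's genes with the upper-tail hypergeometric
#' probability \eqn{P(X \ge x)} of drawing `x` or more annotated genes when
#' `cluster size` genes are drawn without replacement from the clustered
#' population. Unannotated genes are assigned the category `"none"`. All pairs
#' are reported; pairs with `p_value < 0.01` are flagged significant (the
#' conventional reporting threshold for this analysis). A Benjamini-Hochberg
#' adjusted column `bh_q` is emitted additionally as an extension; the raw
#' hypergeometric p-value is the primary statistic.
#'
#' @param clusters A [cluster_profiles()] result, or a tibble with columns
#'   `gene`, `cluster`.
#' @param annotations Tibble with columns `gene`, `cog_category` (one category
#'   per gene). Categories absent from the clustered population get `p = 1`
#'   by convention and are flagged in `note`.
#' @return Tibble with columns `cluster`, `category`, `k_in_cluster`,
#'   `cluster_size`, `pop_annotated`, `pop_size`, `p_value`, `bh_q`,
#'   `significant`, `note`.
#' @export
cog_enrichment <- function(clusters, annotations) {
  if (inherits(clusters, "cluster_result")) clusters <- clusters$assignments
  stopifnot_cols(clusters, c("gene", "cluster"), "cluster assignments")
  stopifnot_cols(annotations, c("gene", "cog_category"), "annotation table")
  if (any(duplicated(annotations$gene))) {
    abort("each gene must carry exactly one category")
  }
  ann <- setNames(annotations$cog_category, annotations$gene)
  cat_by_gene <- ifelse(clusters$gene %in% names(ann),
                        unname(ann[clusters$gene]), "none")
  pop_size <- nrow(clusters)
  categories <- sort(unique(c(cat_by_gene, annotations$cog_category)))

  out <- purrr::map_dfr(sort(unique(clusters$cluster)), function(cl) {
    in_cl <- clusters$cluster == cl
    purrr::map_dfr(categories, function(term) {
      pop_k <- sum(cat_by_gene == term)
      x <- sum(in_cl & cat_by_gene == term)
      n_cl <- sum(in_cl)
      if (pop_k == 0) {
        p <- 1
        note <- "category absent from population"
      } else {
        p <- phyper(x - 1, pop_k, pop_size - pop_k, n_cl, lower.tail = FALSE)
        note <- NA_character_
      }
      tibble(
        cluster = cl, category = term, k_in_cluster = x, cluster_size = n_cl,
        pop_annotated = pop_k, pop_size = pop_size, p_value = p, note = note
      )
    })
  })
  out %>%
    mutate(
      bh_q = p.adjust(.data$p_value, method = "BH"),
      significant = .data$p_value < 0.01,
      .after = "p_value"
    )
}
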
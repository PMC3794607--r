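# Shared fixtures: everything is generated in code at test time.

suppressPackageStartupMessages({
  library(dplyr)
  library(tibble)
})

# An ode_params object without going through calibration.
make_params <- function(k_basal, k_eff, n, k_deg) {
  structure(
    list(k_basal = k_basal, k_eff = k_eff, n = n, k_deg = k_deg,
         negative_basal = k_basal < 0),
    class = "ode_params"
  )
}

# Flat pre/post steady-state trace consistent with planted parameters and a
# binding curve with flat pre/post segments (used for exact calibration).
steady_state_trace <- function(params, b_pre, b_post, grid = design_times()) {
  m_pre <- (params$k_basal + params$k_eff * b_pre^params$n) / params$k_deg
  m_post <- (params$k_basal + params$k_eff * b_post^params$n) / params$k_deg
  tibble(time_min = grid, value = ifelse(grid <= 0, m_pre, m_post))
}

# Step binding curve: b_pre up to and including the perturbation instant
# (occupancy is still undisturbed at t = 0), b_post afterwards.
step_binding <- function(b_pre = 14, b_post = 1, grid = binding_times()) {
  tibble(time_min = grid, enrichment = ifelse(grid <= 0, b_pre, b_post))
}

# Small long-format toy panel: 2 genes x 2 strains x 2 replicates x 10 times.
toy_panel <- function() {
  tidyr::crossing(
    gene = c("gA", "gB"), strain = c("parent", "knockout"),
    replicate = c("R1", "R2"), time_min = design_times()
  ) %>%
    mutate(value = 100 + as.numeric(factor(gene)) * 10 +
             (time_min - min(time_min)) / 60 +
             as.numeric(factor(replicate)))
}

# Brute-force upper-tail hypergeometric p by exhaustive subset enumeration:
# fraction of all size-n subsets of a population (pop_k annotated out of
# pop_n) containing at least x annotated members.
enum_hyper_p <- function(x, pop_k, pop_n, n) {
  flags <- c(rep(1, pop_k), rep(0, pop_n - pop_k))
  subsets <- utils::combn(pop_n, n)
  mean(colSums(matrix(flags[subsets], nrow = n)) >= x)
}

# Fold change planted direct-class parameters (mirrors the generator's
# construction): returns params with the given pre/post fold response.
plant_direct <- function(n, fold, k_deg, level, b_pre) {
  if (n == 1) {
    k_eff <- k_deg * level * (fold - 1) / (b_pre - 1)
    k_basal <- k_deg * level - k_eff
  } else {
    k_eff <- k_deg * level * (fold - 1) / (1 - 1 / b_pre)
    k_basal <- k_deg * fold * level - k_eff
  }
  make_params(k_basal, k_eff, n, k_deg)
}
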
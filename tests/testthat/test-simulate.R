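test_that("binding curve drops fast, relaxes to the post level and respects its invariants", {
  p <- binding_params(b_pre = 14, b_post = 2, lambda = 1, omega = 0)
  b <- simulate_binding(p, grid = c(-60, 0, 1, 2, 5, 10, 100, 1000))
  # constant before the perturbation, monotone approach afterwards (omega = 0)
  expect_true(all(b$enrichment[b$time_min < 0] == 14))
  post <- b$enrichment[b$time_min >= 0]
  expect_true(all(diff(post) <= 0)) # flat only once the tail underflows
  expect_true(all(diff(post[1:5]) < 0))
  # with lambda = 1/min the transition is 1 - exp(-2) ~ 86.5% complete at 2 min
  completion <- (14 - b$enrichment[b$time_min == 2]) / (14 - 2)
  expect_equal(completion, 1 - exp(-2), tolerance = 1e-12)
  # long-time limit is the post-perturbation steady state
  expect_equal(b$enrichment[b$time_min == 1000], 2, tolerance = 1e-6)

  # damped oscillation stays positive through the 0.5 * b_post floor
  osc <- simulate_binding(binding_params(b_pre = 14, b_post = 1, omega = 2),
                          grid = seq(0, 60, 0.5))
  expect_true(all(osc$enrichment >= 0.5))

  expect_error(binding_params(b_pre = 1, b_post = 2), "b_pre > b_post")
  expect_error(binding_params(lambda = 0), "lambda")
  expect_error(simulate_binding(p, grid = c(5, 10)), "perturbation")
})

test_that("decay experiments reproduce the exponential exactly at cv = 0 and are seed-stable", {
  d <- simulate_decay_experiment(0.1, grid = c(0, 5, 10, 20), cv = 0, seed = 1)
  expect_equal(d$value, exp(-0.1 * c(0, 5, 10, 20)), tolerance = 1e-12)

  # half-life 8 min: value halves at 8 min
  d8 <- simulate_decay_experiment(log(2) / 8, grid = c(0, 8, 16), cv = 0)
  expect_equal(d8$value, c(1, 0.5, 0.25), tolerance = 1e-12)

  a <- simulate_decay_experiment(0.05, cv = 0.2, seed = 99)
  b <- simulate_decay_experiment(0.05, cv = 0.2, seed = 99)
  expect_identical(a, b)
  expect_false(identical(
    a, simulate_decay_experiment(0.05, cv = 0.2, seed = 100)
  ))
  expect_error(simulate_decay_experiment(-1), "k_true")
  expect_error(simulate_decay_experiment(0.1, grid = c(5, 10)), "start at 0")
})

test_that("noiseless panel classes have their planted dynamics", {
  cfg <- panel_config(
    n_activated = 2, n_repressed = 2, n_ffl = 2, n_impulse = 2,
    n_no_change = 2, cv = 0, n_rep = 1, seed = 3
  )
  binding <- simulate_binding()
  sim <- simulate_panel(cfg, binding)
  traces <- mean_trace(sim$panel)
  get <- function(g, s) {
    traces %>% filter(gene == g, strain == s) %>% arrange(time_min) %>% pull(value)
  }

  # no-change genes: flat and identical in both strains
  expect_equal(diff(get("ctl_01", "parent")), rep(0, 9), tolerance = 1e-12)
  expect_equal(get("ctl_01", "parent"), get("ctl_01", "knockout"))

  # repressed gene: de-repression, parent rises monotonically after t = 0,
  # knockout flat
  rep_par <- get("rep_01", "parent")
  post <- rep_par[design_times() >= 0]
  expect_true(all(diff(post) > 0))
  expect_equal(diff(get("rep_01", "knockout")), rep(0, 9), tolerance = 1e-12)

  # impulse gene: identical post-perturbation dynamics in both strains, with a
  # transient excursion that returns toward baseline
  imp_par <- get("imp_01", "parent")
  expect_equal(imp_par, get("imp_01", "knockout"))
  expect_gt(max(imp_par), imp_par[1] * 1.5)
  expect_lt(abs(imp_par[10] - imp_par[1]) / imp_par[1], 0.05)

  # direct-class steady states differ between strains before the perturbation
  for (g in c("act_01", "rep_01")) {
    expect_gt(abs(get(g, "parent")[1] - get(g, "knockout")[1]) /
                get(g, "knockout")[1], 0.5)
  }
})

test_that("noiseless direct-class parent traces satisfy the expression ODE with planted parameters", {
  cfg <- panel_config(n_activated = 3, n_repressed = 3, n_ffl = 0,
                      n_impulse = 0, n_no_change = 0, cv = 0, n_rep = 1,
                      seed = 11)
  binding <- simulate_binding()
  sim <- simulate_panel(cfg, binding)
  traces <- mean_trace(sim$panel)
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[i, ]
    params <- make_params(tr$k_basal, tr$k_eff, tr$n, tr$k_deg)
    m0 <- (tr$k_basal + tr$k_eff * binding$enrichment[1]^tr$n) / tr$k_deg
    pred <- predict_expression(params, binding, m0, design_times())
    got <- traces %>%
      filter(gene == tr$gene, strain == "parent") %>%
      arrange(time_min)
    expect_lt(max(abs(got$value - pred$value)) / max(pred$value), 1e-6)
    # knockout sits at its no-binding steady state
    ko <- traces %>% filter(gene == tr$gene, strain == "knockout")
    expect_equal(ko$value, rep((tr$k_basal + tr$k_eff) / tr$k_deg, 10),
                 tolerance = 1e-9)
  }
})

test_that("panels are bit-identical under the same seed and planted folds are honored", {
  a <- simulate_panel(panel_config(seed = 5))
  b <- simulate_panel(panel_config(seed = 5))
  expect_identical(a, b)
  expect_false(identical(a$panel$value,
                         simulate_panel(panel_config(seed = 6))$panel$value))

  # exemplar fold changes are planted exactly (checked on the true means)
  cfg <- panel_config(cv = 0, n_rep = 1, seed = 2)
  sim <- simulate_panel(cfg)
  mt <- mean_trace(sim$panel)
  act <- mt %>% filter(gene == "act_01", strain == "parent") %>% arrange(time_min)
  expect_equal(mean(head(act$value, 3)) / mean(tail(act$value, 2)), 3.6,
               tolerance = 0.01)
  rep1 <- mt %>% filter(gene == "rep_01", strain == "parent") %>% arrange(time_min)
  expect_equal(mean(tail(rep1$value, 2)) / mean(head(rep1$value, 3)), 12.7,
               tolerance = 0.01)
})
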
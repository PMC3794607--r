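test_that("steady-state calibration solves the planted 2x2 system exactly", {
  binding <- step_binding(b_pre = 14, b_post = 1)
  set.seed(21)
  for (i in 1:10) {
    n <- sample(c(-1, 1), 1)
    truth <- make_params(
      k_basal = runif(1, 0.5, 5), k_eff = runif(1, 0.1, 3),
      n = n, k_deg = runif(1, 0.04, 0.2)
    )
    expr <- steady_state_trace(truth, 14, 1)
    fit <- calibrate_ode(expr, binding, n = n, k_deg = truth$k_deg)
    expect_equal(fit$k_basal, truth$k_basal, tolerance = 1e-10)
    expect_equal(fit$k_eff, truth$k_eff, tolerance = 1e-10)
  }
})

test_that("degenerate calibrations are reported as such", {
  flat_binding <- step_binding(b_pre = 5, b_post = 5)
  expr <- tibble(time_min = design_times(), value = rep(10, 10))
  expect_error(calibrate_ode(expr, flat_binding, n = 1, k_deg = 0.1),
               "singular|indistinct")

  # no regulation: equal expression states with distinct binding states
  binding <- step_binding()
  fit <- calibrate_ode(expr, binding, n = 1, k_deg = 0.1)
  expect_equal(fit$k_eff, 0)
  expect_equal(fit$k_basal, 0.1 * 10)

  # negative solved basal synthesis is a warning flag, not an error
  truth <- make_params(k_basal = -0.5, k_eff = 1, n = 1, k_deg = 0.1)
  expr2 <- steady_state_trace(truth, 14, 1)
  expect_warning(fit2 <- calibrate_ode(expr2, binding, n = 1, k_deg = 0.1),
                 "negative")
  expect_true(fit2$negative_basal)
  expect_equal(fit2$k_basal, -0.5, tolerance = 1e-10)
})

test_that("the Euler integrator holds fixed points and matches the closed-form solution", {
  k <- 0.02
  params <- make_params(k_basal = 1, k_eff = 0.2, n = 1, k_deg = k)
  b_const <- tibble(time_min = c(-240, 360), enrichment = c(5, 5))
  m_ss <- (1 + 0.2 * 5) / k

  flat <- predict_expression(params, b_const, m_ss, design_times())
  expect_lt(max(abs(flat$value - m_ss)) / m_ss, 1e-9)

  # analytic solution of the constant-input linear ODE, 1-min Euler step
  grid <- seq(0, 240, 5)
  m0 <- 3 * m_ss
  got <- predict_expression(params, b_const, m0, grid)
  exact <- m_ss + (m0 - m_ss) * exp(-k * grid)
  expect_lt(max(abs(got$value - exact) / exact), 0.005)

  # faster decay at a finer step stays within 0.5% of the closed form
  k2 <- 0.126
  p2 <- make_params(k_basal = 1, k_eff = 0.2, n = 1, k_deg = k2)
  m_ss2 <- (1 + 0.2 * 5) / k2
  got2 <- predict_expression(p2, b_const, 3 * m_ss2, grid, dt = 0.1)
  exact2 <- m_ss2 + (3 * m_ss2 - m_ss2) * exp(-k2 * grid)
  expect_lt(max(abs(got2$value - exact2) / exact2), 0.005)

  expect_error(predict_expression(params, b_const, -1, grid), "m0")
})

test_that("the 1-min Euler trajectory tracks a fine-step oracle through a binding step", {
  params <- make_params(k_basal = 1, k_eff = 0.3, n = 1, k_deg = 0.04)
  binding <- step_binding(b_pre = 8, b_post = 1)
  m0 <- (1 + 0.3 * 8) / 0.04
  coarse <- predict_expression(params, binding, m0, design_times(), dt = 1)
  fine <- predict_expression(params, binding, m0, design_times(), dt = 0.01)
  expect_lt(max(abs(coarse$value - fine$value) / fine$value), 0.01)
})

test_that("Euler refinement converges on panel-scale kinetics", {
  binding <- simulate_binding()
  set.seed(8)
  for (i in 1:6) {
    n <- sample(c(-1, 1), 1)
    params <- plant_direct(n, fold = runif(1, 2, 4.5),
                           k_deg = runif(1, 0.04, 0.15),
                           level = 100, b_pre = binding$enrichment[1])
    m0 <- (params$k_basal + params$k_eff * binding$enrichment[1]^n) /
      params$k_deg
    m1 <- predict_expression(params, binding, m0, design_times(), dt = 1)$value
    m05 <- predict_expression(params, binding, m0, design_times(), dt = 0.5)$value
    m025 <- predict_expression(params, binding, m0, design_times(), dt = 0.25)$value
    m0125 <- predict_expression(params, binding, m0, design_times(), dt = 0.125)$value
    # first-order convergence: each halving shrinks the change; the 1-min
    # step is within a few percent of the refined trajectory (the sharp
    # early binding transient dominates the error for repressed genes)
    r1 <- max(abs(m1 - m05) / m05)
    r2 <- max(abs(m05 - m025) / m025)
    r3 <- max(abs(m025 - m0125) / m0125)
    expect_lt(r1, 0.05)
    expect_lt(r2, r1)
    expect_lt(r3, r2)
    expect_lt(r3, 0.01)
  }
})

test_that("knockout predictions relax monotonically to the no-binding steady state", {
  params <- make_params(k_basal = 1, k_eff = 0.5, n = 1, k_deg = 0.05)
  ss <- (1 + 0.5) / 0.05
  ko <- predict_knockout(params, m0 = 3 * ss, grid_out = seq(0, 360, 5))
  expect_true(all(diff(ko$value) <= 1e-12))
  expect_equal(ko$value[length(ko$value)], ss, tolerance = 1e-4)

  # repressed gene: knockout steady state >= parent pre-perturbation state
  set.seed(31)
  for (i in 1:20) {
    p <- plant_direct(-1, fold = runif(1, 2, 10), k_deg = runif(1, 0.04, 0.2),
                      level = runif(1, 10, 100), b_pre = runif(1, 2, 20))
    ss_ko <- (p$k_basal + p$k_eff) / p$k_deg
    # parent pre-perturbation steady state under strong binding
    m_pre <- (p$k_basal + p$k_eff / 14) / p$k_deg
    expect_gte(ss_ko, m_pre)
  }

  # regulator-independent gene (k_eff = 0): knockout equals parent trajectory
  p0 <- make_params(k_basal = 2, k_eff = 0, n = 1, k_deg = 0.1)
  b <- simulate_binding()
  par_tr <- predict_expression(p0, b, m0 = 10, grid_out = design_times())
  ko_tr <- predict_knockout(p0, m0 = 10, grid_out = design_times())
  expect_equal(par_tr$value, ko_tr$value, tolerance = 1e-12)
})

test_that("predicted expression is sign-consistent with the regulatory mode", {
  binding <- simulate_binding() # drops at t = 0
  for (n in c(1, -1)) {
    params <- plant_direct(n, fold = 3, k_deg = 0.1, level = 100,
                           b_pre = binding$enrichment[1])
    m0 <- (params$k_basal + params$k_eff * binding$enrichment[1]^n) / 0.1
    tr <- predict_expression(params, binding, m0, seq(0, 360, 1))
    if (n == 1) {
      expect_true(all(diff(tr$value) <= 1e-9)) # activation: non-increasing
    } else {
      expect_true(all(diff(tr$value) >= -1e-9)) # repression: non-decreasing
    }
  }
})

test_that("calibration followed by prediction reproduces both steady states", {
  binding <- step_binding(b_pre = 10, b_post = 1.5)
  truth <- make_params(k_basal = 0.8, k_eff = 0.4, n = 1, k_deg = 0.06)
  expr <- steady_state_trace(truth, 10, 1.5)
  fit <- calibrate_ode(expr, binding, n = 1, k_deg = 0.06)
  m_pre <- expr$value[1]
  m_post <- expr$value[10]
  pred <- predict_expression(fit, binding, m_pre, design_times())
  expect_equal(pred$value[1], m_pre, tolerance = 1e-9)
  expect_equal(pred$value[10], m_post, tolerance = 0.01 * m_post)
})

test_that("residual traces separate regulatory classes as planted", {
  binding <- simulate_binding()
  cfg <- panel_config(n_activated = 3, n_repressed = 3, n_ffl = 3,
                      n_impulse = 3, n_no_change = 2, cv = 0, n_rep = 1,
                      seed = 13)
  sim <- simulate_panel(cfg, binding)
  res <- panel_residuals(sim$panel, binding,
                         sim$truth %>% select(gene, k_deg),
                         sim$truth %>% select(gene, n))
  res <- res %>% left_join(sim$truth %>% select(gene, class), by = "gene")

  # direct-class genes: residual small relative to peak synthesis away from
  # the perturbation instant (the discrete derivative smears the jump at t=0)
  direct <- res %>%
    filter(class %in% c("activated_direct", "repressed_direct"),
           strain == "parent")
  by_gene <- direct %>%
    group_by(gene) %>%
    summarise(
      rel = max(abs(residual[time_min >= 10 & time_min <= 180])) /
        max(abs(actual))
    )
  expect_true(all(by_gene$rel < 0.10))

  # FFL targets: positive excursion inside the 20-45 min window in the
  # parent, absent from the knockout
  ffl <- res %>% filter(class == "ffl_target")
  for (g in unique(ffl$gene)) {
    par <- ffl %>% filter(gene == g, strain == "parent")
    ko <- ffl %>% filter(gene == g, strain == "knockout")
    win_par <- max(par$residual[par$time_min >= 20 & par$time_min <= 45])
    win_ko <- max(ko$residual[ko$time_min >= 20 & ko$time_min <= 45])
    expect_gt(win_par, 0.05)
    expect_lt(abs(win_ko), 0.2 * win_par)
  }

  # impulse genes: excursion right after t = 0 and near-identical residuals
  # in both strains
  imp <- res %>% filter(class == "independent_impulse")
  for (g in unique(imp$gene)) {
    wide <- imp %>%
      filter(gene == g) %>%
      select(strain, time_min, residual) %>%
      tidyr::pivot_wider(names_from = strain, values_from = residual)
    expect_gt(cor(wide$parent, wide$knockout), 0.99)
    peak_t <- wide$time_min[which.max(wide$parent)]
    expect_true(peak_t > 0 && peak_t <= 20)
  }
})
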
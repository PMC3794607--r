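#' Parameters of the synthetic promoter-binding curve
#'
#' The binding model emulates the measured occupancy of a sugar-responsive
#' repressor/activator at its reference promoter: constant fold enrichment
#' `b_pre` before the nutrient perturbation, then a damped-cosine relaxation to
#' a new steady state `b_post`,
#' \deqn{B(t) = B_{post} + (B_{pre} - B_{post})\, e^{-\lambda t} \cos(\omega t), \quad t \ge 0,}
#' floored at `0.5 * b_post` so enrichment stays positive. With the default
#' `lambda` = 1/min the dissociation is ~87% complete 2 minutes after the
#' stimulus.
#'
#' @param b_pre Fold enrichment before the perturbation (> `b_post`). The
#'   default 14 makes a 12.7-fold de-repression representable with nonnegative
#'   basal synthesis in the expression model (maximum fold response equals
#'   `b_pre / b_post`).
#' @param b_post Fold enrichment after the perturbation (>= 1; 1 = no binding).
#' @param lambda Relaxation rate, 1/min (> 0).
#' @param omega Oscillation angular frequency, rad/min (>= 0).
#' @param t_perturb Perturbation time, minutes.
#' @return An object of class `binding_params`.
#' @export
binding_params <- function(b_pre = 14, b_post = 1, lambda = 1, omega = 0.15,
                           t_perturb = 0) {
  if (!(b_pre > b_post && b_post >= 1)) abort("need b_pre > b_post >= 1")
  if (lambda <= 0) abort("lambda must be > 0")
  if (omega < 0) abort("omega must be >= 0")
  structure(
    list(b_pre = b_pre, b_post = b_post, lambda = lambda, omega = omega,
         t_perturb = t_perturb),
    class = "binding_params"
  )
}

#' Simulate a promoter-binding enrichment curve
#'
#' @param params A [binding_params()] object.
#' @param grid Sampling times in minutes; must cover the perturbation time.
#'   Default [binding_times()].
#' @return Binding curve tibble with columns `time_min`, `enrichment`.
#' @export
simulate_binding <- function(params = binding_params(), grid = binding_times()) {
  if (!inherits(params, "binding_params")) abort("params must be 'binding_params'")
  grid <- sort(as.numeric(grid))
  if (min(grid) > params$t_perturb || max(grid) < params$t_perturb) {
    abort("sampling grid must cover the perturbation time")
  }
  tt <- grid - params$t_perturb
  b <- ifelse(
    tt < 0,
    params$b_pre,
    params$b_post +
      (params$b_pre - params$b_post) * exp(-params$lambda * tt) *
        cos(params$omega * tt)
  )
  b <- pmax(b, 0.5 * params$b_post)
  tibble(time_min = grid, enrichment = b)
}

#' Simulate an mRNA decay experiment
#'
#' One transcript's abundance after transcription arrest: `exp(-k_true * t)`
#' (t = 0 value fixed to 1 before noise) with multiplicative lognormal
#' measurement noise of coefficient of variation `cv` (mean 1).
#'
#' @param k_true True decay constant, 1/min (> 0).
#' @param grid Sampling times starting at 0, minutes.
#' @param cv Noise coefficient of variation (>= 0).
#' @param seed Integer seed; identical seeds give identical series.
#' @return Tibble with columns `time_min`, `value`.
#' @export
simulate_decay_experiment <- function(k_true,
                                      grid = c(0, 4, 8, 12, 20, 32, 48, 64),
                                      cv = 0.1, seed = 1) {
  if (!is.finite(k_true) || k_true <= 0) abort("k_true must be > 0")
  grid <- sort(as.numeric(grid))
  if (grid[1] != 0) abort("decay sampling grid must start at 0")
  true <- exp(-k_true * grid)
  noise <- with_seed_(seed, lnorm_noise(length(grid), cv))
  tibble(time_min = grid, value = true * noise)
}

#' Configuration of the synthetic two-strain expression panel
#'
#' Defines how many genes of each regulatory class the panel contains and the
#' kinetic ranges their planted parameters are drawn from. Classes:
#' `activated_direct` (regulator-bound promoter activates; expression falls
#' when the regulator dissociates), `repressed_direct` (de-repression: it
#' rises), `ffl_target` (target of a coherent OR feed-forward loop through a
#' slow effector), `independent_impulse` (a regulator-independent transient
#' synthesis pulse, identical in both strains) and `no_change` (flat controls).
#' The first activated and repressed genes are exemplars planted at fixed fold
#' changes (3.6-fold de-activation, 12.7-fold de-repression) so headline fold
#' responses can be re-measured from the simulated data.
#'
#' @param n_activated,n_repressed,n_ffl,n_impulse,n_no_change Class sizes.
#' @param cv Multiplicative measurement noise CV per replicate.
#' @param n_rep Number of replicates.
#' @param seed Integer seed; identical seeds give bit-identical panels.
#' @param k_deg_range Per-gene mRNA decay constants, 1/min (uniform draw).
#' @param level_range Baseline expression levels, counts (log-uniform draw).
#' @param act_fold_range Fold de-activation of activated genes (uniform).
#' @param rep_fold_range Fold de-repression of repressed genes (uniform).
#' @param ffl_k_y Shared effector decay constant of the feed-forward loop,
#'   1/min.
#' @param ffl_k_z_range Per-gene target mRNA decay constants, 1/min (uniform).
#' @param ffl_basal_frac Target basal synthesis as a fraction of its gated
#'   amplitude.
#' @param impulse_amp_range Pulse synthesis amplitude as a multiple of basal
#'   synthesis (uniform).
#' @param impulse_rise,impulse_decay Pulse rise and decay time scales, minutes.
#' @param exemplar_act_fold,exemplar_rep_fold Planted fold changes of the two
#'   exemplar genes.
#' @return An object of class `panel_config`.
#' @export
panel_config <- function(n_activated = 30, n_repressed = 20, n_ffl = 12,
                         n_impulse = 15, n_no_change = 23,
                         cv = 0.1, n_rep = 2, seed = 1,
                         k_deg_range = c(0.04, 0.15),
                         level_range = c(100, 2000),
                         act_fold_range = c(2, 4.5),
                         rep_fold_range = c(3, 10),
                         ffl_k_y = 0.034,
                         ffl_k_z_range = c(0.10, 0.15),
                         ffl_basal_frac = 0.1,
                         impulse_amp_range = c(2, 4),
                         impulse_rise = 5, impulse_decay = 30,
                         exemplar_act_fold = 3.6,
                         exemplar_rep_fold = 12.7) {
  counts <- c(n_activated, n_repressed, n_ffl, n_impulse, n_no_change)
  if (any(counts < 0)) abort("class counts must be >= 0")
  if (cv < 0) abort("cv must be >= 0")
  if (n_rep < 1) abort("need at least one replicate")
  structure(
    list(
      n_activated = n_activated, n_repressed = n_repressed, n_ffl = n_ffl,
      n_impulse = n_impulse, n_no_change = n_no_change,
      cv = cv, n_rep = n_rep, seed = seed,
      k_deg_range = k_deg_range, level_range = level_range,
      act_fold_range = act_fold_range, rep_fold_range = rep_fold_range,
      ffl_k_y = ffl_k_y, ffl_k_z_range = ffl_k_z_range,
      ffl_basal_frac = ffl_basal_frac,
      impulse_amp_range = impulse_amp_range,
      impulse_rise = impulse_rise, impulse_decay = impulse_decay,
      exemplar_act_fold = exemplar_act_fold,
      exemplar_rep_fold = exemplar_rep_fold
    ),
    class = "panel_config"
  )
}

# Integrate dm/dt = s(t) - k_deg * m by explicit Euler at dt and sample at
# `sample_times`. `s_fun` maps times to synthesis rates.
euler_synthesis <- function(s_fun, k_deg, m0, t0, t1, dt, sample_times) {
  n_steps <- ceiling(round((t1 - t0) / dt, 9))
  times <- t0 + (0:n_steps) * dt
  s <- s_fun(times)
  m <- numeric(length(times))
  m[1] <- m0
  for (i in seq_len(length(times) - 1)) {
    m[i + 1] <- max(0, m[i] + dt * (s[i] - k_deg * m[i]))
  }
  stats::approx(times, m, xout = sample_times)$y
}

#' Simulate the two-strain expression panel
#'
#' Generates replicate expression time courses for both the parent and the
#' regulator-knockout strain on the ten-point design grid, plus a ground-truth
#' ledger of every planted parameter. Direct-class genes integrate the
#' binding-driven expression ODE against the supplied binding curve in the
#' parent and against the no-binding baseline (`B == 1`) in the knockout;
#' feed-forward targets follow the logic model driven by the unit-scaled
#' binding curve (knockout input held inactive); impulse genes receive an
#' exogenous synthesis pulse identical in both strains; no-change genes are
#' flat. Measurement noise is multiplicative lognormal per replicate.
#'
#' @param config A [panel_config()].
#' @param binding Binding curve tibble (default [simulate_binding()] with
#'   default parameters).
#' @param grid Design sampling times (default [design_times()]).
#' @return A list with elements `panel` (long tibble: `gene`, `strain`,
#'   `replicate`, `time_min`, `value`) and `truth` (one row per gene:
#'   `gene`, `class`, `n`, `k_deg`, `k_basal`, `k_eff`, `level`, `fold`,
#'   `k_y`, `k_z`, `impulse_amp`).
#' @export
simulate_panel <- function(config = panel_config(),
                           binding = simulate_binding(),
                           grid = design_times()) {
  if (!inherits(config, "panel_config")) abort("config must be a 'panel_config'")
  stopifnot_cols(binding, c("time_min", "enrichment"), "binding curve")
  grid <- sort(as.numeric(grid))
  with_seed_(config$seed, simulate_panel_(config, binding, grid))
}

simulate_panel_ <- function(config, binding, grid) {
  t0 <- min(grid)
  t1 <- max(grid)
  b_pre <- binding$enrichment[1]
  b_fun <- function(tt) interp_flat(binding$time_min, binding$enrichment, tt)
  runif1 <- function(rng) runif(1, rng[1], rng[2])
  rlevel <- function() exp(runif(1, log(config$level_range[1]),
                                 log(config$level_range[2])))

  truth <- list()
  true_traces <- list()
  add_gene <- function(gene, class, n, k_deg, k_basal, k_eff, level, fold,
                       k_y, k_z, impulse_amp, parent, knockout) {
    truth[[gene]] <<- tibble(
      gene = gene, class = class, n = n, k_deg = k_deg, k_basal = k_basal,
      k_eff = k_eff, level = level, fold = fold, k_y = k_y, k_z = k_z,
      impulse_amp = impulse_amp
    )
    true_traces[[gene]] <<- tibble(
      gene = gene,
      strain = rep(c("parent", "knockout"), each = length(grid)),
      time_min = rep(grid, 2),
      true = c(parent, knockout)
    )
  }

  direct_gene <- function(gene, n, fold, k_deg, level) {
    # level = the lower of the two steady states; fold = high/low ratio
    if (n == 1) {
      m_post <- level
      m_pre <- fold * level
      k_eff <- k_deg * level * (fold - 1) / (b_pre - 1)
      k_basal <- k_deg * m_post - k_eff * 1
    } else {
      m_pre <- level
      m_post <- fold * level
      k_eff <- k_deg * level * (fold - 1) / (1 - 1 / b_pre)
      k_basal <- k_deg * m_post - k_eff * 1
    }
    if (k_basal < -1e-9) {
      abort(sprintf("infeasible planted fold %.3g for gene %s", fold, gene))
    }
    k_basal <- max(k_basal, 0)
    params <- structure(
      list(k_basal = k_basal, k_eff = k_eff, n = n, k_deg = k_deg,
           negative_basal = FALSE),
      class = "ode_params"
    )
    parent <- predict_expression(params, binding, m0 = m_pre, grid_out = grid)$value
    m_ko <- (k_basal + k_eff) / k_deg
    knockout <- rep(m_ko, length(grid))
    add_gene(gene, if (n == 1) "activated_direct" else "repressed_direct",
             n, k_deg, k_basal, k_eff, level, fold, NA_real_, NA_real_,
             NA_real_, parent, knockout)
  }

  ffl_gene <- function(gene, k_z, level) {
    x <- scale_unit(tibble(time_min = binding$time_min,
                           value = binding$enrichment))
    model <- ffl_model(k_y = config$ffl_k_y, k_z = k_z)
    sim <- simulate_ffl(model, x, dt = 0.1, t_start = t0, t_end = t1)
    z_unit <- stats::approx(sim$time_min, sim$z, xout = grid)$y
    basal_level <- config$ffl_basal_frac * level
    parent <- level * z_unit + basal_level
    knockout <- rep(basal_level, length(grid))
    add_gene(gene, "ffl_target", 1, k_z, NA_real_, NA_real_, level, NA_real_,
             config$ffl_k_y, k_z, NA_real_, parent, knockout)
  }

  impulse_gene <- function(gene, amp, k_deg, level) {
    k_basal <- k_deg * level
    s_fun <- function(tt) {
      pulse <- ifelse(
        tt > 0,
        (1 - exp(-tt / config$impulse_rise)) * exp(-tt / config$impulse_decay),
        0
      )
      k_basal * (1 + amp * pulse)
    }
    tr <- euler_synthesis(s_fun, k_deg, m0 = level, t0 = t0, t1 = t1, dt = 1,
                          sample_times = grid)
    add_gene(gene, "independent_impulse", 1, k_deg, k_basal, 0, level,
             NA_real_, NA_real_, NA_real_, amp, tr, tr)
  }

  flat_gene <- function(gene, k_deg, level) {
    tr <- rep(level, length(grid))
    add_gene(gene, "no_change", 1, k_deg, k_deg * level, 0, level, NA_real_,
             NA_real_, NA_real_, NA_real_, tr, tr)
  }

  for (i in seq_len(config$n_activated)) {
    fold <- if (i == 1) config$exemplar_act_fold else runif1(config$act_fold_range)
    direct_gene(sprintf("act_%02d", i), 1, fold,
                runif1(config$k_deg_range), rlevel())
  }
  for (i in seq_len(config$n_repressed)) {
    fold <- if (i == 1) config$exemplar_rep_fold else runif1(config$rep_fold_range)
    direct_gene(sprintf("rep_%02d", i), -1, fold,
                runif1(config$k_deg_range), rlevel())
  }
  for (i in seq_len(config$n_ffl)) {
    ffl_gene(sprintf("ffl_%02d", i), runif1(config$ffl_k_z_range), rlevel())
  }
  for (i in seq_len(config$n_impulse)) {
    impulse_gene(sprintf("imp_%02d", i), runif1(config$impulse_amp_range),
                 runif1(config$k_deg_range), rlevel())
  }
  for (i in seq_len(config$n_no_change)) {
    flat_gene(sprintf("ctl_%02d", i), runif1(config$k_deg_range), rlevel())
  }

  truth <- bind_rows(truth)
  true_long <- bind_rows(true_traces)
  reps <- sprintf("R%d", seq_len(config$n_rep))
  panel <- tidyr::crossing(true_long, replicate = reps) %>%
    mutate(value = .data$true * lnorm_noise(dplyr::n(), config$cv)) %>%
    select("gene", "strain", "replicate", "time_min", "value") %>%
    arrange(.data$gene, .data$strain, .data$replicate, .data$time_min)
  list(panel = panel, truth = truth)
}
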
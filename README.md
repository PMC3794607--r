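# grndyn

Dynamic perturbation analysis of transcription-factor-driven gene regulatory
networks.

## The problem

A global metabolic transcription factor can bind ~100 promoters, acting as an
activator at some and a repressor at others, alone at some and together with
secondary regulators at others. Steady-state measurements of expression and
promoter occupancy cannot separate these cases. `grndyn` implements the
dynamic alternative: perturb the system (e.g. add a sugar that strips the
regulator off its sites within minutes), sample promoter occupancy
(ChIP-qPCR fold enrichment) and mRNA abundance (counts) on a common time
grid in a parent strain and a regulator-knockout strain, and decompose each
gene's response into what occupancy explains and what it cannot.

The core quantities:

* **Synthesis rate** — per time point, `S(t) = dm/dt + K_deg * m`, the
  promoter-activity proxy obtained by adding first-order degradation back
  onto the derivative of mRNA abundance (derivative by opposite-interval
  weighted secants on the nonuniform grid; `K_deg` from exponential decay
  fits).
* **Binding-driven expression ODE** — `dm/dt = K_basal + K_eff * B(t)^n -
  K_deg * m`, with `B(t)` the promoter fold enrichment (1 = no binding) and
  `n = +1/-1` for activation/repression. `K_basal` and `K_eff` are solved in
  closed form from the pre- and post-perturbation steady states (means of
  the first three and last three time points); trajectories are integrated
  by explicit Euler at 1-minute steps.
* **Residual traces** — actual minus model-predicted synthesis rate per gene,
  strain and time point (on max-1-scaled expression); clustered with k-means
  (Euclidean, k = 5). Expression profiles are clustered with k-means under
  the Pearson correlation distance (k = 8 in the reference design), and
  clusters are scored for functional-category enrichment with the
  hypergeometric test.
* **Feed-forward-loop logic model** — a three-node motif (regulator X,
  effector Y, target Z) with step activation at threshold 0.5 on unit-scaled
  levels and an OR gate on the target; the two decay constants are fitted by
  bounded least squares at 5, 10, 20 and 45 min, and `ln 2 / k` converts a
  fitted decay rate into a response time.

A synthetic-data module (`simulate_binding()`, `simulate_panel()`,
`simulate_decay_experiment()`) generates two-strain, multi-replicate panels
with planted regulatory classes — direct activated/repressed targets,
feed-forward targets, regulator-independent impulse genes and flat controls —
so the whole pipeline is testable and calibratable without any external data.

## Worked example

```r
library(grndyn)
library(dplyr)

binding <- simulate_binding()                      # occupancy curve, drop at t = 0
sim <- simulate_panel(panel_config(seed = 1), binding)
panel <- sim$panel                                 # 100 genes x 2 strains x 2 reps

# 1. mRNA decay constant from a transcription-arrest time course
fit_degradation(simulate_decay_experiment(log(2) / 8, cv = 0.1, seed = 1))
#> First-order decay fit: k_deg = 0.07793 /min (se 0.0035), half-life = 8.89 min,
#>   rss = 0.00647 (8 points)

# 2. calibrate the expression ODE for a repressed gene
tr <- mean_trace(panel) %>% filter(gene == "rep_01", strain == "parent")
k  <- sim$truth$k_deg[sim$truth$gene == "rep_01"]
calibrate_ode(tr, binding, n = -1, k_deg = k)
#> ODE parameters: K_basal = 0.7979, K_eff = 134.4, n = -1, K_deg = 0.06636 /min

# 3. residual traces flag the feed-forward target's delayed excursion
res <- panel_residuals(panel, binding,
                       deg_table = sim$truth %>% select(gene, k_deg),
                       signs     = sim$truth %>% select(gene, n))
res %>% filter(gene == "ffl_01", strain == "parent", time_min %in% c(10, 20, 45))
#> # A tibble: 3 x 6
#>   gene   strain time_min   actual predicted residual
#> 1 ffl_01 parent       10  0.135     0.00817   0.126
#> 2 ffl_01 parent       20  0.0853    0.00817   0.0772
#> 3 ffl_01 parent       45 -0.00407   0.00817  -0.0122

# 4. fit the feed-forward loop to the target cluster's average scaled profile
ffl_genes <- sim$truth$gene[sim$truth$class == "ffl_target"]
target <- mean_trace(panel) %>%
  filter(gene %in% ffl_genes, strain == "parent") %>%
  group_by(gene) %>% mutate(value = scale_unit(value)) %>%
  group_by(time_min) %>% summarise(value = mean(value))
fit <- fit_ffl(ffl_model(), scale_unit(rename(binding, value = enrichment)),
               scale_unit(target))
fit
#> FFL least-squares fit: k_Y = 0.03769 /min (half-life 18.4 min),
#>   k_Z = 0.1098 /min (half-life 6.31 min), rss = 0.00434
response_time(fit$k_y)
#> [1] 18.38884
```

Reading the output: the decay fit recovers the planted 8-minute half-life
within its sampling spread. The calibrated repressor has a large `K_eff`
relative to `K_basal`, i.e. its promoter is dominated by the regulator. The
feed-forward target's residual is strongly positive at 10–20 min and gone by
45 min — synthesis persisted after the regulator left the promoter, the
signature of a second, delayed activator — and fitting the logic model to the
cluster average puts the effector's response time (`ln 2 / k_Y`) near 20
minutes, consistent with a regulator that must first be translated.
Fitted objects have `tidy()`/`glance()` methods, and `autoplot()` /
`plot_timecourse()` / `plot_binding()` / `plot_residuals()` draw the standard
displays.

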
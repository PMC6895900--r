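# stcox — spatial- and temporal-smoothed Cox models for survival panels

`stcox` is for survival data collected over a grid of locations and
consecutive time intervals — the shape of cancer-registry data, where
subjects are grouped by recording site and by diagnosis decade.  Pooling
such a panel into one Cox model masks real spatial/temporal variation in
covariate effects; fitting every (location, period) cell separately
respects the variation but falls apart in small cells, where partial
likelihoods are flat or monotone and estimates swing implausibly between
adjacent decades.

The package estimates a Cox proportional hazards model *per cell*,

    h_ijk(t) = h0(t) exp(X_ijk' b_ij),

with all cell coefficient vectors `b_ij` fitted jointly under a two-part
ridge penalty:

    sum_ij LL_ij(b_ij)
      - (l1/2) * sum_i sum_{j>=2} ||b_ij - b_i,j-1||^2          (fused, temporal)
      - (l2/2) * sum_j sum_{i<r} w_ir ||b_ij - b_rj||^2         (Laplacian-type, spatial)

where `w_ir = 1 / distance(i, r)`.  Neighbouring models borrow strength
without being forced equal.  Estimation runs an outer Taylor-surrogate
Newton loop with a diagonal curvature approximation and an inner
block-wise Gauss–Seidel cycle with closed-form per-cell updates; `l1, l2`
are chosen by cell-stratified V-fold cross-validation and standard errors
come from a cell-stratified nonparametric bootstrap.  Unpenalized
comparators (separate per-cell MLEs and three pooled analyses) and a
survival-panel simulator with known truth are included.

## Worked example

```r
library(stcox)

sim <- simulate_panel(sim_config(seed = 1))   # 4 x 5 grid, 8 covariates,
print(sim)                                    # 100 subjects per cell
#> simulated panel: 4 x 5 cells, 8 covariates, 2000 subjects
#>   smooth surface (effect scale 1), realized censoring 30.4%

w <- weights_from_distances(sim$distances)
fit <- fit_smoothed(sim$panel, w, penalty_config(1, 1))
print(fit)
#> smoothed Cox fit: 4 x 5 cells, 8 covariates
#>   lambda1 = 1, lambda2 = 1
#>   converged in 23 outer iteration(s); objective -4889.1347

sep <- fit_separate(sim$panel)
mean((fit$beta - sim$truth)^2)            # smoothed: grid MSE vs truth
#> [1] 0.03252549
mean((sep$beta - sim$truth)^2, na.rm = TRUE)  # separate comparator
#> [1] 0.05467561
```

The smoothed fit halves the mean squared error of the separate per-cell
MLEs on this panel: with 100 subjects and 8 covariates per cell, each
cellwise likelihood is noisy, and borrowing strength from the four
spatial neighbours and adjacent periods stabilizes every estimate.  The
objective value is the penalized log partial likelihood at the optimum;
the iteration count is the number of outer surrogate maximizations until
the estimate moved less than `1e-3` in l2 norm.

Real data enter through CSV files — `read_panel_csv()` for long-format
subject records (location, period, time, event, covariates) and
`read_distance_matrix()` for inter-location distances —, and results
leave through `write_estimates()` (one row per location, period and
covariate, with bootstrap standard errors and confidence bounds when
available).  A thin command-line front-end over the same functions is
installed at `inst/cli/stcox.R` with subcommands `fit`, `separate`,
`pooled`, `cv`, `bootstrap`, `simulate`.

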
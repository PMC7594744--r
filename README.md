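# abclock

Quantitative analysis of how cell division and abscission time the exit of
mouse embryonic stem (ES) cells from naive pluripotency.

When ES cells leave the naive state (triggered by removing 2i/LIF medium at
t = 0), a destabilized GFP reporter of the *Rex1* locus is downregulated,
and the time of that downregulation marks exit at the single-cell level.
`abclock` implements the statistics that connect this exit time to the cell
division machinery, for tables exported from live-imaging quantification:

* **Exit-time estimation.** Each cell's reporter trace is fit by a logistic
  decay `I(t) = lo + (hi − lo)/(1 + exp((t − τ)/s))`; the exit time τ is the
  fitted inflection, with a Jacobian-based standard error σ_τ and a quality
  filter discarding fits with σ_τ on the order of τ itself.
* **Division–exit coupling.** OLS regression of τ on the *latest division*
  (the largest division time ≤ τ + 2.5 h), and a 1000-replicate reassignment
  bootstrap: each replicate pairs every τ_i with the division times of a
  random cell (closest division when there are two) and the empirical p is
  the fraction of replicate R² values ≥ the observed R².
* **Sister statistics.** Global (population) versus sister-pair variance of
  first-point-normalized trajectories, both time-averaged with the
  divide-by-n convention; |Δτ| for sisters versus random non-sister pairs;
  correlation of division size asymmetry with exit-time ratios.
* **Bridge kinetics.** Exponential fits
  `w(t) = w_inf + (w0 − w_inf) exp(−t/τ_c)` to cytokinetic-bridge width time
  courses; condition comparison by extra-sum-of-squares F test (or label
  permutation); abscission-duration summaries and per-frame bridge
  fractions.
* **FRAP.** Pre-bleach normalization, trailing 4-point smoothing, and the
  post-bleach minimum in a bridge-connected sister as the readout of
  cytoplasmic exchange (two-compartment model,
  `c_s(t) = (1+b)/2 + (1−b)/2 exp(−2kt)`).

Because no trajectory-level data from the motivating experiments are
publicly deposited, the package also ships a synthetic-data generator
(`simulate_lineage()`, `simulate_bridge_widths()`, `simulate_frap()`,
`simulate_abscission_durations()`, `simulate_frame_counts()`) whose defaults
encode the documented study conditions and which emits ground truth for
parameter-recovery validation. See the methods vignette
(`vignettes/abclock-methods.Rmd`) for the models, defaults and their
rationale.

## Worked example

```r
library(abclock)

# simulate 50 lineages under default (division-coupled) conditions
sim  <- simulate_lineage(sim_config(seed = 1))
fits <- filter_fits(fit_trajectories(sim$trajectories))
sum(fits$kept)
#> [1] 100

# couple exit times to the latest division and test against the bootstrap null
kept <- merge(fits[fits$kept, c("cell_id", "tau_h")],
              sim$cells[c("cell_id", "d1_h", "d2_h")], by = "cell_id")
kept$latest_division_h <- mapply(function(tau, a, b)
  latest_division(tau, c(a, b)[!is.na(c(a, b))]),
  kept$tau_h, kept$d1_h, kept$d2_h)
bootstrap_null(kept, n_boot = 1000, seed = 1)
#> Exit-division coupling: R^2 = 0.703 (slope 0.88, n = 100)
#> Bootstrap null (1000 replicates): p = 0
```

R² ≈ 0.70 says that most of the cell-to-cell spread in exit time is
explained by when the gating division happened; none of the 1000
reassignment replicates reached the observed R², so the coupling is far
beyond what chance pairing produces.

```r
# sisters track each other far more closely than the population
sv <- sister_variance_analysis(sim$trajectories, sister_pairs(sim$cells))
round(c(global = sv$global_variance,
        pair = mean(sv$pair_variances), fold = sv$fold_reduction), 4)
#>  global    pair    fold
#>  0.0290  0.0028 10.2000

# bridge thinning: naive vs exiting kinetics
naive   <- simulate_bridge_widths(bridge_sim_config("naive",   seed = 1))
exiting <- simulate_bridge_widths(bridge_sim_config("exiting", seed = 2))
cmp <- compare_conditions(naive$traces, exiting$traces, method = "F")
c(tau_naive = cmp$tau_a, tau_exiting = cmp$tau_b, p = cmp$p_value)
#>   tau_naive tau_exiting           p
#>       45.64       15.05           0
```

The pooled characteristic times recover the generating 45 min (naive) and
15 min (exiting) kinetics, and the extra-sum-of-squares F test rejects a
shared τ_c at below machine precision.

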
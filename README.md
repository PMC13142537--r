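# tautraj

Trajectory analysis of tau accumulation in single-neuron proteomes.

In Alzheimer's disease cortex, neighbouring neurons carry anything from no
detectable phospho-tau to mature neurofibrillary tangles. Given a log2
protein × sample intensity matrix from laser-microdissected single neurons
(or mini-pools of ~20 neurons) with donor and pTau (AT8) annotations,
**tautraj** orders the cells along a tau-accumulation axis and asks every
downstream question against that continuum rather than a two-group
contrast:

* **Preprocessing** — contaminant removal, group-wise detection filtering,
  cell-quality filters, and per-sample downshifted-normal imputation of
  MNAR missing values: missing entries in a sample with observed mean μ
  and SD σ are drawn from N(μ − 1.8σ, (0.3σ)²).
* **Trajectory** — diffusion-map pseudotime from a root cell (mini-pools)
  or log2 MAPT intensity as a direct proxy (single cells), plus
  equal-width tau binning.
* **Association screen** — per-protein Pearson r against the axis,
  two-sided t-test on n − 2 df, Benjamini–Hochberg FDR (q < 0.05), Ward
  clustering of significant proteins, curated-panel screening, and
  hypergeometric over-representation of GMT gene sets.
* **Proteostasis scores** — mean member z-score for the proteasome, 20S
  core, 19S regulatory particle and lysosomal V-ATPase acidification
  machinery, with mean ± SEM trends across tau bins.
* **Phospho-occupancy excess** — a random-intercept mixed model
  `phospho ~ tau + (1 | donor)` fitted by profile REML on pTau-negative
  cells; residuals for all cells quantify phosphorylation beyond what tau
  abundance predicts, and a status fixed-effect refit gives the excess β
  with a standard error (fold change = 2^β).
* **Breakpoint analysis** — per protein, continuous piecewise-linear fits
  with 0/1/2 breakpoints (exhaustive candidate scan + Muggeo iterative
  linearisation + bootstrap restarting), model selection by
  BIC = n·ln(RSS/n) + k·ln(n) with k = 2 + 2B, retention of
  one-breakpoint fits inside [0.20, 0.80] of the tau range, and
  stratification into early/late × up/down modules around the valley of
  the breakpoint-position KDE.

A synthetic-cohort generator (`generate_cohort()`) with full ground-truth
tables — latent tau, donor intercepts, per-protein response classes and
slopes, injected phospho excess — drives the validation suite and supports
power exploration.

## Worked example

```r
library(tautraj)

cfg    <- cohort_config(n_cells = 150, n_proteins = 500,
                        frac_early_break = 0.1, frac_late_break = 0.1,
                        seed = 42)
cohort <- generate_cohort(cfg)                 # matrix + ground truth
raw    <- inject_missingness(cohort$matrix, cfg)
pm     <- preprocess_matrix(raw, "single_cell", min_proteins = 300, seed = 42)
#> 0 contaminant protein(s) removed
#> 6 protein(s) below detection threshold removed
#> 0 sample(s) removed with < 300 detected proteins
#> 42 sample(s) removed with undetected tau; 6 below the 5th tau percentile (cut = 13.52)
#> 6955 value(s) imputed

traj  <- tau_proxy_ordering(pm)
assoc <- correlate_with_axis(pm, traj)
sum(assoc$significant)
#> [1] 132

bp <- run_breakpoint_analysis(pm, traj, n_boot = 50, seed = 42,
                              exclude = "MAPT")
bp$summary[c("n_linear", "n_one_breakpoint", "n_retained")]
#> $n_linear          [1] 457
#> $n_one_breakpoint  [1] 33
#> $n_retained        [1] 21
round(bp$cut, 2)       # early/late boundary, log2 tau units
#> [1] 15.27

ph   <- generate_phospho_layer(cohort$matrix, cohort$truth,
                               beta_true = 1.16, seed = 42)
base <- fit_random_intercept_lmm(ph$intensity, ph$tau, ph$donor_id,
                                 subset = ph$ptau_status == "negative")
ex   <- phospho_excess(base, ph$intensity, ph$tau, ph$donor_id,
                       ph$ptau_status)
sprintf("occupancy excess: %.2f log2 (%.1f-fold), p = %.2g",
        ex$beta_excess, ex$fold_change, ex$p_value)
#> [1] "occupancy excess: 1.14 log2 (2.2-fold), p = 5.2e-28"
```

Of the 100 simulated hinge proteins, 33 are selected as one-breakpoint by
BIC in this small cohort, 21 survive the central-range filter, and the KDE
valley at log2 tau ≈ 15.3 separates the early (truth: 14) from the late
(truth: 17) responders. The injected 1.16 log2 occupancy excess is
recovered as 1.14 ± SE, i.e. the printed 2.2-fold.

`run_pipeline(raw, pipeline_config("single_cell"), "run1")` chains all
stages and writes each report as TSV plus a JSON run manifest.

## Vignette

`vignettes/tau-trajectory-methods.Rmd` documents the models, their
assumptions, the default parameters and the design decisions in detail.
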
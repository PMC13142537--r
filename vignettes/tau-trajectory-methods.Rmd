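---
title: "Methods: ordering single-neuron proteomes along a tau-accumulation axis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ordering single-neuron proteomes along a tau-accumulation axis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

In Alzheimer's disease, neighbouring neurons within the same cortical layer
carry very different loads of hyperphosphorylated tau, from none to mature
neurofibrillary tangles. Laser-microdissected single neurons (or mini-pools
of ~20 neurons) measured by data-independent-acquisition mass spectrometry
give one log2-intensity proteome per cell, annotated by donor and by
AT8 immunoreactivity (pTau-positive vs pTau-negative). Instead of a
two-group comparison, **tautraj** treats the cohort as a continuum: cells
are ordered along a scalar tau-accumulation axis and every downstream
question — which proteins track the axis, how proteostasis pathway
activity evolves, whether phospho-site occupancy outpaces tau abundance,
and *when* along the axis each molecular response changes course — is asked
against that ordering.

```{r, eval = FALSE}
library(tautraj)
cfg <- cohort_config(n_cells = 200, n_proteins = 1000, seed = 1)
cohort <- generate_cohort(cfg)
raw <- inject_missingness(cohort$matrix, cfg)
out <- run_pipeline(raw, pipeline_config("single_cell"), "run1")
```

# Preprocessing

The preprocessing chain mirrors the Perseus conventions common in MS
proteomics:

* **Contaminant removal** by the `Cont_` accession prefix.
* **Group-wise detection filtering**: a protein is retained when detected
  (observed before imputation — imputation can never rescue a protein) in
  at least `min_frac` of pTau-positive *or* pTau-negative samples,
  inclusive. Defaults are 0.7 for mini-pools and 0.3 for single cells,
  reflecting the lower coverage of true single-cell captures.
* **Cell filtering** (single-cell mode): samples with fewer than 1,000
  detected proteins are dropped first; then samples whose observed tau
  falls below the 5th percentile of the remaining samples are dropped.
  The percentile uses linear interpolation between order statistics
  (`quantile` type 7), recorded in the configuration so it can be
  switched. The order of the two filters is itself a choice — protein
  count first — and is configurable. Samples in which tau was never
  detected cannot be placed on the axis at all and are removed with the
  percentile step.
* **Downshifted-normal imputation** (missing-not-at-random): per sample,
  missing entries are drawn from `Normal(mu - 1.8 * sigma, (0.3 * sigma)^2)`
  where `mu` and `sigma` are that sample's observed mean and SD. The
  moments use observed values only; a sample with observed mean 20 and SD 1
  therefore receives imputed draws centred at 18.2 with SD 0.3. Observed
  values are never altered, and the `imputed` mask keeps the provenance of
  every entry.

# Trajectory construction

Two orderings are provided. For single-cell cohorts the **tau proxy** is
simply each cell's log2 MAPT intensity — tau abundance is the biological
axis of interest, is measured directly, and carries no donor intercept in
expectation. For mini-pool cohorts, **diffusion pseudotime**: samples are
PCA-reduced, a k-nearest-neighbour graph (k = 10) built, and an adaptive
Gaussian kernel applied with per-sample bandwidth equal to the distance to
the 5th neighbour. The symmetrised kernel defines a reversible Markov
chain; the top 5 non-trivial eigenvectors, weighted by
`lambda / (1 - lambda)`, span a multiscale diffusion space, and pseudotime
is the Euclidean distance from a caller-chosen root sample, min-max scaled
to [0, 1]. Determinism is enforced by a fixed eigenvector sign convention
(largest-magnitude entry positive). Kernel weights on kNN edges are
floored at the smallest positive double so that an edge present in the
graph always carries connectivity; a genuinely disconnected graph is an
error naming the component sizes. Waypoint refinement, terminal states and
branch probabilities found in full trajectory tool-chains are deliberately
absent: downstream analysis consumes only a 1-D ordering.

Equal-width binning of the tau axis (5 bins by default) uses left-closed
internal bins with the maximum included in the last bin, so a value on an
internal edge belongs to the right bin and every sample is assigned.

# Association screen, clustering and enrichment

Per protein, Pearson correlation with the axis and the two-sided t-test on
n − 2 degrees of freedom, with Benjamini–Hochberg control across proteins
(q < 0.05). Zero-variance proteins have an undefined correlation and are
excluded *before* the BH step rather than assigned p = 1, so they do not
deflate the q-values of real tests. Significant proteins are z-scored per
protein and clustered with Ward's method on Euclidean distances
(`ward.D2`, the Euclidean-distance form matching SciPy's `ward`), cut at a
fixed k (6 single-cell, 4 mini-pool by default). Curated panels (e.g.
cell-death proteins) are screened by intersecting with the detected
proteome; BH is then computed *within* the panel, a convention recorded in
the report because either choice is defensible. Over-representation of
user-supplied gene sets (GMT) uses the one-sided hypergeometric tail
against an explicit background — the post-filter proteome, which is the
universe the screen actually interrogated.

# Proteostasis pathway scores

A pathway score is the per-sample mean of member z-scores (z computed per
protein across all cells, after imputation). Built-in definitions: the
full proteasome (PSMA1–7, PSMB1–8, PSME1, PSMF1), the 20S core
(PSMA1–7, PSMB1–8), the 19S regulatory particle (every detected PSMC* or
PSMD* subunit, resolved at runtime by prefix), and the lysosomal
acidification machinery (11 V-ATPase subunits spanning V0 and V1). Binned
trends report mean ± SEM per tau bin; SEM uses the n − 1 sample SD
(configurable), single-sample bins report no SEM, and empty bins are
omitted rather than reported as zero.

# Phosphorylation excess beyond tau abundance

Rising phospho-tau intensity may only reflect rising tau. To separate
occupancy from abundance, a Gaussian linear mixed model
`phospho ~ tau + (1 | donor)` is fitted to pTau-negative cells only,
establishing the baseline abundance–phosphorylation relation. The fit is
restricted maximum likelihood with the single variance ratio profiled out
and maximised in one dimension; the block structure of a one-factor random
intercept gives closed-form matrix inverses, and the optimum is compared
against the boundary (zero donor variance), where the fit collapses to
OLS exactly. Residuals are then computed for *all* cells — donors unseen
in the baseline fit get fixed-part predictions only, since their
intercepts are not estimable — and positive residuals in pTau-positive
cells indicate occupancy beyond expectation. The headline excess is
estimated by refitting with a pTau-status fixed effect: numerically
equivalent to the residual framing but yielding a standard error and a
Wald p-value. A log2 excess `beta` converts to a `2^beta` fold change
(1.16 log2 units is a 2.2-fold occupancy increase).

PTM peptide reports are filtered with the DIA-NN thresholds at their
printed strictness (`Q.Value < 0.01` strict, `PEP <= 0.05` inclusive,
`PTM.Site.Confidence > 0.9` strict, plus four library/peptidoform q-value
rules at 0.5 and 0.01; phospho mode adds site localization ≥ 0.99).
Phospho sites are keyed residue letter + 1-based position on the 2N4R tau
isoform (441 aa), e.g. `pT231`. The single-maximum Gly-Gly outlier policy
is off by default and refuses ties so no replicate is dropped silently.

# Breakpoint analysis

The temporal-ordering question: does a protein respond to tau linearly, or
does its trajectory change slope at some tau level? Per protein, in
order:

1. **Outlier removal**: values beyond ±3 scaled MADs of the median are
   excluded from fitting (the clipping variant is available behind a
   flag). A zero MAD disables removal with a warning.
2. **z-scoring** of the retained intensities.
3. **Continuous piecewise-linear fits** with B = 0, 1, 2 breakpoints.
   B = 0 is ordinary least squares. For B ≥ 1 the profile RSS over
   breakpoint positions is non-convex, so three mechanisms are combined:
   an exhaustive scan of candidate positions (midpoints between
   consecutive x values, capped at 512 quantile-spaced candidates; pairs
   from a coarse grid seeded with the B = 1 optimum for B = 2), Muggeo's
   iterative linearisation (refitting with a gap covariate whose
   coefficient updates the breakpoint), and bootstrap restarting
   (resample residuals of the incumbent, refit on the perturbed response,
   re-evaluate the resulting breakpoints on the original data, keep the
   best original-data RSS). Every configuration visited is evaluated by
   exact least squares and the best is returned, which makes RSS nesting
   across B = 0, 1, 2 structural rather than accidental. Fits are
   deterministic given the seed.
4. **Model selection** by BIC = `n ln(RSS/n) + k ln(n)` with
   `k = 2 + 2B` (intercept, base slope, one slope change and one position
   per breakpoint); ties go to fewer breakpoints; a zero-RSS fit maps to
   −Inf and is flagged.
5. **Edge filtering**: one-breakpoint fits with relative position inside
   [0.20, 0.80] of the observed tau range (inclusive) are retained.
6. **Stratification** into four modules. The early/late cut is the
   minimum of a Gaussian KDE (Silverman's rule-of-thumb bandwidth) of the
   retained breakpoint positions between its two largest modes; a
   unimodal KDE falls back to the median and is flagged. Modules combine
   timing with slope direction: early_up_plateau (`alpha1 > 0`),
   early_down_plateau (`alpha1 < 0`), late_decline (`alpha2 < 0`),
   late_recover (`alpha2 > 0`). Which slope's sign defines direction for
   each timing class is not uniquely determined by the four verbal
   profiles; the mapping above (first segment for early, second for late)
   reproduces increase-then-plateau, decrease-then-stabilise,
   rise-then-decline and suppress-then-recover, and is an explicit,
   documented choice. A zero slope defers to the other segment's sign.

# The synthetic cohort generator

`generate_cohort()` draws a latent log2 tau level uniformly over
`tau_range` (uniform coverage keeps breakpoint positions identifiable
across the whole axis), assigns cells to donors, and builds each protein
as baseline + response + donor intercept + Gaussian log2 noise. Response
classes: linear up/down (slope ±`slope_scale`), early hinge (slope then
plateau at `breakpoint_early`), late hinge (flat then slope at
`breakpoint_late`), or null; hinges are continuous because the downstream
model is continuous. One row, `MAPT`, is the latent tau plus noise and
carries no donor intercept. The pTau label is a hard threshold on latent
tau with optional label noise (default 0). Mini-pool mode averages
`pool_size` (default 20) cell-level expectations per pool before noise.
MNAR dropout retains each entry with probability
`plogis((value - midpoint) * steepness)`. The phospho layer generates
`a0 + a1 * tau + donor intercept + beta_true * [pTau+] + noise`, the exact
generative counterpart of the mixed model above.

Default conditions: 200 cells from 8 donors, ~1,000 proteins, tau range
12–19 log2 units, hinges at 14 and 17 (relative positions 0.29 and 0.71,
inside the edge filter), slope 0.5, donor SD 0.5, noise SD 0.3, pTau
threshold 16, logistic dropout midpoint 14 with unit steepness. These are
chosen once as a realistic single-neuron DIA regime: ~5–15% missingness
concentrated at low abundance, within-protein dynamic range a few log2
units, donor offsets comparable to biological noise.

What the generator does *not* emulate: peptide-level rollup, cross-run
normalisation artefacts, retention-time structure, correlated protein
modules beyond the shared latent axis, and non-Gaussian heavy-tailed
noise. Passing tests therefore demonstrate correctness of the estimators
under the stated statistical structure, not robustness to every artefact
of real MS data.

Two validation conditions deserve a note. The pseudotime fidelity check
uses a *continuum* cohort with `donor_sd = 0`: with donor offsets applied
to every protein, cells cluster by donor and any neighbourhood-graph
method will partly order by donor rather than by the latent axis — a
property of the condition, not a defect of the algorithm, and the reason
the tau proxy (which is donor-free in expectation) is preferred for
single-cell cohorts. Second, the occupancy-excess recovery uses the
default hard pTau threshold, which makes the status indicator nearly
collinear with tau; the excess estimate is unbiased (mean bias well under
0.05 log2 units across seeds) but has a per-seed standard error around
0.08 log2 units at 200 cells, so individual-cohort estimates scatter
accordingly.

# Numerical choices and degenerate inputs

* Quantile type 7 for the tau percentile; `ward.D2` for Ward on Euclidean
  distances; BH via the standard step-up with monotonicity enforcement.
* Piecewise fitting requires `2(B+1) + B` distinct x values; breakpoints
  are kept strictly inside the observed range and strictly ascending,
  with collisions pulled apart by a range-scaled epsilon; non-convergence
  of the iteration is reported, never silently accepted.
* A constant tau axis is a degenerate ordering: flagged on the trajectory,
  an error for binning.
* Problem sizes in the validation suite — 20 cohorts of 200 cells and 100
  proteins for breakpoint recovery with 50 bootstrap restarts per fit, 20
  null cohorts for FDR control, 10,000 imputation draws — were chosen as
  the smallest designs at which the Monte-Carlo error of each check is
  comfortably below its acceptance margin.

# Known limitations

* Pseudotime is a single ordering; branching fates are out of scope.
* The breakpoint model allows at most two breakpoints and no
  breakpoint-significance test (Davies-type); BIC comparison against the
  linear fit is the only arbiter of non-linearity.
* The LMM supports exactly one random intercept; crossed or nested random
  effects (e.g. section within donor) are not modelled.
* The ORA test treats gene sets as flat lists: no ontology hierarchy, no
  term redundancy pruning.
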
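---
title: "Methods: body-size macroevolution on fossil phylogenies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: body-size macroevolution on fossil phylogenies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the models, the numerical choices, and the design
decisions behind `paleosize`, in the order the pipeline runs: tree dating,
the body-size proxy, trait-evolution models and their MCMC machinery,
time-series reconstruction, environmental regression, and the synthetic
data the package validates itself against.

## Dated trees and the equal method

All analyses run on a `dated_tree`: an `ape` topology plus absolute node
ages in Ma (larger = older), with branch durations in Myr equal to
parent–child age differences. Fossil cladograms arrive undated;
`equal_dating()` time-scales them from occurrence ranges in four steps:
tips are placed at their first appearance (FAD); each internal node is
initialised to the oldest age among its descendant tips; the root is
pushed back by a buffer beyond the oldest FAD; and every remaining
zero-duration branch is resolved by finding the nearest ancestral branch
with positive duration and dividing its span equally among itself and the
consecutive zero-duration branches below it on that root-to-tip path.

Two properties are worth knowing. First, the initialisation *always*
creates at least one zero-duration chain per internal node (the node age
equals its oldest descendant's age), so the equal-division step is not an
edge case but the ordinary mechanism by which internal nodes acquire ages
older than their oldest tip. Second, the procedure depends only on the
tree and the FADs, never on the order of the occurrence rows.

Choices made here, exposed as arguments:

* **Tips at FAD, not range midpoints.** Lineages are plotted and binned
  from first appearance; the LAD is retained in the occurrence table and
  used for bin membership, which reproduces both uses of the range.
* **Root buffer** defaults to 5 Myr. Any positive value works; it only
  sets how much time the basal branches can absorb.
* **Bins are half-open `[old, young)`** to avoid double counting, ages in
  Ma; the Mesozoic/Cenozoic split is fixed at 66.0 Ma (the
  end-Cretaceous mass extinction). A geological-stage table (international
  stages, Induan–Holocene) ships as `stage_bins()` for stage-resolution
  binning.

`trim_to()` returns the induced subtree on a taxon set with degree-2
nodes suppressed and all retained ages preserved, for matching a large
dated tree to the taxa with trait data.

## The body-size proxy

The proxy is the taxon score on PC-1 of a covariance-matrix PCA of up to
21 linear measurements in cm. Two deliberate departures from textbook
morphometrics:

* **No log-transformation.** The target is isometric size, not allometric
  shape; log-transforming would equalise variances across characters and
  suppress exactly the size-driven covariance the proxy depends on.
  Covariance (not correlation) PCA keeps large, size-dominated characters
  influential.
* **Iterative imputation** instead of complete-case analysis. Missing
  cells start at column means; the covariance matrix of the completed
  matrix is eigen-decomposed; missing cells are re-estimated from the
  rank-`n_components` reconstruction; repeat until the largest change in
  any imputed cell is below `tol`. Defaults: `n_components = 3`
  (enough to capture size plus the leading shape axes without fitting
  noise), `tol = 1e-6` cm, `max_iter = 500`. Convergence is geometric but
  can be slow on very sparse matrices; hitting `max_iter` sets a warning
  flag and returns the current decomposition.

The PC-1 sign is fixed so that the skull-width loading is positive
(larger animals score higher); if no `skull_width` column exists, the
character with the largest absolute loading is forced positive. Where a
taxon has several specimen rows, per-character medians are taken first —
medians resist outlier specimens.

Centred PCA scores average to approximately zero by construction. A
nonzero arithmetic mean of reported scores can arise from uncentred or
imputation-shifted configurations in other software; this package reports
centred scores and the arithmetic mean as computed, and the skull-width
back-transform (`pc1_to_skull_width()`, an OLS calibration over taxa with
skull width observed) makes any score interpretable regardless of offset
convention.

One empirical caveat, visible in the package's own tests: measurement
noise and imputation error enter the proxy as taxon-specific,
non-phylogenetic variance. When PC-1 scores (rather than a noise-free
trait) are fitted, that error inflates apparent tip-specific change and
can favour punctuational-looking transformations. Interpreting small
transform parameters estimated from noisy proxies should keep this in
mind.

## Trait-evolution models

All models are Gaussian on a fixed-root tree. The Brownian random walk
(the null) has tip covariance `σ²C` with `C_ij` the shared root-to-MRCA
path length, evaluated by Felsenstein's pruning algorithm in a C++
kernel; the same pass returns the GLS phylogenetic mean, so the
likelihood can be re-evaluated at any root state α at no cost. The Pagel
transformations are implemented as branch-length surgeries that
reproduce their covariance definitions exactly (verified against dense
matrix constructions to 1e-8 in the tests): κ raises branch durations to
a power, δ raises node depths, λ scales internal branches with terminal
branches adjusted to preserve root-to-tip depths (rejected if a terminal
branch would go negative). κ, δ and λ are all well defined on
non-ultrametric fossil trees.

The Ornstein–Uhlenbeck model uses the fixed-root, root-equals-optimum
form with covariance
`V_ij = σ²/(2a) · e^{−a(t_i+t_j−2t_ij)} · (1 − e^{−2a·t_ij})`,
evaluated densely (the matrix is not tree-additive); `a < 1e-10` falls
back to the BM limit. The directional trend adds `β·(root-to-tip
duration)` to each tip mean — identifiable only on non-ultrametric trees,
so an ultrametric input raises a warning. The variable-rates model
multiplies branch durations by scalars attached to branches or clades
(stem plus descendants), sampled by reversible jump (below).

### Priors and MCMC

Priors (all overridable in `model_spec()`):
`log σ² ~ U(−20, 20)`; `α ~ U(data range ± 3 SD)` (a normal prior is
also accepted, which enables conjugate validation); `λ ~ U(0,1)`;
`δ, κ ~ U(0,3)`; OU `a ~ U(0, 5/tree depth)`;
`β ~ U(±10 SD/tree depth)`. The sampler is component-wise
Metropolis–Hastings with normal proposals whose scales adapt every 200
iterations during burn-in toward ~30% acceptance and are then frozen.
Default chain settings are 2,000,000 iterations, 10,000 burn-in,
thinning 1,000; every validation run in the package reduces these
(typically 2×10⁵/10⁴/10²) to keep the suite inside desk-scale run times,
which is a choice about test problem sizes, not about the method.
Diagnostics: acceptance rates outside [0.05, 0.95] after adaptation set a
warning flag, and the retained log-likelihood trace is summarised by a
flatness statistic (first-half vs second-half mean in posterior-SD
units), mirroring the practice of inspecting the likelihood profile for a
uniform band.

### Reversible-jump variable rates

The state is a set of (node, scope, scalar) assignments; scope is
*branch* (the stem edge) or *clade* (stem plus all descendant edges),
both enabled. The prior is: assignment count `k ~ Poisson(mean 2)`
truncated at the number of assignable nodes; assigned nodes a uniform
subset; scopes Bernoulli(½); scalars log-normal(0, 1.5). Birth proposals
draw a node uniformly from the unassigned set and a scalar from its
prior, so the acceptance ratio collapses to the likelihood ratio times
the Poisson count ratio (`λ/(k+1)` for birth, `k/λ` for death) — the
subset-uniform prior's combinatorial term exactly cancels the uniform
node-choice proposal. Scalar updates are random walks on the log scale
with the explicit prior ratio. No split/merge or node-relocation moves
are implemented; birth + death + modify mix well at the problem sizes
validated here (planted-shift recovery in the tests), and the move set is
deliberately minimal so the acceptance algebra stays auditable.

Reported outputs: the posterior mean of `k` (the "number of rates"), and
per-branch posterior mean scalars — the mean over retained draws of the
product of scalars covering each branch, 1 when none — which are also
exportable as a Newick tree with branch lengths set to the scalars
(`export_rate_tree()`).

### Marginal likelihoods and model comparison

Evidence is estimated by stepping-stone sampling along the power
posterior path `β_j = (j/K)^{1/0.3}` (stretched toward the prior), with
`K = 48` stones by default, each stone warm-started from the previous
one; at `β = 0` fixed-dimension models sample their proper priors
exactly. The per-stone Monte-Carlo SE is combined by the delta method;
it is computed from raw draws and therefore understates the error when
stones mix slowly — lengthen `per_stone_iters` for publication-grade
runs. A harmonic-mean estimator (`harmonic_mean_logZ()`) is provided
solely for fidelity checks against legacy workflows; it is biased and
unstable and should not be used for inference. The stepping-stone
estimator is validated against a closed-form conjugate evidence (normal
prior on α, σ² fixed) to within 0.1 log units in the tests.

Comparison uses `2(log Z_model − log Z_null)` with significance at > 2 —
the convention under which a log BF of ~5 counts as significant and ~−1
does not. The Bayes-factor-weighted mean of the significant models' root
states, `Σ(logBF·α)/Σ(logBF)`, is the phylogenetically adjusted mean
trait value; with no significant model the function directs the user to
the null's α rather than silently averaging.

Whether a reported random-walk α is a posterior mean or an ML value is a
real reporting ambiguity; fits therefore expose both (`summary` and
`alpha_mle`, the GLS mean at posterior-mean parameters).

## Ancestral states and time series

`ancestral_states()` computes BM maximum-likelihood node states by a
two-pass Gaussian belief propagation: an upward (pruning) pass collects
each subtree's information, a downward pass conditions on the rest of
the tree. The estimates equal the rerooted-GLS (weighted-average)
estimator, are independent of σ², need no numerical optimisation, work
down to two-tip trees, and are cross-checked in the tests against both a
dense rerooted-GLS oracle and `ape::ace`.

`build_series()` bins a statistic through time under three methods:
observed `[FAD, LAD]` ranges; ranges extended back to each tip's parent
node age (ghost ranges — a superset of the empirical membership in every
bin, which is asserted as an invariant); and additionally ancestral
states. Ancestors occupy the single bin containing their node age — the
node is a point event in time — with a `"branch"` option spreading them
over their stem branch instead. Disparity is the per-bin sample variance
(n−1 denominator; bins with fewer than two members are missing, never
zero). Rate series average per-branch scalars over the branches
intersecting each bin by default; a taxon-presence mode (terminal-branch
scalars of the taxa present) is provided because either reading of
"taxa included in each interval" is defensible, and the two are labelled.

`bootstrap_envelope()` recomputes each bin's statistic on random
subsamples — by default 50% of the bin's members, drawn without
replacement, 100 iterations — reporting the replicate median with
interquartile and total-range envelopes. Resampling is per-bin and
independent by default; a global mode (one taxon subsample applied to
all bins) is available since the choice is ambiguous in common practice.

## Environmental regression

δ¹⁸O is interpolated linearly to bin midpoints (`align_to_bins()`;
within-bin averaging of the proxy is the natural alternative and can be
composed by hand); bins outside the record's coverage go missing.
`regress_on_temperature()` is plain OLS of the binned statistic on
δ¹⁸O, era-partitioned at 66 Ma by bin midpoint, requiring at least three
paired bins. Because both series are autocorrelated, a Durbin–Watson
statistic is reported alongside as a caveat — it does not adjust the
inference, matching the plain-OLS reporting convention of the analyses
this package serves. Note the sign semantics: δ¹⁸O scales inversely with
temperature, so a negative slope of size or rate on δ¹⁸O means warmer =
larger / faster.

## The synthetic-data generator

`sim_config()` defaults describe the study conditions the package
validates against: 280 total tips (extinct + extant), birth 0.035 and
death 0.015 /Myr/lineage — chosen so the expected tree span is on the
order of 250 Myr at that tip count — Poisson fossil sampling at 0.1/Myr
along terminal branches, 21 characters with allometric slopes spread
over [0.3, 2] (skull width at slope 1), measurement noise 0.5 cm, 60%
missingness, and a δ¹⁸O random walk with 0.15 ‰ steps at 1-Myr
resolution. Realised spans vary widely around the expectation, as
birth–death spans do. Missingness is completely at random by default; a
size-biased mode (smaller taxa more often missing, mimicking the greater
preservation potential of large specimens) is used in robustness tests.
Traits are simulated root-to-tips with exact transition laws (including
the OU law and Pagel-transformed branches), and true node states and
per-edge rates are returned so ancestral-state and rate-recovery tests
have ground truth.

What the generator does *not* emulate — and hence what passing tests do
not establish about real data: temporally structured preservation
(Lagerstätten pulses, stage-boundary rot), topological error in the
tree, correlated character suites beyond a single latent size factor,
taxonomic over-splitting, or geographic structure in either traits or
temperature. Validation on this generator demonstrates that the
machinery recovers what was planted under the stated statistical
assumptions, not that those assumptions hold for any particular fossil
dataset.

### Validation design notes

Three validation choices deserve explanation:

* **Root-state recovery is information-limited.** Under BM the posterior
  SD of α is about `sqrt(σ²·v_root)` with `v_root = 1/(1ᵀC⁻¹1)`; it does
  not shrink with more tips on a fixed tree depth, because the root state
  of a single realisation is a latent draw, not an averaged quantity.
  Recovery tests therefore simulate at unit σ² and average estimates over
  replicate datasets (five 200-tip trees), which brings the replicate-mean
  error comfortably inside a 15% band around the planted α; single-dataset
  recovery at large σ² would be testing the realisation, not the sampler.
* **Transform-parameter recovery** is checked at the parameter regimes of
  interest (κ planted at 0.4, δ at 0.75) with posterior means required to
  land in generous bands ([0.25, 0.55] and [0.55, 0.95]), reflecting
  honest posterior width at 150-tip, reduced-chain scale.
* **Coupling recovery is era-partitioned**, so the planted rate variation
  must exist inside each era: the test plants four 20× rate-shift clades
  at spread node ages and uses a strongly negative coupling (−2 on the
  standardised rate series). With a single episode, the era not
  containing it has no signal and OLS on two autocorrelated series
  recovers noise — a useful reminder that the era-partitioned regressions
  are only as informative as the within-era variation.

## Known limitations

* OU likelihoods are dense (O(n³) per evaluation); fine at hundreds of
  tips, slow inside long chains at thousands.
* The RJ sampler assigns at most one scalar per node and has no
  relocation move; posteriors with many overlapping regimes may mix
  slowly.
* Stepping-stone SEs ignore within-stone autocorrelation.
* The equal dating method is one of several a-posteriori time-scaling
  conventions; node ages inherit its artefacts (notably, internal nodes
  hugging the midpoint of long basal spans).
* Plain OLS on autocorrelated binned series overstates significance; the
  Durbin–Watson statistic is reported so users can see how badly.
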
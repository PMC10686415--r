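---
title: "Models and methods behind fassprot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fassprot}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fassprot)
```

# The experiment fassprot models

Fluorescence-activated synaptosome sorting (FASS) isolates synaptosomes —
resealed nerve-terminal particles — belonging to a genetically labeled
synapse population out of a brain region's crude synaptosome fraction. Each
sorted sample (the "P3" gate) is acquired together with an unsorted control
sample ("P2") from the same animal and region, and both are quantified by
data-independent-acquisition (DIA) mass spectrometry, which yields
feature-level intensities (precursor and fragment ions) per protein group
and run.

The statistical questions this package answers, stage by stage:

1. Which proteins are enriched (or depleted) in the sorted fraction of a
   synapse type relative to its unsorted control? (`fit_protein_models()`,
   `compare_groups()`, `adjust_and_call()`)
2. Which proteins belong to a synapse type's proteome, given enrichment
   against control and against sibling types from the same region?
   (`call_proteome()`, `partition_shared()`, `interaction_contrast()`)
3. How do per-protein sorted/control profiles behave across many synapse
   types — principal components, covariate contributions, co-abundance
   modules, module–trait links, complex co-regulation, anti-correlated
   pairs? (`build_profile_matrix()`, `run_pca()`, `partition_variance()`,
   `build_network()`, `complex_coregulation()`, `screen_negative_pairs()`)
4. How large are the sorted particles, given 2-D electron-microscopy
   cross-sections? (`sample_cross_sections()`, `build_calibration()`,
   `estimate_diameter()`)

Because real deposited raw data are not required anywhere, a synthetic-data
generator (`ground_truth()`, `sorting_scenario()`,
`simulate_experiment()`) simulates the entire paired experiment with a
known latent truth, so that every stage can be verified quantitatively.

# The per-protein enrichment model

For each protein the feature-level log2 intensities are modeled as

$$\log_2 y_{fr} = \mu_{g(r)} + \beta_f + \varepsilon_{fr},
\qquad \varepsilon_{fr} \sim N(0, \sigma^2),$$

with fixed feature effects $\beta_f$ (sum-to-zero coding) and group
cell-means $\mu_g$; the $\mu_g$ are therefore least-squares means at the
average feature response. With one biological replicate per run and no
technical replicates, a run-level random effect is not separately
identifiable from the residual, so the feature-level mixed model reduces to
this fixed-effects form; that reduction is an explicit design decision, and
the synthetic generator is constructed to be consistent with it (see below).
Residual degrees of freedom are $N - (n_\text{features} + n_\text{groups}
- 1)$. Features observed in fewer than two runs are dropped; rank-deficient
designs fall back to a pivoted fit that drops unestimable feature levels.

A contrast $w$ (weights summing to zero) gives
$\widehat{\mathrm{log_2FC}} = w^\top \hat\mu$, with standard error from the
pooled residual variance and the design, and a two-sided p value from the
$t$ distribution on the residual df. The subfield interaction contrast is
the difference of differences
$(\text{A}_\text{sorted}-\text{A}_\text{control}) -
(\text{B}_\text{sorted}-\text{B}_\text{control})$ computed inside one
joint four-group fit, so its standard error is propagated correctly rather
than assembled from two separate fits.

## Testability, the fold-change gate, and calling

A protein is testable for a comparison when it has at least 6 distinct
features and at least 12 observed measurements in each compared condition
(defaults `min_features = 6`, `min_measurements = 12`). Proteins whose
estimated fold-change passes the gate $|\mathrm{log_2FC}| >
\log_2 1.1$ (strict, symmetric) enter Benjamini–Hochberg adjustment; the
conventional all-protein adjustment is available via
`bh_scope = "all"`. Calls require both the gate and adjusted $p < 0.05$.
A zero t statistic with positive variance reports $p = 1$; fits with zero
residual variance or zero residual df are flagged untestable rather than
reported with meaningless standard errors.

Control runs are pooled per brain region across cell-type lines when the
pipeline builds its contrasts, reflecting how unsorted controls are shared
within a region.

## Membership criteria

For target type A with region siblings B and C, a protein joins the type-A
proteome when it satisfies at least one of: (I) enriched vs control and not
significantly different in the direct A-vs-B comparison; (II) significantly
enriched in A-over-B and positive fold-change vs control; (III) as II for
A-over-C. "Not significantly different" means absence from the direct
comparison's adjusted-significant set, whether by the gate, the p value,
testability, or absence altogether. Criteria II/III here additionally
require the vs-control comparison to be testable — the point of the
positive-FC clause is corroboration, and an untestable control comparison
cannot corroborate; affected proteins are flagged rather than silently
admitted. Shared proteins between two types are those enriched in both
vs-control comparisons and not significant in the direct comparison.

# Profile matrix, PCA and variance partitioning

The cross-type analysis object is the matched-pair log2 fold-change: for
each animal's sorted/control run pair, the per-protein value is the median
over shared features of the per-feature log2 ratio. This is equivalent to
differencing the two runs' feature-centered median abundances, is robust to
feature outliers, and cancels any per-run constant offset, making the
matrix invariant to run-median normalization. Proteins missing in either
run of a pair are missing in that column.

PCA treats columns (samples or type averages) as observations. Proteins
with more than 30% missing values are dropped and remaining gaps imputed by
the protein-wise mean (both counts are recorded on the result); components
carry a deterministic sign (largest-magnitude loading positive) so runs are
reproducible down to the orientation.

Per-protein variance partitioning uses sequential sums of squares averaged
over all covariate orderings — exact and order-free for up to four
covariates, requiring no random-effects machinery and no convergence
diagnostics. This is a deliberate methodological substitute for
random-effects variance partitioning: it is deterministic and directly
testable (fractions of a pure covariate signal are exactly 1, null
fractions concentrate at df/(n−1)), at the cost of not modeling covariates
as random draws from a population. Aliased covariates are flagged with
undefined fractions instead of silently absorbing each other's variance.
The covariate-level summary compares per-protein fraction distributions
with paired two-sided t tests (paired, because the same proteins underlie
each distribution).

# The correlation network

The network stage runs on proteins with complete profiles only (the count
of filtered proteins is reported), because robust correlation weights and
topological overlap are not well defined under per-entry missingness.

* **Correlation** — biweight midcorrelation with tuning constant 9 and
  unscaled MAD; vectors with zero MAD fall back to the Pearson form for
  that vector (recorded). Bicor is exactly invariant under positive affine
  transforms on both paths.
* **Adjacency** — signed hybrid: $a_{ij} = \max(r_{ij}, 0)^\beta$ with
  soft power $\beta = 6$ by default. Negative co-abundance never creates
  edges.
* **Topological overlap** — $\mathrm{TOM}_{ij} = (\sum_u a_{iu}a_{uj} +
  a_{ij}) / (\min(k_i,k_j) + 1 - a_{ij})$.
* **Modules** — average-linkage clustering of $1-\mathrm{TOM}$ (or
  $1-a$ by flag), a *static* cut, a minimum-size filter (label 0 =
  unassigned, the "grey" convention), then iterative merging of modules
  whose eigenproteins correlate above 0.75. The default cut height is the
  midpoint of the largest gap between consecutive merge heights in the
  upper half of the dendrogram: tight planted or biological clusters
  complete their internal merges well below the diffuse top-level merges,
  and the largest gap separates the two regimes without a data-scale
  constant. A fixed numeric `cut_height` overrides it. On the package's
  standard recovery benchmark (5 planted modules of 50 proteins, member
  loading 0.9, 15 types) this choice recovers modules with adjusted Rand
  index 0.90–0.99 across seeds.
* **Eigenproteins** — the first principal component of a module's
  standardized member profiles, unit variance, sign-aligned to the module
  mean. Module–trait links are Pearson correlations with two-sided t-based
  p values ($n-2$ df); categorical traits are one-hot encoded.
* **Export** — undirected edge list with weights strictly above 0.3 by
  default.

# Pair statistics

Complex co-regulation compares all within-complex pairwise Pearson
correlations (across the type-averaged profiles) to randomly sampled
cross-protein pairs, excluding within-complex pairs from the null so the
two distributions are disjoint by construction. Significance is a
permutation p: resampled null sets of the same size as the complex pair
set, with the add-one correction, so the smallest attainable p is
$1/(B+1)$.

The negative-pair screen computes Pearson r per candidate pair, a
two-sided t test on $n-2$ df, and BH adjustment across all screened pairs;
significant negatives satisfy $r < 0$ and adjusted $p < \alpha$ (a raw-p
mode exists behind `adjust = "none"`). Because the screen's candidate
universe is not prescribed, the default takes user-supplied family
groupings (all within-family pairs); `all_pairs = TRUE` screens every pair
through a vectorized whole-matrix path. Pairs are evaluated on the
type-averaged matrix so that n equals the number of synapse types.

Over-representation analysis is the standard upper-tail hypergeometric
test per gene set (GMT input), each set intersected with the quantified
universe, BH across sets.

# Sphere geometry

Random 2-D sections of spheres systematically under-represent the true
diameter. The simulation samples the section plane's offset uniformly:
$X \sim U(0, R)$, section area $\pi(R^2 - X^2)$, with expectation
$\tfrac{2}{3}\pi R^2$. The calibration curve averages 4 repeats of 30
sections per diameter (both configurable), mirroring a repeated simulated
sampling design, and is monotonized by isotonic regression before
inversion — sampling noise can invert adjacent grid points, and inversion
requires monotonicity. An analytic closed-form mode exists alongside the
sampled mode for exactness checks. Diameter estimation inverts the curve
by monotone linear interpolation and refuses to extrapolate outside the
calibrated range.

# What the synthetic generator emulates — and what it does not

`ground_truth()` builds a latent proteins × types log2 abundance matrix
with planted structure:

* **Modules**: member profiles are
  $\text{baseline} + A(\ell F_m + \sqrt{1-\ell^2}\,\epsilon)$ with member
  loading $\ell = 0.9$ and amplitude $A = 1$ log2 unit by default, so
  within-module correlations are $\approx \ell^2$. Module factors are
  standardized across types and, where specified, linearly tied to traits
  (the default ties module 1 to a vGat-like inhibitory trait and module 2
  to a VGlut1-like excitatory trait with loading 0.9; remaining modules
  get independent factors).
* **Negative pairs**: both members load on a private factor with opposite
  signs (default loading 0.95, latent $r \approx -0.90$; loading 1 gives
  exactly −1).
* **Complexes**: random subsets of single modules, so complex members
  co-regulate through the module factor.
* **Markers**: per-type proteins elevated by +2 log2 units in exactly one
  type — the recoverable "type-enriched" anchors.

`simulate_experiment()` mixes types on the linear intensity scale, the way
physical particle pools combine: a sorted run is
$\text{purity}\times\text{target} + (1-\text{purity})\times\text{background}$,
where the background is the prevalence-weighted mean of the region's other
types plus a fixed 10% contaminant pseudo-proteome; a control run is the
region's types at their prevalences with the remainder contaminant. The
contaminant is a free parameter, not an estimate — unsorted fractions are
dominated by membranes that no part of the paper quantifies — and it exists
mainly so de-enrichment calls have something real to detect. Purity
defaults to 0.9 (within the 80–95% operating band of calibrated sorts);
prevalences default to log-uniform draws from [0.005, 0.5] per type,
spanning the printed operating range from rare interneuron populations
(~0.5%) to abundant types (~50%), rescaled proportionally when a region's
draws plus the contaminant would exceed the pool.

Feature counts are shifted Poisson (minimum 1, mean 8); feature responses
are log-normal with 1 log2-unit spread. **Replicate noise is applied per
feature and run** (i.i.d. log-normal measurement noise), with the
per-feature CV calibrated analytically so that the median protein-level
summed-intensity CV across biological replicates equals the scenario's
`replicate_cv` (20% by default): for multiplicative noise the CV of the
feature sum is $c\,\sqrt{\sum w_f^2}/\sum w_f$ with feature weights
$w_f$, so the generator solves for $c$ from the realized weights. This
placement matters: it makes the fixed-effects feature+group model exactly
correctly specified, so null p values are uniform and false-call fractions
sit at their nominal level. A run-level shared biological term would
instead make feature-level fixed-effects inference anti-conservative
(features would be pseudoreplicates of the run); the package treats the
per-feature realization as the generator's definition of replicate
variability and documents it as such. Dropout is logistic in log2
intensity (default midpoint 17, slope 1 on a baseline scale centered at
20), giving intensity-dependent missingness of a few percent overall.

Consequences for interpreting the recovery results:

* Passing tests show the pipeline recovers truth under log-normal,
  independent measurement noise with MAR intensity-dependent dropout. Real
  DIA data add correlated feature noise within runs, interference,
  batch structure and non-MAR missingness; none of these are simulated.
* ~17% of proteins draw fewer than 6 features and are untestable *by
  design* of the feature-count distribution. Membership-recovery
  sensitivity is therefore reported among testable proteins; the
  unconditional number would measure the feature lottery, not the calling
  procedure. Precision counts calls on proteins whose noise-free expected
  sorted/control fold-change is ≤ 1 as false; "truly enriched" for
  sensitivity requires expected FC ≥ 1.5, leaving an indeterminate band
  around the 1.1 gate that counts for neither — with a continuous latent
  truth, proteins arbitrarily close to the gate would otherwise make both
  metrics meaningless.
* Ages and sexes are assigned balanced across conditions, so sex/age are
  null covariates for variance partitioning by default.

# Numerical choices

* Per-protein fits share one QR decomposition across all proteins with the
  same observation pattern (multi-response least squares); a dataset of
  1,000 complete proteins fits in well under a second, which is what makes
  the 200-contrast null-calibration study routine.
* BH adjustment is `stats::p.adjust(method = "BH")` on the gated subset;
  the gate uses a strict inequality on the linear scale (>1.1 and its
  reciprocal).
* Ties at the edge-weight cutoff are excluded (strict >).
* The permutation p for complex co-regulation uses the add-one correction.
* `detect_modules` re-labels modules by decreasing size; label 0 is
  reserved for unassigned proteins.
* All randomness flows through explicit seeds; library calls never disturb
  the caller's RNG state (seeds are scoped and restored). Pipeline stages
  derive their seeds deterministically from the master seed, and pipeline
  outputs are byte-identical across reruns of the same configuration.

# Problem sizes used in the shipped verification

The test-suite and acceptance studies run at desk scale, chosen to keep
every Monte-Carlo margin comfortable: 200 null contrasts × 1,000 proteins
for calibration; 1,000 proteins with 200 planted 2-fold enrichments for
power; a 600-protein, 15-type, 4-animal experiment for membership
recovery; 5 planted modules × 50 proteins over repeated seeds for network
recovery; 10,000 random pairs for the co-regulation null; 10^5 sections
for the sphere expectation. These sizes are the package's verification
conditions, not statements about the scale of real experiments.

# Known limitations

* No imputation: missing feature measurements are dropped (MAR
  assumption), guarded by the testability filter.
* The run-level random effect is out of scope; with technical replicates
  the fixed-effects reduction would no longer be appropriate.
* Module detection uses a static cut, not dynamic tree cutting; deeply
  nested module structure may need a manual `cut_height`.
* The negative-pair screen's BH family is whatever candidate set the user
  supplies; its FDR is relative to that family.
* Sphere estimation assumes perfect spheres and ignores section thickness.
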
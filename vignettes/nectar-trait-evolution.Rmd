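---
title: "Methods: nectar sugar traits on a phylogeny"
author: "nectarphylo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nectar sugar traits on a phylogeny}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the statistical machinery in `nectarphylo`: the
models it fits, the assumptions each makes, the tunable parameters and
their defaults, what the synthetic-data generators emulate, and the design
choices made where several defensible options existed.

## 1. Trait summarization

Sample-level input is per-flower sugar masses (µg) of sucrose, glucose and
fructose over 24 h of accumulation. Proportions are computed per sample
(`m_i / Σ m_j`) and then averaged per species with equal weight per sample;
the species profile also carries the sample SD, the mean total amount, and
the sucrose/hexose ratio `S/(G+F)`.

Three conventions matter and are fixed deliberately:

* **Equal species weighting.** Dataset-level means average species
  profiles, not samples, so heavily sampled species do not dominate the
  community summary.
* **Printed percentages are not renormalized.** When a species-level table
  is loaded (percentages with one printed decimal), rows may sum to
  100 ± 0.3 points; the loader stores the values exactly as given and
  records each row's deviation in `prop_sum_error`, so published tables can
  be reproduced by direct arithmetic.
* **Ratio averaging.** With sample-level data the sucrose/hexose ratio is
  computed per sample and averaged, excluding (and counting) samples with
  zero hexoses; from a species-level table it can only be computed from the
  mean proportions and is flagged `ratio_approximate`. The two versions
  differ because the ratio is a nonlinear function of the proportions.
* **Rounding** for report output is half away from zero (`round_half_up`),
  the convention of printed percentage tables, not R's banker's rounding.

## 2. Pollinator assignment

The visitation frequency of a pollinator group on a plant species is total
visits divided by total flower-hours of observation. Observation effort
belongs to the plant, not the visitor group: flower-hours are summed over
distinct `(species, plant individual)` observation units. Each species is
affiliated with the group of maximal VF; exact ties are broken
lexicographically and flagged (the tie-break must be deterministic for
reproducible pipelines, and no biological ordering is defensible). Groups
that are primary for fewer than `min_species = 5` plants are excluded from
group-level analyses, mirroring the field rule that a selection-regime
category needs a minimal number of species to be estimable at all.

The packaged `synthetic_pollinator_assignments.csv` is a constructed
stand-in (the underlying survey's species-by-species affiliations are not
available as data): it has the right group structure — five groups, each
with ≥ 5 species, birds concentrated on sucrose-rich, high-production
flowers — but individual labels should not be treated as observations.
No verified quantity depends on it.

## 3. Trees and derived matrices

Trees are ape `phylo` objects; any user Newick with branch lengths is
accepted. Three derived matrices drive the statistics: the
variance–covariance matrix `C` (shared root-to-MRCA path lengths), the
patristic distance matrix `D`, and the Abouheif proximity `A[i,j] = 1 /
Π(direct descendants of internal nodes on the path i–j)`, which uses
topology only.

When no calibrated phylogeny is available, `taxonomy_tree()` builds a
three-level ultrametric fallback (species within genus, genus within
family, family at the root; default depths 1 : 2 : 3). This is a
deliberately crude substitute — it encodes taxonomic nestedness, not
divergence times — and signal statistics computed on it are statements
about taxonomic clustering. Polytomies (ubiquitous in the fallback tree)
are resolved randomly with zero-length inserted branches under a fixed
seed, which preserves every patristic distance. A consequence is tied and
zero distances; inverse-distance weights map zero distances between
distinct tips to the maximum finite proximity, with a warning, to avoid
division by zero.

Species absent from a reference tree are handled by an explicit
substitution mapping (`substitute_taxa`) supplied by the user; the package
never guesses a placement.

## 4. Phylogenetic signal

Four complementary indices are reported because they respond to different
aspects of signal:

* **Moran's I / Abouheif's Cmean**: autocorrelation `z'Wz / z'z` with
  row-normalized weights (inverse patristic distance, or Abouheif
  proximity). Expectation under random tip permutation is `−1/(n−1)`.
* **Blomberg's K**: `(MSE0/MSE) / E_BM[MSE0/MSE]` with the GLS mean; K = 1
  under Brownian motion on the supplied tree, K > 1 means more variance
  among clades than BM predicts.
* **Pagel's λ**: ML multiplier of the off-diagonal entries of `C`, profile
  likelihood over λ ∈ [0, 1] with the mean and rate maximized analytically
  at each λ. The search is bounded at 1 because `C(λ > 1)` can lose
  positive definiteness; implementations that allow λ slightly above 1 can
  therefore report marginally higher likelihoods on BM-like data.

Permutation tests default to `n_perm = 999` (a standard randomization
count; p-values then resolve to 1/1000) with one-sided "greater"
alternatives, since all four indices are oriented so that positive signal
is the scientific alternative; two-sided tests are a flag away. P-values
use `(1 + exceedances)/(n_perm + 1)`, which makes the test exact under
exchangeability. K's randomization permutes tip values, never tree
topology. λ's test is a likelihood-ratio test against λ = 0 on one degree
of freedom (a boundary-respecting mixture would halve the p-value; the
plain χ²₁ is conservative and is the common convention).

**Local Moran's I** decomposes the global I per tip,
`I_i = z_i (Wz)_i / (Σz²/n)`; with row-normalized weights the local values
average exactly to the global statistic. Significance uses conditional
permutation (tip i held fixed, all other values shuffled), and tips with
p < 0.05 are flagged as hotspots. Two caveats are inherent to the
statistic: a *cold* cluster (coherently low clade) also yields positive
local I, and when the community splits into one high and one low block,
both blocks can be flagged — the flags mark local coherence relative to
the community mean, not "high values".

## 5. Phylogenetic ANOVA / MANOVA

Species values are not independent, so classical F tests of
pollinator-group differences overstate significance whenever groups are
phylogenetically clumped. The simulation approach keeps the observed
statistic (one-way F, or Wilks' Λ) but generates its null distribution by
simulating trait evolution under Brownian motion on the tree — rate σ²
estimated by ML with the GLS mean for univariate traits, rate matrix from
phylogenetically independent contrasts for multivariate — recomputing the
statistic with the same group labels, and counting exceedances
(`n_sim = 1000` by default). On a star tree this collapses to the
classical Monte-Carlo test; with groups confined to clades the corrected p
is (correctly) much larger than the classical one.

The three sugar proportions sum to 1, so their MANOVA is rank-deficient.
Default preprocessing detects the compositional constraint and drops the
last column (the remaining two columns carry all the information); an
isometric-log-ratio transform is available for users who prefer a
coordinate-free treatment but requires strictly positive parts. The choice
is recorded in the result (`columns_used`).

Games–Howell post hoc comparisons use Welch-type pairwise t statistics
referred to the studentized range (`q = |t|√2`, k groups,
Welch–Satterthwaite df). They operate on the species values without
phylogenetic correction — the post hoc step characterizes *which* groups
differ once the omnibus test is interesting, in keeping with its standard
usage alongside the simulation tests.

## 6. Evolutionary models

Five Gaussian models are compared per trait. BM1: a single Brownian rate
(k = 2: σ², root mean θ₀). BMS: per-regime rates, covariance
`V[i,j] = Σ_r σ²_r · (shared root-path time in regime r)` (k = 1 + R).
OU1: single-optimum Ornstein–Uhlenbeck (k = 3). OU-PG(R): one optimum per
regime with shared σ² and α (k = 2 + R); OU-PG(2) groups all insect
regimes against birds. The OU covariance is the stationary form
`σ²/(2α) e^{−αD}(1 − e^{−2αC})`, which assumes an ultrametric tree
(checked, with an explicit error otherwise); optimum weights follow each
tip's regime history along its root path, with the root's weight
`e^{−αT}` assigned to the root regime so rows sum to 1 (the stationary-root
convention; a fixed-root variant is a deliberate non-goal).

**Fitting.** For fixed α the optima are a GLS problem and σ² profiles out
analytically, so OU fitting reduces to a 1-D search over α — evaluated on
a 24-point log-spaced grid over `[1e-9, 50/depth]` and refined locally.
This deterministic profile search replaces a generic multi-start
optimization over all parameters: it evaluates at least as many distinct
basins as five random starts would, cannot be trapped on the ridge that
couples σ² and α (the classic OU pathology), and makes fits exactly
reproducible. BMS optimizes log relative rates (Brent for two regimes,
Nelder–Mead above) from three deterministic starts. Boundary behavior is
meaningful: on BM data the OU α estimate sits at the lower bound and the
OU1 likelihood equals BM1's, so AICc's parameter penalty decides — which
is exactly the desired model-selection behavior.

**Regime histories.** Pollinator regimes are mapped onto the tree by
stochastic character mapping under an Mk model fitted by maximum
likelihood (pruning algorithm, uniform root prior). The default Mk model
is equal-rates — the fewest parameters for a 5-state character on 61 tips;
symmetric rates are available. Node states are drawn root-down from the
conditional likelihoods; branch histories are sampled by rejection
(forward simulation conditioned on the endpoint, 200 tries) with an exact
uniformization sampler as fallback, so no branch is ever silently dropped.
The number of maps defaults to 10; regime-model likelihoods and AICc are
averaged over maps with per-map fits retained, making the Monte-Carlo
variability inspectable.

AICc uses n = number of tips. Model tables flag the lowest AICc per trait;
exact ties are all flagged and messaged.

## 7. Synthetic data: what it does and does not emulate

The generators produce: Yule/birth–death trees conditioned on n tips and
rescaled to unit depth (so α and σ² have a common scale across
replicates); forward-simulated Mk regime histories; traits under BM,
λ-transformed BM, and multi-regime OU (branch-wise exact transition
sampling, stationary root); per-sample nectar masses as log-normal totals
with Dirichlet sugar splits around species means; and Poisson visitation
counts at group-specific rates over a 5-plant × 24 h design, the typical
effort of camera-based visitation studies. Test problem sizes — 64–128-tip
trees, 100–500 trait replicates, 199–999 permutations — were chosen as the
smallest sizes at which the calibration targets (mean K, λ medians, exact
type-I error) have comfortably small Monte-Carlo error.

The log-normal/Dirichlet choice is a modeling convenience: real nectar
data make no distributional claim, and the parameters are configuration,
not constants. What the generators do **not** emulate: measurement error
of refractometry/chromatography, within-plant correlation of samples,
elevational or spatial sampling structure, missing data, and
non-ultrametric (fossil) trees. Green tests therefore certify the
estimators and their calibration under clean Gaussian/Markov ground truth,
not robustness to those field realities.

## 8. Numerical choices and degenerate inputs

* Likelihoods use Cholesky factorizations throughout; non-positive-definite
  covariances at extreme parameters return a large finite penalty inside
  optimizers and an explicit error at the user surface.
* OU variance factors use `expm1` so the α → 0 limit is exact to roundoff;
  at α = 1e−8 the OU1 likelihood matches BM1 to < 1e−4.
* Constant traits make K and the autocorrelation indices undefined; results
  are returned flagged `degenerate` rather than erroring mid-pipeline.
* A single observed regime state puts the Mk rate at the zero boundary,
  flagged, and stochastic maps degenerate to the single-regime painting.
* Zero-length branches (polytomy resolutions) are kept at exactly zero;
  ties they induce in `D` are tolerated everywhere, and zero distances are
  remapped only inside inverse-distance weights (with a warning).

## 9. Known limitations

* Signal statistics and model fits on the taxonomy fallback tree measure
  taxonomic clustering, not calibrated evolutionary divergence; users with
  a dated phylogeny should supply it.
* λ is bounded at 1; traits "more Brownian than the tree" are reported as
  λ = 1.
* The MANOVA rate matrix comes from independent contrasts on a fully
  resolved tree; heavily polytomous trees rely on the zero-length
  resolution convention.
* Games–Howell is non-phylogenetic by design; its p-values inherit species
  non-independence.
* Regime-model averaging treats stochastic maps as fixed alternatives
  (mean lnL/AICc), not as a formal integration over histories.
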
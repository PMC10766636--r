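---
title: "Methods: D-loop phylogeography, expansion dating and ABC scenario choice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: D-loop phylogeography, expansion dating and ABC scenario choice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models behind `dloopr`, the tunable parameters
and their defaults, what the synthetic-data generator does and does not
emulate, and the numerical and design choices a maintainer would want
written down. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The data model

The unit of analysis is a rectangular alignment of haploid (maternally
inherited) control-region sequences over `{A, C, G, T}` plus gap, `N` and
the IUPAC ambiguity codes. Throughout the package every non-ACGT symbol is
*missing*: it is counted against a site in the missing-data filter and
excluded pair-by-pair ("pairwise deletion") when differences are counted.
The filter removes a site only when its missing fraction strictly exceeds
the threshold (default 0.70), so a site at exactly 70 % is kept.
Coordinates are 0-based internally; reports print 1-based positions.

Haplotype identity is exact string match on the retained sites, including
any residual ambiguity characters. Programs differ in how they treat
residual ambiguity when collapsing haplotypes, so haplotype counts can
deviate slightly from other software on dirty data; on data with no
ambiguity the definitions coincide.

## Diversity and expansion dating

* π is the mean over unordered pairs of `d_ij / comparable_ij` — a
  per-site p-distance without multiple-hit correction, matching how short
  intraspecific distances are normally reported.
* H uses the bias-corrected form n/(n−1)(1−Σp²).
* Tajima's D uses the standard constants (a₁, a₂, b₁, b₂, c₁, c₂, e₁, e₂)
  computed from their definitional sums; `k_hat` is the mean pairwise
  difference count under pairwise deletion, and S counts sites with at
  least two distinct unambiguous bases. Significance uses the
  beta-distribution approximation: D is treated as a rescaled beta variate
  on (D_min, D_max) with mean 0 and variance 1, giving the usual
  `ns / p<0.05 / p<0.01` flag. A coalescent-resampling p-value could be
  assembled from the simulator but the beta flag is what desktop
  popgen software reports, so it is the default and the only implemented
  path.
* The mismatch distribution is fitted with the three-parameter
  sudden-expansion curve (τ, θ₀, θ₁). We evaluate the expected curve in a
  numerically safe closed form derived from the pairwise coalescent with a
  piecewise-constant rate:
  F_j = F̂_j(θ₁)·[1 − P(Pois(λ₁τ) ≤ j)] + e^(−τ/θ₁) Σ_{i≤j} dpois(i; τ)
  F̂_{j−i}(θ₀), with F̂_j(θ) = θʲ/(θ+1)ʲ⁺¹ and λ₁ = (θ₁+1)/θ₁. This is
  algebraically identical to the classical expansion formula (it reduces
  to F̂(θ₀) at τ = 0, to F̂(θ₁) as τ → ∞, and to a Poisson when θ₀ → 0,
  θ₁ → ∞) but avoids overflow at large difference counts. The fit is a
  deterministic coarse grid (τ, θ₀, θ₁; θ₁ capped at 1000) followed by
  Nelder–Mead refinement, minimizing the sum of squared deviations between
  normalized curves. Which estimator a given desktop program uses for τ is
  usually undocumented; least squares on the full histogram is the
  reproducible choice here.
* Datings: `expansion_time(tau)` = τ/(2μ_seq) and `divergence_time(d)` =
  d/(2μ_site). The default constants are μ_site = 3.13 × 10⁻⁷
  mutations/site/year (chicken control region), L = 1230 sites, one-year
  generations, hence μ_seq = 3.85 × 10⁻⁴ per sequence per year. (A widely
  circulated version of that per-sequence rate omits the minus sign of the
  exponent; only 3.85 × 10⁻⁴ is dimensionally consistent with the per-site
  rate and the ~320-year dating it accompanies.)

## Median-joining networks

`build_mj_network()` follows the median-joining heuristic: alternate an
ε-relaxed minimum spanning network over the current node set with the
addition of majority-consensus (median) vectors for connected triplets,
keeping per round only candidates whose connection cost is within ε of the
minimum, and deleting median vectors whose degree falls to ≤ 2. Defaults:
ε = 0 (the common software default), uniform site weights, and sites
containing a gap or ambiguity in any haplotype excluded from the network
distance. Tie-breaking is lexicographic in (distance, node id) and
candidate medians are added in sorted order, so the output is
deterministic. With ε = 0 and all pairwise distances distinct the network
is exactly the unique MST; with ties it is the union of all MSTs, so tied
parallel links are a feature, and the meaningful "medians never lengthen
the network" property is that the spanning structure *through* the network
(medians acting as Steiner points) is never heavier than the MST over
observed haplotypes alone — that is what the tests assert.

## Spatial structure

Net between-population distance is dA = dXY − (dX + dY)/2 on per-site
p-distances, clamped at zero (negative estimates are sampling noise);
singleton populations have within-distance 0. Neighbor-joining uses the
standard agglomeration; negative branch lengths are set to zero with the
deficit moved to the adjacent branch. Midpoint rooting places the root at
the middle of the longest leaf-to-leaf path.

AMOVA treats pairwise difference counts as squared Euclidean distances and
decomposes them into among-group (σ²a), among-population-within-group
(σ²b) and within-population (σ²c) components with the usual unequal-size
coefficients; Φ_CT = σ²a/σ²tot, Φ_SC = σ²b/(σ²b+σ²c), Φ_ST =
(σ²a+σ²b)/σ²tot. The SAMOVA-style search maximizes Φ_CT over partitions of
subpopulations into K non-empty groups by simulated annealing (geometric
cooling from T₀ = 1, ratio 0.95, 100 moves per temperature, 60 levels, 20
seeded restarts; a move reassigns one deme). No geographic-contiguity
constraint is imposed: empirically interesting K = 2 solutions can group
non-adjacent demes, and at survey scale (≈ 10 demes) the exhaustive K = 2
enumeration (`samova_exhaustive_k2()`) guards the annealing result — the
acceptance suite checks their equality across seeds. The annealing inner
loop is compiled (C++) with the R implementation of the variance
components retained as the reference path, so the two routes stay
independent.

## The coalescent simulator

`simulate_genealogy()` is a structured haploid coalescent: within a
population of effective (female) size N each lineage pair coalesces at
rate 1/N per generation; at a split time the daughter's lineages move into
the ancestor; no migration (mtDNA splits cleanly here) and no
recombination. Time is continuous in years with a one-year generation.

Three colonization scenarios relate an island population (Madagascar), a
mainland neighbor (EastAfrica) and a source region (WestAsia); their time
priors are uniform — Ta ~ U(800, 1200), T1 ~ U(800, 2000) with T1 > Ta,
T2 ~ U(700, 2000), T3 ~ U(700, 1200) with Ta > T3 — drawn by rejection on
the order constraints. Effective sizes default to a log-uniform prior
on (10, 10⁵) independently per population, with a plain uniform available
(`n_prior_log = FALSE`). This N prior is the key free choice for any
attempt to reproduce published posterior probabilities: the source
analysis software's internal defaults are not documented. The log-uniform
default is a deliberate design decision backed by measurement: under the
plain uniform, prior mass concentrates at effective sizes of tens of
thousands, where splits 700–2000 years deep leave no detectable trace and
the three scenarios become statistically indistinguishable (mean posterior
probability ≈ 1/3 for every scenario in the package's own recovery
experiments); a log-uniform prior — the standard choice for a scale
parameter spanning orders of magnitude — restores the identifiability
that any meaningful scenario comparison presupposes.

Sequence evolution is HKY+I+Γ: defaults κ = 10 (strong transition bias,
typical of the control region), equal base frequencies unless supplied,
gamma shape α = 0.5 in 4 discrete categories (quantile-median rates
normalized to mean 1), invariant-site proportion p_inv = 0.5. A site is
invariant with probability p_inv, otherwise its rate is μ × category
multiplier, so the realized sequence-wide mean rate is μ(1 − p_inv).
Substitutions are generated by uniformization of the normalized HKY chain
(Poisson number of candidate events per branch; each candidate mutates
with probability leave-rate/max-rate), which is exact for a CTMC and fast
at the low divergences involved; the analytic matrix exponential
(`hky_transition_matrix()`) is kept as the independent check used by the
tests.

## ABC

The summary vector holds, per population: S, number of haplotypes, H,
mean and variance of pairwise differences, Tajima's D (0 with a validity
mask when undefined); per population pair: mean between-population
differences and FST in the 1 − within/between form. Rejection standardizes
each statistic by its reference-table MAD (degenerate statistics are
dropped with a warning), uses Euclidean distance, and keeps the
⌈tolerance × rows⌉ closest rows. Scenario posterior probabilities come
from a multinomial logistic regression of the scenario label on the
centered statistics among retained rows, evaluated at zero (the observed
point); the regression is hand-rolled Newton–Raphson with a small ridge
(10⁻⁴) because no multinomial-logit package can be assumed present, with
delta-method confidence intervals from the intercept block of the inverse
information, and a retained-fraction fallback when the regression is
singular. Parameter posteriors use the local-linear (Beaumont) adjustment
with Epanechnikov weights, clipping adjusted draws to the prior, and
report the weighted median and weighted 95 % HPD.

Two scale choices are documented deliberately. The reference table default
is 30,000 rows (10,000/scenario) — a desk-scale stand-in for the
3-million-row analyses run on clusters; the scenario-choice tolerance is
0.01 (300 retained). For *parameter* estimation the retained count must
comfortably exceed the ~26 summary statistics or the local-linear
adjustment over-fits and its HPDs under-cover; calibration experiments in
the development history (78/100 nominal-95 % coverage at 100 retained
versus 92–93/100 at ≥ 300) fixed the parameter-estimation protocol at 500
retained rows from the 10,000-row single-scenario table. The acceptance
experiments use the survey's per-population sample sizes (76, 30, 50):
halving them (an earlier runtime shortcut) measurably destroyed the
scenario-recovery signal — with only 15 mainland samples the nesting
direction that separates the island-from-mainland and mainland-from-island
scenarios is invisible — so the coalescent and mutation inner loops are
compiled instead.

## The synthetic-data generator

`generate_study_like()` emulates a 78-bird, 11-locality island survey:

* a Lowland pool that underwent a sudden expansion at mutational time
  τ = 0.248 (≈ 322 years at the default rate): coalescent with a large
  post-expansion size (θ₁ = 50, effectively star-like on the sampling
  horizon) collapsing to θ₀ = 0.001 before the expansion;
* a Highland deme (the two > 1000 m localities plus one mid-elevation
  trade-route locality, Manja) of effective size 50 splitting from the
  Lowland pool at d/(2μ_site) ≈ 455 years, where d = 2.85 × 10⁻⁴/site;
* two outlier birds at the port locality (Fort Dauphin), the expansion
  founder mutated at 20 random sites — mimicking introgression from a
  distant foreign haplogroup;
* locality sample sizes near-equal (7–8), elevations consistent with the
  Highland-iff-> 1000 m rule; the generator model sets p_inv = 0 so the
  realized mean rate equals μ_site and the two datings stay internally
  consistent with the τ and d inputs.

One conditioning step is essential and documented: at these rates a clean
split only ~455 years deep leaves a Highland-distinguishing mutation in
only ~20–30 % of genealogies, so an unconditioned generator cannot
reproduce the *observed* feature of the emulated survey — clear
Highland/Lowland differentiation. The generator therefore redraws the
genealogy (mean ≈ 5 tries, recorded as `n_tries` in the truth record)
until the modal Highland haplotype differs from the modal Lowland
haplotype. Consequences: the spatial K = 2 signal is present by
construction (that is the point of a fixture generator), and Tajima's D is
slightly less negative than an unconditioned expansion would give —
occasionally even positive — because the conditioning enriches
mid-frequency variants. A green pipeline test on these data therefore
establishes that the code recovers a planted signal, not that such signals
are always detectable at these diversity levels.

What the generator does not emulate: real haplogroup nomenclature,
sequencing error, alignment artifacts (its output has no gaps or
ambiguities, so the site filter is exercised by dedicated unit fixtures
instead), unequal locality sizes, and within-island migration after the
split.

## Numerical and degenerate-input conventions

* `fit_sudden_expansion` on a point mass at zero differences returns
  τ = 0, θ₀ = 0 without fitting.
* Tajima's D is an error (not NaN) at S = 0; the ABC summary encodes such
  undefined entries as 0 with a validity mask so vectors keep fixed
  length.
* Net distances and adjusted ABC draws are clamped to their supports;
  negative NJ branch lengths are zeroed with the deficit transferred.
* Zero-diameter trees are rooted arbitrarily and flagged
  (`zero_diameter` attribute).
* All stochastic entry points take explicit seeds (`samova`,
  `simulate_dataset`, `generate_study_like`, `build_reference_table`) and
  restore or isolate RNG state where they seed internally; identical
  seeds give byte-identical outputs.
* The pipeline config is JSON (not YAML): it keeps the dependency
  footprint to packages guaranteed present, with identical structure.

## Known limitations

* PP values for the three colonization scenarios are reproducible in rank
  order and rough magnitude only; they are sensitive to the undocumented
  effective-size prior and to reference-table scale.
* The mismatch τ estimator can differ from other programs' moment
  estimators by more than rounding on ragged multimodal histograms; and on
  near-monomorphic histograms (mean pairwise differences well below 1) τ
  is only weakly identified — a small-θ₁ equilibrium curve fits a monotone
  histogram about as well as a star-expansion curve, so τ point estimates
  there should not be over-interpreted. The recovery tests use
  parameter regions where the curve is identifiable.
* SAMOVA here implements the published *objective* (maximize Φ_CT); the
  original program's annealing internals are not documented and are not
  reproduced move-for-move; a geographic-contiguity constraint (an option
  in some implementations) is not available — the search is unconstrained.
* The haplogroup classifier is nearest-reference only — it stands in for
  tree-based haplogroup reading and should not be used for nomenclature
  decisions.
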
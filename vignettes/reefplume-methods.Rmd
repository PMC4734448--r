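---
title: "Methods: river-plume exposure and microbial community statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: river-plume exposure and microbial community statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reefplume)
```

This vignette is the package's own account of its models, the choices made
where the design was genuinely open, and what the synthetic tests do and do
not demonstrate about real monitoring data.

## 1. Tracer transport

River influence is modelled with conservative passive tracers: each river
releases its own tracer at unit concentration and the tracer is moved by
advection and horizontal diffusion only — no decay, no reaction, no
feedback on the (prescribed) flow. The solver is a 2D depth-averaged
explicit scheme on a regular grid:

* **advection**: flux-form first-order upwind, with face velocities
  averaged from the adjacent cell centres and zeroed across land faces;
* **diffusion**: centred differences across water–water faces;
* **boundaries**: either closed (no flux) or open (zero-gradient advective
  outflow at the domain edge; the exported mass is accounted in a budget,
  not conserved).

A 2D column of effective mixed-layer depth (`depth`, default 5 m) stands in
for the vertically resolved circulation of a regional coastal model:
vertical structure is irrelevant to the exposure-index arithmetic this
package exists to exercise, and the depth-averaged stand-in keeps the
conservation and monotonicity properties provable (and tested) at desk
scale. First-order upwind is deliberately diffusive; we accept the extra
numerical mixing in exchange for positivity and an exact discrete mass
budget (verified to 1e-10 relative over 1000 steps in the tests).

**Stability.** The explicit scheme requires a Courant number at most 1 and
a diffusion number `K·dt·(1/dx² + 1/dy²)` at most 0.5; positivity of the
*combined* update additionally requires `Cx + Cy + 2(ax + ay) ≤ 1`, which
the two classical bounds do not imply on their own. All three are checked
before every step and violations raise configuration errors rather than
silently corrupting the field.

**Source injection.** The injection scheme of regional tracer runs is
rarely published, so the package defines its own: the mouth cell is relaxed
towards the source concentration (1.0) with weight
`min(1, Q·dt / (dx·dy·depth))`, i.e. the fraction of the cell volume the
river discharge `Q` replaces per step. A flood refills the mouth cell
within a step; a trickle barely moves it. Discharge is read from a
`date → ML/day` hydrograph.

**Defaults.** The bundled scenario uses a 90 × 60 grid at 2 km resolution,
`K = 50 m²/s`, an alongshore residual current of 0.1 m/s, a wet-season
flood hydrograph (60,000 ML/d during the flood months against a 2,000 ML/d
baseflow — a typical tropical-catchment flood magnitude), and `dt = 1800 s`
(the scenario's own choice; `transport_params()` defaults to 600 s). All
default combinations satisfy the stability constraints above.

## 2. The cumulative exposure index

For a cell's daily concentration series the index is the time-integral of
exceedance above a threshold:

* `exceedance(c) = c − thresh` when `c > thresh` (strictly), else 0, with
  `thresh` = 1% of source concentration;
* `Conc.Days = Σ exceedance(Conc(t)) · Δt` with `Δt` = 1 day, accumulated
  over the wet-season window 01 November – 31 March (inclusive on both
  ends: 151 days across a non-leap February).

Defined this way the index satisfies the equivalence that anchors its
interpretation — 20 days at 1% above the threshold and 10 days at 2% above
both give 0.2 conc.d — together with additivity over disjoint windows,
linearity in the exceedance, and monotonicity in the concentration series,
all of which are property-tested. An alternative reading that weights each
day's exceedance by its elapsed time since the season start is provided as
`method = "literal_t"` for comparison; it breaks the 20-day/10-day
equivalence and is not the default.

Maps are produced per tracer and combined by summation across rivers (the
combination rule for multi-river exposure is the package's choice), capped
at 20 conc.d for display, with running cumulative snapshots every 7 days.
Site-level exposure at a sampling date accumulates the *current* wet
season's index up to that date and is zero for dates outside the season:
the index describes ongoing river influence, which the dry season resets.

Sites are classified by their distance to the nearest influencing river
mouth: upstream → riverine, < 20 km downstream → plume, otherwise marine.
Exactly 20 km is classified marine (the plume rule uses a strict `<`; the
boundary case is undefined in the field convention the rule comes from, so
the package fixes it and documents it here).

## 3. The synthetic study generator

The generator exists so that every downstream statistic can be exercised,
with known truth, without any sequencing data. It emulates the *output* of
an amplicon workflow — a taxonomy-annotated OTU count table — not reads.

**Communities.** Two fixed endmember profiles with geometric rank-abundance
within taxonomic blocks: a marine community of 95 OTUs dominated by
Rickettsiales/Pelagibacteraceae (29.6%), Thermoplasmata E2 / Marine Group
II (17.7%), Synechococcales (*Prochlorococcus*, *Synechococcus*) and
Acidimicrobiales/OCS155; and a poorer riverine community of 65 OTUs
dominated by Burkholderiales (Comamonadaceae, Oxalobacteraceae),
Sphingobacteriales and Xanthomonadales, with Flavobacteriales present in
both. The 65 vs 95 OTU richness contrast and the marine order-level means
are calibration anchors chosen once; tests check the generated tables stay
near them.

**Mixing.** A sample's expected composition is
`w · riverine + (1 − w) · marine`, with
`w = plogis(intercept + β · exposure + wet_offset · is_wet)`. The defaults
(`intercept = −4`, `β` such that 20 conc.d → w ≈ 0.8, `wet_offset = 0.5`)
put unexposed marine samples near w ≈ 0.02 and a heavily exposed mouth
site near w ≈ 0.8. The marine endmember itself is season-modulated:
5% of total abundance moves from Pelagibacteraceae to Marine Group II in
the wet season (and back in the dry), giving the offshore community its
own seasonal signal independent of river exposure. No quantitative
seasonal effect sizes exist to copy, so these are fixed qualitative
choices, stated here once.

**Counts.** Expected relative abundances are multiplied by per-OTU 16S
copy numbers (1–8 by lineage: oligotrophic marine clades low, copiotrophic
riverine Proteobacteria high) and renormalised *before* the multinomial
draw at the sample's sequencing depth (lognormal around ~2,500 reads,
clipped at 300). This deliberately injects the copy-number bias that
`copy_number_correct()` is meant to remove, so the correction has real
signal to act on; the round trip is verified in the tests. Eukaryote
contaminant reads (a small hydrozoan/diatom profile) are appended at a 2%
expected rate for the eukaryote-to-prokaryote ratio statistic.

**Environment.** Fourteen covariates are generated from four independent
standard-normal latent factors through a loading matrix with primary
loadings 0.8 and unique noise sd 0.6: MR1 rainfall + discharge, MR2 the
particulate/water-quality block (chlorophyll a, SS, POC, PN, PP, and
diuron, which travels with sediments), MR3 freshwater mixing (DIN and Si
positive, salinity negative), MR4 temperature + solar exposure. Si's
assignment to MR3 and bottom depth being site-fixed (factor-free) are
package assumptions — the factor memberships reported for the remaining
variables do not pin them down. The implied cross-loading correlation
(e.g. r(rain, discharge) = 0.8²/(0.8² + 0.6²) = 0.64) is what the EFA
recovery tests rely on, and the latent scores are stored as truth columns.

Everything is deterministic given the scenario seed; the environment and
community generators derive distinct sub-seeds so stages are independently
reproducible.

**What passing tests show — and do not.** The generator produces clean
two-endmember mixtures with multinomial noise and an exactly linear factor
model. Real amplicon data add over-dispersion, taxa shared between river
and sea, chimeric/contaminant OTUs, depth-dependent taxon detection and
non-Gaussian covariates. Passing the recovery tests therefore validates
the *statistical machinery* (the estimators recover what generated the
data), not the field behaviour of any specific reef system.

## 4. Diversity processing

* **Rarefaction** (`rarefy()`): `mode = "draw"` subsamples without
  replacement; `mode = "expected"` returns expected counts under repeated
  resampling — the infinite-replicate limit. Two resampling models are
  shipped because "bootstrap rarefaction" is ambiguous in the literature:
  with replacement (multinomial, the default, expected richness
  `Σ 1 − (1 − pᵢ)^d`) and without replacement (classical hypergeometric,
  `Σ 1 − C(N−nᵢ, d)/C(N, d)`). Both are verified against 10,000-draw
  Monte-Carlo oracles; the difference between them shrinks as `N/d` grows.
  Samples below the target depth are dropped and reported, and a per-run
  depth override exists for re-analyses that need to keep a shallow sample.
* **Alpha diversity**: richness, Shannon–Wiener H in nats (the log base is
  a documented choice; base-2 available via `base =`), evenness H/ln S
  (defined 0 at S = 1), and Chao1 `S + F1²/(2F2)` with the bias-corrected
  form when no doubletons exist. Chao1 requires integer counts and is NA on
  expected-mode tables.
* **Mann–Whitney** (`mann_whitney_one_sided()`): exact via the null U
  distribution when the pooled n is at most 12 with no ties; otherwise a
  tie-corrected, continuity-corrected normal approximation.
* **EPR**: eukaryote/prokaryote read ratio on unrarefied counts; undefined
  (NA with warning) when a sample has no prokaryote reads.

## 5. Multivariate statistics

All implemented in the package, with vegan used in the test suite as an
independent cross-check where it offers the same statistic.

* **Hellinger + PCoA**: square-root of relative abundances; PCoA by Gower
  double-centring and eigendecomposition, scores scaled by √eigenvalue.
  Negative eigenvalues are reported but excluded from proportions and no
  Lingoes/Cailliez correction is applied by default — Hellinger distances
  are Euclidean-embeddable, so none is needed on the main pipeline.
* **PERMANOVA**: sequential (order-dependent) sums of squares from hat
  matrices applied to the Gower-centred inner-product matrix; pseudo-F
  tested by permuting raw rows (the simplest defensible null for
  unconditioned models), `p = (1 + #{F* ≥ F}) / (1 + n_perm)`. The
  one-term case reduces algebraically to the classical within/between
  group-distance form, which the tests exploit as an oracle, and the
  type-I error at α = 0.05 is verified to sit in [0.03, 0.07] over 1,000
  null simulations.
* **IndVal**: group-mean-based specificity A (group-size-corrected),
  occurrence-fraction fidelity B, statistic `max_g √(A·B)`; significance by
  label permutation. No site-group combinations and no ×100 scaling; raw
  permutation p-values by default (Benjamini–Hochberg available via
  `p.adjust` on the output if desired).
* **Partial RDA**: response and constraints residualised on the condition
  block, multivariate regression, SVD of the fitted values; eigenvalues on
  the variance scale so constrained + unconstrained eigenvalues equal the
  total variance of the (residualised) response to 1e-10. Constraints
  absorbed entirely by the condition block are dropped rather than fitted
  to numerical noise. The overall-model permutation test permutes rows of
  the residualised response.
* **Stepwise AIC**: `n·ln(RSS/n) + 2k` on the residual sum of squares of
  the constrained fit. No AIC is uniquely defined for distance-based RDA in
  the literature; this RSS-based analogue is fixed, documented, and has the
  properties the selector needs (duplicated covariates can never both
  enter; pure-noise candidates are usually rejected), verified by
  simulation.
* **EFA**: iterated principal-axis factoring on the correlation matrix
  (communalities initialised at squared multiple correlations, iterated to
  1e-6 with a Heywood guard capping communalities just below 1),
  factor count by parallel analysis (95th percentile of eigenvalues from
  column-permuted data), varimax rotation, regression factor scores,
  max-|loading| variable assignment. Non-convergence within the iteration
  cap is an error, not a silent fallback.

## 6. Numerical and degenerate-input policy

Validation errors are raised for: NaN or negative tracer fields, stability
violations, empty concentration series, all-zero community rows, aliased
PERMANOVA designs (naming the aliased terms), collinear RDA constraints
(naming the dependent columns), missing water-quality indicators (no
silent imputation), and zero/negative copy numbers. Permutation p-values
always respect `p ≥ 1/(n_perm + 1)` and are reproducible under a seed. Ties
in the stepwise selector break towards the first-listed candidate.

## 7. Problem sizes

The bundled end-to-end scenario uses a 90 × 60 / 2 km grid for one
151-day wet season at dt = 1800 s, 7 sites × 6 dates = 42 samples,
rarefaction depth 279 and 999 permutations — sizes chosen so a complete
run takes well under a minute on a laptop while leaving every statistic
enough samples to be meaningful. The test suite's simulations (1,000-run
type-I error studies, 10,000-draw rarefaction oracles) were sized the same
way.

## 8. Known limitations

* The flow is prescribed, not solved: no tides, wind events or momentum
  dynamics, hence no attempt to reproduce any specific year's observed
  exposure fields.
* First-order upwind advection smears plume fronts at coarse resolution;
  exposure gradients are qualitatively right, not hydrodynamically sharp.
* The water-quality index is a simplified guideline-ratio scoring
  (±1 per indicator, averaged), not the full monitoring-program index it
  is inspired by.
* The generator's seasonal effect sizes are qualitative calibrations; real
  effect magnitudes vary by system and year.
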
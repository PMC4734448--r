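# reefplume

Inshore coral-reef lagoons receive pulses of river floodwater every wet
season, carrying sediments, nutrients and herbicides that alter water
quality and leave a measurable imprint on the planktonic microbial
community. `reefplume` packages the computational chain used to study that
imprint at desk scale: a passive-tracer river-plume model, a cumulative
river-exposure index with a distance-based site classifier, a seeded
synthetic-data generator for community and environmental covariates, and
the community statistics (diversity, ordination, permutation tests, factor
analysis) that connect exposure to community structure.

## The quantities at the core

**River exposure.** Each river releases a conservative tracer at unit
concentration; the tracer is advected and diffused on a 2D depth-averaged
coastal grid (first-order upwind + explicit centred diffusion, no
sources/sinks in the transport operator). For a cell with daily tracer
concentration Conc(t), the cumulative exposure index over the wet season
(01 Nov–31 Mar) is

    Conc.Days = Σ_t Conc_exceed(t) · Δt,   Δt = 1 day
    Conc_exceed(t) = Conc(t) − Conc_thresh  if Conc(t) > Conc_thresh, else 0

with Conc_thresh = 1% of the source concentration. Units are
concentration-days (conc.d): 20 days at 1% above the threshold gives 0.2
conc.d, the same as 10 days at 2%. Sites are classified **riverine**
(upstream of a mouth), **plume** (< 20 km downstream) or **marine**
(≥ 20 km).

**Community statistics.** Profiles are rarefied to a common depth
(subsampled, or the analytic expectation under with/without-replacement
resampling), corrected for 16S copy-number bias
(aᵢ/cᵢ normalised), and summarised by richness, Shannon–Wiener H,
evenness H/ln S and Chao1, with one-sided Mann–Whitney group tests.
Community structure is analysed on Hellinger-transformed profiles:
PCoA, PERMANOVA (distance-based linear model with sequential SS and row
permutation), indicator-species IndVal = √(A·B) with permutation p-values,
partial RDA with an AIC-based stepwise selector, Pearson screening, and
exploratory factor analysis (iterated principal-axis factoring, parallel
analysis, varimax).

All of the multivariate machinery is implemented in the package itself and
is cross-checked in the test suite against independent oracles (closed
forms, brute-force enumeration, and vegan where it implements the same
statistic).

## Worked example

The bundled scenario simulates one wet season (Nov 2010–Mar 2011) of a
single river on a 90 × 60 cell / 2 km grid with an alongshore residual
current, samples seven monitoring sites (one riverine, three plume, three
marine) on six dates spanning wet and dry seasons, generates 42 synthetic
community profiles along the exposure gradient, and runs the statistics:

```r
library(reefplume)
man <- run_pipeline(default_run_config(seed = 1), outdir = "run1")
man$results$permanova
#>       term df        SS         F         R2     p
#> 1 category  2 7.2585026 18.212951 0.46170527 0.001
#> 2   season  1 0.8904019  4.468372 0.05663747 0.003
#> 3 Residual 38 7.5721692        NA 0.48165726    NA
```

Site category explains the largest share of community variation (R² =
0.46, p = 0.001), with a smaller but significant seasonal effect (R² =
0.057, p = 0.003) — the spatial gradient dominates the seasonal one. The
maximum simulated exposure is ~21 conc.d at the site 2 km from the mouth,
decaying to ~3–5 conc.d at the marine sites, and the rarefied profiles
give median richness 55 OTUs at the riverine site versus ~90–96 at plume
and marine sites:

```r
div <- read.delim(file.path(man$outdir, "diversity.tsv"))
head(div, 3)
#>         sample richness  shannon  evenness     chao1
#> 1  20110120_TR       56 3.631433 0.9021405  61.04167
#> 2 20110120_TT1      106 4.371524 0.9374035 127.23529
#> 3 20110120_TT2       99 4.424072 0.9627762 119.63158
```

The generator also stores the true riverine mixing fraction per sample;
unmixing the generated profiles recovers it almost exactly
(r ≈ 0.999), which is the backbone of the end-to-end test.

Every output (tracer fields, exposure maps, site exposure, OTU table,
covariates, diversity, test tables) is written as TSV plus a
`manifest.json` with seeds and checksums; identical config + seed gives
byte-identical outputs.

## Package layout

- `R/grid.R`, `R/transport.R` — grid/flow/source types and the tracer solver
- `R/exposure.R` — exceedance, cumulative index, maps, site classifier
- `R/synthetic.R`, `R/otu_table.R` — scenario generator, OTU-table container and I/O (TSV, BIOM-JSON)
- `R/diversity.R` — rarefaction, copy-number correction, alpha diversity, Mann–Whitney, EPR
- `R/multivariate.R` — Hellinger, PCoA, PERMANOVA, IndVal, RDA, stepwise AIC, EFA, Pearson
- `R/pipeline.R` — `run_pipeline()`; a thin CLI wrapper lives in `inst/scripts/reefplume-run.R`
- `vignettes/reefplume-methods.Rmd` — models, assumptions, parameter choices and limitations
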
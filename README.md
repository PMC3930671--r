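# stemmosaic

Spatial structure of frequent-fire conifer forests from stem maps.

Old-growth pine and mixed-conifer stands shaped by frequent low-severity
fire are not uniform: trees occur as a mosaic of **patches** (groups with
overlapping crowns), **single trees**, and **canopy gaps**, and that mosaic
— together with the fire regime that maintains it — is the reference
condition restoration prescriptions aim for. stemmosaic implements the
analysis suite used to characterise such stands from 4 ha stem maps (one
row per stem: location, species, DBH, height, live/snag status) and from
fire-scar chronologies, for forest ecologists and silviculturists working
with mapped plots.

## What it computes

**Second-order spatial statistics.** The pair correlation function

    g(r) = 1 under complete spatial randomness (CSR),
         > 1 aggregation, < 1 regularity

estimated with an Epanechnikov kernel and Ripley's isotropic edge
correction, univariate or bivariate, homogeneous or normalised by a kernel
intensity surface λ(u); Ripley's K/L for the large-scale homogeneity
screen. Significance comes from rank-5-of-199 Monte Carlo simulation
envelopes (pointwise two-sided 0.05) under four null models — CSR,
inhomogeneous Poisson, toroidal-shift independence of two populations, and
random labeling of live/snag marks — paired with the Loosemore–Ford
goodness-of-fit test over 0–50 m.

**The stand mosaic.** Crown radii from per-species allometries
(CW = b0 + b1·DBH + b2·DBH² + b3·CR + b4·BA + b5·HI, with the Hopkins
bioclimatic index as geographic covariate); patches as connected components
of strict crown overlap, with exact union-of-disks areas and perimeters
(circular-arc integration, no polygon approximation); morphological gap
delineation (2 m gap / 12 m spur thresholds) with edge-gap bookkeeping
over a 5 m interior buffer; patch typology by correlation-matrix PCA and
Ward clustering with an automatic group count; ANOVA + Bonferroni letters
and Kruskal–Wallis + Nemenyi comparisons.

**Fire history.** Composite fire-return intervals from per-sample scar
years and recording spans, at the all-fires and "≥3 samples and >25% of
recording samples" filters.

**Synthetic stands.** A first-class generator (CSR, Thomas cluster and
trended-intensity processes; species mixtures; truncated-Weibull diameters;
random or clustered snag placement; fire regimes with known fire years)
provides ground truth for every stage, since real stem maps of this kind
are rarely shared.

## Worked example

```r
library(stemmosaic)

w  <- plot_window(200, 200)                      # a 4 ha plot, 5 m buffer
sm <- simulate_stem_map(
  w, point_process_spec("csr", lambda = 0.0325), # ~1300 stems on 4 ha
  mark_model_spec(species_probs = c(JP = 0.844, WF = 0.125,
                                    SP = 0.023, LP = 0.008),
                  snag_fraction = 0.02),
  site_label = "synthetic 4 ha stand", seed = 42)
sm
#> Stem map 'synthetic 4 ha stand': 1349 stems (1322 live, 27 snag) on 4 ha

sm   <- assign_crowns(sm, geo = site_geography(2410, 31.62, -115.98))
part <- delineate_patches(sm)
part
#> <mosaic_partition> 126 patches, 102 interior single trees, 1189 interior live trees

summarize_mosaic(part)$stand
#>   patches_per_ha pct_area_in_patches mean_trees_per_patch trees_per_patch_se
#> 1           31.5                51.6                 9.59               1.27

summarize_gaps(filter_edge_gaps(delineate_gaps(sm)))
#>   edge_gaps     n pct_area mean_size size_se
#> 1 with         35    4.02       45.9    9.80
#> 2 without      2    0.651    130.       8.03

env <- envelope(sm[sm$status == "live" & sm$dbh < 25, ],
                null_model = "csr", n_sim = 99, seed = 9)
gof(env)
#> Goodness-of-fit (Loosemore-Ford): u = 0.068037, p = 0.75 (99 simulations, 0-50 m)
```

Read this as: the simulated stand packs 88% of its interior live trees into
126 crown-overlap patches covering 51.6% of the plot (a CSR stand at this
density is well connected); gaps surviving the 2 m/12 m morphological
thresholds are few and small; and the small-tree pattern shows no
significant departure from CSR (p = 0.75), as it should on a CSR stand —
`autoplot(env)` draws the envelope. On a real (or Thomas-clustered) map the
same calls return the aggregation scales, patch-type groups and FRI tables;
`run_site_analysis()` chains every stage — homogeneity screen, mode
selection, size-class and live/snag analyses, mosaic, typology, fire
history — and writes tidy CSV/JSON reports.

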
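# greenmig

Insectivorous bats navigate and hunt by echolocation, so the structural
complexity of vegetation — how cluttered the understorey is, how closed and
fragmented the canopy — shapes where they can fly and forage. In urban
green spaces this matters directly for conservation management, but
measuring complexity in the field (cover-board profiles, tree inventories)
is slow. `greenmig` implements the alternative: a complexity metric
computed from ordinary digital photographs, **mean information gain
(MIG)**, together with the full analysis pipeline that relates image- and
field-based complexity to bat activity and species richness from acoustic
surveys.

For a quantized image with `M` intensity bins, MIG compares the Shannon
entropy of 2×2 pixel neighborhoods (`k = 4` pixels, spatial heterogeneity)
with the entropy of single pixel values (aspatial heterogeneity):

    MIG = ( −Σ_j p(χ_j) log p(χ_j) + Σ_i p(γ_i) log p(γ_i) ) / log(M^k / M)

where `χ_j` ranges over the observed 2×2 configurations and `γ_i` over
pixel values of the HSV value channel (`V = max(R,G,B)/255`). MIG is 0 for
uniform or perfectly periodic scenes and approaches 1 for random ones.
Each sampling site contributes five photographs (four cardinal side views
and one upward canopy view), summarized as `mig_sides`, `mig_top` and
`mig_all`.

Around the metric, the package provides:

* **field_vegetation** — cover-board clutter per height class, Shannon
  vertical heterogeneity, cover/height means, tree-density and DBH metrics;
* **acoustic_response** — nightly activity (median of nightly summed
  call-sequence lengths), species richness with acoustic-group merging,
  and edge-space/open-space forager summaries;
* **stats_pipeline** — Pearson redundancy screening, iterative VIF
  filtering (with optional protection of focal predictors), Gaussian mixed
  models with a green-space-type random intercept, Poisson/quasi-Poisson
  richness models, bidirectional stepwise-AIC selection, pseudo-R²;
* **synthetic_data** — a generator that emulates the whole study design
  (180 sites in 9 green-space types × 4 size quartiles, 3 survey nights,
  14 taxa with a realistic occupancy ranking, scene images whose MIG is
  monotone in a latent complexity) with known effect sizes, so the entire
  pipeline is testable without any field data.

## Worked example

The `analysis/` scripts run the study end to end on synthetic data:

```sh
Rscript analysis/01_simulate.R 1     # design, images -> MIG, vegetation, surveys
Rscript analysis/02_complexity.R     # MIG vs field-descriptor correlations
Rscript analysis/03_models.R         # screening, VIF, stepwise AIC, model tables
Rscript analysis/04_recovery.R 1     # reduced-replicate recovery checks
```

Stage 1 reports the simulated survey:

    180 sites, 540 surveyed site-nights, 5423 call-sequence records.
    MIG top ranges 0.064-0.774; 0 sites silent (zero activity).

Stage 2 shows that the image metric tracks the field survey — canopy-view
complexity aligns with canopy descriptors, side-view complexity with
understorey clutter:

    clutter_0.5_1             0.70      0.73    0.22
    clutter_10_15             0.39      0.23    0.79
    canopy_cover              0.47      0.29    0.89
    ground_cover             -0.16     -0.08   -0.36
                           (mig_all  mig_sides  mig_top)

Stage 3 fits the selected models per response:

    activity_total     (gaussian-mixed, pseudo-R2 0.21): ground_cover +0.174, mig_top -0.193
    activity_edge      (gaussian-mixed, pseudo-R2 0.10): ground_cover +0.171, mean_dbh -0.058
    activity_open      (gaussian-mixed, pseudo-R2 0.31): ground_cover +0.185, mig_top -0.325
    activity_noctula   (gaussian-mixed, pseudo-R2 0.22): ground_cover +0.155, mig_top -0.291
    activity_pygmaeus  (gaussian-mixed, pseudo-R2 0.05): ground_cover +0.162
    richness_total     (poisson, pseudo-R2 0.28): ground_cover +0.086, mig_top -0.094

Read: total bat activity falls with canopy complexity (`mig_top`, a
standardized coefficient on the log-activity scale) and rises with ground
cover; the open-space foragers and *N. noctula* respond to canopy
complexity considerably more strongly than the community average, while
the edge-space guild and *P. pygmaeus* are driven by ground cover rather
than canopy structure. This is exactly the effect structure
the generator encodes, recovered through photographs, survey records and
model selection.

The same pipeline runs on real inputs via `run_pipeline()`: an image
manifest CSV (`site_id, view, path`), cover-board and tree CSVs, and a
call-record CSV (see `make_fixture_bundle()` for the exact formats).

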
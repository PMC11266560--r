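# smlmdomains

Quantitative analysis of single-molecule localization microscopy
(PALM/dSTORM) data from plasma-membrane leaflet imaging: nanodomain
segmentation, dual-colour colocalization, and single-molecule diffusion /
transient confinement. The package targets researchers who have
per-channel localization tables (ThunderSTORM-style CSV) and
single-molecule trajectory tables, and who want the downstream statistics
— not the raw-image processing — in reproducible, tested R.

## What it computes

**Voronoï cluster segmentation.** Localizations are tessellated inside the
ROI; the local density of each point is 1/area of its (ROI-clipped)
Voronoï cell. A Monte Carlo threshold against complete spatial randomness
(CSR) is found by intersecting the observed cell-area histogram with the
histograms of simulated CSR patterns of equal count; clusters are
connected components of above-threshold cells, components with ≤ 5
localizations are eliminated, and each domain is summarized as a circle of
equivalent diameter 2·√(area/π). The median equivalent diameter is the
domain-size statistic.

**Degree of colocalization (DoC).** For each localization *Aᵢ*, radial
density gradients of both channels are computed over bins r = dR…R_max
(defaults 50…500 nm),

    D(r) = [N(r) / N(R_max)] · [R_max² / r²],

compared by Spearman rank correlation S, and weighted by the distance E to
the nearest localization of the other channel:

    C = S · exp(−E / R_max)  ∈ [−1, 1],

from −1 (segregated) through 0 (random) to +1 (totally colocalized).
Focal points are excluded when both channels have fewer than 100
localizations within R_max. The colocalization index is the fraction of
scored localizations with C in [0.7, 1]; its null is obtained by
recomputing against randomly shifted pseudo-localizations.

**Diffusion.** Overlapping-window MSD per trajectory and
ensemble-averaged MSD–Δt curves; effective diffusion coefficients from
window fits (slope/4), e.g. at the 8/12/16 ms timepoints or over 8–40 ms
for 4 ms/frame data; Brownian/suppressed/directed classification against a
simulated Brownian percentile envelope.

**TALL.** Temporary arrest of lateral diffusion: maximal runs of positions
inside a 50-nm detection circle lasting at least 32 ms (4 ms/frame) or
8 ms (1 ms/frame), pooled into mobile/TALL/immobile time fractions and a
mean lifetime τ_TALL.

**Synthetic data.** Generators for CSR patterns, clustered scenes with
multi-blink overcounting and ground-truth labels, coupled two-channel
scenes with tunable colocalization, and Brownian / confined / 58-nm-hop /
immobile trajectories — the ground truth behind every test.

## Worked example

```r
library(smlmdomains)

cfg  <- scene_config(n_clusters = 20, cluster_radius_sd = 45, locs_per_cluster = 50,
                     background_locs = 1000, localization_precision_sd = 22, seed = 1)
pair <- gen_paired_channels(cfg, cfg, coloc_fraction = 1, seed = 1)
A <- pair$channel_a$localizations
B <- pair$channel_b$localizations

# --- nanodomain segmentation of channel A
thr <- csr_threshold(A, n_simulations = 25, seed = 2)
cl  <- segment_clusters(voronoi_densities(A), thr)
cluster_summary(cl)
#>   n_clusters diameter_median diameter_q25 diameter_q75 area_median area_total
#> 1         19            246.         235.         253.      47664.    934578.
```

19 of the 20 simulated domains are recovered; the median equivalent
diameter (246 nm) reflects the generated domains (Gaussian σ = 45 nm plus
22 nm localization error; twice the 95th-percentile member radius is
~242 nm for this seed).

```r
# --- colocalization of the coupled channels, against a shifted control
p <- doc_params(min_total_localizations = 30)
coloc_index(doc_scores(A, B, p))
#>   channel n_scored n_high     index sum_c_high
#> 1       A     1183   1052 0.8892646   991.9092
#> 2       B     1197   1050 0.8771930   987.6937
#> 3  pooled     2380   2102 0.8831933  1979.6030
ctl <- coloc_index(doc_control(A, B, p, seed = 3))
ctl[ctl$channel == "pooled", ]
#>   channel n_scored n_high     index sum_c_high
#> 3  pooled     2021    733 0.3626917   644.9661
```

88% of scored localizations of the fully coupled channels sit in the high
DoC range, versus 36% after the random-shift control — the separation that
identifies genuine co-clustering.

```r
# --- diffusion and confinement of simulated Brownian molecules
set <- gen_trajectories(trajectory_model("brownian", D = 1, frame_interval = 0.004,
                                         n_frames = 50, seed = 4), 500)
fit_deff(ensemble_msd(set), "24ms@4ms")
#> <diffusion_estimate> D_eff = 0.9566 um^2/s (window 24ms@4ms)
tall_analysis(set)$summary[, 1:5]
#>   n_trajectories n_frames fraction_mobile fraction_tall fraction_immobile
#> 1            500    25000               1             0                 0
```

The ensemble fit recovers the generator's D = 1 µm²/s within 5%, and fast
Brownian motion produces no spurious TALL events.

A configuration-driven end-to-end run (simulate → cluster → DoC → track →
TALL, with a provenance manifest) is available through `run_pipeline()`
with `inst/extdata/default_pipeline.yaml` as a template, or from a shell
via `Rscript inst/cli/leaflet-smlm.R run --config cfg.yaml`.

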
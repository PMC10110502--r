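# pgcprot

Quantification of protrusion plasticity and migration of primordial germ
cells (PGCs) from in-vivo time-lapse microscopy.

Zebrafish PGCs are amoeboid cells that migrate through embryonic tissues by
switching between two protrusion modes: pressure-driven **blebs** (initially
actin-free membrane expansions) and **actin-rich fronts** (pseudopod-like
protrusions with continuous actin polymerization at the edge). Which mode
dominates depends on the mechanical and adhesive properties of the
surrounding germ layer, on cortical regulators such as ezrin and RhoA, and
on physical obstacles the cells encounter. Studying this plasticity requires
a battery of image-quantification procedures; `pgcprot` implements that
battery as a tested, reusable R package:

* **Cortical angular profiling** — segment the cell (threshold, largest
  component, fill holes), build a cortex ring mask as the difference between
  the mask and its 4-fold erosion, slice the masked signal into 120 angular
  bins of 3°, and fit a circular Gaussian
  `f(θ) = c + A·exp(−Δ(θ, μ)² / 2σ²)` whose width `σ` summarizes how focused
  the cortical distribution is. Profiles can be peak-normalized and centered
  on 180° for plotting, and compared between groups with a two-sample
  Kolmogorov–Smirnov test.
* **Bleb metrics** — blebbing frequency (events/min over the analyzed time),
  relative bleb size (bleb area at maximum expansion / cell area at the same
  time point), eligibility filtering (only cells moving forward for > 3 min),
  normalization to a reference group's mean, and an automated bleb detector
  for synthetic benchmarks.
* **Migration kinetics** — track speed (path length / duration), track
  straightness (net displacement / path length), drift correction relative
  to the k nearest somatic-cell tracks, per-repeat normalization to control
  cells, and retrograde-flow estimation from kymographs by sub-pixel
  cross-correlation.
* **Ratiometric (FRET-style) readouts** — per-pixel acceptor/donor maps with
  a donor floor, whole-cell means, per-day normalization, and front/back
  ratios from quartering the mask along its principal axis.
* **Stain quantification** — average (10-slice) or sum projections, region
  means, two-region background subtraction.
* **Nuclei density** — mean distance to the 5 nearest neighbours per nucleus.
* **Gel-encounter scoring** — classify a cell's response in the 6-minute
  window (−1/+5 min around contact) as `turn`, `loss_of_polarity` or
  `no_change`; response times; Fisher's exact tests with Bonferroni
  correction on the category counts.
* **Statistics** — the D'Agostino–Pearson-gated decision tree (both groups
  normal → F-test → pooled or Welch t-test; otherwise Mann–Whitney), all
  two-sided, with median/IQR summaries.
* **Synthetic microscopy generator** — star-convex cells with a configurable
  cortical profile, Poisson bleb events, biased-random-walk tracks in a
  drifting tissue, two-channel ratio fields, moving stripes, 3D nuclei
  fields and scripted gel encounters, all with machine-readable ground truth
  and bit-reproducible output, so every stage is testable without any
  external data.

## Worked example

```r
library(pgcprot)

## a polarized synthetic cell: cortical Gaussian sigma = 40 deg, noise 0.1*A
sc  <- generate_cell_movie(list(frames = 6, noise_sd = 15, bleb_rate_per_min = 0,
                                profile = list(A = 150, mu_deg = 90,
                                               sigma_deg = 40, c = 30)), seed = 7)
res <- profile_movie(sc$stacks[[1]])   # segment -> cortex ring -> 120 bins -> fit
res$fit
#> <GaussianFit> A = 149.7, mu = 90.11 deg, sigma = 40.20 deg, c = 90.48

## bleb metrics from an 11-minute annotated movie at 1.2 events/min
long <- generate_cell_movie(list(frames = 132, frame_interval_s = 5,
                                 bleb_rate_per_min = 1.2), seed = 7,
                            truth_only = TRUE)
bleb_metrics(long$truth$bleb_events, analyzed_time_min = 11)
#> <ProtrusionMetrics> 1.91 events/min over 11 min; mean relative size 0.0717

## retrograde flow from a kymograph: 1.5 px/frame at 0.2 um/px, 2 s interval
st <- generate_stripe_movie(speed = 1.5, frames = 12, size = c(8, 128),
                            pixel_size_um = 0.2, frame_interval_s = 2)
flow_speed(build_kymograph(st$stacks[[1]], c(0, 4, 127, 4)))
#> <FlowEstimate> V = 8.93 um/min
```

The fitted σ recovers the generator value to 0.5%; the blebbing frequency is
the exact event count divided by the analyzed minutes; the flow estimate is
within 1% of the true 9 µm/min (1.5 px/frame × 0.2 µm/px × 60/2 s).

The end-to-end demo builds two synthetic tissues — "ectoderm-like" (bleb
rate 1.6/min, broad cortical profile σ = 80°) and "mesoderm-like" (0.8/min,
σ = 40°) with equal migration speeds — measures 30 cells per group through
the full pipeline, and runs the group statistics:

```r
r <- demo_replica(seed = 42, n_cells = 30)
r$summary
#>               metric ectoderm_mean mesoderm_mean ratio    test_used  p_value
#>            sigma_deg       81.5436       39.8529 2.046 mann_whitney 1.69e-17
#>       bleb_frequency        1.6758        0.7000 2.394      t_welch 5.70e-16
#>   relative_bleb_size        0.0697        0.0683 1.020      t_welch 1.27e-01
#>  actin_rich_fraction        0.4886        0.7457 0.655            t 6.37e-17
#>         speed_um_min        5.9903        6.0752 0.986            t 3.15e-01
#>         straightness        0.5651        0.5892 0.959            t 6.71e-01
```

The configured group differences (profile width, bleb rate, actin-rich time)
come out strongly significant; the deliberately equal speeds and
straightness do not — the null behaves.

A small command-line front end ships in `inst/cli/pgcprot`
(`simulate | demo | density | flow` subcommands).

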
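# cafcontact

Quantitative microscopy of fibroblast–T cell interactions: an R
pipeline for measuring how long regulatory T cells (Tregs) stay in
contact with cancer-associated fibroblasts (CAFs) in time-lapse
co-culture movies, how confined their trajectories become under
antigen-dependent movement arrest, how marker-positive cells distribute
between CAF-rich and CAF-poor tissue regions, and how many autophagy
puncta (LC3, p62, Lamp-1) each cell carries.

It is written for imaging labs that have such movies or fixed fields
and want a scripted, deterministic, testable alternative to chained
ImageJ plugins — and for anyone who needs a seeded synthetic-imagery
benchmark with full ground truth to validate a tracking/contact
pipeline end to end.

## The method in brief

* **Detection.** Cells appear as bright blobs; each frame is filtered
  with a scale-normalized Laplacian of Gaussian at σ = d/(2√2) for an
  expected diameter d (default 8 µm). Strict local maxima above a
  quality threshold (default 1) become spots; maxima closer than d/2
  are suppressed.
* **Tracking.** Frame-to-frame linking is a capped linear assignment:
  minimize Σ(squared link distances) + (36 µm)² per unmatched spot,
  links over 36 µm forbidden. Track fragments are joined by gap closing
  (≤ 12 µm, ≤ 5 skipped frames, greedy by distance).
* **Stromal segmentation.** The CAF-occupied area is the region where
  the windowed coefficient of variation C = std/mean (Gaussian window,
  σ = 4 px) exceeds ε = 0.08, holes filled, small objects dropped.
* **Contact episodes.** A cell is in contact when its center lies
  within 4 µm (its radius) of the stromal mask, by exact Euclidean
  distance transform. Maximal runs of ≥ 2 consecutive in-contact frames
  are episodes; duration = n_frames × Δt, so 2 frames at 5-min sampling
  = 10 min. Conditions are compared with rank-sum (exact enumeration
  for small samples) or Welch's t-test.
* **Spatial density.** Fields are classed CAF-rich/poor by the median
  marker area fraction within each experiment (strictly above = rich);
  cell counts per region are divided by region pixel area (per 10⁶ px).
* **Puncta.** Cells are segmented by nuclei propagated through the
  cytoplasm mask; puncta are counted per cell with the same blob
  detector at 0.8 µm diameter and a gain-invariant relative threshold.
* **Simulators.** `simulate_movie()`, `simulate_if_field()` and
  `simulate_puncta_image()` generate movies, IF fields and puncta
  images with complete ground truth (true tracks, masks, contact
  states, episodes, counts) under a two-state arrest motility model
  (antigen: p_on 0.6 / p_off 0.05; control: 0.1 / 0.5).

## Worked example

```r
library(cafcontact)

sim <- simulate_movie(n_cells = 40, n_frames = 90,
                      model = motility_model("antigen"), seed = 11)
cfg <- default_config()
cfg$detection$subpixel <- TRUE
res <- run_pipeline(sim$movie, cfg, condition = "antigen")
res$summary
#> # A tibble: 1 × 7
#>   condition n_tracks n_episodes mean_duration_min median_duration_min
#>   <chr>        <int>      <int>             <dbl>               <dbl>
#> 1 antigen         54         38              243.                252.
#> # ℹ 2 more variables: mean_arrest_coefficient <dbl> (0.384),
#> #   mean_net_displacement_um <dbl> (38.5)
```

38 contact episodes were recovered from 40 simulated cells over 7.5
simulated hours; the mean episode lasted ≈ 4 h (antigen-driven arrest
keeps cells on the fibroblast layer), and each track's arrest
coefficient and net displacement are in `res$stats`. Compare
conditions:

```r
ctrl <- simulate_movie(n_cells = 40, n_frames = 90,
                       model = motility_model("control"), seed = 12)
res_c <- run_pipeline(ctrl$movie, cfg, condition = "control")
compare_conditions(res$episodes$duration_min, res_c$episodes$duration_min)
#> <condition_comparison> Wilcoxon rank-sum (normal approximation)
#>   n = 38 vs 57, medians 252.5 vs 40
#>   statistic = 1548, two-sided p = 0.000394
```

A 10-minute contact (2 frames at 5-minute sampling) is the shortest
counted interaction; the antigen condition's median contact of ≈ 250
min against the control's 40 min is the movement-arrest signature the
pipeline exists to quantify. `tidy()` and `glance()` return these
results as tibbles.

`run_pipeline(..., outdir = "out/")` writes `tracks.csv`,
`episodes.csv`, `stats.csv`, `summary.csv`, mask PNGs and the resolved
`config.yaml`. `plot_trajectories()`, `plot_episode_durations()` and
`autoplot()` methods draw the standard figures.

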
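# cenfrac

Quantification of centrosome fracturing, cell polarity and migration from
calibrated time-lapse microscopy.

## The problem

The centrosome of a migrating cell is a pair of centrioles (visualized as two
CETN2 fluorescence puncta) normally held 0.5–1 µm apart. When cells navigate
complex environments — path junctions, collagen matrices, bead obstacles —
mechanical load can *fracture* the pair: the inter-centriole distance *d*
suddenly grows at rates of µm/min, sometimes re-cohering ("repair"), sometimes
splitting permanently. cenfrac is for cell biologists who need reproducible,
scriptable versions of the measurements this phenotype is defined by:

- **Per-frame categories** of *d* (half-open, inclusive lower bounds):
  dendritic-cell scheme close `[0,1.5)` / near `[1.5,3.5)` / short-distance
  separated `[3.5,5)` / long-distance separated `[5,∞)` µm; fibroblast scheme
  close `[0,1.5)` / near `[1.5,3)` / far `[3,∞)` µm.
- **Fracture calls**: a frame is fractured iff `d ≥ 1.5 µm`; a cell iff that
  holds for ≥ 2 (not necessarily consecutive) time points. Breakage frequency
  is the fractured fraction of a cohort.
- **Separation velocity**: max over sliding 3-observation windows of
  `Δd/Δt` after onset (µm/min); **maximal separation**; **repair outcome**
  (repaired / non-repaired / censored); **junction decision time**.
- **Intensity readouts**: 5-µm line profiles normalized to the pooled first
  and last four samples; two-ROI (r = 0.35 µm) centrosome intensity ratio
  `min(m₁,m₂)/max(m₁,m₂)`; FRAP normalization
  `(bleached − bg)/(reference − bg)` rescaled to unit pre-bleach mean, with a
  single-exponential fit for τ½ and mobile fraction.
- **Back-to-front polarity profiles**: reporter/reference ratio in 50 (or 2)
  length-normalized segments, excluding a 1.5-µm disk around each centriole,
  averaged per time point then per cell, stratified by fracture status.
- **Bulk velocimetry**: background correction by temporal-mean subtraction,
  size filtering, overlap-optimizing (NCC) frame registration, chemotactic
  velocity from the y-displacement toward the source.
- **Vessel proximity**: exact Euclidean distance maps, per-cell nearest-vessel
  distance and inside/outside counts.

Detection is Laplacian-of-Gaussian + band-passed centroid refinement; linking
is greedy two-identity nearest-neighbour with 3-frame gap bridging. A
synthetic-movie generator with exact ground truth (`make_centriole_movie()`,
`make_polarity_movie()`, `make_frap_series()`, `make_drift_sequence()`,
`make_vessel_image()`) makes every stage testable end to end.

## Worked example

Generate a synthetic cell whose centrosome fractures at frame 20 at
2 µm/min and repairs from frame 26, then recover the phenotype from pixels:

```r
library(cenfrac)

syn <- make_centriole_movie(
  n_frames = 40, width = 128, height = 128, frame_interval = 30,
  cohesive_distance = 0.8,
  fracture = list(onset = 20, rate = 2, repair = 26),
  snr = 5, seed = 11)
syn$movie
#> calibrated_movie: 40 frame(s), 128 x 128 px, 1 channel(s) [centriole]
#>   pixel size 0.1426 um/px, frame interval 30 s, source along +y

track <- track_centriole_pair(syn$movie)
track
#> centriole_pair_track: 40 frame(s), 40 with both centrioles
#>   distance range 0.730 - 6.796 um

series <- distance_series(track, frame_interval = 30)
fracture_report(series, cell_id = "cell-11")
#> fracture_report (cell cell-11, dc scheme): FRACTURED
#>   max separation 6.80 um; onset 600 s; separation velocity 2.02 um/min; repaired
```

The report reads: the pair stayed cohesive (≈ 0.8 µm) until the distance
first reached 1.5 µm at t = 600 s; the fastest sustained separation was
2.02 µm/min (scripted: 2); the pair peaked at 6.80 µm (scripted: 6.8) and
re-cohered below 1.5 µm for ≥ 3 observations, hence `repaired`.

A full multi-stage run (synthesis → tracking → fracture reports → FRAP →
polarity → velocimetry → vessels), writing CSVs plus a run log:

```r
run_pipeline(analysis_config(), stages = "all", out_dir = "out", seed = 1)
```

or from a shell: `Rscript inst/cli/cenfrac.R all --seed 1 --out out`.

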
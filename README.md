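# geotaxr

Automated analysis of *Drosophila* negative-geotaxis ("tap-and-climb")
assays. Flies knocked to the bottom of a vial climb back up; how high and
how fast a cohort climbs is a sensitive, widely used readout of motor
function, aging, circadian disruption and neurodegeneration. Manual
scoring of such assays is slow and subjective. `geotaxr` is for labs
running multi-vial tap rigs — a rack of 12 vials filmed at 60 fps,
1280 x 720, with four tap-pause cycles per recording — and turns raw
recordings into replicate-level statistics with no manual intervention.

## What it computes

For each recording the pipeline:

1. **Splits trials** from a per-frame motion-energy trace (summed areas of
   moving regions ≥ 2,000 px²). Tap spikes are local maxima above 100,000
   movement units; a trial runs from the first frame below 30,000 units
   after a spike until a ≥ 270-frame quiet run ends it, capped at 900
   frames (15 s).
2. **Locates vials** with a deterministic rule-based detector (dark
   vertical wall strips), filters detections at confidence ≥ 0.85, sorts
   them left-to-right, and matches them positionally to the metadata
   table (`Vial_Num,Genotype,Gender,N`). Any learned detector can be
   plugged in behind the same interface and scored by bounding-box IoU.
3. **Tracks flies** per frame over the first 780 frames of each trim:
   background = per-pixel maximum of the red channel, dual-half
   thresholding, connected components, centroids assigned to vials and to
   low/middle/high performer zones (vertical thirds by default). Heights
   convert to cm via `Y_cm = 17 · adj / 720`, frames to seconds via
   `t = frame / fps`, subsampled at 2 Hz.
4. **Aggregates** across trims (mean ± SEM) and across the experiment
   into ten wide tables — {male, female} × {position, velocity, LP, MP,
   HP} — with replicate labels `Genotype_repN`; velocity is the numerical
   gradient of position per replicate.
5. **Tests** genotype effects with a linear mixed-effects model per
   modality,

   `Y_ijt = β₀ + β_geno + β_time + β_geno×time + b_j + b_j⁽¹⁾ t + ε_ijt`

   (REML; categorical time in the fixed effects, numeric random slope per
   subject), Wald z p-values combined per comparison genotype with the
   harmonic-mean p-value `min(1, r / Σ 1/(pᵢ + ε))`, plus two-sided
   Mann-Whitney U tests per time point (−log10(p) heatmaps) and on
   per-replicate peak metrics.

A synthetic scene generator (`render_recording()`,
`write_experiment_folder()`) renders the whole rig — vials, climbing fly
blobs, tap bursts — with ground-truth boxes and trajectories, so every
stage is testable without laboratory video.

## Worked example

Split a recording's movement trace into trials (here a synthetic trace of
the full four-cycle protocol):

```r
library(geotaxr)
trace <- synth_movement_trace(4 * 905 + 100, tap_frames = 1 + (0:3) * 905,
                              tap_height = 150000, baseline = 5000)
find_trials(trace)
#>   index start_frame end_frame peak_frame peak_value
#> 1     1           4       904          1     150000
#> 2     2         909      1809        906     150000
#> 3     3        1814      2714       1811     150000
#> 4     4        2719      3619       2716     150000
```

Four trials, each exactly 900 frames (15 s at 60 fps), starting at the
first quiet frame after each tap spike.

Compare a control against a mutant that climbs normally but cannot hold
its height (10 replicates per genotype, simulated at the series level):

```r
tabs <- synth_dissociation_tables(seed = 1)
comparison_report(tabs, control = "ctrl", comparisons = "collapse",
                  tmax = 12.5)
#> Comparison report: control 'ctrl' vs collapse
#>                Metrics ctrl vs collapse
#>           position_LME       0.006 (**)
#>          position_Peak       0.190 (NS)
#>           velocity_LME       0.061 (NS)
#>          velocity_Peak       0.105 (NS)
#>      low performer_LME        0.029 (*)
#>     low performer_Peak       0.595 (NS)
#>   middle performer_LME       0.139 (NS)
#>  middle performer_Peak       0.280 (NS)
#>     high performer_LME        0.101 (NS)
#>    high performer_Peak       0.190 (NS)
```

The report reads like the assay's standard results table: each cell is
the combined p-value with its star annotation. Here the climbing-height
trajectory differs clearly (`position_LME`, harmonic-mean p = 0.006)
while instantaneous climbing velocity does not (`velocity_LME` and
`velocity_Peak` non-significant) — the signature of a mutant that starts
climbing normally but fails to sustain the height it gains.

To run the full pipeline over an experiment tree (one subfolder per
recording, each with a `frames/` directory or video plus
`geotaxis_metadata.csv`):

```r
run_pipeline("path/to/experiment",
             pipeline_config(control = "w1118", comparisons = "ClockOut"))
```

which writes per-recording summaries, the ten modality CSVs under
`Output Males` / `Output Females`, the comparison table, p-value JSON and
figure panels, and a `run_manifest.json` recording configuration, seed
and per-folder status. Already-completed folders are skipped on rerun. A
command-line front end with `run`, `synth` and `eval-detector`
subcommands ships in `inst/cli/geotax.R`.

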
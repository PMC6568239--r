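# stmapr

Quantitative analysis of gastrointestinal motility from time-lapse
recordings of tubular organs, built around spatio-temporal (ST) maps —
kymographs of gut diameter with position along the intestine on one axis
and time on the other. Contractions appear on such maps as transient local
decreases in diameter; `stmapr` turns segmented video into calibrated
diameter matrices, detects and classifies individual contraction events,
and runs the before/after statistics used to quantify hormonal effects
(for example cholecystokinin, CCK) on motility. It was designed for ex
vivo preparations of the ballan wrasse intestine but applies to any
tube-shaped organ imaged as binary masks.

## The method

1. **Diameter matrix.** Each video frame's binary mask is sampled in
   transverse bins (ROIs) of width 0.5 mm stacked along the gut's long
   axis; the diameter in a bin is the distance between the outermost
   foreground pixels perpendicular to the long axis. Frames are first
   thinned (every third frame of a 3.5 fps recording, giving ~1.2
   analyzed frames per second). The result is the matrix *D[x, t]* in mm.

2. **Detection.** In every frame profile *D[·, t]*, contractions are
   local diameter minima whose depth — relative to the lower of the two
   valley-bounding maxima — reaches a threshold (default 0.1 mm, one
   pixel-equivalent). Each minimum extends to contiguous neighbours of
   similar diameter; every cell of a run carries the run's amplitude
   (lower flanking maximum minus minimum). Cells across frames are
   grouped into events by 8-connectivity, so a contraction advancing one
   bin per frame stays one event.

3. **Classification.** Per event: initiation site (earliest cell,
   oral-most on ties), propagating distance (spatial extent), duration,
   and an ordinary least-squares regression of position on time over all
   cells giving slope and *r²*. Events with distance ≤ 1.0 mm are
   **standing contractions**; among longer events, *r² ≥ 0.8* defines
   **ripples** and *r² < 0.8* **slow propagating contractions**. Velocity
   is |slope|; slope > 0 is anterograde (oral → anal), slope < 0
   retrograde. Relative amplitude is the percent decrease from the
   maximum diameter of the position where the contraction occurred.

4. **Summaries and statistics.** Event frequencies are reported as
   contractions per minute per mm of segment length (cpm), by initiation
   site within four segments of default length fractions
   0.39/0.23/0.23/0.15. Treatment contrasts use log₂(after/before) ratios
   over 10-minute windows tested against 0 with one-sample t-tests at the
   90% confidence level (`*` for 0.05 ≤ p < 0.1, `**` for p < 0.05);
   parameters are compared across types with Kruskal–Wallis + Dunn and
   across segments with ANOVA + Tukey; amplitude/distance/duration/
   velocity values are binned into low/medium/high by sample quartiles.

A seeded synthetic-kymograph generator injects standing, ripple and slow
events with known parameters so the whole chain is testable end to end
without any imaging data.

## Worked example

```r
library(stmapr)
library(dplyr)

spec <- simulation_spec(length_mm = 60, n_frames = 720, seed = 1L)
gt <- sample_ground_truth(spec, 5, seed = 1)
gt$onset_time_s <- seq(30, 510, length.out = 5)
sim <- simulate_diameter_matrix(spec, gt)
sim$dm
#> <diameter_matrix> 120 positions x 720 frames (dx = 0.5 mm, dt = 0.833333 s, length = 60 mm)
#>   diameters 0.592-4.000 mm, 0 missing cells

cells  <- st_detect(sim$dm, depth_threshold = 0.1)
events <- st_classify(cells, dm = sim$dm, window = c(0, 599))
select(events, event_id, type, distance_mm, velocity_mm_per_s, r2,
       direction, amplitude_pct)
#> # A tibble: 5 x 7
#>   event_id type     distance_mm velocity_mm_per_s      r2 direction   amplitude_pct
#>      <int> <chr>          <dbl>             <dbl>   <dbl> <chr>               <dbl>
#> 1        1 standing         0              0      NA      none                 36.7
#> 2        2 ripple          10              0.0325  0.989  anterograde          60.7
#> 3        3 slow             7              0.0138  0.346  anterograde          40.4
#> 4        4 standing         0              0      NA      none                 48.8
#> 5        5 ripple           7.5            0.0786  0.980  anterograde          28.5
```

The five injected events (two standing, two ripples, one slow) are each
recovered as one event of the correct class: the standing contractions
have zero propagating distance and no defined regression; the ripples are
near-perfectly linear (*r²* ≈ 0.98–0.99); the slow event propagates
irregularly (*r²* = 0.35). `amplitude_pct` is the percent narrowing
relative to each site's maximum diameter. Windowed summaries then give
cpm per segment and type:

```r
s <- summarize_motility(events, segment_scheme(), window = c(0, 599))
tidy(s)
#> # A tibble: 12 x 5
#>    segment type         n segment_length_mm     cpm
#>  1       1 standing     1              23.4 0.00428
#>  ...
#>  8       3 ripple       2              13.8 0.0145
```

Gray-scale and classified (binary) ST maps render with
`render_gray_map()` / `render_binary_map()` plus `autoplot()` or
`write_st_png()`; `run_pipeline()` chains every stage from a config list
or YAML file and writes all tables, maps and a log. A thin command-line
front end is installed at `inst/exec/stmapr`.

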
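# calquant

Automated, simultaneous single-cell and population-level quantification
of **global intracellular Ca²⁺ responses** from time-lapse fluorescence
microscopy.

Non-excitable cells (lymphocytes being the motivating case) loaded with
a calcium indicator such as Fluo-4 and settling onto a stimulating
surface show a stereotyped intensity history: a dim, mobile phase in
suspension; a small brightness step and an immediate stop of movement
at **landing**; and, in responding cells, a sharp calcium-driven rise
followed by a slow decay at **triggering**. `calquant` turns a raw
multi-page TIFF movie containing hundreds of such cells into per-cell
event annotations and population statistics, for anyone who needs
responder fractions, response kinetics or agonist-potency readouts from
imaging rather than flow cytometry.

## What it computes

For each tracked, included cell with mean-intensity trace `I(t)`:

- relative response `R(t) = I(t) / Imax`, after Savitzky–Golay
  smoothing; baseline `I0` (post-landing, pre-trigger median) and
  `dI = Imax − I0`;
- landing time (cessation of movement) and triggering time (onset of
  the large peak in `dR/dt`);
- responder classification: `dI/I0 > 5` by default (a >500 % increase
  over background, user-settable) **and** a subsequent decrease of
  `R(t)`;
- triggering interval `T = t_triggering − t_landing`.

Per population: responder fraction with binomial s.d.m., mean aligned
`R(t)` ± s.d.m. over responders (t = 0 set 2 s after landing), `T`
distribution, time-resolution and pixel-count robustness scans, and a
blue-to-red maximum-intensity projection.

Segmentation combines feature detection (robust noise-floor threshold +
connected components) with distance-regularized level-set evolution
(DRLSE) mask refinement. A fully ground-truthed synthetic movie
generator (`scene_config()` / `generate_movie()`) makes the whole
pipeline testable by parameter recovery.

## Worked example

Simulate a 256 × 256 px movie (600 frames at 2 Hz, 50 cells, 60 %
responders) and analyze it:

```r
library(calquant)

scene <- scene_config(image_size = c(256L, 256L), n_cells = 50L, seed = 7L)
sim   <- generate_movie(scene)
res   <- run_full(sim$stack, run_config(), out_dir = "demo_out")
#> filter_cells: 54 tracked; included 37; excluded no_landing=8
#>   late_landing=0 edge=2 overlap=7
print(res$summary)
#> population_summary: N = 37, responders = 22, fraction = 0.595 +/- 0.081
#>   triggering interval T = 121.1 +/- 8.3 s (n = 22)

rec <- recovery_report(res, sim$ground_truth, sim$stack)
str(rec$summary[c("true_fraction_realized", "detected_fraction",
                  "landing_within_1_frame", "trigger_within_1_s")])
#> $ true_fraction_realized: num 0.6
#> $ detected_fraction     : num 0.595
#> $ landing_within_1_frame: num 0.973
#> $ trigger_within_1_s    : num 1
```

Reading: of 50 simulated cells, 37 passed the inclusion filters
(overlapping or border cells are excluded); 22 were classified as
responders, a fraction of 0.595 ± 0.081 against a realized truth of
0.600; 97 % of landings were found to within one frame and every
detected triggering onset fell within 1 s of the truth. `demo_out/`
holds `cells.csv`, `traces.csv`, `events.csv`, `summary.json`,
`summary_curves.csv` and the figures.

Real movies enter the same way:

```r
run_full("movie.tif", run_config(response_threshold = 5), "out",
         frame_interval = 0.5,
         scan_intervals = c(0.5, 1, 5, 15, 30, 60))
```

A thin command-line front end with `simulate`, `run`, `events` and
`demo` subcommands is installed at `inst/cli/calquant`.

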
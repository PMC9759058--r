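# AlveoTrack

Quantitative analysis of two-channel intravital microscopy videos of the
ventilated lung. In these recordings the interstitial tissue is labeled with
a fluorescent dextran, so alveolar airspaces appear as dark regions on a
bright background in one channel, while antibody-labeled neutrophils appear
as bright blobs on a dark background in the other. AlveoTrack turns such
frame sequences into per-frame feature statistics, per-respiratory-cycle
summaries, and two-experiment comparison analytics — the kind of readout
used to quantify alveolar dynamics and neutrophil infiltration in models of
acute lung injury.

## What the pipeline computes

Per channel and frame:

1. **Non-local-means denoising** — each pixel is averaged with pixels whose
   surrounding patches look alike, with weight `exp(-d²/h²)` where `d²` is
   the mean squared difference over a template patch searched within a
   larger window. Defaults: `h = 35`, template `7`, search `21` for the
   alveolar channel; `h = 45, 7, 21` for the neutrophil channel.
2. **Mask formation** — Gaussian blur (kernel 11), intensity threshold
   (dark side for alveoli, bright side for neutrophils), morphological
   dilation (kernel 4).
3. **Contour extraction** — external boundaries of 8-connected foreground
   components, with pixel area and centroid, filtered by per-channel area
   restrictions to suppress false positives.
4. **Temporal-consistency filter** — a detection at frame *t* is kept only
   if a matching feature exists at frame *t−1* or *t+1*: centroid within a
   radius and area within a relative tolerance (alveoli, which grow and
   shrink with breathing) or a fixed absolute tolerance (neutrophils).
   One-frame spurious detections cannot satisfy this and are removed.

From the filtered detections: alveolar area as % of the image, alveoli
count, airspace per alveolus, neutrophil count and area, interstitial area.
The alveolar-area signal is segmented into **respiratory cycles** at its
troughs (end-expiration), giving per-cycle min/max, amplitude, and length;
two experiments can be offset-aligned and compared cycle by cycle.

A parametric synthetic scene generator (`generateScene()`) produces
two-channel videos with breathing ellipses, drifting neutrophils,
single-frame transient blobs, sensor noise, and exact analytic ground
truth, so the whole pipeline is testable without animal data.

## Worked example

```r
library(AlveoTrack)

cfg <- SyntheticConfig(nTransients = 20)  # 256x256, 64 frames, period 16
rep <- runRecoveryExperiment(cfg)

rep$analysis$cycles
#>   cycle_index start_frame end_frame min_alveolar_pct max_alveolar_pct
#> 1           0          12        28         9.625244         21.71936
#> 2           1          28        44         9.629822         21.72089
#> 3           2          44        60         9.632874         21.71478

round(rep$analysis$summary, 2)
#>   mean_alveolar_area_pct     mean_cycle_amplitude       mean_alveoli_count
#>                    15.38                    12.09                     6.00
#>    mean_neutrophil_count mean_neutrophil_area_pct        mean_cycle_length
#>                     5.00                     1.19                    16.00

rep$transientRemovalRate    # 1    (all 20 one-frame blobs removed)
rep$persistentRetentionRate # 1    (5 drifting neutrophils kept, all frames)
rep$meanAreaRelError        # 0.0091 (alveolar area vs analytic truth)
```

The three detected cycles each span 16 frames — the configured breathing
period — with troughs at the analytic end-expiration frames (12, 28, 44,
60), and the detected min/max alveolar area track the analytic trough/peak
areas to about 1%.

A command-line front end (`inst/scripts/alveotrack.R`) exposes the same
pipeline as `synth`, `preprocess`, `analyze` and `compare` subcommands with
YAML configuration, provenance manifests, CSV/JSON exports and static PNG
plots.

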
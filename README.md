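# multisyn

Tools for quantifying **multi-directed synaptic transmission** — the idea
that a single vesicle of acetylcholine released from a starburst amacrine
cell varicosity can rapidly activate receptors on *several* postsynaptic
direction-selective ganglion cells (DSGCs) within a micron of the release
site, rather than signalling through a single private synapse.

The package implements the four quantitative analyses with which that claim
can be established, plus seeded synthetic-data generators with full ground
truth so every stage is testable without any recordings:

1. **Quantal EPSC analysis** (`lowpass()`, `detect_events()`,
   `event_metrics()`): template-subtraction detection of spontaneous
   excitatory postsynaptic currents in voltage-clamp traces (5–7 pA
   thresholds, 2.5-ms separation decay), with peak amplitude, 20–80% rise
   time and decay-constant measurement.
2. **Paired-recording synchrony** (`sepsc_triggered_average()`,
   `match_events()`, `property_ztest()`): the event-triggered average of a
   second cell's current, whose peak relative to the mean event,

   `correlation strength = peak(STA) / peak(mean sEPSC)`,

   estimates the fraction of quanta shared between two cells; matched-event
   property correlations are tested against a one-step circular shuffle with
   the Fisher-z statistic

   `z_observed = (z_orig − z_shuff) / sqrt(1/(n_orig−3) + 1/(n_shuff−3))`.
3. **Dendritic overlap** (`resample_segments()`, `nnd()`,
   `structure_function_compare()`): skeletons are divided into 1-µm
   segments; per-segment nearest-neighbor distances to a second cell's
   arbor give cumulative overlap fractions that are compared with the
   physiological correlation strengths at 0–3 µm.
4. **Sensor-imaging analysis** (`preprocess_stack()`, `dff()`,
   `segment_rois()`, `roi_tuning()`, `hodges_ajne()`): ΔF/F movies of a
   fluorescent acetylcholine sensor are segmented into release-site ROIs by
   noise-correlation scores `C = (c₀ − M_c)/SD_c > 2.5`, gated by a
   response-quality index `RI = (R − (M₀+2SD₀))/(R + (M₀+2SD₀)) > 0.6`, and
   characterized by the direction-selectivity index
   `DSI = (R_pref − R_null)/(R_pref + R_null)` with the preferred angle from
   the quadrant-correct vector sum.
5. **Cleft diffusion / receptor kinetics** (`cleft_concentration()`,
   `receptor_response()`, `compare_sites()`): closed-form point-source
   diffusion in a planar cleft vs a porous 3-D neuropil with first-order
   esterase loss, driving a five-state nicotinic receptor scheme at a
   proximal (0 µm) and a distal (~1 µm) site.

## Worked example

Simulate a ten-minute paired recording in which half of the quantal events
are shared, then recover that fraction from the traces alone:

```r
library(multisyn)

out  <- gen_paired_traces(paired_train_spec(duration = 600,
                                            shared_fraction = 0.5,
                                            seed = 5))
tr_a <- lowpass(out$trace_a)          # 300-Hz zero-phase conditioning
tr_b <- lowpass(out$trace_b)
ev_a <- detect_events(tr_a, threshold = 5)
sta  <- sepsc_triggered_average(ev_a, tr_a, tr_b)
sta
#> <sta_result> correlation strength 0.517 (1733 trigger events)
autoplot(sta)                          # STA overlaid on the mean sEPSC
```

The printed correlation strength (0.517 here) is the estimated shared
fraction: with 1733 trigger events its seed-to-seed spread is about ±0.015,
so the injected 0.5 is recovered. For two *independent* trains the same
statistic falls below 0.01, while the chance that independent 3-Hz trains
co-fire in a 1-ms bin is

```r
chance_coincidence(0.003, 0.003)
#> [1] 9e-04        # percent, i.e. 0.0009%
```

Direction tuning from an eight-direction response vector:

```r
direction_tuning(c(3, 0, 0, 0, 1, 0, 0, 0), seq(0, 315, by = 45))
#> # A tibble: 1 × 7
#>     dsi theta_deg r_pref r_null pref_dir null_dir resultant
#>   <dbl>     <dbl>  <dbl>  <dbl>    <dbl>    <dbl>     <dbl>
#> 1   0.5         0      3      1        0      180         2
```

A response three times larger at 0° than at 180° gives DSI = (3−1)/(3+1) =
0.5 with the preferred angle at 0°.

## Vignette

`vignettes/multidirected-transmission.Rmd` documents the models, the
synthetic-data generators and their defaults, the numerical choices, and
the known limitations of each stage.
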
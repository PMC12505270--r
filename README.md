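# adhesiondyn

Quantification of cell–substrate adhesion dynamics from fluorescence
timelapse microscopy, for cell biologists studying adhesion-based
migration in fast-turnover systems such as *Dictyostelium discoideum*.

Adhesions appear as diffraction-limited punctae when a tagged adhesion
protein is imaged by confocal timelapse. `adhesiondyn` takes such movies
(or its own simulated ones) through the complete measurement chain:

* **Detection & tracking** — white top-hat enhancement, per-frame Otsu
  thresholding, binary cleanup, greedy nearest-neighbour linking, and the
  standard track filters (no first/last-frame tracks, no tracks ≤ 8
  frames).
* **Kinetics** — per-track intensity traces are baseline-subtracted,
  smoothed with a 3-frame running average, and fitted with a logistic
  assembly curve and an exponential disassembly curve:

  ```
  assembly     y(t) = A_a / (1 + exp(-s_a (t - t_half_a))) + C
  disassembly  y(t) = A_d exp(-s_d max(0, t - t_on)) + C
  lifetime     t_half_d - t_half_a,   t_half_d = t_on + ln(2)/s_d
  ```

  The steepness parameters `s_a`, `s_d` (1/s) are the assembly and
  disassembly rates; the lifetime is the time the fitted intensity spends
  above half of its maximum.
* **FRAP** — relative fluorescence intensity
  `RFI = (I_t − I_bgt)/(I_pre − I_bgpre)`, exponential-plateau recovery
  fits `Y(t) = Ym − (Ym − Y0) e^(−kt)`, half-times `t½ = ln(2)/k`,
  immobile fractions `IMf = 1 − (FRFIf − FRFI0)/(1 − FRFI0)`, a 45-s
  half-time cutoff, ROUT outlier removal (Q = 1%), and cumulative
  mean ± s.e.m. recovery curves.
* **Statistics** — Wilcoxon rank-sum comparisons with distribution-free
  median 95% CIs, a four-test normality suite, simple linear regression
  for speed–duration correlations, and SuperPlot-style replicate tables.
* **Simulation** — seeded synthetic two-channel movies, single intensity
  traces and FRAP series with ground-truth tables, so every stage above
  is validated against known truth without any external data.

## Worked example

Simulate two biological replicates in which half of the punctae carry a
second-channel marker and are programmed with longer lifetimes (≈ 20 s vs
≈ 15 s) and slower disassembly, then run the full pipeline:

```r
library(adhesiondyn)

cfg <- pipeline_config(
  sim = sim_config(n_punctae = 20L, coloc_fraction = 0.5,
                   lifetime_range = c(14.5, 15.5),
                   lifetime_range_coloc = c(19.5, 20.5),
                   decay_rate_range = c(0.16, 0.2),
                   decay_rate_range_coloc = c(0.10, 0.13)),
  n_replicates = 2L, seed = 1L)

res <- run_pipeline(cfg, out_dir = "adhesion_run")
subset(res$comparisons, metric == "lifetime_s")
#>     group  n median ci_lower ci_upper outliers_removed outlier_method   p_value
#>  positive 16  21.86    19.23    25.36                1      ROUT Q=1% 0.0007111
#>  negative 22  14.64    13.17    15.39                0      ROUT Q=1% 0.0007111
```

The channel-2-positive population is recovered with a significantly
longer median lifetime (21.9 s vs 14.6 s, two-sided rank-sum
p ≈ 7 × 10⁻⁴), matching the programmed difference. The bundled FRAP
stage fits all 50 simulated recovery traces:

```r
kept <- res$frap$results[!res$frap$results$excluded, ]
median(kept$t_half)            #> 2.344  (programmed half-time: 2.4 s)
median(kept$immobile_fraction) #> 0.631  (programmed immobile fraction: 0.63)
res$cells$mean_speed_um_s      #> 0.0501 0.0501  (programmed: 0.05 um/s)
```

`run_pipeline()` writes `tracks.csv`, `kinetics.csv`, `cells.csv`,
`comparison.csv`, `superplot.csv`, `frap_results.csv`, `frap_curve.csv`
and a `manifest.json` with the resolved configuration and per-stage
counts; identical configurations reproduce every file byte for byte.
See the vignette (`vignettes/adhesion-dynamics.Rmd`) for the model
details, parameter choices and limitations.

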
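# imeqc

Recording-quality and tissue-response analytics for chronic intracortical
microelectrode (IME) studies.

Chronic IME experiments evaluate whether an intervention (here, the
motivating case is systemic delivery of an anti-inflammatory drug carried by
platelet-inspired nanoparticles) preserves extracellular recording quality
over weeks and reduces the foreign-body response around the implant. The
quantitative chain behind such studies spans three very different data
types, and `imeqc` implements all of it as tested R code with seeded,
ground-truthed synthetic generators standing in for the raw animal data:

* **Extracellular electrophysiology** — common-median referencing; 300–3000
  Hz zero-phase band-pass; spike detection at −4σ̂ with
  σ̂ = median(|x|)/0.6745; removal of abnormal-amplitude events (|V| > 500
  µV) and of motion artifacts (coincident events spanning > 14 of 16
  channels); per-channel k-means-scan sorting over PCA features; rule-based
  unit verification.
* **Unit metrics and yield** — Vpp = max − min of the mean waveform, noise =
  spike-excised RMS, SNR = Vpp/noise, spike rate = 1/median(ISI); putative
  filter at Vpp ≥ 40 µV; ROUT outlier removal (Q = 5%) on SNR; channel ×
  phase aggregation; weekly and phase-pooled **active electrode yield**
  AEY = active channels / ever-active channels, compared with two-sided
  pooled two-proportion z-tests
  z = (p̂₁ − p̂₂)/√(p̂(1−p̂)(1/n₁ + 1/n₂)).
* **Implant-site histology** — concentric 50 µm rings from the implant-hole
  edge (exact Euclidean distance transform), artifact masking, ring means
  normalized as N_k = Ī_k/Ī_bg − (1 − f) to the 600–650 µm background ring
  (f = 1 for GFAP/NeuN, f = 0 for CD68/IgG), and neuron density per ring in
  mm⁻².
* **Release chemistry** — encapsulation efficiency
  EE(%) = (total − free)/total × 100, internal-standard calibration, and
  replacement-corrected cumulative dialysis release
  M(t_i) = C_i·V_res + Σ_{j<i} C_j·V_aliquot.

See `vignettes/imeqc-methods.Rmd` for the full model descriptions,
parameter defaults, and design rationale.

## Worked example

Simulate a short 4-channel session with planted units, run the analysis
chain, and score it against ground truth:

```r
library(imeqc)

sc  <- reference_scene(seed = 1, duration = 60, n_channels = 4)
sim <- simulate_recording(sc)
rec <- bandpass_filter(common_median_reference(sim$recording))
ev  <- detect_spikes(rec)
scr <- reject_artifacts(ev)
units <- verify_units(sort_units(scr$kept, sort_config(seed = 2)))
met <- unit_metrics_table(units, rec, scr$kept)
head(met[met$putative & met$verified, c("channel", "n_spikes", "vpp_uv",
                                        "noise_uv", "snr", "rate_hz")], 4)
#>   channel n_spikes    vpp_uv noise_uv       snr   rate_hz
#> 1       1      110  92.09912 7.862977 11.713009  2.975503
#> 2       1      605  42.92133 7.862977  5.458661 15.481294
#> 4       2      605  42.76101 7.942239  5.384000 13.946872
#> 5       2      210 147.20643 7.942239 18.534626  5.833692
```

Each row is a sorted, verified unit: its channel, spike count, peak-to-peak
amplitude (µV), the channel's spike-excised noise RMS (µV), their ratio
(SNR), and the inverse-median-ISI rate (Hz). Channels 1 and 2 carried
planted units of 100 and 167 µV Vpp at 2 and 4 Hz: the ~92 and ~147 µV rows
recover them (a few percent low because the acquisition band-pass is applied
once more in the pipeline). The ~43 µV rows are the clusters that collect
the −4σ̂ threshold's irreducible noise crossings — the sorter isolates them
from the real units, which is exactly what the best-match scoring measures:

```r
ss <- score_sorting(units, sim$truth)
round(c(sensitivity = ss$sensitivity, precision = ss$precision), 4)
#> sensitivity   precision
#>      0.9923      0.9873
```

Yield statistics work from a plain activity table (one row per group,
animal, week, channel with the active-unit count):

```r
ph <- phase_proportion(activity_table, weeks = 1:4)
two_proportion_ztest(ph$n_active[1], ph$n_total[1],
                     ph$n_active[2], ph$n_total[2])
```

A thin CLI over these functions is installed at
`system.file("scripts", "imeqc", package = "imeqc")` with subcommands
`simulate-ephys`, `simulate-histo`, `simulate-release`, `detect`, `yield`,
`histo`, `release`, `ee`, and `run`.

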
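---
title: "Methods: recording-quality and tissue-response analytics for chronic intracortical microelectrodes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: recording-quality and tissue-response analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## What this package computes

Chronic intracortical microelectrode (IME) studies ask whether an
intervention preserves recording quality over weeks of implantation, and
whether the tissue around the implant shows less scarring, inflammation, and
neuron loss. `imeqc` implements the quantitative chain used in such studies
as tested, reusable code:

1. **Ephys preprocessing** — common-median referencing, zero-phase 300–3000
   Hz band-pass, −4σ spike detection, and amplitude/motion artifact
   screening.
2. **Unit sorting** — silhouette-selected k-means over PCA waveform features
   ("k-means scan"), with a rule-based stand-in for manual verification.
3. **Unit metrics** — peak-to-peak voltage (Vpp), spike-excised channel
   noise RMS, SNR = Vpp/noise, median-ISI spike rate, a 40 µV putative-unit
   filter, and ROUT outlier removal on SNR.
4. **Yield statistics** — weekly and phase-pooled active electrode yield
   (AEY) with two-sided proportion z-tests.
5. **Histology quantification** — concentric 50 µm rings from the implant
   hole edge, artifact masking, marker-specific background normalization,
   and neuron density per ring.
6. **Release chemistry** — encapsulation efficiency, internal-standard
   calibration, and replacement-corrected cumulative dialysis release.
7. **Synthetic generators** — seeded, ground-truthed simulators for all
   three data modalities, used by the test-suite and by anyone who needs to
   validate changes against known truth.

Because the raw animal data behind such studies are typically unavailable,
the generators define the package's validation conditions: every claim the
tests make is a claim about recovery of known planted structure.

## The recording simulator and what it does (not) emulate

`simulate_recording()` builds, per channel, Gaussian noise band-limited to
the 300–3000 Hz acquisition band and rescaled so its in-band RMS equals
`noise_sd` (default 10 µV). Spike trains are homogeneous Poisson with a 1 ms
refractory (the simplest model consistent with ISI-based metrics); templates
are area-balanced biphasics (`spike_template()`) whose negative lobe is ~70%
of Vpp, typical of extracellular cortical units. The default acquisition
rate is 24 414 Hz (the hardware's nominal 24 414.0625 Hz is configurable via
`fs`), sessions default to 600 s, arrays to 16 channels.

Motion artifacts use a heterogeneous-coupling model: each hit channel
receives a Ricker (Mexican-hat) transient (`artifact_template()`, σ =
0.25 ms — mechanically slower than a spike, so it passes the acquisition
band without ringing) scaled by a magnitude in ×0.8–1.2 and a sign
(majority negative). A perfectly common-mode artifact would be annihilated
by the median reference; real grooming/movement artifacts are not, because
coupling differs across sites. The differential residue survives
referencing, is detected on all hit channels — the symmetric side lobes
keep opposite-polarity peaks inside the coincidence window — and is what
the >14-channel rule is designed to remove. Amplitude outliers are
single-channel spike-shaped transients with extremes beyond ±500 µV
(abnormal spike-like events).

The generators do **not** model electrode drift, week-scale gliosis-driven
signal decay, unit waveform nonstationarity, or correlated (shared-source)
neural background. Passing tests therefore demonstrate correctness of the
analysis chain under stationary conditions, not robustness to every failure
mode of chronic recordings.

`reference_scene()` freezes the validation scene: one unit per channel with
Vpp evenly spaced 100–300 µV and rates cycling 2–10 Hz, five motion
artifacts on 15 of 16 channels, three amplitude outliers (−600, +600, −800
µV).

## Detection, and two deliberate interpretations

The detection threshold is −4σ̂ per channel with
σ̂ = median(|x|)/0.6745, the standard robust noise scale (the alternative
`sigma_method = "sd"` is selectable). Peaks are local minima within a 1 ms
lockout; snippets span 0.5 ms before to 1.0 ms after the peak and are
edge-padded. Two facts shape how recovery is scored:

* **The −4σ̂ rule has an irreducible false-crossing rate.** On 300–3000 Hz
  band-limited noise the level-crossing rate at 4σ is a fraction of an event
  per second per channel, and after median referencing the robust scale
  slightly underestimates the heavier-tailed residual, raising it further.
  With planted rates of 2–10 Hz, raw event-level precision is therefore
  mathematically capped below ~0.95 no matter how good the implementation.
  End-to-end recovery is consequently scored the way spike-sorting
  benchmarks score it: each planted unit is matched to the sorted unit
  sharing the most spikes (`score_sorting()`), and sensitivity/precision are
  event-level agreement with the matched unit, pooled over planted units.
  Raw detection-level behavior is still property-tested (false positives
  < 1/s on noise, event-level sensitivity/precision ≥ 0.95 on a
  two-units-per-channel scene at realistic ~14 Hz/channel drive, where the
  stated rules can meet those bounds).
* **The noise floor of the processed signal is not the generator's
  `noise_sd`.** Median referencing of independent noise *reduces* per-channel
  RMS (the reference is correlated with each channel), and the second pass
  of the acquisition-band filter trims a few percent more. The noise-RMS
  estimator is therefore validated against the true processed floor: the
  identical seed re-simulated without spikes or artifacts and pushed through
  the same referencing and filtering.

Both choices are about what "recovered correctly" means; neither alters the
stated rules (−4σ, ±500 µV, >14 channels), which are applied literally. The
ambiguous phrase describing the threshold ("from the mean of the peak
heights") is resolved to the robust-SD convention; the `sd` option preserves
the literal alternative.

## Sorting and verification

Plexon's proprietary "K-Means Scan" is reproduced as an open analogue:
waveforms → PCA (2 components by default) → seeded k-means with 10 restarts
for k = 2…5 → mean silhouette; the best k wins if its silhouette reaches
0.5, else one cluster. For channels with more than 1500 events the
silhouette is estimated on a seeded subsample of 1500 (labels are still
assigned to every event); this bounds the O(n²) distance work without
affecting determinism. Sorting is per channel, consistent with per-channel
unit counting downstream.

Manual true-positive verification is replaced by explicit rules —
≥ 30 spikes and ≤ 5% of ISIs under 1 ms — so the pipeline is automatable;
flags are recorded, so metrics can be recomputed under different rules.

## Metrics, ROUT, and aggregation

Vpp is max − min of the unit mean waveform; noise is the RMS of the channel
signal outside all snippet windows; SNR is their ratio; spike rate is the
inverse median ISI (undefined below 2 spikes — such units count toward unit
totals but not rate means). Units under 40 µV Vpp are non-putative (40.0
retained).

ROUT, defined in the literature for robust nonlinear regression, reduces for
a single metric column to its constant-model specialization: center =
median; RSDR = 68.27th percentile of |residuals| × n/(n−1); residual
t-ratios (df = n−1) tested outermost-first against the false-discovery
schedule α_j = Q·j/n, stopping at the first non-significant point. It is
applied in one global pass to the SNR of putative, verified units pooled
across groups and phases, before aggregation. The procedure is scale- and
shift-equivariant, and its null flagging rate at Q = 0.05 is Monte-Carlo
checked (≤ 0.07 over 1000 runs at n = 100).

Aggregation averages qualifying units (putative ∧ verified ∧ not outlier) at
the channel level within phases W1–4 and W5–8; units-per-active-channel
divides the qualifying count by the 4 weeks of a phase.

## Active electrode yield

A channel is *ever-active* if it has at least one active unit in any week of
the whole study; never-active channels are excluded from denominators —
evaluated over the entire study, the only reading consistent with fixed
weekly denominators (107/104/104/118 per group, giving phase totals
428/416/416/472). Twice-weekly sessions collapse to the week level: a
channel is active in a week if active in at least one of its sessions.
Weekly AEY is active/total per group; phase proportions sum both counts over
the phase's weeks. Group comparisons use the pooled two-proportion z-test,
two-sided, without multiplicity correction (pairwise tests are reported as
such).

## Radial histology quantification

The implant hole enters as an explicit mask (the spec'd interactive
definition is an input here; `radial_bins()` checks it is one connected
region). Distance is the exact Euclidean distance transform from the hole
region (`EBImage::distmap`), in µm; for circular holes this reduces to
r − r₀. Rings are half-open 50 µm intervals — a pixel at exactly 50 µm falls
in ring 1 — out to 650 µm; the 600–650 µm ring is the background. Ring means
exclude artifact-masked pixels; empty rings are reported missing.

Normalization sends ring k to N_k = Ī_k/Ī_bg − (1 − f), the unique affine
map preserving ratio scaling that maps the background ring to the marker
factor exactly: f = 1 for markers present in healthy parenchyma (GFAP,
NeuN), f = 0 for markers absent from it (CD68, IgG), so f = 0 profiles read
as relative excess over background. Neuron density divides centroid counts
(each centroid assigned to the ring containing its pixel; border cells are
not split) by unmasked ring area in mm², normalized to the background ring's
density. Segmentation itself (e.g. Cellpose) is out of scope; centroids or
label masks are inputs. When several slice depths exist per implant they
should be averaged after normalization.

## Release chemistry

Encapsulation efficiency is (total − free)/total × 100. Calibration is OLS
of analyte/internal-standard peak-area ratio on concentration ratio, with
closed-form inversion. For the sample-and-replace dialysis assay (14 mL
reservoir, 1 mL aliquots replaced by fresh buffer), cumulative release at
t_i is the mass-balance estimate C_i·V_res + Σ_{j<i} C_j·V_aliquot; the
uncorrected C_i·V_res is also emitted for comparison since published release
curves do not always state the correction. Released fractions above
1 + tolerance (default 5%, covering measurement noise) raise an error;
non-monotonicity is flagged, never silently repaired. The default simulator
kinetics are biexponential with parameters anchored to ~65% released at 24 h
and ~98% at 24 days; the infinite-sink assumption is taken as given, not
modeled.

## Numerical and engineering choices

* **Filter**: 4th-order Butterworth band-pass (the acquisition chain's
  design is unknown; this is the conventional stand-in), applied zero-phase.
  The forward–backward IIR loop runs in compiled code
  (`src/iir.cpp`), matching `signal::filtfilt` to ~1e−13 while being ~20×
  faster — a 10-minute 16-channel session is ~235 M samples.
* **Memory**: session matrices are ~1.9 GB; the median reference and the
  row filter mutate in place when their input is unshared (copy-on-modify
  is preserved otherwise), row filtering reuses one compiled buffer so no
  per-channel temporaries accumulate, and the long-session loops trigger
  minor collections so a full pipeline run peaks near twice the matrix
  size rather than several times it.
* **Medians**: across-channel medians (one per sample) and the even-count
  mean-of-middle-two convention are computed in compiled code.
* **Determinism**: every stage draws from a seed derived from the global
  seed and a stage label (`derive_seed()`); identical configs reproduce
  outputs byte for byte, which the test-suite asserts at the file level.
* **Indexing/units**: samples are 0-based in serialized events; times are
  seconds (= peak_sample/fs); voltages µV; distances µm; densities mm⁻².
* **Validation problem sizes**: the full reference scene (16 × 600 s) runs
  once in the acceptance checks; module property tests use shorter scenes
  (2–4 channels, 10–60 s) chosen so every asserted bound still has clear
  statistical margin.

## Command-line interface

A thin wrapper (`inst/scripts/imeqc`) exposes the simulators and the
file-based stages (`simulate-ephys`, `simulate-histo`, `simulate-release`,
`detect`, `yield`, `histo`, `release`, `ee`, `run`). Sorting and unit
metrics run inside `run` (the end-to-end pipeline); the R functions are the
primary interface for stage-by-stage work.

## Known limitations

* Recovery guarantees hold for the stationary synthetic conditions above;
  real chronic data add drift, bursting, waveform overlap, and correlated
  noise that the generators do not emulate.
* The silhouette-selected k-means scan is a documented open analogue of a
  proprietary method, not a reimplementation of it.
* The ROUT specialization applies to a single metric column; it is not a
  general robust-regression outlier engine.
* Mixed-effects modeling, ANOVA/post-hoc chains, and segmentation are
  intentionally out of scope; standard tools cover them.
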
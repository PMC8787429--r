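---
title: "Analysing evoked and chronic recordings from small-nerve interfaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing evoked and chronic recordings from small-nerve interfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nervesignal)
```

## Scope

`nervesignal` implements the signal-analysis chain used to characterise a
multichannel bioelectronic interface on a small peripheral nerve (the
motivating system is a six-channel stretchable microelectrode array wrapped
around the ~150 µm tracheosyringeal nerve of the zebra finch):

* **acute analysis** — stimulation-evoked compound responses: trial
  extraction and alignment, artifact blanking, peak-to-peak quantification,
  bootstrap detection, fiber-recruitment curves and their sigmoid fits,
  and condition comparisons (e.g. lidocaine conduction block);
* **chronic analysis** — singing-related multi-unit activity: envelope
  extraction, dynamic-time-warping alignment of motif renditions to a
  common template, and multi-week stability metrics;
* **electromechanics** — the closed forms that justify the device design
  (bending strain, neutral-plane placement, Poisson compression, current
  and charge density, impedance fold change, compliance voltage);
* **synthetic data** — generators for both session types with retrievable
  ground truth, so every stage of the pipeline is testable without animal
  recordings.

No public recordings accompany the motivating experiments, so the package
treats the simulator as a first-class module: its defaults encode the
study conditions (24.4 kHz sampling, biphasic 200 µs/phase pulses at 1 Hz,
10–110 µA commanded currents, a recruitment curve saturating near 50 µA,
4–24 m/s conduction velocities over a ~20 mm path), and the analysis
functions are validated by parameter-recovery and calibration experiments
against that ground truth.

## Preprocessing

Recordings are time × channel matrices in µV (`nerve_recording`), stored
on disk as a float32 container with a JSON sidecar. Preprocessing follows
standard extracellular practice:

* `common_mode_subtract()` removes the per-sample across-channel mean,
  cancelling pickup shared by all sites. The output's channel mean is
  identically zero, which makes the operation idempotent.
* `bandpass_zero_phase()` applies a Butterworth or Bessel IIR bandpass
  forward and backward (zero net phase). The Bessel analog prototype is
  designed in-package from the reverse Bessel polynomial, magnitude-
  normalised to −3 dB at the corner, and discretised with the same
  prewarped bilinear transform the Butterworth path uses. Edges are
  padded by odd reflection over at least three time constants of the low
  corner so edge transients do not leak into retained samples. Typical
  bands: 1 Hz–10 kHz (acute, Bessel), 0.3–6 kHz (chronic, 2-pole
  Butterworth).
* `envelope()` squares the trace and smooths with a centred 20 ms boxcar
  advanced in 1 ms steps. Bins whose window would cross the trace edge
  are dropped rather than padded, so every bin is an unbiased window mean
  — this matters for the correlation metrics downstream.
* `noise_metrics()` reports band-limited RMS and peak-to-peak voltage plus
  a Welch power spectral density (Hann window, 1 s segments, 50%
  overlap). The estimator choice is conventional; only band medians of
  the PSD are interpreted in tests, since single-bin periodogram values
  fluctuate by several dB.

## Evoked-response analysis

Trials are cut −5…+25 ms around each stimulation event. The onset is
re-detected as the first sample within ±1 ms of the commanded time at
which any channel exceeds 8× the pre-stimulus SD (the stimulation
artifact); if nothing crosses — e.g. at very low currents — the commanded
time is used. Responses are quantified as the peak-to-peak voltage (Vpp)
inside a response window, 0.75–4 ms after onset by default, matching
conduction latencies of 4–24 m/s myelinated fibers over ~20 mm. The
artifact can be blanked by linear interpolation over (−0.1, 0.75) ms; the
blank window is required to stay clear of the response window, so Vpp is
unchanged by blanking.

**Detection.** The SNR is the RMS ratio of the response window to a
pre-stimulus window on the trial-averaged trace (per-trial SNR is the
single-trial special case). The null distribution is built by resampling:
each of `n_boot` draws takes one contiguous block — the response window's
length — per trial from the pre-stimulus interval, averages across trials,
and forms an RMS ratio of two such draws. Using contiguous blocks
preserves the noise autocorrelation that a sample-wise bootstrap would
destroy. A response is *detected* when the observed SNR exceeds the upper
bound of the central 90% interval of the null; the one-sided rule reflects
that an evoked component can only raise the SNR. The detector's
calibration is checked empirically: on null sessions the observed SNR
falls inside the central interval at the nominal rate.

**Recruitment.** Trials are binned on |current| into half-open 5 µA bins
and per-bin mean Vpp is fitted with the four-parameter logistic

  V(I) = Vmin + (Vmax − Vmin) / (1 + exp(−(I − I50)/slope)),

the standard phenomenological model of progressive fiber recruitment.
`fit_recruitment()` returns a classed model object (`print`, `summary`,
`coef`, `predict`, `plot`, `residuals` methods) fitted by bounded
Levenberg–Marquardt least squares with a five-point multistart over I50
(bounds: Vmin ≥ 0, I50 inside the observed current range, slope > 0; bins
weighted by trial count). On noiseless 4PL samples the fit recovers the
generating parameters to ≤ 1e−6 relative error; flat data raise an
explicit fit-failure. The *saturation* (plateau) current is where the
fitted curve reaches 95% of its span, I50 + slope·ln 19. The simulator's
default recruitment preset (Vmax = 100 µV amplitude, I50 = 35 µA,
slope = 5 µA) places that point at 49.7 µA, encoding a recruitment curve
that saturates near 50 µA with peak-to-peak responses up to ~200 µV.

**Condition comparisons.** `compare_conditions()` takes per-subject mean
Vpp under complete repeated conditions (control / treatment / washout),
runs a one-way repeated-measures ANOVA and control-referenced Dunnett
post-hoc tests at α = 0.05 (via `multcomp`). In simulated conduction-block
experiments we quantify Vpp over 0.75–7 ms — wide enough to contain the
evoked component at every velocity in the simulated 4–24 m/s range.
With the default window, trials whose (random) conduction velocity is slow
have their response clipped at the 4 ms edge; that clipping inflates the
variance of control and washout cells relative to the near-silent
lidocaine cells and makes the pooled-error Dunnett comparison
anticonservative for washout. With the velocity-covering window the
washout false-flag rate sits at the nominal level.

## Song alignment

Chronic analyses align each motif rendition to a common template so that
activity envelopes can be compared bin-by-bin across renditions and days.
The alignment feature is the motif's amplitude envelope at 1 ms
resolution; the template is the element-wise mean of a block of
renditions (conventionally 25 consecutive motifs from day 1; scaled-down
experiments here use smaller blocks) after resampling to the median
length. `dtw_align()` minimises summed squared differences of z-scored
sequences under the step set {(1,0), (0,1), (1,1)} and a Sakoe–Chiba band
(default 20% of the longer length); z-scoring makes alignment invariant
to amplitude drift across days, and the band bounds worst-case cost and
forbids degenerate paths. Ties prefer the diagonal step, then the
rendition-advancing step, so self-alignment returns exactly the
zero-cost diagonal. The dynamic program (implemented in C++) is verified
against exhaustive path enumeration on all short sequence pairs.
`apply_warp()` re-expresses an envelope on the template timeline by
averaging rendition bins that map to the same template bin, with no
premotor time shift. On simulated renditions with known piecewise-linear
warps, the recovered template-index correspondence has a median absolute
error of ~2 ms (well under the 3 ms acceptance bound).

## Stability metrics

* `envelope_corr()` — Pearson correlation of aligned envelopes.
* `within_across_summary()` — all distinct-rendition envelope
  correlations partitioned into same-channel and different-channel sets
  (same-rendition cross-channel pairs are excluded so the two sets have
  the same pair structure; a `all_pairs = FALSE` switch restricts
  across-channel pairs to simultaneous renditions instead). Channel-wise
  within/across means are compared by a two-tailed paired t-test.
* `running_stability()` — Pearson correlation between the mean envelope
  of the first `ref_block` renditions and a sliding window of `window`
  renditions (defaults 25/25, advance 1), with a day-1 self-consistency
  point from two disjoint consecutive blocks. Windows overlapping the
  reference correlate high by construction — drift checks should use
  reference-disjoint windows, which is exactly why the day-1 point uses
  disjoint blocks.
* `motif_vpp()` and `event_rate()` — per-motif peak-to-peak voltage and
  envelope threshold-crossing rate. The threshold is set per motif at
  mean + 5 SD of its own envelope; crossings are upward only, with no
  debounce, and rates are divided by the *unwarped* motif duration. The
  rate is invariant to positive affine rescaling of the envelope. A
  mean + 5 SD threshold is only ever crossed when high activity occupies
  less than ~4% of the motif, so simulated (and real) rates are low and
  frequently zero for individual motifs.
* `first_last_compare()` — two-tailed paired t-tests across channels
  between day-1 and last-day metric values.

## The synthetic generators

**Acute sessions** place biphasic stimulation events at 1 Hz. Each event
carries (i) a biphasic square artifact with an exponential tail, fully
contained within 0.75 ms of onset so the conventional blank window covers
it, with amplitude proportional to |current| and slightly different gain
per channel (so common-mode subtraction attenuates but does not nullify
it); (ii) an evoked waveform — a Gaussian-derivative kernel, distinct in
width and asymmetry per channel, normalised so unit amplitude gives
exactly 2 µV peak-to-peak — scaled by `block_factor ×
sigmoid(|current|)` (defined as exactly 0 at 0 µA) and delayed by
distance/velocity with a fresh uniform velocity per trial; (iii)
band-limited Gaussian noise shaped to a preset RMS. The noise presets
mirror the two plating states of the device: `preset_pre_plating()`
(10 µV RMS; long-trace Vpp above 60 µV in the 1 Hz–7.5 kHz acquisition
band) and `preset_post_plating()` (0.9 µV RMS; Vpp below 10 µV). The RMS
values are chosen to realise those peak-to-peak classes, which is how the
plating states are reported.

**Chronic sessions** express per-channel envelopes — `shared_weight` ×
shared template + (1 − `shared_weight`) × channel-unique template — as
multi-unit spiking plus noise. Envelope templates are sparse Gaussian
bursts (lognormal heights, 3–6 ms widths, ~1 burst per 80 ms) over a low
baseline: singing-related multi-unit envelopes are quiet between
discrete, syllable-locked activity peaks, and only sparse envelopes ever
cross a mean + 5 SD event threshold. Multi-unit events are drawn once per
seed and channel as an inhomogeneous Poisson process on the template
timeline and then *warped* per rendition by a piecewise-linear monotone
time map (knots every 50 ms, slopes within 1 ± `warp_jitter`). Drawing
the events once makes the motor pattern stereotyped — rendition
variability comes from tempo warps and additive noise — and yields the
exact degenerate case that zero jitter with zero noise produces
sample-identical renditions. The audio feature handed to the aligner is
the warped shared template itself (realistic birdsong audio synthesis is
out of scope). A consequence of fixed canonical events is that
channel-specific rendition-to-rendition variability comes only from
recording noise, while tempo warps are shared across channels; metrics
averaged over few renditions therefore covary strongly across channels,
which any channel-paired test should be read against.

Reproducibility: every generator expands a single integer seed into
per-trial/per-channel substreams through a counter, so identical
(scenario, seed) pairs give bit-identical sessions and trials are
mutually independent.

**What the simulator does not emulate.** Real sessions contain movement
artifacts, non-Gaussian and nonstationary noise, electrode drift,
cross-channel correlated interference beyond a common mode, spike-shape
diversity, amplitude drift across days, and imperfect motif annotation.
Passing the package's calibration and recovery experiments therefore
shows the pipeline is correct and well-calibrated under the stated
statistical conditions, not that it is robust to every artifact of real
recordings.

## Electromechanics

All device formulas are pure closed forms: bending strain ε = d_N/BR;
neutral-plane offsets under a uniform-modulus assumption (metal films as
zero-thickness markers, neutral plane at half the stack thickness — layer
moduli are not available, so composite-beam weighting is deliberately not
attempted); first-order Poisson thickness t = t0(1 − ν·ε) with ν = 0.5
for an incompressible elastomer (uniaxial strain state assumed); disc
area πd²/4; current density with µA/µm² → mA/mm² conversion (the
motivating report prints charge-density units as mA mm⁻¹; dimensional
analysis and its printed 22/40 values identify the unit as mA mm⁻²);
impedance fold change; and compliance voltage V = I·Z. The default stack
(45/30/30 µm, electrodes of 80 µm diameter) gives d_N of 7.5 µm (L1) and
22.5 µm (L2), an area of ≈5000 µm², 21.9 mA/mm² at 110 µA, and 7.5 V at
100 µA through a 75 kΩ in-vivo impedance — under the 10 V stimulator
compliance limit.

## Numerical and design choices

* Zero-phase realisation: forward–backward filtering with odd-reflection
  padding ≥ 3 time constants of the low corner; Bessel order default 2
  per band edge (4 for the wide acute band), configurable.
* Envelope edge policy: partial windows dropped (no padding bias).
* 4PL fit: five I50 multistarts across the observed currents,
  `nlsLM` with ftol = ptol = 1e−15; non-convergence of all starts and
  flat input raise distinct errors.
* Detection sidedness: one-sided exceedance of the central 90% interval's
  upper bound; the interval itself (both bounds) is reported, and the
  `inside` flag is the quantity whose long-run null frequency matches the
  nominal level.
* DTW: squared difference on z-scored sequences; sequences whose length
  difference exceeds the band half-width raise an infeasible-band error.
* Binning: half-open [k·w, (k+1)·w) bins on |current|; polarity is kept
  as trial metadata only.
* Degenerate inputs are explicit errors: zero-variance envelopes
  (correlation), zero noise RMS (detection), flat curves (fitting),
  single channels (common-mode subtraction, within/across summaries).

## Problem sizes

The package's own experiments are sized to run in minutes on one CPU:
detector calibration uses 500 single-channel null sessions of 8 trials
with 2000 bootstrap resamples (200 sessions with 500 resamples in the
test suite); recruitment recovery uses the full 10–110 µA × 40-trial
design on one channel (20 sessions in the acceptance script, 3 in the
test suite); chronic experiments use 4–6 channels, 400–600 ms motifs,
8–40 renditions per day and 16 kHz sampling, with template/reference
blocks of 8–10 renditions standing in for the conventional 25-motif
blocks. These sizes are choices of the package, stated here so results
are read at the right granularity; all defaults remain at the full study
conditions.

## Limitations

* The DTW feature is an amplitude envelope; spectral features would
  discriminate better for real song and can be substituted by the user.
* The paired channel-level tests inherit the clustering caveat above:
  channels within a bird share tempo variability, so their t-tests are
  only approximately calibrated (measurably anticonservative when
  few renditions are averaged).
* The electromechanical neutral-plane model ignores the metal films'
  stiffness; it is the design heuristic, not a mechanics simulation.
* The bootstrap null assumes the pre-stimulus interval is response-free
  and stationary across trials.
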
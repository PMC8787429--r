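# nervesignal

Signal analysis for multichannel bioelectronic interfaces on small
peripheral nerves.

Recording from and stimulating sub-millimetre nerves (the motivating
system is a six-channel stretchable microelectrode array on the ~150 µm
tracheosyringeal nerve of the zebra finch) poses two analysis problems:
deciding whether a stimulation pulse evoked a genuine compound nerve
response and how response amplitude grows with current, and quantifying
whether chronically recorded, behaviour-locked multi-unit activity stays
stable over weeks. `nervesignal` implements that full chain for
electrophysiologists and interface engineers, together with synthetic
session generators (known ground truth) so every stage is testable
without animal data, and the closed-form electromechanics used to design
thin-film electrode arrays.

## What it computes

**Evoked responses.** Trials are aligned on the stimulation artifact,
optionally blanked, and quantified as peak-to-peak voltage `Vpp` in a
response window (0.75–4 ms after onset by default). Detection compares
the SNR — RMS(response window) / RMS(pre-stimulus window) on the
trial-averaged trace — against a block-bootstrap null built from the
pre-stimulus interval (10 000 resamples, central 90% interval, one-sided
exceedance). Recruitment curves bin trials on |current| (5 µA bins) and
are fitted with the four-parameter logistic

    V(I) = Vmin + (Vmax − Vmin) / (1 + exp(−(I − I50)/slope)),

the standard fiber-recruitment model; the saturation ("plateau") current
is where the fit reaches 95% of its span, `I50 + slope·ln 19`. Condition
comparisons (control / lidocaine / washout) use repeated-measures ANOVA
with Dunnett post-hoc tests.

**Chronic stability.** Activity envelopes (signal squared, 20 ms boxcar,
1 ms advance) of song-motif renditions are aligned to a common template
by dynamic time warping (squared-difference cost on z-scored amplitude
envelopes, Sakoe–Chiba band, C++ dynamic program verified against
exhaustive enumeration), then summarised as within- vs across-channel
correlation structure, running correlation to a day-1 reference,
per-motif `Vpp`, and mean + 5 SD threshold-crossing event rates.

**Electromechanics.** Bending strain `ε = d_N/BR`, neutral-plane offsets
of a layered stack, Poisson compression, disc electrode area and current
or charge density, impedance fold change, and Ohmic compliance voltage
`V = I·Z`.

## Worked example

```r
library(nervesignal)

scenario <- acute_scenario(currents = seq(10, 110, by = 20),
                           trials_per_current = 8, n_channels = 2,
                           noise = noise_preset(3, c(300, 6000)))
session <- gen_acute_session(scenario, seed = 42)
trials  <- extract_trials(session$recording, session$events)
fit     <- fit_recruitment(recruitment_curve(trials, bin_width = 5))
fit
#> Four-parameter logistic recruitment fit
#>   Vmin = 14 uV, Vmax = 194 uV, I50 = 40.2 uA, slope = 4.94 uA
#>   saturation (95% of max): 54.8 uA

strong <- trials[abs(sapply(trials, function(t) t$current)) >= 90]
detect_response(strong, n_boot = 2000, seed = 1)
#> <detection_result> SNR = 40.237 vs null 90% CI [0.768, 1.287] -> DETECTED
```

The fitted maximum (~194 µV peak-to-peak) and saturation current
(~55 µA, against a generating ground truth of 49.7 µA from eight trials
per current) describe the recruitment curve; the detection result says
the high-current trial average carries ~40× more RMS in the response
window than the bootstrap null tolerates at the 90% level.

The chronic pipeline composes the same way: `gen_chronic_session()` →
`motif_renditions()` → `build_template()` / `dtw_align()` /
`apply_warp()` → `within_across_summary()`, `running_stability()`,
`event_rate()`, `first_last_compare()`. See the vignette
(`vignettes/nerve-interface-analysis.Rmd`) for the models, parameter
meanings and numerical choices.

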
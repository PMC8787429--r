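#' @useDynLib nervesignal, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Deterministic substream seeds: one integer session seed expands to
# per-trial/per-channel streams via a counter. Products stay well inside
# double precision; result is a valid 32-bit seed.
substream_seed <- function(seed, counter) {
  ((seed %% 97561) * 22013 + (counter %% 99991) * 21011 + 1) %% 2147483647
}

#' Baseline-noise preset
#'
#' Describes band-limited Gaussian baseline noise by its RMS amplitude and
#' shaping band. The bundled presets mirror the two noise classes of a
#' plated vs. unplated microelectrode: `"pre-plating"` (10 uV RMS, so the
#' peak-to-peak noise of a long trace exceeds 60 uV in the 1 Hz - 7.5 kHz
#' acquisition band) and `"post-plating"` (1.1 uV RMS, peak-to-peak below
#' 10 uV).
#'
#' @param rms Target RMS (uV), >= 0.
#' @param band Shaping band `c(low, high)` in Hz, `low < high`.
#' @param name Label.
#' @return An object of class `noise_preset`.
#' @export
noise_preset <- function(rms, band = c(300, 6000), name = "") {
  if (rms < 0) stop("'rms' must be >= 0", call. = FALSE)
  if (band[1] >= band[2]) stop("band low must be < band high", call. = FALSE)
  structure(list(rms = rms, band = band, name = name), class = "noise_preset")
}

#' @rdname noise_preset
#' @export
preset_pre_plating <- function() noise_preset(10, c(1, 7500), "pre-plating")

#' @rdname noise_preset
#' @export
preset_post_plating <- function() noise_preset(0.9, c(1, 7500), "post-plating")

#' Generate band-limited Gaussian baseline noise
#'
#' White Gaussian noise is shaped by a zero-phase Butterworth bandpass over
#' the preset's band and rescaled so each channel's realised RMS matches the
#' preset. Identical `(preset, duration, fs, n_channels, seed)` give
#' bit-identical output.
#'
#' @param preset A [noise_preset()].
#' @param duration Trace length (s), > 0.
#' @param fs Sampling rate (Hz), > 0 and > 2x the preset's upper band edge.
#' @param n_channels Number of channels.
#' @param seed Integer seed; each channel uses its own substream.
#' @return A [nerve_recording()].
#' @export
gen_noise <- function(preset, duration, fs, n_channels = 1, seed = 1) {
  stopifnot(inherits(preset, "noise_preset"))
  if (duration <= 0 || fs <= 0) {
    stop("'duration' and 'fs' must be positive", call. = FALSE)
  }
  n <- round(duration * fs)
  if (preset$rms == 0) {
    return(nerve_recording(matrix(0, n, n_channels), fs))
  }
  if (fs <= 2 * preset$band[2]) {
    stop("'fs' must exceed twice the preset's upper band edge", call. = FALSE)
  }
  filt <- design_bandpass(preset$band[1], preset$band[2], fs,
                          "butterworth", 2)
  samples <- vapply(seq_len(n_channels), function(ch) {
    set.seed(substream_seed(seed, ch))
    x <- filtfilt_padded(filt, stats::rnorm(n), fs, preset$band[1])
    x * preset$rms / sqrt(mean(x^2))
  }, numeric(n))
  nerve_recording(samples, fs)
}

#' Ground-truth fiber-recruitment sigmoid
#'
#' Four-parameter logistic relating stimulation current to evoked-response
#' amplitude: `V(I) = Vmin + (Vmax - Vmin) / (1 + exp(-(I - I50)/slope))`.
#' The default parameters place the 95%-of-maximum point
#' (`I50 + slope*log(19)`) at 49.7 uA, i.e. a recruitment curve saturating
#' near 50 uA with amplitudes up to 100 uV (peak-to-peak 200 uV).
#'
#' @param Vmin,Vmax Lower/upper asymptote (uV amplitude); `Vmax >= Vmin`.
#' @param I50 Half-maximum current (uA).
#' @param slope Logistic scale (uA), > 0.
#' @return An object of class `sigmoid_params` with derived
#'   `plateau_current`.
#' @export
sigmoid_params <- function(Vmin = 0, Vmax = 100, I50 = 35, slope = 5) {
  if (Vmax < Vmin) stop("'Vmax' must be >= 'Vmin'", call. = FALSE)
  if (slope <= 0) stop("'slope' must be > 0", call. = FALSE)
  structure(
    list(Vmin = Vmin, Vmax = Vmax, I50 = I50, slope = slope,
         plateau_current = I50 + slope * log(19)),
    class = "sigmoid_params"
  )
}

# 4PL evaluation
fourpl <- function(I, p) {
  p$Vmin + (p$Vmax - p$Vmin) / (1 + exp(-(I - p$I50) / p$slope))
}

# Biphasic compound-action-potential kernel: Gaussian first derivative
# (optionally mixed with a second-derivative component for per-channel
# shape diversity), normalised so max - min = 2, i.e. unit amplitude gives
# a peak-to-peak of exactly 2.
evoked_kernel <- function(fs, sigma_ms = 0.3, asym = 0) {
  sigma <- sigma_ms / 1000
  t <- seq(0, 8 * sigma, by = 1 / fs)
  u <- (t - 4 * sigma) / sigma
  k <- -u * exp(-u^2 / 2) + asym * (u^2 - 1) * exp(-u^2 / 2)
  k * 2 / (max(k) - min(k))
}

# Stimulation artifact: biphasic square (one phase per polarity) with an
# exponentially decaying tail. Shape is deliberately simple; only its
# removal/blanking is analysed. The kernel is contained within 0.75 ms of
# onset so the conventional blank window covers it entirely.
artifact_kernel <- function(fs, phase_us = 200, tau_ms = 0.08) {
  ph <- max(1, round(phase_us * 1e-6 * fs))
  tail_n <- round(tau_ms * 4 / 1000 * fs)
  tail <- -0.4 * exp(-(seq_len(tail_n)) / (tau_ms / 1000 * fs))
  c(rep(1, ph), rep(-1, ph), tail)
}

#' Acute stimulation-session scenario
#'
#' Conditions for a simulated acute session: biphasic pulses delivered at
#' regular intervals (1 Hz by default) over a set of commanded currents,
#' with evoked-response amplitude following a ground-truth recruitment
#' sigmoid and onset latency set by conduction distance over a per-trial
#' velocity drawn uniformly from `velocity_range`.
#'
#' @param currents Commanded amplitudes (uA, signed; positive = cathodic-
#'   first). Default 10-110 uA in 5 uA steps.
#' @param trials_per_current Trials per current; default 40.
#' @param fs Sampling rate (Hz); default 24400.
#' @param distance Conduction path length (mm); default 20.
#' @param velocity_range Conduction velocity bounds (m/s); default 4-24.
#' @param recruit Ground-truth [sigmoid_params()].
#' @param artifact_amp Artifact amplitude (uV) at the largest commanded
#'   current; scales linearly with |current|.
#' @param block_factor Response scaling in \[0, 1\] (1 = saline control,
#'   near 0 = full conduction block).
#' @param noise A [noise_preset()]; default 5 uV RMS in 300-6000 Hz.
#' @param n_channels Number of recorded channels; default 6.
#' @param isi Inter-stimulus interval (s); default 1.
#' @return An object of class `acute_scenario`.
#' @export
acute_scenario <- function(currents = seq(10, 110, by = 5),
                           trials_per_current = 40,
                           fs = 24400,
                           distance = 20,
                           velocity_range = c(4, 24),
                           recruit = sigmoid_params(),
                           artifact_amp = 300,
                           block_factor = 1,
                           noise = noise_preset(5, c(300, 6000), "moderate"),
                           n_channels = 6,
                           isi = 1) {
  if (length(currents) == 0) stop("'currents' must be non-empty", call. = FALSE)
  if (trials_per_current < 1) {
    stop("'trials_per_current' must be >= 1", call. = FALSE)
  }
  if (block_factor < 0 || block_factor > 1) {
    stop("'block_factor' must lie in [0, 1]", call. = FALSE)
  }
  if (noise$rms > 0 && fs <= 2 * noise$band[2]) {
    stop("'fs' must exceed twice the noise band's upper edge", call. = FALSE)
  }
  structure(
    list(currents = currents, trials_per_current = trials_per_current,
         fs = fs, distance = distance, velocity_range = velocity_range,
         recruit = recruit, artifact_amp = artifact_amp,
         block_factor = block_factor, noise = noise,
         n_channels = n_channels, isi = isi),
    class = "acute_scenario"
  )
}

#' Generate an acute stimulation session
#'
#' Builds a multichannel recording containing, at each stimulation event:
#' a biphasic artifact at t = 0 (amplitude proportional to |current|), an
#' evoked waveform whose amplitude is `block_factor * sigmoid(|current|)`
#' (exactly 0 at 0 uA) and whose onset latency is `distance / velocity`,
#' and additive preset noise. Channels carry distinct evoked kernel shapes.
#'
#' @param s An [acute_scenario()].
#' @param seed Integer seed; trials and channels use counter substreams.
#' @return List with `recording` ([nerve_recording()]), `events`
#'   (data.frame: `time_s`, `current_uA`, `polarity`) and `truth` (list:
#'   per-trial data.frame with true amplitude, velocity and latency, plus
#'   the per-channel kernels and the scenario).
#' @export
gen_acute_session <- function(s, seed = 1) {
  stopifnot(inherits(s, "acute_scenario"))
  trial_currents <- rep(s$currents, each = s$trials_per_current)
  n_ev <- length(trial_currents)
  set.seed(substream_seed(seed, 1))
  trial_currents <- sample(trial_currents)
  times <- 0.5 + (seq_len(n_ev) - 1) * s$isi
  dur <- times[n_ev] + 0.5
  rec <- gen_noise(s$noise, dur, s$fs, s$n_channels,
                   seed = substream_seed(seed, 2))
  x <- rec$samples
  n <- nrow(x)
  nc <- s$n_channels

  kernels <- lapply(seq_len(nc), function(ch) {
    evoked_kernel(s$fs, sigma_ms = 0.2 + 0.06 * ((ch - 1) %% 5),
                  asym = 0.15 * (((ch - 1) %% 3) - 1))
  })
  art <- artifact_kernel(s$fs)
  art_scale <- 0.8 + 0.4 * (seq_len(nc) - 1) / max(1, nc - 1)
  imax <- max(abs(s$currents))

  velocity <- latency_ms <- amplitude <- numeric(n_ev)
  for (i in seq_len(n_ev)) {
    set.seed(substream_seed(seed, 100 + i))
    v <- stats::runif(1, s$velocity_range[1], s$velocity_range[2])
    velocity[i] <- v
    latency_ms[i] <- s$distance / v
    I <- trial_currents[i]
    amplitude[i] <- if (I == 0) 0 else s$block_factor * fourpl(abs(I), s$recruit)
    ev_sample <- round(times[i] * s$fs) + 1
    on_sample <- round((times[i] + latency_ms[i] / 1000) * s$fs) + 1
    a_amp <- if (imax > 0) s$artifact_amp * abs(I) / imax else 0
    for (ch in seq_len(nc)) {
      ia <- ev_sample:min(n, ev_sample + length(art) - 1)
      x[ia, ch] <- x[ia, ch] + a_amp * art_scale[ch] * art[seq_along(ia)]
      k <- kernels[[ch]]
      ik <- on_sample:min(n, on_sample + length(k) - 1)
      x[ik, ch] <- x[ik, ch] + amplitude[i] * k[seq_along(ik)]
    }
  }
  rec$samples <- x
  events <- data.frame(
    time_s = times,
    current_uA = trial_currents,
    polarity = ifelse(trial_currents >= 0, "cathodic-first", "anodic-first")
  )
  truth <- list(
    trials = data.frame(time_s = times, current_uA = trial_currents,
                        amplitude_uV = amplitude, velocity_ms = velocity,
                        latency_ms = latency_ms),
    kernels = kernels,
    scenario = s
  )
  list(recording = rec, events = events, truth = truth)
}

# Strictly positive per-ms envelope template built from sparse Gaussian
# bursts with lognormal heights over a low baseline: singing-related
# multi-unit envelopes are quiet between discrete, syllable-locked
# activity peaks, and only such sparse envelopes ever cross a
# mean + 5 SD event threshold. Normalised to unit mean.
smooth_envelope_template <- function(len_ms, seed, burst_sd_ms = c(3, 6)) {
  set.seed(seed)
  K <- max(3, round(len_ms / 80))
  pos <- stats::runif(K, 10, len_ms - 10)
  h <- exp(stats::rnorm(K, 0, 1.3))
  wid <- stats::runif(K, burst_sd_ms[1], burst_sd_ms[2])
  t <- seq_len(len_ms)
  e <- rep(0.02, len_ms)
  for (k in seq_len(K)) {
    e <- e + h[k] * exp(-(t - pos[k])^2 / (2 * wid[k]^2))
  }
  e / mean(e)
}

#' Chronic singing-session scenario
#'
#' Conditions for simulated chronic sessions: each of `n_channels` carries a
#' stereotyped song-aligned activity envelope that mixes a shared template
#' (weight `shared_weight`) with a channel-unique template, expressed as
#' multi-unit spiking plus baseline noise. Renditions of the motif are
#' tempo-warped by a smooth random monotone map (piecewise linear, knots
#' every 50 ms, slopes within `1 +/- warp_jitter`).
#'
#' Unless supplied, the shared and unique envelope templates are generated
#' deterministically from `template_seed` (smooth positive per-ms curves of
#' unit mean).
#'
#' @param n_channels Channels; default 6.
#' @param motif_len Template motif length (ms); default 600.
#' @param shared_envelope Optional per-ms shared template (length
#'   `motif_len`, non-negative).
#' @param unique_envelopes Optional list of per-channel per-ms templates.
#' @param shared_weight Mixing fraction in \[0, 1\]; default 0.8.
#' @param warp_jitter Max local tempo deviation (fraction, >= 0); default
#'   0.05.
#' @param spike_rate Mean multi-unit event rate during singing (events/s);
#'   default 150.
#' @param noise A [noise_preset()]; default 2 uV RMS in 300-6000 Hz.
#' @param renditions_per_day Renditions per generated session; default 30.
#' @param n_days Days in the experiment (bookkeeping for multi-day runs).
#' @param fs Sampling rate (Hz); default 24400.
#' @param gap_s Silent gap between renditions (s); default 0.3.
#' @param template_seed Seed for the default envelope templates.
#' @return An object of class `chronic_scenario`.
#' @export
chronic_scenario <- function(n_channels = 6,
                             motif_len = 600,
                             shared_envelope = NULL,
                             unique_envelopes = NULL,
                             shared_weight = 0.8,
                             warp_jitter = 0.05,
                             spike_rate = 150,
                             noise = noise_preset(2, c(300, 6000), "chronic"),
                             renditions_per_day = 30,
                             n_days = 14,
                             fs = 24400,
                             gap_s = 0.3,
                             template_seed = 1) {
  if (shared_weight < 0 || shared_weight > 1) {
    stop("'shared_weight' must lie in [0, 1]", call. = FALSE)
  }
  if (warp_jitter < 0) stop("'warp_jitter' must be >= 0", call. = FALSE)
  if (is.null(shared_envelope)) {
    shared_envelope <- smooth_envelope_template(motif_len,
                                                substream_seed(template_seed, 501))
  }
  if (is.null(unique_envelopes)) {
    unique_envelopes <- lapply(seq_len(n_channels), function(ch) {
      smooth_envelope_template(motif_len, substream_seed(template_seed, 600 + ch))
    })
  }
  if (any(shared_envelope < 0) ||
      any(vapply(unique_envelopes, function(e) any(e < 0), logical(1)))) {
    stop("envelope templates must be non-negative", call. = FALSE)
  }
  if (noise$rms > 0 && fs <= 2 * noise$band[2]) {
    stop("'fs' must exceed twice the noise band's upper edge", call. = FALSE)
  }
  structure(
    list(n_channels = n_channels, motif_len = motif_len,
         shared_envelope = shared_envelope,
         unique_envelopes = unique_envelopes,
         shared_weight = shared_weight, warp_jitter = warp_jitter,
         spike_rate = spike_rate, noise = noise,
         renditions_per_day = renditions_per_day, n_days = n_days,
         fs = fs, gap_s = gap_s, template_seed = template_seed),
    class = "chronic_scenario"
  )
}

# Piecewise-linear monotone warp from template time to rendition time:
# knots every 50 ms, per-segment slopes uniform in [1 - j, 1 + j].
make_warp <- function(motif_len, warp_jitter, seed) {
  knots <- unique(c(seq(0, motif_len, by = 50), motif_len))
  set.seed(seed)
  slopes <- stats::runif(length(knots) - 1, 1 - warp_jitter, 1 + warp_jitter)
  rend <- c(0, cumsum(slopes * diff(knots)))
  list(template_knots = knots, rendition_knots = rend)
}

warp_forward <- function(w, t_template) {
  stats::approx(w$template_knots, w$rendition_knots, xout = t_template,
                rule = 2)$y
}

warp_inverse <- function(w, t_rendition) {
  stats::approx(w$rendition_knots, w$template_knots, xout = t_rendition,
                rule = 2)$y
}

# 1 ms biphasic multi-unit spike shape (one sine cycle), unit peak.
spike_shape <- function(fs) {
  nk <- max(2, round(fs / 1000))
  sin(2 * pi * seq_len(nk) / nk)
}

#' Generate one day of a chronic singing session
#'
#' Multi-unit spiking is drawn once per `(seed, channel)` as an
#' inhomogeneous Poisson process on the template timeline, with rate
#' proportional to the channel's true envelope
#' (`shared_weight * shared + (1 - shared_weight) * unique`). Each
#' rendition then time-warps those canonical events by its own random
#' monotone map, so rendition-to-rendition variability comes from tempo
#' warps and additive noise while the underlying motor pattern is
#' stereotyped (with `warp_jitter = 0` and zero noise, renditions are
#' sample-identical).
#'
#' @param s A [chronic_scenario()].
#' @param day Day index (enters the per-rendition substream counters, so
#'   different days of one seed are independent sessions of the same
#'   "bird").
#' @param seed Integer seed.
#' @return List with `recording`, `motifs` (data.frame: `start_s`,
#'   `stop_s`, `duration_unwarped_s`, `day`, `rendition`) and `truth`
#'   (per-rendition warps, audio features, true envelopes; plus the true
#'   template envelopes and scenario).
#' @export
gen_chronic_session <- function(s, day = 1, seed = 1) {
  stopifnot(inherits(s, "chronic_scenario"))
  L <- s$motif_len
  nc <- s$n_channels
  true_template <- vapply(seq_len(nc), function(ch) {
    s$shared_weight * s$shared_envelope +
      (1 - s$shared_weight) * s$unique_envelopes[[ch]]
  }, numeric(L))

  # canonical multi-unit events on the template timeline, one draw per
  # channel, reused (warped) by every rendition
  canonical <- lapply(seq_len(nc), function(ch) {
    set.seed(substream_seed(seed, ch))
    env <- true_template[, ch]
    lam <- s$spike_rate * env / mean(env) / 1000   # events per ms bin
    counts <- stats::rpois(L, lam)
    t_ms <- rep(seq_len(L) - 1, counts) + stats::runif(sum(counts))
    amp <- 45 * stats::runif(sum(counts), 0.75, 1.25)
    list(t_ms = t_ms, amp = amp)
  })

  R <- s$renditions_per_day
  warps <- lapply(seq_len(R), function(r) {
    make_warp(L, s$warp_jitter, substream_seed(seed, 1000 * day + 10 + r))
  })
  rend_len_ms <- vapply(warps, function(w) max(w$rendition_knots), numeric(1))

  gap_n <- round(s$gap_s * s$fs)
  rend_n <- round(rend_len_ms / 1000 * s$fs)
  starts_n <- gap_n + c(0, cumsum(rend_n + gap_n))[seq_len(R)]
  total_n <- starts_n[R] + rend_n[R] + gap_n

  rec <- gen_noise(s$noise, total_n / s$fs, s$fs, nc,
                   seed = substream_seed(seed, 1000 * day + 5))
  x <- rec$samples[seq_len(total_n), , drop = FALSE]
  shape <- spike_shape(s$fs)

  truth_rend <- vector("list", R)
  for (r in seq_len(R)) {
    w <- warps[[r]]
    u <- seq_len(round(rend_len_ms[r])) - 0.5          # rendition ms grid
    t_temp <- warp_inverse(w, u)
    feature <- stats::approx(seq_len(L) - 0.5, s$shared_envelope,
                             xout = t_temp, rule = 2)$y
    env_true <- vapply(seq_len(nc), function(ch) {
      stats::approx(seq_len(L) - 0.5, true_template[, ch],
                    xout = t_temp, rule = 2)$y
    }, numeric(length(u)))
    for (ch in seq_len(nc)) {
      sp_ms <- warp_forward(w, canonical[[ch]]$t_ms)
      sp_idx <- starts_n[r] + round(sp_ms / 1000 * s$fs) + 1
      for (k in seq_along(sp_idx)) {
        ii <- sp_idx[k]:min(total_n, sp_idx[k] + length(shape) - 1)
        x[ii, ch] <- x[ii, ch] + canonical[[ch]]$amp[k] * shape[seq_along(ii)]
      }
    }
    truth_rend[[r]] <- list(
      warp = w, feature = feature, envelope = env_true,
      len_ms = rend_len_ms[r]
    )
  }
  rec$samples <- x
  motifs <- data.frame(
    start_s = starts_n / s$fs,
    stop_s = (starts_n + rend_n) / s$fs,
    duration_unwarped_s = rend_len_ms / 1000,
    day = day,
    rendition = seq_len(R)
  )
  truth <- list(
    renditions = truth_rend,
    template_envelopes = true_template,
    audio_template = s$shared_envelope,
    canonical_events = canonical,
    scenario = s
  )
  list(recording = rec, motifs = motifs, truth = truth)
}
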
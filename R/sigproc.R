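#' Subtract the across-channel common mode
#'
#' Removes the per-sample mean across channels from every channel. Shared
#' pickup (motion, stimulation artifact common to all sites, line noise)
#' cancels; after subtraction the across-channel mean is identically zero at
#' every sample, which also makes the operation idempotent.
#'
#' @param rec A [nerve_recording()] with at least two channels.
#' @return A [nerve_recording()] of the same shape.
#' @export
common_mode_subtract <- function(rec) {
  stopifnot(inherits(rec, "nerve_recording"))
  if (ncol(rec$samples) < 2) {
    stop("common-mode subtraction needs at least 2 channels", call. = FALSE)
  }
  rec$samples <- rec$samples - rowMeans(rec$samples)
  rec
}

# Analog Bessel lowpass prototype: poles are the roots of the reverse
# Bessel polynomial theta_n(s), rescaled so the magnitude response is
# -3 dB at 1 rad/s. Gain makes the DC response unity.
bessel_prototype <- function(n) {
  k <- 0:n
  # a_k = (2n-k)! / (2^(n-k) k! (n-k)!)
  loga <- lgamma(2 * n - k + 1) - (n - k) * log(2) -
    lgamma(k + 1) - lgamma(n - k + 1)
  coefs <- exp(loga - loga[1])        # normalised, increasing powers
  pole <- polyroot(coefs)
  mag <- function(w) {
    abs(prod(-pole)) / abs(prod(complex(imaginary = w) - pole))
  }
  w3 <- stats::uniroot(function(w) mag(w) - 1 / sqrt(2),
                       lower = 1e-3, upper = 10, tol = 1e-12)$root
  pole <- pole / w3
  signal::Zpg(zero = numeric(0), pole = pole, gain = Re(prod(-pole)))
}

# Digital bandpass design shared by both families; W in normalised
# frequency (1 = Nyquist), mirroring signal::butter's bilinear pathway.
design_bandpass <- function(low, high, fs, family, order) {
  W <- c(low, high) / (fs / 2)
  if (family == "butterworth") {
    return(signal::butter(order, W, type = "pass"))
  }
  Tb <- 2
  Wp <- 2 / Tb * tan(pi * W / Tb)
  zpg <- bessel_prototype(order)
  zpg <- signal::sftrans(zpg, W = Wp, stop = FALSE)
  zpg <- signal::bilinear(zpg, T = Tb)
  signal::as.Arma(zpg)
}

# Forward-backward IIR filtering with odd-reflection padding of at least
# three time constants of the lowest passband corner (capped at the trace
# length), so edge transients do not leak into the retained samples.
filtfilt_padded <- function(filt, x, fs, low) {
  n <- length(x)
  npad <- min(n - 1, ceiling(3 * fs / low))
  head_pad <- 2 * x[1] - x[(npad + 1):2]
  tail_pad <- 2 * x[n] - x[(n - 1):(n - npad)]
  y <- c(head_pad, x, tail_pad)
  y <- signal::filter(filt, y)
  y <- rev(signal::filter(filt, rev(y)))
  y[(npad + 1):(npad + n)]
}

#' Zero-phase bandpass filtering
#'
#' Applies an IIR bandpass of the requested family forward and backward
#' (zero net phase; the group delay of any feature is preserved), with
#' odd-reflection edge padding. The effective magnitude response is the
#' square of the one-pass design.
#'
#' @param rec A [nerve_recording()].
#' @param low,high Band edges (Hz); `0 < low < high < fs/2`.
#' @param family `"butterworth"` or `"bessel"`.
#' @param order One-pass filter order per band edge; default 2.
#' @return Filtered [nerve_recording()].
#' @export
bandpass_zero_phase <- function(rec, low, high,
                                family = c("butterworth", "bessel"),
                                order = 2) {
  stopifnot(inherits(rec, "nerve_recording"))
  family <- match.arg(family)
  if (!(low > 0 && low < high && high < rec$fs / 2)) {
    stop("band must satisfy 0 < low < high < fs/2", call. = FALSE)
  }
  filt <- design_bandpass(low, high, rec$fs, family, order)
  rec$samples <- apply(rec$samples, 2, function(x) {
    filtfilt_padded(filt, x, rec$fs, low)
  })
  rec
}

#' Multi-unit activity envelope (squared, boxcar-smoothed signal)
#'
#' The per-channel signal is squared and smoothed with a centred boxcar
#' (default 20 ms) advanced in steps (default 1 ms). Bins whose boxcar
#' window would extend past the trace are dropped, so every reported bin is
#' an unbiased window mean.
#'
#' @param rec A [nerve_recording()].
#' @param window Boxcar width (ms); must be at least `advance` and at least
#'   one sample.
#' @param advance Bin spacing (ms).
#' @return An object of class `nerve_envelope`: list with `values`
#'   (bins x channels matrix, uV^2), `times_ms` (bin centres, relative to
#'   trace start), `window`, `bin_width`, `fs`.
#' @export
envelope <- function(rec, window = 20, advance = 1) {
  stopifnot(inherits(rec, "nerve_recording"))
  if (window < advance) stop("'window' must be >= 'advance'", call. = FALSE)
  win_samp <- round(window * rec$fs / 1000)
  if (win_samp < 1) {
    stop("'window' is shorter than one sample", call. = FALSE)
  }
  n <- nrow(rec$samples)
  half <- win_samp / 2
  # centres at k*advance ms for which the full window fits inside the trace
  t_max <- (n - 1) / rec$fs * 1000
  centers <- seq(0, t_max, by = advance)
  cidx <- round(centers * rec$fs / 1000) + 1
  lo <- cidx - floor(half)
  hi <- lo + win_samp - 1
  keep <- lo >= 1 & hi <= n
  if (!any(keep)) stop("trace shorter than one envelope window", call. = FALSE)
  lo <- lo[keep]; hi <- hi[keep]
  vals <- apply(rec$samples, 2, function(x) {
    cs <- cumsum(c(0, x^2))
    (cs[hi + 1] - cs[lo]) / win_samp
  })
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1)
  structure(
    list(values = vals, times_ms = centers[keep],
         window = window, bin_width = advance, fs = rec$fs),
    class = "nerve_envelope"
  )
}

#' Write an envelope to CSV (bin time in ms, one column per channel)
#'
#' @param env A [envelope()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_envelope_csv <- function(env, path) {
  stopifnot(inherits(env, "nerve_envelope"))
  df <- data.frame(bin_time_ms = env$times_ms, env$values)
  names(df)[-1] <- paste0("ch", seq_len(ncol(env$values)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.nerve_envelope <- function(x, ...) {
  cat(sprintf(
    "<nerve_envelope> %d bins x %d channels (%g ms boxcar, %g ms advance)\n",
    nrow(x$values), ncol(x$values), x$window, x$bin_width
  ))
  invisible(x)
}

# Welch averaged modified periodogram: Hann-windowed segments with 50%
# overlap, one-sided density in units^2/Hz.
welch_psd <- function(x, fs, segment_s = 1, overlap = 0.5) {
  n <- length(x)
  seg <- min(n, round(segment_s * fs))
  step <- max(1, round(seg * (1 - overlap)))
  starts <- seq(1, n - seg + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg) / (seg + 1))
  scale <- 1 / (fs * sum(w^2))
  nf <- floor(seg / 2) + 1
  acc <- numeric(nf)
  for (s in starts) {
    xs <- x[s:(s + seg - 1)]
    xs <- (xs - mean(xs)) * w
    p <- abs(stats::fft(xs))^2 * scale
    acc <- acc + p[seq_len(nf)]
  }
  pow <- acc / length(starts)
  # double non-DC, non-Nyquist bins for the one-sided density
  if (seg %% 2 == 0) pow[2:(nf - 1)] <- 2 * pow[2:(nf - 1)]
  else pow[2:nf] <- 2 * pow[2:nf]
  list(freq = (seq_len(nf) - 1) * fs / seg, power = pow)
}

#' Baseline-noise metrics of a recording
#'
#' Band-limits the trace (zero-phase Butterworth) and reports per-channel
#' RMS and peak-to-peak voltage, plus an averaged-periodogram power
#' spectral density (Hann window, default 1 s segments, 50% overlap).
#'
#' @param rec A [nerve_recording()].
#' @param band Two-element band (Hz) within Nyquist.
#' @param order Filter order for the band limiting; default 2.
#' @param segment_s PSD segment length (s).
#' @return List with `rms` (uV, per channel), `vpp` (uV, per channel),
#'   `psd` (list: `freq` Hz, `power` matrix freq x channels, uV^2/Hz).
#' @export
noise_metrics <- function(rec, band = c(1, 7500), order = 2, segment_s = 1) {
  stopifnot(inherits(rec, "nerve_recording"))
  if (nrow(rec$samples) == 0) stop("empty trace", call. = FALSE)
  filt <- bandpass_zero_phase(rec, band[1], band[2], "butterworth", order)
  x <- filt$samples
  pows <- apply(x, 2, function(col) welch_psd(col, rec$fs, segment_s)$power)
  freq <- welch_psd(x[, 1], rec$fs, segment_s)$freq
  list(
    rms = apply(x, 2, function(col) sqrt(mean(col^2))),
    vpp = apply(x, 2, function(col) max(col) - min(col)),
    psd = list(freq = freq, power = as.matrix(pows))
  )
}
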
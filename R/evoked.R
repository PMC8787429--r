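#' Evoked-response analysis window
#'
#' Post-stimulus window in which compound evoked responses are quantified.
#' The 0.75-4 ms default matches conduction latencies of 4-24 m/s
#' myelinated fibers over a ~20 mm path.
#'
#' @param start,stop Window bounds (ms after stimulation onset);
#'   `0 < start < stop <= 25`.
#' @return An object of class `response_window`.
#' @export
response_window <- function(start = 0.75, stop = 4.0) {
  if (!(start > 0 && start < stop && stop <= 25)) {
    stop("window must satisfy 0 < start < stop <= 25 ms", call. = FALSE)
  }
  structure(list(start = start, stop = stop), class = "response_window")
}

# sample indices of trial times (ms, relative to onset) inside [a, b]
trial_window_idx <- function(trial, a, b) {
  which(trial$t_ms >= a & trial$t_ms <= b)
}

#' Extract stimulation-aligned trials from a recording
#'
#' Cuts a -pre..+post ms snippet around every stimulation event. The onset
#' is re-detected as the first sample, within +/-1 ms of the commanded
#' time, at which any channel exceeds `thresh_mult` times the pre-stimulus
#' standard deviation (artifact onset); if nothing crosses, the commanded
#' time is used. Events whose window would leave the recording are skipped
#' with a warning (the skip count is attached as attribute `n_skipped`).
#'
#' @param rec A [nerve_recording()].
#' @param events Data.frame with `time_s` and `current_uA` (e.g. from
#'   [gen_acute_session()] or a session's `events.csv`).
#' @param pre,post Window extent (ms); defaults 5 and 25.
#' @param thresh_mult Artifact-detection threshold as a multiple of the
#'   pre-stimulus SD; default 8.
#' @return List of `stim_trial` objects (snippet matrix, `current`,
#'   `polarity`, `fs`, `t_ms` time base with onset at 0).
#' @export
extract_trials <- function(rec, events, pre = 5, post = 25,
                           thresh_mult = 8) {
  stopifnot(inherits(rec, "nerve_recording"))
  fs <- rec$fs
  n <- nrow(rec$samples)
  pre_n <- round(pre * fs / 1000)
  post_n <- round(post * fs / 1000)
  search_n <- round(1 * fs / 1000)
  trials <- list()
  skipped <- 0L
  for (i in seq_len(nrow(events))) {
    cmd <- round(events$time_s[i] * fs) + 1
    if (cmd - pre_n - search_n < 1 || cmd + post_n + search_n > n) {
      skipped <- skipped + 1L
      next
    }
    base <- rec$samples[(cmd - pre_n):(cmd - search_n), , drop = FALSE]
    thr <- thresh_mult * stats::sd(as.vector(base))
    seg <- rec$samples[(cmd - search_n):(cmd + search_n), , drop = FALSE]
    hit <- which(apply(abs(seg) > thr, 1, any))
    onset <- if (length(hit) > 0) cmd - search_n + hit[1] - 1 else cmd
    snip <- rec$samples[(onset - pre_n):(onset + post_n), , drop = FALSE]
    trials[[length(trials) + 1]] <- structure(
      list(
        snippet = snip,
        current = events$current_uA[i],
        polarity = if ("polarity" %in% names(events)) events$polarity[i] else NA,
        fs = fs,
        onset_index = pre_n + 1,
        t_ms = (seq_len(pre_n + post_n + 1) - pre_n - 1) / fs * 1000
      ),
      class = "stim_trial"
    )
  }
  if (skipped > 0) {
    warning(skipped, " event(s) too close to the trace edge were skipped")
  }
  attr(trials, "n_skipped") <- skipped
  trials
}

#' Blank the stimulation artifact by linear interpolation
#'
#' Replaces samples in the blank window (default -0.1 to 0.75 ms around
#' onset) by a straight line between the window's endpoint samples, per
#' channel; all other samples are untouched. The blank window must not
#' reach into the response window.
#'
#' @param trial A `stim_trial`.
#' @param blank Two-element window (ms) around onset.
#' @param w The [response_window()] the blank must stay clear of.
#' @return The trial with the artifact span blanked.
#' @export
blank_artifact <- function(trial, blank = c(-0.1, 0.75),
                           w = response_window()) {
  stopifnot(inherits(trial, "stim_trial"))
  if (blank[2] > w$start) {
    stop("blank window overlaps the response window", call. = FALSE)
  }
  idx <- trial_window_idx(trial, blank[1], blank[2])
  if (length(idx) == 0) return(trial)
  i0 <- max(1, min(idx) - 1)
  i1 <- min(nrow(trial$snippet), max(idx) + 1)
  for (ch in seq_len(ncol(trial$snippet))) {
    trial$snippet[idx, ch] <- stats::approx(
      x = c(i0, i1),
      y = trial$snippet[c(i0, i1), ch],
      xout = idx
    )$y
  }
  trial
}

#' Peak-to-peak response amplitude in the response window
#'
#' `max - min` of the snippet restricted to the response window, per
#' channel; by default averaged across channels, or reported per channel /
#' for a selected channel.
#'
#' @param trial A `stim_trial` (typically common-mode subtracted and
#'   filtered upstream).
#' @param w A [response_window()].
#' @param channel `"mean"` (default), `"per_channel"`, or a channel index.
#' @return Vpp in uV (scalar, or per-channel vector).
#' @export
response_vpp <- function(trial, w = response_window(), channel = "mean") {
  stopifnot(inherits(trial, "stim_trial"))
  idx <- trial_window_idx(trial, w$start, w$stop)
  if (length(idx) == 0) stop("empty response window", call. = FALSE)
  seg <- trial$snippet[idx, , drop = FALSE]
  vpp <- apply(seg, 2, function(x) max(x) - min(x))
  if (identical(channel, "mean")) mean(vpp)
  else if (identical(channel, "per_channel")) vpp
  else vpp[channel]
}

# single trace per trial for detection: channel mean or a selected channel
trial_trace <- function(trial, channel) {
  if (identical(channel, "mean")) rowMeans(trial$snippet)
  else trial$snippet[, channel]
}

#' Bootstrap detection of an evoked response
#'
#' The signal-to-noise ratio is the RMS of the response window divided by
#' the RMS of a pre-stimulus noise window, computed on the trial-averaged
#' trace (or per trial with `average = FALSE` and a single trial). The
#' null distribution is built by `n_boot` resamples in which both the
#' "signal" and the "noise" segment are contiguous blocks, of the response
#' window's length, drawn with replacement from the pre-stimulus interval
#' across trials. A response is detected when the observed SNR exceeds the
#' upper bound of the central `level`% interval of the null (one-sided
#' exceedance; responses can only raise the SNR). The result records
#' whether the observed SNR fell inside the central interval, which is the
#' quantity whose long-run frequency should match `level` on null data.
#'
#' @param trials List of `stim_trial` objects.
#' @param w A [response_window()].
#' @param noise_window Pre-stimulus interval (ms, negative = before onset);
#'   default -5 to -0.25. Must be at least as long as the response window.
#' @param n_boot Bootstrap resamples; default 10000 (>= 100).
#' @param level Central interval level (%); default 90.
#' @param seed Integer seed for the resampling.
#' @param channel Passed to the per-trial trace: `"mean"` or an index.
#' @return An object of class `detection_result`: `snr`, `ci`, `detected`,
#'   `inside`, `n_boot`, `level`, and metadata field `sidedness`.
#' @export
detect_response <- function(trials, w = response_window(),
                            noise_window = c(-5, -0.25),
                            n_boot = 10000, level = 90, seed = 1,
                            channel = "mean") {
  if (length(trials) == 0) stop("no trials", call. = FALSE)
  if (n_boot < 100) stop("'n_boot' must be >= 100", call. = FALSE)
  tr1 <- trials[[1]]
  ridx <- trial_window_idx(tr1, w$start, w$stop)
  nidx <- trial_window_idx(tr1, noise_window[1], noise_window[2])
  L <- length(ridx)
  if (length(nidx) < L) {
    stop("pre-stimulus noise interval must be at least as long as the response window",
         call. = FALSE)
  }
  traces <- vapply(trials, trial_trace, numeric(length(tr1$t_ms)),
                   channel = channel)
  avg <- rowMeans(traces)
  noise_rms <- sqrt(mean(avg[nidx]^2))
  if (noise_rms == 0) {
    stop("degenerate input: zero noise RMS in the pre-stimulus window",
         call. = FALSE)
  }
  snr <- sqrt(mean(avg[ridx]^2)) / noise_rms

  # vectorised block bootstrap: for each resample, one contiguous block per
  # trial is averaged across trials; an RMS ratio of two such draws forms
  # one null SNR
  prestim <- traces[nidx, , drop = FALSE]      # P x T
  P <- nrow(prestim)
  T_ <- ncol(prestim)
  n_start <- P - L + 1
  set.seed(substream_seed(seed, 7))
  # draw n_boot across-trial mean waves: one contiguous L-block per trial,
  # elements ordered (resample, trial, offset), summed over trials per
  # (resample, offset)
  draw_means <- function() {
    starts <- sample.int(n_start, n_boot * T_, replace = TRUE)
    rows <- rep(starts, each = L) + rep(0:(L - 1), times = n_boot * T_)
    cols <- rep(rep(seq_len(T_), each = L), times = n_boot)
    vals <- prestim[cbind(rows, cols)]
    g <- rep(seq_len(L), times = n_boot * T_) +
      rep((seq_len(n_boot) - 1) * L, each = T_ * L)
    sums <- rowsum(vals, g, reorder = TRUE)
    matrix(sums / T_, nrow = L)               # L x n_boot mean waves
  }
  sig_mean <- draw_means()
  noi_mean <- draw_means()
  null_snr <- sqrt(colMeans(sig_mean^2)) / sqrt(colMeans(noi_mean^2))

  alpha <- (1 - level / 100) / 2
  ci <- unname(stats::quantile(null_snr, c(alpha, 1 - alpha)))
  structure(
    list(
      snr = snr,
      ci = ci,
      detected = snr > ci[2],
      inside = snr >= ci[1] && snr <= ci[2],
      n_boot = n_boot,
      level = level,
      sidedness = "one-sided upper exceedance of the central interval"
    ),
    class = "detection_result"
  )
}

#' @export
print.detection_result <- function(x, ...) {
  cat(sprintf(
    "<detection_result> SNR = %.3f vs null %g%% CI [%.3f, %.3f] -> %s\n",
    x$snr, x$level, x$ci[1], x$ci[2],
    if (x$detected) "DETECTED" else "not detected"
  ))
  invisible(x)
}

#' Recruitment curve: binned current vs mean peak-to-peak response
#'
#' Trials are grouped on |current| into half-open bins
#' `[k*bin_width, (k+1)*bin_width)`; empty bins are omitted. Bin order of
#' the input trials does not affect the result.
#'
#' @param trials List of `stim_trial` objects.
#' @param bin_width Current bin width (uA); default 5.
#' @param w A [response_window()] for the per-trial Vpp.
#' @param channel Passed to [response_vpp()].
#' @return An object of class `recruitment_curve`: data.frame with
#'   `bin_center` (uA), `mean_vpp` (uV), `n_trials`.
#' @export
recruitment_curve <- function(trials, bin_width = 5, w = response_window(),
                              channel = "mean") {
  if (length(trials) == 0) stop("no trials", call. = FALSE)
  cur <- abs(vapply(trials, function(t) t$current, numeric(1)))
  vpp <- vapply(trials, response_vpp, numeric(1), w = w, channel = channel)
  k <- floor(cur / bin_width)
  agg <- tapply(vpp, k, mean)
  cnt <- tapply(vpp, k, length)
  kk <- as.numeric(names(agg))
  out <- data.frame(
    bin_center = kk * bin_width + bin_width / 2,
    mean_vpp = as.numeric(agg),
    n_trials = as.integer(cnt)
  )
  out <- out[order(out$bin_center), ]
  rownames(out) <- NULL
  structure(out, class = c("recruitment_curve", "data.frame"),
            bin_width = bin_width)
}

#' Fit a four-parameter logistic recruitment model
#'
#' Fits `V(I) = Vmin + (Vmax - Vmin) / (1 + exp(-(I - I50)/slope))` to a
#' binned recruitment curve by bounded Levenberg-Marquardt least squares
#' (`Vmin >= 0`, `I50` within the observed current range, `slope > 0`),
#' with a multistart over five `I50` initialisations spread across the
#' observed currents. The saturation ("plateau") current is the current at
#' which the fitted curve reaches 95% of its span:
#' `I50 + slope * log(19)`.
#'
#' @param curve A [recruitment_curve()] with at least 5 distinct bins.
#' @param weights Optional per-bin weights; defaults to `n_trials`.
#' @return An object of class `recruitment_fit` with methods `print`,
#'   `summary`, `coef`, `predict`, `plot`, `residuals` and `fitted`.
#' @export
fit_recruitment <- function(curve, weights = NULL) {
  stopifnot(inherits(curve, "recruitment_curve"))
  df <- as.data.frame(curve)
  if (nrow(df) < 5) stop("need at least 5 distinct bins", call. = FALSE)
  if (diff(range(df$mean_vpp)) < 1e-9 * (abs(mean(df$mean_vpp)) + 1)) {
    stop("fit-failure: flat recruitment data", call. = FALSE)
  }
  if (is.null(weights)) weights <- df$n_trials
  rng <- range(df$bin_center)
  span <- diff(range(df$mean_vpp))
  i50_starts <- seq(rng[1], rng[2], length.out = 5)
  best <- NULL
  for (i50 in i50_starts) {
    st <- list(Vmin = max(0, min(df$mean_vpp)),
               Vmax = max(df$mean_vpp),
               I50 = i50,
               slope = diff(rng) / 10)
    fit <- tryCatch(
      minpack.lm::nlsLM(
        mean_vpp ~ Vmin + (Vmax - Vmin) / (1 + exp(-(bin_center - I50) / slope)),
        data = df, start = st, weights = weights,
        lower = c(Vmin = 0, Vmax = 0, I50 = rng[1], slope = 1e-3),
        upper = c(Vmin = max(df$mean_vpp), Vmax = 4 * max(df$mean_vpp),
                  I50 = rng[2], slope = diff(rng)),
        control = minpack.lm::nls.lm.control(
          ftol = 1e-15, ptol = 1e-15, maxiter = 500
        )
      ),
      error = function(e) NULL
    )
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    stop("fit-failure: no multistart converged", call. = FALSE)
  }
  cf <- stats::coef(best$fit)
  structure(
    list(
      coefficients = cf,
      plateau_current = unname(cf["I50"] + cf["slope"] * log(19)),
      fitted.values = stats::fitted(best$fit),
      residuals = stats::residuals(best$fit),
      rss = best$rss,
      curve = df,
      nls = best$fit
    ),
    class = "recruitment_fit"
  )
}

#' @export
coef.recruitment_fit <- function(object, ...) object$coefficients

#' @export
fitted.recruitment_fit <- function(object, ...) object$fitted.values

#' @export
residuals.recruitment_fit <- function(object, ...) object$residuals

#' @export
predict.recruitment_fit <- function(object, newdata = NULL, ...) {
  cf <- object$coefficients
  I <- if (is.null(newdata)) object$curve$bin_center
       else if (is.data.frame(newdata)) newdata$bin_center
       else newdata
  unname(cf["Vmin"] + (cf["Vmax"] - cf["Vmin"]) /
           (1 + exp(-(I - cf["I50"]) / cf["slope"])))
}

#' @export
print.recruitment_fit <- function(x, ...) {
  cf <- x$coefficients
  cat("Four-parameter logistic recruitment fit\n")
  cat(sprintf("  Vmin = %.3g uV, Vmax = %.3g uV, I50 = %.3g uA, slope = %.3g uA\n",
              cf["Vmin"], cf["Vmax"], cf["I50"], cf["slope"]))
  cat(sprintf("  saturation (95%% of max): %.1f uA\n", x$plateau_current))
  invisible(x)
}

#' @export
summary.recruitment_fit <- function(object, ...) {
  s <- summary(object$nls)
  out <- list(coefficients = s$coefficients,
              plateau_current = object$plateau_current,
              rss = object$rss, n_bins = nrow(object$curve))
  class(out) <- "summary.recruitment_fit"
  out
}

#' @export
print.summary.recruitment_fit <- function(x, ...) {
  cat("Four-parameter logistic recruitment fit\n")
  stats::printCoefmat(x$coefficients)
  cat(sprintf("\nSaturation current (95%% of max): %.2f uA on %d bins (RSS %.3g)\n",
              x$plateau_current, x$n_bins, x$rss))
  invisible(x)
}

#' @export
plot.recruitment_fit <- function(x, ...) {
  df <- x$curve
  graphics::plot(df$bin_center, df$mean_vpp, pch = 16,
                 xlab = "stimulation current (uA)",
                 ylab = "response Vpp (uV)", ...)
  I <- seq(min(df$bin_center), max(df$bin_center), length.out = 200)
  graphics::lines(I, predict(x, I))
  graphics::abline(v = x$plateau_current, lty = 3)
  invisible(x)
}

#' Compare evoked responses across repeated conditions
#'
#' Repeated-measures one-way ANOVA across conditions (complete blocks, one
#' value per subject and condition) followed by control-referenced Dunnett
#' post-hoc comparisons at alpha = 0.05. The first column/level is the
#' control.
#'
#' @param vpp Matrix or data.frame, rows = subjects, columns = conditions
#'   (first column = control), of per-subject mean Vpp.
#' @param alpha Decision level; default 0.05.
#' @return List with `anova` (`F`, `df`, `p`) and `posthoc` (data.frame of
#'   condition vs control: estimate, p, reject).
#' @export
compare_conditions <- function(vpp, alpha = 0.05) {
  vpp <- as.matrix(vpp)
  if (nrow(vpp) < 2 || ncol(vpp) < 2) {
    stop("need >= 2 subjects and >= 2 conditions", call. = FALSE)
  }
  if (any(!is.finite(vpp))) {
    stop("unbalanced/incomplete blocks: every subject needs every condition",
         call. = FALSE)
  }
  conds <- colnames(vpp)
  if (is.null(conds)) conds <- paste0("cond", seq_len(ncol(vpp)))
  long <- data.frame(
    value = as.vector(vpp),
    condition = factor(rep(conds, each = nrow(vpp)), levels = conds),
    subject = factor(rep(seq_len(nrow(vpp)), times = ncol(vpp)))
  )
  rm_fit <- stats::aov(value ~ condition + Error(subject), data = long)
  tab <- summary(rm_fit)[["Error: Within"]][[1]]
  # no variation at all across conditions: omnibus is vacuous
  if (tab["condition", "Sum Sq"] + tab["Residuals", "Sum Sq"] <
      1e-12 * (1 + sum(vpp^2))) {
    nc <- length(conds) - 1
    return(list(
      anova = list(F = 0, df = c(tab["condition", "Df"],
                                 tab["Residuals", "Df"]), p = 1),
      posthoc = data.frame(
        comparison = paste(conds[-1], "-", conds[1]),
        estimate = numeric(nc), p = rep(1, nc), reject = rep(FALSE, nc)
      ),
      alpha = alpha
    ))
  }
  omnibus <- list(F = tab["condition", "F value"],
                  df = c(tab["condition", "Df"], tab["Residuals", "Df"]),
                  p = tab["condition", "Pr(>F)"])
  block_fit <- stats::aov(value ~ condition + subject, data = long)
  dn <- multcomp::glht(block_fit, linfct = multcomp::mcp(condition = "Dunnett"))
  ds <- summary(dn)
  posthoc <- data.frame(
    comparison = names(ds$test$coefficients),
    estimate = as.numeric(ds$test$coefficients),
    p = as.numeric(ds$test$pvalues),
    reject = as.numeric(ds$test$pvalues) < alpha
  )
  list(anova = omnibus, posthoc = posthoc, alpha = alpha)
}
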
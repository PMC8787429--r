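#' Pearson correlation between two activity envelopes
#'
#' @param a,b Numeric vectors (or single-channel envelopes) of equal
#'   length >= 3 with nonzero variance.
#' @return Pearson product-moment correlation.
#' @export
envelope_corr <- function(a, b) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) != length(b) || length(a) < 3) {
    stop("envelopes must have equal length >= 3", call. = FALSE)
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("undefined correlation: zero variance", call. = FALSE)
  }
  stats::cor(a, b)
}

#' Within- vs across-channel envelope correlation structure
#'
#' All pairwise Pearson correlations between rendition envelopes are
#' partitioned into same-channel and different-channel sets (disjoint by
#' construction). Per channel, the mean same-channel correlation is paired
#' with the mean of that channel's correlations to other channels'
#' renditions, and the two are compared by a two-tailed paired t-test. A
#' channel x channel matrix of mean-envelope correlations is returned
#' alongside.
#'
#' @param env_sets List (one element per channel) of renditions x bins
#'   matrices of template-aligned envelopes.
#' @param all_pairs Use all distinct-rendition pairs for across-channel
#'   correlations (default); `FALSE` restricts to simultaneous renditions
#'   (same rendition index).
#' @return List with `within_mean`, `across_mean`, `per_channel`
#'   (data.frame), `corr_matrix` (of channel-mean envelopes), and `test`
#'   (htest, or NULL for < 2 channels' worth of pairs).
#' @export
within_across_summary <- function(env_sets, all_pairs = TRUE) {
  C <- length(env_sets)
  if (C < 2) stop("need >= 2 channels", call. = FALSE)
  if (any(vapply(env_sets, nrow, numeric(1)) < 2)) {
    stop("need >= 2 renditions per channel", call. = FALSE)
  }
  within <- vapply(env_sets, function(m) {
    cc <- stats::cor(t(m))
    mean(cc[upper.tri(cc)])
  }, numeric(1))
  across <- numeric(C)
  for (ci in seq_len(C)) {
    vals <- c()
    for (cj in setdiff(seq_len(C), ci)) {
      cc <- stats::cor(t(env_sets[[ci]]), t(env_sets[[cj]]))
      # distinct renditions only, mirroring the same-channel pair set
      vals <- c(vals,
                if (all_pairs) cc[row(cc) != col(cc)] else diag(cc))
    }
    across[ci] <- mean(vals)
  }
  mean_envs <- vapply(env_sets, colMeans, numeric(ncol(env_sets[[1]])))
  test <- if (stats::sd(within - across) > 0) {
    stats::t.test(within, across, paired = TRUE)
  } else {
    structure(list(statistic = c(t = 0), parameter = c(df = C - 1),
                   p.value = 1,
                   method = "Paired t-test (degenerate: zero difference variance)"),
              class = "htest")
  }
  list(
    within_mean = mean(within),
    across_mean = mean(across),
    per_channel = data.frame(channel = seq_len(C), within = within,
                             across = across),
    corr_matrix = stats::cor(mean_envs),
    test = test
  )
}

#' Running stability of song-aligned activity envelopes
#'
#' The reference is the mean envelope of the first `ref_block` renditions.
#' The series at position k is the Pearson correlation between the
#' reference and the mean envelope of the `window` renditions starting at
#' k. The day-1 self-consistency point is the correlation between the mean
#' envelopes of the first two consecutive `ref_block`-sized blocks.
#'
#' @param env_mat Renditions x bins matrix of template-aligned envelopes,
#'   in recording order.
#' @param ref_block Renditions averaged into the reference; default 25.
#' @param window Sliding-window width (renditions); default 25.
#' @param advance Window advance (renditions); default 1.
#' @return List with `series` (data.frame: `start` rendition index,
#'   `correlation`), `day1_self`, and `reference` (mean envelope).
#' @export
running_stability <- function(env_mat, ref_block = 25, window = 25,
                              advance = 1) {
  n <- nrow(env_mat)
  if (n < ref_block + window) {
    stop("need at least ref_block + window renditions", call. = FALSE)
  }
  reference <- colMeans(env_mat[seq_len(ref_block), , drop = FALSE])
  starts <- seq(1, n - window + 1, by = advance)
  series <- vapply(starts, function(k) {
    stats::cor(reference,
               colMeans(env_mat[k:(k + window - 1), , drop = FALSE]))
  }, numeric(1))
  block2 <- colMeans(env_mat[(ref_block + 1):(2 * ref_block), , drop = FALSE])
  list(
    series = data.frame(start = starts, correlation = series),
    day1_self = stats::cor(reference, block2),
    reference = reference
  )
}

#' Peak-to-peak voltage of a recording within a motif interval
#'
#' @param rec A (typically filtered) [nerve_recording()].
#' @param bounds Two-element interval (s, relative to the recording
#'   start), inside the recording.
#' @return Per-channel `max - min` (uV).
#' @export
motif_vpp <- function(rec, bounds) {
  stopifnot(inherits(rec, "nerve_recording"))
  i0 <- floor(bounds[1] * rec$fs) + 1
  i1 <- ceiling(bounds[2] * rec$fs)
  if (i0 >= i1 || i0 < 1 || i1 > nrow(rec$samples)) {
    stop("interval empty or outside the recording", call. = FALSE)
  }
  seg <- rec$samples[i0:i1, , drop = FALSE]
  apply(seg, 2, function(x) max(x) - min(x))
}

#' Envelope threshold-crossing event rate
#'
#' A per-motif threshold is set at `k_sd` standard deviations above the
#' envelope's own mean; the rate is the number of upward crossings (bin
#' rises from below to at-or-above threshold) divided by the duration of
#' the unwarped song. Because the threshold co-scales, the rate is
#' invariant to positive affine rescaling of the envelope.
#'
#' @param env Numeric envelope vector (one channel, one motif).
#' @param duration_unwarped Unwarped motif duration (s), > 0.
#' @param k_sd Threshold multiplier; default 5.
#' @return Event rate (Hz).
#' @export
event_rate <- function(env, duration_unwarped, k_sd = 5) {
  env <- as.numeric(env)
  if (length(env) == 0) stop("zero-length envelope", call. = FALSE)
  if (duration_unwarped <= 0) {
    stop("'duration_unwarped' must be positive", call. = FALSE)
  }
  thr <- mean(env) + k_sd * stats::sd(env)
  if (length(env) < 2) return(0)
  up <- env[-1] >= thr & env[-length(env)] < thr
  sum(up) / duration_unwarped
}

#' Paired first-day vs last-day comparison of chronic metrics
#'
#' Two-tailed paired t-tests across channels between day-1 and last-day
#' values of each supplied metric (e.g. correlation-to-reference, motif
#' Vpp, event rate).
#'
#' @param day1,last Data.frames with a `channel` column and one column per
#'   metric; must cover the same channels.
#' @return Data.frame with one row per metric: `t`, `df`, `p`.
#' @export
first_last_compare <- function(day1, last) {
  if (!identical(sort(day1$channel), sort(last$channel))) {
    stop("day-1 and last-day channels do not match", call. = FALSE)
  }
  day1 <- day1[order(day1$channel), , drop = FALSE]
  last <- last[order(last$channel), , drop = FALSE]
  metrics <- setdiff(intersect(names(day1), names(last)), "channel")
  out <- lapply(metrics, function(mtr) {
    d <- day1[[mtr]] - last[[mtr]]
    if (stats::sd(d) == 0) {
      data.frame(metric = mtr, t = 0, df = length(d) - 1, p = 1)
    } else {
      ht <- stats::t.test(day1[[mtr]], last[[mtr]], paired = TRUE)
      data.frame(metric = mtr, t = unname(ht$statistic),
                 df = unname(ht$parameter), p = ht$p.value)
    }
  })
  do.call(rbind, out)
}
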
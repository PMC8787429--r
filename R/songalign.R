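#' Build a common motif template
#'
#' Element-wise mean of the first `n` rendition feature sequences after
#' resampling each to the median rendition length (linear interpolation).
#' Conventionally the template is built from a block of consecutive motifs
#' on the first day of recording (default block of 25).
#'
#' @param features List of numeric per-ms feature sequences (e.g. smoothed
#'   audio amplitude envelopes).
#' @param n Number of leading renditions to average; default 25 (capped at
#'   the number supplied).
#' @return An object of class `motif_template`: `feature`, `n_source`.
#' @export
build_template <- function(features, n = 25) {
  if (length(features) == 0) stop("empty rendition list", call. = FALSE)
  n <- min(n, length(features))
  med_len <- round(stats::median(vapply(features, length, numeric(1))))
  res <- lapply(features[seq_len(n)], function(f) {
    if (length(f) == med_len) return(as.numeric(f))
    stats::approx(seq_along(f), f,
                  xout = seq(1, length(f), length.out = med_len))$y
  })
  structure(
    list(feature = Reduce(`+`, res) / n, n_source = n),
    class = "motif_template"
  )
}

zscore <- function(x) {
  s <- stats::sd(x)
  if (s < 1e-12) x - mean(x) else (x - mean(x)) / s
}

#' Dynamic time warping of a rendition to a template
#'
#' Aligns a feature sequence to a template by dynamic programming over the
#' step set \{(1,0), (0,1), (1,1)\} with squared-difference local cost and
#' a Sakoe-Chiba band of half-width `band * max(m, n)`. Both sequences are
#' z-scored first (`normalize = TRUE`) so alignment is invariant to
#' amplitude scale and offset, e.g. across recording days. Ties prefer the
#' diagonal step, then the rendition-advancing step, so identical
#' sequences map to the exact diagonal with zero cost.
#'
#' @param feature Numeric rendition sequence (length m).
#' @param template A `motif_template` or numeric sequence (length n).
#' @param band Band half-width as a fraction of `max(m, n)`; default 0.2.
#' @param normalize Z-score both sequences before alignment; default TRUE.
#' @return An object of class `warp_path`: `pairs` (two-column matrix of
#'   1-based (rendition, template) correspondences from (1,1) to (m,n)),
#'   `cost`, `m`, `n`.
#' @export
dtw_align <- function(feature, template, band = 0.2, normalize = TRUE) {
  y <- if (inherits(template, "motif_template")) template$feature
       else as.numeric(template)
  x <- as.numeric(feature)
  if (length(x) == 0 || length(y) == 0) {
    stop("sequences must be non-empty", call. = FALSE)
  }
  w <- max(1L, as.integer(round(band * max(length(x), length(y)))))
  if (w < abs(length(x) - length(y))) {
    stop("infeasible band: narrower than the sequence length difference",
         call. = FALSE)
  }
  if (normalize) {
    x <- zscore(x)
    y <- zscore(y)
  }
  res <- dtw_core(x, y, w)
  if (!is.finite(res$cost)) {
    stop("infeasible band: no admissible warping path", call. = FALSE)
  }
  structure(
    list(pairs = res$path, cost = res$cost,
         m = length(x), n = length(y)),
    class = "warp_path"
  )
}

#' @export
print.warp_path <- function(x, ...) {
  cat(sprintf("<warp_path> %d -> %d bins, %d steps, cost %.4g\n",
              x$m, x$n, nrow(x$pairs) - 1, x$cost))
  invisible(x)
}

#' Re-express a rendition envelope on the template timeline
#'
#' Each template bin receives the mean of all rendition bins the warping
#' path maps to it. No temporal offset is applied (no premotor
#' time-shifting): bin 1 of the rendition feeds bin 1 of the template.
#'
#' @param env Numeric vector (one channel) or bins x channels matrix on
#'   the rendition timeline; length must equal the aligned rendition
#'   feature's length.
#' @param path A `warp_path` from [dtw_align()].
#' @param template_len Template length; defaults to the path's.
#' @return Warped envelope of `template_len` bins (vector or matrix).
#' @export
apply_warp <- function(env, path, template_len = NULL) {
  stopifnot(inherits(path, "warp_path"))
  if (is.null(template_len)) template_len <- path$n
  vec_in <- is.null(dim(env))
  env <- as.matrix(env)
  if (nrow(env) != path$m) {
    stop("envelope length does not match the warping path", call. = FALSE)
  }
  if (template_len != path$n) {
    stop("'template_len' does not match the warping path", call. = FALSE)
  }
  ri <- path$pairs[, 1]
  ti <- path$pairs[, 2]
  out <- apply(env, 2, function(col) {
    as.numeric(rowsum(col[ri], ti) / tabulate(ti, template_len))
  })
  out <- matrix(out, nrow = template_len)
  if (vec_in) out[, 1] else out
}

#' Extract motif renditions (feature + neural envelopes) from a session
#'
#' Convenience constructor for the alignment pipeline on simulated chronic
#' sessions: for every annotated motif, returns the audio feature sequence
#' and the per-channel neural envelope over the same 1 ms time base,
#' computed from the (optionally common-mode subtracted and bandpass
#' filtered) recording.
#'
#' @param session Output of [gen_chronic_session()], or a list with
#'   `recording`, `motifs` and per-rendition features.
#' @param band Bandpass for the neural trace (Hz); default 300-6000 Hz,
#'   zero-phase 2-pole Butterworth. `NULL` skips filtering.
#' @param common_mode Subtract the across-channel common mode first
#'   (default TRUE; requires >= 2 channels).
#' @param window,advance Envelope parameters (ms).
#' @return List of renditions, each with `feature`, `neural` (bins x
#'   channels envelope matrix), `bounds` (s), `duration_unwarped` (s).
#' @export
motif_renditions <- function(session, band = c(300, 6000),
                             common_mode = TRUE,
                             window = 20, advance = 1) {
  rec <- session$recording
  if (common_mode && ncol(rec$samples) >= 2) {
    rec <- common_mode_subtract(rec)
  }
  if (!is.null(band)) {
    rec <- bandpass_zero_phase(rec, band[1], band[2], "butterworth", 2)
  }
  motifs <- session$motifs
  out <- vector("list", nrow(motifs))
  for (r in seq_len(nrow(motifs))) {
    i0 <- round(motifs$start_s[r] * rec$fs) + 1
    i1 <- min(nrow(rec$samples), round(motifs$stop_s[r] * rec$fs))
    sub <- nerve_recording(rec$samples[i0:i1, , drop = FALSE], rec$fs,
                           rec$channels, t0 = motifs$start_s[r])
    env <- envelope(sub, window = window, advance = advance)
    feat <- session$truth$renditions[[r]]$feature
    # envelope drops edge bins; crop the feature to the same interior span
    first_bin <- round(env$times_ms[1] / advance) + 1
    feat <- feat[seq(first_bin, length.out = nrow(env$values))]
    out[[r]] <- list(
      feature = feat,
      neural = env$values,
      bounds = c(motifs$start_s[r], motifs$stop_s[r]),
      duration_unwarped = motifs$duration_unwarped_s[r]
    )
  }
  out
}
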
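#' Multichannel extracellular voltage recording
#'
#' Container for a time x channel voltage matrix in microvolts, with its
#' sampling rate and per-channel metadata (electrode id and layer, L1 or
#' L2, of a bi-layer array).
#'
#' @param samples Numeric matrix, rows = samples, columns = channels (uV).
#'   A vector is treated as a single channel.
#' @param fs Sampling rate (Hz), > 0.
#' @param channels Optional data.frame with columns `id` and `layer`
#'   (values "L1"/"L2"); defaults to ids `ch1..chC` alternating layers.
#' @param t0 Session-relative start time (s).
#' @return An object of class `nerve_recording`.
#' @export
nerve_recording <- function(samples, fs, channels = NULL, t0 = 0) {
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1)
  if (!is.matrix(samples) || !is.numeric(samples)) {
    stop("'samples' must be a numeric matrix", call. = FALSE)
  }
  if (!all(is.finite(samples))) {
    stop("'samples' must be finite", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) {
    stop("'fs' must be a positive scalar", call. = FALSE)
  }
  nc <- ncol(samples)
  if (is.null(channels)) {
    channels <- data.frame(
      id = paste0("ch", seq_len(nc)),
      layer = rep(c("L1", "L2"), length.out = nc),
      stringsAsFactors = FALSE
    )
  }
  if (nrow(channels) != nc) {
    stop("'channels' rows must match the number of signal columns",
         call. = FALSE)
  }
  structure(
    list(samples = samples, fs = fs, channels = channels, t0 = t0),
    class = "nerve_recording"
  )
}

#' @export
print.nerve_recording <- function(x, ...) {
  cat(sprintf(
    "<nerve_recording> %d channels, %.3f s at %g Hz (t0 = %g s)\n",
    ncol(x$samples), nrow(x$samples) / x$fs, x$fs, x$t0
  ))
  invisible(x)
}

#' @export
dim.nerve_recording <- function(x) dim(x$samples)

#' Duration of a recording in seconds
#' @param rec A [nerve_recording()].
#' @return Duration (s).
#' @export
rec_duration <- function(rec) nrow(rec$samples) / rec$fs

#' Write a recording session to a directory container
#'
#' The on-disk session is a directory holding `signal.f32` (little-endian
#' IEEE float32; channels interleaved within each time frame, i.e. the
#' channel index varies fastest, as documented in the sidecar), `meta.json`
#' (sampling rate, channel metadata, units), and optionally `events.csv`
#' (stimulation events) and/or `motifs.csv` (song-motif annotations).
#'
#' Voltages are stored at 32-bit precision, so a first write quantises
#' doubles; writing what was read back is bit-stable.
#'
#' @param dir Output directory (created if missing).
#' @param rec A [nerve_recording()].
#' @param events Optional data.frame of stimulation events
#'   (`time_s`, `current_uA`, `polarity`).
#' @param motifs Optional data.frame of motif annotations
#'   (`start_s`, `stop_s`, ...).
#' @return `dir`, invisibly.
#' @export
write_session <- function(dir, rec, events = NULL, motifs = NULL) {
  stopifnot(inherits(rec, "nerve_recording"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  con <- file(file.path(dir, "signal.f32"), "wb")
  on.exit(close(con), add = TRUE)
  # t(samples) serialises frame by frame with channel fastest
  writeBin(as.numeric(t(rec$samples)), con, size = 4, endian = "little")
  meta <- list(
    fs = rec$fs,
    n_channels = ncol(rec$samples),
    n_samples = nrow(rec$samples),
    units = "uV",
    t0 = rec$t0,
    interleave = "channel-major (channel index varies fastest within a frame)",
    channels = rec$channels
  )
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(events)) {
    utils::write.csv(events, file.path(dir, "events.csv"), row.names = FALSE)
  }
  if (!is.null(motifs)) {
    utils::write.csv(motifs, file.path(dir, "motifs.csv"), row.names = FALSE)
  }
  invisible(dir)
}

#' Read a recording session from a directory container
#'
#' @param dir Session directory written by [write_session()].
#' @return List with elements `recording` ([nerve_recording()]), `events`
#'   (data.frame or NULL) and `motifs` (data.frame or NULL).
#' @export
read_session <- function(dir) {
  meta_path <- file.path(dir, "meta.json")
  sig_path <- file.path(dir, "signal.f32")
  if (!file.exists(meta_path) || !file.exists(sig_path)) {
    stop("'", dir, "' is not a session directory (missing meta.json/signal.f32)",
         call. = FALSE)
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  n <- meta$n_samples * meta$n_channels
  con <- file(sig_path, "rb")
  on.exit(close(con), add = TRUE)
  raw <- readBin(con, what = "numeric", n = n, size = 4, endian = "little")
  samples <- t(matrix(raw, nrow = meta$n_channels))
  rec <- nerve_recording(samples, fs = meta$fs,
                         channels = as.data.frame(meta$channels),
                         t0 = meta$t0)
  read_tab <- function(f) {
    p <- file.path(dir, f)
    if (file.exists(p)) utils::read.csv(p, stringsAsFactors = FALSE) else NULL
  }
  list(recording = rec,
       events = read_tab("events.csv"),
       motifs = read_tab("motifs.csv"))
}
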
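# Signal standardisation and harmonisation.

#' Standardise a recording: resample, band-pass, truncate
#'
#' Resamples to `target_fs` (polyphase, with anti-alias filtering), applies a
#' zero-phase Butterworth band-pass (an `order`-pole filter run
#' forward-backward, i.e. an 8th-order zero-phase response at the default),
#' and truncates the analysis window to the first `max_duration` seconds.
#' Resampling always precedes filtering: the transfer-function form of a
#' band-pass with a 0.5 Hz low edge is numerically unstable at high sampling
#' rates.
#'
#' @param rec A [recording()].
#' @param low,high Band edges, Hz.
#' @param order Net two-pass filter order (even; `order/2` poles per section).
#' @param target_fs Target sampling rate, Hz.
#' @param max_duration Maximum analysis length, seconds.
#' @return A standardised [recording()].
#' @export
standardize_recording <- function(rec, low = 0.5, high = 40, order = 8,
                                  target_fs = 512, max_duration = 300) {
  stopifnot(inherits(rec, "recording"))
  if (order %% 2 != 0) stop("order must be even (two-pass zero-phase design)")
  if (rec_duration(rec) < 1) stop("length error: recording shorter than one epoch")
  data <- rec$data
  fs <- rec$fs
  if (fs != target_fs) {
    pq <- ratio_pq(target_fs, fs)
    data <- t(apply(data, 1, function(v) signal::resample(v, pq[1], pq[2])))
    fs <- target_fs
  }
  if (fs < 2 * high) stop("target_fs must exceed twice the upper band edge")
  bf <- signal::butter(order / 2, c(low, high) / (fs / 2), type = "pass")
  data <- t(apply(data, 1, function(v) signal::filtfilt(bf, v)))
  n_max <- round(max_duration * fs)
  if (ncol(data) > n_max) data <- data[, seq_len(n_max), drop = FALSE]
  nd_log("standardize", shape = dim(rec$data), fs_in = rec$fs, fs_out = fs,
         band = c(low, high), order = order)
  meta <- rec$meta
  meta$standardized <- list(band = c(low, high), order = order,
                            fs_original = rec$fs)
  recording(data, fs = fs, labels = rec$labels, centre_id = rec$centre_id,
            meta = meta)
}

# Small-denominator rational approximation of a resampling ratio.
ratio_pq <- function(p, q) {
  if (abs(p - round(p)) < 1e-9 && abs(q - round(q)) < 1e-9) {
    p <- round(p); q <- round(q)
    g <- function(a, b) if (b == 0) a else g(b, a %% b)
    d <- g(p, q)
    return(c(p / d, q / d))
  }
  stop("non-integer sampling rates are not supported")
}

#' Z-score harmonisation of recordings
#'
#' Per-channel z-transform, (v - mean(v)) / sd(v), applied within each
#' channel of each recording. The transform is per channel, so grouping by
#' recruitment centre affects bookkeeping only. Channels with (near-)zero
#' variance are flagged in `meta$bad_channels` and left centred but unscaled.
#'
#' @param recs A [recording()] or list of recordings.
#' @return Object of the same shape with harmonised data.
#' @export
zscore_harmonize <- function(recs) {
  single <- inherits(recs, "recording")
  if (single) recs <- list(recs)
  out <- lapply(recs, function(rec) {
    mu <- rowMeans(rec$data)
    sdv <- apply(rec$data, 1, stats::sd)
    bad <- sdv < 1e-12
    sdv[bad] <- 1
    data <- (rec$data - mu) / sdv
    meta <- rec$meta
    if (any(bad)) {
      meta$bad_channels <- rec$labels[bad]
      warning("constant channel(s) excluded from z-scoring: ",
              paste(rec$labels[bad], collapse = ", "))
    }
    recording(data, fs = rec$fs, labels = rec$labels,
              centre_id = rec$centre_id, meta = meta)
  })
  if (single) out[[1]] else out
}

#' Merge atlas-region channels into ROIs
#'
#' Each output row is the unweighted mean of its member-region rows. When the
#' recording is already labelled by ROI names the map is the identity. The
#' sentinel "all" ROI (mean of every region row) is appended on request.
#'
#' @param rec A [recording()].
#' @param map A `roi_map` (default [default_roi_map()]).
#' @param include_all Append the "all ROIs" mean row.
#' @param strict Error on unmapped channel labels (otherwise drop with a flag).
#' @return A [recording()] with one row per ROI.
#' @export
map_to_rois <- function(rec, map = default_roi_map(), include_all = FALSE,
                        strict = TRUE) {
  stopifnot(inherits(rec, "recording"))
  rois <- unique(map$roi)
  if (all(rec$labels %in% rois)) {
    out <- rec
  } else {
    unmapped <- setdiff(rec$labels, map$region)
    if (length(unmapped)) {
      if (strict) stop("mapping error: unmapped labels: ",
                       paste(unmapped, collapse = ", "))
      rec$data <- rec$data[!rec$labels %in% unmapped, , drop = FALSE]
      rec$labels <- setdiff(rec$labels, unmapped)
    }
    roi_of <- map$roi[match(rec$labels, map$region)]
    present <- unique(map$roi[map$roi %in% roi_of])
    data <- t(vapply(present, function(r) {
      colMeans(rec$data[roi_of == r, , drop = FALSE])
    }, numeric(ncol(rec$data))))
    out <- recording(data, fs = rec$fs, labels = present,
                     centre_id = rec$centre_id, meta = rec$meta)
  }
  if (include_all && !"all" %in% out$labels) {
    out <- recording(rbind(out$data, all = colMeans(rec$data)),
                     fs = out$fs, labels = c(out$labels, "all"),
                     centre_id = out$centre_id, meta = out$meta)
  }
  out
}

#' Segment a recording into fixed-length epochs
#'
#' Contiguous, non-overlapping epochs; a partial trailing epoch is dropped.
#'
#' @param rec A [recording()].
#' @param epoch_length Epoch length, seconds (> 0).
#' @return An `epoched_recording`: `epochs` array
#'   \[epochs x channels x samples\], `epoch_length`, `fs`, `labels`.
#' @export
epoch_signal <- function(rec, epoch_length = 1) {
  stopifnot(inherits(rec, "recording"))
  if (epoch_length <= 0) stop("spec error: epoch_length must be > 0")
  spe <- round(epoch_length * rec$fs)
  n_ep <- floor(ncol(rec$data) / spe)
  if (n_ep < 1) stop("length error: recording shorter than one epoch")
  epochs <- array(0, dim = c(n_ep, nrow(rec$data), spe))
  for (e in seq_len(n_ep)) {
    epochs[e, , ] <- rec$data[, ((e - 1) * spe + 1):(e * spe)]
  }
  structure(list(epochs = epochs, epoch_length = epoch_length, fs = rec$fs,
                 labels = rec$labels, centre_id = rec$centre_id,
                 meta = rec$meta),
            class = "epoched_recording")
}
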
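# Overall Data Quality (OQD) index.

#' Per-epoch quality flags
#'
#' Labels each 1-s epoch under four criteria, on z-scored input (amplitude
#' thresholds are in z units): (i) constant-amplitude channels or missing /
#' infinite voltages; (ii) unusually high amplitudes (any |z| > `z_max`) or a
#' degenerate peak-to-peak range; (iii) high-frequency noise, i.e. power in
#' `hf_band` exceeding `hf_ratio_max` of broadband power on any channel;
#' (iv) low inter-channel correlation, i.e. more than `corr_channel_fraction`
#' of channels whose maximum absolute Pearson correlation with every other
#' channel is below `corr_min`. An epoch is bad iff any criterion fires.
#'
#' @param ep An `epoched_recording` (see [epoch_signal()]).
#' @param z_max Amplitude threshold in z units.
#' @param p2p_min Minimum peak-to-peak range (z units) before an epoch channel
#'   counts as degenerate.
#' @param hf_band,broadband High-frequency and broadband ranges, Hz.
#' @param hf_ratio_max Maximal tolerated hf/broadband power ratio.
#' @param corr_min,corr_channel_fraction Criterion (iv) thresholds.
#' @return Data frame with one row per epoch: logical columns
#'   `constant_or_nonfinite`, `amplitude`, `hf_noise`, `low_correlation`, `bad`.
#' @export
epoch_quality_flags <- function(ep, z_max = 5, p2p_min = 1e-6,
                                hf_band = c(25, 40), broadband = c(0.5, 40),
                                hf_ratio_max = 0.5, corr_min = 0.2,
                                corr_channel_fraction = 0.25) {
  stopifnot(inherits(ep, "epoched_recording"))
  n_ep <- dim(ep$epochs)[1]
  n_ch <- dim(ep$epochs)[2]
  spe <- dim(ep$epochs)[3]
  f <- (0:(spe %/% 2)) * ep$fs / spe
  in_hf <- f >= hf_band[1] & f <= hf_band[2]
  in_bb <- f >= broadband[1] & f <= broadband[2]
  flags <- data.frame(
    epoch = seq_len(n_ep),
    constant_or_nonfinite = FALSE, amplitude = FALSE,
    hf_noise = FALSE, low_correlation = FALSE
  )
  for (e in seq_len(n_ep)) {
    x <- ep$epochs[e, , , drop = TRUE]
    if (n_ch == 1) x <- matrix(x, 1, spe)
    if (any(!is.finite(x))) {
      flags$constant_or_nonfinite[e] <- TRUE
      next
    }
    p2p <- apply(x, 1, function(v) diff(range(v)))
    if (any(p2p == 0)) flags$constant_or_nonfinite[e] <- TRUE
    if (any(abs(x) > z_max) || any(p2p < p2p_min)) flags$amplitude[e] <- TRUE
    pw <- abs(stats::mvfft(t(x)))^2
    pw <- pw[seq_along(f), , drop = FALSE]
    hf_ratio <- colSums(pw[in_hf, , drop = FALSE]) /
      pmax(colSums(pw[in_bb, , drop = FALSE]), 1e-300)
    if (any(hf_ratio > hf_ratio_max)) flags$hf_noise[e] <- TRUE
    if (n_ch > 1) {
      ok <- p2p > 0
      if (sum(ok) > 1) {
        cm <- abs(stats::cor(t(x[ok, , drop = FALSE])))
        diag(cm) <- 0
        frac_low <- mean(apply(cm, 1, max) < corr_min)
        # channels with zero variance count as uncorrelated
        frac_low <- (frac_low * sum(ok) + sum(!ok)) / n_ch
      } else {
        frac_low <- 1
      }
      if (frac_low > corr_channel_fraction) flags$low_correlation[e] <- TRUE
    }
  }
  flags$bad <- flags$constant_or_nonfinite | flags$amplitude |
    flags$hf_noise | flags$low_correlation
  flags
}

#' Summarise per-epoch flags into the OQD index
#'
#' OQD is the percentage of good epochs, discretised as: excellent for
#' OQD >= 90, good for 90 > OQD >= 80, poor for 80 > OQD >= 60, bad below 60.
#'
#' @param flags Data frame from [epoch_quality_flags()] (or any data frame
#'   with a logical `bad` column).
#' @return A `quality_report` list: `flags`, `oqd`, `category`, `n_epochs`.
#' @export
oqd_summary <- function(flags) {
  if (is.null(flags$bad) || nrow(flags) == 0) {
    stop("domain error: need at least one epoch with a 'bad' flag")
  }
  oqd <- 100 * mean(!flags$bad)
  category <- oqd_category(oqd)
  structure(list(flags = flags, oqd = oqd, category = category,
                 n_epochs = nrow(flags)),
            class = "quality_report")
}

#' OQD category from the percentage value
#'
#' @param oqd OQD percentage(s) in \[0, 100\].
#' @return Character vector: "excellent", "good", "poor" or "bad".
#' @export
oqd_category <- function(oqd) {
  stopifnot(all(oqd >= 0 & oqd <= 100))
  ifelse(oqd >= 90, "excellent",
         ifelse(oqd >= 80, "good",
                ifelse(oqd >= 60, "poor", "bad")))
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("<quality_report> OQD %.1f%% (%s), %d epochs\n",
              x$oqd, x$category, x$n_epochs))
  invisible(x)
}

#' Assess the quality of a recording
#'
#' Convenience wrapper: z-scores (if not already standardised), epochs into
#' 1-s segments, flags and summarises.
#'
#' @param rec A [recording()].
#' @param ... Passed to [epoch_quality_flags()].
#' @return A `quality_report`.
#' @export
assess_quality <- function(rec, ...) {
  zr <- suppressWarnings(zscore_harmonize(rec))
  oqd_summary(epoch_quality_flags(epoch_signal(zr, 1), ...))
}
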
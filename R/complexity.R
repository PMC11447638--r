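# Complexity metrics: Higuchi fractal dimension, permutation entropy,
# Wiener entropy (spectral flatness), spectral structure variability, and the
# uniform folded complexity scale.

#' Higuchi fractal dimension
#'
#' Curve-length scaling estimate of the fractal dimension of a time series:
#' mean curve length L(k) over reconstruction offsets is computed for
#' k = 1..kmax and FD is the slope of log L(k) against log(1/k). A smooth
#' line gives 1, uncorrelated noise 2.
#'
#' @param x Numeric time series of length >= 4 * kmax.
#' @param kmax Maximum time lag (default 8, standard for EEG).
#' @return FD in \[1, 2\]; a constant series returns 1 with attribute
#'   `degenerate = TRUE`.
#' @export
higuchi_fd <- function(x, kmax = 8) {
  n <- length(x)
  if (n < 4 * kmax) stop("length error: need length >= 4 * kmax")
  if (diff(range(x)) == 0) {
    return(structure(1.0, degenerate = TRUE))
  }
  lk <- numeric(kmax)
  for (k in seq_len(kmax)) {
    d <- abs(x[(k + 1):n] - x[1:(n - k)])
    m_idx <- ((seq_along(d) - 1L) %% k) + 1L
    sums <- rowsum(d, m_idx)[, 1]
    m <- as.integer(names(sums))
    n_terms <- floor((n - m) / k)
    lm <- sums * (n - 1) / (n_terms * k) / k
    lk[k] <- mean(lm)
  }
  stats::coef(stats::lm(log(lk) ~ log(1 / seq_len(kmax))))[[2]]
}

#' Permutation entropy
#'
#' Shannon entropy (natural log) of the distribution of ordinal rank patterns
#' of order `m` at delay `tau` (Bandt-Pompe), normalised by log(m!). Ties are
#' broken by temporal order (the earlier sample ranks lower).
#'
#' @param x Numeric time series.
#' @param m Embedding order (>= 2).
#' @param tau Embedding delay.
#' @param normalize Divide by log(m!).
#' @return Entropy in \[0, 1\] (normalised) or nats.
#' @export
permutation_entropy <- function(x, m = 3, tau = 1, normalize = TRUE) {
  if (m < 2) stop("spec error: order m must be >= 2")
  n <- length(x)
  n_win <- n - (m - 1) * tau
  if (n_win < 1) stop("length error: series too short for (m, tau)")
  if (m == 3) {
    a <- x[seq_len(n_win)]
    b <- x[seq_len(n_win) + tau]
    cc <- x[seq_len(n_win) + 2 * tau]
    # rank of each element; strict '>' against earlier samples, '>=' against
    # later ones, so equal values rank in temporal order
    ra <- (a > b) + (a > cc)
    rb <- (b >= a) + (b > cc)
    rc <- (cc >= a) + (cc >= b)
    code <- ra * 9L + rb * 3L + rc
  } else {
    idx <- outer(seq_len(n_win), seq(0, (m - 1) * tau, by = tau), `+`)
    code <- apply(idx, 1, function(ii) paste(order(x[ii]), collapse = "."))
  }
  p <- tabulate(factor(code))
  p <- p / sum(p)
  h <- -sum(p * log(p))
  if (normalize) h / log(factorial(m)) else h
}

#' Wiener entropy (spectral flatness)
#'
#' Geometric over arithmetic mean of power spectral density bins: 1 for a
#' flat (white-noise-like) spectrum, near 0 for a tone.
#'
#' @param psd Non-negative spectrum (e.g. the 0.5-40 Hz analysis bins), or a
#'   `spectral_profile` from [welch_psd()] whose analysis-range bins are used.
#' @param floor_eps Floor applied to zero bins before the geometric mean;
#'   when applied the result carries attribute `floored = TRUE`.
#' @return Flatness in \[0, 1\].
#' @export
wiener_entropy <- function(psd, floor_eps = 1e-30) {
  if (inherits(psd, "spectral_profile")) psd <- analysis_psd(psd)
  if (any(psd < 0)) stop("psd must be non-negative")
  if (all(psd == 0)) stop("degenerate input: all-zero spectrum")
  floored <- any(psd == 0)
  p <- pmax(psd, floor_eps)
  v <- exp(mean(log(p))) / mean(p)
  if (floored) structure(v, floored = TRUE) else v
}

#' Spectral structure variability
#'
#' Short-time spectra (Hann-windowed) are computed on `window`-second
#' segments with the given overlap and normalised to unit length; SSV is the
#' mean over consecutive window pairs of one minus their cosine similarity.
#' Stationary signals give ~0; signals whose spectral content changes from
#' window to window approach 1.
#'
#' @param x Numeric time series.
#' @param fs Sampling rate, Hz.
#' @param window Window length, seconds.
#' @param overlap Fractional overlap between consecutive windows.
#' @param range Frequency range, Hz, over which spectra are compared.
#' @return SSV >= 0.
#' @export
spectral_structure_variability <- function(x, fs, window = 2, overlap = 0.5,
                                           range = c(0.5, 40)) {
  nwin <- round(window * fs)
  step <- max(1, round(nwin * (1 - overlap)))
  if (length(x) < nwin + 2 * step) stop("length error: need at least 3 windows")
  starts <- seq(1, length(x) - nwin + 1, by = step)
  w <- hann_window(nwin)
  f <- (0:(nwin %/% 2)) * fs / nwin
  keep <- f >= range[1] & f <= range[2]
  spectra <- vapply(starts, function(s) {
    seg <- x[s:(s + nwin - 1)]
    pw <- abs(stats::fft((seg - mean(seg)) * w))^2
    pw <- pw[seq_along(f)][keep]
    nrm <- sqrt(sum(pw^2))
    if (nrm == 0) rep(0, sum(keep)) else pw / nrm
  }, numeric(sum(keep)))
  cs <- colSums(spectra[, -1, drop = FALSE] *
                  spectra[, -ncol(spectra), drop = FALSE])
  mean(1 - cs)
}

#' Fold standardised values onto the uniform complexity scale
#'
#' Applies the reversal rule to already-standardised values: z-scores above
#' `threshold` are sign-flipped, all others pass through. The resulting scale
#' is bounded above by `threshold`: both extremes (overly regular and overly
#' noisy signals) map low, mid-range values stay high.
#'
#' @param z Standardised values.
#' @param threshold Fold point in SD units (default 1.2).
#' @return Folded values.
#' @export
fold_scale <- function(z, threshold = 1.2) {
  ifelse(z > threshold, -z, z)
}

#' Uniform complexity scale across subjects
#'
#' Standardises one metric's per-subject values (z-score across subjects) and
#' reverses the high tail: z > `threshold` becomes -z. Low values thus mark
#' atypical signals at either extreme and high values normal ones.
#'
#' @param values Per-subject metric values (>= 2 distinct).
#' @param threshold Fold point in SD units (default 1.2).
#' @return Folded z-scores, max <= `threshold` by construction.
#' @export
uniform_complexity_scale <- function(values, threshold = 1.2) {
  if (length(values) < 2 || stats::sd(values) == 0) {
    stop("domain error: need >= 2 distinct values")
  }
  fold_scale(zstd(values), threshold)
}

#' All four complexity metrics for one recording
#'
#' @param rec A standardised [recording()] (ROI rows).
#' @param kmax,pe_order,pe_tau,ssv_window,ssv_overlap Metric parameters.
#' @return Data frame with one row per ROI: `roi`, `fd`, `pe`, `we`, `ssv`.
#' @export
complexity_vector <- function(rec, kmax = 8, pe_order = 3, pe_tau = 1,
                              ssv_window = 2, ssv_overlap = 0.5) {
  stopifnot(inherits(rec, "recording"))
  rows <- lapply(seq_len(nrow(rec$data)), function(i) {
    x <- rec$data[i, ]
    sp <- welch_psd(x, rec$fs)
    data.frame(
      roi = rec$labels[i],
      fd = as.numeric(higuchi_fd(x, kmax)),
      pe = permutation_entropy(x, pe_order, pe_tau),
      we = as.numeric(wiener_entropy(sp)),
      ssv = spectral_structure_variability(x, rec$fs, ssv_window, ssv_overlap),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
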
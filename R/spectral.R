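# Welch spectral estimation, band powers with canonical and subject-specific
# schemes, spectral landmarks (IAF, TF), and Lorentzian aperiodic
# parameterisation.

hann_window <- function(n) 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / n))

#' Welch power spectral density
#'
#' One-sided PSD via Welch's method: `seg`-second Hann-windowed segments with
#' the given overlap, each zero-padded to `pad` seconds so the grid spacing is
#' `1/pad` Hz (0.5 Hz at the defaults), mean-detrended per segment, scaled as
#' a density (the integral over frequency approximates signal variance). The
#' normalised PSD (nPSD) is computed over the analysis `range` and sums to 1
#' there.
#'
#' @param x Numeric time series (>= `pad` seconds).
#' @param fs Sampling rate, Hz.
#' @param seg Segment length, seconds.
#' @param overlap Fractional overlap.
#' @param pad Zero-padded segment length, seconds.
#' @param range Analysis range, Hz.
#' @param average Segment averaging: `"mean"` (classical) or `"median"`
#'   (robust to transient artifacts; corrected by 1/ln 2, the median of a
#'   unit-mean exponential, so stochastic spectra stay unbiased).
#' @return A `spectral_profile`: `freqs` (full one-sided grid), `psd`, `npsd`
#'   (NA outside `range`), `range`, `df`, `fs`, `n_segments`.
#' @export
welch_psd <- function(x, fs, seg = 1, overlap = 0.5, pad = 2,
                      range = c(0.5, 40), average = c("mean", "median")) {
  average <- match.arg(average)
  nseg <- round(seg * fs)
  nfft <- round(pad * fs)
  if (length(x) < nfft) stop("length error: need at least ", pad, " s of data")
  step <- max(1, round(nseg * (1 - overlap)))
  starts <- seq(1, length(x) - nseg + 1, by = step)
  w <- hann_window(nseg)
  u <- sum(w^2)
  nf <- nfft %/% 2 + 1
  pws <- matrix(0, nf, length(starts))
  for (i in seq_along(starts)) {
    segx <- x[starts[i]:(starts[i] + nseg - 1)]
    segx <- (segx - mean(segx)) * w
    pw <- abs(stats::fft(c(segx, numeric(nfft - nseg))))^2
    pws[, i] <- pw[seq_len(nf)]
  }
  psd <- if (average == "mean") {
    rowMeans(pws) / (fs * u)
  } else {
    apply(pws, 1, stats::median) / (fs * u * log(2))
  }
  psd[2:(nf - 1)] <- 2 * psd[2:(nf - 1)]   # one-sided doubling, not DC/Nyquist
  freqs <- (0:(nf - 1)) * fs / nfft
  in_range <- freqs >= range[1] & freqs <= range[2]
  npsd <- rep(NA_real_, nf)
  npsd[in_range] <- psd[in_range] / sum(psd[in_range])
  structure(list(freqs = freqs, psd = psd, npsd = npsd, range = range,
                 df = fs / nfft, fs = fs, n_segments = length(starts)),
            class = "spectral_profile")
}

#' @export
print.spectral_profile <- function(x, ...) {
  cat(sprintf("<spectral_profile> %.2g-Hz grid, range %g-%g Hz, %d segments\n",
              x$df, x$range[1], x$range[2], x$n_segments))
  invisible(x)
}

#' Squared-magnitude response of the standardisation filter
#'
#' Two-pass (zero-phase) power gain |H(f)|^4 of the Butterworth band-pass
#' used by [standardize_recording()], for deconvolving its imprint from PSD
#' estimates before aperiodic parameterisation.
#'
#' @param freqs Frequencies at which to evaluate, Hz.
#' @param low,high,order Filter parameters as in [standardize_recording()].
#' @param fs Sampling rate the filter ran at, Hz.
#' @return Power gain values in (0, 1\].
#' @export
filter_power_gain <- function(freqs, low = 0.5, high = 40, order = 8,
                              fs = 512) {
  bf <- signal::butter(order / 2, c(low, high) / (fs / 2), type = "pass")
  h <- signal::freqz(bf, Fs = fs, n = 4096)
  stats::approx(h$f, pmin(abs(h$h)^4, 1), xout = freqs, rule = 2)$y
}

# PSD restricted to the analysis range.
analysis_psd <- function(sp) {
  sp$psd[sp$freqs >= sp$range[1] & sp$freqs <= sp$range[2]]
}
analysis_freqs <- function(sp) {
  sp$freqs[sp$freqs >= sp$range[1] & sp$freqs <= sp$range[2]]
}

#' Detect spectral landmarks: IAF and TF
#'
#' The individual alpha peak frequency (IAF) is the frequency of maximum nPSD
#' within `iaf_window`; the theta/alpha transition frequency (TF) is the
#' frequency of minimum nPSD within `tf_window`, constrained below the IAF.
#' Each landmark must be a local extremum of the spectrum; otherwise the
#' canonical default (IAF 10 Hz, TF 6 Hz) is returned with a fallback flag.
#'
#' @param sp A `spectral_profile`.
#' @param iaf_window,tf_window Search windows, Hz.
#' @return List with `iaf`, `tf`, and logical `fallback` (named for each).
#' @export
detect_landmarks <- function(sp, iaf_window = c(7.5, 12.5),
                             tf_window = c(4, 8)) {
  stopifnot(inherits(sp, "spectral_profile"))
  f <- sp$freqs
  p <- sp$psd
  local_max <- function(i) i > 1 && i < length(p) &&
    p[i] > p[i - 1] && p[i] > p[i + 1]
  local_min <- function(i) i > 1 && i < length(p) &&
    p[i] < p[i - 1] && p[i] < p[i + 1]
  fallback <- c(iaf = FALSE, tf = FALSE)
  win <- which(f >= iaf_window[1] & f <= iaf_window[2])
  i_max <- win[which.max(p[win])]
  if (local_max(i_max)) {
    iaf <- f[i_max]
  } else {
    iaf <- 10
    fallback["iaf"] <- TRUE
  }
  win <- which(f >= tf_window[1] & f <= tf_window[2] & f < iaf)
  if (length(win)) {
    i_min <- win[which.min(p[win])]
    if (local_min(i_min)) {
      tf <- f[i_min]
    } else {
      tf <- 6
      fallback["tf"] <- TRUE
    }
  } else {
    tf <- 6
    fallback["tf"] <- TRUE
  }
  list(iaf = iaf, tf = tf, fallback = fallback)
}

#' Canonical EEG frequency bands
#'
#' delta 1.5-6, theta 6.5-8, alpha1 8.5-10, alpha2 10.5-12, beta1 12.5-18,
#' beta2 18.5-21, beta3 21.5-30, gamma 30-40 Hz.
#'
#' @return Named list of c(low, high) pairs.
#' @export
canonical_bands <- function() {
  list(delta = c(1.5, 6), theta = c(6.5, 8), alpha1 = c(8.5, 10),
       alpha2 = c(10.5, 12), beta1 = c(12.5, 18), beta2 = c(18.5, 21),
       beta3 = c(21.5, 30), gamma = c(30, 40))
}

#' Subject-specific frequency bands from IAF and TF
#'
#' delta \[TF-4, TF-2), theta \[TF-2, TF), alpha_low \[TF, IAF),
#' alpha_high \[IAF, IAF+2\]; beta and gamma follow the canonical division.
#'
#' @param iaf,tf Landmarks in Hz (IAF > TF required).
#' @return Named list of c(low, high) pairs.
#' @export
subject_bands <- function(iaf, tf) {
  if (!(iaf > tf)) stop("landmarks invalid: IAF must exceed TF")
  cb <- canonical_bands()
  list(delta = c(tf - 4, tf - 2), theta = c(tf - 2, tf),
       alpha_low = c(tf, iaf), alpha_high = c(iaf, iaf + 2),
       beta1 = cb$beta1, beta2 = cb$beta2, beta3 = cb$beta3,
       gamma = cb$gamma)
}

# Assign each analysis bin to at most one band. Bands are closed intervals as
# printed; a bin shared by two adjacent bands is given to the higher band.
# Contiguous schemes therefore behave as closed-left half-open intervals.
band_membership <- function(f, bands) {
  member <- rep(NA_character_, length(f))
  for (nm in names(bands)) {     # later (higher) bands overwrite shared edges
    b <- bands[[nm]]
    member[f >= b[1] & f <= b[2]] <- nm
  }
  member
}

#' Band powers from a spectral profile
#'
#' Two summaries per band: the mean nPSD of in-band bins ("equivalent percent
#' power") and the relative power density, 100 times the in-band nPSD sum over
#' the total nPSD.
#'
#' @param sp A `spectral_profile`.
#' @param scheme `"canonical"` or `"subject"`.
#' @param landmarks Result of [detect_landmarks()] (required for the
#'   subject-specific scheme).
#' @param bands Optional explicit named list of bands, overriding `scheme`.
#' @return Data frame: `band`, `mean_npsd`, `rel_power`; empty bands give NA
#'   with attribute `empty_bands`.
#' @export
band_powers <- function(sp, scheme = c("canonical", "subject"),
                        landmarks = NULL, bands = NULL) {
  stopifnot(inherits(sp, "spectral_profile"))
  if (is.null(bands)) {
    scheme <- match.arg(scheme)
    bands <- if (scheme == "canonical") {
      canonical_bands()
    } else {
      if (is.null(landmarks)) stop("subject scheme requires landmarks")
      subject_bands(landmarks$iaf, landmarks$tf)
    }
  }
  f <- analysis_freqs(sp)
  np <- sp$npsd[sp$freqs >= sp$range[1] & sp$freqs <= sp$range[2]]
  member <- band_membership(f, bands)
  total <- sum(np)
  out <- data.frame(band = names(bands),
                    mean_npsd = NA_real_, rel_power = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(bands)) {
    sel <- !is.na(member) & member == names(bands)[i]
    if (any(sel)) {
      out$mean_npsd[i] <- mean(np[sel])
      out$rel_power[i] <- 100 * sum(np[sel]) / total
    }
  }
  if (anyNA(out$rel_power)) {
    attr(out, "empty_bands") <- out$band[is.na(out$rel_power)]
  }
  out
}

# ---- Lorentzian aperiodic fit -------------------------------------------

ap_model <- function(f, par) par[1] - log10(par[2] + f^par[3])

# Least-squares Lorentzian fit in log10 space with multi-start bounded
# optimisation. y = log10(psd).
fit_lorentzian <- function(f, y, chi_max = 8, knee_max = 1e4) {
  sse <- function(par) {
    r <- y - ap_model(f, par)
    sum(r * r)
  }
  span <- (y[1] - y[length(y)]) / log10(f[length(f)] / f[1])
  chi0 <- min(max(span, 0.05), chi_max)
  starts <- list(
    c(y[1] + log10(0 + f[1]^chi0), 0, chi0),
    c(y[1] + log10(1 + f[1]^chi0), 1, chi0),
    c(y[1] + log10(10 + f[1]^chi0), 10, max(chi0, 1)),
    c(y[1] + log10(100 + f[1]^chi0), 100, max(chi0, 2))
  )
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      stats::nlminb(st, sse,
                    lower = c(-30, 0, 0), upper = c(30, knee_max, chi_max),
                    control = list(abs.tol = 0, rel.tol = 1e-14,
                                   x.tol = 1e-14, iter.max = 500)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$objective < best$objective)) {
      best <- fit
    }
  }
  best
}

gauss_model <- function(f, p) p[2] * exp(-(f - p[1])^2 / (2 * p[3]^2))

# Lower-envelope iteration: refit using only bins at or below the current
# aperiodic estimate, where oscillatory power cannot lie. Robust to peaks
# that occupy a large share of the fit range.
envelope_fit <- function(f, y, n_iter = 3) {
  fit <- fit_lorentzian(f, y)
  if (is.null(fit)) return(NULL)
  for (i in seq_len(n_iter)) {
    r <- y - ap_model(f, fit$par)
    mask <- r <= 1e-9
    if (sum(mask) < 10) break
    fit2 <- fit_lorentzian(f[mask], y[mask])
    if (is.null(fit2)) break
    fit <- fit2
  }
  fit
}

# Quantile-trimmed robust fit: drop the quarter of bins bulging most above
# the first pass and refit. Near-unbiased when peaks are small.
trimmed_fit <- function(f, y) {
  fit0 <- fit_lorentzian(f, y)
  if (is.null(fit0)) return(NULL)
  r <- y - ap_model(f, fit0$par)
  mask <- r <= stats::quantile(r, 0.75)
  fit1 <- fit_lorentzian(f[mask], y[mask])
  if (is.null(fit1)) fit0 else fit1
}

# Contiguous run around the residual maximum that stays above half height.
contiguous_halfspan <- function(resid, i_max) {
  h2 <- resid[i_max] / 2
  lo <- i_max
  hi <- i_max
  n <- length(resid)
  while (lo > 1 && resid[lo - 1] >= h2) lo <- lo - 1
  while (hi < n && resid[hi + 1] >= h2) hi <- hi + 1
  c(lo, hi)
}

# Extract Gaussian peaks from the residual against an anchor aperiodic fit.
# Detection threshold is median + thr * MAD of the initial residual.
extract_peaks <- function(f, y, anchor_par, max_peaks, thr, pw) {
  resid <- y - ap_model(f, anchor_par)
  med0 <- stats::median(resid)
  sig0 <- stats::mad(resid)
  peaks <- list()
  for (i in seq_len(max_peaks)) {
    i_max <- which.max(resid)
    if (sig0 == 0 || resid[i_max] <= med0 + thr * sig0) break
    ctr0 <- f[i_max]
    ht0 <- resid[i_max]
    span <- contiguous_halfspan(resid, i_max)
    bw0 <- max((f[span[2]] - f[span[1]]) / 2.355, pw[1])
    g_sse <- function(q) sum((resid - gauss_model(f, q))^2)
    gfit <- tryCatch(
      stats::nlminb(c(ctr0, ht0, min(bw0, pw[2])), g_sse,
                    lower = c(max(ctr0 - 2, min(f)), 0, pw[1]),
                    upper = c(min(ctr0 + 2, max(f)), 2 * ht0, pw[2])),
      error = function(e) NULL)
    if (is.null(gfit)) break
    peaks[[length(peaks) + 1]] <- gfit$par
    resid <- resid - gauss_model(f, gfit$par)
  }
  peaks
}

peak_sum <- function(f, peaks) {
  if (length(peaks)) {
    Reduce(`+`, lapply(peaks, function(q) gauss_model(f, q)))
  } else rep(0, length(f))
}

#' Parameterise a power spectrum into aperiodic and oscillatory parts
#'
#' Iterative fit in log10 space of the Lorentzian background
#' A(F) = b - log10(k + F^chi) plus Gaussian oscillatory peaks. Two fitting
#' paths are run: (A) a quantile-trimmed robust fit with a plain final refit
#' of the peak-subtracted spectrum (near-unbiased when oscillations are
#' small), and (B) a lower-envelope fit anchored on the bins that oscillatory
#' power cannot inflate, with the final refit excluding peak-dominated bins
#' (robust when broad peaks cover much of the range). The path whose
#' aperiodic component leaves less median-centred negative-residual energy is
#' reported -- oscillations only add power, so a correct background never
#' leaves large negative residuals.
#'
#' Peaks are detected largest-first while the residual maximum exceeds the
#' median + `peak_threshold_sd` robust SDs of the anchor residual, up to
#' `max_peaks`, with widths bounded to `peak_width`. Reported peaks are
#' those with height at least `min_peak_height` (log10 units).
#'
#' @param sp A `spectral_profile`, or a list with `freqs` and `psd`.
#' @param range Fit range, Hz.
#' @param max_peaks Maximum number of Gaussian peaks.
#' @param peak_threshold_sd Peak detection threshold in robust residual SDs.
#' @param peak_width Gaussian width bounds, Hz.
#' @param min_peak_height Minimum reported peak height, log10 units.
#' @return An `aperiodic_fit`: `offset`, `knee`, `exponent`,
#'   `slope` (= -exponent), `peaks` (data frame), `r_squared`, `converged`.
#' @export
fit_aperiodic <- function(sp, range = c(0.5, 40), max_peaks = 6,
                          peak_threshold_sd = 2, peak_width = c(0.5, 12),
                          min_peak_height = 0.05) {
  f <- sp$freqs
  p <- sp$psd
  keep <- f >= range[1] & f <= range[2]
  f <- f[keep]
  p <- p[keep]
  if (any(p <= 0)) stop("psd must be strictly positive on the fit range")
  y <- log10(p)

  fail <- structure(
    list(offset = NA_real_, knee = NA_real_, exponent = NA_real_,
         slope = NA_real_, peaks = NULL, r_squared = NA_real_,
         converged = FALSE),
    class = "aperiodic_fit")

  paths <- list()
  # path A: trimmed anchor, plain final refit
  fa <- trimmed_fit(f, y)
  if (!is.null(fa)) {
    pka <- extract_peaks(f, y, fa$par, max_peaks, peak_threshold_sd,
                         peak_width)
    psa <- peak_sum(f, pka)
    fina <- fit_lorentzian(f, y - psa)
    if (!is.null(fina)) paths$a <- list(fit = fina, ps = psa, peaks = pka)
  }
  # path B: envelope anchor, peak-masked debiased final refit
  fb <- envelope_fit(f, y)
  if (!is.null(fb)) {
    pkb <- extract_peaks(f, y, fb$par, max_peaks, peak_threshold_sd,
                         peak_width)
    psb <- peak_sum(f, pkb)
    yy <- y - psb
    fe <- envelope_fit(f, yy)
    finb <- fe
    if (!is.null(fe)) {
      r <- yy - ap_model(f, fe$par)
      mask <- (r <= stats::median(r) + 2.5 * stats::mad(r)) & (psb < 0.01)
      if (sum(mask) >= 10) {
        f2 <- fit_lorentzian(f[mask], yy[mask])
        if (!is.null(f2)) finb <- f2
      }
      paths$b <- list(fit = finb, ps = psb, peaks = pkb)
    }
  }
  if (!length(paths)) return(fail)
  crit <- vapply(paths, function(pt) {
    r <- (y - pt$ps) - ap_model(f, pt$fit$par)
    r <- r - stats::median(r)
    mean(pmin(r, 0)^2)
  }, numeric(1))
  sel <- if (length(paths) == 2 && crit[["b"]] < 0.7 * crit[["a"]]) "b" else
    names(paths)[1]
  best <- paths[[sel]]
  yhat <- ap_model(f, best$fit$par) + best$ps
  r2 <- 1 - sum((y - yhat)^2) / max(sum((y - mean(y))^2), 1e-300)
  pk <- best$peaks
  if (length(pk)) {
    keep_pk <- vapply(pk, function(q) q[2] >= min_peak_height, TRUE)
    pk <- pk[keep_pk]
  }
  peaks_df <- if (length(pk)) {
    data.frame(centre = vapply(pk, function(q) q[1], numeric(1)),
               height = vapply(pk, function(q) q[2], numeric(1)),
               width = vapply(pk, function(q) q[3], numeric(1)))
  } else NULL
  structure(
    list(offset = best$fit$par[1], knee = best$fit$par[2],
         exponent = best$fit$par[3], slope = -best$fit$par[3],
         peaks = peaks_df, r_squared = r2, converged = TRUE),
    class = "aperiodic_fit")
}

#' @export
print.aperiodic_fit <- function(x, ...) {
  cat(sprintf(
    "<aperiodic_fit> offset %.3f, knee %.3f, exponent %.3f (R2 %.4f), %d peak(s)\n",
    x$offset, x$knee, x$exponent, x$r_squared,
    if (is.null(x$peaks)) 0L else nrow(x$peaks)))
  invisible(x)
}
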
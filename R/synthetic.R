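# Synthetic ROI-level EEG and multi-country cohort generation.
#
# Recordings are synthesised in the frequency domain: white-noise Fourier
# coefficients are shaped to the square root of a target one-sided PSD
#   S(F) = 10^(b - log10(k + F^chi)) + sum_p a_p exp(-(F - f0_p)^2 / (2 w_p^2))
# so the aperiodic parameters and oscillatory peaks of every subject are known
# exactly and recoverable by the spectral module.

#' Specification of one synthetic ROI-level recording
#'
#' @param fs Sampling rate, Hz.
#' @param duration Recording length, seconds; `fs * duration` must be integer.
#' @param offset Aperiodic offset b, log10-power units.
#' @param knee Aperiodic knee k (>= 0), in Hz^exponent units.
#' @param exponent Aperiodic exponent chi (> 0); the log-log slope is -chi.
#' @param peaks Data frame with columns `f0` (centre Hz), `amp` (linear PSD
#'   height) and `bw` (Gaussian width, Hz). At least an alpha peak at the
#'   subject's individual alpha frequency for realistic spectra.
#' @param coupling Fraction (0-1) of each ROI's variance carried by a shared
#'   global broadband component (baseline inter-ROI correlation).
#' @param module_coupling Variance fraction of pair-specific latents shared
#'   along a chain of neighbouring ROIs within each of two modules
#'   (anterior/posterior halves): the modular backbone of the network.
#' @param cross_coupling Variance fraction of pair-specific latents linking
#'   each ROI to its cross-module partner; raises between-module integration
#'   (global efficiency of partialised connectivity).
#' @param noise_sd Standard deviation of additive white measurement noise.
#' @param artifact_epoch_fraction Fraction of 1-s epochs corrupted by an
#'   artifact (one of four failure modes, drawn at random per bad epoch).
#' @return A `signal_spec` list.
#' @export
signal_spec <- function(fs = 512, duration = 300, offset = 0.5, knee = 3,
                        exponent = 1.5,
                        peaks = data.frame(f0 = 10, amp = 0.4, bw = 1.2),
                        coupling = 0.3, module_coupling = 0,
                        cross_coupling = 0, noise_sd = 0,
                        artifact_epoch_fraction = 0) {
  if (exponent <= 0) stop("spec error: exponent must be > 0")
  if (knee < 0) stop("spec error: knee must be >= 0")
  n <- fs * duration
  if (abs(n - round(n)) > 1e-9) stop("spec error: fs * duration must be integer")
  if (artifact_epoch_fraction < 0 || artifact_epoch_fraction > 1) {
    stop("spec error: artifact_epoch_fraction must lie in [0, 1]")
  }
  if (coupling < 0 || module_coupling < 0 || cross_coupling < 0 ||
      coupling + 2 * module_coupling + cross_coupling >= 1) {
    stop("spec error: coupling fractions must be >= 0 and sum below 1")
  }
  structure(list(fs = fs, duration = duration, offset = offset, knee = knee,
                 exponent = exponent, peaks = peaks, coupling = coupling,
                 module_coupling = module_coupling,
                 cross_coupling = cross_coupling, noise_sd = noise_sd,
                 artifact_epoch_fraction = artifact_epoch_fraction),
            class = "signal_spec")
}

#' Lorentzian aperiodic power spectrum
#'
#' One-sided PSD model \eqn{10^{b - \log_{10}(k + F^{\chi})}}.
#'
#' @param f Frequencies, Hz.
#' @param offset,knee,exponent Aperiodic parameters.
#' @return Linear power values; 0 at F = 0 when the model diverges there.
#' @export
aperiodic_psd <- function(f, offset, knee, exponent) {
  s <- 10^(offset - log10(knee + f^exponent))
  s[!is.finite(s)] <- 0
  s
}

# Target one-sided PSD of a signal_spec on frequency grid f.
spec_target_psd <- function(spec, f) {
  s <- aperiodic_psd(f, spec$offset, spec$knee, spec$exponent)
  pk <- spec$peaks
  if (!is.null(pk) && nrow(pk)) {
    for (i in seq_len(nrow(pk))) {
      s <- s + pk$amp[i] * exp(-(f - pk$f0[i])^2 / (2 * pk$bw[i]^2))
    }
  }
  if (spec$noise_sd > 0) s <- s + 2 * spec$noise_sd^2 / spec$fs
  s
}

# One realisation with one-sided PSD S: shape white-noise Fourier amplitudes.
shape_noise <- function(n, fs, s_fun) {
  w <- stats::rnorm(n)
  wf <- stats::fft(w)
  k <- 0:(n - 1)
  f <- pmin(k, n - k) * fs / n     # folded frequency of each bin
  g <- sqrt(s_fun(f) * fs / 2)
  g[1] <- 0                         # no DC power
  Re(stats::fft(wf * g, inverse = TRUE)) / n
}

#' Simulate one multichannel ROI-level recording
#'
#' Each ROI is `sqrt(1 - c) * private + sqrt(c) * common`, with private and
#' common components drawn from the same target spectrum, so the per-ROI PSD
#' equals the specification exactly in expectation while `c` (coupling) sets
#' inter-ROI dependence. Artifact epochs are then injected: per bad 1-s epoch
#' one of four failure modes is chosen at random (large-amplitude burst,
#' flatline, high-frequency noise, channel decorrelation).
#'
#' @param spec A [signal_spec()].
#' @param n_rois Number of ROI rows.
#' @param seed Integer seed (required: reproducibility contract).
#' @param labels Optional ROI labels.
#' @param centre_id Acquisition-site identifier.
#' @return A [recording()]; `meta$truth` holds the generating parameters and
#'   `meta$artifacts` the injected epoch/mode table.
#' @export
simulate_recording <- function(spec, n_rois = 10, seed, labels = NULL,
                               centre_id = "synthetic") {
  stopifnot(inherits(spec, "signal_spec"))
  if (missing(seed)) stop("seed is required")
  n <- as.integer(round(spec$fs * spec$duration))
  with_seed(seed, {
    s_fun <- function(f) spec_target_psd(spec, f)
    cg <- spec$coupling
    cw <- spec$module_coupling
    cx <- spec$cross_coupling
    half <- ceiling(n_rois / 2)
    # pair-specific latents: chain edges within each module half, plus one
    # cross-module edge per ROI pair (i, i + half); these survive
    # partialisation, unlike shared factors
    edges <- list()
    if (cw > 0 && n_rois > 1) {
      for (i in seq_len(n_rois - 1)) {
        if (i != half) edges[[length(edges) + 1]] <- c(i, i + 1, cw)
      }
    }
    if (cx > 0) {
      for (i in seq_len(min(half, n_rois - half))) {
        edges[[length(edges) + 1]] <- c(i, i + half, cx)
      }
    }
    share <- numeric(n_rois)
    for (e in edges) share[e[1:2]] <- share[e[1:2]] + e[3]
    if (any(share + cg >= 1)) stop("spec error: coupling fractions exceed 1")
    common <- if (cg > 0) shape_noise(n, spec$fs, s_fun) else numeric(n)
    edge_latent <- lapply(edges, function(e) shape_noise(n, spec$fs, s_fun))
    data <- matrix(0, n_rois, n)
    for (r in seq_len(n_rois)) {
      private <- shape_noise(n, spec$fs, s_fun)
      x <- sqrt(1 - cg - share[r]) * private + sqrt(cg) * common
      for (j in seq_along(edges)) {
        if (r %in% edges[[j]][1:2]) x <- x + sqrt(edges[[j]][3]) * edge_latent[[j]]
      }
      data[r, ] <- x
    }
    artifacts <- NULL
    if (spec$artifact_epoch_fraction > 0) {
      spe <- as.integer(spec$fs)
      n_ep <- floor(n / spe)
      n_bad <- round(spec$artifact_epoch_fraction * n_ep)
      if (n_bad > 0) {
        bad <- sort(sample.int(n_ep, n_bad))
        modes <- sample(c("burst", "flatline", "hf_noise", "decorrelated"),
                        n_bad, replace = TRUE)
        sd0 <- stats::sd(as.vector(data))
        tt <- (seq_len(spe) - 1) / spec$fs
        for (j in seq_along(bad)) {
          idx <- ((bad[j] - 1) * spe + 1):(bad[j] * spe)
          data[, idx] <- switch(
            modes[j],
            burst = data[, idx] * 8,
            flatline = matrix(data[, idx[1]], n_rois, spe),
            hf_noise = data[, idx] + 6 * sd0 *
              sin(outer(rep(1, n_rois), 2 * pi * 32 * tt) +
                    stats::runif(n_rois, 0, 2 * pi)),
            decorrelated = matrix(stats::rnorm(n_rois * spe, sd = sd0),
                                  n_rois, spe)
          )
        }
        artifacts <- data.frame(epoch = bad, mode = modes)
      }
    }
    recording(data, fs = spec$fs,
              labels = labels %||% paste0("roi", seq_len(n_rois)),
              centre_id = centre_id,
              meta = list(truth = unclass(spec), artifacts = artifacts,
                          seed = seed))
  })
}

#' Effect specification for the cohort generator
#'
#' Effects are expressed on standardised predictors (Gini (x-40)/10, age
#' (x-55)/15, sex x-0.5, education (x-12)/4, MMSE (x-27.5)/2) and act on the
#' generating parameters of each subject's [signal_spec()]. The defaults
#' plant the qualitative inequality pattern the pipeline is meant to detect:
#' a steeper aperiodic exponent (hence lower slope and lower complexity),
#' lower offset, weaker alpha/beta oscillations, and stronger inter-ROI
#' coupling (hence higher network integration) with higher Gini.
#'
#' @param exponent_gini,offset_gini,alpha_gini,beta_gini,coupling_gini Effects
#'   of standardised Gini on the exponent, offset, log10 alpha and beta peak
#'   ratios (height above the aperiodic background at the peak frequency),
#'   and between-module coupling (network integration).
#' @param exponent_age,alpha_age,coupling_age Age effects.
#' @param exponent_sex,exponent_education,exponent_mmse Remaining covariate
#'   effects on the exponent (0 by default).
#' @param gini_age Interaction of standardised Gini and age on the exponent.
#' @param noise Named list of residual SDs for exponent, offset, log-alpha,
#'   log-beta and coupling.
#' @return An `effect_spec` list.
#' @export
effect_spec <- function(exponent_gini = 0.45, offset_gini = -0.2,
                        alpha_gini = -0.15, beta_gini = -0.15,
                        coupling_gini = 0.025,
                        exponent_age = -0.1, alpha_age = -0.1,
                        coupling_age = -0.008,
                        exponent_sex = 0, exponent_education = 0,
                        exponent_mmse = 0, gini_age = 0,
                        noise = list(exponent = 0.08, offset = 0.05,
                                     alpha = 0.08, beta = 0.08,
                                     coupling = 0.01)) {
  spec <- list(exponent_gini = exponent_gini, offset_gini = offset_gini,
               alpha_gini = alpha_gini, beta_gini = beta_gini,
               coupling_gini = coupling_gini, exponent_age = exponent_age,
               alpha_age = alpha_age, coupling_age = coupling_age,
               exponent_sex = exponent_sex,
               exponent_education = exponent_education,
               exponent_mmse = exponent_mmse, gini_age = gini_age,
               noise = noise)
  stopifnot(all(vapply(spec[-length(spec)], is.finite, TRUE)))
  structure(spec, class = "effect_spec")
}

#' Null effect specification (all planted effects zero)
#'
#' @param noise As in [effect_spec()]; residual variation is retained so
#'   parameters vary but are independent of every predictor.
#' @return An `effect_spec`.
#' @export
null_effect_spec <- function(noise = list(exponent = 0.08, offset = 0.05,
                                          alpha = 0.08, beta = 0.08,
                                          coupling = 0.01)) {
  effect_spec(exponent_gini = 0, offset_gini = 0, alpha_gini = 0,
              beta_gini = 0, coupling_gini = 0, exponent_age = 0,
              alpha_age = 0, coupling_age = 0, gini_age = 0, noise = noise)
}

#' Specification of one country in a synthetic cohort
#'
#' @param name Country name.
#' @param n_subjects Number of subjects (>= 1).
#' @param gini Gini coefficient, percent (0-100); alternatively supply
#'   `incomes` and the Gini is computed via [gini_coefficient()].
#' @param gdp GDP per capita (arbitrary units, used as a covariate).
#' @param incomes Optional raw income sample.
#' @param age_mean,age_sd,education_mean,education_sd,mmse_mean,mmse_sd
#'   Sampling distributions for subject covariates.
#' @param p_female Probability a subject is female.
#' @return A `country_spec` list.
#' @export
country_spec <- function(name, n_subjects, gini = NULL, gdp = 20,
                         incomes = NULL, age_mean = 55, age_sd = 15,
                         education_mean = 12, education_sd = 4,
                         mmse_mean = 27.5, mmse_sd = 2, p_female = 0.5) {
  if (n_subjects < 1) stop("spec error: n_subjects must be >= 1")
  if (is.null(gini)) {
    if (is.null(incomes)) stop("supply gini or incomes")
    gini <- gini_coefficient(incomes)
  }
  if (gini < 0 || gini > 100) stop("spec error: gini must lie in [0, 100]")
  structure(list(name = name, n_subjects = n_subjects, gini = gini,
                 gdp = gdp, age_mean = age_mean, age_sd = age_sd,
                 education_mean = education_mean,
                 education_sd = education_sd, mmse_mean = mmse_mean,
                 mmse_sd = mmse_sd, p_female = p_female),
            class = "country_spec")
}

#' Default ten-country cohort layout
#'
#' Ten countries spanning Gini 25-55 percent (the observed range of national
#' income inequality) with GDP loosely anti-correlated with Gini.
#'
#' @param n_per_country Subjects per country.
#' @return List of [country_spec()]s.
#' @export
default_countries <- function(n_per_country = 40) {
  gini <- c(25, 28, 32, 35, 38, 41, 44, 48, 52, 55)
  gdp <- c(55, 48, 42, 35, 28, 22, 18, 14, 10, 8)
  lapply(seq_along(gini), function(i) {
    country_spec(name = sprintf("country%02d", i),
                 n_subjects = n_per_country, gini = gini[i], gdp = gdp[i])
  })
}

# Build one subject's signal_spec from covariates under an effect_spec.
# Oscillatory peak heights are parameterised as ratios above the aperiodic
# background at the peak frequency (the specparam view of peak height), so a
# planted amplitude effect survives per-channel z-scoring.
subject_signal_spec <- function(gini, age, sex, education, mmse, effects,
                                fs, duration, artifact_epoch_fraction) {
  zg <- (gini - 40) / 10
  za <- (age - 55) / 15
  zs <- sex - 0.5
  ze <- (education - 12) / 4
  zm <- if (is.na(mmse)) 0 else (mmse - 27.5) / 2
  e <- effects
  chi <- 1.5 + e$exponent_gini * zg + e$exponent_age * za +
    e$exponent_sex * zs + e$exponent_education * ze + e$exponent_mmse * zm +
    e$gini_age * zg * za + stats::rnorm(1, 0, e$noise$exponent)
  chi <- max(chi, 0.3)
  b <- 0.5 + e$offset_gini * zg + stats::rnorm(1, 0, e$noise$offset)
  alpha_ratio <- 10^(log10(4.5) + e$alpha_gini * zg + e$alpha_age * za +
                       stats::rnorm(1, 0, e$noise$alpha))
  beta_ratio <- 10^(log10(2.5) + e$beta_gini * zg +
                      stats::rnorm(1, 0, e$noise$beta))
  # cross-module links stay weaker than the intra-module backbone (0.12):
  # integration varies below segregation, keeping graph metrics monotone in cx
  cx <- 0.06 + e$coupling_gini * zg + e$coupling_age * za +
    stats::rnorm(1, 0, e$noise$coupling)
  cx <- min(max(cx, 0.01), 0.11)
  iaf <- min(max(10 + stats::rnorm(1, 0, 0.5), 8.5), 11.5)
  amp_a <- alpha_ratio * aperiodic_psd(iaf, b, 3, chi)
  amp_b <- beta_ratio * aperiodic_psd(20, b, 3, chi)
  signal_spec(
    fs = fs, duration = duration, offset = b, knee = 3, exponent = chi,
    peaks = data.frame(f0 = c(iaf, 20), amp = c(amp_a, amp_b),
                       bw = c(1.2, 2.5)),
    coupling = 0.15, module_coupling = 0.12, cross_coupling = cx,
    artifact_epoch_fraction = artifact_epoch_fraction
  )
}

#' Simulate a multi-country cohort
#'
#' Draws covariates per country, maps them through the [effect_spec()] to a
#' per-subject [signal_spec()], and simulates one ROI-level recording per
#' subject. The returned table carries the true generating parameters
#' (`true_*` columns) for recovery tests.
#'
#' @param countries List of [country_spec()]s (>= 2 for any inequality test).
#' @param effects An [effect_spec()].
#' @param seed Integer seed.
#' @param fs,duration,n_rois Recording geometry.
#' @param artifact_epoch_fraction Fraction of corrupted 1-s epochs.
#' @param recordings If `FALSE`, return only the table of covariates and
#'   generating parameters (fast; no signal synthesis).
#' @return List with `table` (a `cohort_table`) and `recordings` (list of
#'   [recording()]s, or `NULL`).
#' @export
simulate_cohort <- function(countries, effects = effect_spec(), seed,
                            fs = 512, duration = 300, n_rois = 10,
                            artifact_epoch_fraction = 0.05,
                            recordings = TRUE) {
  if (length(countries) == 0) stop("spec error: empty country list")
  if (missing(seed)) stop("seed is required")
  stopifnot(inherits(effects, "effect_spec"))
  rows <- list()
  specs <- list()
  with_seed(seed, {
    sid <- 0L
    for (co in countries) {
      stopifnot(inherits(co, "country_spec"))
      for (i in seq_len(co$n_subjects)) {
        sid <- sid + 1L
        age <- min(max(stats::rnorm(1, co$age_mean, co$age_sd), 20), 90)
        sex <- stats::rbinom(1, 1, co$p_female)
        edu <- min(max(stats::rnorm(1, co$education_mean, co$education_sd), 0), 25)
        mmse <- min(max(round(stats::rnorm(1, co$mmse_mean, co$mmse_sd)), 18), 30)
        sp <- subject_signal_spec(co$gini, age, sex, edu, mmse, effects,
                                  fs, duration, artifact_epoch_fraction)
        specs[[sid]] <- sp
        rows[[sid]] <- data.frame(
          subject_id = sprintf("sub%04d", sid), country = co$name,
          gini = co$gini, gdp = co$gdp, age = age, sex = sex,
          education = edu, mmse = mmse,
          true_exponent = sp$exponent, true_offset = sp$offset,
          true_alpha_amp = sp$peaks$amp[1], true_beta_amp = sp$peaks$amp[2],
          true_alpha_ratio = sp$peaks$amp[1] /
            aperiodic_psd(sp$peaks$f0[1], sp$offset, sp$knee, sp$exponent),
          true_coupling = sp$cross_coupling, true_iaf = sp$peaks$f0[1],
          stringsAsFactors = FALSE
        )
      }
    }
  })
  table <- do.call(rbind, rows)
  recs <- NULL
  if (recordings) {
    sub_seeds <- derive_seeds(seed, nrow(table))
    recs <- lapply(seq_len(nrow(table)), function(i) {
      simulate_recording(specs[[i]], n_rois = n_rois, seed = sub_seeds[i],
                         centre_id = table$country[i])
    })
    names(recs) <- table$subject_id
  }
  nd_log("simulate_cohort", n_subjects = nrow(table),
         n_countries = length(countries), fs = fs, duration = duration,
         seed = seed)
  list(table = as_cohort_table(table), recordings = recs, specs = specs)
}
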
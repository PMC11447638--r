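# Welch estimation, landmarks, band powers, aperiodic parameterisation.

test_that("Welch PSD satisfies Parseval for tones and white noise", {
  fs <- 512
  t <- seq_len(fs * 30) / fs
  w <- welch_psd(sin(2 * pi * 10 * t), fs)
  band_power <- sum(w$psd[abs(w$freqs - 10) <= 2]) * w$df
  expect_lt(abs(band_power - 0.5) / 0.5, 0.05)
  with_seed_test(21, {
    x <- rnorm(fs * 30, sd = 2)
    wn <- welch_psd(x, fs)
    expect_lt(abs(sum(wn$psd) * wn$df - 4) / 4, 0.05)
  })
})

test_that("the grid spacing is exactly 0.5 Hz and nPSD is normalised", {
  w <- welch_psd(rnorm(2048), 256)
  expect_equal(w$df, 0.5)
  expect_equal(diff(w$freqs[1:2]), 0.5)
  expect_equal(sum(w$npsd, na.rm = TRUE), 1, tolerance = 1e-12)
  expect_true(all(is.na(w$npsd[w$freqs < 0.5 | w$freqs > 40])))
  expect_error(welch_psd(rnorm(100), 256), "length error")
})

test_that("median-averaged Welch stays calibrated and resists transients", {
  with_seed_test(22, {
    fs <- 256
    x <- rnorm(fs * 60)
    wm <- welch_psd(x, fs, average = "median")
    expect_lt(abs(sum(wm$psd) * wm$df - 1), 0.1)
    # one gross burst barely moves the median spectrum
    xb <- x
    xb[3001:3256] <- xb[3001:3256] * 20
    wb_med <- welch_psd(xb, fs, average = "median")
    wb_mean <- welch_psd(xb, fs, average = "mean")
    dev <- function(w) abs(sum(w$psd) * w$df - 1)
    expect_lt(dev(wb_med), 0.15)
    expect_gt(dev(wb_mean), 1)
  })
})

test_that("landmarks find a synthetic alpha bump and fall back on 1/f", {
  f <- seq(0, 128, by = 0.5)
  bump <- 10^(-log10(1 + f^1.5)) + 0.3 * exp(-(f - 10.5)^2 / (2 * 1.5^2))
  sp <- structure(list(freqs = f, psd = bump, npsd = bump / sum(bump),
                       range = c(0.5, 40)), class = "spectral_profile")
  lm1 <- detect_landmarks(sp)
  expect_lt(abs(lm1$iaf - 10.5), 0.5)
  expect_false(any(lm1$fallback))
  mono <- 10^(-log10(1 + f^1.5))
  sp2 <- structure(list(freqs = f, psd = mono, npsd = mono / sum(mono),
                        range = c(0.5, 40)), class = "spectral_profile")
  lm2 <- detect_landmarks(sp2)
  expect_equal(lm2$iaf, 10)
  expect_equal(lm2$tf, 6)
  expect_true(all(lm2$fallback))
})

test_that("subject-specific bands are anchored at TF and IAF", {
  b <- subject_bands(iaf = 10, tf = 6)
  expect_equal(b$delta, c(2, 4))
  expect_equal(b$theta, c(4, 6))
  expect_equal(b$alpha_low, c(6, 10))
  expect_equal(b$alpha_high, c(10, 12))
  expect_equal(b$beta1, c(12.5, 18))
  expect_error(subject_bands(iaf = 5, tf = 6), "IAF")
})

test_that("band edges shift one-for-one with the synthetic alpha centre", {
  fs <- 512
  iafs <- c(9.5, 10.5)
  lows <- vapply(iafs, function(ia) {
    sp <- signal_spec(fs = fs, duration = 40,
                      peaks = data.frame(f0 = ia, amp = 0.5, bw = 1),
                      coupling = 0)
    rec <- simulate_recording(sp, n_rois = 1, seed = 17)
    lm <- detect_landmarks(welch_psd(rec$data[1, ], fs))
    subject_bands(lm$iaf, lm$tf)$alpha_high[1]
  }, numeric(1))
  expect_equal(lows[2] - lows[1], 1, tolerance = 0.51)
})

test_that("relative power densities sum to 100 over an exhaustive partition", {
  with_seed_test(23, {
    w <- welch_psd(rnorm(512 * 20), 512)
    part <- list(low = c(0.5, 10), mid = c(10.5, 25), high = c(25.5, 40))
    bp <- band_powers(w, bands = part)
    expect_equal(sum(bp$rel_power), 100, tolerance = 1e-9)
  })
})

test_that("a 10 Hz tone concentrates relative power in the alpha bands", {
  fs <- 512
  t <- seq_len(fs * 60) / fs
  with_seed_test(24, {
    x <- sin(2 * pi * 10 * t) + 0.001 * rnorm(length(t))
    bp <- band_powers(welch_psd(x, fs), "canonical")
    a1 <- bp$rel_power[bp$band == "alpha1"]
    expect_equal(bp$band[which.max(bp$rel_power)], "alpha1")
    # window leakage at the band edge splits the remainder into alpha2
    expect_gt(a1 + bp$rel_power[bp$band == "alpha2"], 90)
    expect_gt(a1, 60)
  })
})

test_that("flat spectra spread relative power in proportion to bin counts", {
  f <- seq(0, 128, by = 0.5)
  flat <- rep(1, length(f))
  sp <- model_profile(rep(1, 80))
  bp <- band_powers(sp, "canonical")
  cb <- canonical_bands()
  bins <- vapply(names(cb), function(nm) {
    fr <- seq(0.5, 40, by = 0.5)
    member <- fr >= cb[[nm]][1] & fr <= cb[[nm]][2]
    if (nm == "beta3") member <- member & fr < 30   # shared edge goes to gamma
    sum(member)
  }, numeric(1))
  expect_equal(bp$rel_power, unname(100 * bins / 80), tolerance = 1e-9)
})

test_that("aperiodic fit recovers exact Lorentzian parameters", {
  f <- seq(0.5, 40, by = 0.5)
  ap <- fit_aperiodic(model_profile(10^(1 - log10(0 + f^2))))
  expect_lt(abs(ap$offset - 1), 1e-3)
  expect_lt(abs(ap$knee - 0), 1e-3)
  expect_lt(abs(ap$exponent - 2), 1e-3)
  expect_equal(ap$slope, -ap$exponent)
  expect_gt(ap$r_squared, 0.999)
})

test_that("one oscillatory peak leaves the aperiodic recovery within 5%", {
  f <- seq(0.5, 40, by = 0.5)
  y <- 1 - log10(f^2) + 0.6 * exp(-(f - 10)^2 / (2 * 1.5^2))
  ap <- fit_aperiodic(model_profile(10^y))
  expect_lt(abs(ap$offset - 1) / 1, 0.05)
  expect_lt(abs(ap$exponent - 2) / 2, 0.05)
  expect_gte(nrow(ap$peaks), 1)
  expect_lt(abs(ap$peaks$centre[1] - 10), 0.5)
})

test_that("a flat spectrum fits a near-zero exponent", {
  ap <- fit_aperiodic(model_profile(rep(1, 80)))
  expect_lt(abs(ap$exponent), 0.05)
  expect_error(fit_aperiodic(model_profile(c(rep(1, 79), 0))), "positive")
})

test_that("parameter recovery across the (b, k, chi) grid under 5% noise", {
  f <- seq(0.5, 40, by = 0.5)
  rel <- function(e, t) abs(e - t) / max(abs(t), 1)
  eb <- ek <- ec <- c()
  with_seed_test(25, {
    for (b in c(-1, 0, 1)) for (k in c(0, 5, 25)) for (chi in c(0.5, 1, 2)) {
      for (r in 1:2) {
        psd <- 10^(b - log10(k + f^chi)) * (1 + 0.05 * rnorm(length(f)))
        ap <- fit_aperiodic(model_profile(psd))
        eb <- c(eb, rel(ap$offset, b))
        ek <- c(ek, rel(ap$knee, k))
        ec <- c(ec, rel(ap$exponent, chi))
      }
    }
  })
  expect_lt(median(eb), 0.1)
  expect_lt(median(ek), 0.1)
  expect_lt(median(ec), 0.1)
})
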
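# Permutation testing, FDR, effect sizes, regression, classification.

test_that("permutation test honours its defined limits", {
  expect_equal(permutation_mean_test(0), 1)
  expect_equal(permutation_mean_test(rep(0, 10)), 1)
  p <- permutation_mean_test(rep(1, 30), n_perm = 5000, seed = 3)
  expect_equal(p, 1 / 5001)
})

test_that("permutation test p values are calibrated under the null", {
  with_seed_test(41, {
    ps <- vapply(1:300, function(i)
      permutation_mean_test(rnorm(20), n_perm = 500, seed = i), numeric(1))
    ks <- suppressWarnings(stats::ks.test(ps, "punif"))
    expect_gt(ks$p.value, 0.01)
    expect_lt(abs(mean(ps < 0.05) - 0.05), 0.035)
  })
})

test_that("BH step-up matches the hand-worked examples", {
  expect_identical(bh_fdr(c(.01, .02, .03, .04)), rep(TRUE, 4))
  expect_identical(bh_fdr(c(.04, .04, .04, .5)), rep(FALSE, 4))
  expect_identical(bh_fdr(1), FALSE)
  expect_identical(bh_fdr(numeric(0)), logical(0))
  expect_error(bh_fdr(c(0.5, 1.2)), "p values")
})

test_that("BH step-up equals brute-force evaluation and p.adjust", {
  brute_bh <- function(p, alpha) {
    m <- length(p)
    o <- order(p)
    ok <- which(p[o] <= seq_len(m) * alpha / m)
    rej <- logical(m)
    if (length(ok)) rej[o[1:max(ok)]] <- TRUE
    rej
  }
  with_seed_test(42, {
    grid <- seq(0, 1, by = 0.01)
    for (i in 1:200) {
      m <- sample(1:6, 1)
      p <- sample(grid, m, replace = TRUE)
      flags <- bh_fdr(p, 0.05)
      expect_identical(flags, brute_bh(p, 0.05))
      expect_identical(flags, unname(p.adjust(p, "BH") <= 0.05))
    }
  })
})

test_that("ROI reduction keeps signal ROIs and controls the null", {
  with_seed_test(43, {
    tabs <- matrix(rnorm(8 * 100), nrow = 8,
                   dimnames = list(paste0("roi", 1:8), NULL))
    tabs["roi3", ] <- tabs["roi3", ] + 1
    kept <- reduce_rois(tabs, n_perm = 1000, seed = 7)
    expect_true("roi3" %in% kept)
    null_keeps <- vapply(1:20, function(i) {
      m <- matrix(rnorm(8 * 30), nrow = 8,
                  dimnames = list(paste0("r", 1:8), NULL))
      length(reduce_rois(m, n_perm = 500, seed = i))
    }, numeric(1))
    expect_lte(mean(null_keeps / 8), 0.10)
    expect_identical(reduce_rois(matrix(numeric(0), 0, 0)), character(0))
  })
})

test_that("Cohen's f2 identity and limits", {
  expect_equal(cohens_f2(0), 0)
  expect_equal(round(cohens_f2(0.2996), 4), 0.4278)
  expect_equal(round(cohens_f2(0.16), 2), 0.19)
  expect_error(cohens_f2(1), "domain error")
  r2 <- seq(0.01, 0.9, by = 0.01)
  expect_true(all(diff(cohens_f2(r2)) > 0))
  expect_equal(cohens_f2(1e-8) / 1e-8, 1, tolerance = 1e-6)
})

test_that("regression recovers a noiseless linear outcome", {
  with_seed_test(44, {
    tab <- data.frame(subject_id = sprintf("s%03d", 1:80), country = "x",
                      gini = runif(80, 25, 55), age = rnorm(80, 50, 10),
                      sex = rbinom(80, 1, 0.5), education = rnorm(80, 12, 3),
                      mmse = 28)
    tab$y <- 2 - 0.5 * tab$gini
    # lm warns about the (intended) numerically perfect fit
    fit <- suppressWarnings(hierarchical_regression(tab, "y", "gini"))
    expect_gt(fit$r_squared, 1 - 1e-10)
    expect_lt(fit$coefficients$p_value[1], 1e-10)
    expect_lt(fit$coefficients$estimate[1], 0)
    expect_equal(fit$f_squared, cohens_f2(min(fit$r_squared, 1 - 1e-12)))
    expect_equal(fit$n, 80)
  })
})

test_that("regression supports covariates, interactions, and flags
          collinearity", {
  with_seed_test(45, {
    n <- 200
    tab <- data.frame(subject_id = sprintf("s%03d", 1:n), country = "x",
                      gini = runif(n, 25, 55), age = rnorm(n, 50, 10),
                      sex = rbinom(n, 1, 0.5), education = rnorm(n, 12, 3),
                      mmse = round(runif(n, 24, 30)))
    zg <- scale(tab$gini)[, 1]
    za <- scale(tab$age)[, 1]
    tab$y <- -0.4 * zg + 0.2 * za + 0.3 * zg * za + rnorm(n, 0, 0.3)
    fit <- hierarchical_regression(tab, "y", c("gini", "age", "gini:age"))
    est <- fit$coefficients$estimate
    expect_equal(est, c(-0.4, 0.2, 0.3), tolerance = 0.15)
    expect_lt(fit$coefficients$p_value[3], 0.001)
    tab$gini2 <- tab$gini
    expect_error(hierarchical_regression(tab, "y", c("gini", "gini2")),
                 "rank-deficient|collinear")
  })
})

test_that("regression type-I error is near nominal on null cohorts", {
  with_seed_test(46, {
    hits <- vapply(1:100, function(i) {
      n <- 200
      tab <- data.frame(subject_id = as.character(1:n), country = "x",
                        gini = runif(n, 25, 55), age = rnorm(n, 50, 10),
                        sex = rbinom(n, 1, .5), education = rnorm(n, 12, 3),
                        mmse = 28, y = rnorm(n))
      hierarchical_regression(tab, "y", "gini")$coefficients$p_value[1] < 0.05
    }, logical(1))
    expect_lt(abs(mean(hits) - 0.05), 0.05)
  })
})

test_that("classifier achieves perfect AUC on a separable outcome", {
  with_seed_test(47, {
    n <- 120
    # two country-level point masses: the class boundary cannot fall inside
    # a feature cluster, so discrimination must be perfect
    tab <- data.frame(subject_id = as.character(1:n), country = "x",
                      gini = rep(c(25, 55), each = n / 2),
                      age = rnorm(n, 50, 10), sex = rbinom(n, 1, .5),
                      education = 12, mmse = 28)
    tab$y <- tab$gini * 10 + runif(n, -1, 1)
    rep_ <- classify_outcomes(tab, "y", "gini", seed = 2)
    expect_equal(unname(rep_$mean["auc"]), 1)
    expect_equal(sum(rep_$importance), 1)
    expect_equal(nrow(rep_$metrics), 10)
  })
})

test_that("classifier is at chance on null outcomes and errors on constants", {
  with_seed_test(48, {
    n <- 400
    tab <- data.frame(subject_id = as.character(1:n), country = "x",
                      gini = runif(n, 25, 55), age = rnorm(n, 50, 10),
                      sex = rbinom(n, 1, .5), education = rnorm(n, 12, 3),
                      mmse = 28, y = rnorm(n))
    rep_ <- classify_outcomes(tab, "y", c("gini", "age"), seed = 3)
    expect_gt(unname(rep_$mean["auc"]), 0.4)
    expect_lt(unname(rep_$mean["auc"]), 0.6)
    tab$y <- 1
    expect_error(classify_outcomes(tab, "y", "gini"), "degenerate")
  })
})

test_that("feature importance ranks a strong effect above a weak one", {
  with_seed_test(49, {
    n <- 300
    tab <- data.frame(subject_id = as.character(1:n), country = "x",
                      gini = runif(n, 25, 55), age = rnorm(n, 50, 10),
                      sex = rbinom(n, 1, .5), education = 12, mmse = 28)
    tab$y <- -0.8 * scale(tab$gini)[, 1] + 0.15 * scale(tab$age)[, 1] +
      rnorm(n, 0, 0.4)
    rep_ <- classify_outcomes(tab, "y", c("gini", "age"), seed = 4)
    expect_gt(rep_$importance["gini"], rep_$importance["age"])
  })
})

test_that("classification is reproducible under a fixed seed", {
  with_seed_test(50, {
    n <- 100
    tab <- data.frame(subject_id = as.character(1:n), country = "x",
                      gini = runif(n, 25, 55), age = rnorm(n, 50, 10),
                      sex = rbinom(n, 1, .5), education = 12, mmse = 28,
                      y = rnorm(n))
    r1 <- classify_outcomes(tab, "y", c("gini", "age"), seed = 11)
    r2 <- classify_outcomes(tab, "y", c("gini", "age"), seed = 11)
    expect_identical(r1$metrics, r2$metrics)
    expect_identical(r1$importance, r2$importance)
  })
})
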
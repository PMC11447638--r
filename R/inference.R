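# Statistical reduction, hierarchical regressions with effect sizes, and
# median-binarised gradient-boosted classification.

#' Mean-versus-zero sign-flipping permutation test
#'
#' Two-sided nonparametric test of H0: mean = 0 built by randomly flipping
#' the sign of each observation; p = (1 + #{|T_perm| >= |T_obs|}) /
#' (1 + n_perm), so the smallest attainable p is 1/(n_perm + 1).
#'
#' @param values Numeric vector (>= 1 value).
#' @param n_perm Number of sign-flip randomisations (default 5000).
#' @param seed Seed for the randomisation.
#' @return The p value.
#' @export
permutation_mean_test <- function(values, n_perm = 5000, seed = 1) {
  n <- length(values)
  if (n < 1) stop("need at least one value")
  t_obs <- mean(values)
  if (all(values == 0)) return(1)
  with_seed(seed, {
    signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
    t_perm <- as.vector(signs %*% values) / n
    (1 + sum(abs(t_perm) >= abs(t_obs) - 1e-12)) / (1 + n_perm)
  })
}

#' Benjamini-Hochberg step-up rejection flags
#'
#' Rejects all hypotheses with p(i) <= i * alpha / m up to the largest such
#' rank i (step-up rule).
#'
#' @param p P values in \[0, 1\].
#' @param alpha FDR level.
#' @return Logical rejection flags in the input order (empty in, empty out).
#' @export
bh_fdr <- function(p, alpha = 0.05) {
  if (length(p) == 0) return(logical(0))
  if (any(p < 0 | p > 1)) stop("p values must lie in [0, 1]")
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  below <- which(ps <= seq_len(m) * alpha / m)
  reject <- logical(m)
  if (length(below)) reject[o[seq_len(max(below))]] <- TRUE
  reject
}

#' Statistical reduction of the ROI space
#'
#' Runs a mean-versus-zero permutation test per ROI and keeps the ROIs whose
#' BH-FDR-adjusted result is significant. Applied to relative power / percent
#' power per band, and analogously to complexity and aperiodic metrics.
#'
#' @param table Matrix or data frame, ROIs x subjects (ROI names as row
#'   names).
#' @param alpha FDR level.
#' @param n_perm Randomisations per ROI.
#' @param seed Seed.
#' @return Character vector (or indices when unnamed) of retained ROIs.
#' @export
reduce_rois <- function(table, alpha = 0.05, n_perm = 5000, seed = 1) {
  table <- as.matrix(table)
  if (nrow(table) == 0) {
    return(character(0))
  }
  seeds <- derive_seeds(seed, nrow(table))
  p <- vapply(seq_len(nrow(table)), function(i) {
    permutation_mean_test(table[i, ], n_perm = n_perm, seed = seeds[i])
  }, numeric(1))
  keep <- bh_fdr(p, alpha)
  if (!is.null(rownames(table))) rownames(table)[keep] else which(keep)
}

#' Cohen's f-squared from R-squared
#'
#' f2 = R2 / (1 - R2).
#'
#' @param r_squared R-squared in \[0, 1).
#' @return f-squared.
#' @examples
#' cohens_f2(0.2996)  # 0.4278
#' @export
cohens_f2 <- function(r_squared) {
  if (any(r_squared < 0 | r_squared >= 1)) {
    stop("domain error: r_squared must lie in [0, 1)")
  }
  r_squared / (1 - r_squared)
}

#' Hierarchical linear regression of an EEG outcome
#'
#' Ordinary least squares of `outcome` on `features` (Gini alone or with one
#' demographic/cognitive factor, optionally a gini x age interaction term
#' written `"gini:age"`), plus extra covariates. Continuous predictors are
#' z-scored; `sex` is coded 0/1. Complete cases only, with n reported.
#'
#' @param table A cohort table.
#' @param outcome Outcome column name.
#' @param features Character vector of predictor columns; interaction terms
#'   as `"a:b"` are formed from the standardised main effects.
#' @param covariates Optional extra covariate columns (e.g. gdp, oqd).
#' @return A `regression_report`: `outcome`, `coefficients` (estimate, t, p
#'   per feature), `r_squared`, `f_squared`, `f_value`, `model_p`, `n`.
#' @export
hierarchical_regression <- function(table, outcome, features,
                                    covariates = NULL) {
  df <- as.data.frame(table)
  main <- unique(unlist(strsplit(c(features, covariates), ":", fixed = TRUE)))
  need <- c(outcome, main)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) stop("columns not found: ",
                                 paste(missing_cols, collapse = ", "))
  df <- df[stats::complete.cases(df[, need, drop = FALSE]), , drop = FALSE]
  preds <- c(features, covariates)
  if (nrow(df) <= length(preds) + 2) stop("too few complete cases")
  x <- data.frame(row.names = seq_len(nrow(df)))
  std <- list()
  for (v in main) {
    col <- df[[v]]
    if (v == "sex") {
      if (!is.numeric(col)) col <- as.integer(col %in% c("female", "F", "1"))
      std[[v]] <- col
    } else {
      if (stats::sd(col) == 0) stop("rank-deficient design: constant column ", v)
      std[[v]] <- zstd(col)
    }
  }
  for (v in preds) {
    parts <- strsplit(v, ":", fixed = TRUE)[[1]]
    x[[v]] <- Reduce(`*`, std[parts])
  }
  qrx <- qr(cbind(1, as.matrix(x)))
  if (qrx$rank < ncol(x) + 1) {
    stop("rank-deficient design; collinear columns among: ",
         paste(preds, collapse = ", "))
  }
  dat <- cbind(.y = df[[outcome]], x)
  names(dat) <- c(".y", paste0("f", seq_along(preds)))
  fit <- stats::lm(.y ~ ., data = dat)
  sm <- summary(fit)
  coefs <- sm$coefficients[-1, , drop = FALSE]
  rownames(coefs) <- preds
  r2 <- sm$r.squared
  fstat <- sm$fstatistic
  model_p <- stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
  structure(list(
    outcome = outcome,
    coefficients = data.frame(
      feature = preds, estimate = coefs[, 1], t_value = coefs[, 3],
      p_value = coefs[, 4], row.names = NULL),
    r_squared = r2, f_squared = cohens_f2(min(r2, 1 - 1e-12)),
    f_value = unname(fstat[1]), model_p = unname(model_p),
    n = nrow(df)),
    class = "regression_report")
}

#' @export
print.regression_report <- function(x, ...) {
  cat(sprintf("<regression_report> %s ~ %s: R2 %.4f, f2 %.4f, F %.2f, p %.3g, n %d\n",
              x$outcome, paste(x$coefficients$feature, collapse = " + "),
              x$r_squared, x$f_squared, x$f_value, x$model_p, x$n))
  print(x$coefficients)
  invisible(x)
}

#' Median-binarised gradient-boosted classification of an EEG outcome
#'
#' The outcome is binarised at its median (ties to class 0, ensuring classes
#' are as balanced as the data allow), then a gradient-boosted tree
#' classifier is trained on a fresh stratified 80/20 split for each of `k`
#' repeats. AUC, accuracy, precision, recall and F1 are reported per repeat
#' and averaged; gain-based feature importances are averaged over repeats and
#' normalised to sum 1.
#'
#' @param table A cohort table.
#' @param outcome Numeric outcome column (n >= 50 complete cases).
#' @param features Predictor columns, e.g. `"gini"` or
#'   `c("gini", "age")`.
#' @param k Number of repeats.
#' @param train_frac Training fraction.
#' @param seed Seed (controls both splits and the learner).
#' @param nrounds,max_depth,eta Gradient-boosting hyperparameters.
#' @return A `classifier_report`: `metrics` (per-repeat data frame), `mean`
#'   and `sd` summaries, `importance` (named, sums to 1), `outcome`, `seed`.
#' @export
classify_outcomes <- function(table, outcome, features, k = 10,
                              train_frac = 0.8, seed = 1, nrounds = 100,
                              max_depth = 3, eta = 0.1) {
  df <- as.data.frame(table)
  need <- c(outcome, features)
  df <- df[stats::complete.cases(df[, need, drop = FALSE]), , drop = FALSE]
  if (nrow(df) < 50) stop("need at least 50 complete cases")
  y_num <- df[[outcome]]
  if (stats::sd(y_num) == 0) stop("degenerate outcome: constant column")
  y <- as.integer(y_num > stats::median(y_num))
  xmat <- as.matrix(as.data.frame(lapply(df[features], as.numeric)))
  colnames(xmat) <- features
  split_seeds <- derive_seeds(seed, k)
  rows <- vector("list", k)
  imp <- matrix(0, k, length(features), dimnames = list(NULL, features))
  for (r in seq_len(k)) {
    idx_tr <- with_seed(split_seeds[r], {
      unlist(lapply(unique(y), function(cl) {
        ic <- which(y == cl)
        sample(ic, round(train_frac * length(ic)))
      }))
    })
    idx_te <- setdiff(seq_along(y), idx_tr)
    dtr <- xgboost::xgb.DMatrix(xmat[idx_tr, , drop = FALSE],
                                label = y[idx_tr])
    bst <- xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = max_depth,
                    eta = eta, nthread = 1, seed = split_seeds[r]),
      data = dtr, nrounds = nrounds, verbose = 0)
    prob <- stats::predict(bst,
                           xgboost::xgb.DMatrix(xmat[idx_te, , drop = FALSE]))
    pred <- as.integer(prob > 0.5)
    truth <- y[idx_te]
    auc <- if (length(unique(truth)) == 2) {
      as.numeric(pROC::auc(pROC::roc(truth, prob, quiet = TRUE,
                                     direction = "<", levels = c(0, 1))))
    } else NA_real_
    tp <- sum(pred == 1 & truth == 1)
    fp <- sum(pred == 1 & truth == 0)
    fn <- sum(pred == 0 & truth == 1)
    prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0) {
      2 * prec * rec / (prec + rec)
    } else NA_real_
    rows[[r]] <- data.frame(repeat_ = r, auc = auc,
                            accuracy = mean(pred == truth),
                            precision = prec, recall = rec, f1 = f1)
    # gain importance from the tree dump (robust to single-feature models)
    tr <- as.data.frame(xgboost::xgb.model.dt.tree(model = bst))
    tr <- tr[tr$Feature != "Leaf", , drop = FALSE]
    if (nrow(tr)) {
      gains <- tapply(tr$Gain, tr$Feature, sum)
      gains <- gains / sum(gains)
      imp[r, names(gains)] <- gains
    }
  }
  metrics <- do.call(rbind, rows)
  imp_mean <- colMeans(imp)
  if (sum(imp_mean) > 0) imp_mean <- imp_mean / sum(imp_mean)
  structure(list(
    outcome = outcome, features = features, metrics = metrics,
    mean = colMeans(metrics[, -1], na.rm = TRUE),
    sd = apply(metrics[, -1], 2, stats::sd, na.rm = TRUE),
    importance = imp_mean, k = k, split = train_frac, seed = seed),
    class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("<classifier_report> %s ~ %s: mean AUC %.3f (+/- %.3f), k=%d\n",
              x$outcome, paste(x$features, collapse = " + "),
              x$mean["auc"], x$sd["auc"], x$k))
  invisible(x)
}
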
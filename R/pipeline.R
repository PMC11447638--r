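# End-to-end feature extraction: standardised recording -> one feature row.

sanitize_label <- function(x) gsub("[^a-z0-9]+", "_", tolower(x))

#' Extract EEG outcome features from one recording
#'
#' Standardises (band-pass, resample, truncate), z-scores, computes the OQD
#' quality index, and derives per-ROI outcomes: complexity metrics (FD, PE,
#' WE, SSV), aperiodic parameters (offset, knee, slope), spectral landmarks
#' and band powers (canonical and subject-specific schemes), plus system-wide
#' connectivity graph metrics (MI / CMI / O-information global efficiency,
#' transitivity, density, small-worldness). The sentinel "all" ROI (mean of
#' all channels) is always included for the per-ROI metrics.
#'
#' Aggregates `alpha_rel_<roi>` (alpha1 + alpha2 relative power) and
#' `beta_rel_<roi>` (beta1 + beta2 + beta3) are added for convenience.
#'
#' @param rec A [recording()] at atlas-region or ROI level.
#' @param roi_map Optional `roi_map` applied when the labels are atlas
#'   regions.
#' @param metrics Subset of `c("complexity", "aperiodic", "power",
#'   "connectivity")`.
#' @param per_roi Compute the per-ROI metric columns; when `FALSE` only the
#'   "all" sentinel (mean series) carries complexity/aperiodic/power metrics,
#'   which is much faster. Connectivity always uses all ROI rows.
#' @param standardize Run [standardize_recording()] first.
#' @param target_fs,max_duration Standardisation parameters.
#' @param seed Seed for the graph null models.
#' @return A one-row data frame of named features (includes `oqd`,
#'   `oqd_category`, `n_channels`, `fs_original`).
#' @export
extract_features <- function(rec, roi_map = NULL,
                             metrics = c("complexity", "aperiodic", "power",
                                         "connectivity"),
                             per_roi = TRUE,
                             standardize = TRUE, target_fs = 512,
                             max_duration = 300, seed = 1) {
  stopifnot(inherits(rec, "recording"))
  fs_original <- rec$fs
  n_channels <- nrow(rec$data)
  if (standardize) rec <- standardize_recording(rec, target_fs = target_fs,
                                                max_duration = max_duration)
  rec <- suppressWarnings(zscore_harmonize(rec))
  if (!is.null(roi_map)) rec <- map_to_rois(rec, roi_map)
  qr <- oqd_summary(epoch_quality_flags(epoch_signal(rec, 1)))
  out <- list(oqd = qr$oqd, oqd_category = qr$category,
              n_channels = n_channels, fs_original = fs_original)

  if (per_roi) {
    rois <- rbind(rec$data, all = colMeans(rec$data))
    labs <- c(rec$labels, "all")
  } else {
    rois <- matrix(colMeans(rec$data), nrow = 1)
    labs <- "all"
  }
  # median-averaged Welch resists residual artifact epochs; the known
  # band-pass power gain is divided out before spectral parameterisation
  gain <- if (!is.null(rec$meta$standardized)) {
    st <- rec$meta$standardized
    function(freqs) filter_power_gain(freqs, st$band[1], st$band[2],
                                      st$order, rec$fs)
  } else NULL
  profiles <- lapply(seq_len(nrow(rois)), function(i) {
    w <- welch_psd(rois[i, ], rec$fs, average = "median")
    if (!is.null(gain)) w$psd <- w$psd / pmax(gain(w$freqs), 1e-3)
    inr <- w$freqs >= w$range[1] & w$freqs <= w$range[2]
    w$npsd[inr] <- w$psd[inr] / sum(w$psd[inr])
    w
  })
  for (i in seq_along(labs)) {
    roi <- sanitize_label(labs[i])
    x <- rois[i, ]
    sp <- profiles[[i]]
    if ("complexity" %in% metrics) {
      out[[paste0("fd_", roi)]] <- as.numeric(higuchi_fd(x))
      out[[paste0("pe_", roi)]] <- permutation_entropy(x)
      out[[paste0("we_", roi)]] <- as.numeric(wiener_entropy(sp))
      out[[paste0("ssv_", roi)]] <-
        spectral_structure_variability(x, rec$fs)
    }
    if ("aperiodic" %in% metrics) {
      # interior fit range: the lowest bins are limited by the 1-s Welch
      # window resolution and the edge bins by the band-pass rolloff
      ap <- fit_aperiodic(sp, range = c(1, 38))
      out[[paste0("offset_", roi)]] <- ap$offset
      out[[paste0("knee_", roi)]] <- ap$knee
      out[[paste0("slope_", roi)]] <- ap$slope
    }
    if ("power" %in% metrics) {
      lm_ <- detect_landmarks(sp)
      out[[paste0("iaf_", roi)]] <- lm_$iaf
      out[[paste0("tf_", roi)]] <- lm_$tf
      bp <- band_powers(sp, "canonical")
      for (j in seq_len(nrow(bp))) {
        out[[paste0("relpow_", bp$band[j], "_", roi)]] <- bp$rel_power[j]
        out[[paste0("pctpow_", bp$band[j], "_", roi)]] <- bp$mean_npsd[j]
      }
      bs <- band_powers(sp, "subject", landmarks = lm_)
      for (j in seq_len(nrow(bs))) {
        out[[paste0("relpow_subj_", bs$band[j], "_", roi)]] <- bs$rel_power[j]
      }
      out[[paste0("alpha_rel_", roi)]] <-
        sum(bp$rel_power[bp$band %in% c("alpha1", "alpha2")])
      out[[paste0("beta_rel_", roi)]] <-
        sum(bp$rel_power[bp$band %in% c("beta1", "beta2", "beta3")])
    }
  }
  if ("connectivity" %in% metrics && nrow(rec$data) >= 3) {
    cg <- connectivity_graph(rec)
    for (nm in c("mi", "cmi", "oinfo")) {
      w <- cg[[paste0("w_", nm)]]
      gm <- tryCatch(graph_metrics(w, seed = seed), error = function(e) NULL)
      if (!is.null(gm)) {
        out[[paste0("geff_", nm)]] <- gm$global_efficiency
        out[[paste0("trans_", nm)]] <- gm$transitivity
        out[[paste0("dens_", nm)]] <- gm$density
        out[[paste0("sw_", nm)]] <- gm$small_worldness
      }
    }
    out[["oinfo_total"]] <- cg$omega
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Run the full pipeline on a synthetic cohort
#'
#' Simulates the cohort, extracts features per subject, and returns the
#' cohort feature table (predictors + quality + outcomes + generator truth).
#' Identical arguments and seed give an identical table.
#'
#' @param countries List of [country_spec()]s.
#' @param effects An [effect_spec()].
#' @param seed Master seed.
#' @param fs,duration,n_rois Recording geometry.
#' @param metrics Feature families to compute (see [extract_features()]).
#' @param per_roi Compute per-ROI metric columns (see [extract_features()]).
#' @param artifact_epoch_fraction Fraction of corrupted epochs.
#' @return A `cohort_table` with one row per subject.
#' @export
run_cohort_pipeline <- function(countries = default_countries(10),
                                effects = effect_spec(), seed = 1,
                                fs = 512, duration = 60, n_rois = 10,
                                metrics = c("complexity", "aperiodic",
                                            "power", "connectivity"),
                                per_roi = TRUE,
                                artifact_epoch_fraction = 0.05) {
  sim <- simulate_cohort(countries, effects, seed = seed, fs = fs,
                         duration = duration, n_rois = n_rois,
                         artifact_epoch_fraction = artifact_epoch_fraction,
                         recordings = FALSE)
  n <- nrow(sim$table)
  # recordings are simulated one at a time (same sub-seeds as
  # simulate_cohort would use) to keep memory flat for large cohorts
  rec_seeds <- derive_seeds(seed, n)
  feat_seeds <- derive_seeds(seed + 1L, n)
  feats <- lapply(seq_len(n), function(i) {
    rec <- simulate_recording(sim$specs[[i]], n_rois = n_rois,
                              seed = rec_seeds[i],
                              centre_id = sim$table$country[i])
    extract_features(rec, metrics = metrics, per_roi = per_roi,
                     target_fs = fs, max_duration = duration,
                     seed = feat_seeds[i])
  })
  feats <- do.call(rbind, feats)
  nd_log("run_cohort_pipeline", n = nrow(feats), seed = seed,
         duration = duration, fs = fs)
  as_cohort_table(cbind(sim$table, feats))
}
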
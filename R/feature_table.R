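# Cohort feature table I/O.

pred_cols <- c("subject_id", "country", "gini", "gdp", "age", "sex",
               "education", "mmse")
qual_cols <- c("oqd", "oqd_category", "n_channels", "fs_original",
               "reference_code")

#' Validate a cohort feature table
#'
#' One row per subject; predictor columns (country, gini 0-100, gdp, age,
#' sex, education, mmse 0-30), quality columns (oqd and friends) and numeric
#' EEG outcome columns.
#'
#' @param df A data frame.
#' @return The validated data frame (invisibly classed `cohort_table`).
#' @export
as_cohort_table <- function(df) {
  stopifnot(is.data.frame(df))
  if (!"subject_id" %in% names(df)) stop("cohort table needs a subject_id column")
  if (anyDuplicated(df$subject_id)) stop("one row per subject required")
  if ("gini" %in% names(df) &&
      any(df$gini < 0 | df$gini > 100, na.rm = TRUE)) {
    stop("gini must lie in [0, 100]")
  }
  if ("mmse" %in% names(df) &&
      any(df$mmse < 0 | df$mmse > 30, na.rm = TRUE)) {
    stop("mmse must lie in [0, 30]")
  }
  outcome <- setdiff(names(df), c(pred_cols, qual_cols))
  bad <- outcome[!vapply(df[outcome], is.numeric, TRUE)]
  if (length(bad)) stop("outcome columns must be numeric: ",
                        paste(bad, collapse = ", "))
  class(df) <- unique(c("cohort_table", class(df)))
  df
}

#' Write a cohort feature table to CSV
#'
#' Stable column order (predictors, then quality, then outcomes
#' alphabetically); 12 significant digits; missing values as empty cells.
#' Writing, reading and re-writing produces a byte-identical file.
#'
#' @param table A cohort table (see [as_cohort_table()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  if (nrow(table) == 0) stop("refusing to write an empty table")
  table <- as_cohort_table(as.data.frame(table))
  outcome <- sort(setdiff(names(table), c(pred_cols, qual_cols)))
  cols <- c(intersect(pred_cols, names(table)),
            intersect(qual_cols, names(table)), outcome)
  df <- table[, cols, drop = FALSE]
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]])) {
      v <- ifelse(is.na(df[[j]]), "",
                  format(df[[j]], digits = 12, trim = TRUE, scientific = NA))
      df[[j]] <- v
    } else {
      df[[j]] <- ifelse(is.na(df[[j]]), "", as.character(df[[j]]))
    }
  }
  ok <- tryCatch({
    utils::write.table(df, path, sep = ",", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("I/O error: cannot write ", path)
  invisible(path)
}

#' Read a cohort feature table from CSV
#'
#' @param path File path written by [write_feature_table()].
#' @return A `cohort_table` data frame; empty cells become `NA`.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        na.strings = "")
  as_cohort_table(df)
}
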
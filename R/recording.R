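#' Construct a multichannel recording
#'
#' The basic container of the pipeline: a channels-or-ROIs by samples matrix
#' with a sampling rate, channel labels and acquisition-site identifier.
#' Values are voltage-like; units become arbitrary after z-scoring.
#'
#' @param data Numeric matrix, one row per channel/ROI.
#' @param fs Sampling rate in Hz (> 0).
#' @param labels Character vector of unique channel/ROI names, one per row.
#' @param centre_id Acquisition-site identifier.
#' @param meta Free-form provenance list.
#' @return An object of class `recording`.
#' @export
recording <- function(data, fs, labels = NULL,
                      centre_id = "unknown", meta = list()) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (is.null(labels)) labels <- rownames(data) %||% paste0("ch", seq_len(nrow(data)))
  labels <- as.character(labels)
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) {
    stop("fs must be a single positive number")
  }
  if (length(labels) != nrow(data)) stop("labels must have one entry per row")
  if (anyDuplicated(labels)) stop("labels must be unique")
  if (anyNA(data) && !isTRUE(meta$allow_missing)) {
    stop("recording contains missing values")
  }
  rownames(data) <- labels
  structure(
    list(data = data, fs = fs, labels = labels,
         centre_id = centre_id, meta = meta),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d channel(s) x %d samples @ %g Hz (%.1f s), centre %s\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs,
              x$centre_id))
  invisible(x)
}

# Duration in seconds.
rec_duration <- function(rec) ncol(rec$data) / rec$fs

#' Read a recording from disk
#'
#' Two formats are supported. `tsv-matrix` is the canonical exchange format:
#' tab-separated, a `# fs=<Hz>` comment line, a header row of channel labels,
#' one column per channel. `edf` is the standard 16-bit European Data Format
#' (read via [read_edf()]); channel order is preserved.
#'
#' @param path File path.
#' @param format `"tsv-matrix"` or `"edf"`; default guesses from the extension.
#' @param fs Sampling rate override for TSV files lacking an `# fs=` line.
#' @param centre_id Acquisition-site identifier to attach.
#' @return A [recording()].
#' @export
read_recording <- function(path, format = c("auto", "tsv-matrix", "edf"),
                           fs = NULL, centre_id = "unknown") {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "tsv-matrix"
  }
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "edf") {
    return(read_edf(path, centre_id = centre_id))
  }
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  fs_line <- grep("^#\\s*fs\\s*=", meta_lines, value = TRUE)
  if (length(fs_line)) {
    fs <- as.numeric(sub("^#\\s*fs\\s*=\\s*", "", fs_line[1]))
  }
  if (is.null(fs) || !is.finite(fs)) {
    stop("configuration error: sampling rate missing (no '# fs=' line and no fs argument)")
  }
  body <- lines[!grepl("^#", lines)]
  if (length(body) < 2) stop("format error: no data rows in ", path)
  con <- textConnection(body)
  on.exit(close(con))
  df <- utils::read.delim(con, header = TRUE, check.names = FALSE,
                          colClasses = "character")
  mat <- suppressWarnings(vapply(df, as.numeric, numeric(nrow(df))))
  if (anyNA(mat)) stop("format error: non-numeric cell in ", path)
  # columns are channels on disk; internal layout is channels x samples
  recording(t(as.matrix(mat)), fs = fs, labels = colnames(df),
            centre_id = centre_id, meta = list(source = path))
}

#' Write a recording as a TSV matrix
#'
#' Channels as columns, header row of labels, leading `# fs=<Hz>` comment.
#' Round-trips losslessly at 12 significant digits.
#'
#' @param rec A [recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%.10g", rec$fs), con)
  writeLines(paste(rec$labels, collapse = "\t"), con)
  utils::write.table(
    format(t(rec$data), digits = 12, trim = TRUE, scientific = NA),
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

# ---- EDF (European Data Format), minimal 16-bit implementation ----------

edf_pad <- function(x, width) formatC(as.character(x), width = width, flag = "-")

#' Read an EDF file
#'
#' Minimal reader for standard (continuous, 16-bit) EDF: parses the ASCII
#' header, converts digital values to physical units per channel, and
#' concatenates data records. Annotation channels are not supported.
#'
#' @param path File path.
#' @param centre_id Acquisition-site identifier to attach.
#' @return A [recording()].
#' @export
read_edf <- function(path, centre_id = "unknown") {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- rawToChar(readBin(con, "raw", 256L))
  fld <- function(s, from, len) substr(s, from, from + len - 1L)
  n_records <- as.integer(fld(hdr, 237, 8))
  rec_dur <- as.numeric(fld(hdr, 245, 8))
  ns <- as.integer(fld(hdr, 253, 4))
  if (is.na(ns) || ns < 1) stop("format error: not an EDF header in ", path)
  sig_hdr <- rawToChar(readBin(con, "raw", 256L * ns))
  grab <- function(offset, width) {
    vapply(seq_len(ns), function(i)
      trimws(substr(sig_hdr, offset * ns + (i - 1L) * width + 1L,
                    offset * ns + i * width)), "")
  }
  labels <- grab(0, 16)
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i)
    substr(sig_hdr, 16 * ns + 80 * ns + 8 * ns + (i - 1) * 8 + 1,
           16 * ns + 80 * ns + 8 * ns + i * 8), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i)
    substr(sig_hdr, 16 * ns + 80 * ns + 16 * ns + (i - 1) * 8 + 1,
           16 * ns + 80 * ns + 16 * ns + i * 8), ""))
  dmin_ <- as.numeric(vapply(seq_len(ns), function(i)
    substr(sig_hdr, 16 * ns + 80 * ns + 24 * ns + (i - 1) * 8 + 1,
           16 * ns + 80 * ns + 24 * ns + i * 8), ""))
  dmax_ <- as.numeric(vapply(seq_len(ns), function(i)
    substr(sig_hdr, 16 * ns + 80 * ns + 32 * ns + (i - 1) * 8 + 1,
           16 * ns + 80 * ns + 32 * ns + i * 8), ""))
  spr <- as.integer(vapply(seq_len(ns), function(i)
    substr(sig_hdr, 16 * ns + 160 * ns + 40 * ns + (i - 1) * 8 + 1,
           16 * ns + 160 * ns + 40 * ns + i * 8), ""))
  if (anyNA(c(pmin_, pmax_, dmin_, dmax_, spr))) {
    stop("format error: malformed EDF signal header in ", path)
  }
  scale <- (pmax_ - pmin_) / (dmax_ - dmin_)
  data <- matrix(0, nrow = ns, ncol = n_records * spr[1])
  if (length(unique(spr)) != 1) stop("EDF with mixed per-signal rates not supported")
  for (r in seq_len(n_records)) {
    for (s in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[s], size = 2L,
                     signed = TRUE, endian = "little")
      data[s, ((r - 1) * spr[s] + 1):(r * spr[s])] <-
        (dig - dmin_[s]) * scale[s] + pmin_[s]
    }
  }
  fs <- spr[1] / rec_dur
  recording(data, fs = fs, labels = labels, centre_id = centre_id,
            meta = list(source = path, format = "edf"))
}

#' Write a recording as EDF
#'
#' Minimal standard 16-bit EDF writer. Physical ranges are set per channel to
#' the data range, so values round-trip within one quantisation step
#' (range / 65534). The recording is split into 1-s data records; trailing
#' samples that do not fill a record are dropped.
#'
#' @param rec A [recording()]. `fs` must be a positive integer.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  if (rec$fs != round(rec$fs)) stop("EDF export requires integer fs")
  ns <- nrow(rec$data)
  spr <- as.integer(rec$fs)
  n_records <- floor(ncol(rec$data) / spr)
  if (n_records < 1) stop("recording shorter than one EDF record")
  x <- rec$data[, seq_len(n_records * spr), drop = FALSE]
  pmin_ <- apply(x, 1, min)
  pmax_ <- apply(x, 1, max)
  flat <- pmax_ - pmin_ <= 0
  pmax_[flat] <- pmin_[flat] + 1
  dmin_ <- rep(-32768L, ns)
  dmax_ <- rep(32767L, ns)
  scale <- (pmax_ - pmin_) / (dmax_ - dmin_)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad("X X X X", 80), edf_pad("Startdate X", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256L * (1L + ns), 8), edf_pad("", 44),
    edf_pad(n_records, 8), edf_pad("1", 8), edf_pad(ns, 4)
  )
  writeChar(hdr, con, eos = NULL)
  wfield <- function(vals, width) {
    writeChar(paste0(vapply(vals, edf_pad, "", width = width), collapse = ""),
              con, eos = NULL)
  }
  wfield(rec$labels, 16)
  wfield(rep("", ns), 80)                   # transducer
  wfield(rep("uV", ns), 8)                  # physical dimension
  wfield(formatC(pmin_, digits = 5, format = "g"), 8)
  wfield(formatC(pmax_, digits = 5, format = "g"), 8)
  wfield(dmin_, 8)
  wfield(dmax_, 8)
  wfield(rep("", ns), 80)                   # prefiltering
  wfield(rep(spr, ns), 8)
  wfield(rep("", ns), 32)
  for (r in seq_len(n_records)) {
    for (s in seq_len(ns)) {
      seg <- x[s, ((r - 1) * spr + 1):(r * spr)]
      dig <- as.integer(round((seg - pmin_[s]) / scale[s]) + dmin_[s])
      dig <- pmin(pmax(dig, -32768L), 32767L)
      writeBin(dig, con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}
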
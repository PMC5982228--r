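# Record and annotation I/O plus long-record segmentation planning.
#
# The CSV dialect is self-describing: the first line is `fs=<Hz>`, the
# second line holds comma-separated lead names, and each following line
# one sample per lead. Values are written with 17 significant digits so
# a write -> read round trip is bit-exact for doubles.

#' Read a multilead ECG record
#'
#' @param path Path to the record: for WFDB, the record base name or the
#'   `.hea` file; for CSV, the file written by [write_record()].
#' @param format `"wfdb"` or `"csv"`; `"auto"` guesses from the
#'   extension (`.csv` is CSV, anything else WFDB).
#' @return A [multilead_signal] at the native sampling rate (no
#'   resampling is performed anywhere in this package).
#' @export
read_record <- function(path, format = c("auto", "wfdb", "csv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "wfdb"
  if (format == "wfdb") return(wfdb_read_record(path))
  if (!file.exists(path)) stop("record file not found: ", path)
  lines <- readLines(path, n = 2L, warn = FALSE)
  if (!grepl("^fs=", lines[1L]))
    stop("CSV record must start with a `fs=<Hz>` header line: ", path)
  fs <- as.numeric(sub("^fs=", "", lines[1L]))
  if (!is.finite(fs) || fs <= 0) stop("invalid sampling rate in ", path)
  tab <- utils::read.csv(path, skip = 1L, check.names = FALSE)
  m <- as.matrix(tab)
  if (any(!is.finite(m))) stop("non-numeric or missing samples in ", path)
  multilead_signal(m, fs, colnames(tab))
}

#' Write a multilead ECG record
#'
#' @param signal A [multilead_signal].
#' @param path Output path (CSV) or WFDB record base name.
#' @param format `"csv"` (default) or `"wfdb"` (16-bit integer format;
#'   quantized at the given gain).
#' @param gain ADC gain in units per millivolt for WFDB output.
#' @return The path, invisibly.
#' @export
write_record <- function(signal, path, format = c("csv", "wfdb"), gain = 200) {
  format <- match.arg(format)
  if (format == "wfdb") return(invisible(wfdb_write_record(signal, path,
                                                           gain = gain)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("fs=%.10g", signal$fs), con)
  writeLines(paste(signal$lead_names, collapse = ","), con)
  rows <- apply(signal$samples, 1L, function(r)
    paste(sprintf("%.17g", r), collapse = ","))
  writeLines(rows, con)
  invisible(path)
}

#' Read reference beat annotations
#'
#' Reads a WFDB annotation file (e.g., `.atr`) or a one-column CSV of
#' 0-based sample indices.
#'
#' @param path Annotation file path.
#' @param beat_only If `TRUE` (default), keep only standard WFDB beat
#'   type codes, dropping rhythm/noise/comment events.
#' @param format `"wfdb"`, `"csv"`, or `"auto"` (by extension).
#' @return An [annotation_set].
#' @export
read_annotations <- function(path, beat_only = TRUE,
                             format = c("auto", "wfdb", "csv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "wfdb"
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (format == "csv") {
    tab <- utils::read.csv(path)
    if (!nrow(tab)) {
      warning("no annotations found in ", path)
      return(annotation_set(integer(0), character(0)))
    }
    lab <- if ("label" %in% names(tab)) as.character(tab$label) else "N"
    return(annotation_set(tab[[1L]], lab))
  }
  ann <- wfdb_read_annotations(path)
  if (beat_only) ann <- ann[ann$code %in% .wfdb_beat_codes, , drop = FALSE]
  if (!nrow(ann)) {
    warning("no ", if (beat_only) "beat " else "", "annotations found in ",
            path)
    return(annotation_set(integer(0), character(0)))
  }
  lab <- ann$label
  lab[is.na(lab)] <- "Q"
  annotation_set(ann$time, lab)
}

#' Write detected peaks
#'
#' @param peaks A [peak_list] (or an [annotation_set]).
#' @param path Output path.
#' @param format `"csv"` (one `index` column, 0-based samples) or
#'   `"wfdb_ann"` (MIT annotation format, all beats typed `N`).
#' @return The path, invisibly.
#' @export
write_detections <- function(peaks, path, format = c("csv", "wfdb_ann")) {
  format <- match.arg(format)
  idx <- peaks$indices
  if (format == "wfdb_ann") {
    lab <- if (!is.null(peaks$labels)) peaks$labels else rep("N", length(idx))
    return(invisible(wfdb_write_annotations(idx, lab, path)))
  }
  utils::write.csv(data.frame(index = idx), path, row.names = FALSE)
  invisible(path)
}

#' Plan segmentation of a long record
#'
#' Long-term records are processed in fixed-length segments with a small
#' overlap so every beat is seen with full filter context by at least
#' one segment; overlap-zone duplicates are removed downstream by
#' [detect_beats()]. The default 300-s segment length minimizes
#' processing time for the polling detector.
#'
#' @param signal A [multilead_signal] (or its sample count via `n`).
#' @param segment_length_s Segment length in seconds (default 300).
#' @param overlap_s Overlap between consecutive segments in seconds
#'   (default 2); must satisfy `segment_length_s > 2 * overlap_s`.
#' @return An object of class `segmentation_plan`: a list with
#'   `segment_length_s`, `overlap_s`, `fs`, and `segments`, a data frame
#'   of half-open 0-based `[start, end)` sample ranges.
#' @examples
#' x <- multilead_signal(matrix(rnorm(200 * 700), ncol = 1), fs = 200)
#' plan_segments(x, segment_length_s = 300, overlap_s = 0)
#' @export
plan_segments <- function(signal, segment_length_s = 300, overlap_s = 2) {
  if (segment_length_s <= 0 || overlap_s < 0)
    stop("segment and overlap lengths must be positive")
  if (segment_length_s <= 2 * overlap_s)
    stop("`segment_length_s` must exceed twice `overlap_s`")
  n <- n_samples(signal); fs <- signal$fs
  seg <- max(1L, as.integer(round(segment_length_s * fs)))
  ov <- as.integer(round(overlap_s * fs))
  step <- seg - ov
  starts <- seq(0L, by = step, length.out = max(1L, ceiling(max(0L, n - ov) / step)))
  starts <- starts[starts < n]
  if (!length(starts)) starts <- 0L
  ends <- pmin(starts + seg, n)
  keep <- c(TRUE, ends[-1L] > ends[-length(ends)])  # drop fully-contained tails
  starts <- starts[keep]; ends <- ends[keep]
  # a stub tail segment gives the adaptive threshold too little context;
  # fold it into the previous segment instead
  k <- length(starts)
  if (k > 1L && ends[k] - starts[k] < seg %/% 2L) {
    ends[k - 1L] <- ends[k]
    starts <- starts[-k]; ends <- ends[-k]
  }
  structure(list(segment_length_s = segment_length_s, overlap_s = overlap_s,
                 fs = fs,
                 segments = data.frame(start = as.integer(starts),
                                       end = as.integer(ends))),
            class = "segmentation_plan")
}

#' @export
print.segmentation_plan <- function(x, ...) {
  cat(sprintf("<segmentation_plan> %d segments of %g s (overlap %g s)\n",
              nrow(x$segments), x$segment_length_s, x$overlap_s))
  invisible(x)
}
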
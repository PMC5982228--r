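#' ltmbeat: multilead R-wave detection for long-term ECG monitoring
#'
#' Tools for locating QRS complexes (R-peaks) in multilead ambulatory ECG
#' recordings lasting from minutes to many days. The pipeline follows the
#' classical three-stage waveform-analysis architecture: signal
#' preprocessing, feature-signal extraction, and threshold-based R-wave
#' detection, extended with simultaneous multilead processing and fusion
#' of per-lead detections by majority polling (or AND/OR/simple-coupling
#' rules). Long records are processed in segments for bounded memory and
#' near-linear runtime.
#'
#' @section Main entry points:
#' * [read_record()] / [synth_ecg()] — obtain a [multilead_signal].
#' * [detect_beats()] — the full detection pipeline.
#' * [evaluate_detections()] — beat-by-beat scoring against annotations.
#' * [tune_threshold()] — K-fold grid search for threshold parameters.
#'
#' @name ltmbeat-package
#' @keywords internal
"_PACKAGE"

#' Construct a multilead ECG signal
#'
#' A `multilead_signal` holds an n-sample by L-lead matrix of amplitudes
#' (millivolts), the sampling rate, lead names, and the start offset of
#' the first sample. All sample indices in this package are 0-based and
#' ranges are half-open.
#'
#' @param samples Numeric matrix (or vector for a single lead), one
#'   column per lead, in millivolts.
#' @param fs Sampling rate in Hz (> 0).
#' @param lead_names Optional character vector of lead names; defaults
#'   to `"lead1"`, `"lead2"`, ...
#' @param t0 Start offset of the first sample, in samples (0-based).
#' @return An object of class `multilead_signal` with fields `samples`,
#'   `fs`, `lead_names`, `t0`.
#' @examples
#' x <- multilead_signal(cbind(sin(1:100), cos(1:100)), fs = 100)
#' n_samples(x); n_leads(x)
#' @export
multilead_signal <- function(samples, fs, lead_names = NULL, t0 = 0L) {
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1L)
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (nrow(samples) < 1L || ncol(samples) < 1L)
    stop("`samples` must have at least one sample and one lead")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a single positive number")
  if (is.null(lead_names)) lead_names <- paste0("lead", seq_len(ncol(samples)))
  if (length(lead_names) != ncol(samples))
    stop("`lead_names` length must equal the number of leads")
  colnames(samples) <- lead_names
  structure(
    list(samples = samples, fs = as.numeric(fs),
         lead_names = as.character(lead_names), t0 = as.integer(t0)),
    class = "multilead_signal")
}

#' @rdname multilead_signal
#' @param x A `multilead_signal`.
#' @export
n_samples <- function(x) nrow(x$samples)

#' @rdname multilead_signal
#' @export
n_leads <- function(x) ncol(x$samples)

#' @export
print.multilead_signal <- function(x, ...) {
  cat(sprintf("<multilead_signal> %d samples x %d leads @ %g Hz (%.1f s)\n",
              n_samples(x), n_leads(x), x$fs, n_samples(x) / x$fs))
  cat("  leads:", paste(x$lead_names, collapse = ", "), "\n")
  invisible(x)
}

# extract a sample range [start, end) (0-based) as a new signal
slice_signal <- function(x, start, end) {
  stopifnot(start >= 0, end > start, end <= n_samples(x))
  multilead_signal(x$samples[(start + 1L):end, , drop = FALSE], x$fs,
                   x$lead_names, t0 = x$t0 + as.integer(start))
}

#' Construct a reference annotation set
#'
#' Holds beat fiducial positions (0-based sample indices, strictly
#' increasing) with per-beat type labels, as read from a WFDB annotation
#' file or produced by the synthetic generator.
#'
#' @param indices Integer vector of strictly increasing 0-based sample
#'   positions.
#' @param labels Optional character vector of beat-type codes (WFDB
#'   mnemonics such as `"N"`, `"V"`); recycled if length 1.
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(indices, labels = "N") {
  indices <- as.integer(round(indices))
  if (length(indices) && any(diff(indices) <= 0))
    stop("annotation indices must be strictly increasing")
  if (length(indices) && any(indices < 0))
    stop("annotation indices must be nonnegative")
  if (length(labels) == 1L) labels <- rep(labels, length(indices))
  if (length(labels) != length(indices))
    stop("`labels` must match `indices` in length")
  structure(list(indices = indices, labels = as.character(labels)),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set> %d beats", length(x$indices)))
  if (length(x$indices))
    cat(sprintf(" [%d .. %d]", x$indices[1L], x$indices[length(x$indices)]))
  cat("\n")
  invisible(x)
}

#' Construct a peak list
#'
#' Strictly increasing 0-based sample indices of detected R-peaks, with
#' the lead they came from (`"FUSED"` after lead fusion) and, optionally,
#' the feature amplitude at each peak (used by the refractory filter and
#' by segment-boundary deduplication).
#'
#' @param indices Integer vector, strictly increasing, 0-based.
#' @param lead Lead identifier string or `"FUSED"`.
#' @param amplitudes Optional numeric vector of per-peak amplitudes.
#' @param fs Sampling rate the indices refer to.
#' @return An object of class `peak_list`.
#' @export
peak_list <- function(indices, lead = "FUSED", amplitudes = NULL, fs = NA_real_) {
  indices <- as.integer(round(indices))
  if (length(indices) && any(diff(indices) <= 0))
    stop("peak indices must be strictly increasing")
  if (!is.null(amplitudes) && length(amplitudes) != length(indices))
    stop("`amplitudes` must match `indices` in length")
  structure(list(indices = indices, lead = lead,
                 amplitudes = amplitudes, fs = fs),
            class = "peak_list")
}

#' @export
print.peak_list <- function(x, ...) {
  cat(sprintf("<peak_list> %d peaks (lead %s)\n", length(x$indices), x$lead))
  invisible(x)
}

#' @export
length.peak_list <- function(x) length(x$indices)

#' Feature signal
#'
#' A detection-oriented transform of the ECG in which QRS complexes are
#' enhanced. Either a single vector (RMS, PCA, ICA, single-lead
#' Pan-Tompkins) or an n x L matrix for per-lead methods.
#'
#' @param y Numeric vector or matrix, sample-aligned with its source.
#' @param method One of `"PT"`, `"PTLEAD"`, `"RMS"`, `"PROD"`, `"PCA"`,
#'   `"ICA"`.
#' @param fs Sampling rate in Hz.
#' @return An object of class `feature_signal`.
#' @export
feature_signal <- function(y, method, fs) {
  method <- toupper(method)
  structure(list(y = y, method = method, fs = as.numeric(fs)),
            class = "feature_signal")
}

#' @export
print.feature_signal <- function(x, ...) {
  d <- if (is.matrix(x$y)) sprintf("%d x %d", nrow(x$y), ncol(x$y))
       else sprintf("%d", length(x$y))
  cat(sprintf("<feature_signal> method %s, %s samples @ %g Hz\n",
              x$method, d, x$fs))
  invisible(x)
}
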
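# Whole-database benchmarking against WFDB annotation files, producing
# a per-record merit-figure table with a mean summary row.

#' Benchmark the detector over a WFDB database directory
#'
#' Runs [detect_beats()] on every record and scores it against the
#' corresponding annotation file. Intended for local copies of
#' PhysioNet databases (e.g., the MIT-BIH arrhythmia or noise stress
#' test sets).
#'
#' @param dir Directory containing `<record>.hea`, `<record>.dat`, and
#'   annotation files.
#' @param records Character vector of record names; by default all
#'   `.hea` basenames in `dir`.
#' @param ann_ext Annotation file extension (default `"atr"`).
#' @param match_tol_ms Evaluation matching tolerance in ms.
#' @param verbose Print one line per record.
#' @param ... Passed to [detect_beats()] (feature, fusion, thr, ...).
#' @return Data frame with one row per record (`sen`, `spe`, `ppv`,
#'   `acc`, `error`, counts) plus a final `"Mean"` row averaging the
#'   percentage columns.
#' @export
benchmark_database <- function(dir, records = NULL, ann_ext = "atr",
                               match_tol_ms = 150, verbose = FALSE, ...) {
  if (!dir.exists(dir)) stop("database directory not found: ", dir)
  if (is.null(records)) {
    records <- sub("\\.hea$", "",
                   basename(list.files(dir, pattern = "\\.hea$")))
    records <- sort(records)
  }
  if (!length(records)) stop("no records found in ", dir)
  rows <- vector("list", length(records))
  for (i in seq_along(records)) {
    rec <- records[i]
    sig <- read_record(file.path(dir, rec))
    ref <- read_annotations(file.path(dir, paste0(rec, ".", ann_ext)))
    pk <- detect_beats(sig, ...)
    m <- evaluate_detections(pk, ref, sig$fs, match_tol_ms)
    rows[[i]] <- data.frame(record = rec, sen = m$sen, spe = m$spe,
                            ppv = m$ppv, acc = m$acc, error = m$error,
                            TP = m$TP, FP = m$FP, FN = m$FN, TN = m$TN)
    if (verbose)
      message(sprintf("%s: Sen %.2f PPV %.2f Err %.2f", rec, m$sen,
                      m$ppv, m$error))
  }
  tab <- do.call(rbind, rows)
  mean_row <- data.frame(record = "Mean", sen = mean(tab$sen),
                         spe = mean(tab$spe), ppv = mean(tab$ppv),
                         acc = mean(tab$acc), error = mean(tab$error),
                         TP = sum(tab$TP), FP = sum(tab$FP),
                         FN = sum(tab$FN), TN = sum(tab$TN))
  rbind(tab, mean_row)
}
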
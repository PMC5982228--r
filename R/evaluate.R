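# Beat-by-beat scoring of detections against reference annotations.
#
# Matching convention: a detection within a short tolerance of an
# annotated beat is a true positive (one-to-one); leftover detections
# are false positives and leftover annotations false negatives. A true
# negative is an interval between consecutive annotated beats that
# contains no false positive. Merit figures: Sen = TP/(TP+FN),
# PPV = TP/(TP+FP), Spe = TN/(TN+FP), Acc = (TP+TN)/B,
# Error = (FP+FN)/B with B = TP+FP+FN+TN, all as percentages.

#' Match detections to reference beats
#'
#' One-to-one greedy sweep: detections are processed in time order and
#' each is matched to the earliest still-unmatched reference within
#' `match_tol_ms`. With a uniform tolerance this sweep attains the
#' maximum possible number of matches (fewest FP + FN) in linear time,
#' which matters at long-term-monitoring scale (over half a million
#' beats per week-long record).
#'
#' @param detected A [peak_list] (sorted).
#' @param reference An [annotation_set] (sorted).
#' @param fs Sampling rate in Hz.
#' @param match_tol_ms Matching tolerance in ms (default 150, the
#'   beat-by-beat comparison convention of AAMI EC57).
#' @return A list with counts `TP`, `FP`, `FN`, the matched index pairs
#'   (`pairs`, 1-based into each list), `fp_indices` (sample positions
#'   of false positives) and `fn_indices` (missed reference beats).
#' @export
match_beats <- function(detected, reference, fs, match_tol_ms = 150) {
  d <- detected$indices; r <- reference$indices
  tol <- match_tol_ms * fs / 1000
  nd <- length(d); nr <- length(r)
  if (!nd || !nr) {
    return(list(TP = 0L, FP = nd, FN = nr,
                pairs = cbind(det = integer(0), ref = integer(0)),
                fp_indices = d, fn_indices = r))
  }
  pd <- integer(min(nd, nr)); pr <- integer(min(nd, nr))
  np <- 0L
  j <- 1L
  for (i in seq_len(nd)) {
    while (j <= nr && r[j] < d[i] - tol) j <- j + 1L
    if (j <= nr && r[j] <= d[i] + tol) {
      np <- np + 1L
      pd[np] <- i; pr[np] <- j
      j <- j + 1L
    }
  }
  pd <- pd[seq_len(np)]; pr <- pr[seq_len(np)]
  det_used <- logical(nd); det_used[pd] <- TRUE
  ref_used <- logical(nr); ref_used[pr] <- TRUE
  list(TP = np, FP = sum(!det_used), FN = sum(!ref_used),
       pairs = cbind(det = pd, ref = pr),
       fp_indices = d[!det_used], fn_indices = r[!ref_used])
}

#' Count true negatives
#'
#' A true negative is an interval between two consecutive annotated
#' beats containing no false-positive detection (strictly inside).
#'
#' @param reference An [annotation_set].
#' @param fp_indices Sample positions of the false positives.
#' @return Integer count; 0 when fewer than two reference beats exist.
#' @export
count_true_negatives <- function(reference, fp_indices) {
  r <- reference$indices
  if (length(r) < 2L) return(0L)
  n_gaps <- length(r) - 1L
  if (!length(fp_indices)) return(n_gaps)
  gap <- findInterval(fp_indices, r)
  bad <- unique(gap[gap >= 1L & gap <= n_gaps &
                      !(fp_indices %in% r)])
  n_gaps - length(bad)
}

#' Merit figures from detection counts
#'
#' @param counts A list with `TP`, `FP`, `FN`, `TN`.
#' @return A list of class `beat_metrics` with `sen`, `spe`, `ppv`,
#'   `acc`, `error` (percentages) and `B = TP+FP+FN+TN`. A metric with
#'   a zero denominator is `NaN` with a warning.
#' @examples
#' m <- compute_metrics(list(TP = 98, FN = 2, FP = 1, TN = 97))
#' round(m$sen, 2); round(m$error, 2)
#' @export
compute_metrics <- function(counts) {
  TP <- counts$TP; FP <- counts$FP; FN <- counts$FN; TN <- counts$TN
  B <- TP + FP + FN + TN
  ratio <- function(num, den, what) {
    if (den <= 0) {
      warning("zero denominator for ", what, "; reporting NaN")
      return(NaN)
    }
    100 * num / den
  }
  structure(list(
    sen = ratio(TP, TP + FN, "sensitivity"),
    ppv = ratio(TP, TP + FP, "positive predictive value"),
    spe = ratio(TN, TN + FP, "specificity"),
    acc = ratio(TP + TN, B, "accuracy"),
    error = ratio(FP + FN, B, "error"),
    TP = TP, FP = FP, FN = FN, TN = TN, B = B), class = "beat_metrics")
}

#' @export
print.beat_metrics <- function(x, ...) {
  cat(sprintf(
    "Sen %.2f  Spe %.2f  PPV %.2f  Acc %.2f  Error %.2f  (TP %d FP %d FN %d TN %d)\n",
    x$sen, x$spe, x$ppv, x$acc, x$error, x$TP, x$FP, x$FN, x$TN))
  invisible(x)
}

#' Evaluate detections against reference annotations
#'
#' Runs [match_beats()], [count_true_negatives()], and
#' [compute_metrics()] in one call.
#'
#' @inheritParams match_beats
#' @return A `beat_metrics` list (see [compute_metrics()]), with the
#'   matching result attached as field `match`.
#' @export
evaluate_detections <- function(detected, reference, fs,
                                match_tol_ms = 150) {
  m <- match_beats(detected, reference, fs, match_tol_ms)
  tn <- count_true_negatives(reference, m$fp_indices)
  out <- compute_metrics(list(TP = m$TP, FP = m$FP, FN = m$FN, TN = tn))
  out$match <- m
  out
}

#' Detection-error profile over time
#'
#' Bins the record into `bin_s`-second bins (per day by default) and
#' computes the error rate per bin from the beats, detections, and
#' true-negative gaps falling in it. True positives and false negatives
#' are binned by reference-beat time, false positives by detection
#' time, and true-negative gaps by their midpoint, so per-bin FP and FN
#' totals sum exactly to the global counts.
#'
#' @inheritParams match_beats
#' @param bin_s Bin width in seconds (default 86400 = 1 day).
#' @return Data frame with one row per bin: `bin`, `start_s`, `TP`,
#'   `FP`, `FN`, `TN`, `error` (percent; `NA` for empty bins).
#' @export
error_over_time <- function(detected, reference, fs, bin_s = 86400,
                            match_tol_ms = 150) {
  m <- match_beats(detected, reference, fs, match_tol_ms)
  r <- reference$indices
  last <- max(c(r, detected$indices, 0)) / fs
  n_bins <- max(1L, ceiling((last + 1e-9) / bin_s))
  bin_of <- function(samp) pmin(n_bins - 1L, floor(samp / fs / bin_s))
  tp_b <- bin_of(r[m$pairs[, "ref"]])
  fn_b <- bin_of(m$fn_indices)
  fp_b <- bin_of(m$fp_indices)
  tn_b <- integer(0)
  if (length(r) >= 2L) {
    inside <- !(m$fp_indices %in% r)
    gaps_bad <- findInterval(m$fp_indices[inside], r)
    mid <- (r[-length(r)] + r[-1L]) / 2
    good <- !(seq_len(length(r) - 1L) %in%
                gaps_bad[gaps_bad >= 1L & gaps_bad < length(r)])
    tn_b <- bin_of(mid[good])
  }
  cnt <- function(b) tabulate(b + 1L, nbins = n_bins)
  out <- data.frame(bin = seq_len(n_bins) - 1L,
                    start_s = (seq_len(n_bins) - 1L) * bin_s,
                    TP = cnt(tp_b), FP = cnt(fp_b), FN = cnt(fn_b),
                    TN = cnt(tn_b))
  B <- out$TP + out$FP + out$FN + out$TN
  out$error <- ifelse(B > 0, 100 * (out$FP + out$FN) / B, NA_real_)
  out
}

#' K-fold grid search for threshold parameters
#'
#' Evaluates every `(alpha, beta)` grid point on every record by
#' running the full detector, splits the records into K folds, and for
#' each fold picks the grid point minimizing the mean training error
#' and scores it on the held-out fold. The returned parameters are the
#' grid point with minimal mean held-out error.
#'
#' @param records List of `list(signal = , annotations = )` pairs; at
#'   least K entries.
#' @param K Fold count (>= 2).
#' @param alpha_grid,beta_grid Candidate values.
#' @param match_tol_ms Evaluation matching tolerance in ms.
#' @param ... Passed to [detect_beats()] (feature, fusion, plan, ...).
#' @return A list: `alpha`, `beta`, `cv_error` (mean held-out error of
#'   the selected point), `fold_fits` (per-fold training-selected grid
#'   points), `fold_errors` (held-out error of each fold's fit), and
#'   the full `error_matrix` (records x grid).
#' @export
tune_threshold <- function(records, K = 4, alpha_grid = c(2, 3, 4),
                           beta_grid = c(0.25, 0.5, 1),
                           match_tol_ms = 150, ...) {
  if (length(alpha_grid) < 1L || length(beta_grid) < 1L)
    stop("empty parameter grid")
  R <- length(records)
  if (R < K) stop("need at least K = ", K, " records (got ", R, ")")
  grid <- expand.grid(alpha = alpha_grid, beta = beta_grid,
                      KEEP.OUT.ATTRS = FALSE)
  E <- matrix(NA_real_, R, nrow(grid))
  for (ri in seq_len(R)) {
    rec <- records[[ri]]
    for (gi in seq_len(nrow(grid))) {
      pk <- detect_beats(rec$signal,
                         thr = threshold_params(grid$alpha[gi],
                                                grid$beta[gi]), ...)
      # extreme grid points can yield no detections at all; their PPV
      # is undefined but only the error rate is consumed here
      ev <- suppressWarnings(
        evaluate_detections(pk, rec$annotations, rec$signal$fs,
                            match_tol_ms))
      E[ri, gi] <- ev$error
    }
  }
  fold_of <- rep_len(seq_len(K), R)   # round-robin assignment
  fold_fits <- integer(K); fold_errors <- numeric(K)
  heldout <- matrix(NA_real_, K, nrow(grid))
  for (k in seq_len(K)) {
    tr <- fold_of != k
    train_err <- colMeans(E[tr, , drop = FALSE])
    fold_fits[k] <- which.min(train_err)
    heldout[k, ] <- colMeans(E[!tr, , drop = FALSE])
    fold_errors[k] <- heldout[k, fold_fits[k]]
  }
  mean_heldout <- colMeans(heldout)
  best <- which.min(mean_heldout)
  list(alpha = grid$alpha[best], beta = grid$beta[best],
       cv_error = mean_heldout[best],
       fold_fits = cbind(alpha = grid$alpha[fold_fits],
                         beta = grid$beta[fold_fits]),
       fold_errors = fold_errors,
       grid = grid, error_matrix = E)
}

#' Compare two detectors beat by beat
#'
#' Classifies each reference beat by which detector found it, and each
#' detection by whether it is a false positive of one detector only.
#' Beats detected by `a` but missed by `b` are sub-classified into
#' bursts (runs of at least 3 consecutive missed reference beats) or
#' single-beat misses.
#'
#' @param a,b [peak_list] detections of the two detectors.
#' @param reference An [annotation_set].
#' @param fs Sampling rate in Hz.
#' @param match_tol_ms Matching tolerance in ms.
#' @param burst_len Minimum run length counting as a burst (default 3).
#' @return A list of counts and index vectors: `a_only`, `b_only`
#'   (reference beats detected by exactly one), `shared_missed`,
#'   `fp_a`, `fp_b`, and for the `a_only` set the split into
#'   `burst_beats` and `single_beats`.
#' @export
compare_detectors <- function(a, b, reference, fs, match_tol_ms = 150,
                              burst_len = 3L) {
  ma <- match_beats(a, reference, fs, match_tol_ms)
  mb <- match_beats(b, reference, fs, match_tol_ms)
  nr <- length(reference$indices)
  hit_a <- logical(nr); hit_a[ma$pairs[, "ref"]] <- TRUE
  hit_b <- logical(nr); hit_b[mb$pairs[, "ref"]] <- TRUE
  a_only <- which(hit_a & !hit_b)
  b_only <- which(!hit_a & hit_b)
  shared <- which(!hit_a & !hit_b)
  burst_beats <- integer(0); single_beats <- integer(0)
  if (length(a_only)) {
    runs <- split(a_only, cumsum(c(1L, diff(a_only) != 1L)))
    for (rn in runs) {
      if (length(rn) >= burst_len) burst_beats <- c(burst_beats, rn)
      else single_beats <- c(single_beats, rn)
    }
  }
  list(a_only = a_only, b_only = b_only, shared_missed = shared,
       fp_a = ma$fp_indices, fp_b = mb$fp_indices,
       burst_beats = burst_beats, single_beats = single_beats,
       counts = c(a_only = length(a_only), b_only = length(b_only),
                  shared_missed = length(shared),
                  fp_a = length(ma$fp_indices),
                  fp_b = length(mb$fp_indices),
                  burst = length(burst_beats),
                  single = length(single_beats)))
}
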
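# R-wave detection: adaptive amplitude thresholding of a feature
# signal, widening of supra-threshold regions, coarse (filtered-lead
# argmax) and fine (soft-filtered signal argmax) localization, a
# refractory period, and multilead fusion of per-lead detections.

#' Adaptive threshold parameters
#'
#' The detection threshold over a feature signal `y` is
#' `alpha * mean(y) + beta * sd(y)`, recomputed over consecutive
#' disjoint windows of `update_s` seconds and held constant within each
#' window. The short update interval lets the threshold follow
#' amplitude changes from beat to beat. Defaults `alpha = 3`,
#' `beta = 0.5`, `update_s = 3`.
#'
#' @param alpha Mean multiplier (>= 0).
#' @param beta Standard-deviation multiplier (>= 0).
#' @param update_s Threshold refresh interval in seconds (> 0).
#' @return A list of class `threshold_params`.
#' @export
threshold_params <- function(alpha = 3, beta = 0.5, update_s = 3) {
  stopifnot(alpha >= 0, beta >= 0, update_s > 0)
  structure(list(alpha = alpha, beta = beta, update_s = update_s),
            class = "threshold_params")
}

#' Lead-fusion configuration
#'
#' @param method Fusion rule: `"POLL"` (majority of leads), `"AND"`
#'   (all leads), `"SC"` (simple coupling, at least two leads), `"OR"`
#'   (any lead).
#' @param tolerance_ms Clustering tolerance between per-lead peak
#'   positions, in ms (default 10; at low sampling rates the tolerance
#'   is at least one sample).
#' @param refractory_ms Minimum spacing between detected beats, ms.
#' @return A list of class `fusion_config`.
#' @export
fusion_config <- function(method = c("POLL", "AND", "SC", "OR"),
                          tolerance_ms = 10, refractory_ms = 250) {
  method <- toupper(method)
  method <- match.arg(method)
  stopifnot(tolerance_ms > 0, refractory_ms >= 0)
  structure(list(method = method, tolerance_ms = tolerance_ms,
                 refractory_ms = refractory_ms),
            class = "fusion_config")
}

#' Per-window adaptive threshold
#'
#' @param y Nonnegative feature vector.
#' @param fs Sampling rate in Hz.
#' @param params A [threshold_params()].
#' @return Numeric vector of thresholds, one per sample, constant
#'   within each update window. A window that is entirely zero (signal
#'   loss) inherits the previous window's threshold.
#' @export
adaptive_threshold <- function(y, fs, params = threshold_params()) {
  n <- length(y)
  w <- max(2L, as.integer(round(params$update_s * fs)))
  thr <- numeric(n)
  prev <- NA_real_
  starts <- seq(1L, n, by = w)
  for (s in starts) {
    e <- min(n, s + w - 1L)
    yw <- y[s:e]
    if (all(yw == 0) && !is.na(prev)) {
      t_w <- prev
    } else {
      sdw <- if (length(yw) > 1L) stats::sd(yw) else 0
      t_w <- params$alpha * mean(yw) + params$beta * sdw
    }
    thr[s:e] <- t_w
    prev <- t_w
  }
  thr
}

#' Supra-threshold candidate regions
#'
#' Maximal runs where `y > thr`, widened by `widen_ms` on both sides
#' (clipped to the record) with overlapping regions merged.
#'
#' @param y Feature vector.
#' @param thr Threshold vector of equal length.
#' @param fs Sampling rate in Hz.
#' @param widen_ms Widening in ms (default 75 each side).
#' @return Data frame with 0-based half-open `start`, `end` columns;
#'   zero rows when nothing exceeds the threshold.
#' @export
candidate_regions <- function(y, thr, fs, widen_ms = 75) {
  stopifnot(length(y) == length(thr))
  above <- y > thr
  if (!any(above)) return(data.frame(start = integer(0), end = integer(0)))
  r <- rle(above)
  ends_1b <- cumsum(r$lengths)
  starts_1b <- ends_1b - r$lengths + 1L
  keep <- r$values
  w <- as.integer(round(widen_ms * fs / 1000))
  start <- pmax(0L, starts_1b[keep] - 1L - w)          # to 0-based
  end <- pmin(length(y), ends_1b[keep] + w)            # half-open
  # merge overlapping or touching widened runs
  o <- order(start)
  start <- start[o]; end <- end[o]
  ms <- start[1L]; me <- end[1L]
  out_s <- integer(0); out_e <- integer(0)
  for (i in seq_along(start)[-1L]) {
    if (start[i] <= me) {
      me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- start[i]; me <- end[i]
    }
  }
  data.frame(start = c(out_s, ms), end = c(out_e, me))
}

#' Coarse peak localization
#'
#' One peak per candidate region: the argmax of the absolute search
#' signal within the region (earliest sample on ties).
#'
#' @param regions Data frame from [candidate_regions()].
#' @param x Search signal (typically the band-pass + derivative
#'   filtered lead).
#' @param fs Sampling rate.
#' @param lead Lead identifier for the returned [peak_list].
#' @return A [peak_list] with per-peak `|x|` amplitudes.
#' @export
coarse_peaks <- function(regions, x, fs = NA_real_, lead = "1") {
  if (!nrow(regions))
    return(peak_list(integer(0), lead = lead, amplitudes = numeric(0),
                     fs = fs))
  idx <- integer(nrow(regions)); amp <- numeric(nrow(regions))
  ax <- abs(x)
  for (i in seq_len(nrow(regions))) {
    s <- regions$start[i] + 1L; e <- regions$end[i]
    j <- which.max(ax[s:e])                       # earliest max on ties
    idx[i] <- s + j - 2L                          # back to 0-based
    amp[i] <- ax[s + j - 1L]
  }
  peak_list(idx, lead = lead, amplitudes = amp, fs = fs)
}

#' Fine peak localization
#'
#' Moves each coarse peak to the argmax of the absolute soft-filtered
#' signal in a window of `window_ms` centered on it (clipped at record
#' edges). The soft signal is a gently low-passed version of the
#' preprocessed ECG, so peaks land on the actual R-wave apex.
#'
#' @param coarse A [peak_list] of coarse peaks.
#' @param soft Numeric vector, the soft-filtered single-lead signal.
#' @param fs Sampling rate.
#' @param window_ms Full search-window width in ms (default 100).
#' @return A [peak_list] with `|soft|` amplitudes; peaks that snap to
#'   the same sample are collapsed.
#' @export
fine_peaks <- function(coarse, soft, fs, window_ms = 100) {
  if (!length(coarse$indices))
    return(peak_list(integer(0), lead = coarse$lead,
                     amplitudes = numeric(0), fs = fs))
  h <- max(1L, as.integer(round(window_ms * fs / 1000 / 2)))
  n <- length(soft)
  asoft <- abs(soft)
  idx <- vapply(coarse$indices, function(p) {
    s <- max(0L, p - h); e <- min(n - 1L, p + h)
    s + which.max(asoft[(s + 1L):(e + 1L)]) - 1L
  }, 0L)
  keep <- !duplicated(idx)
  idx <- idx[keep]
  o <- order(idx)
  idx <- idx[o]
  peak_list(idx, lead = coarse$lead, amplitudes = asoft[idx + 1L], fs = fs)
}

#' Enforce a refractory period
#'
#' Greedy pruning by amplitude: peaks are accepted in order of
#' decreasing amplitude (earliest first on ties) provided they lie at
#' least `refractory_ms` from every already-accepted peak. Suppresses
#' double detections such as prominent T-waves.
#'
#' @param peaks A [peak_list] carrying amplitudes.
#' @param fs Sampling rate.
#' @param refractory_ms Minimum inter-peak spacing in ms.
#' @return A [peak_list] with spacing >= the refractory period.
#' @export
apply_refractory <- function(peaks, fs, refractory_ms = 250) {
  idx <- peaks$indices
  if (length(idx) < 2L) return(peaks)
  amp <- peaks$amplitudes
  if (is.null(amp)) amp <- rep(1, length(idx))
  rf <- as.integer(round(refractory_ms * fs / 1000))
  ord <- order(-amp, idx)
  accepted <- integer(0)
  for (k in ord) {
    if (!length(accepted) || all(abs(idx[k] - idx[accepted]) >= rf))
      accepted <- c(accepted, k)
  }
  accepted <- sort(accepted)
  peak_list(idx[accepted], lead = peaks$lead,
            amplitudes = amp[accepted], fs = fs)
}

# support needed for a fusion rule over L leads
.fusion_support <- function(method, L) {
  switch(method,
    AND = L,
    POLL = L %/% 2L + 1L,
    SC = if (L < 2L) stop("SC fusion requires >= 2 leads") else 2L,
    OR = 1L,
    stop("unknown fusion method: ", method))
}

#' Fuse per-lead peak lists
#'
#' Pools the per-lead detections, clusters peaks lying within the
#' tolerance of each other (one peak per lead per cluster), and emits a
#' fused peak (the median of the cluster member positions) when the
#' cluster's lead support meets the rule: AND = all L leads, POLL =
#' majority (`floor(L/2) + 1`), SC = at least 2, OR = any. With a
#' single lead the input list is returned unchanged whatever the rule.
#'
#' @param per_lead List of per-lead [peak_list] objects (sorted).
#' @param cfg A [fusion_config()].
#' @param fs Sampling rate in Hz.
#' @return A fused [peak_list].
#' @export
fuse_leads <- function(per_lead, cfg = fusion_config(), fs) {
  L <- length(per_lead)
  if (L == 0L) return(peak_list(integer(0), fs = fs))
  if (L == 1L) {
    out <- per_lead[[1L]]
    out$lead <- "FUSED"
    return(out)
  }
  need <- .fusion_support(cfg$method, L)
  tol <- max(1L, as.integer(round(cfg$tolerance_ms * fs / 1000)))
  idx <- unlist(lapply(per_lead, `[[`, "indices"))
  amp <- unlist(lapply(per_lead, function(p) {
    a <- p$amplitudes
    if (is.null(a)) rep(1, length(p$indices)) else a
  }))
  lead <- rep(seq_len(L), vapply(per_lead, function(p)
    length(p$indices), 0L))
  if (!length(idx)) return(peak_list(integer(0), fs = fs))
  o <- order(idx, lead)
  idx <- idx[o]; lead <- lead[o]; amp <- amp[o]
  cl <- integer(length(idx))
  cl[1L] <- 1L
  members_leads <- lead[1L]
  for (i in seq_along(idx)[-1L]) {
    if (idx[i] - idx[i - 1L] <= tol && !(lead[i] %in% members_leads)) {
      cl[i] <- cl[i - 1L]
      members_leads <- c(members_leads, lead[i])
    } else {
      cl[i] <- cl[i - 1L] + 1L
      members_leads <- lead[i]
    }
  }
  fused_idx <- integer(0); fused_amp <- numeric(0)
  for (c_id in unique(cl)) {
    sel <- cl == c_id
    if (sum(sel) >= need) {
      fused_idx <- c(fused_idx, as.integer(floor(stats::median(idx[sel]))))
      fused_amp <- c(fused_amp, max(amp[sel]))
    }
  }
  if (length(fused_idx)) {
    keep <- !duplicated(fused_idx)
    fused_idx <- fused_idx[keep]; fused_amp <- fused_amp[keep]
  }
  peak_list(fused_idx, lead = "FUSED", amplitudes = fused_amp, fs = fs)
}

# detection on one feature vector: threshold -> regions -> coarse ->
# fine -> refractory
.detect_on_vector <- function(y, search, soft, fs, thr_params, cfg,
                              widen_ms = 75, fine_window_ms = 100,
                              lead = "1") {
  thr <- adaptive_threshold(y, fs, thr_params)
  regions <- candidate_regions(y, thr, fs, widen_ms)
  pk <- coarse_peaks(regions, search, fs, lead)
  pk <- fine_peaks(pk, soft, fs, fine_window_ms)
  apply_refractory(pk, fs, cfg$refractory_ms)
}

#' Detect R-peaks in a multilead record
#'
#' The full pipeline: the record is processed in (overlapping) segments;
#' each segment is preprocessed, transformed into the requested feature
#' signal(s), thresholded adaptively, and peaks are localized with the
#' coarse/fine two-stage search and a refractory period. For per-lead
#' features (`"ptlead"`, `"prod"`) the per-lead detections are fused
#' with the configured rule; single-vector features (`"pt"`, `"rms"`,
#' `"pca"`, `"ica"`) yield the detection list directly. Segment results
#' are stitched: each segment contributes only the peaks in its core
#' (non-overlap) zone and residual duplicates within the fusion
#' tolerance are dropped.
#'
#' @param signal A raw [multilead_signal].
#' @param feature Feature method (see [extract_feature()]).
#' @param fusion A [fusion_config()].
#' @param thr A [threshold_params()].
#' @param plan A [plan_segments()] result, or `NULL` for the default
#'   300-s segments with 2-s overlap.
#' @param pre A [preprocess_config()].
#' @param widen_ms Region widening in ms (default 75).
#' @param fine_window_ms Fine-search window in ms (default 100).
#' @param soft_lowpass_hz Cutoff of the soft-filtered signal used by
#'   the fine search (default 40 Hz).
#' @param seed Seed for the ICA feature.
#' @return A fused [peak_list] of R-peak sample indices (0-based).
#' @examples
#' rec <- synth_ecg(synth_config(duration_s = 30, seed = 7))
#' pk <- detect_beats(rec$signal)
#' length(pk$indices)
#' @export
detect_beats <- function(signal, feature = "ptlead",
                         fusion = fusion_config(),
                         thr = threshold_params(),
                         plan = NULL,
                         pre = preprocess_config(),
                         widen_ms = 75, fine_window_ms = 100,
                         soft_lowpass_hz = 40, seed = 1L) {
  if (is.null(plan)) plan <- plan_segments(signal)
  fs <- signal$fs
  n <- n_samples(signal)
  ov <- as.integer(round(plan$overlap_s * fs))
  tol <- max(1L, as.integer(round(fusion$tolerance_ms * fs / 1000)))
  segs <- plan$segments
  all_idx <- integer(0); all_amp <- numeric(0)
  for (si in seq_len(nrow(segs))) {
    s0 <- segs$start[si]; s1 <- segs$end[si]
    seg <- slice_signal(signal, s0, s1)
    pk <- .detect_segment(seg, feature, fusion, thr, pre, widen_ms,
                          fine_window_ms, soft_lowpass_hz, seed)
    core_lo <- if (si == 1L) 0L else s0 + ov %/% 2L
    core_hi <- if (si == nrow(segs)) n else s1 - ov %/% 2L
    abs_idx <- pk$indices + s0
    keep <- abs_idx >= core_lo & abs_idx < core_hi
    all_idx <- c(all_idx, abs_idx[keep])
    amp <- if (is.null(pk$amplitudes)) rep(1, length(pk$indices))
           else pk$amplitudes
    all_amp <- c(all_amp, amp[keep])
  }
  if (length(all_idx)) {
    o <- order(all_idx)
    all_idx <- all_idx[o]; all_amp <- all_amp[o]
    keep <- c(TRUE, diff(all_idx) > tol)   # boundary duplicates
    all_idx <- all_idx[keep]; all_amp <- all_amp[keep]
  }
  peak_list(all_idx, lead = "FUSED", amplitudes = all_amp, fs = fs)
}

.detect_segment <- function(seg, feature, fusion, thr, pre, widen_ms,
                            fine_window_ms, soft_lowpass_hz, seed) {
  fs <- seg$fs
  if (all(seg$samples == 0))
    return(peak_list(integer(0), fs = fs))
  clean <- preprocess_record(seg, pre)
  soft_sig <- lowpass(clean, min(soft_lowpass_hz, fs / 2 * 0.9))
  feat <- extract_feature(clean, feature, seed = seed)
  y <- feat$y
  if (is.matrix(y) && ncol(y) > 1L) {
    xf <- derivative_filter_leads(clean)
    per_lead <- lapply(seq_len(ncol(y)), function(i) {
      .detect_on_vector(abs(y[, i]), xf$xf[, i], soft_sig$samples[, i],
                        fs, thr, fusion, widen_ms, fine_window_ms,
                        lead = as.character(i)) })
    fuse_leads(per_lead, fusion, fs)
  } else {
    y <- as.numeric(y)
    soft_comb <- if (feature == "pt" && !is.null(feat$lead))
      soft_sig$samples[, feat$lead]
    else sqrt(rowSums(soft_sig$samples^2))
    search <- if (feature == "pt" && !is.null(feat$lead))
      derivative_filter_leads(clean)$xf[, feat$lead]
    else y
    pk <- .detect_on_vector(abs(y), search, soft_comb, fs, thr, fusion,
                            widen_ms, fine_window_ms, lead = "FUSED")
    pk$lead <- "FUSED"
    pk
  }
}
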
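test_that("beat matching follows the tolerance and is one-to-one", {
  fs <- 1000
  ref <- annotation_set(c(1000L, 2000L))
  det <- peak_list(c(1100L, 2000L), fs = fs)   # first is ref + 100 ms
  m <- match_beats(det, ref, fs, match_tol_ms = 150)
  expect_equal(c(m$TP, m$FP, m$FN), c(2L, 0L, 0L))

  none <- peak_list(integer(0), fs = fs)
  ten <- annotation_set(seq(1000L, 10000L, by = 1000L))
  m2 <- match_beats(none, ten, fs)
  expect_equal(c(m2$TP, m2$FN), c(0L, 10L))
  expect_equal(m2$fn_indices, ten$indices)
})

test_that("greedy sweep matching attains the optimal match count", {
  fs <- 1000
  tol_ms <- 150
  tol <- tol_ms * fs / 1000
  set.seed(14)
  for (rep_i in 1:30) {
    # references with roughly physiologic spacing; jittered/dropped
    # detections plus occasional spurious extras
    r <- cumsum(sample(400:1200, sample(3:8, 1), replace = TRUE))
    keep <- runif(length(r)) > 0.2
    d <- r[keep] + sample(-200:200, sum(keep), replace = TRUE)
    d <- sort(unique(c(d, sample.int(max(r), sample(0:2, 1)))))
    m <- match_beats(peak_list(d, fs = fs),
                     annotation_set(sort(unique(r))), fs, tol_ms)
    expect_equal(m$TP, oracle_max_matching(d, sort(unique(r)), tol))
    expect_equal(m$TP + m$FN, length(unique(r)))
    expect_equal(m$TP + m$FP, length(d))
  }
})

test_that("true negatives count the clean inter-beat gaps", {
  ref <- annotation_set(seq(1000L, 10000L, by = 1000L))  # 10 beats
  expect_equal(count_true_negatives(ref, integer(0)), 9L)
  expect_equal(count_true_negatives(ref, 1500L), 8L)
  expect_equal(count_true_negatives(annotation_set(100L), 50L), 0L)

  set.seed(15)
  for (rep_i in 1:20) {
    refs <- sort(sample.int(100000, 12))
    fps <- sort(sample.int(100000, 5))
    got <- count_true_negatives(annotation_set(refs), fps)
    expect_equal(got, oracle_true_negatives(refs, fps))
  }
})

test_that("merit figures follow the printed formulas", {
  m <- compute_metrics(list(TP = 98, FN = 2, FP = 1, TN = 97))
  expect_equal(m$sen, 98.00, tolerance = 1e-10)
  expect_equal(m$ppv, 100 * 98 / 99, tolerance = 1e-10)
  expect_equal(m$spe, 100 * 97 / 98, tolerance = 1e-10)
  expect_equal(m$acc, 100 * 195 / 198, tolerance = 1e-10)
  expect_equal(m$error, 100 * 3 / 198, tolerance = 1e-10)
  expect_equal(m$B, 198)

  # a perfect record: FP = FN = 0
  p <- compute_metrics(list(TP = 2000, FN = 0, FP = 0, TN = 1999))
  expect_equal(c(p$sen, p$spe, p$ppv), c(100, 100, 100))
  expect_equal(p$acc, 100)
  expect_equal(p$error, 0)

  set.seed(16)
  for (rep_i in 1:20) {
    c_ <- as.list(setNames(sample(1:500, 4, TRUE),
                           c("TP", "FP", "FN", "TN")))
    g <- compute_metrics(c_)
    B <- c_$TP + c_$FP + c_$FN + c_$TN
    expect_equal(g$sen, 100 * c_$TP / (c_$TP + c_$FN))
    expect_equal(g$acc + g$error, 100)      # identity under this B
    expect_equal(g$acc, 100 * (c_$TP + c_$TN) / B)
  }
  expect_warning(z <- compute_metrics(list(TP = 0, FN = 0, FP = 1, TN = 1)),
                 "zero denominator")
  expect_true(is.nan(z$sen))
})

test_that("evaluation is invariant to a uniform time shift", {
  fs <- 200
  set.seed(17)
  ref <- sort(sample.int(50000, 40))
  det <- sort(unique(ref + sample(-5:5, 40, TRUE)))
  e1 <- evaluate_detections(peak_list(det, fs = fs),
                            annotation_set(ref), fs)
  sh <- 1234L
  e2 <- evaluate_detections(peak_list(det + sh, fs = fs),
                            annotation_set(ref + sh), fs)
  expect_equal(c(e1$TP, e1$FP, e1$FN, e1$TN),
               c(e2$TP, e2$FP, e2$FN, e2$TN))
})

test_that("the error-over-time profile conserves global error counts", {
  fs <- 200
  rec <- synth_ltm(synth_config(seed = 41),
                   day_snr_db = c(Inf, Inf, 0, Inf), day_s = 30)
  pk <- detect_beats(rec$signal,
                     plan = plan_segments(rec$signal, 60, 2))
  prof <- error_over_time(pk, rec$annotations, fs, bin_s = 30)
  glob <- evaluate_detections(pk, rec$annotations, fs)
  expect_equal(sum(prof$FP) + sum(prof$FN), glob$FP + glob$FN)
  expect_equal(sum(prof$TP), glob$TP)

  # perfect detection: an all-zero error profile
  perf <- error_over_time(peak_list(rec$annotations$indices, fs = fs),
                          rec$annotations, fs, bin_s = 30)
  expect_true(all(perf$error == 0))

  # all errors concentrated in one bin show up only there
  det <- rec$annotations$indices
  fp_extra <- sort(c(det, 30 * fs * 2 + c(100L, 350L, 600L)))
  prof2 <- error_over_time(peak_list(fp_extra, fs = fs),
                           rec$annotations, fs, bin_s = 30)
  expect_true(all(prof2$error[prof2$bin != 2] == 0))
  expect_gt(prof2$error[prof2$bin == 2], 0)
})

test_that("threshold tuning agrees with an exhaustive CV oracle", {
  recs <- lapply(1:4, function(i)
    synth_ecg(synth_config(duration_s = 45, seed = 50 + i,
                           noise = list(list(type = "muscle",
                                             snr_db = 8)))))
  records <- lapply(recs, function(r)
    list(signal = r$signal, annotations = r$annotations))
  plan_args <- list(plan = NULL)
  res <- tune_threshold(records, K = 4, alpha_grid = c(2, 3, 6),
                        beta_grid = c(0.25, 0.5, 2))
  # oracle: recompute fold logic by hand from the error matrix
  E <- res$error_matrix
  fold_of <- rep_len(1:4, 4)
  held <- matrix(NA_real_, 4, ncol(E))
  for (k in 1:4) {
    held[k, ] <- colMeans(E[fold_of == k, , drop = FALSE])
  }
  best <- which.min(colMeans(held))
  expect_equal(c(res$alpha, res$beta),
               c(res$grid$alpha[best], res$grid$beta[best]))
  expect_equal(res$cv_error, min(colMeans(held)))

  # a single-point grid is returned as-is
  one <- tune_threshold(records[1:2], K = 2, alpha_grid = 3,
                        beta_grid = 0.5)
  expect_equal(c(one$alpha, one$beta), c(3, 0.5))
  expect_error(tune_threshold(records, K = 4, alpha_grid = numeric(0)),
               "empty")
  expect_error(tune_threshold(records[1:2], K = 4), "at least K")
})

test_that("detector comparison classifies bursts and single misses", {
  fs <- 200
  ref <- annotation_set(seq(1000L, 20000L, by = 1000L))  # 20 beats
  full <- peak_list(ref$indices, fs = fs)
  ident <- compare_detectors(full, full, ref, fs)
  expect_equal(sum(ident$counts[c("a_only", "b_only", "shared_missed",
                                  "fp_a", "fp_b")]), 0)

  # b misses reference beats 10..14 (a run of 5) and beat 2 (single)
  b <- peak_list(ref$indices[-c(2, 10:14)], fs = fs)
  res <- compare_detectors(full, b, ref, fs)
  expect_equal(res$burst_beats, 10:14)
  expect_equal(res$single_beats, 2L)
  expect_equal(res$counts[["burst"]], 5L)

  set.seed(18)
  for (rep_i in 1:10) {
    miss_a <- sample(20, 4); miss_b <- sample(20, 6)
    a_ <- peak_list(ref$indices[-miss_a], fs = fs)
    b_ <- peak_list(ref$indices[-miss_b], fs = fs)
    res <- compare_detectors(a_, b_, ref, fs)
    expect_equal(sort(res$a_only), sort(setdiff(miss_b, miss_a)))
    expect_equal(sort(res$b_only), sort(setdiff(miss_a, miss_b)))
    expect_equal(sort(res$shared_missed),
                 sort(intersect(miss_a, miss_b)))
  }
})
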
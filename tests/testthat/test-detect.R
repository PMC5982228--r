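test_that("the adaptive threshold follows the printed formula per window", {
  fs <- 10
  p <- threshold_params()
  expect_equal(p$alpha, 3)
  expect_equal(p$beta, 0.5)
  expect_equal(p$update_s, 3)

  const <- rep(2, 100)
  expect_equal(adaptive_threshold(const, fs, p), rep(6, 100))

  # one full window engineered to mean 1, sd 0.5
  y <- rep(c(0.5, 1.5), 15)
  thr <- adaptive_threshold(y, fs, threshold_params(3, 0.5, 3))
  expect_equal(thr[1], 3 * 1 + 0.5 * sd(y[1:30]))
  expect_lt(abs(thr[1] - 3.25), 0.01)

  # an all-zero window inherits the previous window's threshold
  y2 <- c(rep(2, 30), rep(0, 30), rep(2, 30))
  thr2 <- adaptive_threshold(y2, fs, p)
  expect_equal(thr2[31], thr2[30])
})

test_that("candidate regions widen, merge, and clip as specified", {
  fs <- 200
  y <- rep(0, 1000)
  expect_equal(nrow(candidate_regions(y, rep(1, 1000), fs)), 0L)

  y[501] <- 5   # single supra-threshold sample at 0-based index 500
  reg <- candidate_regions(y, rep(1, 1000), fs, widen_ms = 75)
  expect_equal(nrow(reg), 1L)
  expect_equal(reg$end - reg$start, 31L)   # 15 samples each side
  expect_equal(reg$start, 485L)

  # two crossings 50 ms (10 samples) apart merge after 75-ms widening
  y2 <- rep(0, 1000); y2[c(501, 511)] <- 5
  reg2 <- candidate_regions(y2, rep(1, 1000), fs, 75)
  expect_equal(nrow(reg2), 1L)

  # clipping at the record edges
  y3 <- rep(0, 100); y3[c(1, 100)] <- 5
  reg3 <- candidate_regions(y3, rep(1, 100), fs, 75)
  expect_equal(reg3$start[1], 0L)
  expect_equal(reg3$end[nrow(reg3)], 100L)
})

test_that("coarse search takes the earliest absolute maximum per region", {
  x <- c(0, 1, 5, 2, 0, -7, 3, 0)
  reg <- data.frame(start = c(0L, 4L), end = c(4L, 8L))
  pk <- coarse_peaks(reg, x, fs = 200)
  expect_equal(pk$indices, c(2L, 5L))
  expect_equal(pk$amplitudes, c(5, 7))

  flat <- data.frame(start = 2L, end = 6L)
  expect_equal(coarse_peaks(flat, rep(1, 8), 200)$indices, 2L)

  set.seed(11)
  for (rep_i in 1:10) {
    x <- rnorm(50)
    reg <- data.frame(start = c(0L, 25L), end = c(20L, 50L))
    got <- coarse_peaks(reg, x, 200)$indices
    brute <- c(which.max(abs(x[1:20])) - 1L,
               24L + which.max(abs(x[26:50])))
    expect_equal(got, brute)
  }
})

test_that("fine search snaps to the soft-signal apex and clips at edges", {
  fs <- 200
  soft <- rep(0, 400)
  soft[201] <- 1                    # apex at 0-based 200
  co <- peak_list(200L, amplitudes = 1, fs = fs)
  expect_equal(fine_peaks(co, soft, fs)$indices, 200L)

  off <- peak_list(205L, amplitudes = 1, fs = fs)
  expect_equal(fine_peaks(off, soft, fs, window_ms = 100)$indices, 200L)

  edge <- peak_list(c(1L, 398L), amplitudes = c(1, 1), fs = fs)
  got <- fine_peaks(edge, soft, fs)
  expect_true(all(got$indices >= 0 & got$indices < 400))
})

test_that("the refractory filter keeps the larger of close peaks", {
  fs <- 1000
  close <- peak_list(c(1000L, 1100L), amplitudes = c(1, 2), fs = fs)
  out <- apply_refractory(close, fs, 250)
  expect_equal(out$indices, 1100L)

  far <- peak_list(c(1000L, 1400L), amplitudes = c(1, 2), fs = fs)
  expect_equal(apply_refractory(far, fs, 250)$indices, c(1000L, 1400L))

  set.seed(12)
  for (rep_i in 1:20) {
    idx <- sort(sample.int(5000, 15))
    amp <- runif(15)
    got <- apply_refractory(peak_list(idx, amplitudes = amp, fs = fs),
                            fs, 250)
    expect_equal(got$indices, oracle_refractory(idx, amp, 250))
    if (length(got$indices) > 1)
      expect_true(all(diff(got$indices) >= 250))
  }
})

test_that("fusion rules emit clusters at the required lead support", {
  fs <- 200
  mk <- function(idx) peak_list(idx, fs = fs)
  three <- list(mk(1000L), mk(1001L), mk(1000L))
  poll <- fuse_leads(three, fusion_config("POLL"), fs)
  expect_equal(poll$indices, 1000L)

  one_of3 <- list(mk(1000L), mk(integer(0)), mk(integer(0)))
  expect_length(fuse_leads(one_of3, fusion_config("POLL"), fs)$indices, 0)
  expect_equal(fuse_leads(one_of3, fusion_config("OR"), fs)$indices, 1000L)

  # single lead: returned unchanged whatever the rule
  single <- list(mk(c(10L, 400L)))
  expect_equal(fuse_leads(single, fusion_config("AND"), fs)$indices,
               c(10L, 400L))
})

test_that("fusion inclusions hold against the brute-force cluster oracle", {
  fs <- 200
  tol <- max(1L, round(0.010 * fs))
  set.seed(13)
  for (rep_i in 1:100) {
    L <- sample(2:4, 1)
    cfgs <- random_peak_config(n_leads = L)
    per_lead <- lapply(cfgs, function(ix) peak_list(ix, fs = fs))
    got <- list(
      AND = fuse_leads(per_lead, fusion_config("AND"), fs)$indices,
      POLL = fuse_leads(per_lead, fusion_config("POLL"), fs)$indices,
      SC = fuse_leads(per_lead, fusion_config("SC"), fs)$indices,
      OR = fuse_leads(per_lead, fusion_config("OR"), fs)$indices)
    for (m in names(got)) {
      need <- switch(m, AND = L, POLL = L %/% 2 + 1, SC = 2, OR = 1)
      expect_equal(got[[m]], oracle_fused_indices(cfgs, tol, need))
    }
    expect_true(all(got$AND %in% got$POLL))
    expect_true(all(got$POLL %in% got$OR))
    expect_true(all(got$AND %in% got$SC))
    expect_true(all(got$SC %in% got$OR))
    if (L == 3) expect_equal(got$POLL, got$SC)
  }
})

test_that("detection is empty on an all-zero record", {
  zero <- multilead_signal(matrix(0, nrow = 200 * 60, ncol = 2), 200)
  expect_length(detect_beats(zero)$indices, 0)
})

test_that("a clean two-lead record is detected essentially perfectly", {
  rec <- synth_ecg(synth_config(duration_s = 300, seed = 3))
  pk <- detect_beats(rec$signal)
  ev <- evaluate_detections(pk, rec$annotations, rec$signal$fs)
  n_ref <- length(rec$annotations$indices)
  expect_gte(ev$TP, n_ref - 3)
  expect_equal(ev$FP, 0)
})

test_that("segmented and whole-record detection agree", {
  rec <- synth_ecg(synth_config(duration_s = 600, seed = 23))
  whole <- detect_beats(rec$signal,
                        plan = plan_segments(rec$signal, 600, 0))
  segd <- detect_beats(rec$signal,
                       plan = plan_segments(rec$signal, 120, 2))
  expect_equal(length(whole$indices), length(segd$indices))
  tol <- round(0.010 * rec$signal$fs)
  expect_true(all(abs(whole$indices - segd$indices) <= tol))
})

test_that("detections are invariant to global amplitude scaling", {
  rec <- synth_ecg(synth_config(duration_s = 120, seed = 29,
                                noise = list(list(type = "muscle",
                                                  snr_db = 10))))
  pk <- detect_beats(rec$signal)
  scaled <- rec$signal; scaled$samples <- scaled$samples * 10
  pk10 <- detect_beats(scaled)
  expect_equal(pk$indices, pk10$indices)
  # inter-peak spacing respects the refractory period
  expect_true(all(diff(pk$indices) >= round(0.250 * rec$signal$fs)))
})
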
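make_ecg_session <- function(seed = 3, n_trials = 4, sample_rate = 1000) {
  # 1000 Hz here: R-peak detection precision is specified at the
  # millisecond scale
  simulate_session(sim_config(n_trials = n_trials, fixation_range = c(8, 10),
                              sample_rate = sample_rate, seed = seed))
}

test_that("automatic template recovers the generating QRS shape", {
  ses <- make_ecg_session()
  ecg <- get_channel(ses$recording, "ECG")
  tpl <- build_template(ecg, 1000)
  truth <- qrs_shape(sample_rate = 1000, half_ms = 60)
  # align centers before correlating
  ctr_t <- which.max(truth)
  lo <- tpl$center - (ctr_t - 1)
  expect_gt(cor(tpl$waveform, truth[seq(ctr_t - tpl$center + 1,
                                        length.out = length(tpl$waveform))]),
            0.95)
  expect_equal(sqrt(sum(tpl$waveform^2)), 1)
  expect_equal(which.max(abs(tpl$waveform)), tpl$center)
})

test_that("template construction: degenerate inputs and length control", {
  expect_error(build_template(rep(0, 40000), 1000), "flat")
  expect_error(build_template(rnorm(1000), 1000), "30 s")
  ses <- make_ecg_session(seed = 5)
  tpl <- build_template(get_channel(ses$recording, "ECG"), 1000,
                        length_ms = 100)
  expect_length(tpl$waveform, 100)
  expect_error(build_template(get_channel(ses$recording, "ECG"), 1000,
                              length_ms = 300), "40 and 200")
})

test_that("noise-free tiled template is recovered at exact offsets", {
  w <- qrs_shape(sample_rate = 1000, half_ms = 60)
  tpl <- build_template(NULL, 1000, waveform = w)
  x <- rep(0, 20000)
  offsets <- c(2000, 3100, 4500, 9000, 15000)   # sample of template start
  for (s in offsets) x[s:(s + length(w) - 1)] <- x[s:(s + length(w) - 1)] + w
  pk <- detect_r_peaks(x, tpl, 1000, threshold = 0.9)
  expect_equal(pk$times, (offsets + tpl$center - 2) / 1000)
})

test_that("simulated ECG at default noise: every peak within 2 ms, no false positives", {
  ses <- make_ecg_session(seed = 11)
  ecg <- get_channel(ses$recording, "ECG")
  tpl <- build_template(ecg, 1000)
  pk <- detect_r_peaks(ecg, tpl, 1000)
  truth <- ses$truth$true_r_times
  expect_equal(length(pk$times), length(truth))
  expect_lte(max(abs(pk$times - truth)), 0.002)
})

test_that("detection is invariant to global scaling and monotone in threshold", {
  ses <- make_ecg_session(seed = 13)
  ecg <- get_channel(ses$recording, "ECG")
  tpl <- build_template(ecg, 1000)
  a <- detect_r_peaks(ecg, tpl, 1000)
  b <- detect_r_peaks(ecg * 1750, tpl, 1000)
  expect_identical(a$times, b$times)
  lo <- detect_r_peaks(ecg, tpl, 1000, threshold = 0.5)
  hi <- suppressWarnings(detect_r_peaks(ecg, tpl, 1000, threshold = 0.98))
  expect_lte(length(hi$times), length(lo$times))
})

test_that("empty detection warns and returns an empty series", {
  tpl <- build_template(NULL, 1000, waveform = qrs_shape(half_ms = 40))
  expect_warning(pk <- detect_r_peaks(rnorm(5000) * 0.01 + sin(1:5000 / 500),
                                      tpl, 1000, threshold = 0.999),
                 "no R-peaks")
  expect_length(pk$times, 0)
})

test_that("IBI QC flags constructed outliers and only those", {
  # homogeneous series: nothing flagged
  pk <- qc_ibi(rpeak_series(seq(0, 20, by = 0.8)))
  expect_false(any(pk$qc_flags))

  # one missed beat: exactly the long interval flagged
  times <- seq(0, 20, by = 0.8)
  times <- times[times != 8.0]
  pk <- qc_ibi(rpeak_series(times))
  expect_equal(which(pk$qc_flags), which(abs(pk$ibi - 1.6) < 1e-9))
  expect_equal(sum(pk$qc_flags), 1)

  expect_error(qc_ibi(rpeak_series(c(0, 1))), "at least 3")
})

test_that("deleted beats are flagged in proportion on simulated sessions", {
  ses <- make_ecg_session(seed = 17, n_trials = 8)
  truth <- ses$truth$true_r_times
  drop <- seq(10, length(truth) - 10, by = 50)  # ~2% deletions, separated
  pk <- qc_ibi(rpeak_series(truth[-drop]))
  expect_equal(sum(pk$qc_flags), length(drop))
})

test_that("rpeak_series enforces strictly increasing times", {
  expect_error(rpeak_series(c(1, 1, 2)), "strictly increasing")
  expect_error(rpeak_series(c(2, 1)), "strictly increasing")
})
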
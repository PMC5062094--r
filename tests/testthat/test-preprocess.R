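trial_row <- function(id, stim, rating = 0.5, skipped = 0) {
  data.frame(trial_id = id, stim_onset_s = stim, I_rating = rating,
             skipped = skipped)
}

flat_recording <- function(n_ch = 1, n_s = 20000, fs = 1000,
                           labels = paste0("SITE", seq_len(n_ch))) {
  continuous_recording(matrix(0, n_ch, n_s), fs, labels)
}

test_that("peak-pair selection matches a brute-force scan, including the 700 ms edge", {
  rec <- flat_recording()
  # stimulus at 10.0 s; the 9.4 s peak leads by only 600 ms -> excluded
  pk <- rpeak_series(c(7.5, 8.4, 9.2, 9.4))
  ep <- extract_her_epochs(rec, pk, trial_row(1, 10.0))
  expect_equal(sort(ep$meta$r_time), c(8.4, 9.2))
  expect_equal(sort(ep$meta$r_time),
               oracle_select_peaks(pk$times, 10.0))

  # randomized property check
  set.seed(99)
  for (k in 1:20) {
    times <- sort(runif(30, 0.5, 18))
    stim <- runif(1, 5, 19)
    ep <- extract_her_epochs(rec, rpeak_series(times), trial_row(1, stim))
    expect_equal(sort(ep$meta$r_time), oracle_select_peaks(times, stim))
  }
})

test_that("skipped trials yield no epochs; incomplete trials are recorded", {
  rec <- flat_recording()
  pk <- rpeak_series(c(5, 5.8, 6.6, 7.4))
  tt <- rbind(trial_row(1, 9, skipped = 1), trial_row(2, 9.5))
  ep <- extract_her_epochs(rec, pk, tt)
  expect_true(all(ep$meta$trial_id == 2))

  # only one peak leads the stimulus by >= 700 ms
  ep2 <- extract_her_epochs(rec, rpeak_series(c(8.0, 8.5)), trial_row(3, 9.0))
  expect_equal(ep2$incomplete, 3)
})

test_that("epoch geometry: 701 samples at 1000 Hz, axis -100..600 ms", {
  rec <- flat_recording()
  ep <- extract_her_epochs(rec, rpeak_series(c(4, 4.8)), trial_row(1, 6))
  expect_equal(dim(ep$values)[2], 701)
  expect_equal(ep$time_ms[1], -100)
  expect_equal(ep$time_ms[701], 600)
})

test_that("epoch extraction is translation-equivariant", {
  set.seed(5)
  x <- rnorm(20000)
  shift_s <- 4
  y <- c(rep(0, shift_s * 1000), x)[1:24000]   # same signal, delayed 4 s
  rec1 <- continuous_recording(matrix(x, 1), 1000, "SITE1")
  rec2 <- continuous_recording(matrix(y, 1), 1000, "SITE1")
  pk <- c(6.0, 6.9, 7.8)
  ep1 <- extract_her_epochs(rec1, rpeak_series(pk), trial_row(1, 9))
  ep2 <- extract_her_epochs(rec2, rpeak_series(pk + shift_s),
                            trial_row(1, 9 + shift_s))
  expect_equal(ep2$values, ep1$values)
  expect_equal(ep2$meta$r_time, ep1$meta$r_time + shift_s)
})

test_that("artifact rejection reproduces the sliding-window oracle", {
  rec <- flat_recording()
  pk <- rpeak_series(c(4, 4.8))
  base <- extract_her_epochs(rec, pk, trial_row(1, 6))

  inject <- function(ep, epoch, wave) {
    ep$values[epoch, seq_along(wave) + 100, 1] <- wave
    ep
  }
  # amplitude crossing
  ep <- inject(base, 1, c(10, 250, 10))
  rej <- reject_artifacts(ep)
  expect_equal(rej$excluded$epoch, 1)
  expect_equal(rej$excluded$reason, "amplitude")

  # exact 300-in-20ms ramp: rejected with reason "range";
  # 299 ramp retained. 21 samples span exactly 20 ms at 1000 Hz.
  ramp300 <- seq(-150, 150, length.out = 21)
  ramp299 <- seq(-149.5, 149.5, length.out = 21)
  expect_gte(oracle_sliding_range(ramp300, 21), 300)
  expect_lt(oracle_sliding_range(ramp299, 21), 300)
  rej300 <- reject_artifacts(inject(base, 2, ramp300))
  expect_equal(rej300$excluded$reason, "range")
  expect_equal(rej300$excluded$epoch, 2)
  rej299 <- reject_artifacts(inject(base, 2, ramp299))
  expect_equal(nrow(rej299$excluded), 0)

  # all-zero epochs retained
  expect_equal(nrow(reject_artifacts(base)$excluded), 0)
})

test_that("rejection decisions agree with the oracle on random epochs and ignore order", {
  set.seed(7)
  rec <- flat_recording()
  pk <- rpeak_series(seq(2, 15, by = 0.8))
  tt <- do.call(rbind, lapply(1:6, function(i) trial_row(i, 2.2 + i * 2.2)))
  ep <- extract_her_epochs(rec, pk, tt)
  ep$values[, , 1] <- rnorm(length(ep$values), sd = 90)
  rej <- reject_artifacts(ep, abs_limit = 200, range_limit = 300)
  oracle_bad <- which(vapply(seq_len(dim(ep$values)[1]), function(e) {
    x <- ep$values[e, , 1]
    max(abs(x)) > 200 || oracle_sliding_range(x, 21) >= 300
  }, logical(1)))
  expect_setequal(rej$excluded$epoch, oracle_bad)

  # reversing epoch order reverses decisions consistently
  ep_rev <- ep
  ne <- dim(ep$values)[1]
  ep_rev$values <- ep$values[ne:1, , , drop = FALSE]
  rej_rev <- reject_artifacts(ep_rev, abs_limit = 200, range_limit = 300)
  expect_setequal(ne + 1 - rej_rev$excluded$epoch, oracle_bad)
})

test_that("per-trial averaging: idempotence, cancellation, bookkeeping", {
  rec <- flat_recording()
  pk <- rpeak_series(c(4, 4.8))
  ep <- extract_her_epochs(rec, pk, trial_row(1, 6))
  w <- sin(seq(0, 3, length.out = 701)) * 50

  ep$values[1, , 1] <- w; ep$values[2, , 1] <- w
  her <- average_trial_her(ep)
  expect_equal(her$values[1, , 1], w)

  ep$values[2, , 1] <- -w
  her2 <- average_trial_her(ep)
  expect_equal(her2$values[1, , 1], rep(0, 701))

  # one epoch rejected: default keeps the survivor, strict mode drops
  ep$values[2, , 1] <- rep(500, 701)
  rej <- reject_artifacts(ep)
  keep <- average_trial_her(rej)
  expect_equal(keep$values[1, , 1], w)
  expect_equal(unname(keep$n_epochs[1, 1]), 1L)
  strict <- average_trial_her(rej, min_epochs = 2)
  expect_equal(strict$dropped$trial_id, 1)
  expect_equal(nrow(her_matrix(strict)), 0)
})

test_that("rejection-rate bookkeeping matches generator ground truth", {
  # artifact rate chosen so well under 14.8% of trials are lost
  ses <- simulate_session(quick_cfg(n_trials = 25, artifact_rate = 0.1,
                                    seed = 31))
  pk <- rpeak_series(ses$truth$true_r_times)
  ep <- reject_artifacts(extract_her_epochs(ses$recording, pk, ses$trials))
  corrupted <- unique(ses$truth$corrupted_epochs[c("trial_id", "r_time")])
  expect_equal(nrow(ep$excluded), nrow(corrupted))
  her <- average_trial_her(ep, min_epochs = 2)
  expect_equal(nrow(her$dropped), length(unique(corrupted$trial_id)))
  expect_equal(nrow(her_matrix(her)),
               25 - length(unique(corrupted$trial_id)))
})

test_that("bipolar re-referencing cancels common-mode signals", {
  set.seed(11)
  common <- rnorm(5000)
  priv <- matrix(rnorm(3 * 5000, sd = 0.1), 3)
  data <- sweep(priv, 2, common, "+")
  rec <- continuous_recording(data, 1000, c("A1", "A2", "A3"),
                              shaft = c("A", "A", "A"))
  bp <- to_bipolar(rec)
  expect_equal(bp$channel_labels, c("A1-A2", "A2-A3"))
  expect_equal(bp$data[1, ], priv[1, ] - priv[2, ])
  expect_equal(bp$montage, "bipolar")

  # identical signal everywhere -> exactly zero
  rec0 <- continuous_recording(rbind(common, common), 1000, c("A1", "A2"),
                               shaft = c("A", "A"))
  expect_equal(max(abs(to_bipolar(rec0)$data)), 0)

  # 8 contacts -> 7 channels; single-contact shaft warns
  rec8 <- continuous_recording(matrix(rnorm(9 * 100), 9), 100,
                               c(paste0("A", 1:8), "B1"),
                               shaft = c(rep("A", 8), "B"))
  expect_warning(b8 <- to_bipolar(rec8), "single contact")
  expect_equal(sum(b8$shaft == "A", na.rm = TRUE), 7)
  expect_error(to_bipolar(b8), "already bipolar")
})

test_that("common cardiac-field artifact is suppressed by the bipolar montage", {
  # constructed common-mode fixture: the artifact dominates, private
  # noise is kept small so the ratio measures common-mode suppression
  ses <- simulate_session(quick_cfg(n_neural = 4, montage = "referential",
                                    cfa_amplitude = 5, coupling_beta = 0,
                                    noise_model = list(exponent = 1, sd = 0.02),
                                    seed = 37))
  pk <- rpeak_series(ses$truth$true_r_times)
  ref_amp <- function(rec, label) {
    ep <- extract_her_epochs(rec, pk, ses$trials)
    early <- ep$time_ms >= 0 & ep$time_ms < 300
    mean(abs(colMeans(ep$values[, , label])[early]))
  }
  a_ref <- ref_amp(ses$recording, "SITE1")
  bp <- to_bipolar(ses$recording)
  a_bip <- ref_amp(bp, "SITE1-SITE2")
  expect_lt(a_bip / a_ref, 0.05)
})
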
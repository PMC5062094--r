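test_that("identical config and seed give bit-identical sessions", {
  a <- simulate_session(quick_cfg())
  b <- simulate_session(quick_cfg())
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  c <- simulate_session(quick_cfg(seed = 43))
  expect_false(identical(a$recording$data, c$recording$data))
})

test_that("config invariants are enforced with the offending field named", {
  expect_error(sim_config(fixation_range = c(0.5, 2)), "fixation_range")
  expect_error(sim_config(mean_rr = 2), "mean_rr")
  expect_error(sim_config(coupling_window = c(500, 700)), "coupling_window")
  expect_error(sim_config(inter_scale_r = 1.2), "inter_scale_r")
  expect_error(sim_config(sample_rate = -1), "sample_rate")
  expect_error(sim_config(artifact_rate = 1.5), "artifact_rate")
})

test_that("rating generator: correlation structure and degenerate cases", {
  r <- simulate_ratings(10000, c("I", "Me"), 0.91, seed = 7)
  expect_true(all(r$I >= 0 & r$I <= 1))
  expect_gt(cor(r$I, r$Me), 0.89)
  expect_lt(cor(r$I, r$Me), 0.93)

  r0 <- simulate_ratings(10000, c("I", "Me"), 0, seed = 8)
  expect_lt(abs(cor(r0$I, r0$Me)), 0.03)

  r1 <- simulate_ratings(50, c("I", "Me"), 1, seed = 9)
  expect_equal(r1$I, r1$Me)

  expect_error(simulate_ratings(2, c("I", "Me"), 0.5), "n_trials")
})

test_that("every stimulus is preceded by >= 2 R-peaks with >= 700 ms lead, inside its fixation", {
  for (seed in c(1, 2)) {
    ses <- simulate_session(quick_cfg(n_trials = 8, seed = seed))
    for (i in seq_len(nrow(ses$trials))) {
      s <- ses$trials$stim_onset_s[i]
      lead_ok <- ses$truth$true_r_times[
        ses$truth$true_r_times <= s - 0.7 &
          ses$truth$true_r_times >= ses$truth$trial_start[i]]
      expect_gte(length(lead_ok), 2)
      expect_gte(s - ses$truth$trial_start[i], 4)  # fixation lower bound
    }
  }
})

test_that("heartbeat-locked kernel is recovered by epoch averaging", {
  cfg <- quick_cfg(n_trials = 30, coupling_beta = 0.5, seed = 11)
  ses <- simulate_session(cfg)
  pk <- rpeak_series(ses$truth$true_r_times)
  ep <- extract_her_epochs(ses$recording, pk, ses$trials)
  avg <- colMeans(ep$values[, , 1])
  kern_full <- rep(0, length(ep$time_ms))
  idx <- findInterval(ses$truth$kernel$t_ms, ep$time_ms)
  kern_full[idx] <- ses$truth$kernel$shape
  expect_gt(cor(avg, kern_full), 0.9)
})

test_that("null coupling gives near-zero empirical amplitude/rating correlation", {
  cfg <- quick_cfg(n_trials = 200, fixation_range = c(3, 4), coupling_beta = 0,
                   seed = 13)
  ses <- simulate_session(cfg)
  her <- her_pipeline_from_truth(ses, filter = FALSE)
  m <- her_matrix(her)
  peak_col <- which.min(abs(attr(m, "time_ms") - 425))
  r <- cor(m[, peak_col], session_ratings(ses)[rownames(m)])
  expect_lt(abs(r), 2 / sqrt(200))
  expect_identical(ses$truth$true_beta, 0)
})

test_that("Monte Carlo coupling strength matches the closed-form implied r", {
  # 100 replicate sessions at implied r = 0.5; the mean sample
  # correlation at the kernel peak must fall within +/- 0.15 of 0.5
  base <- quick_cfg(n_trials = 40)
  beta <- coupling_beta_for_r(0.5, base)
  expect_equal(implied_coupling_r(quick_cfg(coupling_beta = beta)), 0.5)
  rs <- vapply(1:100, function(k) {
    ses <- simulate_session(quick_cfg(n_trials = 40, coupling_beta = beta,
                                      seed = 500 + k))
    her <- her_pipeline_from_truth(ses, filter = FALSE)
    m <- her_matrix(her)
    peak_col <- which.min(abs(attr(m, "time_ms") - 425))
    cor(m[, peak_col], session_ratings(ses)[rownames(m)])
  }, numeric(1))
  expect_lt(abs(mean(rs) - 0.5), 0.15)
})

test_that("cardiac-field artifact is confined below 300 ms post R", {
  clean <- simulate_session(quick_cfg(seed = 17, cfa_amplitude = 0))
  cfa <- simulate_session(quick_cfg(seed = 17, cfa_amplitude = 3))
  pk <- rpeak_series(clean$truth$true_r_times)
  ep_c <- extract_her_epochs(clean$recording, pk, clean$trials)
  ep_a <- extract_her_epochs(cfa$recording, pk, cfa$trials)
  late <- ep_c$time_ms >= 300
  # same seed, same noise: late samples are bit-identical, early differ
  expect_identical(ep_a$values[, late, 1], ep_c$values[, late, 1])
  expect_false(identical(ep_a$values[, !late, 1], ep_c$values[, !late, 1]))
})

test_that("skipped trials carry NA ratings and are flagged", {
  ses <- simulate_session(quick_cfg(n_trials = 40, skip_prob = 0.3, seed = 19))
  sk <- ses$trials$skipped == 1
  expect_gt(sum(sk), 0)
  expect_true(all(is.na(ses$trials$I_rating[sk])))
  expect_true(all(!is.na(ses$trials$I_rating[!sk])))
})

test_that("corrupted epochs are bookkept and reference selected peak pairs", {
  ses <- simulate_session(quick_cfg(n_trials = 20, artifact_rate = 0.15,
                                    seed = 23))
  corr <- ses$truth$corrupted_epochs
  expect_gt(nrow(corr), 0)
  for (i in seq_len(nrow(corr))) {
    stim <- ses$trials$stim_onset_s[ses$trials$trial_id == corr$trial_id[i]]
    sel <- oracle_select_peaks(ses$truth$true_r_times, stim)
    expect_true(corr$r_time[i] %in% sel)
  }
})
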
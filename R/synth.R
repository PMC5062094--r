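#' Simulation configuration for a synthetic thought-sampling session
#'
#' Describes the full stated world of a synthetic session: trial timing
#' (long fixations ending in a visual stimulus), ECG morphology and
#' heart-rate variability, a heartbeat-locked evoked component in the
#' neural channels whose amplitude covaries with a continuous rating,
#' optional residual cardiac-field artifact (CFA) confined to early
#' post-R latencies, optional epoch corruption, and an optional slow
#' stimulus-locked drift used as a non-heartbeat-locked confound.
#'
#' @param n_trials number of trials.
#' @param fixation_range seconds, \code{c(min, max)} of the uniform
#'   fixation duration (default 13.5--29.9 s).
#' @param sample_rate Hz (default 1000).
#' @param mean_rr mean interbeat interval in seconds (default 0.85).
#' @param rr_jitter_sd SD of the i.i.d. Gaussian RR jitter in seconds,
#'   truncated at +/- 3 SD (default 0.05, a typical resting SDNN).
#' @param qrs_template named list describing the synthetic ECG beat
#'   morphology (P/Q/R/S/T Gaussian components); see
#'   [default_qrs_descriptor()].
#' @param rt_interval seconds from R-peak to T-wave apex (default 0.269).
#' @param her_kernel list \code{latency_ms}, \code{width_ms} (Gaussian
#'   SD), \code{shape} ("gaussian") of the heartbeat-evoked component.
#' @param her_baseline kernel peak amplitude at rating 0, in recording
#'   units (default 1).
#' @param coupling_beta amplitude units added to the kernel peak per
#'   unit rating; 0 gives a null session.
#' @param coupling_window ms pair inside \code{[-100, 600]} where the
#'   coupled component lives (default \code{c(400, 450)}).
#' @param coupling_scale name of the rating scale driving the coupling
#'   (default: first of \code{scales}).
#' @param scales rating scale names (default \code{c("I", "Me")}).
#' @param inter_scale_r latent correlation between scales (default 0.91).
#' @param skip_prob probability a trial is skipped (no usable rating).
#' @param artifact_rate fraction of analyzable epochs corrupted with a
#'   large spike (default 0).
#' @param artifact_amplitude spike amplitude in recording units
#'   (default 500, i.e. beyond the conventional rejection limits).
#' @param cfa_amplitude residual cardiac-field artifact amplitude; the
#'   artifact waveform is identically zero from 300 ms post R onwards.
#' @param noise_model list \code{exponent} (1/f slope) and \code{sd}
#'   (per-sample SD, recording units) of the neural background
#'   (default exponent 1, sd 0.5).
#' @param ecg_noise_sd white-noise SD on the ECG channel relative to an
#'   R amplitude of 1 (default 0.1).
#' @param n_neural number of neural channels (default 1).
#' @param montage \code{"bipolar"}: channels are independent recording
#'   sites; \code{"referential"}: channels are contacts on one shaft
#'   sharing the CFA as a common-mode signal and seeing the evoked
#'   kernel with a decreasing spatial gain.
#' @param drift_beta amplitude of a slow stimulus-locked, rating-
#'   correlated drift (non-heartbeat-locked confound; default 0).
#' @param seed integer RNG seed; identical configs give bit-identical
#'   sessions.
#' @return validated object of class \code{sim_config}.
#' @export
sim_config <- function(n_trials = 40,
                       fixation_range = c(13.5, 29.9),
                       sample_rate = 1000,
                       mean_rr = 0.85,
                       rr_jitter_sd = 0.05,
                       qrs_template = default_qrs_descriptor(),
                       rt_interval = 0.269,
                       her_kernel = list(latency_ms = 425, width_ms = 12,
                                         shape = "gaussian"),
                       her_baseline = 1,
                       coupling_beta = 0,
                       coupling_window = c(400, 450),
                       coupling_scale = NULL,
                       scales = c("I", "Me"),
                       inter_scale_r = 0.91,
                       skip_prob = 0,
                       artifact_rate = 0,
                       artifact_amplitude = 500,
                       cfa_amplitude = 0,
                       noise_model = list(exponent = 1, sd = 0.5),
                       ecg_noise_sd = 0.1,
                       n_neural = 1,
                       montage = c("bipolar", "referential"),
                       drift_beta = 0,
                       seed = 1) {
  cfg <- list(n_trials = n_trials, fixation_range = fixation_range,
              sample_rate = sample_rate, mean_rr = mean_rr,
              rr_jitter_sd = rr_jitter_sd, qrs_template = qrs_template,
              rt_interval = rt_interval, her_kernel = her_kernel,
              her_baseline = her_baseline, coupling_beta = coupling_beta,
              coupling_window = coupling_window,
              coupling_scale = coupling_scale %||% scales[1],
              scales = scales, inter_scale_r = inter_scale_r,
              skip_prob = skip_prob, artifact_rate = artifact_rate,
              artifact_amplitude = artifact_amplitude,
              cfa_amplitude = cfa_amplitude, noise_model = noise_model,
              ecg_noise_sd = ecg_noise_sd, n_neural = n_neural,
              montage = match.arg(montage), drift_beta = drift_beta,
              seed = seed)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (!is.numeric(cfg$n_trials) || cfg$n_trials < 1) {
    stopf("invalid 'n_trials': need at least 1 trial")
  }
  fr <- cfg$fixation_range
  if (length(fr) != 2 || fr[1] < 1 || fr[1] > fr[2]) {
    stopf("invalid 'fixation_range': need c(min, max) with min >= 1 s")
  }
  if (!is.numeric(cfg$sample_rate) || cfg$sample_rate <= 0) {
    stopf("invalid 'sample_rate': must be > 0")
  }
  if (cfg$mean_rr < 0.4 || cfg$mean_rr > 1.5) {
    stopf("invalid 'mean_rr': must lie in [0.4, 1.5] s")
  }
  cw <- cfg$coupling_window
  if (length(cw) != 2 || cw[1] < -100 || cw[2] > 600 || cw[1] >= cw[2]) {
    stopf("invalid 'coupling_window': must lie within [-100, 600] ms")
  }
  if (abs(cfg$inter_scale_r) > 1) {
    stopf("invalid 'inter_scale_r': |r| must be <= 1")
  }
  if (length(cfg$scales) > 2 && cfg$inter_scale_r < -1 / (length(cfg$scales) - 1)) {
    stopf("invalid 'inter_scale_r': equicorrelation not positive definite")
  }
  if (cfg$artifact_rate < 0 || cfg$artifact_rate > 1) {
    stopf("invalid 'artifact_rate': must lie in [0, 1]")
  }
  if (!cfg$coupling_scale %in% cfg$scales) {
    stopf("invalid 'coupling_scale': '%s' is not among the scales", cfg$coupling_scale)
  }
  invisible(cfg)
}

#' Default synthetic ECG beat morphology
#'
#' P, Q, R, S Gaussian components (amplitudes relative to R = 1, offsets
#' in ms from the R-peak, widths as Gaussian SDs in ms). The T-wave is
#' placed at the configured R-T interval by the simulator.
#' @return named list of morphology parameters.
#' @export
default_qrs_descriptor <- function() {
  list(r_amp = 1, r_width_ms = 7,
       q_amp = -0.15, q_offset_ms = -28, q_width_ms = 5,
       s_amp = -0.25, s_offset_ms = 28, s_width_ms = 5,
       p_amp = 0.12, p_offset_ms = -180, p_width_ms = 25,
       t_amp = 0.35, t_width_ms = 40)
}

gauss_bump <- function(t_ms, center_ms, width_ms) {
  exp(-(t_ms - center_ms)^2 / (2 * width_ms^2))
}

# full ECG waveform of one beat sampled around the R-peak
ecg_beat_wave <- function(q = default_qrs_descriptor(), sample_rate,
                          rt_interval = 0.269) {
  t_ms <- seq(-300, rt_interval * 1000 + 4 * q$t_width_ms,
              by = 1000 / sample_rate)
  w <- q$r_amp * gauss_bump(t_ms, 0, q$r_width_ms) +
    q$q_amp * gauss_bump(t_ms, q$q_offset_ms, q$q_width_ms) +
    q$s_amp * gauss_bump(t_ms, q$s_offset_ms, q$s_width_ms) +
    q$p_amp * gauss_bump(t_ms, q$p_offset_ms, q$p_width_ms) +
    q$t_amp * gauss_bump(t_ms, rt_interval * 1000, q$t_width_ms)
  list(wave = w, center = which.min(abs(t_ms)))
}

#' Ground-truth QRS shape of the simulator
#'
#' The QRS complex (Q, R, S components only) over +/- \code{half_ms}
#' around the R-peak, as placed in simulated ECG. Used as the reference
#' when validating template construction.
#' @param q morphology descriptor, see [default_qrs_descriptor()].
#' @param sample_rate Hz.
#' @param half_ms half-width of the returned window in ms.
#' @return numeric waveform with the R-peak at the central sample.
#' @export
qrs_shape <- function(q = default_qrs_descriptor(), sample_rate = 1000,
                      half_ms = 60) {
  t_ms <- seq(-half_ms, half_ms, by = 1000 / sample_rate)
  q$r_amp * gauss_bump(t_ms, 0, q$r_width_ms) +
    q$q_amp * gauss_bump(t_ms, q$q_offset_ms, q$q_width_ms) +
    q$s_amp * gauss_bump(t_ms, q$s_offset_ms, q$s_width_ms)
}

# residual cardiac-field artifact: damped oscillation, tapered to exactly
# zero at 280 ms post R (the analysis window 300-600 ms must stay clean)
cfa_wave <- function(sample_rate) {
  t_ms <- seq(0, 280, by = 1000 / sample_rate)
  taper <- ifelse(t_ms > 200, 0.5 * (1 + cos(pi * (t_ms - 200) / 80)), 1)
  exp(-t_ms / 60) * sin(2 * pi * t_ms / 90) * taper
}

# 1/f^alpha background noise via spectral shaping, exact per-sample sd.
# Generated at a 5-smooth FFT length (R's mixed-radix FFT is quadratic
# for awkward lengths) and truncated.
one_over_f_noise <- function(n, exponent = 1, sd = 1) {
  if (sd == 0) return(numeric(n))
  m <- stats::nextn(n, c(2, 3, 5))
  x <- stats::rnorm(m)
  if (exponent != 0) {
    X <- stats::fft(x)
    f <- c(0, seq_len(m - 1))
    f <- pmin(f, m - f)            # symmetric frequency index
    amp <- c(0, f[-1]^(-exponent / 2))
    x <- Re(stats::fft(X * amp, inverse = TRUE)) / m
  }
  x <- x[seq_len(n)]
  x <- x - mean(x)
  x / stats::sd(x) * sd
}

#' Simulate continuous ratings on correlated scales
#'
#' Ratings are generated on a latent Gaussian with equicorrelation
#' \code{inter_scale_r} and mapped to \code{[0, 1]} through the standard
#' normal CDF (a Gaussian copula with uniform marginals), so the sample
#' correlation between scales converges to \code{inter_scale_r}
#' (up to the small rank-correlation shrinkage of the copula map).
#'
#' @param n_trials number of trials (at least 3).
#' @param scales character vector of scale names.
#' @param inter_scale_r latent inter-scale correlation, |r| <= 1.
#' @param seed RNG seed.
#' @return data.frame of ratings in \code{[0, 1]}, one column per scale.
#' @export
simulate_ratings <- function(n_trials, scales = c("I", "Me"),
                             inter_scale_r = 0.91, seed = 1) {
  if (n_trials < 3) stopf("'n_trials' must be >= 3 (correlations undefined below)")
  if (abs(inter_scale_r) > 1) stopf("|inter_scale_r| must be <= 1")
  k <- length(scales)
  if (k > 2 && inter_scale_r < -1 / (k - 1)) {
    stopf("equicorrelation %g is not positive semi-definite for %d scales",
          inter_scale_r, k)
  }
  with_seed(seed, {
    z <- matrix(stats::rnorm(n_trials * k), n_trials, k)
    if (k > 1 && inter_scale_r != 0) {
      sigma <- matrix(inter_scale_r, k, k); diag(sigma) <- 1
      # chol of equicorrelation; r = 1 handled by duplication
      if (abs(inter_scale_r) == 1) {
        z <- matrix(z[, 1] * sign(inter_scale_r)^(col(z) - 1), n_trials, k)
      } else {
        z <- z %*% chol(sigma)
      }
    }
    out <- as.data.frame(stats::pnorm(z))
    names(out) <- scales
    out
  })
}

#' Simulate a complete synthetic session
#'
#' Builds a continuous recording (ECG plus neural channels), a trial
#' table and the generating ground truth. The ECG contains QRS
#' complexes at the true R-peak times and T-waves at
#' \code{rt_interval} later; each neural channel contains 1/f background
#' noise plus, at every heartbeat, an evoked kernel whose peak amplitude
#' is \code{her_baseline + coupling_beta * rating} for beats inside a
#' trial. Stimulus onsets respect the configured fixation range and are
#' guaranteed to be preceded by at least two R-peaks with >= 700 ms
#' lead.
#'
#' @param config a [sim_config()].
#' @return list of class \code{her_session} with elements
#'   \code{recording} ([continuous_recording()]), \code{trials}
#'   (trial table data.frame), \code{truth} (ground-truth list) and
#'   \code{config}.
#' @export
simulate_session <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  cfg <- config
  fs <- cfg$sample_rate

  ratings <- simulate_ratings(max(cfg$n_trials, 3), cfg$scales,
                              cfg$inter_scale_r, seed = cfg$seed + 1L)
  ratings <- ratings[seq_len(cfg$n_trials), , drop = FALSE]

  with_seed(cfg$seed, {
    # ---- trial timeline -------------------------------------------------
    lead_in <- 5; iti <- 6; tail <- 2
    fix <- stats::runif(cfg$n_trials, cfg$fixation_range[1], cfg$fixation_range[2])
    skipped <- stats::rbinom(cfg$n_trials, 1, cfg$skip_prob)

    # ---- heartbeats -----------------------------------------------------
    total_guess <- lead_in + sum(fix + iti) + tail
    n_beats <- ceiling(total_guess / max(cfg$mean_rr - 3 * cfg$rr_jitter_sd, 0.3)) + 8
    jit <- stats::rnorm(n_beats, 0, cfg$rr_jitter_sd)
    jit <- pmin(pmax(jit, -3 * cfg$rr_jitter_sd), 3 * cfg$rr_jitter_sd)
    rr <- pmax(cfg$mean_rr + jit, 0.3)
    r_times <- 0.35 + cumsum(c(0, rr[-length(rr)]))

    # ---- stimulus placement --------------------------------------------
    trial_start <- numeric(cfg$n_trials)
    stim <- numeric(cfg$n_trials)
    cursor <- lead_in
    for (i in seq_len(cfg$n_trials)) {
      trial_start[i] <- cursor
      s <- cursor + fix[i]
      # guarantee >= 2 R-peaks inside the trial with >= 700 ms lead
      repeat {
        ok <- sum(r_times >= trial_start[i] & r_times <= s - 0.7) >= 2
        if (ok) break
        s <- s + cfg$mean_rr
      }
      stim[i] <- s
      cursor <- s + iti
    }
    total <- cursor - iti + tail + 1
    n <- ceiling(total * fs)
    r_times <- r_times[r_times < total - 1.2]

    # ---- ECG channel ----------------------------------------------------
    beat <- ecg_beat_wave(cfg$qrs_template, fs, cfg$rt_interval)
    ecg <- stats::rnorm(n, 0, cfg$ecg_noise_sd)
    ecg <- add_at(ecg, beat$wave, round(r_times * fs) + 1 - (beat$center - 1))

    # ---- neural channels ------------------------------------------------
    rating_cpl <- ratings[[cfg$coupling_scale]]
    rating_cpl[is.na(rating_cpl) | skipped == 1] <- 0.5
    # which trial each beat falls in (fixation period), 0 = between trials
    beat_trial <- integer(length(r_times))
    for (i in seq_len(cfg$n_trials)) {
      beat_trial[r_times >= trial_start[i] & r_times <= stim[i]] <- i
    }
    amp <- ifelse(beat_trial > 0,
                  cfg$her_baseline + cfg$coupling_beta * rating_cpl[pmax(beat_trial, 1)],
                  cfg$her_baseline)

    kern_t <- seq(-4 * cfg$her_kernel$width_ms, 4 * cfg$her_kernel$width_ms,
                  by = 1000 / fs)
    kern <- gauss_bump(kern_t, 0, cfg$her_kernel$width_ms)
    kern_start <- round((cfg$her_kernel$latency_ms - 4 * cfg$her_kernel$width_ms) *
                          fs / 1000)
    cfa <- cfa_wave(fs) * cfg$cfa_amplitude

    if (cfg$montage == "referential") {
      site_gain <- seq(1, 0.3, length.out = cfg$n_neural)
    } else {
      site_gain <- rep(1, cfg$n_neural)
    }

    beat_idx <- round(r_times * fs) + 1
    neural <- matrix(0, cfg$n_neural, n)
    for (ch in seq_len(cfg$n_neural)) {
      x <- one_over_f_noise(n, cfg$noise_model$exponent, cfg$noise_model$sd)
      x <- add_at(x, kern, beat_idx + kern_start, scale = amp * site_gain[ch])
      if (cfg$cfa_amplitude != 0) x <- add_at(x, cfa, beat_idx)
      if (cfg$drift_beta != 0) {
        # slow-drift limit: rating-proportional level over the fixation,
        # reaching a plateau well before any analyzable epoch (cosine
        # onset over the first quarter of the fixation)
        drift <- numeric(n)
        tt <- (seq_len(n) - 1) / fs
        for (i in seq_len(cfg$n_trials)) {
          if (skipped[i] == 1) next
          span <- which(tt >= trial_start[i] & tt <= stim[i])
          u <- (tt[span] - trial_start[i]) / (stim[i] - trial_start[i])
          g <- ifelse(u >= 0.25, 1, 0.5 * (1 - cos(pi * u / 0.25)))
          drift[span] <- drift[span] +
            cfg$drift_beta * (rating_cpl[i] - 0.5) * g
        }
        x <- x + drift
      }
      neural[ch, ] <- x
    }

    # ---- epoch corruption ----------------------------------------------
    corrupted <- data.frame(trial_id = integer(0), r_time = numeric(0))
    if (cfg$artifact_rate > 0) {
      cand <- list()
      for (i in seq_len(cfg$n_trials)) {
        if (skipped[i] == 1) next
        pk <- r_times[r_times <= stim[i] - 0.7]
        pk <- utils::tail(pk, 2)
        for (p in pk) cand[[length(cand) + 1]] <- c(i, p)
      }
      cand <- do.call(rbind, cand)
      n_bad <- floor(cfg$artifact_rate * nrow(cand))
      if (n_bad > 0) {
        pick <- sample(nrow(cand), n_bad)
        for (j in pick) {
          at <- round((cand[j, 2] + stats::runif(1, -0.05, 0.55)) * fs) + 1
          neural[, at] <- neural[, at] + cfg$artifact_amplitude
        }
        corrupted <- data.frame(trial_id = cand[pick, 1], r_time = cand[pick, 2])
      }
    }

    labels <- c(paste0("SITE", seq_len(cfg$n_neural)), "ECG")
    shafts <- c(rep(if (cfg$montage == "referential") "A" else NA_character_,
                    cfg$n_neural), NA_character_)
    rec <- continuous_recording(rbind(neural, ecg), fs, labels,
                                montage = "referential", shaft = shafts)
    rec$provenance <- sprintf("simulated:seed%d", cfg$seed)

    trials <- data.frame(trial_id = seq_len(cfg$n_trials),
                         stim_onset_s = stim, check.names = FALSE)
    for (sc in cfg$scales) {
      v <- ratings[[sc]]
      v[skipped == 1] <- NA_real_
      trials[[paste0(sc, "_rating")]] <- v
    }
    trials$skipped <- skipped

    truth <- list(true_r_times = r_times,
                  true_coupling_window = cfg$coupling_window,
                  true_beta = cfg$coupling_beta,
                  corrupted_epochs = corrupted,
                  latent_ratings = ratings,
                  trial_start = trial_start,
                  kernel = list(t_ms = kern_t + cfg$her_kernel$latency_ms,
                                shape = kern))

    structure(list(recording = rec, trials = trials, truth = truth,
                   config = cfg), class = "her_session")
  })
}

# add waveform w into x at (possibly scaled) integer start positions,
# clipping at the edges
add_at <- function(x, w, starts, scale = rep(1, length(starts))) {
  m <- length(w)
  n <- length(x)
  for (j in seq_along(starts)) {
    s <- starts[j]
    lo <- max(1, s); hi <- min(n, s + m - 1)
    if (lo > hi) next
    x[lo:hi] <- x[lo:hi] + w[(lo - s + 1):(hi - s + 1)] * scale[j]
  }
  x
}

#' @export
print.her_session <- function(x, ...) {
  cat(sprintf("<her_session> %d trials, %d heartbeats, beta=%g, seed=%d\n",
              x$config$n_trials, length(x$truth$true_r_times),
              x$config$coupling_beta, x$config$seed))
  print(x$recording)
  invisible(x)
}

#' Implied single-sample HER/rating correlation of the generator
#'
#' At the kernel peak, the trial HER amplitude is
#' \code{baseline + beta * rating + noise}, with noise SD reduced by
#' \code{sqrt(epochs_per_trial)} through epoch averaging. The implied
#' Pearson correlation with the rating is
#' \code{beta * sd_rating / sqrt(beta^2 sd_rating^2 + sd_noise^2)};
#' ratings are uniform on \code{[0, 1]}, so \code{sd_rating =
#' 1/sqrt(12)}.
#'
#' @param config a [sim_config()].
#' @param epochs_per_trial epochs averaged per trial (default 2).
#' @return implied correlation (signed).
#' @export
implied_coupling_r <- function(config, epochs_per_trial = 2) {
  s_r <- 1 / sqrt(12)
  s_n <- config$noise_model$sd / sqrt(epochs_per_trial)
  config$coupling_beta * s_r /
    sqrt(config$coupling_beta^2 * s_r^2 + s_n^2)
}

#' Coupling coefficient that yields a target implied correlation
#'
#' Inverse of [implied_coupling_r()]: the \code{coupling_beta} for which
#' the generator's implied single-sample correlation equals
#' \code{target_r}.
#'
#' @param target_r desired correlation in (-1, 1).
#' @param config a [sim_config()] supplying the noise SD.
#' @param epochs_per_trial epochs averaged per trial (default 2).
#' @return the required \code{coupling_beta}.
#' @export
coupling_beta_for_r <- function(target_r, config, epochs_per_trial = 2) {
  stopifnot(abs(target_r) < 1)
  s_r <- 1 / sqrt(12)
  s_n <- config$noise_model$sd / sqrt(epochs_per_trial)
  sign(target_r) * s_n / s_r * abs(target_r) / sqrt(1 - target_r^2)
}

#' Simulate a group-level set of "high"/"low" condition HER traces
#'
#' Emulates the per-subject condition-average traces entering the
#' group median-split comparison: each subject contributes a pair of
#' smooth noise traces on the standard -100..600 ms axis; the "high"
#' trace additionally carries an effect bump inside
#' \code{effect_window} scaled so the across-subject standardized
#' difference at the bump peak is Cohen's d = \code{effect_d}.
#'
#' @param n_subjects number of subjects (default 16).
#' @param effect_window ms pair of the injected difference
#'   (default \code{c(384, 480)}).
#' @param effect_d standardized effect size of the high-low difference
#'   at the bump peak (0 for a null group).
#' @param noise_sd per-sample SD of each condition trace.
#' @param sample_rate Hz of the trace time axis (default 1000).
#' @param smooth_ms Gaussian smoothing SD of the trace noise in ms
#'   (temporal autocorrelation of an evoked average; default 20).
#' @param scale rating-scale label carried in the result.
#' @param seed RNG seed.
#' @return object of class \code{group_herset}: list with \code{high},
#'   \code{low} (subjects x time matrices), \code{time_ms},
#'   \code{n_subjects}, \code{scale}.
#' @export
simulate_group <- function(n_subjects = 16, effect_window = c(384, 480),
                           effect_d = 1, noise_sd = 1, sample_rate = 1000,
                           smooth_ms = 20, scale = "I", seed = 1) {
  time_ms <- seq(-100, 600, by = 1000 / sample_rate)
  nt <- length(time_ms)
  with_seed(seed, {
    smooth_trace <- function() {
      w <- stats::dnorm(seq(-3 * smooth_ms, 3 * smooth_ms, by = 1000 / sample_rate),
                        0, smooth_ms)
      pad <- length(w)
      x <- stats::rnorm(nt + 2 * pad)
      y <- stats::filter(x, w / sqrt(sum(w^2)), sides = 2)
      as.numeric(y)[pad + seq_len(nt)] * noise_sd
    }
    # tapered plateau: the standardized difference equals effect_d across
    # the bulk of the window (10% raised-cosine edges)
    env <- rep(0, nt)
    inside <- which(time_ms >= effect_window[1] & time_ms <= effect_window[2])
    u <- seq(0, 1, length.out = length(inside))
    edge <- 0.1
    ramp <- pmin(1, pmin(u, 1 - u) / edge)
    env[inside] <- 0.5 * (1 - cos(pi * ramp))
    mu <- effect_d * sqrt(2) * noise_sd
    high <- t(vapply(seq_len(n_subjects),
                     function(i) smooth_trace() + mu * env, numeric(nt)))
    low <- t(vapply(seq_len(n_subjects),
                    function(i) smooth_trace(), numeric(nt)))
    structure(list(high = high, low = low, time_ms = time_ms,
                   n_subjects = n_subjects, scale = scale),
              class = "group_herset")
  })
}
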
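#' Extract heartbeat-locked epochs preceding each stimulus
#'
#' For every non-skipped trial, selects the last two R-peaks that
#' precede the visual stimulus by at least \code{min_lead} ms (peak time
#' \code{<= stim_onset - min_lead/1000}) and cuts one epoch per peak
#' over \code{window} ms around the R-peak. Trials with fewer than two
#' qualifying peaks are recorded as incomplete, not an error.
#'
#' @param rec a [continuous_recording()] (neural channels only are
#'   epoched; an "ECG" channel, if present, is ignored).
#' @param peaks an [rpeak_series()].
#' @param trials trial table data.frame (see [read_trials()]): columns
#'   \code{trial_id}, \code{stim_onset_s}, per-scale ratings,
#'   \code{skipped}.
#' @param window ms pair relative to the R-peak, default
#'   \code{c(-100, 600)}.
#' @param min_lead minimum R-peak-to-stimulus lead in ms, default 700.
#' @param n_peaks how many pre-stimulus peaks to keep per trial
#'   (default 2).
#' @return object of class \code{her_epochs}: \code{values} array
#'   (epoch x time x channel), \code{meta} data.frame (\code{epoch},
#'   \code{trial_id}, \code{r_time}), \code{time_ms}, \code{sample_rate},
#'   \code{channels}, \code{incomplete} (trial ids), \code{excluded}
#'   (empty; filled by [reject_artifacts()]).
#' @export
extract_her_epochs <- function(rec, peaks, trials, window = c(-100, 600),
                               min_lead = 700, n_peaks = 2) {
  stopifnot(inherits(rec, "continuous_recording"),
            inherits(peaks, "rpeak_series"))
  check_trial_table(trials)
  fs <- rec$sample_rate
  chans <- setdiff(rec$channel_labels, "ECG")
  if (!length(chans)) stopf("recording has no neural channels")
  rel <- seq(round(window[1] * fs / 1000), round(window[2] * fs / 1000))
  time_ms <- rel * 1000 / fs

  sel_trial <- integer(0); sel_time <- numeric(0); incomplete <- integer(0)
  n_samp <- ncol(rec$data)
  for (i in seq_len(nrow(trials))) {
    if (trials$skipped[i] == 1) next
    ok <- peaks$times[peaks$times <= trials$stim_onset_s[i] - min_lead / 1000]
    ok <- utils::tail(ok, n_peaks)
    # peaks whose epoch would run off the recording cannot be used
    ok <- ok[round(ok * fs) + 1 + rel[1] >= 1 &
               round(ok * fs) + 1 + rel[length(rel)] <= n_samp]
    if (length(ok) < n_peaks) incomplete <- c(incomplete, trials$trial_id[i])
    sel_trial <- c(sel_trial, rep(trials$trial_id[i], length(ok)))
    sel_time <- c(sel_time, ok)
  }
  meta <- data.frame(epoch = seq_along(sel_time), trial_id = sel_trial,
                     r_time = sel_time)

  values <- array(0, dim = c(nrow(meta), length(rel), length(chans)),
                  dimnames = list(NULL, NULL, chans))
  ch_rows <- match(chans, rec$channel_labels)
  if (nrow(meta)) {
    idx_mat <- outer(round(meta$r_time * fs) + 1L, rel, "+")
    for (ch in seq_along(ch_rows)) {
      values[, , ch] <- rec$data[ch_rows[ch], ][idx_mat]
    }
  }
  structure(list(values = values, meta = meta, time_ms = time_ms,
                 sample_rate = fs, channels = chans,
                 incomplete = incomplete,
                 excluded = data.frame(epoch = integer(0),
                                       channel = character(0),
                                       reason = character(0)),
                 provenance = c(rec$provenance,
                                sprintf("epochs:%g..%gms:lead%gms",
                                        window[1], window[2], min_lead))),
            class = "her_epochs")
}

#' @export
print.her_epochs <- function(x, ...) {
  cat(sprintf("<her_epochs> %d epoch(s) x %d samples x %d channel(s), %g..%g ms\n",
              dim(x$values)[1], dim(x$values)[2], dim(x$values)[3],
              min(x$time_ms), max(x$time_ms)))
  if (nrow(x$excluded)) cat(sprintf("  %d excluded epoch-channel pair(s)\n",
                                    nrow(x$excluded)))
  if (length(x$incomplete)) cat("  incomplete trials:",
                                paste(x$incomplete, collapse = ", "), "\n")
  invisible(x)
}

# sliding-window range (max - min) over a fixed sample width, evaluated
# at every start position; x is an epochs x time matrix
sliding_range_max <- function(x, width) {
  nt <- ncol(x)
  if (width > nt) width <- nt
  hi <- x[, seq_len(nt - width + 1), drop = FALSE]
  lo <- hi
  if (width > 1) {
    for (k in seq_len(width - 1)) {
      shifted <- x[, (1 + k):(nt - width + 1 + k), drop = FALSE]
      hi <- pmax(hi, shifted)
      lo <- pmin(lo, shifted)
    }
  }
  apply(hi - lo, 1, max)
}

#' Reject artifact-contaminated epochs
#'
#' An epoch is excluded (per channel) if any sample exceeds
#' \code{abs_limit} in absolute value, or if any sliding window of
#' \code{range_window} ms (evaluated at every sample) has a dynamic
#' range (max - min) of \code{range_limit} or more. Exclusions are
#' logged with a reason; nothing is silently dropped. Thresholds are in
#' recording units -- conventional defaults 200 and 300 (the printed
#' "mV" unit of the originating criteria is implausible for bipolar
#' physiology and is treated as a label, not a unit; see the vignette).
#'
#' @param epochs a [extract_her_epochs()] result.
#' @param abs_limit absolute amplitude limit (default 200).
#' @param range_limit dynamic-range limit (default 300); an epoch
#'   reaching \code{range_limit} exactly is rejected.
#' @param range_window window width in ms (default 20).
#' @return epochs object with \code{excluded} filled in.
#' @export
reject_artifacts <- function(epochs, abs_limit = 200, range_limit = 300,
                             range_window = 20) {
  stopifnot(inherits(epochs, "her_epochs"))
  if (abs_limit <= 0 || range_limit <= 0 || range_window <= 0) {
    stopf("rejection limits must be positive")
  }
  width <- max(1L, round(range_window * epochs$sample_rate / 1000) + 1L)
  out <- list()
  for (ch in seq_along(epochs$channels)) {
    x <- epochs$values[, , ch, drop = FALSE]
    dim(x) <- dim(epochs$values)[1:2]
    if (nrow(x) == 0) next
    amp_bad <- apply(abs(x), 1, max) > abs_limit
    rng_bad <- sliding_range_max(x, width) >= range_limit
    for (e in which(amp_bad)) {
      out[[length(out) + 1]] <- data.frame(epoch = e,
                                           channel = epochs$channels[ch],
                                           reason = "amplitude")
    }
    for (e in which(rng_bad & !amp_bad)) {
      out[[length(out) + 1]] <- data.frame(epoch = e,
                                           channel = epochs$channels[ch],
                                           reason = "range")
    }
  }
  epochs$excluded <- if (length(out)) do.call(rbind, out) else epochs$excluded
  epochs$provenance <- c(epochs$provenance,
                         sprintf("reject:abs%g:range%gin%gms", abs_limit,
                                 range_limit, range_window))
  epochs
}

#' Average retained epochs into one HER per trial
#'
#' Per channel, the retained (non-excluded) epochs of each trial are
#' averaged into a single heartbeat-evoked response. Trials whose
#' retained-epoch count falls below \code{min_epochs} are dropped and
#' logged; with the default \code{min_epochs = 1}, a trial that lost
#' one of its two epochs keeps the surviving epoch as its HER (flagged
#' in \code{n_epochs}). Strict mode (\code{min_epochs = 2}) drops such
#' trials.
#'
#' @param epochs a (possibly rejected) [extract_her_epochs()] result.
#' @param min_epochs minimum retained epochs per trial (default 1).
#' @return object of class \code{trial_her}: \code{values} array
#'   (trial x time x channel), \code{trial_id} per channel list,
#'   \code{time_ms}, \code{n_epochs} (trial x channel count matrix,
#'   rownames = trial id), \code{dropped} data.frame.
#' @export
average_trial_her <- function(epochs, min_epochs = 1) {
  stopifnot(inherits(epochs, "her_epochs"))
  trial_ids <- sort(unique(epochs$meta$trial_id))
  nt <- length(trial_ids)
  n_time <- dim(epochs$values)[2]
  n_ch <- length(epochs$channels)
  values <- array(NA_real_, dim = c(nt, n_time, n_ch),
                  dimnames = list(trial_ids, NULL, epochs$channels))
  n_ep <- matrix(0L, nt, n_ch, dimnames = list(trial_ids, epochs$channels))
  dropped <- list()
  for (ch in seq_len(n_ch)) {
    bad <- epochs$excluded$epoch[epochs$excluded$channel == epochs$channels[ch]]
    for (ti in seq_len(nt)) {
      eps <- epochs$meta$epoch[epochs$meta$trial_id == trial_ids[ti]]
      eps <- setdiff(eps, bad)
      n_ep[ti, ch] <- length(eps)
      if (length(eps) >= min_epochs && length(eps) > 0) {
        x <- epochs$values[eps, , ch, drop = FALSE]
        dim(x) <- c(length(eps), n_time)
        values[ti, , ch] <- colMeans(x)
      } else {
        dropped[[length(dropped) + 1]] <-
          data.frame(trial_id = trial_ids[ti],
                     channel = epochs$channels[ch],
                     n_retained = length(eps))
      }
    }
  }
  structure(list(values = values, trial_ids = trial_ids,
                 time_ms = epochs$time_ms, n_epochs = n_ep,
                 sample_rate = epochs$sample_rate,
                 channels = epochs$channels,
                 dropped = if (length(dropped)) do.call(rbind, dropped) else
                   data.frame(trial_id = integer(0), channel = character(0),
                              n_retained = integer(0)),
                 provenance = c(epochs$provenance,
                                sprintf("average:min%d", min_epochs))),
            class = "trial_her")
}

#' @export
print.trial_her <- function(x, ...) {
  cat(sprintf("<trial_her> %d trial(s) x %d samples x %d channel(s)\n",
              dim(x$values)[1], dim(x$values)[2], dim(x$values)[3]))
  if (nrow(x$dropped)) cat(sprintf("  %d trial-channel pair(s) dropped\n",
                                   nrow(x$dropped)))
  invisible(x)
}

#' HER matrix for one channel
#'
#' Trials-by-time matrix of per-trial HERs for a single channel, with
#' trials lacking a usable HER removed.
#'
#' @param her a [average_trial_her()] result.
#' @param channel channel label or index (default first channel).
#' @return matrix with rownames = trial ids, attribute \code{time_ms}.
#' @export
her_matrix <- function(her, channel = 1) {
  stopifnot(inherits(her, "trial_her"))
  if (is.character(channel)) channel <- match(channel, her$channels)
  if (is.na(channel) || channel < 1 || channel > length(her$channels)) {
    stopf("unknown channel")
  }
  m <- her$values[, , channel, drop = FALSE]
  dim(m) <- dim(her$values)[1:2]
  rownames(m) <- her$trial_ids
  keep <- stats::complete.cases(m)
  m <- m[keep, , drop = FALSE]
  attr(m, "time_ms") <- her$time_ms
  m
}

check_trial_table <- function(trials) {
  need <- c("trial_id", "stim_onset_s", "skipped")
  miss <- setdiff(need, names(trials))
  if (length(miss)) stopf("trial table lacks column(s): %s",
                          paste(miss, collapse = ", "))
  invisible(trials)
}
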
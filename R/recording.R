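#' Continuous multichannel recording
#'
#' Lightweight container for a uniformly sampled multichannel signal:
#' a channels-by-samples matrix plus channel metadata and montage state.
#' All times elsewhere in the package are seconds from the start of the
#' recording (sample 1 is time 0).
#'
#' @param data numeric matrix, channels x samples.
#' @param sample_rate sampling rate in Hz.
#' @param channel_labels character vector, one per row of \code{data}.
#' @param montage \code{"referential"} or \code{"bipolar"}.
#' @param shaft character vector assigning each channel to an electrode
#'   shaft (used by [to_bipolar()]); \code{NA} for non-neural channels
#'   such as ECG.
#' @return an object of class \code{continuous_recording}.
#' @export
continuous_recording <- function(data, sample_rate, channel_labels,
                                 montage = "referential", shaft = NULL) {
  if (!is.matrix(data)) data <- matrix(data, nrow = 1)
  if (!all(is.finite(data))) stopf("recording contains non-finite values")
  assert_scalar_num(sample_rate, "sample_rate", 1e-9)
  if (length(channel_labels) != nrow(data)) {
    stopf("need one label per channel (%d labels, %d channels)",
          length(channel_labels), nrow(data))
  }
  structure(list(
    data = data,
    sample_rate = sample_rate,
    channel_labels = as.character(channel_labels),
    montage = match.arg(montage, c("referential", "bipolar")),
    shaft = shaft %||% rep(NA_character_, nrow(data)),
    provenance = character(0)
  ), class = "continuous_recording")
}

#' @export
print.continuous_recording <- function(x, ...) {
  cat(sprintf("<continuous_recording> %d channel(s) x %d samples @ %g Hz (%.1f s), %s montage\n",
              nrow(x$data), ncol(x$data), x$sample_rate,
              ncol(x$data) / x$sample_rate, x$montage))
  cat("  channels:", paste(utils::head(x$channel_labels, 8), collapse = ", "),
      if (length(x$channel_labels) > 8) "..." else "", "\n")
  if (length(x$provenance)) cat("  provenance:", paste(x$provenance, collapse = " | "), "\n")
  invisible(x)
}

#' Extract one channel as a numeric vector
#' @param rec a [continuous_recording()].
#' @param label channel label.
#' @return numeric vector of samples.
#' @export
get_channel <- function(rec, label) {
  i <- match(label, rec$channel_labels)
  if (is.na(i)) stopf("no channel labelled '%s' (have: %s)", label,
                      paste(rec$channel_labels, collapse = ", "))
  rec$data[i, ]
}

#' Re-reference to a bipolar montage
#'
#' Each neural contact is re-referenced to its nearest neighbour on the
#' same electrode shaft: output channel \code{"A1-A2"} is contact A1
#' minus contact A2. Signals common to both contacts -- notably the
#' volume-conducted cardiac field -- cancel. Channels without a shaft
#' assignment (e.g. ECG) are carried through unchanged.
#'
#' @param rec a referential [continuous_recording()] with shaft
#'   assignments.
#' @return a bipolar recording; shafts with a single contact contribute
#'   no output channel (with a warning).
#' @export
to_bipolar <- function(rec) {
  stopifnot(inherits(rec, "continuous_recording"))
  if (rec$montage != "referential") stopf("recording is already bipolar")
  neural <- which(!is.na(rec$shaft))
  if (!length(neural)) stopf("no channels carry a shaft assignment")
  rows <- list(); labels <- character(0); shafts <- character(0)
  for (sh in unique(rec$shaft[neural])) {
    idx <- neural[rec$shaft[neural] == sh]
    if (length(idx) < 2) {
      warnf("shaft '%s' has a single contact; no bipolar channel emitted", sh)
      next
    }
    for (k in seq_len(length(idx) - 1)) {
      a <- idx[k]; b <- idx[k + 1]
      rows[[length(rows) + 1]] <- rec$data[a, ] - rec$data[b, ]
      labels <- c(labels, paste0(rec$channel_labels[a], "-", rec$channel_labels[b]))
      shafts <- c(shafts, sh)
    }
  }
  keep <- which(is.na(rec$shaft))   # ECG etc. pass through
  out_data <- do.call(rbind, c(rows, lapply(keep, function(i) rec$data[i, ])))
  out <- continuous_recording(
    out_data, rec$sample_rate,
    c(labels, rec$channel_labels[keep]),
    montage = "bipolar",
    shaft = c(shafts, rep(NA_character_, length(keep)))
  )
  out$provenance <- c(rec$provenance, "bipolar")
  out
}
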
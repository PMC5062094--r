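#' Butterworth filter design (transfer-function coefficients)
#'
#' Designs a digital Butterworth filter by the analog-prototype /
#' bilinear-transform route with frequency prewarping, as used throughout
#' electrophysiology preprocessing. Supported types: low-pass, high-pass
#' and band-pass.
#'
#' @param order filter order (of the analog prototype; a band-pass of
#'   order \code{n} has \code{2n} poles).
#' @param cutoff cutoff frequency in Hz (length 1 for low/high, length 2
#'   for band-pass).
#' @param sample_rate sampling rate in Hz.
#' @param type one of \code{"low"}, \code{"high"}, \code{"pass"}.
#' @return list with numerator \code{b} and denominator \code{a}
#'   coefficients (a[1] == 1).
#' @examples
#' bf <- butter_design(4, c(0.5, 25), 1000, "pass")
#' @export
butter_design <- function(order, cutoff, sample_rate,
                          type = c("pass", "low", "high")) {
  type <- match.arg(type)
  assert_scalar_num(order, "order", 1, 12)
  nyq <- sample_rate / 2
  if (any(cutoff <= 0) || any(cutoff >= nyq)) {
    stopf("cutoff frequencies must lie strictly inside (0, Nyquist = %g)", nyq)
  }
  if (type == "pass") {
    if (length(cutoff) != 2L || cutoff[1] >= cutoff[2]) {
      stopf("band-pass needs cutoff = c(low, high) with low < high")
    }
  } else if (length(cutoff) != 1L) {
    stopf("'%s' filter needs a single cutoff", type)
  }

  n <- as.integer(order)
  # analog low-pass prototype: poles on the unit circle, left half-plane
  k <- seq_len(n)
  p <- exp(1i * pi * (2 * k + n - 1) / (2 * n))
  z <- complex(0)
  gain <- 1

  fs2 <- 2 * sample_rate
  warp <- fs2 * tan(pi * cutoff / sample_rate)   # prewarped rad/s

  if (type == "low") {
    p <- p * warp
    gain <- gain * warp^n
  } else if (type == "high") {
    gain <- gain * Re(prod(-p))
    p <- warp / p
    z <- rep(0 + 0i, n)
  } else {
    bw <- warp[2] - warp[1]
    w0 <- sqrt(warp[1] * warp[2])
    gain <- gain * bw^n
    ph <- p * bw / 2
    p <- c(ph + sqrt(ph^2 - w0^2), ph - sqrt(ph^2 - w0^2))
    z <- rep(0 + 0i, n)
  }

  # bilinear transform s -> (2/T)(z-1)/(z+1)
  gain <- gain * Re(prod(fs2 - z) / prod(fs2 - p))
  zd <- (fs2 + z) / (fs2 - z)
  pd <- (fs2 + p) / (fs2 - p)
  zd <- c(zd, rep(-1 + 0i, length(pd) - length(zd)))

  b <- Re(poly_from_roots(zd)) * gain
  a <- Re(poly_from_roots(pd))
  # Polynomial expansion of many poles near |z| = 1 is ill-conditioned
  # (the classic narrow-band Butterworth instability), so the filter is
  # applied as a cascade of second-order sections built from the exact
  # pole/zero pairs.
  list(b = b, a = a, sos = zpk_to_sos(zd, pd, gain))
}

# Pair conjugate poles/zeros into biquads. Both vectors must come in
# conjugate pairs (true for even-order Butterworth designs here); a
# leftover real singleton becomes a first-order section.
zpk_to_sos <- function(z, p, gain) {
  pair_up <- function(r) {
    r <- r[order(-Mod(r), Im(r))]
    used <- logical(length(r))
    out <- list()
    for (i in seq_along(r)) {
      if (used[i]) next
      used[i] <- TRUE
      if (abs(Im(r[i])) < 1e-12) {
        j <- which(!used & abs(Im(r)) < 1e-12)[1]
        if (!is.na(j)) { used[j] <- TRUE; out[[length(out) + 1]] <- c(r[i], r[j]) }
        else out[[length(out) + 1]] <- r[i]
      } else {
        j <- which(!used & abs(r - Conj(r[i])) < 1e-8 * (1 + Mod(r[i])))[1]
        if (is.na(j)) stopf("unpaired complex root in filter design")
        used[j] <- TRUE
        out[[length(out) + 1]] <- c(r[i], r[j])
      }
    }
    out
  }
  pp <- pair_up(p)
  zp <- pair_up(z)
  # balance: give each pole section a zero group; zeros at +1 and -1 are
  # interleaved for band-pass so every biquad is a tiny band-pass itself
  ones <- z[abs(z - 1) < 1e-8]; mins <- z[abs(z + 1) < 1e-8]
  if (length(ones) > 0 && length(mins) > 0 &&
      length(ones) + length(mins) == length(z)) {
    zp <- lapply(seq_along(pp), function(i) c(1 + 0i, -1 + 0i))
  }
  n_sec <- length(pp)
  sos <- matrix(0, n_sec, 6)
  for (i in seq_len(n_sec)) {
    ps <- pp[[i]]
    zs <- if (i <= length(zp)) zp[[i]] else complex(0)
    acf <- Re(poly_from_roots(ps))
    bcf <- Re(poly_from_roots(zs))
    acf <- c(acf, rep(0, 3 - length(acf)))
    bcf <- c(bcf, rep(0, 3 - length(bcf)))
    sos[i, ] <- c(bcf, acf)
  }
  sos[1, 1:3] <- sos[1, 1:3] * gain
  sos
}

# expand monic polynomial from its roots (complex-safe)
poly_from_roots <- function(r) {
  cf <- 1 + 0i
  for (ri in r) cf <- c(cf, 0) - c(0, cf * ri)
  cf
}

# single-pass IIR filter, zero initial conditions; uses C-level
# stats::filter for both the FIR and the recursive part.
iir_filter <- function(b, a, x) {
  v <- stats::filter(c(rep(0, length(b) - 1), x), b, method = "convolution",
                     sides = 1)
  v <- as.numeric(v)[-seq_len(length(b) - 1)]
  if (length(a) > 1) {
    v <- as.numeric(stats::filter(v, -a[-1], method = "recursive"))
  }
  v
}

# cascade of second-order sections, zero initial conditions
sos_filter <- function(sos, x) {
  for (i in seq_len(nrow(sos))) {
    x <- iir_filter(sos[i, 1:3], sos[i, 4:6], x)
  }
  x
}

#' Zero-phase (forward-backward) filtering
#'
#' Applies an IIR filter forward and backward so the net phase response is
#' zero and the magnitude response is squared. Edges are handled by odd
#' (mirror) extension before filtering, which suppresses start-up
#' transients for signals that do not begin at zero.
#'
#' @param coef list with \code{b}, \code{a} as returned by
#'   [butter_design()].
#' @param x numeric signal.
#' @param pad_len samples of odd extension at each end (default: three
#'   filter lengths, capped at \code{length(x) - 1}).
#' @return filtered signal, same length as \code{x}.
#' @export
filtfilt <- function(coef, x, pad_len = NULL) {
  b <- coef$b; a <- coef$a
  ncoef <- max(length(a), length(b))
  if (is.null(pad_len)) pad_len <- 3L * (ncoef - 1L)
  pad_len <- min(pad_len, length(x) - 1L)
  if (pad_len < 0) stopf("signal too short to filter")
  n <- length(x)
  pre <- 2 * x[1] - x[seq(pad_len + 1, 2, length.out = pad_len)]
  post <- 2 * x[n] - x[seq(n - 1, n - pad_len, length.out = pad_len)]
  if (pad_len == 0) pre <- post <- numeric(0)
  xe <- c(pre, x, post)
  if (!is.null(coef$sos)) {
    y <- sos_filter(coef$sos, xe)
    y <- rev(sos_filter(coef$sos, rev(y)))
  } else {
    y <- iir_filter(b, a, xe)
    y <- rev(iir_filter(b, a, rev(y)))
  }
  y[seq(pad_len + 1, pad_len + n)]
}

#' Band-pass filter a continuous recording
#'
#' Fourth-order (by default) Butterworth band-pass applied forward and
#' backward (zero-phase), so evoked-response latencies are not shifted.
#' The channel means (DC) are removed before filtering.
#'
#' @param rec a [continuous_recording()].
#' @param low,high band edges in Hz; defaults 0.5 and 25 Hz, the band
#'   conventionally used for heartbeat-evoked responses.
#' @param order Butterworth prototype order (default 4).
#' @return the filtered recording with provenance updated.
#' @export
bandpass <- function(rec, low = 0.5, high = 25, order = 4) {
  stopifnot(inherits(rec, "continuous_recording"))
  nyq <- rec$sample_rate / 2
  if (!(low > 0 && low < high && high < nyq)) {
    stopf("invalid band [%g, %g] Hz for sample rate %g Hz", low, high,
          rec$sample_rate)
  }
  coef <- butter_design(order, c(low, high), rec$sample_rate, "pass")
  # long pad: the high-pass corner transient decays over ~1/low seconds
  pad <- as.integer(min(ncol(rec$data) - 1, ceiling(3 / low * rec$sample_rate)))
  for (ch in seq_len(nrow(rec$data))) {
    x <- rec$data[ch, ]
    rec$data[ch, ] <- filtfilt(coef, x - mean(x), pad_len = pad)
  }
  rec$provenance <- c(rec$provenance,
                      sprintf("bandpass:%g-%gHz:order%d", low, high, order))
  rec
}

#' Downsample a continuous recording
#'
#' Anti-alias low-pass (8th-order zero-phase Butterworth at 0.4 times the
#' target rate) followed by integer decimation.
#'
#' @param rec a [continuous_recording()].
#' @param target_rate new sampling rate in Hz; must divide the current
#'   rate. Upsampling is refused.
#' @return recording at \code{target_rate}.
#' @export
downsample <- function(rec, target_rate) {
  stopifnot(inherits(rec, "continuous_recording"))
  fs <- rec$sample_rate
  if (target_rate > fs) stopf("upsampling (%g -> %g Hz) is not supported",
                              fs, target_rate)
  if (target_rate == fs) return(rec)
  fac <- fs / target_rate
  if (abs(fac - round(fac)) > 1e-9) {
    stopf("sample rate ratio %g/%g is not an integer", fs, target_rate)
  }
  fac <- as.integer(round(fac))
  coef <- butter_design(8, 0.4 * target_rate, fs, "low")
  idx <- seq(1, ncol(rec$data), by = fac)
  out <- matrix(0, nrow(rec$data), length(idx))
  for (ch in seq_len(nrow(rec$data))) {
    out[ch, ] <- filtfilt(coef, rec$data[ch, ])[idx]
  }
  rec$data <- out
  rec$sample_rate <- target_rate
  rec$provenance <- c(rec$provenance, sprintf("downsample:%gHz", target_rate))
  rec
}
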
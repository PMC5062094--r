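# ---- EDF (European Data Format) ------------------------------------------
# Minimal continuous EDF: 16-bit samples, identical sample rate across
# channels, one signal per channel. Written with a fixed header date so
# identical data give byte-identical files.

pad_field <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  sprintf(paste0("%-", width, "s"), x)
}

# most precise numeric representation fitting an 8-char EDF field
num_field <- function(x) {
  for (d in 7:1) {
    s <- sprintf("%.*g", d, x)
    if (nchar(s) <= 8) return(s)
  }
  s
}

#' Write a recording as an EDF file
#'
#' Samples are quantized to 16 bits over each channel's physical range,
#' so round-trip error is bounded by range/65535/2. The record layout
#' uses one-second data records (with a final partial record padded by
#' the last sample value and the true sample count stored in the
#' reserved field, which [read_edf()] honours).
#'
#' @param rec a [continuous_recording()].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "continuous_recording"))
  fs <- rec$sample_rate
  if (abs(fs - round(fs)) > 1e-9) stopf("EDF writer requires an integer sample rate")
  fs <- as.integer(round(fs))
  n <- ncol(rec$data); ns <- nrow(rec$data)
  n_rec <- ceiling(n / fs)

  phys_min <- phys_max <- numeric(ns)
  dig <- matrix(0L, ns, n_rec * fs)
  for (ch in seq_len(ns)) {
    lo <- min(rec$data[ch, ]); hi <- max(rec$data[ch, ])
    if (hi - lo < 1e-12) { lo <- lo - 1; hi <- hi + 1 }
    # quantize against the values actually stored in the 8-char ASCII
    # header fields, so the reader inverts the exact same mapping
    lo <- as.numeric(num_field(lo)); hi <- as.numeric(num_field(hi))
    phys_min[ch] <- lo; phys_max[ch] <- hi
    x <- c(rec$data[ch, ], rep(rec$data[ch, n], n_rec * fs - n))
    d <- round((x - lo) / (hi - lo) * 65535 - 32768)
    dig[ch, ] <- as.integer(pmin(pmax(d, -32768), 32767))
  }

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(
    pad_field("0", 8),
    pad_field("X X X X", 80),
    pad_field(sprintf("Startdate 01-JAN-2000 X X %s", "hertools"), 80),
    pad_field("01.01.00", 8), pad_field("00.00.00", 8),
    pad_field(as.character(256 * (1 + ns)), 8),
    pad_field(sprintf("nsamples=%d", n), 44),
    pad_field(as.character(n_rec), 8),
    pad_field("1", 8),
    pad_field(as.character(ns), 4)
  ), con, eos = NULL)
  fields <- list(
    vapply(rec$channel_labels, pad_field, "", width = 16),
    rep(pad_field("", 80), ns),
    rep(pad_field("uV", 8), ns),
    vapply(vapply(phys_min, num_field, ""), pad_field, "", width = 8),
    vapply(vapply(phys_max, num_field, ""), pad_field, "", width = 8),
    rep(pad_field("-32768", 8), ns),
    rep(pad_field("32767", 8), ns),
    vapply(ifelse(is.na(rec$shaft), "", paste0("shaft=", rec$shaft)),
           pad_field, "", width = 80),
    rep(pad_field(as.character(fs), 8), ns),
    rep(pad_field("", 32), ns)
  )
  for (f in fields) writeChar(paste(f, collapse = ""), con, eos = NULL)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    for (ch in seq_len(ns)) {
      writeBin(dig[ch, idx], con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

read_field <- function(con, width, offset_name) {
  raw <- readChar(con, width, useBytes = TRUE)
  if (nchar(raw, type = "bytes") < width) {
    stopf("truncated EDF file while reading %s at byte %d", offset_name,
          seek(con))
  }
  trimws(raw)
}

#' Read an EDF file into a continuous recording
#'
#' Supports continuous 16-bit EDF with a common sample rate across
#' channels; mixed per-channel rates are refused. A truncated file
#' raises an error naming the byte offset where data ran out.
#'
#' @param path EDF file.
#' @param require_ecg error if no channel is labelled "ECG".
#' @return a [continuous_recording()].
#' @export
read_edf <- function(path, require_ecg = FALSE) {
  con <- file(path, "rb")
  on.exit(close(con))
  read_field(con, 8, "version")
  read_field(con, 80, "patient id")
  read_field(con, 80, "recording id")
  read_field(con, 8, "start date"); read_field(con, 8, "start time")
  header_bytes <- as.integer(read_field(con, 8, "header size"))
  reserved <- read_field(con, 44, "reserved")
  n_rec <- as.integer(read_field(con, 8, "record count"))
  rec_dur <- as.numeric(read_field(con, 8, "record duration"))
  ns <- as.integer(read_field(con, 4, "signal count"))
  if (is.na(ns) || ns < 1) stopf("invalid EDF: bad signal count")

  labels <- vapply(seq_len(ns), function(i) read_field(con, 16, "label"), "")
  for (i in seq_len(ns)) read_field(con, 80, "transducer")
  for (i in seq_len(ns)) read_field(con, 8, "physical dimension")
  phys_min <- as.numeric(vapply(seq_len(ns), function(i)
    read_field(con, 8, "physical min"), ""))
  phys_max <- as.numeric(vapply(seq_len(ns), function(i)
    read_field(con, 8, "physical max"), ""))
  dig_min <- as.numeric(vapply(seq_len(ns), function(i)
    read_field(con, 8, "digital min"), ""))
  dig_max <- as.numeric(vapply(seq_len(ns), function(i)
    read_field(con, 8, "digital max"), ""))
  prefilt <- vapply(seq_len(ns), function(i) read_field(con, 80, "prefiltering"), "")
  nsamp <- as.integer(vapply(seq_len(ns), function(i)
    read_field(con, 8, "samples per record"), ""))
  for (i in seq_len(ns)) read_field(con, 32, "signal reserved")

  if (length(unique(nsamp)) != 1) {
    stopf("unsupported EDF: channels have mixed sample rates (%s)",
          paste(unique(nsamp), collapse = ", "))
  }
  fs <- nsamp[1] / rec_dur
  total <- n_rec * nsamp[1]
  data <- matrix(0, ns, total)
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      v <- readBin(con, integer(), n = nsamp[1], size = 2, endian = "little",
                   signed = TRUE)
      if (length(v) < nsamp[1]) {
        stopf("truncated EDF file: data ended at byte %d (record %d, channel %d)",
              seek(con), r, ch)
      }
      sc <- (phys_max[ch] - phys_min[ch]) / (dig_max[ch] - dig_min[ch])
      data[ch, ((r - 1) * nsamp[1] + 1):(r * nsamp[1])] <-
        (v - dig_min[ch]) * sc + phys_min[ch]
    }
  }
  true_n <- total
  if (grepl("^nsamples=", reserved)) {
    true_n <- min(total, as.integer(sub("^nsamples=", "", reserved)))
  }
  data <- data[, seq_len(true_n), drop = FALSE]
  shaft <- ifelse(grepl("^shaft=", prefilt), sub("^shaft=", "", prefilt),
                  NA_character_)
  if (require_ecg && !"ECG" %in% labels) {
    stopf("EDF file has no channel labelled 'ECG' (found: %s)",
          paste(labels, collapse = ", "))
  }
  continuous_recording(data, fs, labels, montage = "referential",
                       shaft = shaft)
}

#' Read a recording (EDF)
#'
#' Thin wrapper over [read_edf()] kept as the generic entry point of
#' the pipeline.
#' @param path EDF file.
#' @param require_ecg error if no "ECG" channel present.
#' @return a [continuous_recording()].
#' @export
read_recording <- function(path, require_ecg = FALSE) {
  read_edf(path, require_ecg = require_ecg)
}

# ---- trial tables ---------------------------------------------------------

#' Read a trial table (TSV)
#'
#' Expects columns \code{trial_id}, \code{stim_onset_s}, one
#' \code{<scale>_rating} column per rating scale, and \code{skipped}
#' (0/1). Ratings must lie in [0, 1]; a missing rating on a non-skipped
#' trial is an error (skipped trials may carry NA and are excluded from
#' analysis downstream).
#'
#' @param path TSV file.
#' @return validated data.frame.
#' @export
read_trials <- function(path) {
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE)
  check_trial_table(df)
  rating_cols <- grep("_rating$", names(df), value = TRUE)
  if (!length(rating_cols)) stopf("trial table has no *_rating column")
  for (col in rating_cols) {
    v <- df[[col]]
    bad <- which(!is.na(v) & (v < 0 | v > 1))
    if (length(bad)) {
      stopf("rating '%s' out of [0, 1] at row %d (value %g)", col, bad[1],
            v[bad[1]])
    }
    miss <- which(is.na(v) & df$skipped == 0)
    if (length(miss)) {
      stopf("missing rating '%s' on non-skipped trial at row %d", col, miss[1])
    }
  }
  df
}

#' Write a trial table (TSV)
#' @param trials trial table data.frame.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_trials <- function(trials, path) {
  check_trial_table(trials)
  utils::write.table(format_df(trials), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# fixed-format numbers so file bytes do not depend on options(digits)
format_df <- function(df) {
  for (c in names(df)) {
    if (is.numeric(df[[c]]) && !is.integer(df[[c]])) {
      df[[c]] <- sprintf("%.10g", df[[c]])
      df[[c]][df[[c]] == "NA"] <- NA
    }
  }
  df
}

#' Write / read R-peak times (TSV, column time_s)
#' @param peaks an [rpeak_series()].
#' @param path file path.
#' @return \code{path} (write) or an [rpeak_series()] (read).
#' @export
write_rpeaks <- function(peaks, path) {
  stopifnot(inherits(peaks, "rpeak_series"))
  utils::write.table(data.frame(time_s = sprintf("%.10g", peaks$times)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rpeaks
#' @export
read_rpeaks <- function(path) {
  df <- utils::read.delim(path, sep = "\t")
  rpeak_series(df$time_s)
}

#' Write a cluster result as TSV (+ the null distributions implicitly
#' summarized by p)
#' @param res a \code{cluster_result}.
#' @param path output TSV.
#' @param site,scale labels recorded in the output rows.
#' @return \code{path}, invisibly.
#' @export
write_clusters <- function(res, path, site = "SITE1", scale = "I") {
  stopifnot(inherits(res, "cluster_result"))
  df <- res$clusters
  out <- data.frame(site = site, scale = scale,
                    start_ms = df$start_ms, end_ms = df$end_ms,
                    sum_t = sprintf("%.6f", df$sum_t),
                    p_mc = sprintf("%.6g", df$p_mc),
                    p_corrected = sprintf("%.6g", df$p_corrected),
                    status = res$status)
  if (!nrow(df)) {
    out <- data.frame(site = site, scale = scale, start_ms = NA, end_ms = NA,
                      sum_t = NA, p_mc = NA, p_corrected = NA,
                      status = res$status)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- run manifests --------------------------------------------------------

#' Build a run manifest
#'
#' Records the stage name, parameters, input-file MD5 hashes, package
#' version and seed, so every result file is traceable to the exact
#' inputs and configuration that produced it.
#'
#' @param stage pipeline stage name.
#' @param params named list of stage parameters (must be
#'   JSON-serializable).
#' @param inputs character vector of input file paths (hashed).
#' @param seed RNG seed used (or NULL).
#' @return manifest list.
#' @export
run_manifest <- function(stage, params = list(), inputs = character(0),
                         seed = NULL) {
  hashes <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  ver <- tryCatch(as.character(utils::packageVersion("hertools")),
                  error = function(e) "dev")
  list(stage = stage,
       package = "hertools",
       version = ver,
       seed = seed,
       params = params,
       input_md5 = hashes,
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

#' Write a manifest (JSON)
#' @param manifest list from [run_manifest()].
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
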
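#' Construct a multi-lead ECG record
#'
#' The canonical in-memory container for a multi-lead ECG: a numeric matrix of
#' amplitudes in millivolts (one column per lead) together with the sampling
#' frequency and the per-lead ADC calibration (gain in ADC units per mV and
#' ADC zero offset) used when the record is written to disk.
#'
#' @param signal numeric matrix, `n_samples x n_leads`, amplitudes in mV.
#' @param fs sampling frequency in Hz (> 0).
#' @param lead_names character vector of lead names, one per column. Must be
#'   unique and drawn from the standard 12-lead names
#'   (I, II, III, aVR, aVL, aVF, V1--V6).
#' @param record_id identifier string.
#' @param gain ADC units per mV, recycled per lead (default 200, the MIT-BIH
#'   convention).
#' @param baseline_adc ADC value corresponding to 0 mV, recycled per lead.
#' @return an object of class `ecg_record`.
#' @export
ecg_record <- function(signal, fs, lead_names, record_id = "record",
                       gain = 200, baseline_adc = 0) {
  signal <- as.matrix(signal)
  storage.mode(signal) <- "double"
  n_leads <- ncol(signal)
  gain <- rep_len(as.numeric(gain), n_leads)
  baseline_adc <- rep_len(as.numeric(baseline_adc), n_leads)
  colnames(signal) <- lead_names
  rec <- structure(
    list(record_id = as.character(record_id)[1], fs = as.numeric(fs)[1],
         lead_names = as.character(lead_names), signal = signal,
         gain = gain, baseline_adc = baseline_adc),
    class = "ecg_record")
  validate_ecg_record(rec)
  rec
}

STANDARD_LEADS <- c("I", "II", "III", "aVR", "aVL", "aVF",
                    "V1", "V2", "V3", "V4", "V5", "V6")

#' Validate an ECG record's invariants
#'
#' Checks sampling frequency, lead-name uniqueness, matrix shape, finiteness
#' of every sample and positivity of the per-lead gains. Called by every
#' constructor and reader; exported so pipelines can re-validate records they
#' assembled themselves.
#'
#' @param rec an `ecg_record`.
#' @return `rec`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_ecg_record <- function(rec) {
  stopifnot(inherits(rec, "ecg_record"))
  if (!is.finite(rec$fs) || rec$fs <= 0)
    stop("validation error: fs must be a positive number, got ", rec$fs)
  if (anyDuplicated(rec$lead_names))
    stop("validation error: lead names must be unique")
  if (!all(rec$lead_names %in% STANDARD_LEADS))
    stop("validation error: unknown lead name(s): ",
         paste(setdiff(rec$lead_names, STANDARD_LEADS), collapse = ", "))
  if (ncol(rec$signal) != length(rec$lead_names))
    stop("validation error: signal has ", ncol(rec$signal),
         " columns but ", length(rec$lead_names), " lead names")
  if (!all(is.finite(rec$signal)))
    stop("validation error: signal contains non-finite samples")
  if (any(!is.finite(rec$gain)) || any(rec$gain <= 0))
    stop("validation error: gain must be > 0 for every lead")
  if (length(rec$baseline_adc) != ncol(rec$signal))
    stop("validation error: baseline_adc length mismatch")
  invisible(rec)
}

#' @export
#' @method print ecg_record
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record '%s'>  %d leads x %d samples @ %g Hz (%.1f s)\n",
              x$record_id, ncol(x$signal), nrow(x$signal), x$fs,
              nrow(x$signal) / x$fs))
  cat("  leads:", paste(x$lead_names, collapse = " "), "\n")
  invisible(x)
}

#' Extract one lead of an ECG record as a numeric vector
#' @param rec an `ecg_record`.
#' @param lead lead name.
#' @return numeric vector of amplitudes in mV.
#' @export
ecg_lead <- function(rec, lead) {
  if (!lead %in% rec$lead_names)
    stop("validation error: record has no lead '", lead, "'")
  rec$signal[, lead]
}

# ---- Format 212 packing ----------------------------------------------------

#' Pack 12-bit ADC samples into MIT-BIH Format 212 bytes
#'
#' Format 212 stores two 12-bit two's-complement samples in three bytes:
#' byte 1 holds the low 8 bits of the first sample, byte 2 holds the high
#' nibble of the second sample (bits 4--7) and the high nibble of the first
#' (bits 0--3), and byte 3 holds the low 8 bits of the second sample.
#'
#' @param samples integer vector of ADC values in `[-2048, 2047]`. An
#'   odd-length input is padded with one zero sample; the pad is recorded in
#'   the `"padded"` attribute of the result.
#' @return a raw vector, 3 bytes per sample pair, with attribute `padded`
#'   (TRUE if a zero pad sample was appended).
#' @seealso [unpack_format212()]
#' @export
pack_format212 <- function(samples) {
  samples <- as.integer(round(samples))
  bad <- which(samples < -2048L | samples > 2047L)
  if (length(bad))
    stop("range error: sample ", bad[1], " (value ", samples[bad[1]],
         ") outside the 12-bit range [-2048, 2047]")
  padded <- length(samples) %% 2L == 1L
  if (padded) samples <- c(samples, 0L)
  u <- bitwAnd(samples, 0xFFFL)          # 12-bit two's complement
  s1 <- u[seq(1L, length(u), by = 2L)]
  s2 <- u[seq(2L, length(u), by = 2L)]
  bytes <- integer(3L * length(s1))
  bytes[seq(1L, length(bytes), by = 3L)] <- bitwAnd(s1, 0xFFL)
  bytes[seq(2L, length(bytes), by = 3L)] <-
    bitwOr(bitwShiftL(bitwShiftR(s2, 8L), 4L), bitwShiftR(s1, 8L))
  bytes[seq(3L, length(bytes), by = 3L)] <- bitwAnd(s2, 0xFFL)
  out <- as.raw(bytes)
  attr(out, "padded") <- padded
  out
}

#' Unpack MIT-BIH Format 212 bytes into integer samples
#'
#' Inverse of [pack_format212()]; 12-bit values are sign-extended.
#'
#' @param bytes raw vector.
#' @param n_samples number of samples to decode (a trailing pad sample from an
#'   odd-length pack is dropped by passing the true count).
#' @return integer vector of length `n_samples`.
#' @export
unpack_format212 <- function(bytes, n_samples) {
  n_samples <- as.integer(n_samples)
  need <- 3L * ceiling(n_samples / 2)
  if (length(bytes) < need)
    stop("parse error: need ", need, " bytes for ", n_samples,
         " samples, got ", length(bytes))
  b <- as.integer(bytes[seq_len(need)])
  b1 <- b[seq(1L, need, by = 3L)]
  b2 <- b[seq(2L, need, by = 3L)]
  b3 <- b[seq(3L, need, by = 3L)]
  s1 <- bitwOr(b1, bitwShiftL(bitwAnd(b2, 0x0FL), 8L))
  s2 <- bitwOr(b3, bitwShiftL(bitwShiftR(b2, 4L), 8L))
  out <- integer(2L * length(s1))
  out[seq(1L, length(out), by = 2L)] <- s1
  out[seq(2L, length(out), by = 2L)] <- s2
  out <- out[seq_len(n_samples)]
  ifelse(out >= 2048L, out - 4096L, out)  # sign-extend
}

# ---- WFDB-style reader/writer ---------------------------------------------

#' Read an ECG record from a WFDB-style header + Format 212 signal file
#'
#' The header dialect is minimal WFDB: line 1 is
#' `record_id n_leads fs n_samples`; each subsequent non-comment line is
#' `filename format gain baseline lead_name`. Only format 212 is supported.
#' Samples are interleaved across leads and converted to mV as
#' `(adc - baseline) / gain`.
#'
#' @param header_path path to the text header.
#' @param data_path path to the binary signal file; defaults to the filename
#'   named in the header, resolved relative to the header's directory.
#' @return an `ecg_record`.
#' @export
read_ecg <- function(header_path, data_path = NULL) {
  lines <- readLines(header_path, warn = FALSE)
  lines <- trimws(lines[!grepl("^\\s*(#|$)", lines)])
  top <- strsplit(lines[1], "\\s+")[[1]]
  if (length(top) < 4) stop("parse error: malformed header line: ", lines[1])
  record_id <- top[1]
  n_leads <- as.integer(top[2])
  fs <- as.numeric(top[3])
  n_samples <- as.integer(top[4])
  if (!is.finite(fs) || fs <= 0)
    stop("validation error: header declares fs = ", top[3])
  if (length(lines) < 1 + n_leads)
    stop("parse error: header declares ", n_leads, " leads but has ",
         length(lines) - 1, " signal lines")
  lead_rows <- lapply(lines[1 + seq_len(n_leads)],
                      function(l) strsplit(l, "\\s+")[[1]])
  fmt <- vapply(lead_rows, `[`, "", 2)
  if (any(fmt != "212"))
    stop("unsupported-format error: format code(s) ",
         paste(unique(fmt[fmt != "212"]), collapse = ", "),
         " (only 212 is supported)")
  gain <- vapply(lead_rows, function(r) as.numeric(r[3]), 0)
  baseline <- vapply(lead_rows, function(r) as.numeric(r[4]), 0)
  gain[!is.finite(gain) | gain == 0] <- 200     # MIT-BIH default
  baseline[!is.finite(baseline)] <- 0
  lead_names <- vapply(lead_rows, `[`, "", 5)
  if (is.null(data_path))
    data_path <- file.path(dirname(header_path), lead_rows[[1]][1])
  total <- n_samples * n_leads
  bytes <- readBin(data_path, "raw", n = file.size(data_path))
  if (length(bytes) < 3L * ceiling(total / 2))
    stop("parse error: data file holds ", length(bytes),
         " bytes, header implies at least ", 3L * ceiling(total / 2))
  adc <- unpack_format212(bytes, total)
  adc <- matrix(adc, ncol = n_leads, byrow = TRUE)   # sample-interleaved
  mv <- sweep(sweep(adc, 2, baseline, "-"), 2, gain, "/")
  ecg_record(mv, fs = fs, lead_names = lead_names, record_id = record_id,
             gain = gain, baseline_adc = baseline)
}

#' Write an ECG record as WFDB-style header + Format 212 signal file
#'
#' mV amplitudes are quantized to the nearest ADC step at the record's
#' declared gain; the files round-trip through [read_ecg()] to within half an
#' ADC step per sample.
#'
#' @param rec an `ecg_record`.
#' @param header_path,data_path output paths.
#' @return invisibly, the paths written.
#' @export
write_ecg <- function(rec, header_path, data_path = NULL) {
  validate_ecg_record(rec)
  if (is.null(data_path))
    data_path <- sub("\\.hea$", ".dat", header_path)
  if (identical(data_path, header_path))
    stop("validation error: header and data paths coincide")
  adc <- round(sweep(sweep(rec$signal, 2, rec$gain, "*"),
                     2, rec$baseline_adc, "+"))
  if (any(adc < -2048 | adc > 2047)) {
    worst <- max(abs(adc))
    stop("range error: ADC value ", worst, " exceeds the 12-bit range; ",
         "reduce the gain (currently ", paste(rec$gain, collapse = "/"),
         " ADC/mV) so that all amplitudes fit in [-2048, 2047]")
  }
  interleaved <- as.integer(t(adc))
  writeBin(as.raw(pack_format212(interleaved)), data_path)
  hdr <- c(sprintf("%s %d %g %d", rec$record_id, ncol(rec$signal), rec$fs,
                   nrow(rec$signal)),
           sprintf("%s 212 %g %g %s", basename(data_path), rec$gain,
                   rec$baseline_adc, rec$lead_names))
  writeLines(hdr, header_path)
  invisible(c(header = header_path, data = data_path))
}

# ---- CSV fallback ----------------------------------------------------------

#' Read an ECG record from a CSV signal matrix
#'
#' One column per lead with a header row of lead names; values in mV. The
#' sampling frequency is not stored in the CSV and must be supplied.
#'
#' @param path CSV path.
#' @param fs sampling frequency in Hz.
#' @param record_id identifier (defaults to the file stem).
#' @inheritParams ecg_record
#' @return an `ecg_record`.
#' @export
read_ecg_csv <- function(path, fs, record_id = NULL, gain = 200,
                         baseline_adc = 0) {
  if (is.null(record_id))
    record_id <- sub("\\.[^.]*$", "", basename(path))
  df <- utils::read.csv(path, check.names = FALSE)
  ecg_record(as.matrix(df), fs = fs, lead_names = names(df),
             record_id = record_id, gain = gain, baseline_adc = baseline_adc)
}

#' Write an ECG record as a CSV signal matrix
#' @param rec an `ecg_record`.
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_ecg_csv <- function(rec, path) {
  validate_ecg_record(rec)
  utils::write.csv(as.data.frame(rec$signal), path, row.names = FALSE)
  invisible(path)
}

# ---- Potassium labels ------------------------------------------------------

#' Read a serum-potassium label table
#'
#' Delimited text with columns `record_id`, `k_mmol_per_l` and `phase`
#' (`pre_dialysis`, `post_dialysis` or `synthetic`). Potassium values must
#' lie in the physiologically plausible range 1--10 mmol/L, and the
#' (`record_id`, `phase`) pair must be unique.
#'
#' @param path CSV path.
#' @return a data.frame of validated labels.
#' @export
read_potassium_labels <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("record_id", "k_mmol_per_l", "phase")
  if (!all(need %in% names(df)))
    stop("validation error: label table must have columns ",
         paste(need, collapse = ", "))
  df$k_mmol_per_l <- as.numeric(df$k_mmol_per_l)
  bad <- which(!is.finite(df$k_mmol_per_l) |
                 df$k_mmol_per_l < 1 | df$k_mmol_per_l > 10)
  if (length(bad))
    stop("validation error: potassium value out of [1, 10] mmol/L in row ",
         bad[1], " (", df$k_mmol_per_l[bad[1]], ")")
  phases <- c("pre_dialysis", "post_dialysis", "synthetic")
  if (!all(df$phase %in% phases))
    stop("validation error: phase must be one of ",
         paste(phases, collapse = ", "))
  if (anyDuplicated(df[c("record_id", "phase")]))
    stop("validation error: duplicated (record_id, phase) key")
  df
}
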
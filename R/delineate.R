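#' Canonical names of the 48 morphological features
#'
#' Twelve features per chest lead, lead-major over V2--V5. Per lead the order
#' is: the three slope-class features (T right slope, T left slope, ST-segment
#' slope, mV/s), the three amplitude-class features (T, R, S amplitude
#' relative to the isoelectric level, mV, signed), the three area-class
#' features (T, R, S wave area, mV.s, non-negative), and the three
#' rate-normalized areas (area divided by the preceding RR interval).
#'
#' @return character vector of length 48.
#' @export
feature_names <- function() {
  base <- c("t_right_slope", "t_left_slope", "st_slope",
            "t_amp", "r_amp", "s_amp",
            "t_area", "r_area", "s_area",
            "t_area_per_s", "r_area_per_s", "s_area_per_s")
  as.vector(vapply(ANALYSIS_LEADS, function(ld) paste(ld, base, sep = "_"),
                   character(12)))
}

ANALYSIS_LEADS <- c("V2", "V3", "V4", "V5")

#' Detect R peaks in a preprocessed ECG lead
#'
#' Local maxima above an adaptive amplitude threshold (half the median of
#' per-2-second block maxima, so detection is invariant to global amplitude
#' scaling), with a 0.2 s refractory period that keeps the taller of two
#' competing peaks.
#'
#' @param x numeric series in mV (preprocessed, positive R deflection).
#' @param fs sampling frequency in Hz.
#' @return integer vector of R-peak sample indices, ascending.
#' @export
detect_r_peaks <- function(x, fs) {
  n <- length(x)
  if (n / fs < 2)
    stop("validation error: need at least 2 s of signal")
  is_max <- which(diff(sign(diff(x))) < 0) + 1L
  block <- round(2 * fs)
  block_max <- tapply(x, (seq_len(n) - 1L) %/% block, max)
  thr <- 0.5 * stats::median(block_max)
  cand <- is_max[x[is_max] > thr & x[is_max] > 0]
  if (length(cand) >= 2) {
    # refractory: greedy from tallest peak downward
    keep <- logical(length(cand))
    ord <- order(x[cand], decreasing = TRUE)
    taken <- integer(0)
    refr <- round(0.2 * fs)
    for (i in ord) {
      if (!length(taken) || all(abs(cand[i] - taken) > refr)) {
        keep[i] <- TRUE
        taken <- c(taken, cand[i])
      }
    }
    cand <- sort(cand[keep])
  }
  if (length(cand) < 2)
    stop("delineation error: fewer than 2 beats detected")
  cand
}

# Smoothed first derivative in mV per sample (5-point moving average).
smoothed_slope <- function(x) {
  d <- c(diff(x), 0)
  v <- as.numeric(stats::filter(d, rep(1 / 5, 5), sides = 2))
  na <- is.na(v)
  v[na] <- d[na]
  v
}

# Find the edge of QRS activity: scan away from the R peak for the first
# sustained run (>= 8 ms) where |slope| stays below frac * max |slope|.
quiet_edge <- function(slope, from, to, frac_thr, run_len) {
  dir <- if (to >= from) 1L else -1L
  idx <- seq(from, to, by = dir)
  quiet <- abs(slope[idx]) < frac_thr
  run <- 0L
  for (j in seq_along(idx)) {
    run <- if (quiet[j]) run + 1L else 0L
    if (run >= run_len) return(idx[j - run_len + 1L])
  }
  idx[length(idx)]  # no quiet run: fall back to the window edge
}

#' Delineate one beat
#'
#' Locates the QRS onset and offset by a sustained slope-threshold search in
#' a 120 ms neighbourhood of the R peak, the S trough as the minimum within
#' 120 ms after R, the T peak as the largest absolute deviation from the
#' isoelectric level in the window from 60 ms after the J point to 60% of
#' the preceding RR interval, and the T onset/offset by intersecting the
#' tangent at the steepest flank with the isoelectric line. The isoelectric
#' level is the median of the 40 ms PR segment ending 20 ms before QRS onset.
#'
#' @param x numeric series in mV.
#' @param fs sampling frequency in Hz.
#' @param r_peak R-peak sample index.
#' @param rr_prev_s preceding RR interval in seconds (> 0.2).
#' @param min_t_amp smallest |T| deviation (mV) accepted as a present T wave.
#' @return an object of class `beat_fiducials`: sample indices `q_onset`,
#'   `r_peak`, `s_trough`, `s_offset`, `t_onset`, `t_peak`, `t_offset`, plus
#'   `rr_prev_s` and `iso_level_mv`. Throws a delineation error (condition
#'   class `hk_beat_skip`) when the beat cannot be delineated (window
#'   truncated by a record edge, absent T wave).
#' @export
delineate_beat <- function(x, fs, r_peak, rr_prev_s, min_t_amp = 0.05) {
  n <- length(x)
  if (rr_prev_s <= 0.2)
    stop("validation error: rr_prev_s must exceed the 0.2 s refractory")
  ms <- function(t) round(t * fs)
  w120 <- ms(0.120)
  t_end <- r_peak + ms(0.6 * rr_prev_s)
  if (r_peak - w120 - ms(0.060) < 1 || t_end > n)
    beat_skip("search window truncated by record edge")

  slope <- smoothed_slope(x)
  qrs_rng <- (r_peak - w120):(r_peak + w120)
  max_slope <- max(abs(slope[qrs_rng]))
  run8 <- max(2L, ms(0.008))
  q_onset <- quiet_edge(slope, r_peak - ms(0.004), r_peak - w120,
                        0.05 * max_slope, run8)
  s_offset <- quiet_edge(slope, r_peak + ms(0.004), r_peak + w120,
                         0.05 * max_slope, run8)
  s_trough <- r_peak + which.min(x[(r_peak + 1L):(r_peak + w120)])
  s_offset <- max(s_offset, s_trough)

  iso_to <- q_onset - ms(0.020)
  iso_from <- iso_to - ms(0.040)
  if (iso_from < 1) beat_skip("isoelectric segment truncated")
  iso <- stats::median(x[iso_from:iso_to])

  t_from <- s_offset + ms(0.060)
  if (t_from >= t_end) beat_skip("T-wave search window empty")
  dev <- x[t_from:t_end] - iso
  t_peak <- t_from + which.max(abs(dev)) - 1L
  if (abs(x[t_peak] - iso) < min_t_amp) beat_skip("absent T wave")

  t_onset <- tangent_crossing(x, slope, iso, t_peak, t_from, left = TRUE)
  t_offset <- tangent_crossing(x, slope, iso, t_peak, t_end, left = FALSE)
  t_onset <- max(t_onset, s_offset + 1L)
  t_offset <- min(t_offset, n)
  if (!(t_onset < t_peak && t_peak < t_offset))
    beat_skip("degenerate T-wave boundaries")

  structure(list(q_onset = q_onset, r_peak = r_peak, s_trough = s_trough,
                 s_offset = s_offset, t_onset = t_onset, t_peak = t_peak,
                 t_offset = t_offset, rr_prev_s = rr_prev_s,
                 iso_level_mv = iso),
            class = "beat_fiducials")
}

beat_skip <- function(msg) {
  stop(structure(class = c("hk_beat_skip", "error", "condition"),
                 list(message = paste("delineation:", msg), call = NULL)))
}

# Tangent-intersection wave boundary: take the steepest point of the flank
# between the peak and the window edge and extend its tangent to the
# isoelectric line.
tangent_crossing <- function(x, slope, iso, t_peak, edge, left) {
  seg <- if (left) edge:(t_peak - 1L) else (t_peak + 1L):edge
  if (length(seg) < 2) return(edge)
  m <- seg[which.max(abs(slope[seg]))]
  s <- slope[m]
  if (s == 0) return(edge)
  cross <- m + (iso - x[m]) / s
  cross <- as.integer(round(cross))
  if (left) max(edge, min(cross, t_peak - 1L))
  else min(edge, max(cross, t_peak + 1L))
}

trapz <- function(y, dt) if (length(y) < 2) 0 else
  dt * (sum(y) - (y[1] + y[length(y)]) / 2)

#' Compute the 12 morphological features of one beat on one lead
#'
#' Slopes are chord slopes between fiducials (ST slope is the OLS slope over
#' the J-point-to-T-onset segment); amplitudes are signed deviations from the
#' isoelectric level; areas are trapezoidal integrals of the absolute
#' deviation, with the QRS interval split into its positive (R) and negative
#' (S) lobes; per-second areas divide by the preceding RR interval.
#'
#' @param x numeric series in mV.
#' @param fs sampling frequency in Hz.
#' @param fid a `beat_fiducials` object.
#' @return named numeric vector of length 12 (order of [feature_names()]
#'   within a lead).
#' @export
compute_lead_features <- function(x, fs, fid) {
  iso <- fid$iso_level_mv
  sec <- function(i, j) (j - i) / fs
  if (fid$t_peak == fid$t_onset || fid$t_offset == fid$t_peak ||
      fid$t_onset <= fid$s_offset)
    stop("computation error: zero-duration T segment")
  t_left  <- (x[fid$t_peak] - x[fid$t_onset]) / sec(fid$t_onset, fid$t_peak)
  t_right <- (x[fid$t_offset] - x[fid$t_peak]) / sec(fid$t_peak, fid$t_offset)
  st_idx <- fid$s_offset:fid$t_onset
  st_t <- (st_idx - st_idx[1]) / fs
  st_slope <- if (length(st_idx) < 2) 0 else
    stats::cov(st_t, x[st_idx]) / stats::var(st_t)
  dt <- 1 / fs
  qrs <- x[fid$q_onset:fid$s_offset] - iso
  tw <- abs(x[fid$t_onset:fid$t_offset] - iso)
  t_area <- trapz(tw, dt)
  r_area <- trapz(pmax(qrs, 0), dt)
  s_area <- trapz(pmax(-qrs, 0), dt)
  c(t_right_slope = t_right, t_left_slope = t_left, st_slope = st_slope,
    t_amp = x[fid$t_peak] - iso, r_amp = x[fid$r_peak] - iso,
    s_amp = x[fid$s_trough] - iso,
    t_area = t_area, r_area = r_area, s_area = s_area,
    t_area_per_s = t_area / fid$rr_prev_s,
    r_area_per_s = r_area / fid$rr_prev_s,
    s_area_per_s = s_area / fid$rr_prev_s)
}

#' Extract the 48-value feature vector from a preprocessed record
#'
#' For each of the chest leads V2--V5, R peaks are detected, every usable
#' beat is delineated and its 12 features computed, and the per-feature
#' median across beats is taken (robust to a single mis-delineated beat).
#' Beats whose search windows are truncated by the record edges, or whose T
#' wave is absent, are skipped and counted.
#'
#' @param record a preprocessed `ecg_record` containing leads V2--V5.
#' @param min_t_amp passed to [delineate_beat()].
#' @return named numeric vector of length 48 in the canonical
#'   [feature_names()] order, with attribute `n_beats_used` (per lead).
#' @export
extract_feature_vector <- function(record, min_t_amp = 0.05) {
  validate_ecg_record(record)
  missing <- setdiff(ANALYSIS_LEADS, record$lead_names)
  if (length(missing))
    stop("validation error: record lacks required lead(s) ",
         paste(missing, collapse = ", "))
  fs <- record$fs
  used <- integer(length(ANALYSIS_LEADS))
  names(used) <- ANALYSIS_LEADS
  out <- numeric(0)
  for (ld in ANALYSIS_LEADS) {
    x <- record$signal[, ld]
    peaks <- detect_r_peaks(x, fs)
    rr <- diff(peaks) / fs
    rr_prev <- c(stats::median(rr), rr)
    feats <- list()
    for (b in seq_along(peaks)) {
      f <- tryCatch(
        compute_lead_features(x, fs,
          delineate_beat(x, fs, peaks[b], rr_prev[b], min_t_amp)),
        hk_beat_skip = function(e) NULL)
      if (!is.null(f)) feats[[length(feats) + 1L]] <- f
    }
    if (!length(feats))
      stop("delineation error: no usable beats on lead ", ld)
    used[ld] <- length(feats)
    m <- do.call(rbind, feats)
    out <- c(out, apply(m, 2, stats::median))
  }
  names(out) <- feature_names()
  if (!all(is.finite(out)))
    stop("computation error: non-finite feature value")
  attr(out, "n_beats_used") <- used
  out
}
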
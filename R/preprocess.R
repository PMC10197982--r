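#' Preprocessing configuration
#'
#' Parameters for the five-stage preprocessing cascade applied to each raw
#' record: (1) polynomial baseline correction over the full sweep,
#' (2) selection of the smoothest analysis window by linear fitting,
#' (3) a second polynomial baseline correction inside the window,
#' (4) wavelet denoising, (5) zero-phase band-pass filtering.
#'
#' @param poly_order_pass1 polynomial order for the full-length drift fit.
#' @param poly_order_pass2 polynomial order for the in-window drift fit.
#' @param window_s analysis window length in seconds.
#' @param stride_s stride between candidate window starts in seconds.
#' @param wavelet_name mother wavelet, one of `"db4"`, `"db6"`, `"sym4"`.
#' @param wavelet_level decomposition depth.
#' @param threshold_rule detail-coefficient thresholding rule; only
#'   `"universal_soft"` (soft thresholding at the universal threshold) is
#'   implemented.
#' @param band_low_hz,band_high_hz band-pass corner frequencies in Hz.
#' @param filter_order Butterworth order (applied forward and backward, so
#'   the effective attenuation is squared).
#' @param reference_lead lead on which the smoothest window is chosen; the
#'   same window is applied to all leads so beats stay time-aligned.
#' @return an object of class `preprocess_config`.
#' @export
preprocess_config <- function(poly_order_pass1 = 5, poly_order_pass2 = 3,
                              window_s = 10, stride_s = 0.5,
                              wavelet_name = "db6", wavelet_level = 6,
                              threshold_rule = "universal_soft",
                              band_low_hz = 0.5, band_high_hz = 40,
                              filter_order = 5, reference_lead = "V2") {
  cfg <- list(poly_order_pass1 = poly_order_pass1,
              poly_order_pass2 = poly_order_pass2,
              window_s = window_s, stride_s = stride_s,
              wavelet_name = wavelet_name, wavelet_level = wavelet_level,
              threshold_rule = threshold_rule,
              band_low_hz = band_low_hz, band_high_hz = band_high_hz,
              filter_order = filter_order, reference_lead = reference_lead)
  if (cfg$window_s <= 0) stop("validation error: window_s must be > 0")
  if (cfg$poly_order_pass1 < 0 || cfg$poly_order_pass2 < 0)
    stop("validation error: polynomial orders must be >= 0")
  if (!(cfg$band_low_hz > 0 && cfg$band_low_hz < cfg$band_high_hz))
    stop("validation error: need 0 < band_low_hz < band_high_hz")
  if (!identical(cfg$threshold_rule, "universal_soft"))
    stop("configuration error: unknown threshold rule ", cfg$threshold_rule)
  wavelet_filters(cfg$wavelet_name)  # errors early on unknown wavelet
  structure(cfg, class = "preprocess_config")
}

#' Remove baseline drift by polynomial fitting
#'
#' Fits a least-squares polynomial of the given order to the whole series
#' (time rescaled to \[-1, 1\] for conditioning) and subtracts the fitted
#' trend, intercept included, so slow drift and the mean level are removed
#' together.
#'
#' @param x numeric series in mV.
#' @param fs sampling frequency in Hz (kept for interface symmetry; the fit
#'   itself is scale-free).
#' @param order polynomial order (>= 0, < length(x)).
#' @return the detrended series, same length as `x`.
#' @export
correct_baseline_poly <- function(x, fs, order) {
  n <- length(x)
  if (order >= n)
    stop("validation error: polynomial order ", order,
         " >= signal length ", n)
  t <- seq(-1, 1, length.out = n)
  basis <- outer(t, 0:order, "^")
  fit <- stats::lm.fit(basis, x)
  drop(x - basis %*% fit$coefficients)
}

#' Select the smoothest window of a signal by linear fitting
#'
#' Every candidate window at the configured stride is scored by the
#' root-mean-square residual about an ordinary least-squares line fitted to
#' it; the window with the smallest score wins, ties broken by the earliest
#' start. The final possible start is always included as a candidate.
#'
#' @param x numeric series.
#' @param fs sampling frequency in Hz.
#' @param window_s window length in seconds.
#' @param stride_s stride between candidate starts in seconds.
#' @return a list with `start` (1-based sample index), `start_s` (seconds),
#'   `segment` (the selected samples) and `score` (the winning RMS residual).
#' @export
select_smoothest_window <- function(x, fs, window_s, stride_s = 0.5) {
  n <- length(x)
  w <- round(window_s * fs)
  if (n < w)
    stop("validation error: signal (", n / fs, " s) shorter than window (",
         window_s, " s)")
  stride <- max(1L, round(stride_s * fs))
  starts <- unique(c(seq(1L, n - w + 1L, by = stride), n - w + 1L))
  # vectorized per-window OLS residual RMS via prefix sums
  cy  <- c(0, cumsum(x))
  cy2 <- c(0, cumsum(x^2))
  ciy <- c(0, cumsum(seq_along(x) * x))
  t_sum <- w * (w - 1) / 2                 # sum of t = 0..w-1
  t_ss  <- (w - 1) * w * (2 * w - 1) / 6   # sum of t^2
  sxx <- t_ss - t_sum^2 / w
  sy  <- cy[starts + w] - cy[starts]
  sy2 <- cy2[starts + w] - cy2[starts]
  sty <- (ciy[starts + w] - ciy[starts]) - starts * sy   # sum (t * y)
  sxy <- sty - t_sum * sy / w
  b <- sxy / sxx
  rss <- pmax(0, (sy2 - sy^2 / w) - b^2 * sxx)
  score <- sqrt(rss / w)
  best <- which.min(score)                 # first minimum = earliest start
  s <- as.integer(starts[best])
  list(start = s, start_s = (s - 1) / fs,
       segment = x[s:(s + w - 1)], score = score[best])
}

# ---- Discrete wavelet transform (periodized, orthonormal) ------------------

# Orthonormal scaling filters (sum of squares = 1, sum = sqrt(2)).
WAVELET_DEC_LO <- list(
  db4 = c(-1.0597401785069032e-02, 3.2883011666885197e-02,
          3.0841381835560764e-02, -1.8703481171909309e-01,
          -2.7983769416859854e-02, 6.3088076792985892e-01,
          7.1484657055291567e-01, 2.3037781330889651e-01),
  db6 = c(-1.0773010853084796e-03, 4.7772575109455108e-03,
          5.5384220116149613e-04, -3.1582039317486030e-02,
          2.7522865530305727e-02, 9.7501605587323043e-02,
          -1.2976686756726194e-01, -2.2626469396543983e-01,
          3.1525035170919763e-01, 7.5113390802109536e-01,
          4.9462389039845306e-01, 1.1154074335010947e-01),
  sym4 = c(-7.5765714789273325e-02, -2.9635527645998510e-02,
           4.9761866763201545e-01, 8.0373875180591614e-01,
           2.9785779560527736e-01, -9.9219543576847216e-02,
           -1.2603967262037833e-02, 3.2223100604042702e-02))

wavelet_filters <- function(name) {
  h <- WAVELET_DEC_LO[[name]]
  if (is.null(h))
    stop("configuration error: unknown wavelet '", name, "' (available: ",
         paste(names(WAVELET_DEC_LO), collapse = ", "), ")")
  L <- length(h)
  g <- (-1)^(seq_len(L) - 1) * rev(h)      # quadrature mirror high-pass
  list(h = h, g = g, L = L)
}

# One analysis level of the periodized DWT; N must be even.
dwt_step <- function(x, f) {
  n <- length(x)
  k2 <- seq(0L, n - 2L, by = 2L)
  a <- numeric(n / 2)
  d <- numeric(n / 2)
  for (m in seq_len(f$L)) {
    xs <- x[((k2 + m - 1L) %% n) + 1L]
    a <- a + f$h[m] * xs
    d <- d + f$g[m] * xs
  }
  list(a = a, d = d)
}

# Inverse step: the transpose of the (orthogonal) analysis operator.
idwt_step <- function(a, d, f) {
  n <- 2L * length(a)
  k2 <- seq(0L, n - 2L, by = 2L)
  x <- numeric(n)
  for (m in seq_len(f$L)) {
    idx <- ((k2 + m - 1L) %% n) + 1L
    contrib <- f$h[m] * a + f$g[m] * d
    # scatter-add; idx has no duplicates within one m (stride-2 shifts)
    x[idx] <- x[idx] + contrib
  }
  x
}

#' Multilevel periodized discrete wavelet transform
#'
#' The signal is extended at the tail by symmetric reflection to the next
#' multiple of `2^level`, then decomposed with an orthonormal periodized
#' filter bank. The inverse transform reconstructs exactly (to floating
#' point) and trims back to the original length.
#'
#' @param x numeric series.
#' @param wavelet one of `"db4"`, `"db6"`, `"sym4"`.
#' @param level decomposition depth; requires `length(x) >= 2^level`.
#' @return a list with the approximation `a`, details `d` (list, level 1
#'   first), the original length `n`, `wavelet` and `level`.
#' @export
ecg_dwt <- function(x, wavelet = "db6", level = 6) {
  f <- wavelet_filters(wavelet)
  n <- length(x)
  if (n < 2^level)
    stop("validation error: need length >= 2^level = ", 2^level,
         ", got ", n)
  block <- 2^level
  n_pad <- ceiling(n / block) * block
  if (n_pad > n) {
    extra <- n_pad - n
    refl <- x[seq(n, by = -1L, length.out = min(extra, n))]
    x <- c(x, rep_len(refl, extra))
  }
  d <- vector("list", level)
  a <- x
  for (l in seq_len(level)) {
    st <- dwt_step(a, f)
    a <- st$a
    d[[l]] <- st$d
  }
  list(a = a, d = d, n = n, wavelet = wavelet, level = level)
}

#' Inverse of [ecg_dwt()]
#' @param w a decomposition as returned by [ecg_dwt()].
#' @return the reconstructed series, trimmed to the original length.
#' @export
ecg_idwt <- function(w) {
  f <- wavelet_filters(w$wavelet)
  a <- w$a
  for (l in rev(seq_len(w$level))) a <- idwt_step(a, w$d[[l]], f)
  a[seq_len(w$n)]
}

#' Wavelet denoising with the universal soft threshold
#'
#' Multilevel DWT, soft thresholding of all detail coefficients at the
#' universal threshold `sigma * sqrt(2 log N)`, where the noise scale
#' `sigma` is the robust estimate `median(|d1|) / 0.6745` from the
#' finest-level details, then reconstruction.
#'
#' @param x numeric series in mV.
#' @param config a [preprocess_config()] (fields `wavelet_name`,
#'   `wavelet_level` are used), or NULL for defaults.
#' @return the denoised series, same length as `x`.
#' @export
wavelet_denoise <- function(x, config = NULL) {
  if (is.null(config)) config <- preprocess_config()
  w <- ecg_dwt(x, config$wavelet_name, config$wavelet_level)
  sigma <- stats::median(abs(w$d[[1]])) / 0.6745
  thr <- sigma * sqrt(2 * log(length(x)))
  w$d <- lapply(w$d, function(d) sign(d) * pmax(abs(d) - thr, 0))
  ecg_idwt(w)
}

#' Zero-phase Butterworth band-pass filter
#'
#' Forward-backward application (via [signal::filtfilt()]) of a Butterworth
#' band-pass, so the net filter has zero group delay: a symmetric pulse does
#' not shift.
#'
#' @param x numeric series.
#' @param fs sampling frequency in Hz.
#' @param config a [preprocess_config()] (fields `band_low_hz`,
#'   `band_high_hz`, `filter_order`), or NULL for defaults.
#' @return the filtered series, same length as `x`.
#' @export
bandpass_filter <- function(x, fs, config = NULL) {
  if (is.null(config)) config <- preprocess_config()
  if (config$band_high_hz >= fs / 2)
    stop("validation error: band_high_hz (", config$band_high_hz,
         ") must be below the Nyquist frequency ", fs / 2)
  bf <- signal::butter(config$filter_order,
                       c(config$band_low_hz, config$band_high_hz) / (fs / 2),
                       type = "pass")
  signal::filtfilt(bf, x)
}

#' Preprocess an ECG record for feature extraction
#'
#' Runs the full cascade. The smoothest window is chosen once, on the
#' reference lead (after its first-pass baseline correction), and the same
#' window is applied to all leads so that beats remain time-aligned across
#' the chest leads.
#'
#' @param rec an `ecg_record` of duration at least `window_s`.
#' @param config a [preprocess_config()].
#' @param leads optional character vector restricting which leads are
#'   processed and returned (default: all leads in the record).
#' @return an `ecg_record` of duration `window_s`, with attributes
#'   `window_start_s` (chosen window start in seconds of the input record)
#'   and `window_score` (the winning smoothness score).
#' @export
preprocess_record <- function(rec, config = NULL, leads = NULL) {
  validate_ecg_record(rec)
  if (is.null(config)) config <- preprocess_config()
  if (is.null(leads)) leads <- rec$lead_names
  missing <- setdiff(leads, rec$lead_names)
  if (length(missing))
    stop("validation error: record lacks lead(s) ",
         paste(missing, collapse = ", "))
  fs <- rec$fs
  n <- nrow(rec$signal)
  if (n / fs < config$window_s)
    stop("validation error: record shorter than the analysis window")
  ref <- if (config$reference_lead %in% leads) config$reference_lead
         else leads[1]

  pass1 <- vapply(leads, function(ld)
    correct_baseline_poly(rec$signal[, ld], fs, config$poly_order_pass1),
    numeric(n))
  win <- select_smoothest_window(pass1[, ref], fs, config$window_s,
                                 config$stride_s)
  idx <- win$start:(win$start + round(config$window_s * fs) - 1L)
  out <- vapply(leads, function(ld) {
    seg <- correct_baseline_poly(pass1[idx, ld], fs, config$poly_order_pass2)
    seg <- wavelet_denoise(seg, config)
    bandpass_filter(seg, fs, config)
  }, numeric(length(idx)))

  res <- ecg_record(out, fs = fs, lead_names = leads,
                    record_id = rec$record_id,
                    gain = rec$gain[match(leads, rec$lead_names)],
                    baseline_adc = rep(0, length(leads)))
  attr(res, "window_start_s") <- win$start_s
  attr(res, "window_score") <- win$score
  res
}
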
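test_that("R-peak detection finds every beat at the true times", {
  tpl <- beat_template(heart_rate_bpm = 60)
  rec <- generate_record(4.0, template = tpl, noise = noise_model_none(),
                         duration_s = 10, seed = 4)
  truth <- attr(rec, "truth")
  x <- ecg_lead(rec, "V2")
  p <- detect_r_peaks(x, rec$fs)
  expect_identical(length(p), length(truth$r_times))
  err_ms <- 1000 * abs((p - 1) / rec$fs - truth$r_times)
  expect_lt(max(err_ms), 10)
  # invariant to global amplitude scaling
  expect_identical(detect_r_peaks(0.5 * x, rec$fs), p)
  expect_identical(detect_r_peaks(2 * x, rec$fs), p)
  expect_error(detect_r_peaks(rep(0, 5000), 500), "delineation error")
})

test_that("fiducials land within 15 ms of their analytic locations", {
  rec <- clean_record()
  truth <- attr(rec, "truth")
  tpl <- truth$template
  fs <- rec$fs
  x <- ecg_lead(rec, "V2")
  p <- detect_r_peaks(x, fs)
  fid <- delineate_beat(x, fs, p[5], truth$rr_s)
  # analytic: Gaussian tangent-intersection boundaries lie at center +/- 2b
  analytic <- c(q_onset = tpl$center[["Q"]] - 2 * tpl$width[["Q"]],
                s_trough = tpl$center[["S"]],
                s_offset = tpl$center[["S"]] + 2 * tpl$width[["S"]],
                t_onset = tpl$center[["T"]] - 2 * tpl$width[["T"]],
                t_peak = tpl$center[["T"]],
                t_offset = tpl$center[["T"]] + 2 * tpl$width[["T"]])
  got <- (c(fid$q_onset, fid$s_trough, fid$s_offset, fid$t_onset,
            fid$t_peak, fid$t_offset) - 1) / fs - truth$r_times[5]
  expect_lt(max(abs(got - analytic)) * 1000, 15)
})

test_that("a beat with an absent T wave is skipped, not fabricated", {
  tpl <- beat_template(amp = c(P = 0.12, Q = -0.12, R = 1.2, S = -0.3,
                               T = 0.0001))
  rec <- generate_record(4.0, template = tpl,
                         effect = k_effect_model(t_amp_gain = 0),
                         noise = noise_model_none(), duration_s = 10,
                         seed = 2)
  x <- ecg_lead(rec, "V2")
  p <- detect_r_peaks(x, rec$fs)
  expect_error(delineate_beat(x, rec$fs, p[3], 60 / 70),
               class = "hk_beat_skip")
  expect_error(extract_feature_vector(rec), "delineation error")
})

test_that("fiducial ordering holds across random synthetic beats", {
  set.seed(10)
  count <- 0
  for (i in 1:20) {
    k <- stats::runif(1, 3, 7.5)
    rec <- generate_record(k, noise = noise_model(
      baseline_wander_amp_mv = 0, powerline_amp_mv = 0,
      white_noise_sigma_mv = 0.02), seed = 100 + i, duration_s = 10)
    x <- ecg_lead(rec, "V2")
    pp <- preprocess_record(rec, leads = "V2",
                            config = preprocess_config(window_s = 8))
    xs <- pp$signal[, 1]
    p <- detect_r_peaks(xs, rec$fs)
    rr <- c(stats::median(diff(p)), diff(p)) / rec$fs
    for (b in seq_along(p)) {
      fid <- tryCatch(delineate_beat(xs, rec$fs, p[b], rr[b]),
                      hk_beat_skip = function(e) NULL)
      if (is.null(fid)) next
      count <- count + 1
      expect_true(fid$q_onset < fid$r_peak,
                  label = paste("q<r, rec", i, "beat", b))
      expect_true(fid$r_peak < fid$s_trough)
      expect_true(fid$s_trough <= fid$s_offset)
      expect_true(fid$s_offset < fid$t_onset)
      expect_true(fid$t_onset < fid$t_peak)
      expect_true(fid$t_peak < fid$t_offset)
      expect_gt(fid$rr_prev_s, 0.2)
    }
  }
  expect_gt(count, 100)   # the sweep actually exercised many beats
})

test_that("lead features have their textbook closed forms", {
  # isoceles triangular T wave: peak 0.5 mV, base 0.2 s, on a flat baseline
  fs <- 1000
  n <- 1200
  x <- rep(0, n)
  t_on <- 700L; t_pk <- 800L; t_off <- 900L
  x[t_on:t_pk] <- seq(0, 0.5, length.out = 101)
  x[t_pk:t_off] <- seq(0.5, 0, length.out = 101)
  # small QRS so the fiducials are self-consistent
  x[195:205] <- c(seq(0, 1, length.out = 6)[-6], seq(1, 0, length.out = 6)) * 1
  fid <- structure(list(q_onset = 190L, r_peak = 200L, s_trough = 206L,
                        s_offset = 210L, t_onset = t_on, t_peak = t_pk,
                        t_offset = t_off, rr_prev_s = 1.0,
                        iso_level_mv = 0),
                   class = "beat_fiducials")
  f <- compute_lead_features(x, fs, fid)
  expect_equal(unname(f["t_left_slope"]), 5.0, tolerance = 0.01)
  expect_equal(unname(f["t_right_slope"]), -5.0, tolerance = 0.01)
  expect_equal(unname(f["t_area"]), 0.05, tolerance = 0.01)
  expect_equal(unname(f["t_amp"]), 0.5)
  expect_equal(unname(f["r_amp"]), 1.0)
  # rr_prev = 1 makes every per-second area equal its area
  expect_equal(unname(f["t_area_per_s"]), unname(f["t_area"]))
  expect_equal(unname(f["r_area_per_s"]), unname(f["r_area"]))
  expect_equal(unname(f["s_area_per_s"]), unname(f["s_area"]))
})

test_that("a Gaussian T wave integrates to its analytic area", {
  rec <- clean_record()
  truth <- attr(rec, "truth")
  fv <- extract_feature_vector(rec)
  a <- truth$template$amp[["T"]] * truth$lead_scales[["V2"]]
  b <- truth$template$width[["T"]]
  expect_lt(abs(fv[["V2_t_area"]] - a * b * sqrt(2 * pi)) /
              (a * b * sqrt(2 * pi)), 0.05)
})

test_that("feature extraction returns 48 named finite values", {
  fv <- extract_feature_vector(clean_record())
  expect_length(fv, 48)
  expect_identical(names(fv), feature_names())
  expect_true(all(is.finite(fv)))
  # all 12 features appear for each of V2-V5
  expect_identical(sum(startsWith(names(fv), "V2_")), 12L)
  bad <- clean_record()
  bad$signal <- bad$signal[, c("V2", "V3", "V4")]
  bad$lead_names <- c("V2", "V3", "V4")
  bad$gain <- bad$gain[1:3]; bad$baseline_adc <- bad$baseline_adc[1:3]
  expect_error(extract_feature_vector(bad), "V5")
})

test_that("all features are homogeneous of degree 1 in amplitude", {
  rec <- clean_record()
  fv1 <- extract_feature_vector(rec)
  rec2 <- rec
  rec2$signal <- rec2$signal * 2
  fv2 <- extract_feature_vector(rec2)
  expect_true(all(abs(fv2 - 2 * fv1) <= 0.01 * pmax(abs(2 * fv1), 1e-9)))
})

test_that("extracted T amplitude is strictly monotone in true amplitude", {
  amps <- seq(0.25, 0.65, length.out = 6)
  got <- vapply(seq_along(amps), function(i) {
    tpl <- beat_template(amp = c(P = 0.12, Q = -0.12, R = 1.2, S = -0.3,
                                 T = amps[i]))
    rec <- generate_record(4.0, template = tpl,
                           noise = noise_model_none(), duration_s = 12,
                           seed = 50)
    extract_feature_vector(rec)[["V2_t_amp"]]
  }, 0)
  expect_identical(order(got), seq_along(amps))
  expect_equal(stats::cor(got, amps, method = "spearman"), 1)
})
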
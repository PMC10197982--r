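test_that("the potassium effect model is anchored and monotone", {
  base <- beat_template()
  eff <- k_effect_model()
  expect_identical(k_to_template(eff$k_ref, base, eff), base)
  grid <- seq(4.0, 7.5, by = 0.5)
  a_t <- vapply(grid, function(k) k_to_template(k, base, eff)$amp[["T"]], 0)
  b_t <- vapply(grid, function(k) k_to_template(k, base, eff)$width[["T"]], 0)
  expect_true(all(diff(a_t) > 0))          # strictly increasing
  expect_true(all(diff(b_t) < 0))          # T base narrows
  expect_gt(k_to_template(6.5, base, eff)$amp[["T"]],
            k_to_template(5.5, base, eff)$amp[["T"]])
  expect_gt(k_to_template(5.5, base, eff)$amp[["T"]],
            k_to_template(5.0, base, eff)$amp[["T"]])
  # P/PR/QRS effects engage only above the activation point
  t54 <- k_to_template(5.4, base, eff)
  expect_identical(t54$amp[["P"]], base$amp[["P"]])
  t70 <- k_to_template(7.0, base, eff)
  expect_lt(t70$amp[["P"]], base$amp[["P"]])
  expect_lt(t70$center[["P"]], base$center[["P"]])   # PR prolongs
  expect_gt(t70$width[["R"]], base$width[["R"]])     # QRS widens
  expect_error(k_to_template(0.5, base, eff), "\\[1, 10\\]")
})

test_that("record generation is deterministic and validates its config", {
  r1 <- generate_record(5.2, seed = 9)
  r2 <- generate_record(5.2, seed = 9)
  expect_identical(r1$signal, r2$signal)
  r3 <- generate_record(5.2, seed = 10)
  expect_false(identical(r1$signal, r3$signal))
  expect_error(generate_record(5.2, fs = 100), "configuration error")
  validate_ecg_record(r1)
  expect_identical(dim(r1$signal), c(15000L, 12L))
})

test_that("noise-free records give back the generator's own truth", {
  rec <- generate_record(4.0, noise = noise_model_none(), seed = 3,
                         duration_s = 15)
  truth <- attr(rec, "truth")
  fv <- extract_feature_vector(rec)
  a_true <- truth$template$amp[["T"]] * truth$lead_scales[["V2"]]
  expect_lt(abs(fv[["V2_t_amp"]] - a_true) / a_true, 0.05)
  x <- ecg_lead(rec, "V2")
  p <- detect_r_peaks(x, rec$fs)
  rr_est <- stats::median(diff(p)) / rec$fs
  expect_lt(abs(rr_est - 60 / truth$heart_rate_bpm) /
              (60 / truth$heart_rate_bpm), 0.01)
})

test_that("high potassium tents the T wave in paired records", {
  nm <- noise_model_none()
  lo <- generate_record(4.0, noise = nm, seed = 77, duration_s = 12)
  hi <- generate_record(6.5, noise = nm, seed = 77, duration_s = 12)
  f_lo <- extract_feature_vector(lo)
  f_hi <- extract_feature_vector(hi)
  expect_gt(f_hi[["V2_t_amp"]], f_lo[["V2_t_amp"]])
  # T base = area / amplitude is proportional to width for a Gaussian
  expect_lt(f_hi[["V2_t_area"]] / f_hi[["V2_t_amp"]],
            f_lo[["V2_t_area"]] / f_lo[["V2_t_amp"]])
})

test_that("the potassium label distribution matches the study population", {
  cfg <- synthetic_config(n_records = 1024, seed = 11)
  k <- draw_k_values(cfg)
  expect_length(k, 1024)
  expect_true(all(k >= 2.5 & k <= 8.0))
  expect_lt(abs(mean(k) - 4.83), 0.1)
  expect_lt(abs(stats::sd(k) - 1.01), 0.1)
  # tail fraction vs the closed-form truncated-normal probability
  p_tail <- function(thr) {
    lo <- stats::pnorm(2.5, 4.83, 1.01); hi <- stats::pnorm(8.0, 4.83, 1.01)
    (hi - stats::pnorm(thr, 4.83, 1.01)) / (hi - lo)
  }
  expect_lt(abs(mean(k >= 5.0) - p_tail(5.0)), 0.04)
  expect_lt(abs(mean(k >= 6.5) - p_tail(6.5)), 0.04)
  # determinism and the n = 1 edge case
  expect_identical(k, draw_k_values(cfg))
  one <- generate_dataset(synthetic_config(n_records = 1, seed = 2),
                          leads = c("V2", "V3", "V4", "V5"))
  expect_length(one$records, 1)
  expect_identical(nrow(one$labels), 1L)
  validate_ecg_record(one$records[[1]])
})

test_that("generated datasets stay within record invariants", {
  ds <- generate_dataset(synthetic_config(n_records = 3, duration_s = 8,
                                          seed = 5),
                         leads = c("V2", "V3", "V4", "V5"))
  for (r in ds$records) validate_ecg_record(r)
  expect_identical(ds$labels$record_id,
                   vapply(ds$records, `[[`, "", "record_id"))
  expect_true(all(ds$labels$phase == "synthetic"))
})

test_that("feature-based simulation streams and drops cleanly", {
  ds <- simulate_feature_dataset(
    synthetic_config(n_records = 6, duration_s = 15, seed = 4),
    noise = noise_model(effect_jitter_sd = 0.2))
  expect_identical(ncol(ds$features), 48L)
  expect_identical(colnames(ds$features), feature_names())
  expect_true(all(is.finite(ds$features)))
  expect_identical(nrow(ds$features) + ds$n_dropped, 6L)
})

test_that("datasets round-trip to disk with a usable truth manifest", {
  ds <- generate_dataset(synthetic_config(n_records = 2, duration_s = 8,
                                          seed = 6),
                         leads = c("V2", "V3", "V4", "V5"))
  dir <- withr::local_tempdir()
  write_dataset(ds, dir, format = "wfdb")
  expect_true(file.exists(file.path(dir, "labels.csv")))
  back <- read_ecg(file.path(dir, "syn0001.hea"))
  expect_lt(max(abs(back$signal - ds$records[[1]]$signal)), 1 / 400 + 1e-12)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(truth$syn0001$k_mmol_per_l, ds$labels$k_mmol_per_l[1],
               tolerance = 1e-12)
  labs <- read_potassium_labels(file.path(dir, "labels.csv"))
  expect_identical(nrow(labs), 2L)
})

test_that("preprocessing improves T-amplitude recovery under default noise", {
  recover_err <- function(preprocess) {
    vapply(1:15, function(i) {
      rec <- generate_record(4.5 + 0.2 * i %% 3, noise = noise_model(),
                             seed = 400 + i, duration_s = 20)
      truth <- attr(rec, "truth")
      r <- if (preprocess)
        preprocess_record(rec, leads = c("V2", "V3", "V4", "V5"))
      else rec
      fv <- extract_feature_vector(r)
      abs(fv[["V2_t_amp"]] -
            truth$template$amp[["T"]] * truth$lead_scales[["V2"]])
    }, 0)
  }
  expect_lt(stats::median(recover_err(TRUE)),
            stats::median(recover_err(FALSE)))
})
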
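# Run code with a private RNG stream, restoring the caller's state.
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

#' Baseline beat template (Gaussian-sum morphology)
#'
#' One heartbeat is modelled as a sum of five Gaussian waves (P, Q, R, S, T),
#' each with an amplitude (mV), a center relative to the R peak (s) and a
#' width (s) -- the classic ECGSYN-style morphology without the dynamical
#' system, which gives analytic ground truth for every fiducial and area.
#' Chest leads V2--V5 carry per-lead amplitude scalings; the remaining eight
#' leads are filled with a uniformly scaled copy.
#'
#' @param amp,center,width named numeric vectors over P, Q, R, S, T.
#' @param heart_rate_bpm mean heart rate.
#' @param lead_scale named scaling for V2--V5.
#' @param other_lead_scale scaling for the remaining leads.
#' @return an object of class `beat_template`.
#' @export
beat_template <- function(
    amp    = c(P = 0.12, Q = -0.12, R = 1.20, S = -0.30, T = 0.35),
    center = c(P = -0.22, Q = -0.030, R = 0, S = 0.033, T = 0.30),
    width  = c(P = 0.025, Q = 0.008, R = 0.012, S = 0.010, T = 0.070),
    heart_rate_bpm = 70,
    lead_scale = c(V2 = 1.25, V3 = 1.15, V4 = 1.05, V5 = 0.95),
    other_lead_scale = 0.8) {
  waves <- c("P", "Q", "R", "S", "T")
  stopifnot(setequal(names(amp), waves), setequal(names(center), waves),
            setequal(names(width), waves))
  amp <- amp[waves]; center <- center[waves]; width <- width[waves]
  if (any(width <= 0)) stop("validation error: wave widths must be > 0")
  if (is.unsorted(center, strictly = TRUE))
    stop("validation error: wave centers must be ordered P < Q < R < S < T")
  if (heart_rate_bpm <= 0) stop("validation error: heart rate must be > 0")
  structure(list(amp = amp, center = center, width = width,
                 heart_rate_bpm = heart_rate_bpm, lead_scale = lead_scale,
                 other_lead_scale = other_lead_scale),
            class = "beat_template")
}

#' Serum-potassium effect model for ECG morphology
#'
#' A documented monotone map from serum potassium to template changes,
#' following the classic electrophysiology of hyperkalemia: above the
#' reference concentration the T wave grows taller (`t_amp_gain`, mV per
#' mmol/L) and its base narrows (`t_width_shrink`, fractional width
#' reduction per mmol/L, floored at 40% of the base width); above the
#' activation point (5.5 mmol/L) the P wave flattens (`p_amp_loss`,
#' fractional loss per mmol/L, floored at 0), the PR interval prolongs
#' (`pr_prolong_s`, s per mmol/L) and the QRS widens (`qrs_widen_s`, s per
#' mmol/L). T-wave amplitude also declines continuously below the reference,
#' so the map is continuous and monotone over the whole range.
#'
#' @param k_ref reference potassium (mmol/L) at which the template is
#'   unchanged.
#' @param t_amp_gain,t_width_shrink,p_amp_loss,pr_prolong_s,qrs_widen_s
#'   effect magnitudes (all >= 0), see above.
#' @param k_activate potassium above which P/PR/QRS effects engage.
#' @param k_sat saturation scale (mmol/L) of the T-wave response; `Inf`
#'   makes the response linear.
#' @param hypo_slope_frac fraction of `t_amp_gain` governing the (mild)
#'   T-wave flattening below the reference concentration.
#' @return an object of class `k_effect_model`.
#' @export
k_effect_model <- function(k_ref = 4.0, t_amp_gain = 0.4,
                           t_width_shrink = 0.14, p_amp_loss = 0.4,
                           pr_prolong_s = 0.02, qrs_widen_s = 0.004,
                           k_activate = 5.5, k_sat = 2.0,
                           hypo_slope_frac = 0.3) {
  eff <- list(k_ref = k_ref, t_amp_gain = t_amp_gain,
              t_width_shrink = t_width_shrink, p_amp_loss = p_amp_loss,
              pr_prolong_s = pr_prolong_s, qrs_widen_s = qrs_widen_s,
              k_activate = k_activate, k_sat = k_sat,
              hypo_slope_frac = hypo_slope_frac)
  if (eff$k_sat <= 0) stop("validation error: k_sat must be > 0")
  if (any(unlist(eff[2:6]) < 0))
    stop("validation error: effect magnitudes must be >= 0")
  structure(eff, class = "k_effect_model")
}

#' Noise and between-record variability model
#'
#' Additive noise components (baseline wander, powerline interference, white
#' noise) plus the sources of between-record physiological variability (RR
#' jitter, heart-rate spread, per-wave amplitude jitter). Setting everything
#' to zero yields analytically exact, perfectly periodic records.
#'
#' @param baseline_wander_amp_mv,baseline_wander_hz sinusoidal wander.
#' @param powerline_hz,powerline_amp_mv mains interference (50 Hz default).
#' @param white_noise_sigma_mv white measurement noise SD.
#' @param rr_jitter_frac per-beat uniform RR jitter (fraction of RR).
#' @param hr_sd_bpm between-record heart-rate SD.
#' @param amp_jitter_sd between-record log-normal SD applied independently
#'   to each wave amplitude (biological variability; this is what keeps the
#'   potassium-classification task from being trivially separable).
#' @param width_jitter_sd between-record log-normal SD applied independently
#'   to each wave width: QRS duration and T-wave width vary substantially
#'   between individuals, so wave widths must not be a clean deterministic
#'   readout of the potassium effect.
#' @param effect_jitter_sd between-record log-normal SD on the magnitude of
#'   every potassium effect: individuals differ widely in how strongly their
#'   ECG responds to a given serum potassium.
#' @param tail_jitter_per_mmol inflation of all between-record jitter SDs
#'   per mmol/L above the activation point: ECG morphology becomes
#'   increasingly erratic as hyperkalemia worsens.
#' @param atypia_per_mmol probability per mmol/L above the activation point
#'   that a record expresses atypical repolarization (flattened or inverted,
#'   broadened T) instead of the classic tented T. Such atypical responses
#'   are well described in severe hyperkalemia, and together with the
#'   saturating mean response they are what degrades classifier performance
#'   at the severe thresholds.
#' @return an object of class `noise_model`.
#' @export
noise_model <- function(baseline_wander_amp_mv = 0.3,
                        baseline_wander_hz = 0.25,
                        powerline_hz = 50, powerline_amp_mv = 0.05,
                        white_noise_sigma_mv = 0.03,
                        rr_jitter_frac = 0.03, hr_sd_bpm = 5,
                        amp_jitter_sd = 0.12, width_jitter_sd = 0.12,
                        effect_jitter_sd = 0.3,
                        tail_jitter_per_mmol = 0.4,
                        atypia_per_mmol = 0.15) {
  nm <- list(baseline_wander_amp_mv = baseline_wander_amp_mv,
             baseline_wander_hz = baseline_wander_hz,
             powerline_hz = powerline_hz, powerline_amp_mv = powerline_amp_mv,
             white_noise_sigma_mv = white_noise_sigma_mv,
             rr_jitter_frac = rr_jitter_frac, hr_sd_bpm = hr_sd_bpm,
             amp_jitter_sd = amp_jitter_sd, width_jitter_sd = width_jitter_sd,
             effect_jitter_sd = effect_jitter_sd,
             tail_jitter_per_mmol = tail_jitter_per_mmol,
             atypia_per_mmol = atypia_per_mmol)
  if (any(unlist(nm) < 0))
    stop("validation error: noise parameters must be >= 0")
  structure(nm, class = "noise_model")
}

#' A noise model with every component zeroed (analytically clean records)
#' @return a `noise_model` with all amplitudes and jitters zero.
#' @export
noise_model_none <- function() {
  noise_model(baseline_wander_amp_mv = 0, powerline_amp_mv = 0,
              white_noise_sigma_mv = 0, rr_jitter_frac = 0, hr_sd_bpm = 0,
              amp_jitter_sd = 0, width_jitter_sd = 0, effect_jitter_sd = 0,
              tail_jitter_per_mmol = 0, atypia_per_mmol = 0)
}

#' Apply the potassium effect model to a beat template
#'
#' @param k serum potassium in mmol/L (1--10).
#' @param base a [beat_template()].
#' @param effect a [k_effect_model()].
#' @return the modified `beat_template`; equals `base` exactly at
#'   `k = k_ref`.
#' @export
k_to_template <- function(k, base = beat_template(),
                          effect = k_effect_model()) {
  if (!is.finite(k) || k < 1 || k > 10)
    stop("validation error: k must be in [1, 10] mmol/L, got ", k)
  tpl <- base
  dk <- k - effect$k_ref
  # saturating excess above the reference, mild linear decline below it
  dk_eff <- if (dk > 0) {
    if (is.finite(effect$k_sat))
      effect$k_sat * (1 - exp(-dk / effect$k_sat)) else dk
  } else effect$hypo_slope_frac * dk
  # floor guards against the hypokalemic decline driving the amplitude
  # negative; it never raises a template whose T is already small
  tpl$amp["T"] <- max(min(base$amp[["T"]], 0.05),
                      base$amp[["T"]] + effect$t_amp_gain * dk_eff)
  shrink <- max(0.4, 1 - effect$t_width_shrink * max(0, dk_eff))
  tpl$width["T"] <- base$width["T"] * shrink
  e <- max(0, k - effect$k_activate)
  if (e > 0 && is.finite(effect$k_sat))
    e <- effect$k_sat * (1 - exp(-e / effect$k_sat))
  if (e > 0) {
    tpl$amp["P"] <- base$amp["P"] * max(0, 1 - effect$p_amp_loss * e)
    tpl$center["P"] <- base$center["P"] - effect$pr_prolong_s * e
    qrs_base <- (base$center["S"] + 2 * base$width["S"]) -
                (base$center["Q"] - 2 * base$width["Q"])
    f <- 1 + effect$qrs_widen_s * e / qrs_base
    for (w in c("Q", "R", "S")) {
      tpl$width[w] <- base$width[w] * f
      tpl$center[w] <- base$center[w] * f
    }
  }
  if (tpl$width["T"] <= 0)
    stop("configuration error: effect model produced non-positive T width")
  tpl
}

# Gaussian-sum voltage of a beat train on the canonical (unit-scale) lead.
beat_train_signal <- function(t, r_times, tpl) {
  v <- numeric(length(t))
  fs_support <- 0.75  # waves are negligible beyond this distance from R
  for (r in r_times) {
    lo <- findInterval(r - fs_support, t) + 1L
    hi <- findInterval(r + fs_support, t)
    if (lo > hi) next
    tt <- t[lo:hi] - r
    for (w in c("P", "Q", "R", "S", "T"))
      v[lo:hi] <- v[lo:hi] + tpl$amp[w] *
        exp(-(tt - tpl$center[w])^2 / (2 * tpl$width[w]^2))
  }
  v
}

#' Generate one potassium-modulated synthetic ECG record
#'
#' A beat train of Gaussian-sum waveforms at the template heart rate with
#' uniform per-beat RR jitter, modulated by the potassium effect model and
#' the noise model, on all 12 standard leads (V2--V5 at their template
#' scalings, the others at the `other_lead_scale`). Deterministic given
#' `seed`. The generator's ground truth (true potassium, the post-jitter
#' template, true R times, per-lead scalings) is attached as attribute
#' `"truth"` for use as a test oracle.
#'
#' @param k serum potassium in mmol/L.
#' @param template a [beat_template()].
#' @param effect a [k_effect_model()].
#' @param noise a [noise_model()].
#' @param duration_s record length in seconds.
#' @param fs sampling frequency in Hz; must satisfy `fs >= 4 / min(width)`.
#' @param seed integer seed.
#' @param record_id identifier.
#' @param leads which leads to materialize (default all 12).
#' @return an `ecg_record` with attribute `truth`.
#' @export
generate_record <- function(k, template = beat_template(),
                            effect = k_effect_model(),
                            noise = noise_model(), duration_s = 30,
                            fs = 500, seed = 1, record_id = "synthetic",
                            leads = STANDARD_LEADS) {
  base_tpl <- k_to_template(k, template, effect)  # validates k and effect
  if (fs < 4 / min(base_tpl$width))
    stop("configuration error: fs = ", fs,
         " too low to resolve the narrowest wave (need >= ",
         ceiling(4 / min(base_tpl$width)), " Hz)")
  with_seed(seed, {
    # between-record physiological variability: individuals differ in how
    # strongly their ECG responds to a given potassium level
    eff <- effect
    infl <- 1 + noise$tail_jitter_per_mmol * max(0, k - effect$k_activate)
    if (noise$effect_jitter_sd > 0) {
      esc <- exp(stats::rnorm(1, 0, noise$effect_jitter_sd * infl))
      for (fld in c("t_amp_gain", "t_width_shrink", "p_amp_loss",
                    "pr_prolong_s", "qrs_widen_s"))
        eff[[fld]] <- eff[[fld]] * esc
      # keep the jittered effect physically admissible up to k = 10
      eff$t_width_shrink <- min(eff$t_width_shrink, 0.2)
      eff$p_amp_loss <- min(eff$p_amp_loss, 1)
    }
    tpl <- k_to_template(k, template, eff)
    hr <- tpl$heart_rate_bpm + stats::rnorm(1, 0, noise$hr_sd_bpm)
    hr <- min(120, max(40, hr))
    if (noise$amp_jitter_sd > 0)
      tpl$amp <- tpl$amp * exp(stats::rnorm(5, 0, noise$amp_jitter_sd * infl))
    if (noise$width_jitter_sd > 0)
      tpl$width <- pmax(tpl$width *
                          exp(stats::rnorm(5, 0,
                                           noise$width_jitter_sd * infl)),
                        2.5 / fs)
    atypical <- FALSE
    if (noise$atypia_per_mmol > 0) {
      p_atyp <- min(0.9, noise$atypia_per_mmol *
                           max(0, k - effect$k_activate))
      if (stats::runif(1) < p_atyp) {
        # atypical repolarization: flattened or inverted, broadened T
        atypical <- TRUE
        tpl$amp[["T"]] <- tpl$amp[["T"]] * stats::runif(1, -0.5, 0.4)
        tpl$width[["T"]] <- tpl$width[["T"]] * stats::runif(1, 1.2, 1.8)
      }
    }
    rr <- 60 / hr
    n_beats <- ceiling(duration_s / rr) + 2L
    jit <- 1 + stats::runif(n_beats, -noise$rr_jitter_frac,
                            noise$rr_jitter_frac)
    r_times <- 0.5 + cumsum(c(0, rr * jit[-1]))
    r_times <- r_times[r_times < duration_s + 0.5]

    n <- round(duration_s * fs)
    t <- (seq_len(n) - 1) / fs
    v <- beat_train_signal(t, r_times, tpl)
    scales <- ifelse(leads %in% names(tpl$lead_scale),
                     tpl$lead_scale[leads], tpl$other_lead_scale)
    sig <- outer(v, scales)
    for (j in seq_along(leads)) {
      if (noise$baseline_wander_amp_mv > 0)
        sig[, j] <- sig[, j] + noise$baseline_wander_amp_mv *
          sin(2 * pi * noise$baseline_wander_hz * t + stats::runif(1, 0, 2 * pi))
      if (noise$powerline_amp_mv > 0)
        sig[, j] <- sig[, j] + noise$powerline_amp_mv *
          sin(2 * pi * noise$powerline_hz * t + stats::runif(1, 0, 2 * pi))
      if (noise$white_noise_sigma_mv > 0)
        sig[, j] <- sig[, j] + stats::rnorm(n, 0, noise$white_noise_sigma_mv)
    }
    rec <- ecg_record(sig, fs = fs, lead_names = leads,
                      record_id = record_id)
    attr(rec, "truth") <- list(k = k, template = tpl, r_times = r_times,
                               heart_rate_bpm = hr, rr_s = rr,
                               atypical = atypical,
                               lead_scales = stats::setNames(scales, leads))
    rec
  })
}

#' Synthetic dataset configuration
#'
#' Potassium values are drawn from a Normal(`k_mean`, `k_sd`) truncated to
#' `k_bounds`; the defaults reproduce the study population's distribution
#' (mean 4.83, SD 1.01 mmol/L, support approximately 2.5--8 mmol/L).
#'
#' @param n_records number of records.
#' @param k_mean,k_sd,k_bounds truncated-normal parameters (mmol/L).
#' @param duration_s,fs record geometry.
#' @param seed integer master seed; per-record seeds are derived from it.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_records = 1024, k_mean = 4.83, k_sd = 1.01,
                             k_bounds = c(2.5, 8.0), duration_s = 30,
                             fs = 500, seed = 1) {
  if (n_records <= 0) stop("validation error: n_records must be > 0")
  if (k_bounds[1] >= k_bounds[2])
    stop("validation error: k_bounds must be ordered")
  structure(list(n_records = as.integer(n_records), k_mean = k_mean,
                 k_sd = k_sd, k_bounds = k_bounds, duration_s = duration_s,
                 fs = fs, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Draw serum-potassium values from the truncated-normal label distribution
#' @param config a [synthetic_config()].
#' @return numeric vector of length `n_records`, deterministic given the
#'   config seed.
#' @export
draw_k_values <- function(config = synthetic_config()) {
  with_seed(config$seed, {
    plo <- stats::pnorm(config$k_bounds[1], config$k_mean, config$k_sd)
    phi <- stats::pnorm(config$k_bounds[2], config$k_mean, config$k_sd)
    u <- stats::runif(config$n_records, plo, phi)
    stats::qnorm(u, config$k_mean, config$k_sd)
  })
}

record_seed <- function(master, i) (as.numeric(master) + 7919 * i) %%
  .Machine$integer.max

#' Generate a labeled synthetic dataset of ECG records
#'
#' One record per potassium draw, with labels aligned by `record_id`.
#' Deterministic given the config seed.
#'
#' @inheritParams generate_record
#' @param config a [synthetic_config()].
#' @return a list with `records` (list of `ecg_record`) and `labels`
#'   (data.frame: record_id, k_mmol_per_l, phase = "synthetic").
#' @export
generate_dataset <- function(config = synthetic_config(),
                             template = beat_template(),
                             effect = k_effect_model(),
                             noise = noise_model(),
                             leads = STANDARD_LEADS) {
  k <- draw_k_values(config)
  ids <- sprintf("syn%04d", seq_along(k))
  records <- lapply(seq_along(k), function(i)
    generate_record(k[i], template, effect, noise, config$duration_s,
                    config$fs, seed = record_seed(config$seed, i),
                    record_id = ids[i], leads = leads))
  list(records = records,
       labels = data.frame(record_id = ids, k_mmol_per_l = k,
                           phase = "synthetic"))
}

#' Simulate, preprocess and featurize a dataset in one streaming pass
#'
#' Memory-friendly driver used by the pipeline and the experiment wrapper:
#' each record is generated, preprocessed (on the analysis leads only) and
#' reduced to its 48-feature vector before the next one is created. Records
#' whose delineation fails entirely are dropped and counted.
#'
#' @inheritParams generate_dataset
#' @param pp_config a [preprocess_config()], or NULL to skip preprocessing
#'   (features are then extracted from the raw records).
#' @param verbose print progress every 100 records.
#' @return a `labeled_dataset`: list with `features` (n x 48 matrix),
#'   `k` (numeric), `record_ids`, and `n_dropped`.
#' @export
simulate_feature_dataset <- function(config = synthetic_config(),
                                     template = beat_template(),
                                     effect = k_effect_model(),
                                     noise = noise_model(),
                                     pp_config = preprocess_config(),
                                     verbose = FALSE) {
  k <- draw_k_values(config)
  ids <- sprintf("syn%04d", seq_along(k))
  leads <- ANALYSIS_LEADS
  feats <- vector("list", length(k))
  ok <- logical(length(k))
  for (i in seq_along(k)) {
    rec <- generate_record(k[i], template, effect, noise, config$duration_s,
                           config$fs, seed = record_seed(config$seed, i),
                           record_id = ids[i], leads = leads)
    fv <- tryCatch({
      if (!is.null(pp_config)) rec <- preprocess_record(rec, pp_config)
      extract_feature_vector(rec)
    }, error = function(e) NULL)
    if (!is.null(fv)) {
      feats[[i]] <- fv
      ok[i] <- TRUE
    }
    if (verbose && i %% 100 == 0)
      message("simulate_feature_dataset: ", i, "/", length(k))
  }
  features <- do.call(rbind, feats[ok])
  rownames(features) <- ids[ok]
  structure(list(features = features, k = k[ok], record_ids = ids[ok],
                 n_dropped = sum(!ok)),
            class = "labeled_dataset")
}

#' @export
#' @method print labeled_dataset
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset> %d records x %d features; K %0.2f +/- %0.2f mmol/L (%d dropped)\n",
              nrow(x$features), ncol(x$features), mean(x$k),
              stats::sd(x$k), x$n_dropped))
  invisible(x)
}
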
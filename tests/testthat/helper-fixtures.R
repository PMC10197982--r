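# Shared fixtures, all generated in code.

# Small clean multi-lead record for IO tests.
toy_record <- function(n = 2000, fs = 500, leads = c("V2", "V3"), seed = 1) {
  set.seed(seed)
  sig <- matrix(stats::rnorm(n * length(leads), 0, 0.4), ncol = length(leads))
  ecg_record(sig, fs = fs, lead_names = leads, record_id = "toy")
}

# Independent brute-force AUC: explicit loop over positive-negative pairs.
brute_auc <- function(y, s) {
  pos <- s[y == 1]
  neg <- s[y == 0]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# Deterministic two-class toy feature set with signal in the first columns.
toy_features <- function(n = 200, p = 6, seed = 42) {
  set.seed(seed)
  x <- matrix(stats::rnorm(n * p), ncol = p,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  y <- as.integer(x[, 1] + 0.8 * x[, 2] + stats::rnorm(n, 0, 0.7) > 0)
  list(x = x, y = y)
}

# One noise-free default record, cached per test run (delineation fixtures).
clean_record <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_record(4.0, noise = noise_model_none(), seed = 3)
    cache
  }
})

# Record with injected baseline wander + 50 Hz mains and no other noise, at
# 60 bpm with no RR jitter so a 1-s moving mean cancels cardiac content and
# measures residual baseline directly.
drift_test_record <- function(seed = 8) {
  generate_record(
    4.5, template = beat_template(heart_rate_bpm = 60),
    noise = noise_model(white_noise_sigma_mv = 0, rr_jitter_frac = 0,
                        hr_sd_bpm = 0, amp_jitter_sd = 0,
                        width_jitter_sd = 0, effect_jitter_sd = 0,
                        tail_jitter_per_mmol = 0, atypia_per_mmol = 0),
    seed = seed)
}
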
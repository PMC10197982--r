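test_that("confusion metrics and their guards are exact", {
  m <- confusion_metrics(tp = 3, fp = 1, fn = 2, tn = 4)
  expect_equal(m$accuracy, 0.7)
  expect_equal(m$precision, 0.75)
  expect_equal(m$sensitivity, 0.6)
  expect_equal(m$specificity, 0.8)
  all_right <- confusion_metrics(5, 0, 0, 5)
  expect_true(all(unlist(all_right) == 1))
  none_pred <- confusion_metrics(0, 0, 3, 7)
  expect_true(is.na(none_pred$precision))
  expect_false(is.na(none_pred$accuracy))
  expect_error(confusion_metrics(0, 0, 0, 0), "empty")
})

test_that("F1 is the harmonic mean with guarded edges", {
  expect_equal(f1_score(1, 1), 1)
  expect_equal(f1_score(0, 0.9), 0)
  expect_true(is.na(f1_score(NA, 0.5)))
  expect_error(f1_score(1.2, 0.5), "\\[0, 1\\]")
})

test_that("roc_auc equals brute-force concordance, always", {
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8)), 0.75)
  expect_equal(roc_auc(c(0, 0, 1), c(0.1, 0.2, 0.9)), 1)
  expect_equal(roc_auc(c(0, 1, 0, 1), rep(0.5, 4)), 0.5)
  expect_error(roc_auc(c(1, 1), c(0.2, 0.3)), "both classes")
  set.seed(31)
  for (i in 1:25) {
    n <- sample(5:200, 1)
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    s <- if (i %% 2) rnorm(n, y) else sample(seq(0, 1, 0.1), n, TRUE)  # ties
    expect_equal(roc_auc(y, s), brute_auc(y, s))
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(8)
  y <- rbinom(80, 1, 0.5)
  s <- rnorm(80, y)
  a <- roc_auc(y, s)
  expect_equal(roc_auc(y, exp(s)), a)
  expect_equal(roc_auc(y, stats::plogis(3 * s - 1)), a)
  expect_equal(roc_auc(y, rank(s)), a)
})

test_that("DeLong variance matches a bootstrap of the AUC", {
  set.seed(12)
  n <- 200
  y <- rbinom(n, 1, 0.45)
  s <- rnorm(n, 1.2 * y)
  dl <- delong_variance(y, s)
  expect_equal(dl$auc, roc_auc(y, s))
  boot <- vapply(1:2000, function(i) {
    idx <- sample(n, replace = TRUE)
    while (length(unique(y[idx])) < 2) idx <- sample(n, replace = TRUE)
    roc_auc(y[idx], s[idx])
  }, 0)
  expect_lt(abs(dl$variance - stats::var(boot)) / stats::var(boot), 0.2)
  expect_true(dl$ci_low <= dl$auc && dl$auc <= dl$ci_high)
})

test_that("DeLong edge behaviour: perfect separation and clipping", {
  y <- rep(0:1, each = 10)
  s <- c(rnorm(10, 0, 0.1), rnorm(10, 5, 0.1))
  dl <- delong_variance(y, s)
  expect_equal(dl$auc, 1)
  expect_equal(dl$variance, 0)
  expect_equal(dl$ci_low, 1)
  expect_equal(dl$ci_high, 1)
  expect_error(delong_variance(c(0, 1, 1, 1), 1:4), ">= 2")
  # CI is clipped to [0, 1] for high AUC with non-trivial variance
  set.seed(3)
  y2 <- rep(0:1, c(8, 8))
  s2 <- c(rnorm(8, 0), rnorm(8, 4)); s2[9] <- -2
  dl2 <- delong_variance(y2, s2)
  expect_lte(dl2$ci_high, 1)
  expect_gte(dl2$ci_low, 0)
})

test_that("the paired DeLong test agrees with pROC and a permutation oracle", {
  expect_silent({
    y <- rep(0:1, each = 20)
    s <- rnorm(40, y)
    self <- delong_test(y, s, s)
  })
  expect_equal(self$z, 0)
  expect_equal(self$p, 1)
  set.seed(99)
  n <- 150
  y <- rbinom(n, 1, 0.5)
  base <- rnorm(n, y)
  sa <- base + rnorm(n, 0, 0.8)
  sb <- 0.7 * base + rnorm(n, 0, 0.8)
  got <- delong_test(y, sa, sb)
  # independent implementation: pROC's DeLong machinery
  pr <- pROC::roc.test(pROC::roc(y, sa, quiet = TRUE),
                       pROC::roc(y, sb, quiet = TRUE),
                       method = "delong", paired = TRUE)
  expect_equal(got$p, as.numeric(pr$p.value), tolerance = 1e-8)
  prv <- pROC::ci.auc(pROC::roc(y, sa, quiet = TRUE), method = "delong")
  dlv <- delong_variance(y, sa)
  expect_equal(c(dlv$ci_low, dlv$ci_high), as.numeric(prv[c(1, 3)]),
               tolerance = 1e-8)
  # permutation oracle: swap the paired scores at random
  set.seed(7)
  obs <- abs(roc_auc(y, sa) - roc_auc(y, sb))
  perm <- vapply(1:2000, function(i) {
    swap <- runif(n) < 0.5
    pa <- ifelse(swap, sb, sa)
    pb <- ifelse(swap, sa, sb)
    abs(roc_auc(y, pa) - roc_auc(y, pb))
  }, 0)
  expect_lt(abs(mean(perm >= obs) - got$p), 0.02)
})

test_that("the report is internally consistent and complete", {
  set.seed(21)
  n <- 120
  k <- runif(n, 3, 8)
  fams <- c("A1", "B2", "C3", "D4", "E5")
  tab <- do.call(rbind, lapply(fams, function(f)
    do.call(rbind, lapply(c(5.0, 6.0), function(thr) data.frame(
      family = f, threshold = thr, record_id = sprintf("r%03d", 1:n),
      y_true = as.integer(k >= thr),
      score = stats::plogis((k - thr) / 2 + rnorm(n, 0, 0.7)))))))
  rep <- hk_report(tab)
  expect_identical(nrow(rep$metrics), 10L)
  # 5 families -> choose(5,2) = 10 pairwise DeLong tests per threshold
  expect_identical(nrow(rep$delong), 20L)
  expect_true(all(rep$delong$p >= 0 & rep$delong$p <= 1))
  # metrics recomputed from the serialized confusion counts match exactly
  for (i in seq_len(nrow(rep$metrics))) {
    r <- rep$metrics[i, ]
    cm <- confusion_metrics(r$tp, r$fp, r$fn, r$tn)
    expect_equal(r$accuracy, cm$accuracy, tolerance = 1e-12)
    expect_equal(r$precision, cm$precision, tolerance = 1e-12)
    expect_equal(r$sensitivity, cm$sensitivity, tolerance = 1e-12)
    expect_equal(r$specificity, cm$specificity, tolerance = 1e-12)
    expect_equal(r$f1, f1_score(cm$precision, cm$sensitivity),
                 tolerance = 1e-12)
    expect_true(r$auc_ci_low <= r$auc && r$auc <= r$auc_ci_high)
  }
  # mismatched record sets are refused
  bad <- tab
  bad$record_id[bad$family == "B2"][1] <- "zzz"
  expect_error(hk_report(bad), "mismatched record_ids")
})

test_that("single-family reports omit the pairwise comparisons", {
  y <- rep(0:1, each = 15)
  tab <- data.frame(family = "LR", threshold = 5.0,
                    record_id = sprintf("r%02d", 1:30), y_true = y,
                    score = stats::plogis(rnorm(30, y)))
  rep <- hk_report(tab)
  expect_identical(nrow(rep$metrics), 1L)
  expect_null(rep$delong)
  expect_true(all(c("accuracy", "precision", "sensitivity", "specificity",
                    "f1", "auc", "auc_ci_low", "auc_ci_high")
                  %in% names(rep$metrics)))
})
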
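#' Confusion-matrix metrics
#'
#' Accuracy, precision, sensitivity (recall) and specificity from raw
#' counts. Ratios with a zero denominator are reported as `NA` ("absent"),
#' never silently as 0.
#'
#' @param tp,fp,fn,tn non-negative integer counts (n = tp+fp+fn+tn > 0).
#' @return named list with `accuracy`, `precision`, `sensitivity`,
#'   `specificity`.
#' @export
confusion_metrics <- function(tp, fp, fn, tn) {
  n <- tp + fp + fn + tn
  if (n <= 0) stop("validation error: empty confusion matrix")
  if (any(c(tp, fp, fn, tn) < 0))
    stop("validation error: negative confusion count")
  rat <- function(num, den) if (den == 0) NA_real_ else num / den
  list(accuracy = (tp + tn) / n,
       precision = rat(tp, tp + fp),
       sensitivity = rat(tp, tp + fn),
       specificity = rat(tn, tn + fp))
}

#' F1 score from precision and sensitivity
#'
#' Harmonic mean `2 P S / (P + S)`; 0 when either input is 0, `NA` when
#' either is absent.
#'
#' @param precision,sensitivity values in `[0, 1]`.
#' @return the F1 score.
#' @export
f1_score <- function(precision, sensitivity) {
  if (is.na(precision) || is.na(sensitivity)) return(NA_real_)
  if (precision < 0 || precision > 1 || sensitivity < 0 || sensitivity > 1)
    stop("validation error: precision and sensitivity must lie in [0, 1]")
  if (precision == 0 || sensitivity == 0) return(0)
  2 * precision * sensitivity / (precision + sensitivity)
}

#' Area under the ROC curve (Mann--Whitney concordance)
#'
#' AUC computed from midranks, which equals the pairwise concordance over
#' positive--negative pairs with half credit for ties, and the trapezoidal
#' area under the empirical ROC curve.
#'
#' @param y_true 0/1 labels (both classes present).
#' @param scores numeric scores, larger meaning more positive.
#' @return the AUC in `[0, 1]`.
#' @export
roc_auc <- function(y_true, scores) {
  y <- as.integer(y_true > 0)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0)
    stop("validation error: both classes must be present")
  r <- rank(scores)   # midranks: half credit for ties
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# DeLong placement values: V10 (per positive) and V01 (per negative).
delong_placements <- function(y, s) {
  sp <- s[y == 1]
  sn <- s[y == 0]
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(cmp), v01 = colMeans(cmp))
}

#' AUC with DeLong variance and 95% confidence interval
#'
#' The variance of the empirical AUC from DeLong's structural components:
#' `var = S10/n1 + S01/n0`, where `S10`/`S01` are the sample variances of
#' the per-positive and per-negative placement values. The normal 95% CI is
#' clipped to `[0, 1]`.
#'
#' @inheritParams roc_auc
#' @return list with `auc`, `variance`, `ci_low`, `ci_high`.
#' @export
delong_variance <- function(y_true, scores) {
  y <- as.integer(y_true > 0)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 < 2 || n0 < 2)
    stop("validation error: DeLong variance needs >= 2 of each class")
  pl <- delong_placements(y, scores)
  auc <- mean(pl$v10)
  v <- stats::var(pl$v10) / n1 + stats::var(pl$v01) / n0
  half <- stats::qnorm(0.975) * sqrt(v)
  list(auc = auc, variance = v,
       ci_low = max(0, auc - half), ci_high = min(1, auc + half))
}

#' Paired DeLong test for two correlated AUCs
#'
#' Compares two score vectors on the same cases:
#' `z = (auc_a - auc_b) / sqrt(var_a + var_b - 2 cov_ab)` with the
#' covariance taken from the shared placement components; two-sided p from
#' the standard normal.
#'
#' @param y_true 0/1 labels shared by both models.
#' @param scores_a,scores_b paired score vectors.
#' @return list with `auc_a`, `auc_b`, `z`, `p`.
#' @export
delong_test <- function(y_true, scores_a, scores_b) {
  y <- as.integer(y_true > 0)
  if (length(scores_a) != length(y) || length(scores_b) != length(y))
    stop("validation error: scores must be paired with y_true")
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 < 2 || n0 < 2)
    stop("validation error: DeLong test needs >= 2 of each class")
  pa <- delong_placements(y, scores_a)
  pb <- delong_placements(y, scores_b)
  auc_a <- mean(pa$v10); auc_b <- mean(pb$v10)
  v <- stats::var(pa$v10) / n1 + stats::var(pb$v10) / n1 +
       stats::var(pa$v01) / n0 + stats::var(pb$v01) / n0 -
       2 * (stats::cov(pa$v10, pb$v10) / n1 + stats::cov(pa$v01, pb$v01) / n0)
  # rewrite: var_a + var_b - 2 cov
  if (v <= .Machine$double.eps^0.5) {
    if (isTRUE(all.equal(auc_a, auc_b)))
      return(list(auc_a = auc_a, auc_b = auc_b, z = 0, p = 1))
    stop("numerical error: zero variance of the AUC difference with ",
         "unequal AUCs")
  }
  z <- (auc_a - auc_b) / sqrt(v)
  list(auc_a = auc_a, auc_b = auc_b, z = z, p = 2 * stats::pnorm(-abs(z)))
}

# Empirical ROC curve points (thresholds descending).
roc_points <- function(y_true, scores) {
  y <- as.integer(y_true > 0)
  ord <- order(scores, decreasing = TRUE)
  y <- y[ord]; s <- scores[ord]
  keep <- c(diff(s) != 0, TRUE)   # one point per distinct threshold
  tpr <- cumsum(y)[keep] / sum(y)
  fpr <- cumsum(1 - y)[keep] / sum(1 - y)
  data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
}

#' Assemble the full evaluation report
#'
#' From a long score table (one row per record, model family and threshold)
#' computes, per family x threshold: the confusion metrics at the 0.5 score
#' cutoff, F1, AUC with its DeLong 95% CI, and the serialized confusion
#' counts; plus the pairwise DeLong comparison matrix per threshold (raw
#' two-sided p-values, with an additionally Holm-adjusted column), and ROC
#' curve points for plotting.
#'
#' @param score_table data.frame with columns `family`, `threshold`,
#'   `record_id`, `y_true`, `score`. All families at one threshold must
#'   cover an identical record set.
#' @param cutoff score cutoff for dichotomization (default 0.5).
#' @return an object of class `hk_report` with elements `metrics`, `delong`
#'   and `roc` (data.frames).
#' @export
hk_report <- function(score_table, cutoff = 0.5) {
  need <- c("family", "threshold", "record_id", "y_true", "score")
  if (!all(need %in% names(score_table)))
    stop("validation error: score table needs columns ",
         paste(need, collapse = ", "))
  metrics <- NULL
  delong <- NULL
  roc <- NULL
  for (thr in sort(unique(score_table$threshold))) {
    sub <- score_table[score_table$threshold == thr, ]
    fams <- unique(sub$family)
    ref_ids <- sort(sub$record_id[sub$family == fams[1]])
    per_fam <- list()
    for (fam in fams) {
      fsub <- sub[sub$family == fam, ]
      if (!identical(sort(fsub$record_id), ref_ids))
        stop("validation error: mismatched record_ids between families at ",
             "threshold ", thr)
      fsub <- fsub[order(fsub$record_id), ]
      per_fam[[fam]] <- fsub
      pred <- classify_scores(fsub$score, cutoff)
      tp <- sum(pred == 1 & fsub$y_true == 1)
      fp <- sum(pred == 1 & fsub$y_true == 0)
      fn <- sum(pred == 0 & fsub$y_true == 1)
      tn <- sum(pred == 0 & fsub$y_true == 0)
      cm <- confusion_metrics(tp, fp, fn, tn)
      # with fewer than 2 cases of a class, AUC/CI are reported as absent
      dl <- tryCatch(delong_variance(fsub$y_true, fsub$score),
                     error = function(e)
                       list(auc = NA_real_, ci_low = NA_real_,
                            ci_high = NA_real_))
      metrics <- rbind(metrics, data.frame(
        family = fam, threshold = thr, n = nrow(fsub),
        prevalence = mean(fsub$y_true),
        tp = tp, fp = fp, fn = fn, tn = tn,
        accuracy = cm$accuracy, precision = cm$precision,
        sensitivity = cm$sensitivity, specificity = cm$specificity,
        f1 = f1_score(cm$precision, cm$sensitivity),
        auc = dl$auc, auc_ci_low = dl$ci_low, auc_ci_high = dl$ci_high))
      rp <- roc_points(fsub$y_true, fsub$score)
      roc <- rbind(roc, data.frame(family = fam, threshold = thr, rp))
    }
    if (length(fams) > 1) {
      pairs <- utils::combn(fams, 2)
      dthr <- NULL
      for (pj in seq_len(ncol(pairs))) {
        a <- pairs[1, pj]; b <- pairs[2, pj]
        dt <- tryCatch(
          delong_test(per_fam[[a]]$y_true, per_fam[[a]]$score,
                      per_fam[[b]]$score),
          error = function(e) list(auc_a = NA_real_, auc_b = NA_real_,
                                   z = NA_real_, p = NA_real_))
        dthr <- rbind(dthr, data.frame(
          threshold = thr, family_a = a, family_b = b,
          auc_a = dt$auc_a, auc_b = dt$auc_b, z = dt$z, p = dt$p))
      }
      dthr$p_holm <- stats::p.adjust(dthr$p, "holm")  # non-study extra
      delong <- rbind(delong, dthr)
    }
  }
  structure(list(metrics = metrics, delong = delong, roc = roc,
                 cutoff = cutoff),
            class = "hk_report")
}

#' @export
#' @method print hk_report
print.hk_report <- function(x, digits = 3, ...) {
  cat("<hk_report> model performance by hyperkalemia threshold\n\n")
  m <- x$metrics
  show <- c("family", "threshold", "accuracy", "precision", "sensitivity",
            "specificity", "f1", "auc", "auc_ci_low", "auc_ci_high")
  m <- m[order(m$family, m$threshold), show]
  num <- vapply(m, is.numeric, TRUE)
  m[num] <- lapply(m[num], round, digits)
  print(m, row.names = FALSE)
  if (!is.null(x$delong)) {
    sig <- sum(x$delong$p < 0.05, na.rm = TRUE)
    cat(sprintf("\nPairwise DeLong tests: %d of %d comparisons with p < 0.05\n",
                sig, nrow(x$delong)))
  }
  invisible(x)
}

#' @export
#' @method summary hk_report
summary.hk_report <- function(object, ...) {
  m <- object$metrics
  by_thr <- split(m, m$threshold)
  cat("Best family by AUC at each threshold:\n")
  for (thr in names(by_thr)) {
    b <- by_thr[[thr]][which.max(by_thr[[thr]]$auc), ]
    cat(sprintf("  %s mmol/L: %s, AUC %.3f (95%% CI %.3f-%.3f)\n",
                thr, b$family, b$auc, b$auc_ci_low, b$auc_ci_high))
  }
  invisible(object)
}

#' Plot ROC curves of a report
#' @param x an `hk_report`.
#' @param thresholds which potassium thresholds to plot (default all).
#' @param ... passed to [graphics::plot()].
#' @export
plot.hk_report <- function(x, thresholds = NULL, ...) {
  roc <- x$roc
  if (!is.null(thresholds)) roc <- roc[roc$threshold %in% thresholds, ]
  thrs <- sort(unique(roc$threshold))
  fams <- unique(roc$family)
  old <- graphics::par(mfrow = c(1, length(thrs)))
  on.exit(graphics::par(old))
  for (thr in thrs) {
    graphics::plot(0:1, 0:1, type = "l", lty = 3, col = "grey",
                   xlab = "1 - specificity", ylab = "sensitivity",
                   main = paste0("K+ >= ", thr, " mmol/L"), ...)
    for (j in seq_along(fams)) {
      rr <- roc[roc$threshold == thr & roc$family == fams[j], ]
      graphics::lines(rr$fpr, rr$tpr, col = j)
    }
    graphics::legend("bottomright", legend = fams, col = seq_along(fams),
                     lty = 1, bty = "n", cex = 0.8)
  }
  invisible(x)
}
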
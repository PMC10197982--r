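# Discrete AdaBoost with depth-1 decision stumps.
#
# Stump search is vectorized: for each feature the observations are sorted
# once, and the weighted error of every threshold (midpoints between
# consecutive distinct values) and both polarities is computed from a
# cumulative sum of signed weights.

best_stump <- function(x, y_pm, w, ord) {
  n <- nrow(x)
  best <- list(err = Inf)
  for (j in seq_len(ncol(x))) {
    o <- ord[, j]
    xv <- x[o, j]
    swy <- cumsum((w * y_pm)[o])   # sum of w*y for x <= threshold
    total <- swy[n]
    # err(polarity +1: predict -1 below thr, +1 above) for cut after pos i:
    #   err = sum_{x<=thr, y=+1} w + sum_{x>thr, y=-1} w
    # With W1 = total weight of +1, using signed cumsum:
    #   sum_{<=i} w*y = P_i - N_i  (P = weight of +1 below, N = weight of -1)
    # err_up(i)  = P_i + (N_tot - N_i) = N_tot + swy_i... derive directly:
    cand <- which(diff(xv) > 0)
    if (!length(cand)) next
    wpos_tot <- sum(w[y_pm > 0])
    wneg_tot <- sum(w) - wpos_tot
    P <- (cumsum(w[o]) + swy) / 2    # weight of +1 at or below i
    N <- cumsum(w[o]) - P
    err_up <- P[cand] + (wneg_tot - N[cand])    # predict +1 above thr
    err_dn <- N[cand] + (wpos_tot - P[cand])    # predict +1 below thr
    ju <- which.min(err_up); jd <- which.min(err_dn)
    if (err_up[ju] < best$err)
      best <- list(err = err_up[ju], feature = j, polarity = 1,
                   threshold = (xv[cand[ju]] + xv[cand[ju] + 1]) / 2)
    if (err_dn[jd] < best$err)
      best <- list(err = err_dn[jd], feature = j, polarity = -1,
                   threshold = (xv[cand[jd]] + xv[cand[jd] + 1]) / 2)
  }
  best
}

stump_predict <- function(stump, x) {
  s <- ifelse(x[, stump$feature] > stump$threshold, 1, -1)
  stump$polarity * s
}

#' Fit an AdaBoost classifier of decision stumps
#'
#' Discrete AdaBoost (exponential-loss reweighting) with one-split decision
#' stumps as weak learners and shrinkage on the stump weights.
#'
#' @param x numeric feature matrix.
#' @param y 0/1 labels.
#' @param n_estimators number of boosting rounds.
#' @param learning_rate shrinkage applied to each stump weight.
#' @return an object of class `hk_adaboost`.
#' @export
adaboost_fit <- function(x, y, n_estimators = 100, learning_rate = 1.0) {
  x <- as.matrix(x)
  y_pm <- ifelse(y > 0, 1, -1)
  n <- nrow(x)
  w <- rep(1 / n, n)
  ord <- apply(x, 2, order)
  stumps <- vector("list", n_estimators)
  alphas <- numeric(n_estimators)
  used <- 0L
  for (m in seq_len(n_estimators)) {
    st <- best_stump(x, y_pm, w, ord)
    if (!is.finite(st$err)) break
    err <- max(st$err / sum(w), 1e-12)
    if (err >= 0.5) break
    alpha <- learning_rate * 0.5 * log((1 - err) / err)
    pred <- stump_predict(st, x)
    w <- w * exp(-alpha * y_pm * pred)
    w <- w / sum(w)
    used <- used + 1L
    stumps[[used]] <- st
    alphas[used] <- alpha
  }
  structure(list(stumps = stumps[seq_len(used)],
                 alphas = alphas[seq_len(used)]),
            class = "hk_adaboost")
}

#' Score an AdaBoost classifier
#' @param fit an `hk_adaboost`.
#' @param x feature matrix.
#' @return scores in `[0, 1]`: the logistic transform of the boosted margin
#'   (0.5 corresponds to a zero margin).
#' @export
adaboost_predict <- function(fit, x) {
  x <- as.matrix(x)
  f <- numeric(nrow(x))
  for (m in seq_along(fit$stumps))
    f <- f + fit$alphas[m] * stump_predict(fit$stumps[[m]], x)
  as.numeric(stats::plogis(2 * f))
}
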
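# A small 1-D convolutional network for the 4-lead x 12-feature grid:
#   input (channels = 4 leads, length = 12 features)
#   -> conv(kernel 3, same padding, 8 filters) + ReLU
#   -> conv(kernel 3, same padding, 16 filters) + ReLU
#   -> flatten -> dense(1) -> sigmoid
# Trained with full-batch Adam on binary cross-entropy, with early stopping
# on a stratified validation split of the training data. Written in plain
# matrix algebra so training is deterministic given the seed.

cnn_shape <- function(n_feat) {
  if (n_feat %% 12 == 0 && n_feat > 12) list(len = 12L, ch = n_feat %/% 12L)
  else list(len = n_feat, ch = 1L)
}

# x: n x (len*ch) matrix, channel-major blocks (lead-major feature vector).
# Returns the padded activation array [n, len+2, ch].
pad_activation <- function(x, len, ch) {
  n <- nrow(x)
  a <- array(0, dim = c(n, len + 2L, ch))
  a[, 2:(len + 1), ] <- array(x, dim = c(n, len, ch))
  a
}

# im2col for kernel size 3, same padding: (n*len) x (3*ch)
im2col3 <- function(apad, len, ch) {
  n <- dim(apad)[1]
  m <- matrix(0, n * len, 3L * ch)
  q <- 0L
  for (c in seq_len(ch)) for (k in 1:3) {
    q <- q + 1L
    m[, q] <- as.vector(apad[, k:(k + len - 1), c])
  }
  m
}

col2im3 <- function(dm, n, len, ch) {
  dpad <- array(0, dim = c(n, len + 2L, ch))
  q <- 0L
  for (c in seq_len(ch)) for (k in 1:3) {
    q <- q + 1L
    dpad[, k:(k + len - 1), c] <- dpad[, k:(k + len - 1), c] +
      matrix(dm[, q], n, len)
  }
  matrix(dpad[, 2:(len + 1), , drop = FALSE], n, len * ch)
}

cnn_init <- function(n_feat, ch1 = 8L, ch2 = 16L) {
  sh <- cnn_shape(n_feat)
  he <- function(fan_in, nr, nc)
    matrix(stats::rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)
  list(shape = sh, ch1 = ch1, ch2 = ch2,
       W1 = he(3 * sh$ch, 3L * sh$ch, ch1), b1 = numeric(ch1),
       W2 = he(3 * ch1, 3L * ch1, ch2), b2 = numeric(ch2),
       W3 = he(sh$len * ch2, sh$len * ch2, 1L), b3 = 0)
}

cnn_forward <- function(par, x) {
  sh <- par$shape
  n <- nrow(x)
  m1 <- im2col3(pad_activation(x, sh$len, sh$ch), sh$len, sh$ch)
  z1 <- sweep(m1 %*% par$W1, 2, par$b1, "+")       # (n*len) x ch1
  a1 <- pmax(z1, 0)
  a1m <- matrix(a1, n, sh$len * par$ch1)           # n x (len*ch1)
  m2 <- im2col3(pad_activation(a1m, sh$len, par$ch1), sh$len, par$ch1)
  z2 <- sweep(m2 %*% par$W2, 2, par$b2, "+")
  a2 <- pmax(z2, 0)
  a2m <- matrix(a2, n, sh$len * par$ch2)
  logit <- drop(a2m %*% par$W3) + par$b3
  list(m1 = m1, z1 = z1, a1m = a1m, m2 = m2, z2 = z2, a2m = a2m,
       logit = logit, p = stats::plogis(logit))
}

cnn_loss_grad <- function(par, x, y) {
  sh <- par$shape
  n <- nrow(x)
  fw <- cnn_forward(par, x)
  eps <- 1e-12
  loss <- -mean(y * log(fw$p + eps) + (1 - y) * log(1 - fw$p + eps))
  dlogit <- (fw$p - y) / n                          # n
  gW3 <- t(fw$a2m) %*% dlogit
  gb3 <- sum(dlogit)
  da2m <- outer(dlogit, drop(par$W3))               # n x (len*ch2)
  dz2 <- matrix(da2m, n * sh$len, par$ch2) * (fw$z2 > 0)
  gW2 <- t(fw$m2) %*% dz2
  gb2 <- colSums(dz2)
  dm2 <- dz2 %*% t(par$W2)
  da1m <- col2im3(dm2, n, sh$len, par$ch1)
  dz1 <- matrix(da1m, n * sh$len, par$ch1) * (fw$z1 > 0)
  gW1 <- t(fw$m1) %*% dz1
  gb1 <- colSums(dz1)
  list(loss = loss,
       grads = list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2,
                    W3 = gW3, b3 = gb3))
}

#' Fit the small 1-D CNN classifier
#'
#' See the package's model documentation for the architecture. 15% of the
#' rows (stratified) are held out as a validation set for early stopping:
#' training runs full-batch Adam and keeps the weights with the best
#' validation loss, stopping after 10 consecutive evaluations without
#' improvement.
#'
#' @param x numeric feature matrix (rows standardized upstream).
#' @param y 0/1 labels.
#' @param epochs maximum Adam steps.
#' @param lr Adam learning rate.
#' @param batch unused (training is full batch); kept for config stability.
#' @return an object of class `hk_cnn`.
#' @export
cnn_fit <- function(x, y, epochs = 300, lr = 0.01, batch = NULL) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  par <- cnn_init(ncol(x))
  # stratified validation split for early stopping
  val <- unlist(lapply(unique(y), function(cl) {
    idx <- which(y == cl)
    sample(idx, max(1L, round(0.15 * length(idx))))
  }))
  tr <- setdiff(seq_along(y), val)
  wnames <- c("W1", "b1", "W2", "b2", "W3", "b3")
  m <- v <- lapply(par[wnames], function(w) w * 0)
  b1 <- 0.9; b2 <- 0.999; epsa <- 1e-8
  best <- list(loss = Inf, par = par)
  bad <- 0L
  for (ep in seq_len(epochs)) {
    lg <- cnn_loss_grad(par, x[tr, , drop = FALSE], y[tr])
    for (wn in wnames) {
      g <- lg$grads[[wn]]
      m[[wn]] <- b1 * m[[wn]] + (1 - b1) * g
      v[[wn]] <- b2 * v[[wn]] + (1 - b2) * g^2
      mhat <- m[[wn]] / (1 - b1^ep)
      vhat <- v[[wn]] / (1 - b2^ep)
      par[[wn]] <- par[[wn]] - lr * mhat / (sqrt(vhat) + epsa)
    }
    if (ep %% 10 == 0) {
      fv <- cnn_forward(par, x[val, , drop = FALSE])
      eps <- 1e-12
      vloss <- -mean(y[val] * log(fv$p + eps) +
                       (1 - y[val]) * log(1 - fv$p + eps))
      if (vloss < best$loss - 1e-5) {
        best <- list(loss = vloss, par = par)
        bad <- 0L
      } else {
        bad <- bad + 1L
        if (bad >= 10L) break
      }
    }
  }
  structure(list(par = best$par, val_loss = best$loss), class = "hk_cnn")
}

#' Score the small 1-D CNN
#' @param fit an `hk_cnn`.
#' @param x feature matrix.
#' @return sigmoid output scores in `[0, 1]`.
#' @export
cnn_predict <- function(fit, x) {
  as.numeric(cnn_forward(fit$par, as.matrix(x))$p)
}
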
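test_that("label binarization follows the >= convention", {
  expect_identical(binarize_labels(c(4.9, 5.0, 5.1), 5.0), c(0L, 1L, 1L))
  expect_identical(binarize_labels(c(3, 4), 5.0), c(0L, 0L))
  expect_warning(binarize_labels(5, 4.2), "non-canonical")
})

test_that("the 8:2 split is deterministic, exact and stratifiable", {
  s1 <- split_dataset(1024, stratify = FALSE, seed = 5)
  expect_length(s1$test, 205)        # round(0.2 * 1024)
  expect_length(s1$train, 819)
  expect_identical(sort(c(s1$train, s1$test)), 1:1024)
  expect_identical(s1, split_dataset(1024, stratify = FALSE, seed = 5))
  expect_false(identical(s1$test,
                         split_dataset(1024, stratify = FALSE, seed = 6)$test))
  # stratified: the study's class balance at threshold 5.0 (448 / 576)
  y <- rep(c(1L, 0L), c(448, 576))
  s2 <- split_dataset(1024, labels = y, seed = 3, stratify = TRUE)
  expect_length(s2$test, 205)
  expect_lte(abs(sum(y[s2$test]) - 0.2 * 448), 1)
  expect_lte(abs(sum(y[s2$train]) - 0.8 * 448), 1)
  expect_error(split_dataset(5), "at least 10")
})

test_that("standardization is fitted on the training split only", {
  tf <- toy_features()
  tr <- 1:150; te <- 151:200
  m <- hk_train(tf$x[tr, ], tf$y[tr], model_spec("LR"), seed = 2)
  expect_equal(m$scaler$mean, colMeans(tf$x[tr, ]))
  expect_equal(m$scaler$sd, apply(tf$x[tr, ], 2, stats::sd))
  # refitting on train + test must give different parameters (leakage guard)
  expect_false(isTRUE(all.equal(m$scaler$mean, colMeans(tf$x))))
  expect_false(isTRUE(all.equal(m$scaler$sd, apply(tf$x, 2, stats::sd))))
})

test_that("grid selection equals an independently coded CV loop", {
  tf <- toy_features(n = 200)
  spec <- model_spec("XGB", grid = expand.grid(nrounds = c(20, 60),
                                               max_depth = c(1, 3),
                                               eta = 0.3),
                     cv_folds = 3)
  seed <- 11
  m <- hk_train(tf$x, tf$y, spec, seed = seed)
  # oracle: rebuild the same folds and score every grid point by hand
  folds <- hyperkECG:::with_seed(seed,
    hyperkECG:::stratified_folds(tf$y, 3))
  oracle_auc <- vapply(seq_len(nrow(spec$grid)), function(gi) {
    mean(vapply(1:3, function(f) {
      tr <- folds != f
      mu <- colMeans(tf$x[tr, ]); sd <- apply(tf$x[tr, ], 2, stats::sd)
      xtr <- scale(tf$x[tr, ], mu, sd); xva <- scale(tf$x[!tr, ], mu, sd)
      fit <- xgboost::xgboost(x = xtr,
                              y = factor(tf$y[tr], levels = c(0, 1)),
                              nrounds = spec$grid$nrounds[gi],
                              max_depth = spec$grid$max_depth[gi],
                              learning_rate = spec$grid$eta[gi],
                              objective = "binary:logistic",
                              nthreads = 1, verbosity = 0)
      roc_auc(tf$y[!tr], predict(fit, xva))
    }, 0))
  }, 0)
  expect_equal(unname(m$cv_table$mean_cv_auc), unname(oracle_auc),
               tolerance = 1e-8)
  expect_identical(unlist(m$chosen),
                   unlist(spec$grid[which.max(oracle_auc), ]))
})

test_that("a one-point grid is selected and still cross-validated", {
  tf <- toy_features(n = 120)
  spec <- model_spec("LR", grid = data.frame(C = 1), cv_folds = 5)
  m <- hk_train(tf$x, tf$y, spec, seed = 1)
  expect_equal(m$chosen$C, 1)
  expect_identical(nrow(m$cv_table), 1L)
  expect_true(is.finite(m$cv_table$mean_cv_auc))
})

test_that("every family separates linearly separable data perfectly", {
  set.seed(9)
  xs <- rbind(matrix(stats::rnorm(60, -2), 30),
              matrix(stats::rnorm(60, 2), 30))
  colnames(xs) <- c("a", "b")
  ys <- rep(0:1, each = 30)
  for (fam in c("LR", "SVM", "XGB", "AdaBoost", "CNN")) {
    m <- hk_train(xs, ys, model_spec(fam), seed = 1)
    expect_equal(roc_auc(ys, predict(m, xs)), 1, label = fam)
  }
})

test_that("training refuses single-class data", {
  tf <- toy_features(n = 40)
  expect_error(hk_train(tf$x, rep(1L, 40), model_spec("LR")),
               "single class")
})

test_that("scores are in [0,1], length-matched and layout-invariant", {
  tf <- toy_features()
  for (fam in c("LR", "SVM", "XGB", "AdaBoost", "CNN")) {
    m <- hk_train(tf$x[1:150, ], tf$y[1:150], model_spec(fam), seed = 3)
    s <- predict(m, tf$x[151:200, ])
    expect_length(s, 50)
    expect_true(all(s >= 0 & s <= 1), label = fam)
    # column storage order must not matter given canonical names
    perm <- tf$x[151:200, rev(seq_len(ncol(tf$x)))]
    expect_equal(predict(m, perm), s, label = fam)
    # held-out discrimination is real on this noisy-linear task
    expect_gt(roc_auc(tf$y[151:200], s), 0.75)
  }
  m <- hk_train(tf$x[1:150, ], tf$y[1:150], model_spec("LR"), seed = 3)
  expect_error(predict(m, tf$x[, 1:3]), "missing feature")
})

test_that("the whole train/predict path is reproducible given the seed", {
  tf <- toy_features(n = 150)
  for (fam in c("LR", "SVM", "XGB", "AdaBoost", "CNN")) {
    m1 <- hk_train(tf$x, tf$y, model_spec(fam), seed = 8)
    m2 <- hk_train(tf$x, tf$y, model_spec(fam), seed = 8)
    expect_identical(predict(m1, tf$x), predict(m2, tf$x), label = fam)
  }
})

test_that("CNN backpropagation matches finite-difference gradients", {
  set.seed(4)
  n <- 12
  x <- matrix(stats::rnorm(n * 48), n, 48)
  y <- rep(0:1, 6)
  par <- hyperkECG:::with_seed(2, hyperkECG:::cnn_init(48L))
  lg <- hyperkECG:::cnn_loss_grad(par, x, y)
  eps <- 1e-6
  for (wn in c("W1", "b1", "W2", "b2", "W3", "b3")) {
    w <- par[[wn]]
    idx <- if (length(w) > 5) sample(length(w), 5) else seq_along(w)
    for (i in idx) {
      pp <- par; pp[[wn]][i] <- pp[[wn]][i] + eps
      pm <- par; pm[[wn]][i] <- pm[[wn]][i] - eps
      num <- (hyperkECG:::cnn_loss_grad(pp, x, y)$loss -
                hyperkECG:::cnn_loss_grad(pm, x, y)$loss) / (2 * eps)
      expect_lt(abs(lg$grads[[wn]][i] - num), 1e-6 + 1e-4 * abs(num))
    }
  }
})
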
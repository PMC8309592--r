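test_that("compiled conv and pool kernels match the pure-R references", {
  withr::with_seed(20, {
    shapes <- list(c(9L, 7L, 3L, 2L), c(12L, 6L, 2L, 1L), c(16L, 8L, 1L, 4L))
    for (d in shapes) {
      X <- array(runif(prod(d)), d)
      W <- array(rnorm(3 * 3 * d[4] * 5), c(3L, 3L, d[4], 5L))
      b <- rnorm(5)
      fw <- conv_fwd(X, W, b)
      expect_equal(fw, conv_fwd_ref(X, W, b), tolerance = 1e-12)
      dY <- array(rnorm(length(fw)), dim(fw))
      g_cpp <- conv_bwd(dY, X, W, compute_dx = TRUE)
      g_ref <- conv_bwd_ref(dY, X, W, compute_dx = TRUE)
      expect_equal(g_cpp$dW, g_ref$dW, tolerance = 1e-12)
      expect_equal(g_cpp$db, g_ref$db, tolerance = 1e-12)
      expect_equal(g_cpp$dX, g_ref$dX, tolerance = 1e-12)
      expect_equal(pool_fwd(X), pool_fwd_ref(X), tolerance = 1e-12)
    }
  })
})

test_that("analytic gradients match numerical differentiation", {
  cfg <- model_config(conv_filters = c(3L, 4L), dense = 5L, batch = 4L)
  H <- 12L; W <- 10L; B <- 5L
  withr::with_seed(21, {
    X <- array(runif(H * W * B), c(H, W, B))
    y <- c(1, 0, 1, 0, 1)
    params <- nn_init(cfg, H, W)
  })
  fw <- nn_forward(params, cfg, X, cache = TRUE)
  grads <- nn_backward(params, cfg, fw, y)
  eps <- 1e-6
  for (nm in names(grads)) {
    idx <- withr::with_seed(22, sample(length(params[[nm]]),
                                       min(4L, length(params[[nm]]))))
    for (i in idx) {
      p2 <- params
      p2[[nm]][i] <- p2[[nm]][i] + eps
      up <- bce_loss(nn_forward(p2, cfg, X)$prob, y)
      p2[[nm]][i] <- p2[[nm]][i] - 2 * eps
      dn <- bce_loss(nn_forward(p2, cfg, X)$prob, y)
      expect_equal(grads[[nm]][i], (up - dn) / (2 * eps), tolerance = 1e-5)
    }
  }
})

test_that("channel re-ordering permutes columns reversibly and improves adjacency", {
  lay <- default_channel_layout()
  expect_setequal(lay$permutation, 1:32)
  withr::with_seed(23, e <- matrix(rnorm(128 * 32), 128, 32))

  identity_lay <- lay
  identity_lay$permutation <- 1:32
  expect_identical(spatial_reorder(e, identity_lay), e)

  re <- spatial_reorder(e, lay)
  inv <- lay
  inv$permutation <- order(lay$permutation)
  expect_identical(spatial_reorder(re, inv), e)

  # proximity chain beats the raw DEAP channel order
  expect_lt(mean_adjacent_distance(lay$permutation),
            mean_adjacent_distance(1:32))

  expect_error(spatial_reorder(matrix(0, 128, 31), lay), "31 channels")
})

test_that("metrics match closed forms and the pair-counting AUC oracle", {
  y <- c(0, 1, 0, 1, 1)
  expect_equal(unname(evaluate_scores(y, y)), c(1, 1, 1))
  expect_equal(evaluate_scores(1 - y, y)[["auc"]], 0)
  expect_error(evaluate_scores(runif(4), rep(1, 4)), "one class")

  withr::with_seed(24, {
    for (rep in 1:200) {
      n <- sample(4:20, 1)
      y <- c(0L, 1L, sample(0:1, n - 2L, replace = TRUE))
      s <- round(runif(n), 2)                   # rounded scores force ties
      auc <- evaluate_scores(s, y)[["auc"]]
      pos <- s[y == 1L]; neg <- s[y == 0L]
      oracle <- (sum(outer(pos, neg, ">")) + 0.5 * sum(outer(pos, neg, "=="))) /
        (length(pos) * length(neg))
      expect_equal(auc, oracle, tolerance = 1e-12)
    }
  })
})

test_that("ROC and PR areas agree with an independent implementation", {
  withr::with_seed(25, {
    y <- sample(0:1, 300, replace = TRUE)
    s <- plogis(rnorm(300) + y)
  })
  m <- evaluate_scores(s, y)
  roc <- suppressMessages(pROC::roc(y, s, direction = "<"))
  expect_equal(m[["auc"]], as.numeric(pROC::auc(roc)), tolerance = 1e-9)
})

test_that("the decoder learns a separable toy problem and scores stay in [0, 1]", {
  toy <- toy_images(150L, seed = 26L)
  idx <- withr::with_seed(27, sample(300L))
  tr <- idx[1:260]; va <- idx[261:300]
  cfg <- model_config(conv_filters = 4L, dense = 8L, max_passes = 8L,
                      seed = 28L)
  fit <- train_once(toy$x[, , tr], toy$y[tr], toy$x[, , va], toy$y[va], cfg)
  expect_gte(fit$metrics[["auc"]], 0.9)
  expect_true(all(fit$scores >= 0 & fit$scores <= 1))

  # same seed -> identical fit; different seed -> different weights
  fit2 <- train_once(toy$x[, , tr], toy$y[tr], toy$x[, , va], toy$y[va], cfg)
  expect_identical(fit$scores, fit2$scores)

  expect_error(train_once(toy$x[, , tr], rep(1L, 260), toy$x[, , va],
                          toy$y[va], cfg), "single class")
  expect_error(train_once(toy$x[, , tr] * 3, toy$y[tr], toy$x[, , va],
                          toy$y[va], cfg), "normalized")
})

test_that("shuffled labels put the decoder at chance level", {
  toy <- toy_images(150L, seed = 29L)
  aucs <- vapply(1:3, function(s) {
    y_sh <- withr::with_seed(30L + s, sample(toy$y))
    idx <- withr::with_seed(40L + s, sample(300L))
    tr <- idx[1:260]; va <- idx[261:300]
    cfg <- model_config(conv_filters = 4L, dense = 8L, max_passes = 4L,
                        seed = 50L + s)
    train_once(toy$x[, , tr], y_sh[tr], toy$x[, , va], y_sh[va],
               cfg)$metrics[["auc"]]
  }, numeric(1))
  expect_gt(mean(aucs), 0.3)
  expect_lt(mean(aucs), 0.7)
})

test_that("weakening the class effect does not improve decoding", {
  mean_auc <- vapply(c(0, 0.3, 0.8), function(strength) {
    aucs <- vapply(1:2, function(s) {
      toy <- toy_images(120L, strength = strength, seed = 60L + s)
      idx <- withr::with_seed(70L + s, sample(240L))
      tr <- idx[1:200]; va <- idx[201:240]
      cfg <- model_config(conv_filters = 4L, dense = 8L, max_passes = 6L,
                          seed = 80L + s)
      train_once(toy$x[, , tr], toy$y[tr], toy$x[, , va], toy$y[va],
                 cfg)$metrics[["auc"]]
    }, numeric(1))
    mean(aucs)
  }, numeric(1))
  expect_true(all(diff(mean_auc) > -0.05))
  expect_gt(mean_auc[3], mean_auc[1] + 0.2)
})

test_that("Monte-Carlo cross-validation is stratified, sized, and deterministic", {
  cfg <- quick_cfg()
  es <- simulate_epochs(cfg, "colour", 30L, seed = 90L)
  dec <- normalize_epochs(spatial_reorder(es))
  mcfg <- model_config(conv_filters = 2L, dense = 4L, max_passes = 1L,
                       batch = 32L)
  cv <- crossval(dec, k = 3L, cfg = mcfg, seed = 91L)
  expect_equal(nrow(cv$folds), 3L)
  expect_true(all(cv$folds$auc >= 0 & cv$folds$auc <= 1))
  expect_true(all(cv$folds$pr_auc >= 0 & cv$folds$pr_auc <= 1))
  expect_equal(cv$means[["auc"]], mean(cv$folds$auc))

  cv2 <- crossval(dec, k = 3L, cfg = mcfg, seed = 91L)
  expect_identical(cv$folds, cv2$folds)

  expect_error(crossval(dec, k = 1L, cfg = mcfg), "k")
  tiny <- subset_epochs(dec, 1:10)
  expect_error(crossval(tiny, k = 2L, cfg = mcfg), "at least 10")
  expect_error(crossval(es, k = 2L, cfg = mcfg), "normalized")
})

test_that("participant-wise splits hold out whole participants", {
  cfg <- quick_cfg(n_participants = 10L)
  es <- simulate_epochs(cfg, "colour", 40L, seed = 92L)
  dec <- normalize_epochs(es)
  mcfg <- model_config(conv_filters = 2L, dense = 4L, max_passes = 1L,
                       batch = 32L)
  cv <- crossval(dec, k = 2L, cfg = mcfg, seed = 93L, group_split = TRUE)
  expect_equal(nrow(cv$folds), 2L)
  expect_true(all(is.finite(cv$folds$auc)))
})
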
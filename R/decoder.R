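#' Decoder model configuration
#'
#' Hyper-parameters of the compact 2-D convolutional classifier: a stack of
#' conv blocks (3x3 kernels, ReLU, 2x2 average pooling), one dense hidden
#' layer, and a single sigmoid output trained with cross-entropy and Adam.
#' Early stopping monitors validation loss.
#'
#' @param conv_filters Integer vector, filters per conv block (>= 1 block).
#' @param kernel Square kernel size of every conv block.
#' @param dense Hidden units of the fully connected layer.
#' @param lr Adam learning rate.
#' @param batch Mini-batch size.
#' @param max_passes Maximum full passes over the training set.
#' @param patience Passes without validation-loss improvement before
#'   stopping.
#' @param seed Integer seed controlling initialization and batch order.
#' @return A `model_config` list.
#' @export
model_config <- function(conv_filters = c(8L, 16L), kernel = 3L,
                         dense = 32L, lr = 3e-3, batch = 64L,
                         max_passes = 12L, patience = 2L, seed = 1L) {
  if (length(conv_filters) < 1L) stopf("at least one conv block is required")
  cfg <- list(conv_filters = as.integer(conv_filters),
              kernel = assert_count(kernel, "kernel"),
              dense = assert_count(dense, "dense"),
              lr = lr,
              batch = assert_count(batch, "batch"),
              max_passes = assert_count(max_passes, "max_passes"),
              patience = assert_count(patience, "patience", min = 1L),
              seed = as.integer(seed))
  class(cfg) <- "model_config"
  cfg
}

check_decoder_inputs <- function(x, y) {
  stopifnot(is.array(x), length(dim(x)) == 3L, dim(x)[3] == length(y))
  rng <- range(x)
  if (rng[1] < 0 || rng[2] > 1) {
    stopf("decoder inputs must be min-max normalized to [0, 1] (range %g..%g)",
          rng[1], rng[2])
  }
  if (length(unique(y)) < 2L) stopf("training labels contain a single class")
}

#' Train the convolutional decoder once
#'
#' Fits one model on the training split by mini-batch gradient descent
#' (Adam, binary cross-entropy), evaluating the validation split after each
#' pass and early-stopping on validation loss. Deterministic for a fixed
#' seed.
#'
#' @param x_train,x_val Arrays `time x channels x n` of normalized epochs.
#' @param y_train,y_val Binary labels (0/1), both classes present in
#'   training.
#' @param cfg A [model_config()].
#' @return List: `params` (best weights), `scores` (validation
#'   probabilities), `metrics` (named AUC/accuracy/PR-AUC), `history`
#'   (per-pass train/val loss), `passes_run`.
#' @export
train_once <- function(x_train, y_train, x_val, y_val, cfg = model_config()) {
  check_decoder_inputs(x_train, y_train)
  stopifnot(length(y_val) == dim(x_val)[3])
  y_train <- as.numeric(y_train); y_val <- as.numeric(y_val)
  d <- dim(x_train)
  with_local_seed(cfg$seed, {
    params <- nn_init(cfg, d[1], d[2])
    state <- adam_init(params)
    n <- d[3]
    best <- list(loss = Inf, params = params)
    wait <- 0L
    history <- NULL
    passes <- 0L
    for (pass in seq_len(cfg$max_passes)) {
      passes <- pass
      idx <- sample.int(n)
      tr_loss <- 0; nb <- 0L
      for (s in seq(1L, n, cfg$batch)) {
        e <- min(s + cfg$batch - 1L, n)
        bi <- idx[s:e]
        fw <- nn_forward(params, cfg, x_train[, , bi, drop = FALSE],
                         cache = TRUE)
        tr_loss <- tr_loss + bce_loss(fw$prob, y_train[bi]); nb <- nb + 1L
        grads <- nn_backward(params, cfg, fw, y_train[bi])
        st <- adam_step(params, grads, state, cfg$lr)
        params <- st$params; state <- st$state
      }
      val_p <- nn_predict(params, cfg, x_val)
      val_loss <- bce_loss(val_p, y_val)
      history <- rbind(history,
                       data.frame(pass = pass, train_loss = tr_loss / nb,
                                  val_loss = val_loss))
      if (val_loss < best$loss - 1e-6) {
        best <- list(loss = val_loss, params = params)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= cfg$patience) break
      }
    }
    scores <- nn_predict(best$params, cfg, x_val)
    list(params = best$params,
         scores = scores,
         metrics = evaluate_scores(scores, y_val),
         history = tibble::as_tibble(history),
         passes_run = passes)
  })
}

#' Classifier metrics: ROC AUC, accuracy, PR-AUC
#'
#' AUC is computed from the rank statistic (probability that a positive
#' outscores a negative, ties counting half), accuracy at threshold 0.5,
#' and PR-AUC by step integration of the precision-recall curve over
#' decreasing score thresholds.
#'
#' @param scores Numeric scores in `[0, 1]`.
#' @param labels Binary labels (0/1 or logical); both classes present.
#' @return Named vector `auc`, `accuracy`, `pr_auc`.
#' @export
evaluate_scores <- function(scores, labels) {
  y <- as.integer(labels)
  if (!all(y %in% c(0L, 1L))) stopf("labels must be binary 0/1")
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) {
    stopf("metrics undefined: only one class present in labels")
  }
  r <- rank(scores)
  auc <- (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  accuracy <- mean((scores >= 0.5) == (y == 1L))
  # precision-recall step integration over unique thresholds (desc)
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]; ss <- scores[ord]
  grp_end <- cumsum(rle(ss)$lengths)      # last index of each tied block
  tp <- cumsum(ys)[grp_end]
  pos_seen <- grp_end
  precision <- tp / pos_seen
  recall <- tp / n1
  pr_auc <- sum(precision * diff(c(0, recall)))
  c(auc = auc, accuracy = accuracy, pr_auc = pr_auc)
}

#' Monte-Carlo cross-validation of the decoder
#'
#' Runs `k` independent random stratified 90/10 train/validation splits
#' (non-exhaustive cross-validation: fresh random split and fresh model
#' each repeat) and reports AUC, accuracy and PR-AUC per fold plus their
#' means. Class 2 is the positive class.
#'
#' @param es A normalized, class-balanced [epoch_set].
#' @param k Number of random splits (>= 2).
#' @param cfg A [model_config()].
#' @param seed Integer seed; fold seeds are derived from it.
#' @param val_frac Held-out fraction per split.
#' @param group_split If `TRUE`, splits are by participant (all epochs of a
#'   held-out participant go to validation), preventing leakage between
#'   train and validation; the default epoch-level split mirrors pooled
#'   single-epoch decoding and is optimistic in comparison.
#' @return A `cv_result`: list with `folds` (tibble fold x metric),
#'   `means`, `k`, `vdep`, `seed`.
#' @export
crossval <- function(es, k = 10L, cfg = model_config(), seed = 1L,
                     val_frac = 0.1, group_split = FALSE) {
  stopifnot(inherits(es, "epoch_set"))
  if (!es$normalized) stopf("decoder epochs must be normalized first")
  k <- assert_count(k, "k", min = 2L)
  y <- as.integer(es$meta$class == 2L)
  if (min(sum(y == 0L), sum(y == 1L)) < 10L) {
    stopf("need at least 10 epochs per class for cross-validation")
  }
  folds <- vector("list", k)
  for (f in seq_len(k)) {
    fseed <- derive_seed(seed, 100L + f)
    val_idx <- with_local_seed(fseed, {
      if (group_split) {
        parts <- unique(es$meta$participant)
        vi <- NULL
        for (attempt in seq_len(100L)) {
          hold <- sample(parts, max(1L, round(length(parts) * val_frac)))
          cand <- which(es$meta$participant %in% hold)
          if (length(unique(y[cand])) == 2L && length(cand) < length(y)) {
            vi <- cand
            break
          }
        }
        if (is.null(vi)) {
          stopf("could not form a participant-wise validation split containing both classes")
        }
        vi
      } else {
        c(sample(which(y == 0L), max(1L, round(sum(y == 0L) * val_frac))),
          sample(which(y == 1L), max(1L, round(sum(y == 1L) * val_frac))))
      }
    })
    tr_idx <- setdiff(seq_along(y), val_idx)
    fcfg <- cfg
    fcfg$seed <- derive_seed(seed, 200L + f)
    fit <- train_once(es$data[, , tr_idx, drop = FALSE], y[tr_idx],
                      es$data[, , val_idx, drop = FALSE], y[val_idx], fcfg)
    folds[[f]] <- tibble::tibble(
      fold = f,
      auc = fit$metrics[["auc"]],
      accuracy = fit$metrics[["accuracy"]],
      pr_auc = fit$metrics[["pr_auc"]],
      passes = fit$passes_run
    )
  }
  folds <- do.call(rbind, folds)
  structure(list(
    folds = folds,
    means = c(auc = mean(folds$auc), accuracy = mean(folds$accuracy),
              pr_auc = mean(folds$pr_auc)),
    k = k,
    vdep = unique(es$meta$vdep),
    seed = seed,
    group_split = group_split
  ), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s: %d random 90/10 splits%s\n",
              paste(x$vdep, collapse = "/"), x$k,
              if (x$group_split) " (participant-wise)" else ""))
  cat(sprintf("  mean AUC %.4f, accuracy %.4f, PR-AUC %.4f\n",
              x$means[["auc"]], x$means[["accuracy"]], x$means[["pr_auc"]]))
  invisible(x)
}
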
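# Shared fixtures: everything is generated in code at test time.

# Small, fast simulation config for structural tests.
quick_cfg <- function(...) {
  args <- list(...)
  defaults <- list(n_participants = 2L, n_videos = 3L, n_trials = 4L,
                   seed = 11L)
  do.call(sim_config, utils::modifyList(defaults, args))
}

# Build an expert tag tibble for one design dimension from a label vector
# (one label per second of one video).
tagset <- function(labels, vdep = "colour", video = 1L, expert = 1L) {
  tibble::tibble(
    video_id = video,
    second = seq_along(labels) - 1L,
    vdep = vdep,
    expert_id = expert,
    label = as.character(labels)
  )
}

# Resolved timeline built directly from per-second classes (NA = discarded).
timeline_from_classes <- function(classes, vdep = "colour", video = 1L) {
  keep <- !is.na(classes)
  structure(list(
    timeline = tibble::tibble(
      video_id = video,
      second = which(keep) - 1L,
      vdep = vdep,
      class = as.integer(classes[keep])
    ),
    discarded = tibble::tibble(
      video_id = video,
      second = which(!keep) - 1L,
      vdep = vdep,
      reason = rep("unclear", sum(!keep))
    )
  ), class = "resolved_timeline")
}

# Independent band-power oracle: periodogram integration over [lo, hi),
# excluding DC and Nyquist, both conjugate halves folded in.
pgram_band_power <- function(x, lo, hi, fs) {
  n <- length(x)
  X <- stats::fft(x)
  k <- 0:(n - 1)
  f <- pmin(k, n - k) * fs / n
  use <- f >= lo & f < hi
  use[1] <- FALSE
  if (n %% 2 == 0) use[n / 2 + 1] <- FALSE
  sum(Mod(X[use])^2) / n^2
}

# Brute-force Mann-Whitney U by pair counting (wins + half ties).
pair_count_U <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

# Exact two-sided rank-sum p by enumeration of all C(n1+n2, n1) group
# assignments (tie-free samples only).
enumerate_p <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  stopifnot(!any(duplicated(pooled)))
  u_obs <- pair_count_U(x, y)
  combs <- utils::combn(length(pooled), n1)
  us <- apply(combs, 2, function(ix) {
    pair_count_U(pooled[ix], pooled[-ix])
  })
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Brute-force epoch-count enumerator: walk each interval second by second
# and count interior 1-s windows surviving the 0.5-s end trims.
enumerate_epoch_count <- function(iv, n_participants) {
  total <- 0L
  for (i in seq_len(nrow(iv))) {
    L <- iv$end_second[i] - iv$start_second[i]
    n_win <- 0L
    # windows start at interval_start + 0.5 + j, must end by interval_end - 0.5
    j <- 0L
    while (iv$start_second[i] + 0.5 + j + 1 <= iv$end_second[i] - 0.5) {
      n_win <- n_win + 1L
      j <- j + 1L
    }
    total <- total + n_win
  }
  total * n_participants
}

# Random interval set within a video grid (no overlap within a video).
random_interval_set <- function(n_videos = 3L, vdep = "colour",
                                max_seconds = 60L) {
  out <- list()
  for (v in seq_len(n_videos)) {
    s <- 0L
    while (s < max_seconds - 1L) {
      len <- sample(1:7, 1L)
      if (s + len > max_seconds) break
      if (stats::runif(1) < 0.7) {
        out[[length(out) + 1L]] <- tibble::tibble(
          video_id = v, start_second = s, end_second = s + len,
          class = sample(1:2, 1L))
      }
      s <- s + len + sample(0:2, 1L)
    }
  }
  iv <- do.call(rbind, out)
  attr(iv, "vdep") <- vdep
  class(iv) <- c("interval_set", class(iv))
  iv
}

# Tiny separable image data for decoder unit tests: class 1 has a bright
# patch top-left, class 0 bottom-right, plus noise; values clipped to
# [0, 1].
toy_images <- function(n_per_class, H = 16L, W = 8L, strength = 0.6,
                       seed = 1L) {
  n <- 2L * n_per_class
  y <- rep(c(0L, 1L), n_per_class)
  withr::with_seed(seed, {
    X <- array(stats::runif(H * W * n, 0, 0.4), c(H, W, n))
    for (i in seq_len(n)) {
      if (y[i] == 1L) {
        X[1:4, 1:3, i] <- X[1:4, 1:3, i] + strength
      } else {
        X[(H - 3):H, (W - 2):W, i] <- X[(H - 3):H, (W - 2):W, i] + strength
      }
    }
    list(x = pmin(X, 1), y = y)
  })
}
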
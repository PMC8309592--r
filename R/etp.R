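# Extraction-transformation process: tagged video seconds -> labelled 1-s
# epochs (fs x 32 matrices), skipping the pre-trial baseline, dropping
# peripheral channels, trimming interval ends, and (for the decoder path)
# min-max normalizing.

#' Epoch set container
#'
#' Holds one-second EEG epochs as an `fs x n_channels x n_epochs` array plus
#' a metadata tibble (`epoch_id`, `participant`, `video`, `second`, `vdep`,
#' `class`).
#'
#' @param data Numeric array, `fs x n_channels x n_epochs`.
#' @param meta Metadata tibble with one row per epoch.
#' @param fs Sampling rate in Hz.
#' @param normalized Logical: have epochs been min-max normalized?
#' @return An object of class `epoch_set`.
#' @export
new_epoch_set <- function(data, meta, fs, normalized = FALSE) {
  stopifnot(is.array(data), length(dim(data)) == 3L,
            nrow(meta) == dim(data)[3])
  structure(list(data = data, meta = meta, fs = fs, normalized = normalized),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d epochs of %d x %d (%s, %snormalized)\n",
              d[3], d[1], d[2],
              paste(unique(x$meta$vdep), collapse = "/"),
              if (x$normalized) "" else "un-"))
  if (d[3] > 0) {
    tab <- table(x$meta$class)
    cat("  classes:", paste(sprintf("%s: %d", names(tab), tab),
                            collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
length.epoch_set <- function(x) dim(x$data)[3]

#' Sample range of a tagged video second
#'
#' Maps a 0-based video second to the half-open 0-based sample range it
#' occupies in a trial, accounting for the pre-trial baseline: second `s`
#' occupies samples `[(s + baseline) * fs, (s + baseline + 1) * fs)`.
#'
#' @param second 0-based second index within the video (0-59 by default).
#' @param fs Sampling rate in Hz.
#' @param baseline_s Pre-trial baseline length in seconds.
#' @param video_s Video length in seconds (upper bound for `second`).
#' @return Integer vector `c(start, end)`, half-open, 0-based.
#' @export
map_second_to_samples <- function(second, fs = 128L, baseline_s = 3L,
                                  video_s = 60L) {
  if (!is.numeric(second) || length(second) != 1L || is.na(second) ||
      second != floor(second) || second < 0 || second >= video_s) {
    stopf("second must be an integer in [0, %d)", video_s)
  }
  start <- (second + baseline_s) * fs
  c(start = as.integer(start), end = as.integer(start + fs))
}

#' Extract labelled one-second epochs from recordings
#'
#' For every interval of `L` whole seconds and every participant, trims
#' 0.5 s from each end and splits the remainder into `L - 1` contiguous
#' non-overlapping one-second epochs, keeping only the EEG channels. Each
#' epoch inherits the interval's class; its `second` metadata is the tagged
#' second in which the epoch starts. Intervals referencing trials outside
#' the recording set are skipped with a warning; intervals shorter than 2 s
#' yield no epochs.
#'
#' @param rec A `recording_set` (see [make_recordings()] or
#'   [read_recordings()]).
#' @param iv An `interval_set` from [build_intervals()].
#' @param participants Participant indices to use (default all).
#' @param n_channels_eeg EEG channels retained (leading channels).
#' @return An un-normalized [epoch_set].
#' @export
extract_epochs <- function(rec, iv, participants = NULL,
                           n_channels_eeg = 32L) {
  stopifnot(inherits(rec, "recording_set"))
  vdep <- attr(iv, "vdep")
  fs <- rec$fs
  participants <- participants %||% seq_along(rec$data)
  n_trials <- dim(rec$data[[1]])[1]
  half <- fs %/% 2L

  keep <- iv$video_id <= n_trials & iv$video_id <= rec$n_videos
  if (any(!keep)) {
    warning(sprintf("skipping %d interval(s) referencing untagged or missing trials",
                    sum(!keep)), call. = FALSE)
    iv <- iv[keep, ]
  }

  n_ep_per_iv <- pmax(iv$end_second - iv$start_second - 1L, 0L)
  total <- sum(n_ep_per_iv) * length(participants)
  dat <- array(0, dim = c(fs, n_channels_eeg, total))
  meta <- vector("list", total)
  k <- 0L
  for (i in seq_len(nrow(iv))) {
    n_ep <- n_ep_per_iv[i]
    if (n_ep == 0L) next
    v <- iv$video_id[i]
    # 0-based sample offset of the interval start, plus the 0.5-s trim
    base <- map_second_to_samples(iv$start_second[i], fs, rec$baseline_s)[["start"]]
    for (p in participants) {
      trial <- rec$data[[p]][v, seq_len(n_channels_eeg), , drop = TRUE]
      for (j in seq_len(n_ep)) {
        s0 <- base + half + (j - 1L) * fs          # 0-based epoch start
        k <- k + 1L
        dat[, , k] <- t(trial[, (s0 + 1L):(s0 + fs)])
        meta[[k]] <- tibble::tibble(
          epoch_id = k,
          participant = p,
          video = v,
          second = iv$start_second[i] + (j - 1L),
          vdep = vdep,
          class = iv$class[i]
        )
      }
    }
  }
  meta <- if (k > 0) do.call(rbind, meta[seq_len(k)]) else
    tibble::tibble(epoch_id = integer(), participant = integer(),
                   video = integer(), second = integer(),
                   vdep = character(), class = integer())
  new_epoch_set(dat[, , seq_len(k), drop = FALSE], meta, fs = fs,
                normalized = FALSE)
}

#' Min-max normalize an epoch matrix
#'
#' Maps every value of the epoch matrix to `[0, 1]` via
#' `(x - min(X)) / (max(X) - min(X))` where `X` is the whole
#' time-by-channel matrix (all channels jointly). A constant epoch maps to
#' all zeros with a warning.
#'
#' @param e Numeric matrix (time x channels).
#' @param per_channel Normalize each channel column separately instead of
#'   the whole matrix jointly.
#' @return Matrix of the same shape with values in `[0, 1]`.
#' @export
normalize_epoch <- function(e, per_channel = FALSE) {
  stopifnot(is.matrix(e), is.numeric(e))
  norm1 <- function(x) {
    rng <- range(x)
    if (rng[1] == rng[2]) {
      warning("degenerate constant epoch: normalized to all zeros",
              call. = FALSE)
      return(array(0, dim = dim(x)))
    }
    (x - rng[1]) / (rng[2] - rng[1])
  }
  if (per_channel) apply(e, 2L, norm1) else norm1(e)
}

#' Min-max normalize every epoch of a set
#'
#' Applies [normalize_epoch()] to each epoch; refuses to normalize twice.
#'
#' @param es An [epoch_set].
#' @inheritParams normalize_epoch
#' @return The normalized `epoch_set`.
#' @export
normalize_epochs <- function(es, per_channel = FALSE) {
  stopifnot(inherits(es, "epoch_set"))
  if (es$normalized) stopf("epoch set is already normalized")
  n <- length(es)
  for (i in seq_len(n)) {
    es$data[, , i] <- normalize_epoch(es$data[, , i], per_channel)
  }
  es$normalized <- TRUE
  es
}

#' Balance an epoch set across classes
#'
#' Sub-samples the larger class down to the smaller class size `n_v`. With
#' `by = "second"` whole (video, second) groups are kept or dropped so the
#' per-second structure survives (this balances epoch-yielding seconds);
#' with `by = "epoch"` individual epochs are sampled.
#'
#' @param es An [epoch_set].
#' @param seed Integer seed for the sub-sample.
#' @param by `"second"` or `"epoch"`.
#' @return A balanced `epoch_set`.
#' @export
balance_epochs <- function(es, seed = NULL, by = c("second", "epoch")) {
  stopifnot(inherits(es, "epoch_set"))
  by <- match.arg(by)
  m <- es$meta
  if (by == "second" && !anyNA(m$video)) {
    grp <- paste(m$video, m$second, sep = "\r")
    gcls <- tapply(m$class, grp, function(x) x[1])
    g1 <- names(gcls)[gcls == 1L]; g2 <- names(gcls)[gcls == 2L]
    if (!length(g1) || !length(g2)) stopf("a class has no epochs to balance")
    n_v <- min(length(g1), length(g2))
    keep_g <- with_local_seed(seed, {
      c(if (length(g1) > n_v) sample(g1, n_v) else g1,
        if (length(g2) > n_v) sample(g2, n_v) else g2)
    })
    idx <- which(grp %in% keep_g)
  } else {
    i1 <- which(m$class == 1L); i2 <- which(m$class == 2L)
    if (!length(i1) || !length(i2)) stopf("a class has no epochs to balance")
    n_v <- min(length(i1), length(i2))
    idx <- with_local_seed(seed, {
      sort(c(if (length(i1) > n_v) sample(i1, n_v) else i1,
             if (length(i2) > n_v) sample(i2, n_v) else i2))
    })
  }
  subset_epochs(es, sort(idx))
}

#' Subset an epoch set by epoch index
#' @param es An [epoch_set].
#' @param idx Integer indices of epochs to keep.
#' @return The reduced `epoch_set`.
#' @export
subset_epochs <- function(es, idx) {
  new_epoch_set(es$data[, , idx, drop = FALSE], es$meta[idx, ],
                fs = es$fs, normalized = es$normalized)
}
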
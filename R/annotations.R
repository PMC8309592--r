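#' Resolve two experts' tags into a single timeline
#'
#' A (video, second, dimension) is kept iff both experts gave the same
#' non-"unclear" label. Discarded seconds are retained with a reason:
#' `"unclear"` if either expert was unclear, `"disagreement"` otherwise.
#'
#' @param a,b Tag tibbles for expert 1 and 2 (see [make_expert_tags()] for
#'   the schema). Both must cover exactly the same (video, second, vdep)
#'   keys.
#' @return A `resolved_timeline`: list with `timeline` (tibble `video_id`,
#'   `second`, `vdep`, `class`) and `discarded` (same keys plus `reason`).
#' @export
resolve_tags <- function(a, b) {
  need <- c("video_id", "second", "vdep", "label")
  if (!all(need %in% names(a)) || !all(need %in% names(b))) {
    stopf("tag sets must have columns %s", paste(need, collapse = ", "))
  }
  key <- function(d) paste(d$video_id, d$second, d$vdep, sep = "\r")
  ka <- key(a); kb <- key(b)
  if (anyDuplicated(ka) || anyDuplicated(kb)) {
    stopf("duplicate (video, second, vdep) records within one expert's tags")
  }
  if (length(ka) != length(kb) || !setequal(ka, kb)) {
    stopf("expert tag sets cover different (video, second, vdep) keys")
  }
  b <- b[match(ka, kb), ]
  unclear <- a$label == "unclear" | b$label == "unclear"
  agree <- !unclear & a$label == b$label
  timeline <- tibble::tibble(
    video_id = a$video_id[agree],
    second = a$second[agree],
    vdep = a$vdep[agree],
    class = as.integer(a$label[agree])
  )
  disc <- !agree
  discarded <- tibble::tibble(
    video_id = a$video_id[disc],
    second = a$second[disc],
    vdep = a$vdep[disc],
    reason = ifelse(unclear[disc], "unclear", "disagreement")
  )
  structure(list(timeline = timeline, discarded = discarded),
            class = "resolved_timeline")
}

#' @export
print.resolved_timeline <- function(x, ...) {
  cat(sprintf("<resolved_timeline> %d kept seconds, %d discarded (%d unclear, %d disagreement)\n",
              nrow(x$timeline), nrow(x$discarded),
              sum(x$discarded$reason == "unclear"),
              sum(x$discarded$reason == "disagreement")))
  invisible(x)
}

#' Maximal constant-class intervals of a resolved timeline
#'
#' Builds, for one design dimension, the maximal runs of consecutive
#' resolved seconds sharing a class within each video. Discarded seconds
#' break runs; intervals are half-open in seconds.
#'
#' @param t A `resolved_timeline`.
#' @param vdep The design dimension to extract.
#' @return An `interval_set`: tibble `video_id`, `start_second`,
#'   `end_second` (half-open), `class`, with attribute `vdep`.
#' @export
build_intervals <- function(t, vdep) {
  stopifnot(inherits(t, "resolved_timeline"))
  vdep <- match.arg(vdep, VDEPS)
  tl <- t$timeline[t$timeline$vdep == vdep, ]
  out <- list()
  for (v in sort(unique(tl$video_id))) {
    d <- tl[tl$video_id == v, ]
    d <- d[order(d$second), ]
    if (nrow(d) == 0) next
    # new run when seconds are non-consecutive or the class changes
    brk <- c(TRUE, diff(d$second) != 1L | diff(d$class) != 0L)
    run <- cumsum(brk)
    for (r in unique(run)) {
      sec <- d$second[run == r]
      out[[length(out) + 1L]] <- tibble::tibble(
        video_id = v,
        start_second = min(sec),
        end_second = max(sec) + 1L,
        class = d$class[run == r][1]
      )
    }
  }
  iv <- if (length(out)) do.call(rbind, out) else
    tibble::tibble(video_id = integer(), start_second = integer(),
                   end_second = integer(), class = integer())
  attr(iv, "vdep") <- vdep
  class(iv) <- c("interval_set", class(iv))
  iv
}

#' Per-dimension class counts (annotation summary)
#'
#' Counts resolved seconds per class and discarded seconds for each design
#' dimension, and reports `n_v`, the size of the smaller class, which is
#' the sub-sampling target for balancing.
#'
#' @param t A `resolved_timeline`.
#' @return Tibble with one row per dimension: `vdep`, `n_class1`,
#'   `n_class2`, `n_unclear`, `n_disagreement`, `n_discarded`, `total`,
#'   `n_v`.
#' @export
count_classes <- function(t) {
  stopifnot(inherits(t, "resolved_timeline"))
  rows <- lapply(VDEPS, function(vd) {
    tl <- t$timeline[t$timeline$vdep == vd, ]
    dc <- t$discarded[t$discarded$vdep == vd, ]
    n1 <- sum(tl$class == 1L)
    n2 <- sum(tl$class == 2L)
    tibble::tibble(
      vdep = vd,
      n_class1 = n1,
      n_class2 = n2,
      n_unclear = sum(dc$reason == "unclear"),
      n_disagreement = sum(dc$reason == "disagreement"),
      n_discarded = nrow(dc),
      total = n1 + n2 + nrow(dc),
      n_v = min(n1, n2)
    )
  })
  do.call(rbind, rows)
}

#' Balance a timeline's classes by sub-sampling
#'
#' For one design dimension, sub-samples the larger class uniformly without
#' replacement down to `n_v`, the size of the smaller class, so both
#' classes contribute equally many seconds.
#'
#' @param t A `resolved_timeline`.
#' @param vdep Design dimension to balance.
#' @param seed Integer seed for the sub-sample draw.
#' @return A `resolved_timeline` containing only `vdep` rows, with exactly
#'   `n_v` seconds per class; discards are passed through.
#' @export
balance_seconds <- function(t, vdep, seed = NULL) {
  stopifnot(inherits(t, "resolved_timeline"))
  vdep <- match.arg(vdep, VDEPS)
  tl <- t$timeline[t$timeline$vdep == vdep, ]
  n1 <- sum(tl$class == 1L); n2 <- sum(tl$class == 2L)
  if (n1 == 0L || n2 == 0L) {
    stopf("cannot balance '%s': class %d has no resolved seconds",
          vdep, if (n1 == 0L) 1L else 2L)
  }
  n_v <- min(n1, n2)
  keep <- with_local_seed(seed, {
    i1 <- which(tl$class == 1L); i2 <- which(tl$class == 2L)
    sort(c(
      if (n1 > n_v) sample(i1, n_v) else i1,
      if (n2 > n_v) sample(i2, n_v) else i2
    ))
  })
  structure(
    list(timeline = tl[keep, ],
         discarded = t$discarded[t$discarded$vdep == vdep, ]),
    class = "resolved_timeline"
  )
}
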
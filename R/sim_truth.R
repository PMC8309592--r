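#' Latent per-second design classes for the annotated videos
#'
#' Draws the ground-truth class timeline that the simulated experts will
#' observe: for each annotated video and each of the four design dimensions
#' (colour, balance, movement, light), every tagged second gets a class in
#' \{1, 2\}. Classes change in contiguous runs whose lengths are geometric
#' with mean `cfg$mean_run_s`, and consecutive runs alternate class, so
#' interval construction downstream is non-trivial.
#'
#' @param cfg A [sim_config()].
#' @return A tibble with columns `video`, `second` (0-based), `vdep`,
#'   `class` (integer 1/2), one row per (video, second, vdep);
#'   `n_videos * tagged seconds` rows per dimension.
#' @export
make_truth <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n_sec <- tagged_seconds(cfg)
  p <- 1 / cfg$mean_run_s
  if (!is.finite(p) || p <= 0 || p > 1) {
    stopf("invalid run-length parameter: mean_run_s = %s", cfg$mean_run_s)
  }
  with_local_seed(derive_seed(cfg$seed, 1L), {
    rows <- vector("list", length(VDEPS) * cfg$n_videos)
    k <- 0L
    for (vd in VDEPS) {
      for (v in seq_len(cfg$n_videos)) {
        cls <- integer(0)
        cur <- sample(1:2, 1L)
        while (length(cls) < n_sec) {
          len <- 1L + stats::rgeom(1L, p)
          cls <- c(cls, rep(cur, len))
          cur <- 3L - cur
        }
        k <- k + 1L
        rows[[k]] <- tibble::tibble(
          video = v,
          second = seq_len(n_sec) - 1L,
          vdep = vd,
          class = cls[seq_len(n_sec)]
        )
      }
    }
    truth <- do.call(rbind, rows)
    attr(truth, "n_videos") <- cfg$n_videos
    attr(truth, "n_seconds") <- n_sec
    truth
  })
}
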
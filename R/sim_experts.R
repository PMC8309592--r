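#' Simulate two expert annotators
#'
#' Each expert independently reports, for every (video, second, dimension)
#' in `truth`: "unclear" with probability `cfg$annot_unclear`; otherwise the
#' true class with probability `cfg$annot_agreement`, else the wrong class.
#'
#' Under this corruption model the probability that a second survives
#' two-expert resolution (both non-unclear and equal) is
#' `(1 - u)^2 * (a^2 + (1 - a)^2)`.
#'
#' @param cfg A [sim_config()].
#' @param truth Output of [make_truth()].
#' @return A list of two tag tibbles (one per expert) with columns
#'   `video_id`, `second`, `vdep`, `expert_id`, `label` where `label` is
#'   `"1"`, `"2"` or `"unclear"`.
#' @export
make_expert_tags <- function(cfg, truth) {
  stopifnot(inherits(cfg, "sim_config"))
  a <- cfg$annot_agreement
  u <- cfg$annot_unclear
  with_local_seed(derive_seed(cfg$seed, 4L), {
    lapply(1:2, function(ex) {
      n <- nrow(truth)
      unclear <- stats::runif(n) < u
      correct <- stats::runif(n) < a
      lab <- ifelse(correct, truth$class, 3L - truth$class)
      tibble::tibble(
        video_id = truth$video,
        second = truth$second,
        vdep = truth$vdep,
        expert_id = ex,
        label = ifelse(unclear, "unclear", as.character(lab))
      )
    })
  })
}
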
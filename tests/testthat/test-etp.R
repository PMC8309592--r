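# Ramp-valued recording set: sample s (0-based) has value s on every
# channel, so extracted epochs reveal exactly which samples they took.
ramp_recording <- function(n_participants = 1L, n_trials = 1L) {
  n_samples <- 63L * 128L
  arr <- array(rep(0:(n_samples - 1L), each = n_trials * 40L),
               dim = c(n_trials, 40L, n_samples))
  structure(list(
    data = replicate(n_participants, arr, simplify = FALSE),
    fs = 128L, channel_names = paste0("ch", 1:40),
    n_videos = n_trials, n_trials = n_trials,
    baseline_s = 3L, trial_duration_s = 63L
  ), class = "recording_set")
}

interval_set <- function(video, start, end, class = 1L, vdep = "colour") {
  iv <- tibble::tibble(video_id = video, start_second = start,
                       end_second = end, class = class)
  attr(iv, "vdep") <- vdep
  class(iv) <- c("interval_set", class(iv))
  iv
}

test_that("video seconds map to baseline-shifted half-open sample ranges", {
  expect_equal(unname(map_second_to_samples(0L)), c(384L, 512L))
  expect_equal(unname(map_second_to_samples(59L)), c(7936L, 8064L))
  expect_error(map_second_to_samples(60L), "\\[0, 60\\)")
  expect_error(map_second_to_samples(-1L), "\\[0, 60\\)")
})

test_that("a 5-s interval yields 4 trimmed epochs with the exact expected samples", {
  rec <- ramp_recording()
  iv <- interval_set(1L, 2L, 7L)
  es <- extract_epochs(rec, iv)
  expect_equal(length(es), 4L)
  expect_equal(dim(es$data)[1:2], c(128L, 32L))
  # interval starts at sample (2+3)*128 = 640; first epoch starts 0.5 s later
  expect_equal(es$data[, 1, 1], 704:831)
  expect_equal(es$data[, 32, 4], 1088:1215)
  expect_equal(es$meta$second, 2:5)
  expect_true(all(es$meta$class == 1L))
  # nothing from the 3-s baseline (samples < 384)
  expect_true(min(es$data) >= 384)
})

test_that("short intervals yield no epochs and each annotated second yields one epoch per participant", {
  rec1 <- ramp_recording()
  expect_equal(length(extract_epochs(rec1, interval_set(1L, 4L, 5L))), 0L)

  rec8 <- ramp_recording(n_participants = 8L)
  es <- extract_epochs(rec8, interval_set(1L, 10L, 12L))
  expect_equal(length(es), 8L)                 # 2-s interval: 1 epoch each
  expect_setequal(es$meta$participant, 1:8)
  expect_true(all(es$meta$second == 10L))
})

test_that("intervals referencing untagged trials are skipped with a warning", {
  rec <- ramp_recording(n_trials = 2L)
  rec$n_videos <- 1L                           # trial 2 is unannotated filler
  iv <- rbind(interval_set(1L, 0L, 5L), interval_set(2L, 0L, 5L))
  attr(iv, "vdep") <- "colour"
  expect_warning(es <- extract_epochs(rec, iv), "untagged")
  expect_equal(length(es), 4L)
  expect_true(all(es$meta$video == 1L))
})

test_that("epoch totals equal the brute-force per-second enumerator on random interval sets", {
  rec <- ramp_recording(n_participants = 3L, n_trials = 3L)
  withr::with_seed(99, {
    for (rep in 1:25) {
      iv <- random_interval_set(n_videos = 3L)
      es <- extract_epochs(rec, iv)
      expect_equal(length(es), enumerate_epoch_count(iv, 3L))
    }
  })
})

test_that("min-max normalization matches the closed form and pins the range", {
  m <- matrix(c(0, 10, 5, 5), 2, 2)
  expect_equal(normalize_epoch(m), matrix(c(0, 1, 0.5, 0.5), 2, 2))
  withr::with_seed(5, {
    e <- matrix(rnorm(128 * 32), 128, 32)
    ne <- normalize_epoch(e)
    expect_equal(range(ne), c(0, 1))
    # affine invariance: a*x + b (a > 0) normalizes identically
    expect_equal(normalize_epoch(3.7 * e + 11), ne)
    # idempotence
    expect_equal(normalize_epoch(ne), ne)
  })
  expect_warning(z <- normalize_epoch(matrix(2, 4, 4)), "degenerate")
  expect_true(all(z == 0))
})

test_that("epoch-set normalization sets the flag once and refuses a second pass", {
  rec <- ramp_recording()
  es <- extract_epochs(rec, interval_set(1L, 0L, 6L))
  ne <- normalize_epochs(es)
  expect_true(ne$normalized)
  expect_true(all(ne$data >= 0 & ne$data <= 1))
  expect_error(normalize_epochs(ne), "already normalized")
})

test_that("epoch balancing equalizes classes at the second or epoch level", {
  rec <- ramp_recording(n_participants = 2L)
  iv <- rbind(interval_set(1L, 0L, 12L, class = 1L),
              interval_set(1L, 20L, 25L, class = 2L))
  attr(iv, "vdep") <- "colour"
  es <- extract_epochs(rec, iv)       # 11 vs 4 seconds x 2 participants
  bal <- balance_epochs(es, seed = 3L)
  expect_equal(sum(bal$meta$class == 1L), sum(bal$meta$class == 2L))
  expect_equal(length(bal), 2L * 2L * 4L)
  bal_e <- balance_epochs(es, seed = 3L, by = "epoch")
  expect_equal(sum(bal_e$meta$class == 1L), sum(bal_e$meta$class == 2L))
})
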
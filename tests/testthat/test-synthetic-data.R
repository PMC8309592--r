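test_that("truth timeline covers every tagged second and is seed-deterministic", {
  cfg <- sim_config(n_participants = 1L, n_videos = 26L, seed = 3L)
  truth <- make_truth(cfg)
  # 26 one-minute videos -> 1560 (video, second) pairs per dimension
  for (vd in c("colour", "balance", "movement", "light")) {
    tv <- truth[truth$vdep == vd, ]
    expect_equal(nrow(tv), 1560L)
    expect_setequal(unique(tv$second), 0:59)
    expect_true(all(tv$class %in% 1:2))
  }
  expect_identical(make_truth(cfg), truth)
  cfg2 <- sim_config(n_participants = 1L, n_videos = 26L, seed = 4L)
  expect_false(identical(make_truth(cfg2), truth))
})

test_that("latent run lengths follow the geometric law", {
  cfg <- sim_config(n_participants = 1L, n_videos = 300L, n_trials = 300L,
                    mean_run_s = 2, seed = 21L)
  truth <- make_truth(cfg)
  tv <- truth[truth$vdep == "colour", ]
  lens <- unlist(lapply(split(tv, tv$video), function(d) {
    r <- rle(d$class[order(d$second)])$lengths
    # last run is censored by the video end; drop it
    r[-length(r)]
  }))
  p <- 1 / 2
  n <- length(lens)
  expect_gt(n, 3000)
  for (k in 1:3) {
    expected <- p * (1 - p)^(k - 1)
    se <- sqrt(expected * (1 - expected) / n)
    expect_lt(abs(mean(lens == k) - expected), 4 * se + 1e-3)
  }
})

test_that("recordings have the DEAP array shape with filler trials and a clean baseline", {
  cfg <- quick_cfg(seed = 7L)
  truth <- make_truth(cfg)
  rec <- make_recordings(cfg, truth)
  expect_length(rec$data, 2L)
  expect_equal(dim(rec$data[[1]]), c(4L, 40L, 63L * 128L))
  expect_equal(dim(rec$data[[2]]), dim(rec$data[[1]]))
  expect_equal(rec$fs, 128L)
  expect_length(rec$channel_names, 40L)
  # deterministic under the same config + seed
  rec2 <- make_recordings(cfg, truth)
  expect_identical(rec$data, rec2$data)
})

test_that("doubling a band's amplitude gain quadruples that band's power", {
  # power scales with amplitude squared; periodogram oracle over many epochs
  cfg <- sim_config(
    n_participants = 1L, noise_sd = 0.05,
    osc_amp = c(alpha = 1),
    band_gains = list(colour = list("1" = c(alpha = 2), "2" = c(alpha = 1))),
    seed = 31L
  )
  es <- simulate_epochs(cfg, "colour", n_per_class = 300L, seed = 32L)
  p_alpha <- vapply(seq_len(length(es)), function(i) {
    pgram_band_power(es$data[, 1, i], 8, 13, es$fs)
  }, numeric(1))
  ratio <- mean(p_alpha[es$meta$class == 1L]) / mean(p_alpha[es$meta$class == 2L])
  expect_lt(abs(ratio - 4), 0.25)
})

test_that("equal gains for both classes give equal band powers (null effect)", {
  cfg <- sim_config(n_participants = 1L, band_gains = list(), seed = 41L)
  es <- simulate_epochs(cfg, "light", n_per_class = 200L, seed = 42L)
  bp <- band_power_table(es)
  for (b in c("delta", "theta", "alpha", "beta", "gamma")) {
    r <- mean(bp[[b]][bp$class == 1L]) / mean(bp[[b]][bp$class == 2L])
    expect_lt(abs(r - 1), 0.15)
  }
})

test_that("larger gains strictly increase the injected band's mean power", {
  powers <- vapply(c(1, 1.4, 2), function(g) {
    cfg <- sim_config(
      n_participants = 1L,
      band_gains = list(colour = list("1" = c(beta = g))),
      seed = 51L
    )
    es <- simulate_epochs(cfg, "colour", n_per_class = 250L, seed = 52L)
    bp <- band_power_table(es)
    mean(bp$beta[bp$class == 1L])
  }, numeric(1))
  expect_true(all(diff(powers) > 0))
})

test_that("expert tags reproduce the truth in the noiseless limit and degrade as configured", {
  cfg <- quick_cfg(annot_agreement = 1, annot_unclear = 0)
  truth <- make_truth(cfg)
  tags <- make_expert_tags(cfg, truth)
  expect_identical(tags[[1]]$label, as.character(truth$class))
  expect_identical(tags[[2]]$label, as.character(truth$class))

  cfg_u <- quick_cfg(annot_agreement = 1, annot_unclear = 1)
  tags_u <- make_expert_tags(cfg_u, make_truth(cfg_u))
  res_u <- resolve_tags(tags_u[[1]], tags_u[[2]])
  expect_equal(nrow(res_u$timeline), 0L)
})

test_that("discard fraction after resolution matches the closed-form corruption model", {
  a <- 0.9; u <- 0.05
  cfg <- sim_config(n_participants = 1L, n_videos = 420L, n_trials = 420L,
                    annot_agreement = a, annot_unclear = u, seed = 61L)
  truth <- make_truth(cfg)
  tags <- make_expert_tags(cfg, truth)
  res <- resolve_tags(tags[[1]], tags[[2]])
  n <- nrow(truth)                        # ~100k (video, second, vdep) keys
  p_keep <- (1 - u)^2 * (a^2 + (1 - a)^2)
  p_discard <- 1 - p_keep
  emp <- nrow(res$discarded) / n
  se <- sqrt(p_discard * (1 - p_discard) / n)
  expect_lt(abs(emp - p_discard), 4 * se)
})
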
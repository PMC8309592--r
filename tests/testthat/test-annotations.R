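test_that("resolution keeps agreements and discards unclear or conflicting seconds", {
  a <- tagset(c("2", "1", "unclear", "1", "unclear"))
  b <- tagset(c("2", "2", "unclear", "1", "1"), expert = 2L)
  res <- resolve_tags(a, b)
  # (warm, warm) kept as class 2
  expect_equal(res$timeline$class[res$timeline$second == 0L], 2L)
  # (cold, warm) discarded as disagreement
  expect_equal(res$discarded$reason[res$discarded$second == 1L], "disagreement")
  # both unclear, and one-sided unclear, discarded as unclear
  expect_equal(res$discarded$reason[res$discarded$second == 2L], "unclear")
  expect_equal(res$discarded$reason[res$discarded$second == 4L], "unclear")
  expect_equal(sort(res$timeline$second), c(0L, 3L))
})

test_that("resolution rejects mismatched or duplicated tag keys", {
  a <- tagset(c("1", "2"))
  expect_error(resolve_tags(a, tagset(c("1", "2", "1"), expert = 2L)),
               "different")
  dup <- rbind(a, a[1, ])
  expect_error(resolve_tags(dup, dup), "duplicate")
})

test_that("intervals are maximal constant-class runs broken by gaps", {
  t1 <- timeline_from_classes(c(1, 1, 1, 1, 1))
  iv1 <- build_intervals(t1, "colour")
  expect_equal(nrow(iv1), 1L)
  expect_equal(c(iv1$start_second, iv1$end_second, iv1$class), c(0L, 5L, 1L))

  t2 <- timeline_from_classes(c(1, 1, 2, 2, 2))
  iv2 <- build_intervals(t2, "colour")
  expect_equal(iv2$start_second, c(0L, 2L))
  expect_equal(iv2$end_second, c(2L, 5L))
  expect_equal(iv2$class, c(1L, 2L))

  t3 <- timeline_from_classes(c(1, NA, 1))
  iv3 <- build_intervals(t3, "colour")
  expect_equal(iv3$start_second, c(0L, 2L))
  expect_equal(iv3$end_second, c(1L, 3L))
})

test_that("exploding intervals back to seconds recovers the resolved timeline", {
  withr::with_seed(77, {
    for (rep in 1:20) {
      classes <- sample(c(1L, 2L, NA), 40L, replace = TRUE,
                        prob = c(0.4, 0.4, 0.2))
      tl <- timeline_from_classes(classes)
      iv <- build_intervals(tl, "colour")
      seconds <- unlist(lapply(seq_len(nrow(iv)), function(i) {
        iv$start_second[i]:(iv$end_second[i] - 1L)
      }))
      cls <- unlist(lapply(seq_len(nrow(iv)), function(i) {
        rep(iv$class[i], iv$end_second[i] - iv$start_second[i])
      }))
      o <- order(seconds)
      expect_identical(seconds[o], tl$timeline$second)
      expect_identical(as.integer(cls[o]), tl$timeline$class)
      # maximality: adjacent intervals of one video differ in class or have a gap
      if (nrow(iv) > 1L) {
        gap <- iv$start_second[-1] > iv$end_second[-nrow(iv)]
        diffclass <- iv$class[-1] != iv$class[-nrow(iv)]
        expect_true(all(gap | diffclass))
      }
    }
  })
})

test_that("class counts are conserved and n_v is the smaller class", {
  cfg <- quick_cfg(annot_agreement = 0.9, annot_unclear = 0.08)
  truth <- make_truth(cfg)
  tags <- make_expert_tags(cfg, truth)
  res <- resolve_tags(tags[[1]], tags[[2]])
  cc <- count_classes(res)
  expect_equal(nrow(cc), 4L)
  expect_equal(cc$n_class1 + cc$n_class2 + cc$n_discarded, cc$total)
  expect_equal(cc$total, rep(3L * 60L, 4L))
  expect_equal(cc$n_v, pmin(cc$n_class1, cc$n_class2))
  expect_equal(cc$n_discarded, cc$n_unclear + cc$n_disagreement)

  empty <- resolve_tags(tagset("unclear"), tagset("unclear", expert = 2L))
  cc0 <- count_classes(empty)
  expect_true(all(cc0$n_class1 == 0L & cc0$n_class2 == 0L))
})

test_that("balancing sub-samples the larger class to n_v without replacement", {
  tl <- timeline_from_classes(rep(c(1, 1, 1, 1, 2), 20))  # 80 vs 20
  bal <- balance_seconds(tl, "colour", seed = 5L)
  expect_equal(sum(bal$timeline$class == 1L), 20L)
  expect_equal(sum(bal$timeline$class == 2L), 20L)
  # kept seconds are a subset of the original
  expect_true(all(bal$timeline$second %in% tl$timeline$second))
  expect_false(anyDuplicated(bal$timeline$second) > 0)

  # already balanced input is unchanged in counts
  tl_eq <- timeline_from_classes(rep(c(1, 2), 50))
  bal_eq <- balance_seconds(tl_eq, "colour", seed = 1L)
  expect_equal(sum(bal_eq$timeline$class == 1L), 50L)
  expect_equal(sum(bal_eq$timeline$class == 2L), 50L)

  # different seeds generally select different subsets (sizes 50 vs 10)
  tl_big <- timeline_from_classes(c(rep(1, 50), rep(2, 10)))
  picks <- vapply(1:20, function(s) {
    paste(balance_seconds(tl_big, "colour", seed = s)$timeline$second,
          collapse = ",")
  }, character(1))
  expect_gt(length(unique(picks)), 1L)
})

test_that("balancing an empty class is an error naming the dimension", {
  tl <- timeline_from_classes(rep(1, 10))
  expect_error(balance_seconds(tl, "colour", seed = 1L), "colour")
})
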
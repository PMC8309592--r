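# Normality screening and rank-sum comparisons of band power between the
# two classes of each design dimension.

#' Lilliefors-corrected Kolmogorov-Smirnov normality test
#'
#' KS test against a normal distribution whose mean and standard deviation
#' are estimated from the sample (Lilliefors correction); the p-value uses
#' the standard Lilliefors approximation (via `nortest::lillie.test`).
#'
#' @param values Numeric sample, `n >= 5`, non-constant.
#' @return List with `statistic` (D) and `p_value`.
#' @export
lilliefors <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 5L) stopf("lilliefors requires n >= 5")
  if (stats::sd(values) == 0) stopf("lilliefors is undefined for a constant sample")
  res <- nortest::lillie.test(values)
  list(statistic = unname(res$statistic), p_value = unname(res$p.value))
}

#' Mann-Whitney U test (Wilcoxon rank-sum)
#'
#' Two-sided test of the null that P(X > Y) = 0.5. `U` is the number of
#' (x, y) pairs with x > y, counting ties as 1/2 (equivalently, computed
#' from rank sums with midranks). The p-value is exact by enumeration for
#' small tie-free samples (`n1 + n2 <= 12`), otherwise a normal
#' approximation with tie and continuity corrections is used (via
#' `stats::wilcox.test`).
#'
#' @param x,y Numeric samples, both non-empty.
#' @return List: `U` (for `x` vs `y`), `p_value`, `mean_rank_x`,
#'   `mean_rank_y`, `n1`, `n2`.
#' @export
mann_whitney <- function(x, y) {
  if (!length(x) || !length(y)) stopf("mann_whitney requires non-empty samples")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  rx <- r[seq_len(n1)]
  U <- sum(rx) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(c(x, y)))
  exact <- !ties && (n1 + n2) <= 12L
  p <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)$p.value
  )
  list(U = U, p_value = p,
       mean_rank_x = mean(rx), mean_rank_y = mean(r[-seq_len(n1)]),
       n1 = n1, n2 = n2)
}

#' Compare band power between classes of one design dimension
#'
#' Runs a two-sided Mann-Whitney U test per band (class 1 vs class 2 mean
#' band power), reports mean ranks, the direction of the effect (which
#' class has the larger rank mean), significance at `alpha`, and optionally
#' Holm-adjusted p-values.
#'
#' @param table Band-power tibble from [band_power_table()] (or the same
#'   schema read back from CSV), containing both classes.
#' @param vdep Design dimension the table belongs to.
#' @param alpha Significance level (default 0.05).
#' @param holm Add a Holm-adjusted p column and use it for the significance
#'   flag.
#' @param bands Band names (columns of `table`) to test.
#' @return A `stats_report` tibble: `vdep`, `band`, `n1`, `n2`,
#'   `mean_rank_1`, `mean_rank_2`, `U`, `p`, `p_holm`, `direction`,
#'   `significant`.
#' @export
compare_vdep_bands <- function(table, vdep, alpha = 0.05, holm = FALSE,
                               bands = EEG_BAND_NAMES) {
  vdep <- match.arg(vdep, VDEPS)
  missing_bands <- setdiff(bands, names(table))
  if (length(missing_bands)) {
    stopf("band column(s) missing from table: %s",
          paste(missing_bands, collapse = ", "))
  }
  cls <- table$class
  if (length(unique(cls[!is.na(cls)])) < 2L) {
    stopf("band-power table for '%s' has a single class", vdep)
  }
  rows <- lapply(bands, function(b) {
    x <- table[[b]][cls == 1L]
    y <- table[[b]][cls == 2L]
    mw <- mann_whitney(x, y)
    tibble::tibble(
      vdep = vdep, band = b, n1 = mw$n1, n2 = mw$n2,
      mean_rank_1 = mw$mean_rank_x, mean_rank_2 = mw$mean_rank_y,
      U = mw$U, p = mw$p_value,
      direction = if (mw$mean_rank_x >= mw$mean_rank_y) 1L else 2L
    )
  })
  rep <- do.call(rbind, rows)
  rep$p_holm <- stats::p.adjust(rep$p, method = "holm")
  rep$significant <- (if (holm) rep$p_holm else rep$p) < alpha
  class(rep) <- c("stats_report", class(rep))
  rep
}

#' Long-format data for violin plots of band power by class
#'
#' @param table Band-power tibble ([band_power_table()] schema).
#' @param bands Band columns to include.
#' @return Tibble `band`, `class`, `power`, one row per (epoch, band).
#' @export
violin_data <- function(table, bands = EEG_BAND_NAMES) {
  out <- lapply(bands, function(b) {
    tibble::tibble(band = b, class = table$class, power = table[[b]])
  })
  do.call(rbind, out)
}
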
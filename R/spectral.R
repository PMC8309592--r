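# FFT band filtering and mean band power per epoch across the classical
# EEG bands.

#' Default EEG band definitions
#'
#' Conventional band edges truncated at 45 Hz (the upper edge of the DEAP
#' pre-processing band-pass): delta 1-4, theta 4-8, alpha 8-13, beta 13-30,
#' gamma 30-45 Hz. Edges are `[lo, hi)` in the FFT mask.
#'
#' @return Tibble with columns `name`, `lo`, `hi`.
#' @export
default_bands <- function() {
  tibble::tibble(
    name = EEG_BAND_NAMES,
    lo = c(1, 4, 8, 13, 30),
    hi = c(4, 8, 13, 30, 45)
  )
}

validate_bands <- function(bands, fs) {
  stopifnot(all(c("name", "lo", "hi") %in% names(bands)))
  if (any(bands$lo <= 0) || any(bands$hi <= bands$lo)) {
    stopf("bands must satisfy 0 < lo < hi")
  }
  if (any(bands$hi > fs / 2)) {
    stopf("band edge above the Nyquist frequency (%g Hz)", fs / 2)
  }
  bands
}

# Logical mask over FFT bins k = 0..n-1 for frequencies in [lo, hi);
# both conjugate halves; DC and Nyquist always excluded.
fft_band_mask <- function(n, lo, hi, fs) {
  k <- 0:(n - 1)
  f <- pmin(k, n - k) * fs / n
  m <- f >= lo & f < hi
  m[1] <- FALSE
  if (n %% 2 == 0) m[n / 2 + 1] <- FALSE
  m
}

#' FFT band-pass filter of a one-second series
#'
#' Zeroes every discrete-Fourier coefficient whose frequency lies outside
#' `[lo, hi)` (both conjugate halves; DC and Nyquist always zeroed) and
#' inverse-transforms back to a real time series.
#'
#' @param x Numeric vector (one channel, typically `fs` samples).
#' @param lo,hi Band edges in Hz, `lo` inclusive, `hi` exclusive.
#' @param fs Sampling rate in Hz.
#' @return Real filtered series, same length as `x`.
#' @export
band_filter <- function(x, lo, hi, fs) {
  stopifnot(is.numeric(x), length(x) > 1L)
  if (lo <= 0 || hi <= lo || hi > fs / 2) {
    stopf("invalid band [%g, %g) for fs = %g", lo, hi, fs)
  }
  n <- length(x)
  mask <- fft_band_mask(n, lo, hi, fs)
  Re(stats::fft(stats::fft(x) * mask, inverse = TRUE)) / n
}

#' Mean band power of an epoch
#'
#' For each band: band-filter every channel, average the squared filtered
#' samples over time, then average over channels. Epochs must be
#' un-normalized (the statistics path runs on raw amplitudes); pass a bare
#' matrix to bypass the flag check.
#'
#' @param e Numeric `time x channels` matrix, or an [epoch_set] (then a
#'   record per epoch is returned, see [band_power_table()]).
#' @param bands Band definition tibble (default [default_bands()]).
#' @param fs Sampling rate in Hz.
#' @param measure `"power"` (mean squared filtered sample) or
#'   `"amplitude"` (mean rectified filtered sample).
#' @return Named numeric vector, one non-negative value per band.
#' @export
mean_band_power <- function(e, bands = default_bands(), fs = 128L,
                            measure = c("power", "amplitude")) {
  measure <- match.arg(measure)
  stopifnot(is.matrix(e), is.numeric(e))
  validate_bands(bands, fs)
  n <- nrow(e)
  spec <- stats::mvfft(e)
  out <- stats::setNames(numeric(nrow(bands)), bands$name)
  for (b in seq_len(nrow(bands))) {
    mask <- fft_band_mask(n, bands$lo[b], bands$hi[b], fs)
    filt <- Re(stats::mvfft(spec * mask, inverse = TRUE)) / n
    out[b] <- if (measure == "power") mean(filt^2) else mean(abs(filt))
  }
  out
}

#' Band-power records for every epoch of a set
#'
#' Computes [mean_band_power()] per epoch and binds the values to the epoch
#' metadata: the flat table the statistics stage consumes.
#'
#' @param es An **un-normalized** [epoch_set].
#' @inheritParams mean_band_power
#' @return Tibble: epoch metadata plus one column per band.
#' @export
band_power_table <- function(es, bands = default_bands(),
                             measure = c("power", "amplitude")) {
  stopifnot(inherits(es, "epoch_set"))
  if (es$normalized) {
    stopf("band power must be computed on un-normalized epochs")
  }
  measure <- match.arg(measure)
  n <- length(es)
  pw <- matrix(0, n, nrow(bands), dimnames = list(NULL, bands$name))
  for (i in seq_len(n)) {
    pw[i, ] <- mean_band_power(es$data[, , i], bands, es$fs, measure)
  }
  tibble::as_tibble(cbind(es$meta, tibble::as_tibble(pw)))
}

#' Write a band-power table to CSV
#'
#' One row per epoch: metadata plus the five band columns. All epochs must
#' belong to one design dimension. Values round-trip exactly through
#' [read_band_table()].
#'
#' @param records Band-power tibble from [band_power_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_band_table <- function(records, path) {
  if (nrow(records) == 0L) stopf("no band-power records to export")
  if (length(unique(records$vdep)) != 1L) {
    stopf("band-power table mixes design dimensions: %s",
          paste(unique(records$vdep), collapse = ", "))
  }
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname export_band_table
#' @export
read_band_table <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
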
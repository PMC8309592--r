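# Synthetic EEG signal model: 1/f background plus one sinusoid per band at
# the band's geometric-centre frequency, class effects entering as band
# amplitude multipliers.

band_center_freqs <- function(bands = default_bands()) {
  stats::setNames(sqrt(bands$lo * bands$hi), bands$name)
}

# Pink (1/f^a power) noise, one column per channel, fixed overall scale.
pink_noise <- function(n, ncol, exponent = 1, sd = 1) {
  white <- matrix(stats::rnorm(n * ncol), n, ncol)
  if (exponent == 0 || sd == 0) {
    return(white * sd)
  }
  k <- 0:(n - 1)
  f <- pmin(k, n - k)             # symmetric frequency index, DC at 0
  scale <- c(0, f[-1]^(-exponent / 2))
  spec <- stats::mvfft(white) * scale
  x <- Re(stats::mvfft(spec, inverse = TRUE)) / n
  # per-sample variance implied by the mask, for a deterministic rescale
  x * (sd / sqrt(mean(scale^2)))
}

# Amplitude multiplier per band for one (video, second): product of the
# multipliers of all active classes across design dimensions.
gain_for_classes <- function(band_gains, classes) {
  g <- stats::setNames(rep(1, length(EEG_BAND_NAMES)), EEG_BAND_NAMES)
  for (vd in names(band_gains)) {
    cl <- as.character(classes[[vd]])
    mult <- band_gains[[vd]][[cl]]
    if (!is.null(mult)) g[names(mult)] <- g[names(mult)] * mult
  }
  g
}

# One second of band oscillations: fs x n_ch matrix, random phase per
# (band, channel), amplitudes given per band.
osc_second <- function(amps, centers, fs, n_ch) {
  t_sec <- (0:(fs - 1)) / fs
  out <- matrix(0, fs, n_ch)
  for (b in seq_along(centers)) {
    if (amps[b] == 0) next
    phase <- stats::runif(n_ch, 0, 2 * pi)
    arg <- outer(2 * pi * centers[b] * t_sec, rep(1, n_ch)) +
      matrix(phase, fs, n_ch, byrow = TRUE)
    out <- out + amps[b] * sin(arg)
  }
  out
}

#' Generate a DEAP-shaped synthetic recording set
#'
#' Emits one `n_trials x n_channels_total x n_samples` array per
#' participant. EEG channels carry pink noise plus per-band oscillations
#' whose amplitudes follow the latent class timeline in `truth`; the
#' pre-trial baseline carries no oscillatory class effect; trials beyond
#' `cfg$n_videos` are unannotated filler; peripheral channels are white
#' noise placeholders.
#'
#' @param cfg A [sim_config()].
#' @param truth Output of [make_truth()] for the same configuration.
#' @return A `recording_set`: list with `data` (list of participant
#'   arrays), `fs`, `channel_names`, and layout metadata.
#' @export
make_recordings <- function(cfg, truth) {
  stopifnot(inherits(cfg, "sim_config"))
  n_sec <- tagged_seconds(cfg)
  if (!all(c("video", "second", "vdep", "class") %in% names(truth))) {
    stopf("truth must come from make_truth()")
  }
  centers <- band_center_freqs()
  n_samples <- cfg$trial_duration_s * cfg$fs
  n_eeg <- cfg$n_channels_eeg
  n_per <- cfg$n_channels_total - n_eeg

  # per-video amplitude matrix: n_sec x 5 bands
  amp_by_video <- lapply(seq_len(cfg$n_videos), function(v) {
    tv <- truth[truth$video == v, ]
    amp <- matrix(0, n_sec, length(EEG_BAND_NAMES),
                  dimnames = list(NULL, EEG_BAND_NAMES))
    for (s in seq_len(n_sec)) {
      cls <- stats::setNames(
        tv$class[tv$second == s - 1L][match(VDEPS, tv$vdep[tv$second == s - 1L])],
        VDEPS
      )
      g <- gain_for_classes(cfg$band_gains, as.list(cls))
      base <- stats::setNames(rep(0, length(EEG_BAND_NAMES)), EEG_BAND_NAMES)
      base[names(cfg$osc_amp)] <- cfg$osc_amp
      amp[s, ] <- base * g
    }
    amp
  })

  with_local_seed(derive_seed(cfg$seed, 2L), {
    data <- vector("list", cfg$n_participants)
    base_amp <- stats::setNames(rep(0, length(EEG_BAND_NAMES)), EEG_BAND_NAMES)
    base_amp[names(cfg$osc_amp)] <- cfg$osc_amp
    for (p in seq_len(cfg$n_participants)) {
      arr <- array(0, dim = c(cfg$n_trials, cfg$n_channels_total, n_samples))
      for (tr in seq_len(cfg$n_trials)) {
        eeg <- pink_noise(n_samples, n_eeg, cfg$noise_exponent, cfg$noise_sd)
        amp <- if (tr <= cfg$n_videos) amp_by_video[[tr]] else
          matrix(base_amp, n_sec, length(base_amp), byrow = TRUE)
        off <- cfg$baseline_s * cfg$fs
        for (s in seq_len(n_sec)) {
          idx <- (off + (s - 1L) * cfg$fs + 1L):(off + s * cfg$fs)
          eeg[idx, ] <- eeg[idx, ] + osc_second(amp[s, ], centers, cfg$fs, n_eeg)
        }
        arr[tr, seq_len(n_eeg), ] <- t(eeg)
        if (n_per > 0) {
          arr[tr, n_eeg + seq_len(n_per), ] <-
            matrix(stats::rnorm(n_per * n_samples, sd = cfg$noise_sd),
                   n_per, n_samples)
        }
      }
      data[[p]] <- arr
    }
    structure(
      list(
        data = data,
        fs = cfg$fs,
        channel_names = c(deap_channel_names(),
                          paste0("PER", seq_len(max(n_per, 0)))),
        n_videos = cfg$n_videos,
        n_trials = cfg$n_trials,
        baseline_s = cfg$baseline_s,
        trial_duration_s = cfg$trial_duration_s
      ),
      class = "recording_set"
    )
  })
}

#' @export
print.recording_set <- function(x, ...) {
  d <- dim(x$data[[1]])
  cat(sprintf(
    "<recording_set> %d participants, arrays %d x %d x %d @ %d Hz (%d annotated videos)\n",
    length(x$data), d[1], d[2], d[3], x$fs, x$n_videos))
  invisible(x)
}

#' Simulate labelled one-second epochs directly
#'
#' Bypasses the full recording layout and draws ready-made 1-s epochs for a
#' single design dimension: pink noise plus band oscillations whose
#' amplitudes follow `cfg$band_gains[[vdep]]` for the epoch's class. The
#' other three dimensions are held neutral. Useful for calibration and
#' decoding experiments at a chosen class separation.
#'
#' @param cfg A [sim_config()]; `band_gains[[vdep]]` defines the effect.
#' @param vdep One of `"colour"`, `"balance"`, `"movement"`, `"light"`.
#' @param n_per_class Epochs to draw for each class.
#' @param seed Integer seed; defaults to a stream derived from `cfg$seed`.
#' @return An [epoch_set] (un-normalized) with balanced classes.
#' @export
simulate_epochs <- function(cfg, vdep, n_per_class, seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  vdep <- match.arg(vdep, VDEPS)
  n_per_class <- assert_count(n_per_class, "n_per_class")
  centers <- band_center_freqs()
  n_eeg <- cfg$n_channels_eeg
  base_amp <- stats::setNames(rep(0, length(EEG_BAND_NAMES)), EEG_BAND_NAMES)
  base_amp[names(cfg$osc_amp)] <- cfg$osc_amp
  amps <- lapply(c("1", "2"), function(cl) {
    g <- stats::setNames(rep(1, length(EEG_BAND_NAMES)), EEG_BAND_NAMES)
    mult <- cfg$band_gains[[vdep]][[cl]]
    if (!is.null(mult)) g[names(mult)] <- g[names(mult)] * mult
    base_amp * g
  })
  n <- 2L * n_per_class
  classes <- rep(c(1L, 2L), n_per_class)
  with_local_seed(seed %||% derive_seed(cfg$seed, 3L), {
    dat <- array(0, dim = c(cfg$fs, n_eeg, n))
    for (i in seq_len(n)) {
      dat[, , i] <-
        pink_noise(cfg$fs, n_eeg, cfg$noise_exponent, cfg$noise_sd) +
        osc_second(amps[[classes[i]]], centers, cfg$fs, n_eeg)
    }
    meta <- tibble::tibble(
      epoch_id = seq_len(n),
      # class-1/class-2 pairs share a participant, so every simulated
      # participant contributes epochs of both classes
      participant = ((seq_len(n) - 1L) %/% 2L) %% cfg$n_participants + 1L,
      video = NA_integer_,
      second = NA_integer_,
      vdep = vdep,
      class = classes
    )
    new_epoch_set(dat, meta, fs = cfg$fs, normalized = FALSE)
  })
}
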
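#' Simulation configuration
#'
#' Builds the configuration object for the synthetic recording and
#' annotation generator. Defaults emulate the pre-processed DEAP release:
#' 32 participants, 40 one-minute trials (of which `n_videos` carry design
#' annotations), 40 channels (32 EEG + 8 peripheral), 128 Hz, 63-s trials
#' whose first 3 s are a pre-trial baseline.
#'
#' The signal model per EEG channel is 1/f ("pink") background noise plus
#' one sinusoid per classical EEG band at the band's geometric-centre
#' frequency, with a fresh random phase each second. Band amplitudes are
#' modulated by `band_gains` according to the latent per-second class of
#' each visual design dimension, which is how class effects are injected.
#'
#' @param n_participants Number of simulated participants.
#' @param n_videos Number of annotated videos (first `n_videos` trials).
#' @param n_trials Trials per participant; trials beyond `n_videos` are
#'   unannotated filler, which the epoch extractor must skip.
#' @param trial_duration_s Trial length in seconds, including the baseline.
#' @param baseline_s Pre-trial baseline seconds carrying no class effect.
#' @param fs Sampling rate in Hz.
#' @param n_channels_eeg,n_channels_total EEG channel count and total
#'   channel count (EEG + peripheral placeholders).
#' @param band_gains Named list `vdep -> class ("1"/"2") -> band ->
#'   amplitude multiplier` (>= 0). Multipliers from different dimensions
#'   multiply, since all four dimensions label every second. Defaults give
#'   balance/light/movement a broadband effect with the directions reported
#'   for real footage (higher power for symmetrical, bright and fast
#'   content) and colour no effect.
#' @param osc_amp Named base amplitude per band of the injected oscillation.
#' @param noise_sd Standard deviation of the pink background noise.
#' @param noise_exponent Spectral slope of the background (power ~ 1/f^a).
#' @param mean_run_s Mean length, in seconds, of a constant-class run in
#'   the latent truth (geometric run lengths).
#' @param annot_agreement Probability that an expert reports the true class,
#'   conditional on not reporting "unclear".
#' @param annot_unclear Probability that an expert reports "unclear".
#' @param seed Integer seed making all generator output reproducible.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @export
sim_config <- function(n_participants = 32L,
                       n_videos = 26L,
                       n_trials = 40L,
                       trial_duration_s = 63L,
                       baseline_s = 3L,
                       fs = 128L,
                       n_channels_eeg = 32L,
                       n_channels_total = 40L,
                       band_gains = default_band_gains(),
                       osc_amp = c(delta = 1, theta = 0.8, alpha = 1,
                                   beta = 0.6, gamma = 0.4),
                       noise_sd = 1,
                       noise_exponent = 1,
                       mean_run_s = 5,
                       annot_agreement = 0.95,
                       annot_unclear = 0.05,
                       seed = 1L) {
  cfg <- list(
    n_participants = assert_count(n_participants, "n_participants"),
    n_videos = assert_count(n_videos, "n_videos"),
    n_trials = assert_count(n_trials, "n_trials"),
    trial_duration_s = assert_count(trial_duration_s, "trial_duration_s"),
    baseline_s = assert_count(baseline_s, "baseline_s", min = 0L),
    fs = assert_count(fs, "fs"),
    n_channels_eeg = assert_count(n_channels_eeg, "n_channels_eeg"),
    n_channels_total = assert_count(n_channels_total, "n_channels_total"),
    band_gains = band_gains,
    osc_amp = osc_amp,
    noise_sd = noise_sd,
    noise_exponent = noise_exponent,
    mean_run_s = mean_run_s,
    annot_agreement = annot_agreement,
    annot_unclear = annot_unclear,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

#' @rdname sim_config
#' @export
default_band_gains <- function() {
  flat <- function(x) stats::setNames(rep(x, 5L), EEG_BAND_NAMES)
  list(
    balance  = list("2" = flat(1.15)),
    light    = list("1" = flat(1.15)),
    movement = list("1" = flat(1.25))
  )
}

validate_sim_config <- function(cfg) {
  if (cfg$n_videos > cfg$n_trials) {
    stopf("n_videos (%d) cannot exceed n_trials (%d)",
          cfg$n_videos, cfg$n_trials)
  }
  if (cfg$baseline_s >= cfg$trial_duration_s) {
    stopf("baseline_s must be smaller than trial_duration_s")
  }
  if (cfg$n_channels_eeg > cfg$n_channels_total) {
    stopf("n_channels_eeg cannot exceed n_channels_total")
  }
  if (!is.numeric(cfg$mean_run_s) || cfg$mean_run_s < 1) {
    stopf("mean_run_s must be >= 1 (geometric run-length mean)")
  }
  assert_prob(cfg$annot_agreement, "annot_agreement")
  assert_prob(cfg$annot_unclear, "annot_unclear")
  if (!is.numeric(cfg$noise_sd) || cfg$noise_sd < 0) {
    stopf("noise_sd must be non-negative")
  }
  bad_amp <- setdiff(names(cfg$osc_amp), EEG_BAND_NAMES)
  if (length(bad_amp)) {
    stopf("osc_amp names unknown bands: %s", paste(bad_amp, collapse = ", "))
  }
  for (vd in names(cfg$band_gains)) {
    if (!vd %in% VDEPS) {
      stopf("band_gains refers to unknown design dimension '%s'", vd)
    }
    for (cl in names(cfg$band_gains[[vd]])) {
      if (!cl %in% c("1", "2")) {
        stopf("band_gains[[%s]] class keys must be \"1\" or \"2\"", vd)
      }
      g <- cfg$band_gains[[vd]][[cl]]
      bad <- setdiff(names(g), EEG_BAND_NAMES)
      if (length(bad)) {
        stopf("band_gains[[%s]][[%s]] refers to unknown band(s): %s",
              vd, cl, paste(bad, collapse = ", "))
      }
      if (any(!is.finite(g)) || any(g < 0)) {
        stopf("band_gains multipliers must be finite and >= 0")
      }
    }
  }
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  participants: %d, trials: %d (%d annotated videos)\n",
              x$n_participants, x$n_trials, x$n_videos))
  cat(sprintf("  %d s @ %d Hz (%d samples/channel), %d-s baseline\n",
              x$trial_duration_s, x$fs, x$trial_duration_s * x$fs,
              x$baseline_s))
  cat(sprintf("  channels: %d EEG of %d total\n",
              x$n_channels_eeg, x$n_channels_total))
  cat(sprintf("  annotators: agreement %.2f, unclear %.2f; seed %s\n",
              x$annot_agreement, x$annot_unclear,
              x$seed %||% "NULL"))
  invisible(x)
}

# Number of annotated seconds per video (baseline excluded).
tagged_seconds <- function(cfg) cfg$trial_duration_s - cfg$baseline_s
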
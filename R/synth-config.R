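#' Simulation configuration
#'
#' Describes the dimensions and sampling rates of a synthetic
#' sham-controlled, within-subject visual-detection experiment: each
#' participant completes both a sham and a stimulation session of five
#' blocks with 80 detection trials per block, a near-threshold Gabor
#' present on 60% of trials, occipital EEG sampled at 250 Hz, resting
#' fNIRS at ~10.17 Hz, and a high-frequency noise-stimulation waveform.
#'
#' @param n_participants number of participants (default 29)
#' @param n_conditions number of stimulation conditions (sham, tRNS)
#' @param n_blocks blocks per session (default 5; block 1 is baseline,
#'   stimulation is delivered during the rest preceding blocks 2-5)
#' @param trials_per_block trials per block (default 80)
#' @param p_stimulus probability a trial contains a stimulus (default 0.6)
#' @param p_left probability a present stimulus appears on the left
#' @param fs_eeg EEG sampling rate in Hz after preprocessing (250)
#' @param fs_fnirs fNIRS sampling rate in Hz (10.1725)
#' @param fs_trns stimulation waveform sampling rate in Hz; must exceed
#'   twice the 640 Hz upper band edge
#' @param epoch_window EEG epoch window in ms relative to stimulus onset
#' @param rest_duration resting-state recording duration in seconds
#' @param false_alarm probability of reporting "seen" on a stimulus-absent
#'   trial
#' @param seed integer seed controlling all randomness of the generator
#' @return a `sim_config` list
#' @export
sim_config <- function(n_participants = 29L, n_conditions = 2L,
                       n_blocks = 5L, trials_per_block = 80L,
                       p_stimulus = 0.6, p_left = 0.5,
                       fs_eeg = 250, fs_fnirs = 10.1725, fs_trns = 2000,
                       epoch_window = c(-1800, 1500),
                       rest_duration = 300, false_alarm = 0.05,
                       seed = 1L) {
  cfg <- list(n_participants = as.integer(n_participants),
              n_conditions = as.integer(n_conditions),
              n_blocks = as.integer(n_blocks),
              trials_per_block = as.integer(trials_per_block),
              p_stimulus = p_stimulus, p_left = p_left,
              fs_eeg = fs_eeg, fs_fnirs = fs_fnirs, fs_trns = fs_trns,
              epoch_window = epoch_window,
              rest_duration = rest_duration,
              false_alarm = false_alarm,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  counts <- c("n_participants", "n_conditions", "n_blocks",
              "trials_per_block")
  for (nm in counts) {
    if (!is.finite(cfg[[nm]]) || cfg[[nm]] < 1L)
      stop("configuration error: ", nm, " must be a count >= 1")
  }
  for (nm in c("p_stimulus", "p_left", "false_alarm")) {
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1)
      stop("configuration error: ", nm, " must lie in [0, 1]")
  }
  if (cfg$fs_trns <= 2 * 640)
    stop("configuration error: fs_trns must exceed 1280 Hz")
  if (cfg$epoch_window[1] >= cfg$epoch_window[2])
    stop("configuration error: epoch_window must be increasing")
  invisible(cfg)
}

#' Ground truth for a synthetic experiment
#'
#' Encodes the generating parameters downstream recovery tests compare
#' against: per-participant psychometric thresholds and slopes, fatigue
#' trajectories, and the planted state-dependent stimulation effects.
#' Effect sizes are the stimulation-minus-sham differences reached at
#' the final block under low fatigue, ramped linearly over blocks 2-5
#' and absent under high fatigue. Coupling weights map per-trial
#' deviations of band power (dB, relative to the participant's mean)
#' onto shifts of the detection threshold: positive alpha/beta coupling
#' means stronger prestimulus alpha/beta power worsens detection.
#'
#' @param threshold_mean,threshold_sd lognormal location/scale of the
#'   per-participant contrast threshold mu (contrast units)
#' @param slope_frac psychometric SD as a fraction of mu
#' @param fatigue_start_mean,fatigue_start_sd mean/SD of the block-1
#'   fatigue level on the 1-7 scale
#' @param fatigue_gain_mean,fatigue_gain_sd mean/SD of the session-long
#'   fatigue increase
#' @param fatigue_noise_sd rating noise SD
#' @param hbo_base baseline HbO amplitude, micromolar
#' @param hbo_sd between-block HbO amplitude noise SD
#' @param effect_hbo planted HbO amplitude increase under stimulation,
#'   low fatigue, final block (micromolar)
#' @param effect_alpha,effect_beta planted prestimulus alpha/beta power
#'   change (dB, negative = suppression)
#' @param coupling_low,coupling_high weight (contrast units per dB)
#'   from mean alpha+beta deviation to the detection threshold in each
#'   fatigue state
#' @param feature_noise_sd per-trial band-power noise SD in dB
#' @return a `ground_truth` list
#' @export
ground_truth <- function(threshold_mean = 0.35, threshold_sd = 0.25,
                         slope_frac = 0.25,
                         fatigue_start_mean = 2.3, fatigue_start_sd = 0.7,
                         fatigue_gain_mean = 1.6, fatigue_gain_sd = 0.9,
                         fatigue_noise_sd = 0.5,
                         hbo_base = 0.5, hbo_sd = 0.12,
                         effect_hbo = 0.276,
                         effect_alpha = -0.582, effect_beta = -0.482,
                         coupling_low = 0.02, coupling_high = 0,
                         feature_noise_sd = 1.0) {
  gt <- list(threshold_mean = threshold_mean, threshold_sd = threshold_sd,
             slope_frac = slope_frac,
             fatigue_start_mean = fatigue_start_mean,
             fatigue_start_sd = fatigue_start_sd,
             fatigue_gain_mean = fatigue_gain_mean,
             fatigue_gain_sd = fatigue_gain_sd,
             fatigue_noise_sd = fatigue_noise_sd,
             hbo_base = hbo_base, hbo_sd = hbo_sd,
             effect_hbo = effect_hbo,
             effect_alpha = effect_alpha, effect_beta = effect_beta,
             coupling_low = coupling_low, coupling_high = coupling_high,
             feature_noise_sd = feature_noise_sd)
  num <- unlist(gt)
  if (any(!is.finite(num))) stop("ground truth values must be finite")
  class(gt) <- "ground_truth"
  gt
}

#' Null-effect ground truth
#'
#' Convenience constructor with every planted effect and coupling set to
#' zero, so all participant/condition/state groups are exchangeable.
#' This is the basis of the downstream calibration tests.
#' @param ... overrides passed to [ground_truth()]
#' @export
null_truth <- function(...) {
  ground_truth(effect_hbo = 0, effect_alpha = 0, effect_beta = 0,
               coupling_low = 0, coupling_high = 0, ...)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_participants, "participants x",
      x$n_conditions, "conditions x", x$n_blocks, "blocks x",
      x$trials_per_block, "trials; p(stimulus) =", x$p_stimulus, "\n")
  invisible(x)
}
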
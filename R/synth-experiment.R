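# Population-level mean band power profile (dB) used as the anchor for
# per-participant baselines: prominent occipital alpha, weak gamma.
band_baseline_db <- function() {
  c(delta = 6, theta = 4, alpha = 5, beta = 1, gamma = -1)
}

#' Generate a synthetic experiment
#'
#' Simulates the full study structure: every participant completes a
#' sham and a stimulation session of `n_blocks` blocks with
#' `trials_per_block` adaptive-staircase detection trials each, a
#' stimulus present on 60% of trials, per-trial 25-feature prestimulus
#' band-power rows (dB), a per-block resting HbO amplitude, and
#' pre/post fatigue ratings. Planted effects (see [ground_truth()])
#' appear only under stimulation in low-fatigue blocks, ramping
#' linearly over blocks 2 to `n_blocks`: HbO amplitude rises,
#' alpha/beta power falls, and — through the band-power coupling of the
#' observer model — the contrast threshold falls. The staircase runs
#' continuously within a session, carrying its posterior across blocks.
#'
#' The default "features" mode emits band-power feature rows directly,
#' which keeps large statistical simulations cheap; "waveform" mode
#' additionally synthesizes EEG epochs and HbO channel series so the
#' feature-extraction modules can be exercised end to end (use small
#' configurations).
#'
#' @param config a [sim_config()]
#' @param truth a [ground_truth()]
#' @param mode "features" (default) or "waveform"
#' @return a `synthetic_dataset`: `trials` (the feature table, one row
#'   per trial), `blocks` (per-block HbO amplitude, fatigue, VCT),
#'   `truth`, `config`, plus `epochs`/`hbo_series` in waveform mode
#' @export
generate_experiment <- function(config = sim_config(),
                                truth = ground_truth(),
                                mode = c("features", "waveform")) {
  mode <- match.arg(mode)
  validate_sim_config(config)
  with_seed(config$seed, generate_experiment_impl(config, truth, mode))
}

generate_experiment_impl <- function(config, truth, mode) {
  P <- config$n_participants; B <- config$n_blocks
  Te <- config$trials_per_block
  conds <- c("sham", "trns")[seq_len(config$n_conditions)]
  fb <- band_baseline_db()[band_definitions()$band]
  nf <- length(feature_names())
  ab_cols <- feature_band_map() %in% c("alpha", "beta")
  alpha_cols <- feature_band_map() == "alpha"
  beta_cols <- feature_band_map() == "beta"

  trial_rows <- vector("list", P * length(conds) * B)
  block_rows <- vector("list", P * length(conds) * B)
  epochs_list <- if (mode == "waveform") list() else NULL
  hbo_list <- if (mode == "waveform") list() else NULL
  observers <- data.frame(participant = seq_len(P), mu = NA_real_,
                          sigma = NA_real_)
  ri <- 0L

  for (p in seq_len(P)) {
    mu_p <- truth$threshold_mean * exp(rnorm(1, 0, truth$threshold_sd))
    sigma_p <- truth$slope_frac * mu_p
    observers$mu[p] <- mu_p; observers$sigma[p] <- sigma_p
    base_p <- rep(fb, each = 5) + rnorm(1, 0, 0.8) + rnorm(nf, 0, 0.4)
    hbo_p <- truth$hbo_base * exp(rnorm(1, 0, 0.2))
    observer <- list(mu = mu_p, sigma = sigma_p, baseline = base_p)

    for (cond in conds) {
      fat <- generate_fatigue(start = rnorm(1, truth$fatigue_start_mean,
                                            truth$fatigue_start_sd),
                              gain = rnorm(1, truth$fatigue_gain_mean,
                                           truth$fatigue_gain_sd),
                              noise_sd = truth$fatigue_noise_sd,
                              n_blocks = B)
      qs <- quest_init(guess = truth$threshold_mean,
                       gamma = config$false_alarm)

      for (b in seq_len(B)) {
        cls <- classify_fatigue(fat$pre[b], fat$post[b])
        state <- cls$state
        ramp <- if (B > 1 && b >= 2) (b - 1) / (B - 1) else 0
        on <- (cond == "trns" && state == "low")
        d_alpha <- if (on) truth$effect_alpha * ramp else 0
        d_beta <- if (on) truth$effect_beta * ramp else 0
        d_hbo <- if (on) truth$effect_hbo * ramp else 0
        hbo_amp <- max(0, hbo_p + d_hbo + rnorm(1, 0, truth$hbo_sd))

        shift <- numeric(nf)
        shift[alpha_cols] <- d_alpha
        shift[beta_cols] <- d_beta
        X <- matrix(rep(base_p + shift, each = Te), Te, nf) +
          matrix(rnorm(Te * nf, 0, truth$feature_noise_sd), Te, nf)
        present <- rbinom(Te, 1, config$p_stimulus)
        side <- ifelse(present == 1,
                       ifelse(rbinom(Te, 1, config$p_left) == 1,
                              "left", "right"), NA)
        contrast <- numeric(Te); seen <- integer(Te)
        vct <- numeric(Te)
        grp_size <- min(40L, Te)
        grp_start <- 1L
        for (t in seq_len(Te)) {
          contrast[t] <- staircase_recommend(qs)
          r <- simulate_response(contrast[t], observer, X[t, ], truth,
                                 state = state,
                                 present = present[t] == 1,
                                 false_alarm = config$false_alarm)
          seen[t] <- r$seen
          if (present[t] == 1)
            qs <- staircase_update(qs, contrast[t], r$seen)
          if (t - grp_start + 1L == grp_size || t == Te) {
            idx <- grp_start:t
            pres <- idx[present[idx] == 1]
            v <- tryCatch(
              estimate_vct(fit_cumulative_gaussian(contrast[pres],
                                                   seen[pres])),
              error = function(e) staircase_estimate(qs))
            # adaptive runs can leave the fit ill-conditioned (nearly
            # flat slope); fall back to the staircase estimate when the
            # fitted threshold leaves the plausible contrast range
            if (!is.finite(v) || v <= 0.005 || v > 2)
              v <- staircase_estimate(qs)
            vct[idx] <- v
            grp_start <- t + 1L
          }
        }

        labels <- data.frame(participant = p, condition = cond,
                             block = b, trial = seq_len(Te),
                             fatigue_state = state,
                             contrast = contrast, present = present,
                             response = seen, side = side)
        ri <- ri + 1L
        trial_rows[[ri]] <- build_feature_table(X, vct, labels)
        block_rows[[ri]] <- data.frame(
          participant = p, condition = cond, block = b,
          fatigue_pre = fat$pre[b], fatigue_post = fat$post[b],
          fatigue_avg = cls$average, fatigue_state = state,
          hbo = hbo_amp,
          vct = mean(vct[!duplicated(vct)]),
          alpha = mean(X[, alpha_cols]),
          beta = mean(X[, beta_cols]))
        if (mode == "waveform") {
          key <- paste(p, cond, b, sep = "_")
          dur <- (config$epoch_window[2] - config$epoch_window[1]) / 1000
          ep <- array(NA_real_, c(Te, 5, round(dur * config$fs_eeg)))
          for (t in seq_len(Te)) for (e in 1:5) {
            tb <- X[t, seq(e, nf, by = 5)]
            ep[t, e, ] <- generate_eeg_epoch(tb, fs = config$fs_eeg,
                                             duration = dur)
          }
          epochs_list[[key]] <- epoch_set(ep, fs = config$fs_eeg,
                                          window = config$epoch_window)
          hbo_list[[key]] <- generate_hbo_series(
            hbo_amp, fs = config$fs_fnirs,
            duration = config$rest_duration)
        }
      }
    }
  }

  trials <- do.call(rbind, trial_rows)
  rownames(trials) <- NULL
  blocks <- do.call(rbind, block_rows)
  rownames(blocks) <- NULL
  out <- list(trials = trials, blocks = blocks, observers = observers,
              truth = truth, config = config)
  if (mode == "waveform") {
    out$epochs <- epochs_list
    out$hbo_series <- hbo_list
  }
  structure(out, class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("synthetic_dataset:", nrow(x$trials), "trials,",
      nrow(x$blocks), "blocks,", x$config$n_participants,
      "participants\n")
  invisible(x)
}

#' Simulate one observer through a staircase session
#'
#' Runs a cumulative-Gaussian observer (threshold `mu`, spread `sigma`)
#' through `n_blocks` x `trials_per_block` detection trials under the
#' QUEST controller with block-to-block prior carry-over (a single
#' continuously updated posterior).
#'
#' @param mu,sigma observer psychometric parameters (contrast units)
#' @param n_blocks,trials_per_block session dimensions
#' @param p_stimulus stimulus-present probability
#' @param false_alarm false-alarm rate on absent trials
#' @param guess initial staircase guess
#' @return data frame with block, trial, present, contrast, seen
#' @export
simulate_staircase_session <- function(mu, sigma, n_blocks = 5L,
                                       trials_per_block = 80L,
                                       p_stimulus = 0.6,
                                       false_alarm = 0.05,
                                       guess = 0.3) {
  qs <- quest_init(guess = guess, gamma = false_alarm)
  rows <- vector("list", n_blocks)
  for (b in seq_len(n_blocks)) {
    pres <- rbinom(trials_per_block, 1, p_stimulus)
    contrast <- numeric(trials_per_block)
    seen <- integer(trials_per_block)
    for (t in seq_len(trials_per_block)) {
      contrast[t] <- staircase_recommend(qs)
      if (pres[t] == 1) {
        seen[t] <- rbinom(1, 1, pnorm((contrast[t] - mu) / sigma))
        qs <- staircase_update(qs, contrast[t], seen[t])
      } else {
        seen[t] <- rbinom(1, 1, false_alarm)
      }
    }
    rows[[b]] <- data.frame(block = b, trial = seq_len(trials_per_block),
                            present = pres, contrast = contrast,
                            seen = seen)
  }
  do.call(rbind, rows)
}

#' Simulate a two-state feature set with band-specific coupling
#'
#' Direct generator for sensitivity-analysis studies: feature rows are
#' iid standard normal; in each state the target is a weighted sum of
#' the band means plus Gaussian noise. With coupling only on alpha in
#' the "low" state, only the low-state network has an alpha-driven
#' target — the planted contrast the permutation test should recover.
#' With identical coupling in both states the two groups are
#' exchangeable (the calibration null).
#'
#' @param n_low,n_high rows per fatigue state
#' @param coupling_low,coupling_high named numeric vectors of per-band
#'   weights (e.g. `c(alpha = 1)`)
#' @param noise_sd target noise SD
#' @return list with `x_low`, `y_low`, `x_high`, `y_high`
#' @export
simulate_feature_set <- function(n_low, n_high,
                                 coupling_low = c(alpha = 1),
                                 coupling_high = numeric(0),
                                 noise_sd = 0.5) {
  bm <- feature_band_map()
  gen <- function(n, coupling) {
    x <- matrix(rnorm(n * 25), n, 25, dimnames = list(NULL, feature_names()))
    y <- rnorm(n, 0, noise_sd)
    for (band in names(coupling))
      y <- y + coupling[[band]] * rowMeans(x[, bm == band, drop = FALSE])
    list(x = x, y = y)
  }
  lo <- gen(n_low, coupling_low)
  hi <- gen(n_high, coupling_high)
  list(x_low = lo$x, y_low = lo$y, x_high = hi$x, y_high = hi$y)
}
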
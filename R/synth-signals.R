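# White Gaussian noise brick-wall band-limited to [low, high) Hz via
# FFT masking, normalized to unit variance. DC is always excluded.
bandlimited_noise <- function(n, fs, low, high) {
  x <- rnorm(n)
  X <- fft(x)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)                 # two-sided frequency axis
  mask <- f >= low & f <= high
  mask[1] <- FALSE
  X[!mask] <- 0
  y <- Re(fft(X, inverse = TRUE)) / n
  s <- sd(y)
  if (s == 0) return(y)
  y / s
}

#' Generate a tRNS current waveform
#'
#' Gaussian noise band-pass filtered to 100-640 Hz, rescaled so the
#' sample SD equals `sigma`, and hard-clipped at +/- 1 mA (the device
#' ceiling). The default SD of 0.194 mA = 0.5 / z(0.995) places 99% of
#' samples within +/- 0.5 mA while respecting the 1 mA peak limit.
#'
#' @param duration seconds
#' @param fs sampling rate in Hz (> 1280 so the 640 Hz edge is
#'   representable)
#' @param sigma target amplitude SD in mA
#' @param band stimulation frequency band in Hz
#' @param clip hard clipping limit in mA
#' @return numeric waveform in mA
#' @export
generate_trns_waveform <- function(duration, fs = 2000, sigma = 0.194,
                                   band = c(100, 640), clip = 1) {
  if (sigma <= 0) stop("sigma must be positive")
  if (fs <= 2 * band[2]) stop("fs must exceed twice the upper band edge")
  n <- round(duration * fs)
  x <- bandlimited_noise(n, fs, band[1], band[2]) * sigma
  pmin(pmax(x, -clip), clip)
}

#' Generate an EEG epoch with prescribed band powers
#'
#' Sums independent brick-wall band-limited noise components, one per
#' band, each scaled so that its measured Welch band power matches the
#' requested dB target. A target of `-Inf` dB yields a zero-amplitude
#' component. Intended to round-trip through [welch_band_power()].
#'
#' @param target_db 5-vector of band-power targets in dB (band order of
#'   [band_definitions()])
#' @param fs sampling rate (250 Hz)
#' @param duration epoch length in seconds (>= 1.8, the prestimulus span)
#' @param bands band definitions
#' @return numeric waveform of `round(duration * fs)` samples
#' @export
generate_eeg_epoch <- function(target_db, fs = 250, duration = 1.8,
                               bands = band_definitions()) {
  stopifnot(length(target_db) == nrow(bands))
  if (any(is.nan(target_db) | is.na(target_db)) || any(target_db == Inf))
    stop("band targets must be finite (or -Inf for a silent band)")
  if (duration < 1.8) stop("duration must cover the 1.8 s prestimulus span")
  n <- round(duration * fs)
  x <- numeric(n)
  for (i in seq_len(nrow(bands))) {
    if (target_db[i] == -Inf) next
    amp <- sqrt(10^(target_db[i] / 10))
    x <- x + amp * bandlimited_noise(n, fs, bands$low[i], bands$high[i])
  }
  x
}

#' Generate a resting HbO channel series
#'
#' Slow oscillatory noise confined to 0.015-0.1 Hz: a shared global
#' component scaled so the SD of the channel mean matches
#' `target_amplitude`, plus small independent per-channel noise in the
#' same band. Round-trips through the HbO amplitude pipeline.
#'
#' @param target_amplitude target SD of the channel-mean series (uMol)
#' @param n_channels number of channels (21)
#' @param fs sampling rate in Hz
#' @param duration seconds (~300)
#' @param channel_noise SD of the independent per-channel component,
#'   as a fraction of the target
#' @return a `hemo_series`
#' @export
generate_hbo_series <- function(target_amplitude, n_channels = 21,
                                fs = 10.1725, duration = 300,
                                channel_noise = 0.3) {
  if (target_amplitude < 0) stop("target amplitude must be non-negative")
  n <- round(duration * fs)
  if (target_amplitude == 0)
    return(hemo_series(matrix(0, n, n_channels), fs = fs))
  g <- bandlimited_noise(n, fs, 0.015, 0.1) * target_amplitude
  eps <- channel_noise * target_amplitude
  data <- vapply(seq_len(n_channels), function(ch)
    g + eps * bandlimited_noise(n, fs, 0.015, 0.1), numeric(n))
  hemo_series(data, fs = fs)
}

#' Generate pre/post fatigue ratings for a session
#'
#' Monotone linear trend from `start` rising by `gain` over the
#' session, plus Gaussian noise, rounded to the integer 1-7 scale.
#' Independent of stimulation condition by construction.
#'
#' @param start mean rating at block 1
#' @param gain mean increase from block 1 to the final block
#' @param noise_sd rating noise SD (0 gives a deterministic trajectory)
#' @param n_blocks number of blocks
#' @return data frame with columns `block`, `pre`, `post`
#' @export
generate_fatigue <- function(start = 2.3, gain = 1.6, noise_sd = 0.5,
                             n_blocks = 5L) {
  frac <- if (n_blocks > 1) (seq_len(n_blocks) - 1) / (n_blocks - 1) else 0
  level <- start + gain * frac
  clamp <- function(v) pmin(7, pmax(1, round(v)))
  data.frame(block = seq_len(n_blocks),
             pre = clamp(level + rnorm(n_blocks, 0, noise_sd)),
             post = clamp(level + rnorm(n_blocks, 0, noise_sd)))
}

#' Simulate a single detection outcome
#'
#' On stimulus-present trials the observer detects with probability
#' \eqn{\Phi((c - \mu_{eff}) / \sigma)}, where the effective threshold
#' shifts with the trial's prestimulus band-power state:
#' \eqn{\mu_{eff} = \mu + k \cdot \overline{\Delta_{\alpha\beta}}}, the
#' mean deviation of the alpha and beta features from the observer's
#' baseline, weighted by the state-specific coupling `k`. On absent
#' trials the observer reports "seen" with the false-alarm probability.
#'
#' @param contrast stimulus contrast (>= 0)
#' @param observer list with `mu`, `sigma` and `baseline` (the 25-vector
#'   mean feature profile)
#' @param band_state the trial's 25-vector of band powers (dB)
#' @param truth a `ground_truth` (provides the coupling weights)
#' @param state fatigue state, "low" or "high"
#' @param present logical, stimulus present?
#' @param false_alarm false-alarm probability on absent trials
#' @return list: `seen` (0/1), `type` (hit/miss/fa/cr), `p` (detection
#'   probability used), `mu_eff`
#' @export
simulate_response <- function(contrast, observer, band_state, truth,
                              state = "low", present = TRUE,
                              false_alarm = 0.05) {
  if (contrast < 0) stop("contrast must be non-negative")
  k <- if (identical(state, "low")) truth$coupling_low else truth$coupling_high
  ab <- feature_band_map() %in% c("alpha", "beta")
  shift <- k * mean(band_state[ab] - observer$baseline[ab])
  mu_eff <- observer$mu + shift
  if (present) {
    p <- pnorm((contrast - mu_eff) / observer$sigma)
    seen <- rbinom(1, 1, p)
    list(seen = seen, type = if (seen == 1) "hit" else "miss",
         p = p, mu_eff = mu_eff)
  } else {
    seen <- rbinom(1, 1, false_alarm)
    list(seen = seen, type = if (seen == 1) "fa" else "cr",
         p = false_alarm, mu_eff = mu_eff)
  }
}
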
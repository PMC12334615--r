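#' Frequency band definitions
#'
#' The five canonical bands used throughout: delta 0.5-4 Hz, theta
#' 4-8 Hz, alpha 8-13 Hz, beta 13-30 Hz, gamma 30-45 Hz (gamma capped
#' at 45 Hz to stay clear of 50 Hz line noise). Band membership is
#' inclusive on the low edge and exclusive on the high edge.
#'
#' @return data frame with columns `band`, `low`, `high`
#' @export
band_definitions <- function() {
  data.frame(band = c("delta", "theta", "alpha", "beta", "gamma"),
             low = c(0.5, 4, 8, 13, 30),
             high = c(4, 8, 13, 30, 45),
             stringsAsFactors = FALSE)
}

#' Occipital electrode labels
#' @export
electrode_labels <- function() c("O1", "O2", "PO3", "POz", "PO4")

#' Canonical 25-feature column names (band_electrode order)
#'
#' Feature order is fixed: bands vary slowest, electrodes fastest
#' (delta_O1, delta_O2, ..., gamma_PO4).
#' @export
feature_names <- function() {
  as.vector(t(outer(band_definitions()$band, electrode_labels(),
                    paste, sep = "_")))
}

#' Band assignment of the 25 features
#'
#' @return factor of length 25 mapping each feature column to its band
#' @export
feature_band_map <- function() {
  factor(rep(band_definitions()$band, each = length(electrode_labels())),
         levels = band_definitions()$band)
}

# Symmetric windowed-sinc FIR band-pass (Hamming window), applied with
# zero phase by FFT convolution and group-delay compensation. Signal
# edges are reflection-padded.
fir_bandpass_zerophase <- function(x, fs, low, high, order = NULL) {
  if (is.null(order)) order <- ceiling(3.3 * fs / low)
  if (order %% 2 == 1) order <- order + 1
  n <- length(x)
  if (n <= order)
    stop("signal shorter than filter order (", order, " taps)")
  h <- signal::fir1(order, c(low, high) / (fs / 2), type = "pass")
  half <- order / 2
  pad_l <- rev(x[2:(half + 1)])
  pad_r <- rev(x[(n - half):(n - 1)])
  xp <- c(pad_l, x, pad_r)
  m <- length(xp) + length(h) - 1
  nfft <- 2^ceiling(log2(m))
  y <- Re(fft(fft(c(xp, rep(0, nfft - length(xp)))) *
              fft(c(h, rep(0, nfft - length(h)))), inverse = TRUE)) / nfft
  # compensate linear-phase delay and strip padding
  y[(2 * half + 1):(2 * half + n)]
}

#' Preprocess a continuous EEG signal
#'
#' Zero-phase FIR band-pass (default 0.1-80 Hz, windowed-sinc with a
#' Hamming window; transition width tied to the low edge) followed by
#' resampling to 250 Hz.
#'
#' @param x continuous signal (one channel)
#' @param fs_in input sampling rate in Hz (>= 250)
#' @param fs_out output rate (250 Hz)
#' @param band pass band in Hz
#' @param order FIR order; default `ceiling(3.3 * fs_in / band[1])`
#' @return signal resampled to `fs_out`
#' @export
preprocess_eeg <- function(x, fs_in, fs_out = 250, band = c(0.1, 80),
                           order = NULL) {
  stopifnot(fs_in >= fs_out)
  y <- fir_bandpass_zerophase(x, fs_in, band[1], band[2], order)
  if (fs_in == fs_out) return(y)
  t_in <- (seq_along(y) - 1) / fs_in
  t_out <- seq(0, t_in[length(t_in)], by = 1 / fs_out)
  stats::approx(t_in, y, xout = t_out)$y
}

#' Construct an epoch set
#'
#' @param data numeric array trial x electrode x sample
#' @param fs sampling rate (Hz)
#' @param window epoch window in ms relative to stimulus onset
#' @param electrodes electrode labels
#' @export
epoch_set <- function(data, fs = 250, window = c(-1800, 1500),
                      electrodes = electrode_labels()) {
  stopifnot(length(dim(data)) == 3, dim(data)[2] == length(electrodes))
  n_expect <- round((window[2] - window[1]) / 1000 * fs)
  if (abs(dim(data)[3] - n_expect) > 1)
    stop("sample count inconsistent with window and fs")
  structure(list(data = data, fs = fs, window = window,
                 electrodes = electrodes), class = "epoch_set")
}

#' Extract the prestimulus segment of every epoch
#'
#' Keeps samples with timestamps in \[-1800, 0) ms: 450 samples per
#' trial and electrode at 250 Hz. Onset-aligned and poststimulus
#' content is excluded.
#'
#' @param epochs an `epoch_set`
#' @param prestim span in ms before onset (default 1800)
#' @return an `epoch_set` covering \[-prestim, 0) ms
#' @export
extract_prestimulus <- function(epochs, prestim = 1800) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (epochs$window[1] > -prestim || epochs$window[2] < 0)
    stop("epoch window does not cover the prestimulus span")
  t_ms <- epochs$window[1] +
    (seq_len(dim(epochs$data)[3]) - 1) / epochs$fs * 1000
  keep <- t_ms >= -prestim & t_ms < 0
  epoch_set(epochs$data[, , keep, drop = FALSE], fs = epochs$fs,
            window = c(-prestim, 0), electrodes = epochs$electrodes)
}

#' Reject high-amplitude epochs
#'
#' Automated replacement for visual artifact screening: an epoch is
#' dropped when, on any electrode, its peak absolute amplitude exceeds
#' the median peak by more than `z_threshold` robust SDs (MAD) of that
#' electrode's peak distribution.
#'
#' @param epochs an `epoch_set`
#' @param z_threshold robust-z cutoff (default 5); `Inf` keeps all
#' @return list with the retained `epoch_set` and the logical
#'   `rejected` mask
#' @export
reject_epochs <- function(epochs, z_threshold = 5) {
  stopifnot(inherits(epochs, "epoch_set"))
  n <- dim(epochs$data)[1]
  if (n < 1) stop("need at least one epoch")
  peaks <- apply(abs(epochs$data), c(1, 2), max)    # trial x electrode
  rejected <- rep(FALSE, n)
  if (is.finite(z_threshold)) {
    for (e in seq_len(ncol(peaks))) {
      med <- median(peaks[, e])
      scale <- stats::mad(peaks[, e])
      if (scale <= 0) scale <- .Machine$double.eps
      rejected <- rejected | (peaks[, e] > med + z_threshold * scale)
    }
  }
  if (all(rejected)) stop("all epochs rejected")
  list(epochs = epoch_set(epochs$data[!rejected, , , drop = FALSE],
                          fs = epochs$fs, window = epochs$window,
                          electrodes = epochs$electrodes),
       rejected = rejected)
}

#' Welch power spectral density
#'
#' One-sided Welch PSD with a Hamming window of 200 samples, 50%
#' overlap (100 samples), and segments zero-padded to a 256-point FFT
#' (the defaults), matching common EEG practice at 250 Hz. No
#' detrending is applied.
#'
#' @param x numeric segment
#' @param fs sampling rate (Hz)
#' @param window_length,overlap,nfft Welch parameters
#' @return list with `freq` (Hz) and `psd` (power per Hz)
#' @export
welch_psd <- function(x, fs = 250, window_length = 200, overlap = 100,
                      nfft = 256) {
  n <- length(x)
  if (n < window_length)
    stop("segment shorter than the Welch window")
  w <- 0.54 - 0.46 * cos(2 * pi * seq(0, window_length - 1) /
                           (window_length - 1))
  u <- sum(w^2)
  starts <- seq(1, n - window_length + 1, by = window_length - overlap)
  nf <- max(nfft, window_length)
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + window_length - 1)] * w
    X <- fft(c(seg, rep(0, nf - window_length)))
    acc <- acc + Mod(X)^2
  }
  pxx <- acc / (length(starts) * fs * u)
  half <- nf %/% 2 + 1
  pxx <- pxx[1:half]
  pxx[2:(half - 1)] <- 2 * pxx[2:(half - 1)]   # one-sided
  list(freq = (0:(half - 1)) * fs / nf, psd = pxx)
}

#' Band power of a prestimulus segment, in dB
#'
#' Averages the Welch PSD over each band's bins (low edge inclusive,
#' high edge exclusive), multiplies by the band width to obtain power,
#' and converts to decibels (10 log10). An all-zero segment yields
#' `-Inf` for every band (undefined-power guard); such trials are
#' excluded downstream.
#'
#' @param x numeric segment sampled at `fs`
#' @param bands band definition data frame (see [band_definitions()])
#' @param fs sampling rate
#' @param ... passed to [welch_psd()]
#' @return named numeric vector, one dB value per band
#' @export
welch_band_power <- function(x, bands = band_definitions(), fs = 250,
                             ...) {
  p <- welch_psd(x, fs = fs, ...)
  out <- vapply(seq_len(nrow(bands)), function(i) {
    sel <- p$freq >= bands$low[i] & p$freq < bands$high[i]
    pw <- mean(p$psd[sel]) * (bands$high[i] - bands$low[i])
    10 * log10(pw)
  }, numeric(1))
  names(out) <- bands$band
  out
}

# 25-feature rows (bands x electrodes) for every epoch of a
# prestimulus epoch_set.
band_power_features <- function(epochs, bands = band_definitions()) {
  stopifnot(inherits(epochs, "epoch_set"))
  n <- dim(epochs$data)[1]
  ne <- dim(epochs$data)[2]
  out <- matrix(NA_real_, n, nrow(bands) * ne,
                dimnames = list(NULL, feature_names()))
  for (i in seq_len(n)) {
    bp <- vapply(seq_len(ne), function(e)
      welch_band_power(epochs$data[i, e, ], bands, fs = epochs$fs),
      numeric(nrow(bands)))           # bands x electrodes
    out[i, ] <- as.vector(t(bp))
  }
  out
}

#' Assemble the per-trial feature table
#'
#' Joins 25-column band-power rows to their trial labels and the VCT
#' target shared by each 40-trial group. Column order is fixed by
#' [feature_names()].
#'
#' @param features n x 25 band-power matrix (dB)
#' @param vct per-trial VCT targets (one value per 40-trial group)
#' @param labels data frame with per-trial participant, condition,
#'   block, fatigue_state columns
#' @return data frame: labels, `vct`, then the 25 features
#' @export
build_feature_table <- function(features, vct, labels) {
  if (nrow(features) != length(vct) || nrow(features) != nrow(labels))
    stop("misaligned labels: features, vct and labels differ in length")
  stopifnot(ncol(features) == 25)
  colnames(features) <- feature_names()
  cbind(labels, vct = vct, as.data.frame(features))
}
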
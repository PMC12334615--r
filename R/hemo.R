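#' Construct an fNIRS concentration series
#'
#' @param data numeric matrix, samples x channels, relative HbO
#'   concentration in micromolar
#' @param fs sampling rate in Hz
#' @export
hemo_series <- function(data, fs = 10.1725) {
  data <- as.matrix(data)
  stopifnot(nrow(data) >= 2)
  structure(list(data = data, fs = fs,
                 time = (seq_len(nrow(data)) - 1) / fs),
            class = "hemo_series")
}

#' Band-pass filter an HbO series
#'
#' Zero-phase band-pass from 0.015 to 0.1 Hz per channel (windowed-sinc
#' FIR), removing baseline drift below the high-pass edge and
#' cardiac/respiratory physiological noise above the low-pass edge.
#'
#' @param series a `hemo_series`
#' @param band pass band in Hz
#' @param order FIR order; default tied to the 0.015 Hz transition
#' @return the filtered `hemo_series`
#' @export
filter_hemo <- function(series, band = c(0.015, 0.1), order = NULL) {
  stopifnot(inherits(series, "hemo_series"))
  n <- nrow(series$data)
  if (is.null(order)) order <- ceiling(3.3 * series$fs / band[1])
  if (n <= order + 2)
    stop("series too short for the 0.015 Hz high-pass")
  out <- apply(series$data, 2, fir_bandpass_zerophase,
               fs = series$fs, low = band[1], high = band[2],
               order = order)
  hemo_series(out, fs = series$fs)
}

#' Trim artifact-contaminated measurement edges
#'
#' Computes per-channel mean +/- 2 SD bounds on the (filtered) series
#' and discards leading and trailing data until a stretch of
#' `settle` seconds occurs in which no channel exceeds its bounds.
#' Interior excursions are retained: the rule applies to the beginning
#' and end of the measurement only.
#'
#' @param series a filtered `hemo_series`
#' @param n_sd bound width in SDs (default 2)
#' @param settle clean-stretch duration in seconds (default 10)
#' @return the trimmed `hemo_series`
#' @export
trim_artifacts <- function(series, n_sd = 2, settle = 10) {
  stopifnot(inherits(series, "hemo_series"))
  x <- series$data
  n <- nrow(x)
  mu <- colMeans(x)
  s <- apply(x, 2, sd)
  flagged <- rowSums(sweep(abs(sweep(x, 2, mu)), 2, n_sd * s, ">")) > 0
  w <- max(1L, min(n, round(settle * series$fs)))
  clean_from <- function(flags) {
    # first index i such that flags[i:(i+w-1)] are all FALSE
    cs <- cumsum(as.integer(flags))
    for (i in seq_len(length(flags) - w + 1)) {
      if (cs[i + w - 1] - (if (i > 1) cs[i - 1] else 0L) == 0L) return(i)
    }
    length(flags) + 1L
  }
  lead <- clean_from(flagged) - 1L
  trail <- clean_from(rev(flagged)) - 1L
  if (lead + trail > n / 2)
    stop("more than half of the series would be trimmed")
  hemo_series(x[(lead + 1):(n - trail), , drop = FALSE], fs = series$fs)
}

#' Global occipital signal
#'
#' Pointwise mean across channels; averaging over k channels with
#' independent noise improves SNR by about sqrt(k).
#'
#' @param series a `hemo_series`
#' @return numeric vector (the channel-mean time series)
#' @export
global_signal <- function(series) {
  stopifnot(inherits(series, "hemo_series"), ncol(series$data) >= 1)
  rowMeans(series$data)
}

#' HbO amplitude
#'
#' Sample (n-1) standard deviation of the channel-averaged series, in
#' micromolar; the resting-state proxy for cortical excitability.
#'
#' @param global numeric time series (see [global_signal()])
#' @return amplitude in micromolar
#' @export
hbo_amplitude <- function(global) {
  if (length(global) < 2) stop("need at least 2 samples")
  sd(global)
}
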
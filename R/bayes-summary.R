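#' Highest posterior density interval
#'
#' Shortest interval containing `mass` of the draws, found by sweeping
#' windows over the sorted sample; ties break toward the lower start.
#'
#' @param samples numeric draws (>= 100)
#' @param mass interval mass (default 0.95)
#' @return numeric `c(lower, upper)`
#' @export
hpd <- function(samples, mass = 0.95) {
  n <- length(samples)
  if (n < 100) stop("need at least 100 draws for an HPD interval")
  stopifnot(mass > 0, mass <= 1)
  x <- sort(samples)
  m <- ceiling(mass * n)
  if (m >= n) return(c(x[1], x[n]))
  widths <- x[m:n] - x[1:(n - m + 1)]
  i <- which.min(widths)            # first minimum = lowest start
  c(x[i], x[i + m - 1])
}

#' Directional posterior probability
#'
#' Fraction of draws satisfying the directional hypothesis.
#'
#' @param samples numeric draws (>= 100)
#' @param direction "<0", ">0", or a function of the draws returning
#'   logicals
#' @return probability in \[0, 1\]
#' @export
posterior_prob <- function(samples, direction = c("<0", ">0")) {
  if (length(samples) < 100) stop("need at least 100 draws")
  if (is.function(direction)) return(mean(direction(samples)))
  direction <- match.arg(direction)
  if (direction == "<0") mean(samples < 0) else mean(samples > 0)
}

#' Summarize a posterior contrast
#'
#' @param samples draws of the contrast
#' @param name contrast label
#' @param direction directional hypothesis; default: the side of zero
#'   favoured by the posterior mean
#' @return a `contrast_summary`: mean, 95% HPD, Pr, credible flag
#' @export
contrast_summary <- function(samples, name = "contrast",
                             direction = NULL) {
  if (is.null(direction))
    direction <- if (mean(samples) < 0) "<0" else ">0"
  h <- hpd(samples, 0.95)
  pr <- posterior_prob(samples, direction)
  out <- list(name = name, mean = mean(samples), hpd = h,
              direction = direction, pr = pr)
  out$credible <- decide_credible(out)
  class(out) <- "contrast_summary"
  out
}

#' Credibility decision rule
#'
#' Evidence is credible iff the directional posterior probability
#' exceeds 97.5% and the 95% HPD interval excludes zero.
#'
#' @param contrast a `contrast_summary` (or list with `pr` and `hpd`)
#' @return logical flag
#' @export
decide_credible <- function(contrast) {
  contrast$pr > 0.975 && (contrast$hpd[1] > 0 || contrast$hpd[2] < 0)
}

#' @export
print.contrast_summary <- function(x, ...) {
  cat(sprintf("%s: E = %.3f, HPD = [%.3f, %.3f], Pr(%s) = %.3f%s\n",
              x$name, x$mean, x$hpd[1], x$hpd[2], x$direction, x$pr,
              if (x$credible) " *" else ""))
  invisible(x)
}

# Split-chain R-hat (rank-free version) for a draws matrix
# [iterations x chains].
split_rhat <- function(draws) {
  if (is.null(dim(draws))) draws <- matrix(draws, ncol = 1)
  n <- nrow(draws)
  half <- n %/% 2
  sub <- cbind(draws[1:half, , drop = FALSE],
               draws[(n - half + 1):n, , drop = FALSE])
  m <- ncol(sub); k <- nrow(sub)
  means <- colMeans(sub)
  vars <- apply(sub, 2, var)
  B <- k * var(means)
  W <- mean(vars)
  if (W == 0) return(1)
  sqrt(((k - 1) / k * W + B / k) / W)
}

# Crude effective sample size from pooled autocorrelations (Geyer
# initial-positive truncation), summed across chains.
ess_basic <- function(draws) {
  if (is.null(dim(draws))) draws <- matrix(draws, ncol = 1)
  n <- nrow(draws); m <- ncol(draws)
  ac <- rep(0, n - 1)
  for (j in seq_len(m)) {
    x <- draws[, j] - mean(draws[, j])
    v <- mean(x^2)
    if (v == 0) return(n * m)
    a <- stats::acf(x, lag.max = min(n - 2, 200), plot = FALSE,
                    demean = FALSE)$acf[-1] / v
    ac[seq_along(a)] <- ac[seq_along(a)] + a / m
  }
  s <- 0
  for (l in seq(1, length(ac) - 1, by = 2)) {
    pair <- ac[l] + ac[l + 1]
    if (is.na(pair) || pair <= 0) break
    s <- s + pair
  }
  n * m / (1 + 2 * s)
}
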
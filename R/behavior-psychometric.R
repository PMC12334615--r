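#' Fit a cumulative Gaussian psychometric function
#'
#' Maximum-likelihood Bernoulli fit of
#' \deqn{P(\mathrm{seen} \mid x) = \Phi\!\left(\frac{x - \mu}{\sigma}\right)}
#' to binary detection responses at tested contrasts, i.e. a probit
#' regression reparameterized to threshold (mean) and spread. The lapse
#' rate is fixed at zero.
#'
#' @param contrasts tested contrasts on stimulus-present trials
#' @param responses binary outcomes (1 = seen)
#' @return a `psychometric_fit` with fields `mu`, `sigma`, `converged`,
#'   `loglik`, `n`
#' @export
fit_cumulative_gaussian <- function(contrasts, responses) {
  stopifnot(length(contrasts) == length(responses))
  ok <- is.finite(contrasts) & is.finite(responses)
  contrasts <- contrasts[ok]; responses <- as.integer(responses[ok])
  if (length(contrasts) < 10)
    stop("need at least 10 stimulus-present trials")
  if (length(unique(responses)) < 2)
    stop("non-identifiable: responses contain a single class")
  fit <- suppressWarnings(
    glm(responses ~ contrasts, family = binomial(link = "probit")))
  b <- unname(coef(fit))
  conv <- isTRUE(fit$converged) && all(is.finite(b)) && b[2] > 0
  mu <- if (conv) -b[1] / b[2] else NA_real_
  sigma <- if (conv) 1 / b[2] else NA_real_
  structure(list(mu = mu, sigma = sigma, converged = conv,
                 loglik = as.numeric(stats::logLik(fit)),
                 n = length(contrasts)),
            class = "psychometric_fit")
}

#' Visual contrast threshold from a psychometric fit
#'
#' The VCT is the mean of the fitted cumulative Gaussian: the contrast
#' at which detection probability equals 50%.
#'
#' @param fit a converged `psychometric_fit`
#' @return the VCT in contrast units
#' @export
estimate_vct <- function(fit) {
  stopifnot(inherits(fit, "psychometric_fit"))
  if (!isTRUE(fit$converged)) stop("unconverged psychometric fit")
  fit$mu
}

#' Classify the fatigue state of a block
#'
#' Averages the pre- and post-block self-reports (7-point scale) and
#' labels the block low fatigue if the average is strictly below 4,
#' high fatigue otherwise.
#'
#' @param pre,post ratings in \[1, 7\]
#' @return list with `average` and `state` ("low" or "high")
#' @export
classify_fatigue <- function(pre, post) {
  if (any(c(pre, post) < 1) || any(c(pre, post) > 7))
    stop("fatigue ratings must lie in [1, 7]")
  avg <- (pre + post) / 2
  list(average = avg, state = if (avg < 4) "low" else "high")
}
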
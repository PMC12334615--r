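#' Initialize a QUEST adaptive staircase
#'
#' Bayesian grid staircase over log10 contrast threshold. The assumed
#' psychometric family is a Weibull on log contrast,
#' \deqn{p(\mathrm{seen}\mid x, t) = \gamma + (1-\gamma-\delta)
#'   \left(1 - e^{-10^{\beta (x - t)}}\right),}
#' with slope `beta`, guess rate `gamma` (the false-alarm rate) and
#' lapse rate `delta`. The posterior over the threshold grid is updated
#' after every stimulus-present trial; the recommended test contrast is
#' the point where the assumed function crosses 50% "seen", which keeps
#' the realized hit rate near the 50% operating point. Carrying the
#' final posterior of one block into the next block is the default:
#' simply keep updating the same state object.
#'
#' @param guess initial threshold guess (contrast units); centers the prior
#' @param prior_sd prior SD in log10-contrast units
#' @param grid_range contrast range covered by the threshold grid
#' @param n_grid number of log-spaced grid thresholds
#' @param beta Weibull slope
#' @param gamma guess (false-alarm) rate
#' @param delta lapse rate
#' @return a `quest_state` object
#' @export
quest_init <- function(guess = 0.3, prior_sd = 0.5,
                       grid_range = c(0.005, 2), n_grid = 200L,
                       beta = 3.5, gamma = 0.05, delta = 0.02) {
  stopifnot(grid_range[1] > 0, grid_range[2] > grid_range[1], n_grid >= 10)
  log_grid <- seq(log10(grid_range[1]), log10(grid_range[2]),
                  length.out = n_grid)
  prior <- dnorm(log_grid, mean = log10(guess), sd = prior_sd)
  prior <- prior / sum(prior)
  structure(list(log_grid = log_grid, posterior = prior,
                 beta = beta, gamma = gamma, delta = delta,
                 history = data.frame(contrast = numeric(0),
                                      outcome = integer(0))),
            class = "quest_state")
}

# Assumed psychometric function at log10-contrast x, log10-threshold t.
quest_pf <- function(x, t, beta, gamma, delta) {
  gamma + (1 - gamma - delta) * (1 - exp(-10^(beta * (x - t))))
}

#' Update the staircase posterior after a stimulus-present trial
#'
#' Multiplies the threshold posterior by the Bernoulli likelihood of the
#' observed outcome under the assumed psychometric function and
#' renormalizes. Contrasts outside the grid support are clamped with a
#' warning.
#'
#' @param state a `quest_state`
#' @param contrast tested contrast (stimulus-present trial)
#' @param outcome 1 = seen, 0 = not seen
#' @return the updated `quest_state`
#' @export
staircase_update <- function(state, contrast, outcome) {
  stopifnot(inherits(state, "quest_state"), outcome %in% c(0L, 1L))
  rng <- range(10^state$log_grid)
  if (contrast < rng[1] || contrast > rng[2]) {
    warning("contrast outside grid support; clamping")
    contrast <- min(max(contrast, rng[1]), rng[2])
  }
  p <- quest_pf(log10(contrast), state$log_grid,
                state$beta, state$gamma, state$delta)
  lik <- if (outcome == 1L) p else 1 - p
  post <- state$posterior * lik
  s <- sum(post)
  if (!is.finite(s) || s <= 0) stop("degenerate posterior after update")
  state$posterior <- post / s
  state$history <- rbind(state$history,
                         data.frame(contrast = contrast,
                                    outcome = as.integer(outcome)))
  state
}

#' Recommend the next test contrast
#'
#' Takes the posterior-mode threshold and returns the contrast at which
#' the assumed psychometric function equals 50% "seen" (for nonzero
#' guess/lapse rates this sits slightly below the Weibull threshold
#' parameter), so that testing at the recommendation targets a 50% hit
#' rate.
#'
#' @param state a `quest_state`
#' @return recommended contrast (contrast units)
#' @export
staircase_recommend <- function(state) {
  stopifnot(inherits(state, "quest_state"))
  if (any(!is.finite(state$posterior)) || sum(state$posterior) <= 0)
    stop("degenerate posterior")
  t_mode <- state$log_grid[which.max(state$posterior)]
  # offset d solves gamma + (1-gamma-delta)(1 - exp(-10^(beta d))) = 1/2
  gam <- state$gamma; del <- state$delta
  arg <- 1 - (0.5 - gam) / (1 - gam - del)
  if (arg <= 0) stop("assumed psychometric function never reaches 50%")
  d <- log10(-log(arg)) / state$beta
  10^(t_mode + d)
}

#' Posterior-mean threshold estimate
#'
#' @param state a `quest_state`
#' @return threshold estimate on the contrast scale (posterior mean in
#'   log10 space)
#' @export
staircase_estimate <- function(state) {
  stopifnot(inherits(state, "quest_state"))
  10^sum(state$log_grid * state$posterior)
}
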
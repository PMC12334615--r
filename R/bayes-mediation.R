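#' Bayesian mediation analysis of stimulation-induced changes
#'
#' Two linked regressions on the final-block, low-fatigue change
#' scores, with per-participant random intercepts and residual
#' correlations between equations set to zero (so the equations are
#' sampled independently): a mediator model regressing the oscillatory
#' change on the hemodynamic change, and an outcome model regressing
#' the threshold change on both. The indirect effect is the draw-wise
#' product of the hemodynamic-to-mediator path (a) and the
#' mediator-to-outcome path (b); the total effect is the draw-wise sum
#' of the direct effect and the indirect effect.
#'
#' @param deltas a [delta_table()] (or any data frame with `d_hbo`,
#'   the mediator column, `d_vct`, `participant`, and optionally
#'   `block`/`fatigue` columns to filter on)
#' @param mediator "d_alpha" or "d_beta"
#' @param block,fatigue rows to keep (defaults: final block, low state);
#'   `NULL` keeps everything
#' @param seed integer seed
#' @param chains,iterations,warmup sampler configuration
#' @return a `mediation_result`: draw matrices and `contrast_summary`
#'   objects for paths a and b, direct, indirect, and total effects
#' @export
fit_mediation <- function(deltas, mediator = c("d_alpha", "d_beta"),
                          block = max(deltas$block), fatigue = "low",
                          seed = 1L, chains = 4L, iterations = 2000L,
                          warmup = 1000L) {
  mediator <- match.arg(mediator)
  d <- deltas
  if (!is.null(block) && "block" %in% names(d))
    d <- d[d$block == block, ]
  if (!is.null(fatigue) && "fatigue" %in% names(d))
    d <- d[d$fatigue == fatigue, ]
  d <- d[complete.cases(d[, c("d_hbo", mediator, "d_vct")]), ]
  if (nrow(d) < 5)
    stop("insufficient rows for mediation (need >= 5, have ",
         nrow(d), ")")
  seeds <- derive_seeds(seed, 2)

  med_tab <- data.frame(y = d[[mediator]], x = d$d_hbo,
                        participant = d$participant)
  out_tab <- data.frame(y = d$d_vct, x = d$d_hbo, m = d[[mediator]],
                        participant = d$participant)
  fit_m <- sample_posterior(build_design(med_tab, ~ x, ~ 1),
                            chains = chains, iterations = iterations,
                            warmup = warmup, seed = seeds[1],
                            check = FALSE)
  fit_y <- sample_posterior(build_design(out_tab, ~ x + m, ~ 1),
                            chains = chains, iterations = iterations,
                            warmup = warmup, seed = seeds[2],
                            check = FALSE)
  a <- fit_m$draws[, "x"]
  b <- fit_y$draws[, "m"]
  direct <- fit_y$draws[, "x"]
  ndraw <- min(length(a), length(b))
  a <- a[seq_len(ndraw)]; b <- b[seq_len(ndraw)]
  direct <- direct[seq_len(ndraw)]
  indirect <- a * b
  total <- direct + indirect
  structure(list(
    mediator = mediator, n = nrow(d),
    draws = cbind(a = a, b = b, direct = direct,
                  indirect = indirect, total = total),
    a = contrast_summary(a, "path a (d_hbo -> mediator)"),
    b = contrast_summary(b, "path b (mediator -> d_vct)"),
    direct = contrast_summary(direct, "direct effect"),
    indirect = contrast_summary(indirect, "indirect effect"),
    total = contrast_summary(total, "total effect"),
    fits = list(mediator = fit_m, outcome = fit_y)),
    class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat("Bayesian mediation (", x$mediator, ", n = ", x$n, "):\n",
      sep = "")
  for (nm in c("a", "b", "direct", "indirect", "total")) print(x[[nm]])
  invisible(x)
}
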
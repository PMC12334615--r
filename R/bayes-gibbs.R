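#' Gibbs sampler for the Gaussian hierarchical model
#'
#' Fits \eqn{y = X\beta + Z b_{g} + \varepsilon}, with per-participant
#' random effects \eqn{b_g \sim N(0, \Sigma)} and Gaussian residuals,
#' by blocked conjugate Gibbs updates. Priors are weakly informative:
#' independent normals on the coefficients scaled to the outcome and
#' predictor SDs, and half-t(3) priors on the residual SD and the
#' random-effect SDs implemented through inverse-gamma /
#' inverse-Wishart scale-mixture auxiliaries (Huang-Wand
#' parameterization), which keeps every update conjugate. Draws are
#' deterministic given the seed.
#'
#' @param design a [build_design()] result
#' @param chains,iterations,warmup sampling configuration (defaults 4
#'   chains of 2000 iterations, first 1000 discarded)
#' @param seed integer seed
#' @param ranef fit the random-effect part? (`FALSE` gives a
#'   fixed-effects-only model)
#' @param priors list: `beta_scale` (coefficient prior SD multiplier,
#'   default 10; `Inf` for a flat prior), `sd_scale` (half-t scale
#'   multiplier, default 10), `nu` (half-t df, 3)
#' @param fix_sigma optional known residual SD (held fixed; used by the
#'   conjugate-case oracle)
#' @param check run split-R-hat convergence checks (warn above 1.01,
#'   error above 1.1)
#' @return a `posterior_samples` object
#' @export
sample_posterior <- function(design, chains = 4L, iterations = 2000L,
                             warmup = 1000L, seed = 1L, ranef = TRUE,
                             priors = list(), fix_sigma = NULL,
                             check = TRUE) {
  pr <- modifyList(list(beta_scale = 10, sd_scale = 10, nu = 3), priors)
  y <- design$y; X <- design$X
  n <- length(y); k <- ncol(X)
  kept <- iterations - warmup
  stopifnot(kept >= 1)
  use_ranef <- ranef && !is.null(design$Z) && n > 0
  sy <- if (n > 1) sd(y) else 1
  if (!is.finite(sy) || sy == 0) sy <- 1
  sx <- if (n > 0) apply(X, 2, sd) else rep(1, k)
  sx[!is.finite(sx) | sx < 1e-8] <- 1
  tau <- pr$beta_scale * sy / sx           # coefficient prior SDs
  nu <- pr$nu
  A_res <- pr$sd_scale * sy
  A_ran <- pr$sd_scale * sy

  if (n == 0) {                            # prior predictive draws
    seeds <- derive_seeds(seed, 1)
    draws <- with_seed(seeds[1], {
      b <- sapply(seq_len(k), function(j)
        rnorm(chains * kept, 0, min(tau[j], 1e6)))
      sig <- abs(A_res * stats::rt(chains * kept, df = nu))
      cbind(b, sigma = sig)
    })
    colnames(draws) <- c(colnames(X), "sigma")
    return(structure(list(draws = draws, chain_draws = NULL,
                          diagnostics = NULL, design = design,
                          seed = seed, prior_only = TRUE),
                     class = "posterior_samples"))
  }

  if (use_ranef) {
    Z <- design$Z; q <- ncol(Z)
    g <- design$group; J <- max(g)
    gidx <- split(seq_len(n), g)
  } else {
    q <- 0; J <- 0
  }
  XtX <- crossprod(X)
  if (use_ranef && q > 1)
    Zg <- lapply(gidx, function(ix) design$Z[ix, , drop = FALSE])
  qr_rank <- qr(X)$rank
  if (is.finite(pr$beta_scale) == FALSE && qr_rank < k)
    stop("rank-deficient fixed-effect design")

  par_names <- c(colnames(X), "sigma",
                 if (use_ranef) paste0("sd_ranef", seq_len(q)))
  npar <- length(par_names)
  chain_arr <- array(NA_real_, c(kept, chains, npar),
                     dimnames = list(NULL, NULL, par_names))
  seeds <- derive_seeds(seed, chains)

  for (ch in seq_len(chains)) {
    chain_arr[, ch, ] <- with_seed(seeds[ch], {
      beta <- rep(0, k)
      sig2 <- if (is.null(fix_sigma)) var(y) else fix_sigma^2
      if (!is.finite(sig2) || sig2 <= 0) sig2 <- 1
      a0 <- 1
      if (use_ranef) {
        b <- matrix(0, J, q)
        Sigma <- diag(sy^2 / 4, q)
        aW <- rep(1, q)
      }
      out <- matrix(NA_real_, kept, npar)
      for (it in seq_len(iterations)) {
        zb <- if (use_ranef) rowSums(design$Z * b[g, , drop = FALSE])
              else 0
        # -- fixed effects
        prec <- XtX / sig2
        if (is.finite(pr$beta_scale))
          diag(prec) <- diag(prec) + 1 / tau^2
        ch_p <- tryCatch(chol(prec), error = function(e)
          stop("rank-deficient design: cannot factor the coefficient ",
               "precision"))
        mvec <- backsolve(ch_p, forwardsolve(t(ch_p),
                 crossprod(X, y - zb) / sig2))
        beta <- drop(mvec + backsolve(ch_p, rnorm(k)))
        r <- y - drop(X %*% beta)
        # -- random effects
        if (use_ranef) {
          Sinv <- solve(Sigma)
          if (q == 1) {
            z1 <- design$Z[, 1]
            szz <- as.numeric(rowsum(z1 * z1, g))
            szr <- as.numeric(rowsum(z1 * r, g))
            prec_b <- szz / sig2 + Sinv[1, 1]
            b[, 1] <- rnorm(J, (szr / sig2) / prec_b, sqrt(1 / prec_b))
          } else {
            for (j in seq_len(J)) {
              ix <- gidx[[j]]
              Aj <- crossprod(Zg[[j]]) / sig2 + Sinv
              cj <- chol(Aj)
              mj <- backsolve(cj, forwardsolve(t(cj),
                     crossprod(Zg[[j]], r[ix]) / sig2))
              b[j, ] <- drop(mj + backsolve(cj, rnorm(q)))
            }
          }
          # -- random-effect covariance (Huang-Wand inverse-Wishart)
          S <- 2 * nu * diag(1 / aW, q) + crossprod(b)
          W <- rWishart(1, nu + q - 1 + J, solve(S))[, , 1]
          Sigma <- solve(W)
          Sigma <- (Sigma + t(Sigma)) / 2
          Sinv2 <- solve(Sigma)
          aW <- 1 / rgamma(q, (nu + q) / 2,
                           rate = nu * diag(Sinv2) + 1 / A_ran^2)
          zb <- rowSums(design$Z * b[g, , drop = FALSE])
          r2 <- r - zb
        } else r2 <- r
        # -- residual variance (half-t via auxiliary)
        if (is.null(fix_sigma)) {
          sig2 <- 1 / rgamma(1, (nu + n) / 2,
                             rate = nu / a0 + sum(r2^2) / 2)
          a0 <- 1 / rgamma(1, (nu + 1) / 2,
                           rate = nu / sig2 + 1 / A_res^2)
          if (!is.finite(sig2) || sig2 <= 0)
            stop("divergent variance update")
        }
        if (it > warmup) {
          out[it - warmup, ] <- c(beta, sqrt(sig2),
                                  if (use_ranef) sqrt(diag(Sigma)))
        }
      }
      out
    })
  }

  diags <- data.frame(
    parameter = par_names,
    rhat = vapply(seq_len(npar), function(p)
      split_rhat(chain_arr[, , p, drop = TRUE]), numeric(1)),
    ess = vapply(seq_len(npar), function(p)
      ess_basic(chain_arr[, , p, drop = TRUE]), numeric(1)))
  if (check) {
    worst <- max(diags$rhat, na.rm = TRUE)
    if (worst > 1.1)
      stop(sprintf("chains did not converge (max split R-hat %.3f)",
                   worst))
    if (worst > 1.01)
      warning(sprintf("possible non-convergence (max split R-hat %.3f)",
                      worst))
  }
  draws <- do.call(rbind, lapply(seq_len(chains), function(ch)
    chain_arr[, ch, , drop = TRUE]))
  colnames(draws) <- par_names
  structure(list(draws = draws, chain_draws = chain_arr,
                 diagnostics = diags, design = design, seed = seed,
                 prior_only = FALSE),
            class = "posterior_samples")
}

#' Fixed-effect draws
#' @param post a `posterior_samples`
#' @param pars optional parameter names
#' @return draws matrix
#' @export
fixef_draws <- function(post, pars = NULL) {
  d <- post$draws
  if (is.null(pars)) pars <- setdiff(colnames(d),
                                     c("sigma",
                                       grep("^sd_ranef", colnames(d),
                                            value = TRUE)))
  d[, pars, drop = FALSE]
}

# Fixed-effect design row for a named cell (factors at given levels,
# numeric covariates at given values, default 0).
design_row <- function(design, values = list()) {
  vars <- all.vars(design$fixed)
  df <- list()
  for (v in vars) {
    col <- design$data[[v]]
    if (is.factor(col)) {
      lev <- levels(col)
      val <- if (v %in% names(values)) as.character(values[[v]]) else lev[1]
      df[[v]] <- factor(val, levels = lev)
    } else {
      df[[v]] <- if (v %in% names(values)) values[[v]] else 0
    }
  }
  model.matrix(design$fixed, as.data.frame(df))
}

#' Posterior contrast between two cells of the design
#'
#' Draws of the difference in expected outcome between two factor
#' cells, with numeric covariates (e.g. the baseline) held equal so
#' they cancel.
#'
#' @param post a `posterior_samples`
#' @param cell_a,cell_b named lists of factor levels, e.g.
#'   `list(condition = "sham", block = "5", fatigue = "low")`
#' @param name contrast label
#' @return a `contrast_summary` of cell_a minus cell_b
#' @export
cell_contrast <- function(post, cell_a, cell_b, name = "contrast") {
  xa <- design_row(post$design, cell_a)
  xb <- design_row(post$design, cell_b)
  w <- drop(xa - xb)
  beta <- fixef_draws(post, colnames(post$design$X))
  contrast_summary(drop(beta %*% w), name = name)
}
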
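#' Permutation test of state differences in band contributions
#'
#' Observed statistic: per-band difference of normalized sensitivity
#' contributions, low-state minus high-state, each state analyzed with
#' its own freshly trained network. Null distribution: the pooled rows
#' are relabeled `n_perm` times preserving the group sizes, and both
#' networks are retrained for every relabeling. The two-tailed
#' empirical p-value is the position of the observed difference within
#' the permutation distribution,
#' \eqn{p = 2 \min(r, 1 - r)} with
#' \eqn{r = (1 + \#\{\Delta^{perm} \le \Delta^{obs}\}) / (n_{perm}+1)},
#' capped at 1. The permutation distribution need not be centred on
#' zero (nonlinear fits and unequal group sizes shift it); the test is
#' against that distribution, not against zero. Benjamini-Hochberg
#' adjusted p-values across the five bands are included.
#'
#' @param x_low,y_low low-state features and targets
#' @param x_high,y_high high-state features and targets
#' @param spec a [net_spec()]; per-permutation training seeds are
#'   derived from `seed`
#' @param n_perm number of permutations (>= 19)
#' @param seed master seed
#' @param threshold variance share for component selection
#' @param band_map feature-to-band assignment
#' @return a `permutation_result`
#' @export
permutation_test <- function(x_low, y_low, x_high, y_high,
                             spec = net_spec_small(), n_perm = 199L,
                             seed = 1L, threshold = 0.90,
                             band_map = feature_band_map()) {
  x_low <- as.matrix(x_low); x_high <- as.matrix(x_high)
  n_lo <- nrow(x_low); n_hi <- nrow(x_high)
  if (n_lo < 1 || n_hi < 1) stop("both groups must be non-empty")
  if (n_perm < 19) stop("need at least 19 permutations")
  min_split <- ceiling(1 / min(spec$val_frac, 1 - spec$val_frac))
  if (min(n_lo, n_hi) < max(25, min_split))
    stop("group sizes too small to split 8:2")
  seeds <- derive_seeds(seed, 2 * (n_perm + 1))

  contrib_pair <- function(xl, yl, xh, yh, s1, s2) {
    cl <- sensitivity_analysis(xl, yl, modifyList(spec, list(seed = s1)),
                               threshold, band_map)$contributions
    ch <- sensitivity_analysis(xh, yh, modifyList(spec, list(seed = s2)),
                               threshold, band_map)$contributions
    cl - ch
  }
  obs_low <- sensitivity_analysis(
    x_low, y_low, modifyList(spec, list(seed = seeds[1])),
    threshold, band_map)$contributions
  obs_high <- sensitivity_analysis(
    x_high, y_high, modifyList(spec, list(seed = seeds[2])),
    threshold, band_map)$contributions
  observed <- obs_low - obs_high

  xp <- rbind(x_low, x_high)
  yp <- c(y_low, y_high)
  n <- n_lo + n_hi
  perm <- matrix(NA_real_, n_perm, length(observed),
                 dimnames = list(NULL, names(observed)))
  perm_seeds <- derive_seeds(seed + 1L, n_perm)
  for (j in seq_len(n_perm)) {
    lab <- with_seed(perm_seeds[j], sample(n, n_lo))
    perm[j, ] <- contrib_pair(xp[lab, , drop = FALSE], yp[lab],
                              xp[-lab, , drop = FALSE], yp[-lab],
                              seeds[2 * j + 1], seeds[2 * j + 2])
  }
  p <- vapply(seq_along(observed), function(b) {
    r_lo <- (1 + sum(perm[, b] <= observed[b])) / (n_perm + 1)
    r_hi <- (1 + sum(perm[, b] >= observed[b])) / (n_perm + 1)
    min(1, 2 * min(r_lo, r_hi))
  }, numeric(1))
  names(p) <- names(observed)
  structure(list(observed = observed, contributions_low = obs_low,
                 contributions_high = obs_high, perm = perm, p = p,
                 p_adjusted = fdr_adjust(p), n_perm = n_perm,
                 seed = seed, n_low = n_lo, n_high = n_hi),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("permutation_result (", x$n_perm, " permutations):\n", sep = "")
  print(data.frame(band = names(x$observed),
                   delta = round(x$observed, 4),
                   p = round(x$p, 4),
                   p_fdr = round(x$p_adjusted, 4)))
  invisible(x)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values with enforced monotonicity, capped at 1.
#'
#' @param p raw p-values in (0, 1]
#' @return adjusted p-values
#' @export
fdr_adjust <- function(p) {
  if (any(p <= 0 | p > 1 | !is.finite(p)))
    stop("p-values must lie in (0, 1]")
  p.adjust(p, method = "BH")
}

#' Hyperparameter grid search
#'
#' Trains every combination in the grid with early stopping and
#' returns the specification with the lowest final validation loss
#' along with the full loss table. The default grid crosses hidden
#' units (32, 64), batch sizes (32, 64), and learning rates
#' (0.01, 0.001): eight combinations.
#'
#' @param x,y features and targets
#' @param grid data frame with columns `hidden`, `batch`, `lr`
#' @param spec base [net_spec()] supplying the remaining fields
#' @param groups optional grouping for the validation split
#' @return list with `best` (a `net_spec`), `table` (loss table), and
#'   `nets`
#' @export
hyperparameter_search <- function(x, y,
                                  grid = expand.grid(
                                    hidden = c(32L, 64L),
                                    batch = c(32L, 64L),
                                    lr = c(0.01, 0.001)),
                                  spec = net_spec(), groups = NULL) {
  if (nrow(grid) < 1) stop("empty hyperparameter grid")
  nets <- vector("list", nrow(grid))
  loss <- rep(NA_real_, nrow(grid))
  for (i in seq_len(nrow(grid))) {
    si <- modifyList(spec, list(hidden = as.integer(grid$hidden[i]),
                                batch = as.integer(grid$batch[i]),
                                lr = grid$lr[i]))
    class(si) <- "net_spec"
    nets[[i]] <- tryCatch(train_net(x, y, si, groups = groups),
                          error = function(e) NULL)
    if (!is.null(nets[[i]])) loss[i] <- nets[[i]]$best_val
  }
  if (all(is.na(loss))) stop("all hyperparameter runs failed")
  tab <- cbind(grid, val_loss = loss)
  best_i <- which.min(loss)
  best <- modifyList(spec, list(hidden = as.integer(grid$hidden[best_i]),
                                batch = as.integer(grid$batch[best_i]),
                                lr = grid$lr[best_i]))
  class(best) <- "net_spec"
  list(best = best, table = tab, nets = nets, best_index = best_i)
}
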
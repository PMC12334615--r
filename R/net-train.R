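#' Regression network specification
#'
#' Single-hidden-layer rectifier network with a linear scalar output,
#' trained by Adam on mean-squared error with an 8:2 train/validation
#' split and early stopping.
#'
#' @param hidden hidden units (default 64)
#' @param lr learning rate (default 0.001)
#' @param batch minibatch size (default 32)
#' @param max_epochs maximum training epochs (default 200)
#' @param val_frac validation fraction (default 0.2)
#' @param patience early-stopping patience in epochs (default 5)
#' @param seed integer seed (initialization, shuffles, split)
#' @return a `net_spec`
#' @export
net_spec <- function(hidden = 64L, lr = 0.001, batch = 32L,
                     max_epochs = 200L, val_frac = 0.2, patience = 5L,
                     seed = 1L) {
  stopifnot(hidden >= 1, lr > 0, batch >= 1, max_epochs >= 1,
            val_frac > 0, val_frac < 1, patience >= 1)
  structure(list(hidden = as.integer(hidden), lr = lr,
                 batch = as.integer(batch),
                 max_epochs = as.integer(max_epochs),
                 val_frac = val_frac, patience = as.integer(patience),
                 seed = as.integer(seed)),
            class = "net_spec")
}

#' Compact network preset for permutation studies
#'
#' A small architecture (16 hidden units, up to 100 epochs, learning
#' rate 0.01 so the compact net converges before early stopping fires)
#' used for desk-scale permutation and calibration runs, where
#' thousands of retrainings are required.
#' @param ... overrides passed to [net_spec()]
#' @export
net_spec_small <- function(...) {
  do.call(net_spec, modifyList(list(hidden = 16L, max_epochs = 100L,
                                    lr = 0.01),
                               list(...)))
}

#' Train the regression network
#'
#' Splits rows into training and validation sets (seeded random split,
#' or group-respecting if `groups` is given), z-scores the features on
#' the training split only, and trains with Adam and early stopping.
#' The returned weights are those of the best validation epoch.
#' Deterministic given `spec$seed`.
#'
#' @param x feature matrix (n x p)
#' @param y numeric targets
#' @param spec a [net_spec()]
#' @param groups optional group labels; the validation split then
#'   samples whole groups (e.g. 40-trial VCT groups)
#' @return a `trained_net`
#' @export
train_net <- function(x, y, spec = net_spec(), groups = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 25) stop("too few rows to train (need >= 25)")
  if (any(!is.finite(y)) || any(!is.finite(x)))
    stop("features and targets must be finite")
  if (var(y) == 0) stop("degenerate (constant) target")
  seeds <- derive_seeds(spec$seed, 2)
  idx_val <- with_seed(seeds[1], {
    if (is.null(groups)) {
      sample(n, max(1, round(spec$val_frac * n)))
    } else {
      gs <- unique(groups)
      vg <- sample(gs, max(1, round(spec$val_frac * length(gs))))
      which(groups %in% vg)
    }
  })
  idx_tr <- setdiff(seq_len(n), idx_val)
  if (length(idx_tr) < spec$batch)
    stop("training split smaller than one minibatch")
  ctr <- colMeans(x[idx_tr, , drop = FALSE])
  scl <- apply(x[idx_tr, , drop = FALSE], 2, sd)
  scl[!is.finite(scl) | scl < 1e-12] <- 1
  xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  fit <- mlp_train_cpp(xs[idx_tr, , drop = FALSE], y[idx_tr],
                       xs[idx_val, , drop = FALSE], y[idx_val],
                       spec$hidden, spec$lr, spec$batch,
                       spec$max_epochs, spec$patience,
                       as.integer(seeds[2]))
  structure(list(W1 = fit$W1, b1 = drop(fit$b1), w2 = drop(fit$w2),
                 b2 = fit$b2, center = ctr, scale = scl,
                 train_loss = fit$train_loss, val_loss = fit$val_loss,
                 best_val = fit$best_val, best_epoch = fit$best_epoch,
                 stop_epoch = fit$stop_epoch, n_iter = fit$n_iter,
                 spec = spec, n_train = length(idx_tr),
                 n_val = length(idx_val)),
            class = "trained_net")
}

#' @export
predict.trained_net <- function(object, newdata, ...) {
  xs <- sweep(sweep(as.matrix(newdata), 2, object$center), 2,
              object$scale, "/")
  h <- xs %*% t(object$W1)
  h <- sweep(h, 2, object$b1, "+")
  h[h < 0] <- 0
  drop(h %*% object$w2 + object$b2)
}

#' Analytic input gradient
#'
#' Back-propagated gradient of the scalar output with respect to the
#' inputs, chained through the feature standardization so the values
#' refer to original feature units. For a rectifier network the
#' gradient at x is \eqn{\sum_j w^{(2)}_j 1[z_j(x) > 0]\, W^{(1)}_{j,}}.
#'
#' @param net a `trained_net`
#' @param x a single input vector or an n x p matrix
#' @return gradient vector, or n x p matrix of per-row gradients
#' @export
input_gradient <- function(net, x) {
  xm <- if (is.null(dim(x))) matrix(x, nrow = 1) else as.matrix(x)
  xs <- sweep(sweep(xm, 2, net$center), 2, net$scale, "/")
  z <- sweep(xs %*% t(net$W1), 2, net$b1, "+")
  act <- (z > 0) * 1
  g <- (act * matrix(net$w2, nrow(xm), length(net$w2), byrow = TRUE)) %*%
    net$W1
  g <- sweep(g, 2, net$scale, "/")
  if (is.null(dim(x))) drop(g) else g
}

#' Exactly linear network
#'
#' Builds a `trained_net` whose output equals \eqn{w^\top x + b} for
#' every input with \eqn{|w^\top x| < c}: two mirrored rectifier units
#' held in their active region. Used for closed-form checks
#' (gradient = w everywhere, sensitivity matrix \eqn{w w^\top}).
#'
#' @param w weight vector
#' @param b output bias
#' @param c activation margin (keep inputs within `|w'x| < c`)
#' @export
linear_net <- function(w, b = 0, c = 1e6) {
  p <- length(w)
  structure(list(W1 = rbind(w, -w), b1 = c(c, c),
                 w2 = c(0.5, -0.5), b2 = b,
                 center = rep(0, p), scale = rep(1, p),
                 train_loss = numeric(0), val_loss = numeric(0),
                 best_val = NA_real_, best_epoch = 0L,
                 stop_epoch = 0L, n_iter = 0L,
                 spec = NULL, n_train = 0L, n_val = 0L),
            class = "trained_net")
}
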
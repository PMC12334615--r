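#' Gradient sensitivity matrix
#'
#' \deqn{S = \frac{1}{N} \sum_{i=1}^{N} (\nabla_{x_i} y_i)
#'   (\nabla_{x_i} y_i)^\top,}
#' the average outer product of the network's input gradients over the
#' sample: symmetric positive semi-definite by construction, with
#' trace equal to the mean squared gradient norm.
#'
#' @param net a `trained_net`
#' @param x n x p matrix of inputs (N >= 1)
#' @return p x p sensitivity matrix with the per-sample gradients
#'   attached as attribute `"gradients"`
#' @export
sensitivity_matrix <- function(net, x) {
  xm <- if (is.null(dim(x))) matrix(x, nrow = 1) else as.matrix(x)
  stopifnot(nrow(xm) >= 1)
  g <- input_gradient(net, xm)
  s <- crossprod(g) / nrow(g)
  s <- (s + t(s)) / 2
  attr(s, "gradients") <- g
  s
}

#' Eigen-decomposition of a sensitivity matrix
#'
#' @param s symmetric matrix
#' @return list with `values` (descending) and `vectors` (orthonormal
#'   columns)
#' @export
eigendecompose <- function(s) {
  s <- unclass(s); attr(s, "gradients") <- NULL
  if (max(abs(s - t(s))) > 1e-8 * max(1, max(abs(s))))
    stop("input matrix is not symmetric")
  e <- eigen((s + t(s)) / 2, symmetric = TRUE)
  list(values = e$values, vectors = e$vectors)
}

#' Number of components explaining a variance share
#'
#' Smallest k whose leading eigenvalues account for at least
#' `threshold` of the total (default 90%).
#'
#' @param values eigenvalues in descending order
#' @param threshold cumulative share (default 0.9)
#' @export
select_components <- function(values, threshold = 0.90) {
  v <- pmax(values, 0)
  if (is.unsorted(rev(v))) stop("eigenvalues must be descending")
  tot <- sum(v)
  if (tot <= 0) stop("all-zero spectrum")
  which(cumsum(v) / tot >= threshold)[1]
}

#' Band-wise sensitivity contributions
#'
#' For each frequency band: the mean absolute value of the components
#' of the first k eigenvectors over that band's features, normalized
#' across bands to sum to 1. Eigenvectors are unweighted by default;
#' `eigenvalue_weighted = TRUE` weights each eigenvector's components
#' by its eigenvalue share.
#'
#' @param vectors eigenvector matrix (columns)
#' @param k number of leading eigenvectors to use
#' @param band_map factor assigning each feature to a band (default
#'   [feature_band_map()])
#' @param values eigenvalues (needed only when weighting)
#' @param eigenvalue_weighted weight components by eigenvalue share?
#' @return named numeric vector of per-band contributions (sums to 1)
#' @export
band_contributions <- function(vectors, k, band_map = feature_band_map(),
                               values = NULL,
                               eigenvalue_weighted = FALSE) {
  if (length(band_map) != nrow(vectors))
    stop("band_map must assign every feature to a band")
  if (anyNA(band_map)) stop("band_map contains unassigned features")
  v <- abs(vectors[, seq_len(k), drop = FALSE])
  if (eigenvalue_weighted) {
    if (is.null(values)) stop("eigenvalues required for weighting")
    wt <- pmax(values[seq_len(k)], 0)
    v <- sweep(v, 2, wt / sum(wt), "*")
  }
  contrib <- tapply(rowMeans(v), band_map, mean)
  out <- as.numeric(contrib / sum(contrib))
  names(out) <- levels(band_map)
  out
}

#' Full sensitivity analysis of one feature set
#'
#' Train, form the sensitivity matrix over all rows, eigen-decompose,
#' select the components explaining 90% of the variance, and compute
#' normalized band contributions.
#'
#' @param x n x 25 feature matrix
#' @param y targets
#' @param spec a [net_spec()]
#' @param threshold variance share for component selection
#' @param band_map feature-to-band assignment
#' @param groups optional grouping for the validation split
#' @return a `sensitivity_result`
#' @export
sensitivity_analysis <- function(x, y, spec = net_spec(),
                                 threshold = 0.90,
                                 band_map = feature_band_map(),
                                 groups = NULL) {
  net <- train_net(x, y, spec, groups = groups)
  s <- sensitivity_matrix(net, x)
  e <- eigendecompose(s)
  k <- select_components(e$values, threshold)
  contrib <- band_contributions(e$vectors, k, band_map)
  structure(list(net = net, S = s, values = e$values,
                 vectors = e$vectors, k = k,
                 contributions = contrib, n = nrow(as.matrix(x))),
            class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat("sensitivity_result: n =", x$n, ", k =", x$k, "components\n")
  print(round(x$contributions, 4))
  invisible(x)
}
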
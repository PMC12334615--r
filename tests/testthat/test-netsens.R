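test_that("training is deterministic, learns realizable targets, and
           respects the patience contract", {
  set.seed(30)
  x <- matrix(rnorm(2000 * 25), 2000, 25)
  w <- rnorm(25)
  y <- drop(x %*% w)
  spec <- net_spec(hidden = 32, lr = 0.01, max_epochs = 200,
                   patience = 10, seed = 9)
  net <- train_net(x, y, spec)
  expect_lt(net$best_val, 1e-3 * var(y))
  net2 <- train_net(x, y, spec)
  expect_identical(net$W1, net2$W1)
  expect_identical(net$stop_epoch, net2$stop_epoch)
  # early stop only fires after `patience` non-improving epochs
  if (net$stop_epoch < spec$max_epochs)
    expect_equal(net$stop_epoch - net$best_epoch, spec$patience)
  expect_error(train_net(x, rep(1, 300), spec), "constant")
  expect_error(train_net(x, c(y[-1], NA), spec), "finite")
})

test_that("analytic gradients match finite differences and rectifier
           closed forms", {
  set.seed(31)
  for (i in 1:25) {
    net <- random_net()
    x0 <- rnorm(25)
    # stay away from rectifier kinks
    z <- drop(net$W1 %*% ((x0 - net$center) / net$scale)) + net$b1
    if (min(abs(z)) < 1e-3) next
    g <- input_gradient(net, x0)
    fd <- fd_gradient(net, x0)
    expect_lt(max(abs(g - fd)) / max(abs(g)), 1e-5)
  }
  # all hidden units inactive -> zero gradient
  net <- random_net(hidden = 4)
  net$b1 <- rep(-1e6, 4)
  expect_equal(input_gradient(net, rnorm(25)), rep(0, 25))
  # linear region: gradient equals the weight vector everywhere
  w <- rnorm(25)
  expect_equal(input_gradient(linear_net(w), rnorm(25)), w)
})

test_that("sensitivity matrix obeys its algebraic identities", {
  set.seed(32)
  w <- rnorm(25)
  X <- matrix(rnorm(40 * 25), 40, 25)
  S <- sensitivity_matrix(linear_net(w), X)
  expect_lt(max(abs(S - outer(w, w))), 1e-10)        # rank-1 closed form
  net <- random_net()
  Xr <- matrix(rnorm(30 * 25), 30, 25)
  Sr <- sensitivity_matrix(net, Xr)
  expect_equal(Sr, t(Sr))
  ev <- eigen(unclass(Sr), symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-10)                          # PSD
  g <- attr(Sr, "gradients")
  expect_lt(abs(sum(diag(Sr)) - mean(rowSums(g^2))), 1e-10)
  # identical inputs: S = g g'
  one <- Xr[1, ]
  S1 <- sensitivity_matrix(net, rbind(one, one, one))
  g1 <- input_gradient(net, one)
  expect_lt(max(abs(S1 - outer(g1, g1))), 1e-12)
})

test_that("eigen-decomposition reconstructs and matches a brute-force
           small-matrix oracle", {
  set.seed(33)
  A <- matrix(rnorm(75), 25, 3); S <- tcrossprod(A) / 3
  e <- eigendecompose(S)
  expect_lt(norm(S - e$vectors %*% diag(e$values) %*% t(e$vectors), "F"),
            1e-8 * norm(S, "F"))
  expect_equal(crossprod(e$vectors), diag(25), tolerance = 1e-8)
  # 3x3 oracle: roots of the characteristic polynomial
  B <- crossprod(matrix(rnorm(9), 3, 3))
  tr <- sum(diag(B))
  c2 <- (tr^2 - sum(B * B)) / 2     # sum of 2x2 principal minors
  lam <- sort(Re(polyroot(c(-det(B), c2, -tr, 1))), decreasing = TRUE)
  expect_equal(eigendecompose(B)$values, lam, tolerance = 1e-8)
  expect_error(eigendecompose(matrix(rnorm(9), 3, 3)), "symmetric")
  # rank-1: top pair is (|w|^2, w/|w|)
  w <- rnorm(25)
  ew <- eigendecompose(outer(w, w))
  expect_equal(ew$values[1], sum(w^2))
  expect_lt(min(sum((ew$vectors[, 1] - w / sqrt(sum(w^2)))^2),
                sum((ew$vectors[, 1] + w / sqrt(sum(w^2)))^2)), 1e-16)
})

test_that("component selection takes the smallest k reaching the
           variance share", {
  expect_equal(select_components(c(9, 1)), 1)
  expect_equal(select_components(c(5, 4, 1)), 2)
  expect_equal(select_components(rep(1, 10)), 9)
  expect_error(select_components(c(0, 0)), "all-zero")
  expect_error(select_components(c(1, 5)), "descending")
})

test_that("band contributions aggregate eigenvector mass as specified", {
  bm <- feature_band_map()
  v <- matrix(0, 25, 2)
  v[bm == "alpha", 1] <- 1 / sqrt(5)
  expect_equal(band_contributions(v, 1),
               setNames(c(0, 0, 1, 0, 0), levels(bm)))
  u <- matrix(1 / 5, 25, 3)
  expect_equal(unname(band_contributions(u, 2)), rep(0.2, 5))
  # linear net: contributions proportional to band-wise mean |w|
  set.seed(34)
  w <- rnorm(25)
  S <- sensitivity_matrix(linear_net(w), matrix(rnorm(125), 5, 25))
  e <- eigendecompose(S)
  k <- select_components(e$values)
  expect_equal(k, 1)
  mb <- tapply(abs(w), bm, mean)
  expect_equal(unname(band_contributions(e$vectors, k)),
               unname(as.numeric(mb / sum(mb))), tolerance = 1e-10)
  expect_error(band_contributions(v, 1, band_map = bm[1:10]),
               "every feature")
})

test_that("BH adjustment follows the step-up formula", {
  expect_equal(fdr_adjust(0.03), 0.03)
  expect_equal(fdr_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  set.seed(35)
  p <- runif(10, 0.001, 1)
  adj <- fdr_adjust(p)
  expect_true(all(adj >= p))
  # manual step-up with monotone cap
  o <- order(p)
  man <- rev(cummin(rev(p[o] * 10 / seq_len(10))))
  expect_equal(adj[o], pmin(man, 1))
  expect_error(fdr_adjust(c(0.5, 0)), "\\(0, 1\\]")
})

test_that("the permutation test recovers a planted state-specific
           alpha coupling", {
  set.seed(36)
  fs <- simulate_feature_set(800, 800, coupling_low = c(alpha = 1),
                             noise_sd = 0.25)
  pt <- permutation_test(fs$x_low, fs$y_low, fs$x_high, fs$y_high,
                         spec = net_spec_small(seed = 2), n_perm = 49,
                         seed = 13)
  expect_equal(names(which.max(pt$observed)), "alpha")
  expect_lt(pt$p["alpha"], 0.05)
  expect_true(all(pt$p > 0 & pt$p <= 1))
  expect_true(all(pt$p_adjusted >= pt$p - 1e-12))
  expect_error(permutation_test(fs$x_low[1:5, ], fs$y_low[1:5],
                                fs$x_high, fs$y_high, n_perm = 49),
               "too small")
  expect_error(permutation_test(fs$x_low, fs$y_low, fs$x_high,
                                fs$y_high, n_perm = 5), "at least 19")
})

test_that("the hyperparameter grid search returns the argmin of the
           loss table", {
  set.seed(37)
  fs <- simulate_feature_set(150, 10, coupling_low = c(alpha = 1))
  hs <- hyperparameter_search(fs$x_low, fs$y_low,
                              spec = net_spec(max_epochs = 15, seed = 3))
  expect_equal(nrow(hs$table), 8)      # 2 hidden x 2 batch x 2 lr
  expect_equal(min(hs$table$val_loss),
               hs$table$val_loss[hs$best_index], tolerance = 1e-12)
  expect_equal(hs$best$hidden, hs$table$hidden[hs$best_index])
  one <- hyperparameter_search(fs$x_low, fs$y_low,
                               grid = data.frame(hidden = 8L, batch = 32L,
                                                 lr = 0.005),
                               spec = net_spec(max_epochs = 10, seed = 3))
  expect_equal(one$best$hidden, 8L)
  expect_equal(one$best$lr, 0.005)
})
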
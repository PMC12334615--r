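test_that("treatment-coded designs have the expected structure", {
  set.seed(20)
  tab <- expand.grid(participant = 1:6, condition = c("sham", "trns"),
                     block = factor(2:5))
  tab$baseline <- rnorm(nrow(tab))
  tab$y <- rnorm(nrow(tab))
  des <- build_design(tab, ~ baseline + condition * block,
                      ~ 1 + condition, outcome = "y")
  # intercept + baseline + condition + 3 blocks + 3 interactions
  expect_equal(ncol(des$X), 9)
  # reference cell rows: all non-intercept factor columns zero
  ref <- des$X[tab$condition == "sham" & tab$block == "2", ]
  expect_true(all(ref[, -(1:2)] == 0))
  # missing cells are reported explicitly
  tab2 <- tab[!(tab$condition == "trns" & tab$block == "4"), ]
  expect_error(build_design(tab2, ~ condition * block, ~ 1, "y"),
               "missing cells: .*trns/4")
})

test_that("identical arms give an all-zero change table", {
  cfg <- tiny_config(seed = 23, participants = 3L, blocks = 2L)
  ds <- generate_experiment(cfg, null_truth())
  b <- ds$blocks
  b2 <- b[b$condition == "sham", ]
  b2t <- b2; b2t$condition <- "trns"
  dt <- delta_table(rbind(b2, b2t))
  expect_true(all(dt$d_hbo == 0 & dt$d_alpha == 0 & dt$d_vct == 0))
})

test_that("with fixed variance and flat priors the sampler matches the
           conjugate closed form", {
  set.seed(24)
  n <- 60
  X <- cbind(1, rnorm(n), rnorm(n))
  y <- drop(X %*% c(1, 0.5, -0.3)) + rnorm(n, 0, 0.8)
  tab <- data.frame(y = y, x1 = X[, 2], x2 = X[, 3], participant = 1)
  des <- build_design(tab, ~ x1 + x2, ~ 1, outcome = "y")
  post <- sample_posterior(des, ranef = FALSE, fix_sigma = 0.8,
                           priors = list(beta_scale = Inf),
                           chains = 2, iterations = 2000, warmup = 500,
                           seed = 6)
  bh <- drop(solve(crossprod(X), crossprod(X, y)))
  Vh <- 0.8^2 * solve(crossprod(X))
  mc_se <- sqrt(diag(Vh) / nrow(post$draws)) * 4
  est <- colMeans(post$draws[, 1:3])
  expect_true(all(abs(est - bh) < pmax(4 * mc_se, 0.02)))
  expect_true(all(abs(apply(post$draws[, 1:3], 2, sd) - sqrt(diag(Vh)))
                  < 0.25 * sqrt(diag(Vh))))
  # seeded determinism
  post2 <- sample_posterior(des, ranef = FALSE, fix_sigma = 0.8,
                            priors = list(beta_scale = Inf),
                            chains = 2, iterations = 2000, warmup = 500,
                            seed = 6)
  expect_identical(post$draws, post2$draws)
})

test_that("zero-length data returns prior draws", {
  tab <- data.frame(y = numeric(0), x = numeric(0),
                    participant = integer(0))
  des <- build_design(tab, ~ x, ~ 1, outcome = "y")
  post <- sample_posterior(des, seed = 2)
  expect_true(post$prior_only)
  expect_gt(sd(post$draws[, 1]), 1)
  expect_true(all(post$draws[, "sigma"] > 0))
})

test_that("HPD intervals are the shortest credible intervals", {
  expect_equal(hpd(rep(3, 200)), c(3, 3))
  set.seed(25)
  z <- rnorm(1e6)
  expect_equal(hpd(z), c(-1.96, 1.96), tolerance = 0.011)
  x <- rexp(1e5)
  h <- hpd(x)
  eq <- quantile(x, c(0.025, 0.975))
  expect_lt(diff(h), diff(eq))      # shorter than equal-tailed
  expect_lt(h[1], 0.01)             # starts at the density peak
  expect_error(hpd(rnorm(50)), "at least 100")
})

test_that("directional probabilities and the credibility rule follow
           their definitions", {
  expect_equal(posterior_prob(rep(-1, 150), "<0"), 1)
  set.seed(26)
  expect_lt(abs(posterior_prob(rnorm(1e5), "<0") - 0.5), 0.01)
  draws <- c(rep(-1, 999), 1)
  expect_equal(posterior_prob(draws, "<0"), 0.999)
  # final-block hemodynamic contrast pattern: credible
  expect_true(decide_credible(list(pr = 0.999, hpd = c(-0.278, -0.063))))
  expect_false(decide_credible(list(pr = 0.99, hpd = c(-0.1, 0.05))))
  expect_false(decide_credible(list(pr = 0.95, hpd = c(0.01, 0.2))))
})

test_that("hierarchical fit recovers a planted participant-level model", {
  set.seed(27)
  J <- 20; m <- 8
  tab <- data.frame(participant = rep(1:J, each = m),
                    x = rnorm(J * m))
  u <- rnorm(J, 0, 0.7)
  tab$y <- 1 + 0.5 * tab$x + u[tab$participant] + rnorm(J * m, 0, 0.5)
  des <- build_design(tab, ~ x, ~ 1, outcome = "y")
  post <- sample_posterior(des, chains = 2, iterations = 1200,
                           warmup = 400, seed = 8, check = FALSE)
  expect_lt(abs(mean(post$draws[, "x"]) - 0.5), 0.1)
  expect_lt(abs(mean(post$draws[, "sigma"]) - 0.5), 0.1)
  expect_lt(abs(mean(post$draws[, "sd_ranef1"]) - 0.7), 0.25)
})

test_that("mediation draws satisfy the effect identities", {
  set.seed(28)
  J <- 24
  # a = 1, b = 1 chain with almost no noise
  d <- data.frame(participant = 1:J, block = 5, fatigue = "low",
                  d_hbo = rnorm(J))
  d$d_alpha <- d$d_hbo + rnorm(J, 0, 0.3)   # decorrelates the two paths
  d$d_vct <- d$d_alpha + rnorm(J, 0, 0.1)
  med <- fit_mediation(d, "d_alpha", seed = 4, chains = 2,
                       iterations = 1200, warmup = 400)
  expect_equal(max(abs(med$draws[, "total"] - med$draws[, "direct"] -
                         med$draws[, "indirect"])), 0, tolerance = 1e-10)
  expect_lt(abs(med$indirect$mean - 1), 0.25)
  # planted b = 0: indirect posterior centred at zero
  d2 <- d
  d2$d_vct <- rnorm(J, 0, 0.5)
  med2 <- fit_mediation(d2, "d_alpha", seed = 5, chains = 2,
                        iterations = 1200, warmup = 400)
  h <- hpd(med2$draws[, "indirect"])
  expect_true(h[1] < 0 && h[2] > 0)
  expect_error(fit_mediation(d[1:3, ], "d_alpha"), "insufficient")
})
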
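test_that("generated datasets have the configured dimensions and are
           reproducible", {
  cfg <- tiny_config(seed = 11)
  ds <- generate_experiment(cfg)
  expect_equal(nrow(ds$trials),
               cfg$n_participants * cfg$n_conditions * cfg$n_blocks *
                 cfg$trials_per_block)
  expect_equal(nrow(ds$blocks),
               cfg$n_participants * cfg$n_conditions * cfg$n_blocks)
  ds2 <- generate_experiment(cfg)
  expect_identical(ds$trials, ds2$trials)
  expect_identical(ds$blocks, ds2$blocks)
  ds3 <- generate_experiment(tiny_config(seed = 12))
  expect_false(identical(ds$trials$contrast, ds3$trials$contrast))
})

test_that("default-size trial table has 29 x 2 x 5 x 80 rows", {
  expect_equal(sim_config()$n_participants * sim_config()$n_conditions *
                 sim_config()$n_blocks * sim_config()$trials_per_block,
               23200)
})

test_that("every 40-trial group shares a single VCT value", {
  ds <- generate_experiment(tiny_config(seed = 3))
  grp <- with(ds$trials,
              tapply(vct, interaction(participant, condition, block,
                                      ceiling(trial / 40)),
                     function(v) length(unique(v))))
  expect_true(all(grp[!is.na(grp)] == 1))
})

test_that("stimulus presence is Bernoulli with the configured rate", {
  cfg <- tiny_config(seed = 21, participants = 3L, blocks = 3L)
  ds <- generate_experiment(cfg)
  n_blocks_total <- cfg$n_participants * cfg$n_conditions * cfg$n_blocks
  per_block <- with(ds$trials,
                    tapply(present, interaction(participant, condition,
                                                block), sum))
  # mean present count per 80-trial block near 48, and not a fixed count
  expect_lt(abs(mean(per_block) - 48), 3 * 4.38 / sqrt(n_blocks_total))
  expect_gt(var(per_block), 0)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(p_stimulus = 1.2), "configuration error")
  expect_error(sim_config(n_blocks = 0), "configuration error")
  expect_error(sim_config(fs_trns = 1000), "configuration error")
  expect_error(ground_truth(effect_hbo = Inf), "finite")
})

test_that("observer model matches the cumulative-Gaussian closed form", {
  truth <- null_truth()
  obs <- list(mu = 0.5, sigma = 0.1, baseline = rep(0, 25))
  bs <- rep(0, 25)
  # at threshold with zero coupling, detection probability is one half
  r <- simulate_response(0.5, obs, bs, truth)
  expect_equal(r$p, 0.5)
  expect_equal(simulate_response(50, obs, bs, truth)$p, 1)
  expect_error(simulate_response(-0.1, obs, bs, truth), "non-negative")
  # binomial oracle at a fixed off-threshold contrast
  set.seed(42)
  p_true <- pnorm((0.55 - 0.5) / 0.1)
  hits <- replicate(5000, simulate_response(0.55, obs, bs, truth)$seen)
  se <- sqrt(p_true * (1 - p_true) / 5000)
  expect_lt(abs(mean(hits) - p_true), 3 * se)
  # absent trials follow the false-alarm rate and are typed fa/cr
  r0 <- simulate_response(0.55, obs, bs, truth, present = FALSE)
  expect_true(r0$type %in% c("fa", "cr"))
})

test_that("band-power coupling shifts the effective threshold by state", {
  truth <- ground_truth(coupling_low = 0.05, coupling_high = 0)
  obs <- list(mu = 0.5, sigma = 0.1, baseline = rep(3, 25))
  hi_alpha <- rep(3, 25)
  hi_alpha[feature_band_map() %in% c("alpha", "beta")] <- 5
  set.seed(1)
  r_lo <- simulate_response(0.5, obs, hi_alpha, truth, state = "low")
  r_hi <- simulate_response(0.5, obs, hi_alpha, truth, state = "high")
  expect_equal(r_lo$mu_eff, 0.5 + 0.05 * (5 - 3))
  expect_equal(r_hi$mu_eff, 0.5)
})

test_that("stimulation waveform is band-limited, calibrated, and clipped", {
  set.seed(7)
  w <- generate_trns_waveform(100, fs = 2000, sigma = 0.194)
  expect_lte(max(abs(w)), 1)
  expect_lt(abs(mean(abs(w) <= 0.5) - 0.99), 0.005)
  spec <- Mod(fft(w))^2
  f <- (seq_along(w) - 1) * 2000 / length(w)
  f <- pmin(f, 2000 - f)
  in_band <- f >= 100 & f <= 640
  expect_lt(sum(spec[f < 100]) / sum(spec), 0.02)
  expect_lt(sum(spec[f > 640]) / sum(spec), 0.02)
  expect_error(generate_trns_waveform(1, sigma = 0), "positive")
})

test_that("synthetic EEG epochs round-trip through the band-power
           estimator", {
  set.seed(5)
  tg <- c(6, 4, 5, 1, -1)
  bp <- rowMeans(replicate(60, welch_band_power(generate_eeg_epoch(tg))))
  expect_true(all(abs(bp - tg) < 1))
  # raising one band's target raises its measured power accordingly
  tg2 <- tg; tg2[3] <- tg[3] + 6
  bp2 <- rowMeans(replicate(60, welch_band_power(generate_eeg_epoch(tg2))))
  expect_lt(abs((bp2[3] - bp[3]) - 6), 1)
  # doubling amplitude = +20 log10(2) dB, exactly, per realization
  set.seed(8); e1 <- generate_eeg_epoch(tg)
  expect_equal(welch_band_power(2 * e1) - welch_band_power(e1),
               setNames(rep(20 * log10(2), 5), band_definitions()$band),
               tolerance = 1e-10)
  expect_error(generate_eeg_epoch(c(NA, 1, 1, 1, 1)), "finite")
  expect_identical(generate_eeg_epoch(rep(-Inf, 5)), rep(0, 450))
})

test_that("synthetic HbO series hit their target amplitude inside the
           slow band", {
  set.seed(9)
  s0 <- generate_hbo_series(0)
  expect_equal(hbo_amplitude(global_signal(s0)), 0)
  expect_error(generate_hbo_series(-1), "non-negative")
  amps <- replicate(25, hbo_amplitude(global_signal(
    generate_hbo_series(0.3))))
  expect_lt(abs(mean(amps) - 0.3) / 0.3, 0.1)
  g <- global_signal(generate_hbo_series(0.3))
  spec <- Mod(fft(g - mean(g)))^2
  f <- (seq_along(g) - 1) * 10.1725 / length(g)
  f <- pmin(f, 10.1725 - f)
  expect_lt(sum(spec[f < 0.015 | f > 0.1]) / sum(spec), 0.05)
})

test_that("fatigue trajectories are bounded, trend upward, and ignore
           condition", {
  set.seed(10)
  flat <- generate_fatigue(start = 3, gain = 0, noise_sd = 0)
  expect_true(all(flat$pre == 3 & flat$post == 3))
  cross <- generate_fatigue(start = 2, gain = 4, noise_sd = 0)
  st <- mapply(function(p, q) classify_fatigue(p, q)$state,
               cross$pre, cross$post)
  expect_setequal(unique(st), c("low", "high"))
  many <- replicate(400, mean(unlist(
    generate_fatigue()[, c("pre", "post")])))
  expect_true(all(many >= 1 & many <= 7))
  # two arms drawn from the identical process: t-statistic near zero
  tt <- t.test(many[1:200], many[201:400])
  expect_lt(abs(tt$statistic), 4)
})

test_that("null-mode generation plants no condition differences", {
  cfg <- tiny_config(seed = 31, participants = 4L, blocks = 3L)
  ds <- generate_experiment(cfg, null_truth())
  b <- ds$blocks
  tt <- t.test(b$hbo[b$condition == "trns"], b$hbo[b$condition == "sham"])
  expect_gt(tt$p.value, 0.001)
  ta <- t.test(b$alpha[b$condition == "trns"],
               b$alpha[b$condition == "sham"], paired = TRUE)
  expect_gt(ta$p.value, 0.001)
})
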
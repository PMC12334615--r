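test_that("preprocessing passes the EEG band and rejects drift and DC", {
  fs <- 250
  t <- seq(0, 80 - 1 / fs, 1 / fs)
  mid <- 5000:15000
  x50 <- sin(2 * pi * 50 * t)
  gain50 <- sd(preprocess_eeg(x50, fs)[mid]) / sd(x50[mid])
  expect_lt(abs(gain50 - 1), 0.05)
  xd <- sin(2 * pi * 0.01 * t)
  att <- 20 * log10(sd(preprocess_eeg(xd, fs)[mid]) / sd(xd[mid]))
  expect_lt(att, -20)
  dc <- preprocess_eeg(rep(1, length(t)), fs)
  expect_lt(max(abs(dc[mid])), 0.01)
  expect_error(preprocess_eeg(rnorm(100), fs), "shorter than")
})

test_that("prestimulus extraction keeps exactly the 450 samples before
           onset", {
  dur_samp <- round(3.3 * 250)
  ep <- epoch_set(array(rnorm(2 * 5 * dur_samp), c(2, 5, dur_samp)))
  pre <- extract_prestimulus(ep)
  expect_equal(dim(pre$data)[3], 450)
  expect_equal(pre$window, c(-1800, 0))
  expect_gte(dim(pre$data)[3], 200)   # enough for one Welch window
  # onset-aligned content excluded: marker planted at t = 0 is absent
  marked <- array(0, c(1, 5, dur_samp))
  onset_idx <- which.min(abs(-1800 + (seq_len(dur_samp) - 1) * 4))
  marked[1, , onset_idx] <- 99
  pre2 <- extract_prestimulus(epoch_set(marked))
  expect_true(all(pre2$data != 99))
  short <- epoch_set(array(rnorm(5 * 450), c(1, 5, 450)),
                     window = c(-900, 900))
  expect_error(extract_prestimulus(short), "does not cover")
})

test_that("amplitude-based rejection drops exactly the contaminated
           epochs", {
  set.seed(14)
  dat <- array(rnorm(40 * 5 * 450), c(40, 5, 450))
  ep <- epoch_set(dat, window = c(-1800, 0))
  clean <- reject_epochs(ep, z_threshold = 5)
  expect_equal(sum(clean$rejected), 0)
  dat2 <- dat
  dat2[7, 3, 100] <- 10 * max(abs(dat))
  spike <- reject_epochs(epoch_set(dat2, window = c(-1800, 0)), 5)
  expect_identical(which(spike$rejected), 7L)
  ident <- reject_epochs(epoch_set(dat2, window = c(-1800, 0)), Inf)
  expect_equal(sum(ident$rejected), 0)
})

test_that("Welch band power matches sinusoid and flat-spectrum
           closed forms", {
  t <- (0:449) / 250
  x <- sin(2 * pi * 10 * t)
  bp <- welch_band_power(x)
  lin <- 10^(bp / 10)
  expect_gt(lin["alpha"] / sum(lin), 0.95)
  # white noise: band powers proportional to band widths
  set.seed(15)
  lin_w <- rowMeans(replicate(200, 10^(welch_band_power(rnorm(450)) / 10)))
  widths <- with(band_definitions(), high - low)
  ratio <- (lin_w / widths) / mean(lin_w / widths)
  expect_true(all(abs(ratio - 1) < 0.1))
  # doubling amplitude adds 20 log10(2) dB in every band
  expect_equal(unname(welch_band_power(2 * x) - bp),
               rep(20 * log10(2), 5), tolerance = 1e-10)
  # silent segment flags undefined power
  expect_true(all(welch_band_power(rep(0, 450)) == -Inf))
  expect_error(welch_band_power(rnorm(100)), "shorter than")
})

test_that("band powers sum to the in-band variance (Parseval) and are
           offset-invariant", {
  set.seed(16)
  x <- generate_eeg_epoch(c(3, 3, 3, 3, 3))
  lin <- sum(10^(welch_band_power(x) / 10))
  expect_lt(abs(lin - var(x)) / var(x), 0.25)   # Welch bias tolerance
  bp1 <- welch_band_power(x - mean(x))
  bp2 <- welch_band_power(x - mean(x) + 5)
  expect_lt(max(abs(bp2[-1] - bp1[-1])), 0.5)   # offset hits DC bin only
  # dB conversion strictly monotone in linear power
  expect_true(all(diff(10 * log10(c(0.1, 1, 2, 10))) > 0))
})

test_that("feature tables have the fixed 25-column schema", {
  expect_equal(length(feature_names()), 25)
  expect_equal(as.vector(table(feature_band_map())), rep(5, 5))
  expect_equal(feature_names()[1], "delta_O1")
  expect_equal(feature_names()[25], "gamma_PO4")
  labs <- data.frame(participant = 1, condition = "sham", block = 1,
                     fatigue_state = "low")[rep(1, 4), ]
  ft <- build_feature_table(matrix(0, 4, 25), rep(0.3, 4), labs)
  expect_equal(names(ft)[6:30], feature_names())
  expect_error(build_feature_table(matrix(0, 4, 25), rep(0.3, 3), labs),
               "misaligned")
})

test_that("waveform-mode generation feeds the extraction pipeline", {
  cfg <- sim_config(n_participants = 1L, n_blocks = 1L,
                    trials_per_block = 4L, seed = 19)
  ds <- generate_experiment(cfg, mode = "waveform")
  ep <- ds$epochs[[1]]
  expect_equal(dim(ep$data)[1], 4)
  pre <- extract_prestimulus(ep)
  feats <- band_power_features(pre)
  expect_equal(dim(feats), c(4, 25))
  # measured features correlate with the generating targets
  sham <- ds$trials[ds$trials$condition == "sham", feature_names()]
  expect_gt(cor(as.vector(feats), as.vector(as.matrix(sham))), 0.8)
  amp <- hbo_amplitude(global_signal(filter_hemo(ds$hbo_series[[1]])))
  expect_lt(abs(amp - ds$blocks$hbo[1]) / ds$blocks$hbo[1], 0.35)
})
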
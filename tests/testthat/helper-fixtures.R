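# Small shared fixtures, all generated in code.

tiny_config <- function(seed = 1L, participants = 2L, blocks = 2L) {
  sim_config(n_participants = participants, n_blocks = blocks,
             seed = seed)
}

# Deterministic 3-channel hemo series with a clean band-limited signal.
clean_hemo <- function(duration = 300, fs = 10.1725, amp = 0.2) {
  t <- seq(0, duration - 1 / fs, 1 / fs)
  base <- amp * sin(2 * pi * 0.05 * t)
  hemo_series(cbind(base, base + 0.02 * sin(2 * pi * 0.03 * t),
                    base - 0.01 * sin(2 * pi * 0.07 * t)), fs = fs)
}

# Random small rectifier net (untrained weights) for gradient oracles.
random_net <- function(p = 25, hidden = 8) {
  structure(list(W1 = matrix(rnorm(hidden * p, sd = 0.5), hidden, p),
                 b1 = rnorm(hidden, sd = 0.3),
                 w2 = rnorm(hidden, sd = 0.5), b2 = rnorm(1),
                 center = rnorm(p, sd = 0.1),
                 scale = runif(p, 0.5, 2),
                 spec = NULL),
            class = "trained_net")
}

fd_gradient <- function(net, x, h = 1e-5) {
  vapply(seq_along(x), function(j) {
    e <- rep(0, length(x)); e[j] <- h
    (predict(net, rbind(x + e)) - predict(net, rbind(x - e))) / (2 * h)
  }, numeric(1))
}
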
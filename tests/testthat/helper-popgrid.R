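# Shared fixtures, built in code at test time.

# small, fast landscape for module tests
tiny_config <- function(seed = 1, ...) {
  landscape_config(n_cols = 24, n_rows = 24, n_units = 12, poi_rate = 0.05,
                   seed = seed, ...)
}

tiny_study <- function(seed = 1, ...) synthetic_study(tiny_config(seed, ...))

# a plain regression table with one informative feature and pure-noise
# companions; y is a noiseless monotone function of x1
single_signal_table <- function(n = 60, p_noise = 5, seed = 1) {
  withr::with_seed(seed, {
    d <- data.frame(unit_id = seq_len(n))
    d$x1 <- runif(n)
    for (j in seq_len(p_noise)) d[[paste0("noise", j)]] <- runif(n)
    d$density <- 100 * exp(1.5 * d$x1)
    d
  })
}

moment_skewness <- function(v) mean((v - mean(v))^3) / sd(v)^3
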
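# Small fixtures shared across test files; everything is generated in code.

# a quick low-count field that still detects cleanly
small_ihc_params <- function(n_cells = 30, fraction = 0.5, seed = 1, ...) {
  ihc_sim_params(n_cells = n_cells, true_positive_fraction = fraction,
                 field_size_px = c(256, 256), seed = seed, ...)
}

# draw a two-component Gaussian mixture directly (oracle generator for EM)
draw_mixture <- function(n, w1, mu, sd, seed) {
  withr::with_seed(seed, {
    z <- stats::runif(n) < w1
    stats::rnorm(n, ifelse(z, mu[1], mu[2]), sd)
  })
}

# brute-force Pearson r from the definition (independent of cor())
pearson_brute <- function(a, b) {
  am <- a - mean(a); bm <- b - mean(b)
  sum(am * bm) / sqrt(sum(am^2) * sum(bm^2))
}
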
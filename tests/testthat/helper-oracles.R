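# Independent oracles used across the suite.

# Expected social fitness by exhaustive enumeration of all 2^(N-1) co-player
# strategy vectors, each weighted by its Bernoulli(x) probability. Feasible
# for N <= 8; deliberately avoids the binomial shortcut under test.
enumerate_fitness_social <- function(x, params) {
  n_others <- params$N - 1L
  total <- 0
  for (code in 0:(2^n_others - 1L)) {
    v <- as.integer(intToBits(code))[seq_len(n_others)]
    prob <- prod(ifelse(v == 1L, x, 1 - x))
    k <- sum(v) + 1L # focal agent attends
    total <- total + prob * (if (k >= params$M) params$s else 0)
  }
  total
}

# An explicit sample of n points with the given population mean and
# population sd (so that mean(z) = mu and mean(z^2) - mean(z)^2 = sd^2).
pseudo_sample <- function(mu, sd, n) {
  if (n == 1L) return(mu)
  z <- seq_len(n) - (n + 1) / 2
  mu + sd * z / sqrt(mean(z^2))
}

# Pooled batch oracle: fold the prior (as a pseudo-sample) and a batch of
# observations into one pass of population moments.
batch_update_oracle <- function(mean, sd, pseudo_n, ys) {
  xs <- c(pseudo_sample(mean, sd, pseudo_n), ys)
  m <- mean(xs)
  list(mean = m, var = mean(xs^2) - m^2, n = length(xs))
}

# A small config for fast engine tests.
quick_config <- function(...) {
  defaults <- list(N = 10, TMax = 25, RMax = 2, PV = 0.6, p0 = 0.10,
                   seed = 99L)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}
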
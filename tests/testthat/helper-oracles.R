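# Independent oracles used to cross-check the package implementation.
# Everything here is written from the model definitions directly, not by
# calling package internals.

# logistic closed form, independent transcription
oracle_logistic <- function(t, K, r, N0) {
  K / (1 + ((K - N0) / N0) * exp(-r * t))
}

# direct transcription of the two derivative fields as plain functions of
# numeric vectors (no package objects)
oracle_rates_classic <- function(N, r, K, a) {
  # N, r, K in E, Y, B order; a named alpha vector
  c(N[1] * r[1] * (1 - (N[1] + a["alpha_EY"] * N[2] + a["alpha_EB"] * N[3]) / K[1]),
    N[2] * r[2] * (1 - (N[2] + a["alpha_YB"] * N[3] + a["alpha_YE"] * N[1]) / K[2]),
    N[3] * r[3] * (1 - (N[3] + a["alpha_BY"] * N[2] + a["alpha_BE"] * N[1]) / K[3]))
}

oracle_rates_freqdep <- function(N, r, K, a) {
  tot <- sum(N)
  if (tot <= 0) return(c(0, 0, 0))
  f <- N / tot
  c(N[1] * r[1] * (1 - (N[1] + a["alpha_EY"] * f[2] * N[2] + a["alpha_EB"] * f[3] * N[3]) / K[1]),
    N[2] * r[2] * (1 - (N[2] + a["alpha_YB"] * f[3] * N[3] + a["alpha_YE"] * f[1] * N[1]) / K[2]),
    N[3] * r[3] * (1 - (N[3] + a["alpha_BY"] * f[2] * N[2] + a["alpha_BE"] * f[1] * N[1]) / K[3]))
}

# fixed-step classical Runge-Kutta integrator over the oracle rate fields
oracle_rk4 <- function(N0, r, K, a, t_end, dt = 0.001,
                       field = oracle_rates_freqdep) {
  n_steps <- round(t_end / dt)
  y <- N0
  for (i in seq_len(n_steps)) {
    k1 <- field(y, r, K, a)
    k2 <- field(y + dt / 2 * k1, r, K, a)
    k3 <- field(y + dt / 2 * k2, r, K, a)
    k4 <- field(y + dt * k3, r, K, a)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  y
}

# alpha vector helper for oracle calls
oracle_alphas <- function(value = 0.01) {
  setNames(rep(value, 6),
           c("alpha_EY", "alpha_EB", "alpha_YB",
             "alpha_YE", "alpha_BY", "alpha_BE"))
}

# Pearson chi-square statistic by direct formula
oracle_chisq <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# paired t statistic by closed form
oracle_paired_t <- function(x, y) {
  d <- x - y
  mean(d) / (sd(d) / sqrt(length(d)))
}
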
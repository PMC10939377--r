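# Independent oracles and small builders shared across the suite.

# Literal transcription of the displayed two-/three-member equations,
# written independently of the package's vectorized kernel.
brute_rhs <- function(rates, allee, alpha, mu, x) {
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    fac <- if (allee[i] == 0) {
      if (x[i] > 0) 1 else 0
    } else {
      if (x[i] > 0) x[i] / (allee[i] + x[i]) else 0
    }
    inter <- 0
    for (j in seq_len(n)) if (j != i) inter <- inter + alpha[i, j] * x[j]
    out[i] <- rates[i] * x[i] * (fac * (1 - x[i]) - inter) - mu[i] * x[i]
  }
  out
}

# Logistic closed form X(t) = X0 e^{rt} / (1 + X0 (e^{rt} - 1)).
logistic_closed_form <- function(x0, r, t) {
  e <- exp(r * t)
  x0 * e / (1 + x0 * (e - 1))
}

# Fixed-step Euler integrator for the two-member death-free system.
euler_two_member <- function(model, x0, hours, dt = 1e-3) {
  x <- x0
  steps <- round(hours / dt)
  for (k in seq_len(steps)) {
    d <- brute_rhs(model$rates, model$allee, model$alpha, c(0, 0), x)
    x <- pmax(0, x + dt * d)
  }
  x
}

# Exact two-sided Wilcoxon rank-sum p-value by full enumeration of all
# choose(m + n, m) rank assignments.
wilcoxon_enum_p <- function(x, y) {
  m <- length(x)
  pool <- c(x, y)
  r <- rank(pool)
  w <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  cmb <- utils::combn(length(pool), m)
  Wd <- apply(cmb, 2, function(idx) sum(r[idx]) - m * (m + 1) / 2)
  min(1, 2 * min(mean(Wd <= w), mean(Wd >= w)))
}

# Normal-equations OLS (slope, intercept, R^2), independent of lm().
ols_normal_equations <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x^2); sxy <- sum(x * y)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  yhat <- intercept + slope * x
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept, r_squared = r2)
}

# Death-free two-member model with the reference interaction coefficients.
pair_nodeath <- function(alpha_AB = 1.9, alpha_BA = 1.75,
                         r_A = 0.5, r_B = 0.75) {
  kin_pair_model(cooperator_rate = r_A, cheater_rate = r_B,
                 alpha_AB = alpha_AB, alpha_BA = alpha_BA,
                 mu_A = 0, mu_B_max = 0)
}

# Minimal hand-built trajectory carrying only what the classifier reads.
toy_trajectory <- function(starts, ends, floor = 1e-9) {
  starts <- rbind(starts)
  ends <- rbind(ends)
  structure(list(cycle_starts = starts, cycle_ends = ends,
                 solver = list(extinction_floor = floor)),
            class = "community_trajectory")
}
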
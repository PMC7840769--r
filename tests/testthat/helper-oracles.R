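# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths.

# Mean first-passage time to |x| > L for a particle diffusing in potential
# U(x) (kBT units) with absorbing boundaries at +-L, starting at x0.
# Standard double-integral solution of the backward Kolmogorov equation,
# evaluated by dense trapezoidal quadrature.
mfpt_oracle <- function(U, D, L, x0 = 0, n = 20001) {
  xg <- seq(-L, L, length.out = n)
  h <- xg[2] - xg[1]
  eU <- exp(vapply(xg, U, numeric(1)))
  # psi(x) = int_{-L}^{x} exp(-U) dz
  psi <- cumsum(exp(-vapply(xg, U, numeric(1)))) * h
  # T(x) solves D (e^{-U} T')' = -e^{-U}; integrate twice with T(+-L) = 0
  # T(x) = (A * P(x) - Q(x)) / D where
  #   P(x) = int_{-L}^x e^{U} dz, Q(x) = int_{-L}^x e^{U(y)} psi(y) dy,
  #   A chosen so T(L) = 0.
  P <- cumsum(eU) * h
  Q <- cumsum(eU * psi) * h
  A <- Q[n] / P[n]
  Tx <- (A * P - Q) / D
  stats::approx(xg, Tx, xout = x0)$y
}

# Truncated-parabola well of depth U0 and half-width a centered at 0.
well_potential <- function(U0, a) {
  function(x) if (abs(x) <= a) -U0 * (1 - (x / a)^2) else 0
}

# Discrete geometric-run oracle for the mean number of ratchet steps:
# sum over N of N P^N (1-P) normalized, by brute-force summation.
mean_steps_discrete_oracle <- function(P, n_max = 1e6) {
  N <- 0:n_max
  w <- P^N * (1 - P)
  sum(N * w) / sum(w)
}

# Random-walk first-passage oracle: free diffusion on [0, L], absorbing at
# both ends, mean exit time from uniform starts over positions `starts`.
mfpt_interval_uniform <- function(D, L, starts) {
  mean(starts * (L - starts)) / (2 * D)
}

expect_close <- function(object, expected, tol) {
  expect_true(abs(object - expected) <= tol,
              label = sprintf("%g within %g of %g", object, tol, expected))
}
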
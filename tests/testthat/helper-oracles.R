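# Independent numerical oracles used by the tests. These deliberately share
# no code with the package: the PDE is solved on a grid by Crank-Nicolson,
# integrals are done by adaptive quadrature, and bootstrap distributions are
# enumerated exhaustively where small enough.

# Crank-Nicolson solution of dC/dt = DL2 * d2C/du2 on u in [0,1],
# C(0,t) = K*Cveh, C(1,t) = 0, C(u,0) = 0, with Rannacher start-up (a few
# implicit-Euler steps) to damp the oscillations the discontinuous initial
# surface step would otherwise excite.
cn_profile <- function(K, Cveh, DL2, t, nx = 2000, nt = 800, ee_steps = 8) {
  du <- 1 / nx
  u <- seq(du, 1 - du, by = du)        # interior nodes
  n <- length(u)
  dt <- t / nt
  c0 <- K * Cveh                       # left boundary (right boundary is 0)
  solve_tri <- function(a, b, rhs) {   # constant sub/super diagonal `a`
    cp <- numeric(n); dp <- numeric(n)
    cp[1] <- a / b[1]; dp[1] <- rhs[1] / b[1]
    for (i in 2:n) {
      m <- b[i] - a * cp[i - 1]
      cp[i] <- a / m
      dp[i] <- (rhs[i] - a * dp[i - 1]) / m
    }
    x <- numeric(n); x[n] <- dp[n]
    for (i in (n - 1):1) x[i] <- dp[i] - cp[i] * x[i + 1]
    x
  }
  C <- rep(0, n)
  for (step in seq_len(nt)) {
    if (step <= ee_steps) {
      r <- DL2 * dt / du^2
      rhs <- C; rhs[1] <- rhs[1] + r * c0
      C <- solve_tri(-r, rep(1 + 2 * r, n), rhs)
    } else {
      r <- DL2 * dt / (2 * du^2)
      rhs <- (1 - 2 * r) * C
      rhs[1] <- rhs[1] + 2 * r * c0
      rhs[-1] <- rhs[-1] + r * C[-n]
      rhs[-n] <- rhs[-n] + r * C[-1]
      C <- solve_tri(-r, rep(1 + 2 * r, n), rhs)
    }
  }
  list(u = u, C = C)
}

cn_at <- function(u_query, K, Cveh, DL2, t, nx = 2000, nt = 800) {
  sol <- cn_profile(K, Cveh, DL2, t, nx, nt)
  stats::approx(c(0, sol$u, 1), c(K * Cveh, sol$C, 0), xout = u_query)$y
}

# equal-width noiseless or lognormal-noise profile straight from the model,
# used for parameter-recovery experiments
make_synthetic_profile <- function(K, DL2, L = 15, Cveh = 100, t = 6,
                                   n_int = 12, noise_cv = 0) {
  x1 <- (seq_len(n_int) - 1) / n_int
  x2 <- seq_len(n_int) / n_int
  p <- diffusion_params(K = K, DL2 = DL2, L = L, Cveh = Cveh)
  amt <- slab_amount(p, x1, x2, t)
  if (noise_cv > 0)
    amt <- amt * exp(stats::rnorm(n_int, 0, sqrt(log(1 + noise_cv^2))))
  rec <- tape_strips(seq_len(n_int), rep(L * 100 / n_int, n_int), amt)
  build_profile(rec, L = L, t_exposure = t, Cveh = Cveh)
}
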
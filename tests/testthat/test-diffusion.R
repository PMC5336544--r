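# Series solution of Fick's second law in the SC membrane: boundary and
# initial conditions, closed-form limits, agreement with independent
# numerical oracles, and derived transport quantities.

test_that("boundary and initial conditions hold numerically", {
  p <- diffusion_params(K = 2.5, DL2 = 0.04, L = 12, Cveh = 50)
  for (t in c(0.1, 1, 6, 24)) {
    expect_equal(concentration_profile(p, 0, t), p$K * p$Cveh, tolerance = 1e-7)
    expect_equal(concentration_profile(p, 1, t), 0, tolerance = 1e-7)
  }
  # initially drug-free interior
  expect_equal(concentration_profile(p, c(0.25, 0.5, 0.9), 0), c(0, 0, 0))
  expect_true(all(concentration_profile(p, seq(0.1, 0.9, 0.1), 1e-4) <
                    0.05 * p$K * p$Cveh))
})

test_that("steady-state limits match the linear profile", {
  p <- diffusion_params(K = 2, DL2 = 5, L = 15, Cveh = 10)
  t_inf <- 100  # DL2 * t >> 1
  u <- c(0.2, 0.5, 0.8)
  expect_equal(concentration_profile(p, u, t_inf), p$K * p$Cveh * (1 - u),
               tolerance = 1e-10)
  # triangle areas: shallow half holds 3x the deep half
  expect_equal(slab_amount(p, 0, 0.5, t_inf) / slab_amount(p, 0.5, 1, t_inf),
               3, tolerance = 1e-9)
  expect_equal(total_uptake(p, t_inf),
               p$K * p$Cveh * (p$L / 1e4) / 2, tolerance = 1e-10)
})

test_that("profile agrees with a Crank-Nicolson PDE solution", {
  # mid-membrane point at DL2*t = 0.1 (spec-level single-point check) and a
  # sweep across the transient-to-steady range
  p <- diffusion_params(K = 1, DL2 = 0.1 / 6, Cveh = 1)
  expect_equal(concentration_profile(p, 0.5, 6),
               cn_at(0.5, 1, 1, 0.1 / 6, 6), tolerance = 1e-3)
  u <- seq(0.05, 0.95, length.out = 20)
  for (a in c(0.01, 0.2, 1, 5)) {
    s <- concentration_profile(diffusion_params(K = 1, DL2 = a / 6, Cveh = 1), u, 6)
    cc <- cn_at(u, 1, 1, a / 6, 6)
    expect_lt(max(abs(s - cc)), 1e-3)   # relative to the K*Cveh scale of 1
  }
})

test_that("slab amounts and total uptake match adaptive quadrature", {
  p <- diffusion_params(K = 1, DL2 = 0.05, L = 15, Cveh = 1)
  t <- 5   # DL2*t = 0.25
  L_cm <- 15 / 1e4
  q_slab <- stats::integrate(function(u) concentration_profile(p, u, t),
                             0.2, 0.4, rel.tol = 1e-10)$value * L_cm
  expect_equal(slab_amount(p, 0.2, 0.4, t), q_slab, tolerance = 1e-6)
  q_tot <- stats::integrate(function(u) concentration_profile(p, u, t),
                            0, 1, rel.tol = 1e-10)$value * L_cm
  expect_equal(total_uptake(p, t), q_tot, tolerance = 1e-6)
})

test_that("slab amounts are additive over partitions and Q(0) = 0", {
  p <- diffusion_params(K = 3, DL2 = 0.02, L = 18, Cveh = 40)
  cuts <- c(0, 0.13, 0.4, 0.55, 0.8, 1)
  parts <- slab_amount(p, cuts[-length(cuts)], cuts[-1], 6)
  expect_equal(sum(parts), total_uptake(p, 6), tolerance = 1e-10)
  expect_identical(total_uptake(p, 0), 0)
})

test_that("concentration and uptake are monotone in time and scale with Cveh", {
  p <- diffusion_params(K = 2, DL2 = 0.03, L = 15, Cveh = 10)
  ts <- c(0.5, 1, 2, 4, 8, 16)
  for (u in c(0.2, 0.6)) {
    cs <- vapply(ts, function(t) concentration_profile(p, u, t), numeric(1))
    expect_true(all(diff(cs) >= -1e-10))
  }
  qs <- total_uptake(p, ts)
  expect_true(all(diff(qs) >= 0))
  p2 <- diffusion_params(K = 2, DL2 = 0.03, L = 15, Cveh = 20)
  expect_equal(concentration_profile(p2, 0.3, 2),
               2 * concentration_profile(p, 0.3, 2), tolerance = 1e-12)
  expect_equal(total_uptake(p2, 3), 2 * total_uptake(p, 3), tolerance = 1e-12)
})

test_that("derived transport quantities follow from the primary fields", {
  p <- diffusion_params(K = 1, DL2 = 0.1, L = 10, Cveh = NA)
  expect_equal(p$kp, 1e-4)
  p2 <- diffusion_params(K = 1, DL2 = 0.1, L = 10, Cveh = 9300)
  expect_equal(p2$Jss, 0.93)
  p3 <- diffusion_params(K = 1, DL2 = 1 / 78)
  expect_equal(p3$tlag, 13)
  # thickness required before kp can be derived
  expect_error(derive_transport(diffusion_params(K = 1, DL2 = 0.1)),
               "thickness")
})

test_that("domain errors are raised for invalid inputs", {
  p <- diffusion_params(K = 1, DL2 = 0.05, L = 15, Cveh = 1)
  expect_error(concentration_profile(p, 0.5, -1), "must be a single number >= 0")
  expect_error(concentration_profile(p, 1.2, 1), "\\[0, 1\\]")
  expect_error(slab_amount(p, 0.6, 0.4, 1), "x1_rel < x2_rel")
  expect_error(diffusion_params(K = -1, DL2 = 0.05), "'K'")
})
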
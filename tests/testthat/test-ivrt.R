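# IVRT cumulative-release bookkeeping and square-root-of-time kinetics.

test_that("withdrawal/replacement mass balance is exact", {
  # 3 samplings of 1 mL from 7.4 mL at 1, 2, 3 ug/mL over 2 cm2:
  # Q_3 = (3 * 7.4 + 1 + 2) / 2, verified by step-by-step dilution bookkeeping
  cv <- cumulative_from_samples(c(1, 2, 3), times = 1:3, sample_volumes = 1,
                                receptor_volume = 7.4, area = 2)
  expect_equal(cv$cumulative[3], 12.6)
  expect_equal(cv$cumulative[1], 7.4 / 2)
  # no withdrawal: Q_n = C_n * V_r / A
  cv0 <- cumulative_from_samples(c(1, 2, 3), 1:3, sample_volumes = 0,
                                 receptor_volume = 7.4, area = 2)
  expect_equal(cv0$cumulative, c(1, 2, 3) * 7.4 / 2)
  # constant concentration with nonzero sampling still accumulates
  cvc <- cumulative_from_samples(rep(2, 5), 1:5, 1)
  expect_true(all(diff(cvc$cumulative) > 0))
  expect_error(cumulative_from_samples(1, 1, sample_volumes = 10,
                                       receptor_volume = 7.4),
               "exceeds")
})

test_that("mass is conserved between receptor and withdrawn aliquots", {
  concs <- c(0.5, 1.2, 2.0, 2.4)
  vols <- c(0.5, 1, 2, 0.5)
  cv <- cumulative_from_samples(concs, 1:4, vols, receptor_volume = 7.4,
                                area = 2)
  n <- length(concs)
  accounted <- concs[n] * 7.4 + sum(concs[-n] * vols[-n])
  expect_equal(cv$cumulative[n] * 2, accounted, tolerance = 1e-12)
})

test_that("exact square-root kinetics are recovered exactly", {
  t <- c(0.5, 1, 2, 4, 6)
  fit <- higuchi_fit(release_curve(t, 5 * sqrt(t)))
  expect_equal(fit$k, 5, tolerance = 1e-9)
  expect_equal(fit$intercept, 0, tolerance = 1e-9)
  expect_equal(fit$r.squared, 1, tolerance = 1e-9)
  # constant release -> zero slope
  fit0 <- higuchi_fit(release_curve(t, rep(3, 5)))
  expect_equal(fit0$k, 0, tolerance = 1e-9)
  expect_error(higuchi_fit(release_curve(c(1, 2), c(1, 2))), ">= 3 points")
})

test_that("all-zero curves report no release instead of a fit", {
  fit <- higuchi_fit(release_curve(c(1, 2, 3), c(0, 0, 0)))
  expect_true(fit$no_release)
  expect_true(is.na(fit$k))
})

test_that("slope is equivariant under time rescaling", {
  t <- c(0.5, 1, 2, 4, 6)
  set.seed(5)
  Q <- cummax(5 * sqrt(t) + rnorm(5, 0, 0.1))
  k1 <- higuchi_fit(release_curve(t, Q))$k
  k4 <- higuchi_fit(release_curve(4 * t, Q))$k
  expect_equal(k4, k1 / 2, tolerance = 1e-9)
})

test_that("burst exclusion drops early points only", {
  t <- c(0.1, 0.25, 0.5, 1, 2, 4)
  Q <- 5 * sqrt(t)
  Q[1] <- 2.4   # early burst: elevated but still below Q at 0.25 h
  full <- higuchi_fit(release_curve(t, Q))
  nob <- higuchi_fit(release_curve(t, Q), exclude_burst = TRUE)
  expect_equal(nob$k, 5, tolerance = 1e-9)
  expect_gt(abs(full$k - 5), 0.05)
})

test_that("noisy simulated curves recover the generating slope", {
  g <- generate_release_curves(5, times = c(0.5, 1, 2, 3, 4, 5, 6),
                               noise_sd = 0.5, n_cells = 6, seed = 31)
  ks <- vapply(g$curves, function(cv) higuchi_fit(cv)$k, numeric(1))
  # Monte-Carlo scale: SE of the mean slope across 6 cells
  expect_lt(abs(mean(ks) - 5), 3 * stats::sd(ks) / sqrt(6) + 0.2)
})

test_that("release comparison reproduces the membrane-effect design", {
  # three membranes with distinct release levels; within each membrane the
  # three formulations share the same truth
  set.seed(77)
  d <- expand.grid(cell = 1:6, form = c("A", "B", "C"),
                   memb = c("m1", "m2", "m3"))
  level <- c(m1 = 50, m2 = 120, m3 = 300)
  d$amount <- rnorm(nrow(d), level[d$memb], 10)
  cmp <- compare_release(d$amount, d$form, d$memb)
  expect_true(cmp$across_membranes$significant)
  expect_false(any(vapply(cmp$within_membrane, `[[`, logical(1), "significant")))
  # identical groups -> Bonferroni-adjusted p-values of 1
  base <- rep(c(10, 11, 12, 13), 3)
  cmp0 <- compare_release(c(base, base + 100),
                          rep(rep(c("A", "B", "C"), each = 4), 2),
                          rep(c("m1", "m2"), each = 12))
  expect_equal(unname(cmp0$within_membrane$m1$pairwise[!is.na(cmp0$within_membrane$m1$pairwise)]),
               rep(1, 3))
  # strong separation is detected
  big <- compare_release(c(rnorm(6, 10, 1), rnorm(6, 100, 1)),
                         rep(c("A", "B"), each = 6), rep("m", 12))
  expect_true(big$within_membrane$m$significant)
})
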
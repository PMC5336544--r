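# Nonlinear least-squares recovery of K and D/L^2 from strip profiles.

test_that("noiseless self-fit recovers the generating parameters", {
  for (tp in list(c(3, 0.05), c(0.5, 0.015), c(20, 0.1))) {
    prof <- make_synthetic_profile(K = tp[1], DL2 = tp[2])
    fit <- fit_profile(prof)
    expect_equal(fit$K, tp[1], tolerance = 1e-3)
    expect_equal(fit$DL2, tp[2], tolerance = 1e-3)
    expect_false(fit$steady_state)
  }
})

test_that("a steady-state profile is flagged instead of yielding a fake DL2", {
  # concentrations exactly on the linear steady-state profile
  n <- 12
  x1 <- (0:(n - 1)) / n; x2 <- (1:n) / n
  mid <- (x1 + x2) / 2
  Cveh <- 100; K <- 3
  conc <- K * Cveh * (1 - mid)
  amt <- conc * (x2 - x1) * 15 / 1e4
  rec <- tape_strips(1:n, rep(1500 / n, n), amt)
  prof <- build_profile(rec, L = 15, t_exposure = 6, Cveh = Cveh)
  fit <- fit_profile(prof)
  expect_true(fit$steady_state)
  expect_equal(fit$K, K, tolerance = 0.02)
})

test_that("degenerate profiles raise errors", {
  rec <- tape_strips(1:6, rep(250, 6), rep(0, 6))
  prof <- build_profile(rec, L = 15, t_exposure = 6, Cveh = 100)
  expect_error(fit_profile(prof), "zero")
  rec3 <- tape_strips(1:3, rep(500, 3), rep(1, 3))
  prof3 <- build_profile(rec3, L = 15, t_exposure = 6, Cveh = 100)
  expect_error(fit_profile(prof3), ">= 4 intervals")
})

test_that("interval-average fitting beats midpoint evaluation on coarse pools", {
  # 4-strip pools over the deep half: wide slabs where the profile is convex
  truth <- diffusion_params(K = 3, DL2 = 0.03, L = 15, Cveh = 100)
  x1 <- c(0, 0.1, 0.2, 0.3, 0.4, 0.6, 0.8)
  x2 <- c(0.1, 0.2, 0.3, 0.4, 0.6, 0.8, 1)
  obs <- slab_amount(truth, x1, x2, 6) / ((x2 - x1) * 15 / 1e4)
  interval_avg <- obs   # generated as interval averages: exact by definition
  midpoint <- concentration_profile(truth, (x1 + x2) / 2, 6)
  rss_int <- sum((obs - interval_avg)^2)
  rss_mid <- sum((obs - midpoint)^2)
  expect_lte(rss_int, rss_mid)
  expect_gt(rss_mid, 0)   # midpoint evaluation is genuinely biased here
})

test_that("derived kp and Jss carry the right units through the fit", {
  prof <- make_synthetic_profile(K = 2, DL2 = 0.05, L = 10, Cveh = 9300)
  fit <- fit_profile(prof)
  # kp = K * DL2 * L with L in cm: 2 * 0.05 * 1e-3
  expect_equal(fit$params$kp, 1e-4, tolerance = 1e-3)
  expect_equal(fit$params$Jss, 0.93, tolerance = 1e-3)
})

test_that("asymptotic intervals cover the truth at roughly the nominal rate", {
  set.seed(11)
  # log-residual weighting matches the multiplicative noise model, so its
  # asymptotic intervals should be close to nominal
  cover <- replicate(40, {
    prof <- make_synthetic_profile(K = 3, DL2 = 0.02, t = 6, noise_cv = 0.05)
    ci <- confint(fit_profile(prof, weights = "log"))
    ci["K", 1] < 3 && 3 < ci["K", 2]
  })
  expect_gte(mean(cover), 0.7)   # nominal 0.90, wide Monte-Carlo margin
  prof <- make_synthetic_profile(K = 3, DL2 = 0.02, t = 6, noise_cv = 0.05)
  fit <- fit_profile(prof)
  cib <- confint(fit, method = "bootstrap", B = 30, seed = 3)
  expect_true(all(is.finite(cib)))
  expect_lt(cib["K", 1], fit$K)
})

test_that("fit methods expose fitted values, residuals and predictions", {
  prof <- make_synthetic_profile(K = 3, DL2 = 0.05)
  fit <- fit_profile(prof)
  expect_equal(fitted(fit) + residuals(fit), prof$conc)
  expect_equal(predict(fit, x_rel = 1), 0)
  sims <- simulate(fit, nsim = 3, seed = 9)
  expect_equal(dim(sims), c(length(prof$conc), 3))
  expect_true(all(sims >= 0))
  expect_identical(simulate(fit, nsim = 2, seed = 4),
                   simulate(fit, nsim = 2, seed = 4))
})

test_that("replicate summaries aggregate and preserve fold-differences", {
  profA <- make_synthetic_profile(K = 3, DL2 = 0.05, Cveh = 1000)
  profB <- make_synthetic_profile(K = 3, DL2 = 0.05, Cveh = 1000)
  fits <- list(fit_profile(profA), fit_profile(profB))
  summ <- summarize_replicates(fits)
  expect_true(all(summ$sd < 1e-6 * abs(summ$mean)))
  # two formulations engineered to an 8.7-fold Jss difference
  profC <- make_synthetic_profile(K = 3, DL2 = 0.05 / 8.7, Cveh = 1000)
  sC <- summarize_replicates(list(fit_profile(profC), fit_profile(profC)))
  jss_ratio <- summ$mean[summ$parameter == "Jss"] /
    sC$mean[sC$parameter == "Jss"]
  expect_equal(jss_ratio, 8.7, tolerance = 0.01)
  # model-derived vs observed total uptake on noiseless data
  expect_equal(summ$mean[summ$parameter == "Q_model"],
               summ$mean[summ$parameter == "Q_obs"], tolerance = 1e-3)
})
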
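# Average-bioequivalence machinery: phase summaries, combined metric,
# test/reference ratios and verdicts, supporting test battery.

toy_totals <- function(up_T, cl_T, up_R, cl_R) {
  n <- c(length(up_T), length(cl_T), length(up_R), length(cl_R))
  replicate_totals(id = unlist(lapply(n, seq_len)),
                   product = rep(c("T", "T", "R", "R"), n),
                   phase = rep(c("uptake", "clearance", "uptake", "clearance"), n),
                   amount = c(up_T, cl_T, up_R, cl_R))
}

test_that("phase summaries degenerate correctly and need enough replicates", {
  tot <- toy_totals(rep(2, 14), rep(2, 14), rep(3, 14), rep(3, 14))
  s <- phase_summary(tot, "T", "uptake")
  expect_equal(s$mean, 2)
  expect_equal(s$ci, c(2, 2))
  expect_equal(s$n, 14)
  two <- toy_totals(c(1, 2), c(1, 2), c(1, 2), c(1, 2))
  expect_error(phase_summary(two, "T", "uptake"), ">= 3")
})

test_that("log-t interval is asymmetric about the mean for skewed samples", {
  set.seed(12)
  x <- exp(rnorm(14, log(2), 0.8))
  tot <- replicate_totals(1:14, "P", "uptake", x)
  tot <- rbind(tot, replicate_totals(1:14, "P", "clearance", x))
  class(tot) <- c("replicate_totals", "data.frame")
  s <- phase_summary(tot, "P", "uptake")
  expect_gt(s$ci[2] - exp(mean(log(x))), exp(mean(log(x))) - s$ci[1])
})

test_that("combined metric pools phases with equal weight", {
  # printed-table worked numbers: uptake 2.19, clearance 1.96 -> 2.075
  tot <- toy_totals(2.19, 1.96, 1.81, 2.28)
  cm <- combined_metric(tot, "T")
  expect_equal(cm$mean, 2.075)
  expect_equal(unname(cm$phase_means), c(2.19, 1.96))
  # all equal -> combined equals the common value
  cm2 <- combined_metric(toy_totals(rep(5, 4), rep(5, 4), 1, 1), "T")
  expect_equal(cm2$mean, 5)
  # unequal n: pooled mean equals the mean of all observations
  up <- c(1, 2, 3, 4); cl <- c(10, 20)
  cm3 <- combined_metric(toy_totals(up, cl, 1, 1), "T")
  expect_equal(cm3$mean, mean(c(up, cl)))
  expect_equal(cm3$n, 6)
  expect_error(combined_metric(replicate_totals(1, "X", "uptake", 1), "X"),
               "both uptake and clearance")
})

test_that("identical products are judged equivalent with ratio 1", {
  v <- c(1.8, 2.0, 2.3, 2.6, 1.5, 2.2)
  tot <- toy_totals(v, v, v, v)
  r <- be_ratio(tot, "T", "R", seed = 1)
  expect_equal(r$ratio, 1)
  expect_identical(r$verdict, "equivalent")
  expect_true(r$point_within_limits)
})

test_that("raw-scale point ratios are reciprocal", {
  set.seed(3)
  tot <- toy_totals(rlnorm(14, log(2), 0.3), rlnorm(14, log(2), 0.3),
                    rlnorm(14, log(2.2), 0.3), rlnorm(14, log(2.2), 0.3))
  r1 <- be_ratio(tot, "T", "R", seed = 1)
  r2 <- be_ratio(tot, "R", "T", seed = 1)
  expect_equal(r1$ratio * r2$ratio, 1, tolerance = 1e-12)
})

test_that("seeded bootstrap matches exhaustive resampling on a tiny sample", {
  # n = 3 per product (pooled) -> 27 x 27 equally likely resample pairs
  tv <- c(1.6, 2.1, 2.6); rv <- c(1.9, 2.2, 2.4)
  tot <- toy_totals(tv[1:2], tv[3], rv[1:2], rv[3])
  idx <- as.matrix(expand.grid(1:3, 1:3, 1:3))
  means <- rowMeans(matrix(tv[idx], nrow(idx))) # all resample means (test)
  meansR <- rowMeans(matrix(rv[idx], nrow(idx)))
  exact <- as.vector(outer(means, meansR, "/"))
  ci_exact <- stats::quantile(exact, c(0.05, 0.95), names = FALSE)
  r <- be_ratio(tot, "T", "R", B = 40000, seed = 42)
  expect_equal(r$ci_low, ci_exact[1], tolerance = 0.02)
  expect_equal(r$ci_high, ci_exact[2], tolerance = 0.02)
})

test_that("widening the interval never rescues an equivalence verdict", {
  lim <- c(0.8, 1.25)
  base <- c(0.9, 1.1)
  verdicts <- vapply(c(0, 0.1, 0.25, 0.6), function(w) {
    dpkfit:::be_verdict(base + c(-w, w), lim)
  }, character(1))
  expect_identical(verdicts[1], "equivalent")
  rank <- c(equivalent = 1, inconclusive = 2, `not-equivalent` = 2)
  expect_true(all(diff(rank[verdicts]) >= 0))
})

test_that("raw and log scales essentially agree for moderate-CV cohorts", {
  set.seed(9)
  sdlog <- sqrt(log(1 + 0.4^2))
  rel <- replicate(40, {
    tot <- toy_totals(rlnorm(14, log(2), sdlog), rlnorm(14, log(2), sdlog),
                      rlnorm(14, log(2), sdlog), rlnorm(14, log(2), sdlog))
    raw <- mean(c(pick <- tot$amount[tot$product == "T"])) /
      mean(tot$amount[tot$product == "R"])
    lg <- exp(mean(log(tot$amount[tot$product == "T"])) -
                mean(log(tot$amount[tot$product == "R"])))
    abs(raw / lg - 1)
  })
  expect_lt(stats::median(rel), 0.05)
})

test_that("group comparison battery behaves at the null and under separation", {
  g <- rep(c(1, 2, 3, 4), 3)
  cmp <- compare_groups(c(g, g, g), rep(c("A", "B", "C"), each = 4))
  expect_equal(unname(cmp$anova_p), 1, tolerance = 1e-12)
  expect_true(all(cmp$pairwise_p == 1, na.rm = TRUE))
  set.seed(21)
  x <- c(rnorm(14, 0, 1), rnorm(14, 10, 1))
  cmp2 <- compare_groups(x, rep(c("A", "B"), each = 14))
  expect_lt(cmp2$t_test_p, 1e-10)
  expect_true(cmp2$significant)
  # two-way layout runs and reports each term
  d <- expand.grid(r = 1:5, f1 = c("A", "B"), f2 = c("u", "c"))
  set.seed(22)
  cmp3 <- compare_groups(rnorm(nrow(d)), d$f1, d$f2, design = "two-way")
  expect_named(cmp3$anova_p, c("f1", "f2", "f1:f2"))
  expect_error(compare_groups(1:3, c("A", "A", "B")), ">= 2 observations")
})
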
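# Average-bioequivalence assessment from total SC drug amounts after the
# uptake and clearance phases: per-phase summaries, combined
# [uptake + clearance] metric, test/reference ratio with 90% CI against
# the conventional 0.8-1.25 limits, and supporting t-test/ANOVA batteries.

#' Per-replicate total SC drug amounts
#'
#' @param id subject or cell identifier.
#' @param product product identifier.
#' @param phase `"uptake"` (stripped immediately after cleaning) or
#'   `"clearance"` (stripped after the post-removal waiting period).
#' @param amount total drug recovered from the SC (ug/cm2), >= 0.
#' @return a `data.frame` of class `"replicate_totals"`.
#' @export
replicate_totals <- function(id, product, phase, amount) {
  n <- max(length(id), length(amount))
  id <- rep_len(id, n); product <- rep_len(product, n)
  phase <- rep_len(phase, n)
  if (length(amount) != n)
    stop("'amount' length must match the number of replicates", call. = FALSE)
  if (!all(phase %in% c("uptake", "clearance")))
    stop("phase must be 'uptake' or 'clearance'", call. = FALSE)
  if (any(amount < 0)) stop("amounts must be >= 0", call. = FALSE)
  d <- data.frame(id = as.character(id), product = as.character(product),
                  phase = phase, amount = as.numeric(amount),
                  stringsAsFactors = FALSE)
  if (anyDuplicated(d[, c("id", "product", "phase")]))
    stop("one amount per (id, product, phase) allowed", call. = FALSE)
  structure(d, class = c("replicate_totals", "data.frame"))
}

pick_amounts <- function(totals, product, phase = NULL) {
  stopifnot(inherits(totals, "replicate_totals"))
  sel <- totals$product == product
  if (!is.null(phase)) sel <- sel & totals$phase == phase
  totals$amount[sel]
}

#' Mean and 90% confidence interval of one product/phase
#'
#' Arithmetic mean with a 90% CI computed either as a t-interval on
#' log-transformed amounts back-transformed to the raw scale (asymmetric,
#' the natural choice for positively skewed amounts) or as a seeded
#' percentile bootstrap of the mean.
#'
#' @param totals a [replicate_totals()] table.
#' @param product product identifier.
#' @param phase `"uptake"` or `"clearance"`.
#' @param level confidence level, default 0.90.
#' @param method `"logt"` (default) or `"bootstrap"`.
#' @param B bootstrap resamples (default 10000).
#' @param seed seed for the bootstrap.
#' @return list with `mean`, `ci` (length 2), `n`, `method`.
#' @export
phase_summary <- function(totals, product, phase, level = 0.90,
                          method = c("logt", "bootstrap"), B = 10000,
                          seed = NULL) {
  method <- match.arg(method)
  x <- pick_amounts(totals, product, phase)
  if (length(x) < 3) stop("need >= 3 replicates", call. = FALSE)
  alpha <- 1 - level
  if (method == "logt") {
    if (any(x <= 0)) stop("log-t interval needs positive amounts", call. = FALSE)
    lx <- log(x)
    se <- stats::sd(lx) / sqrt(length(x))
    tq <- stats::qt(1 - alpha / 2, df = length(x) - 1)
    ci <- exp(mean(lx) + c(-1, 1) * tq * se)
  } else {
    ci <- with_seed(seed, {
      bm <- rowMeans(matrix(sample(x, length(x) * B, replace = TRUE), nrow = B))
      stats::quantile(bm, c(alpha / 2, 1 - alpha / 2), names = FALSE)
    })
  }
  list(mean = mean(x), ci = ci, n = length(x), method = method)
}

#' Combined \[uptake + clearance\] metric for one product
#'
#' Pools the uptake- and clearance-phase amounts of a product into a
#' single sample. With equal phase sizes the combined mean equals
#' `(mean uptake + mean clearance) / 2`; with unequal sizes it is the
#' mean of all pooled observations.
#'
#' @param totals a [replicate_totals()] table.
#' @param product product identifier.
#' @return list with `values` (pooled amounts), `mean`, `n`,
#'   `phase_means` (named: uptake, clearance).
#' @export
combined_metric <- function(totals, product) {
  up <- pick_amounts(totals, product, "uptake")
  cl <- pick_amounts(totals, product, "clearance")
  if (length(up) == 0 || length(cl) == 0)
    stop(sprintf("product '%s' must have both uptake and clearance data", product),
         call. = FALSE)
  values <- c(up, cl)
  list(values = values, mean = mean(values), n = length(values),
       phase_means = c(uptake = mean(up), clearance = mean(cl)))
}

be_verdict <- function(ci, limits) {
  if (ci[1] >= limits[1] && ci[2] <= limits[2]) "equivalent"
  else if (ci[2] < limits[1] || ci[1] > limits[2]) "not-equivalent"
  else "inconclusive"
}

#' Average-bioequivalence ratio of two products
#'
#' Test/reference ratio of combined \[uptake + clearance\] means with a 90%
#' confidence interval, judged against the conventional 0.8-1.25 limits.
#' On the raw scale the ratio is the ratio of arithmetic means; on the log
#' scale it is the back-transformed difference of log means (a ratio of
#' geometric means). The CI is a seeded percentile bootstrap over
#' replicates (default) or, on the log scale, a Welch t-interval.
#'
#' The regulatory verdict (`"equivalent"` iff the whole CI lies within the
#' limits) is reported alongside the weaker point-estimate check
#' (`point_within_limits`).
#'
#' @param totals a [replicate_totals()] table containing both products.
#' @param test,reference product identifiers.
#' @param scale `"raw"` (default) or `"log"`.
#' @param ci_method `"bootstrap"` (default) or `"logt"` (log scale only).
#' @param B bootstrap resamples, default 10000.
#' @param seed seed for the bootstrap.
#' @param limits equivalence limits, default `c(0.8, 1.25)`.
#' @param level confidence level, default 0.90.
#' @return an object of class `"be_result"`.
#' @examples
#' tot <- replicate_totals(rep(1:6, 4),
#'                         rep(c("T", "R"), each = 12),
#'                         rep(rep(c("uptake", "clearance"), each = 6), 2),
#'                         rep(2, 24))
#' be_ratio(tot, "T", "R", seed = 1)
#' @export
be_ratio <- function(totals, test, reference, scale = c("raw", "log"),
                     ci_method = c("bootstrap", "logt"), B = 10000,
                     seed = NULL, limits = c(0.8, 1.25), level = 0.90) {
  scale <- match.arg(scale)
  ci_method <- match.arg(ci_method)
  te <- combined_metric(totals, test)
  re <- combined_metric(totals, reference)
  if (re$mean == 0) stop("reference mean is zero", call. = FALSE)
  alpha <- 1 - level
  point <- function(x, y) {
    if (scale == "raw") mean(x) / mean(y) else exp(mean(log(x)) - mean(log(y)))
  }
  if (scale == "log" && (any(te$values <= 0) || any(re$values <= 0)))
    stop("log scale needs positive amounts", call. = FALSE)
  ratio <- point(te$values, re$values)
  if (ci_method == "logt") {
    if (scale != "log") stop("'logt' CI is defined on the log scale", call. = FALSE)
    lt <- log(te$values); lr <- log(re$values)
    se <- sqrt(stats::var(lt) / length(lt) + stats::var(lr) / length(lr))
    df <- se^4 / ((stats::var(lt) / length(lt))^2 / (length(lt) - 1) +
                    (stats::var(lr) / length(lr))^2 / (length(lr) - 1))
    if (!is.finite(df) || df <= 0) df <- length(lt) + length(lr) - 2
    tq <- stats::qt(1 - alpha / 2, df)
    ci <- exp(mean(lt) - mean(lr) + c(-1, 1) * tq * se)
  } else {
    ci <- with_seed(seed, {
      nt <- length(te$values); nr <- length(re$values)
      Tb <- matrix(sample(te$values, nt * B, replace = TRUE), nrow = B)
      Rb <- matrix(sample(re$values, nr * B, replace = TRUE), nrow = B)
      rb <- if (scale == "raw") rowMeans(Tb) / rowMeans(Rb)
            else exp(rowMeans(log(Tb)) - rowMeans(log(Rb)))
      stats::quantile(rb, c(alpha / 2, 1 - alpha / 2), names = FALSE)
    })
  }
  structure(list(test = test, reference = reference, ratio = ratio,
                 ci_low = min(ci[1], ratio), ci_high = max(ci[2], ratio),
                 limits = limits, scale = scale, ci_method = ci_method,
                 level = level,
                 verdict = be_verdict(c(min(ci[1], ratio), max(ci[2], ratio)),
                                      limits),
                 point_within_limits = ratio >= limits[1] && ratio <= limits[2],
                 n_test = te$n, n_reference = re$n),
            class = "be_result")
}

#' @export
print.be_result <- function(x, digits = 3, ...) {
  cat(sprintf("Bioequivalence assessment: %s vs %s (%s scale, %s CI)\n",
              x$test, x$reference, x$scale, x$ci_method))
  cat(sprintf("  ratio = %s, %g%% CI [%s, %s], limits [%g, %g]\n",
              format(x$ratio, digits = digits), 100 * x$level,
              format(x$ci_low, digits = digits),
              format(x$ci_high, digits = digits),
              x$limits[1], x$limits[2]))
  cat(sprintf("  verdict: %s (point estimate %swithin limits)\n",
              x$verdict, if (x$point_within_limits) "" else "NOT "))
  invisible(x)
}

#' @export
summary.be_result <- function(object, ...) {
  data.frame(test = object$test, reference = object$reference,
             ratio = object$ratio, ci_low = object$ci_low,
             ci_high = object$ci_high, scale = object$scale,
             verdict = object$verdict,
             point_within_limits = object$point_within_limits)
}

#' Standard comparison battery for group data
#'
#' Two-tailed t-tests (two groups), one-way or two-way ANOVA, and
#' Bonferroni-adjusted pairwise t-tests at alpha = 0.05; the supporting
#' statistics for secondary claims (e.g. no formulation effect, no
#' uptake/clearance difference).
#'
#' @param values numeric observations.
#' @param f1 primary grouping factor.
#' @param f2 optional second factor (two-way ANOVA with interaction dropped
#'   if non-estimable).
#' @param design `"one-way"` (default) or `"two-way"`.
#' @param alpha significance level, default 0.05.
#' @return an object of class `"group_comparison"`: ANOVA table p-values,
#'   pairwise Bonferroni-adjusted p-values on `f1`, and for two groups the
#'   two-tailed t-test p-value.
#' @export
compare_groups <- function(values, f1, f2 = NULL,
                           design = c("one-way", "two-way"), alpha = 0.05) {
  design <- match.arg(design)
  f1 <- factor(f1)
  if (nlevels(f1) < 2) stop("need >= 2 groups", call. = FALSE)
  if (any(table(f1) < 2)) stop("each group needs >= 2 observations", call. = FALSE)
  d <- data.frame(y = values, f1 = f1)
  out <- list(alpha = alpha, design = design)
  if (design == "two-way") {
    if (is.null(f2)) stop("two-way design needs 'f2'", call. = FALSE)
    d$f2 <- factor(f2)
    tab <- summary(stats::aov(y ~ f1 * f2, data = d))[[1]]
    out$anova_p <- stats::setNames(tab[["Pr(>F)"]][seq_len(nrow(tab) - 1)],
                                   trimws(rownames(tab))[seq_len(nrow(tab) - 1)])
  } else {
    tab <- summary(stats::aov(y ~ f1, data = d))[[1]]
    out$anova_p <- stats::setNames(tab[["Pr(>F)"]][1], "f1")
  }
  out$pairwise_p <- stats::pairwise.t.test(d$y, d$f1,
                                           p.adjust.method = "bonferroni")$p.value
  if (nlevels(f1) == 2)
    out$t_test_p <- stats::t.test(y ~ f1, data = d)$p.value
  out$significant <- any(out$anova_p < alpha, na.rm = TRUE)
  structure(out, class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Group comparison (%s ANOVA, alpha = %g)\n", x$design, x$alpha))
  for (nm in names(x$anova_p))
    cat(sprintf("  %s: p = %.4g\n", nm, x$anova_p[nm]))
  if (!is.null(x$t_test_p)) cat(sprintf("  t-test: p = %.4g\n", x$t_test_p))
  cat(sprintf("  any effect significant: %s\n", x$significant))
  invisible(x)
}
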
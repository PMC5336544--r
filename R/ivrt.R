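# In vitro release test (IVRT): cumulative-release bookkeeping for Franz
# diffusion cells with sample withdrawal/replacement, square-root-of-time
# (Higuchi) kinetics, and release comparisons across formulations/membranes.

#' Cumulative release curve
#'
#' @param times sampling times (h), strictly increasing.
#' @param cumulative cumulative amount released per area (ug/cm2),
#'   non-decreasing.
#' @param formulation_id,membrane_id optional labels.
#' @param area membrane area (cm2), default 2.
#' @param receptor_volume receptor volume (mL), default 7.4.
#' @param censored logical flag: readings below the limit of quantitation
#'   recorded as 0 (default all FALSE).
#' @return an object of class `"release_curve"`.
#' @export
release_curve <- function(times, cumulative, formulation_id = NA,
                          membrane_id = NA, area = 2, receptor_volume = 7.4,
                          censored = rep(FALSE, length(times))) {
  if (length(times) != length(cumulative))
    stop("'times' and 'cumulative' must have equal length", call. = FALSE)
  if (any(diff(times) <= 0)) stop("'times' must be strictly increasing", call. = FALSE)
  if (any(diff(cumulative) < -1e-9 * max(abs(cumulative), 1)))
    stop("'cumulative' must be non-decreasing", call. = FALSE)
  structure(list(times = as.numeric(times), cumulative = as.numeric(cumulative),
                 formulation_id = formulation_id, membrane_id = membrane_id,
                 area = area, receptor_volume = receptor_volume,
                 censored = censored),
            class = "release_curve")
}

#' @export
print.release_curve <- function(x, ...) {
  cat(sprintf("IVRT release curve [%s / %s]: %d samples over %g h, Q(end) = %.3g ug/cm2\n",
              x$formulation_id, x$membrane_id, length(x$times),
              max(x$times), x$cumulative[length(x$cumulative)]))
  invisible(x)
}

#' Cumulative amount released, corrected for sample withdrawal
#'
#' Receptor-phase samples are withdrawn at each time point and replaced
#' with fresh medium, diluting the receptor. The cumulative amount released
#' per unit area at sample n is reconstructed by mass balance:
#' `Q_n = (C_n * V_receptor + sum_{i<n} C_i * V_sample_i) / area`.
#'
#' @param concs receptor concentrations (ug/mL) at each sampling time.
#' @param times sampling times (h).
#' @param sample_volumes withdrawn volumes (mL), scalar or per-sample.
#' @param receptor_volume receptor volume (mL), default 7.4.
#' @param area membrane area (cm2), default 2.
#' @param correct_replacement apply the withdrawal correction (default
#'   `TRUE`); with `FALSE` only the receptor term `C_n * V_r / area` is used.
#' @param ... labels passed to [release_curve()].
#' @return a [release_curve()].
#' @examples
#' cumulative_from_samples(c(1, 2, 3), times = 1:3, sample_volumes = 1)$cumulative
#' @export
cumulative_from_samples <- function(concs, times, sample_volumes,
                                    receptor_volume = 7.4, area = 2,
                                    correct_replacement = TRUE, ...) {
  n <- length(concs)
  if (length(times) != n) stop("'concs' and 'times' must match", call. = FALSE)
  sample_volumes <- rep_len(sample_volumes, n)
  if (any(sample_volumes < 0) || receptor_volume <= 0 || area <= 0)
    stop("volumes and area must be positive", call. = FALSE)
  if (any(sample_volumes > receptor_volume))
    stop("sample volume exceeds receptor volume", call. = FALSE)
  withdrawn <- if (correct_replacement)
    c(0, cumsum(concs * sample_volumes)[-n]) else 0
  Q <- (concs * receptor_volume + withdrawn) / area
  release_curve(times, Q, area = area, receptor_volume = receptor_volume, ...)
}

#' Fit square-root-of-time (Higuchi) release kinetics
#'
#' Ordinary least squares of cumulative release on the square root of
#' time, the classic signature of diffusion-controlled release from a
#' semisolid. Curves in which no release was detected (all readings zero
#' or censored) are reported as such rather than fitted.
#'
#' @param curve a [release_curve()] (>= 3 points).
#' @param exclude_burst drop points with t < `burst_cutoff` before fitting
#'   (early burst); default `FALSE`.
#' @param burst_cutoff h, default 0.25.
#' @return an object of class `"higuchi_fit"`: slope `k`
#'   (ug cm-2 h^-1/2) with SE, intercept, `r.squared`, the underlying
#'   [stats::lm] object, and `no_release` flag.
#' @examples
#' cv <- release_curve(c(0.5, 1, 2, 4, 6), 5 * sqrt(c(0.5, 1, 2, 4, 6)))
#' higuchi_fit(cv)
#' @export
higuchi_fit <- function(curve, exclude_burst = FALSE, burst_cutoff = 0.25) {
  stopifnot(inherits(curve, "release_curve"))
  keep <- if (exclude_burst) curve$times >= burst_cutoff else rep(TRUE, length(curve$times))
  t <- curve$times[keep]; Q <- curve$cumulative[keep]
  if (length(t) < 3) stop("need >= 3 points for a Higuchi fit", call. = FALSE)
  if (all(Q == 0)) {
    return(structure(list(no_release = TRUE, k = NA_real_, se = NA_real_,
                          intercept = NA_real_, r.squared = NA_real_,
                          lm = NULL, curve = curve),
                     class = "higuchi_fit"))
  }
  fit <- stats::lm(Q ~ sqrt(t))
  # summary.lm warns on zero-residual fits; exact kinetics are legitimate here
  s <- suppressWarnings(summary(fit))
  structure(list(no_release = FALSE,
                 k = unname(stats::coef(fit)[2]),
                 se = s$coefficients[2, 2],
                 intercept = unname(stats::coef(fit)[1]),
                 r.squared = s$r.squared, lm = fit, curve = curve),
            class = "higuchi_fit")
}

#' @export
print.higuchi_fit <- function(x, digits = 4, ...) {
  if (x$no_release) {
    cat("Higuchi fit: no release detected (all readings zero)\n")
  } else {
    cat(sprintf("Higuchi release kinetics: k = %s ug cm-2 h^-1/2 (SE %s), intercept %s, R^2 = %s\n",
                format(x$k, digits = digits), format(x$se, digits = 3),
                format(x$intercept, digits = 3),
                format(x$r.squared, digits = 4)))
  }
  invisible(x)
}

#' @export
coef.higuchi_fit <- function(object, ...) {
  c(intercept = object$intercept, k = object$k)
}

#' @export
predict.higuchi_fit <- function(object, times = NULL, ...) {
  if (object$no_release) stop("no release detected; nothing to predict", call. = FALSE)
  if (is.null(times)) times <- object$curve$times
  stats::predict(object$lm, newdata = data.frame(t = times))
}

#' @export
plot.higuchi_fit <- function(x, ...) {
  cv <- x$curve
  graphics::plot(sqrt(cv$times), cv$cumulative, xlab = expression(sqrt(t) ~ (h^{1/2})),
                 ylab = "Q (ug/cm2)", ...)
  if (!x$no_release) graphics::abline(x$lm, col = "steelblue")
  invisible(x)
}

#' Compare 6-h cumulative release across formulations and membranes
#'
#' One-way ANOVA of per-cell cumulative amounts across formulations within
#' each membrane, one-way ANOVA across membranes (pooling formulations),
#' and Bonferroni-adjusted pairwise t-tests, at alpha = 0.05.
#'
#' @param amounts per-cell cumulative amounts (ug/cm2).
#' @param formulation,membrane factors of the same length.
#' @param alpha significance level, default 0.05.
#' @return an object of class `"release_comparison"`: per-membrane ANOVA
#'   p-values, the across-membrane ANOVA p-value, Bonferroni-adjusted
#'   pairwise p-value matrices, and significance flags.
#' @export
compare_release <- function(amounts, formulation, membrane, alpha = 0.05) {
  d <- data.frame(amount = amounts, formulation = factor(formulation),
                  membrane = factor(membrane))
  if (any(table(d$formulation, d$membrane) < 2))
    stop("each formulation x membrane group needs >= 2 cells", call. = FALSE)
  within <- lapply(split(d, d$membrane), function(dd) {
    if (nlevels(droplevels(dd$formulation)) < 2) return(NULL)
    p_anova <- summary(stats::aov(amount ~ formulation, data = dd))[[1]][["Pr(>F)"]][1]
    pw <- stats::pairwise.t.test(dd$amount, dd$formulation,
                                 p.adjust.method = "bonferroni")$p.value
    list(p_anova = p_anova, pairwise = pw, significant = p_anova < alpha)
  })
  across <- if (nlevels(d$membrane) >= 2) {
    p_mem <- summary(stats::aov(amount ~ membrane, data = d))[[1]][["Pr(>F)"]][1]
    pw_mem <- stats::pairwise.t.test(d$amount, d$membrane,
                                     p.adjust.method = "bonferroni")$p.value
    list(p_anova = p_mem, pairwise = pw_mem, significant = p_mem < alpha)
  } else list(p_anova = NA_real_, pairwise = NULL, significant = NA)
  structure(list(within_membrane = within, across_membranes = across,
                 alpha = alpha),
            class = "release_comparison")
}

#' @export
print.release_comparison <- function(x, ...) {
  cat("IVRT release comparison (alpha =", x$alpha, ")\n")
  for (m in names(x$within_membrane)) {
    w <- x$within_membrane[[m]]
    if (is.null(w)) next
    cat(sprintf("  membrane %s: formulation effect p = %.4g (%ssignificant)\n",
                m, w$p_anova, if (w$significant) "" else "not "))
  }
  cat(sprintf("  across membranes: p = %.4g (%ssignificant)\n",
              x$across_membranes$p_anova,
              if (x$across_membranes$significant) "" else "not "))
  invisible(x)
}
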
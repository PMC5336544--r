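# SC thickness from TEWL vs cumulative SC removed.
#
# As the SC is progressively removed, TEWL rises in proportion to
# 1/(remaining thickness):  TEWL(x) = Kw / (H - x).  Hence 1/TEWL is
# linear in the depth removed x, and its x-intercept is the total SC
# thickness H.

#' TEWL series recorded during tape-stripping
#'
#' @param depth_removed cumulative SC depth removed before each reading
#'   (um); non-decreasing, starting at 0.
#' @param tewl TEWL readings (g m-2 h-1), > 0; same length.
#' @param baseline pre-stripping TEWL (g m-2 h-1), > 0.
#' @return an object of class `"tewl_series"`.
#' @export
tewl_series <- function(depth_removed, tewl, baseline) {
  if (length(depth_removed) != length(tewl))
    stop("'depth_removed' and 'tewl' must have equal length", call. = FALSE)
  if (length(depth_removed) == 0) stop("empty TEWL series", call. = FALSE)
  if (depth_removed[1] != 0)
    stop("'depth_removed' must start at 0 (pre-stripping reading)", call. = FALSE)
  if (any(diff(depth_removed) < 0))
    stop("'depth_removed' must be non-decreasing", call. = FALSE)
  if (any(tewl <= 0)) stop("'tewl' readings must be > 0", call. = FALSE)
  stopifnot_scalar(baseline, "baseline", positive = TRUE)
  structure(list(depth_removed = as.numeric(depth_removed),
                 tewl = as.numeric(tewl), baseline = baseline),
            class = "tewl_series")
}

#' Has the tape-stripping endpoint been reached?
#'
#' Stripping continues until TEWL indicates that essentially all of the SC
#' barrier has been removed; the conventional endpoint is a final reading
#' of at least 100 g m-2 h-1 (inclusive).
#'
#' @param series a [tewl_series()].
#' @param threshold endpoint TEWL (g m-2 h-1); default 100.
#' @return `TRUE` iff the final reading is >= `threshold`.
#' @export
stripping_endpoint_reached <- function(series, threshold = 100) {
  stopifnot(inherits(series, "tewl_series"))
  series$tewl[length(series$tewl)] >= threshold
}

#' Estimate SC thickness by inverse-TEWL extrapolation
#'
#' Fits 1/TEWL against cumulative depth removed by ordinary least squares
#' and returns the x-intercept, i.e. the depth at which 1/TEWL extrapolates
#' to zero: the total SC thickness H. Early readings still dominated by the
#' intact barrier (TEWL < 2 x baseline) are excluded before fitting. The
#' standard error of H is propagated from the regression coefficients by
#' the delta method.
#'
#' @param series a [tewl_series()].
#' @param min_points minimum number of usable readings (default 3).
#' @return an object of class `"tewl_fit"` with components `H` (um),
#'   `se` (um), `lm` (the underlying [stats::lm] fit of 1/TEWL on depth),
#'   `n_used`, `excluded` and the input `series`. `coef()` returns
#'   `c(H = , Kw = )` where `Kw = -1/slope` is the proportionality
#'   constant of the inverse-thickness law.
#' @examples
#' x <- seq(0, 13, by = 1)
#' s <- tewl_series(x, 105 / (15 - x), baseline = 7)
#' fit_tewl_thickness(s)
#' @export
fit_tewl_thickness <- function(series, min_points = 3) {
  stopifnot(inherits(series, "tewl_series"))
  usable <- series$tewl >= 2 * series$baseline
  n_used <- sum(usable)
  if (n_used < min_points)
    stop(sprintf(paste0("thickness estimation failed: only %d reading(s) above ",
                        "2 x baseline (need >= %d)"), n_used, min_points),
         call. = FALSE)
  d <- data.frame(x = series$depth_removed[usable],
                  inv_tewl = 1 / series$tewl[usable])
  fit <- stats::lm(inv_tewl ~ x, data = d)
  b <- stats::coef(fit)
  if (!is.finite(b[2]) || b[2] >= -1e-10 * max(abs(b[1]), 1e-12))
    stop("thickness estimation failed: 1/TEWL does not decrease with depth ",
         "removed (non-negative slope); the series carries no thickness signal",
         call. = FALSE)
  H <- unname(-b[1] / b[2])
  V <- suppressWarnings(stats::vcov(fit))   # exact data give a zero-residual fit
  # delta method for H = -b0/b1
  g <- c(-1 / b[2], b[1] / b[2]^2)
  se <- sqrt(drop(t(g) %*% V %*% g))
  structure(list(H = H, se = se, Kw = unname(-1 / b[2]), lm = fit,
                 n_used = n_used, excluded = sum(!usable), series = series),
            class = "tewl_fit")
}

#' @export
print.tewl_fit <- function(x, digits = 4, ...) {
  cat("SC thickness from TEWL inverse extrapolation\n")
  cat(sprintf("  H  = %s um (SE %s), %d readings used (%d baseline-dominated excluded)\n",
              format(x$H, digits = digits), format(x$se, digits = 3),
              x$n_used, x$excluded))
  invisible(x)
}

#' @export
coef.tewl_fit <- function(object, ...) c(H = object$H, Kw = object$Kw)

#' @export
summary.tewl_fit <- function(object, ...) {
  s <- summary(object$lm)
  cat(sprintf("SC thickness H = %.3f um (SE %.3f), R^2 of 1/TEWL fit = %.4f\n",
              object$H, object$se, s$r.squared))
  invisible(list(H = object$H, se = object$se, r.squared = s$r.squared,
                 lm_summary = s))
}

#' @export
predict.tewl_fit <- function(object, depth_removed = NULL, ...) {
  if (is.null(depth_removed)) depth_removed <- object$series$depth_removed
  inv <- stats::predict(object$lm, newdata = data.frame(x = depth_removed))
  ifelse(inv > 0, 1 / inv, Inf)
}

#' @export
plot.tewl_fit <- function(x, ...) {
  s <- x$series
  graphics::plot(s$depth_removed, 1 / s$tewl,
                 xlab = "SC depth removed (um)", ylab = "1 / TEWL (m2 h / g)",
                 xlim = c(0, max(x$H, s$depth_removed) * 1.05), ...)
  graphics::abline(x$lm, lty = 2)
  graphics::abline(v = x$H, col = "grey40", lty = 3)
  graphics::mtext(sprintf("H = %.1f um", x$H), side = 3, adj = 1, cex = 0.8)
  invisible(x)
}
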
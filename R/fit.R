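# Nonlinear least-squares fit of the Fickian uptake model to a tape-strip
# concentration-depth profile. The model prediction for an interval is its
# *interval-average* concentration (slab amount / slab width), not a point
# evaluation at the midpoint: pooled deep strips span wide depth ranges and
# midpoint evaluation biases D/L^2.

# interval-average model concentrations (ug/cm3) for a profile
model_interval_conc <- function(K, DL2, profile) {
  p <- diffusion_params(K = K, DL2 = DL2, L = profile$L, Cveh = profile$Cveh)
  x1 <- profile$intervals[, 1]; x2 <- profile$intervals[, 2]
  slab_amount(p, x1, x2, profile$t_exposure) / ((x2 - x1) * um_to_cm(profile$L))
}

#' Fit the Fickian uptake model to a tape-strip profile
#'
#' Least-squares estimation of the SC-vehicle partition coefficient `K` and
#' the diffusivity parameter `DL2` = D/L^2 from a [build_profile()] object.
#' Residuals compare observed interval concentrations with model
#' interval-average concentrations. The objective is minimised over
#' (log K, log D/L^2) by quasi-Newton iterations started from a log-spaced
#' grid over K in \[0.01, 100\] and D/L^2 in \[1e-4, 10\] 1/h; the best
#' converged start is kept.
#'
#' When the exposure time is long enough that the profile has reached its
#' steady-state (linear) shape, the data carry no information on D/L^2 and
#' the estimate runs away upward; the fit then carries `steady_state = TRUE`
#' and the D/L^2 estimate and its uncertainty must not be interpreted.
#'
#' @param profile a [build_profile()] object with >= 4 intervals of
#'   positive concentration.
#' @param n_starts number of multi-start grid points (default 25 = 5 x 5).
#' @param weights `"none"` (default; unweighted residuals on the
#'   concentration scale) or `"log"` (residuals on the log scale, useful
#'   when noise is multiplicative; zero concentrations are then excluded).
#' @param seed optional seed (reserved for bootstrap confidence intervals;
#'   the point fit is deterministic).
#' @return an object of class `"dpk_fit"`: the estimated [diffusion_params()]
#'   (with kp, Jss, tlag derived), asymptotic standard errors, the objective
#'   value, fitted values and residuals, `Q_model` / `Q_obs` (total uptake at
#'   `t_exposure` from the fitted model and as the observed sum of strip
#'   amounts) and the `steady_state` flag.
#' @examples
#' truth <- diffusion_params(K = 3, DL2 = 0.05, L = 15, Cveh = 100)
#' rec <- tape_strips(1:12, rep(125, 12),
#'                    slab_amount(truth, (0:11) / 12, (1:12) / 12, t = 6))
#' prof <- build_profile(rec, L = 15, t_exposure = 6, Cveh = 100)
#' fit <- fit_profile(prof)
#' coef(fit)
#' @export
fit_profile <- function(profile, n_starts = 25, weights = c("none", "log"),
                        seed = NULL) {
  stopifnot(inherits(profile, "strip_profile"))
  weights <- match.arg(weights)
  y <- profile$conc
  use <- rep(TRUE, length(y))
  if (weights == "log") use <- y > 0
  if (sum(y > 0) == 0)
    stop("all interval concentrations are zero: nothing to fit", call. = FALSE)
  if (sum(use & y > 0) < 4 || nrow(profile$intervals) < 4)
    stop("need >= 4 intervals with positive concentration", call. = FALSE)

  obj <- function(par) {
    m <- model_interval_conc(exp(par[1]), exp(par[2]), profile)[use]
    r <- if (weights == "log") log(pmax(m, 1e-300)) - log(y[use]) else m - y[use]
    sum(r^2)
  }

  k_grid <- ceiling(sqrt(n_starts))
  starts <- expand.grid(logK = log(10^seq(-2, 2, length.out = k_grid)),
                        logDL2 = log(10^seq(-4, 1, length.out = k_grid)))
  starts <- starts[seq_len(min(n_starts, nrow(starts))), , drop = FALSE]

  # box wide enough to contain any physically sensible SC fit (DL2 below
  # 1e-5 1/h would mean a lag time beyond 1.6e4 h)
  lower <- log(c(1e-4, 1e-5)); upper <- log(c(1e4, 1e3))
  fits <- lapply(seq_len(nrow(starts)), function(i) {
    tryCatch(stats::optim(as.numeric(starts[i, ]), obj, method = "L-BFGS-B",
                          lower = lower, upper = upper,
                          control = list(maxit = 500)),
             error = function(e) NULL)
  })
  ok <- vapply(fits, function(f) !is.null(f) && f$convergence == 0, logical(1))
  if (!any(ok)) {
    objs <- vapply(fits, function(f) if (is.null(f)) NA_real_ else f$value,
                   numeric(1))
    stop("fit did not converge from any start; grid objectives: ",
         paste(format(objs, digits = 3), collapse = ", "), call. = FALSE)
  }
  best <- fits[ok][[which.min(vapply(fits[ok], `[[`, numeric(1), "value"))]]
  K <- exp(best$par[1]); DL2 <- exp(best$par[2])

  # steady-state identifiability check: series contribution below numerical
  # noise means t carries no D/L^2 information
  steady <- DL2 * pi^2 * profile$t_exposure > -log(1e-10)

  params <- derive_transport(diffusion_params(K, DL2, L = profile$L,
                                              Cveh = profile$Cveh))
  fitted_vals <- model_interval_conc(K, DL2, profile)
  resid_vals <- y - fitted_vals
  n <- sum(use); p <- 2L
  sigma2 <- best$value / max(n - p, 1)

  # asymptotic covariance from a numeric Jacobian on the natural scale
  V <- matrix(NA_real_, 2, 2, dimnames = list(c("K", "DL2"), c("K", "DL2")))
  if (!steady) {
    J <- matrix(NA_real_, n, 2)
    for (j in 1:2) {
      h <- c(K, DL2)[j] * 1e-5
      up <- c(K, DL2); up[j] <- up[j] + h
      dn <- c(K, DL2); dn[j] <- dn[j] - h
      mu <- model_interval_conc(up[1], up[2], profile)[use]
      md <- model_interval_conc(dn[1], dn[2], profile)[use]
      if (weights == "log") { mu <- log(pmax(mu, 1e-300)); md <- log(pmax(md, 1e-300)) }
      J[, j] <- (mu - md) / (2 * h)
    }
    V <- tryCatch(sigma2 * solve(crossprod(J)), error = function(e) V)
    if (is.matrix(V)) dimnames(V) <- list(c("K", "DL2"), c("K", "DL2"))
  }

  structure(list(params = params, K = K, DL2 = DL2,
                 se = sqrt(pmax(diag(V), 0)), vcov = V,
                 objective = best$value, sigma = sqrt(sigma2),
                 fitted = fitted_vals, residuals = resid_vals,
                 steady_state = steady, weights = weights,
                 Q_model = total_uptake(params, profile$t_exposure),
                 Q_obs = sum(profile$amount),
                 profile = profile, n_starts = nrow(starts), seed = seed),
            class = "dpk_fit")
}

#' @export
print.dpk_fit <- function(x, digits = 4, ...) {
  cat("Fickian SC uptake model fit\n")
  cat(sprintf("  K     = %s (SE %s)\n", format(x$K, digits = digits),
              format(x$se[1], digits = 3)))
  if (x$steady_state) {
    cat("  D/L^2 : not identifiable (profile at steady state)\n")
  } else {
    cat(sprintf("  D/L^2 = %s 1/h (SE %s)\n", format(x$DL2, digits = digits),
                format(x$se[2], digits = 3)))
  }
  cat(sprintf("  kp = %s cm/h, Jss = %s ug cm-2 h-1, tlag = %s h\n",
              format(x$params$kp, digits = digits),
              format(x$params$Jss, digits = digits),
              format(x$params$tlag, digits = digits)))
  cat(sprintf("  Q(t=%g h): model %s, observed %s ug/cm2; RSS = %s on %d intervals\n",
              x$profile$t_exposure, format(x$Q_model, digits = digits),
              format(x$Q_obs, digits = digits),
              format(x$objective, digits = 3), length(x$profile$conc)))
  invisible(x)
}

#' @export
summary.dpk_fit <- function(object, ...) {
  ci <- confint(object)
  out <- data.frame(estimate = c(object$K, object$DL2), se = object$se,
                    ci_low_90 = ci[, 1], ci_high_90 = ci[, 2],
                    row.names = c("K", "DL2"))
  print(object)
  cat("\n90% confidence intervals (asymptotic):\n")
  print(out, digits = 4)
  invisible(out)
}

#' @export
coef.dpk_fit <- function(object, ...) {
  c(K = object$K, DL2 = object$DL2, kp = object$params$kp,
    Jss = object$params$Jss, tlag = object$params$tlag,
    Q_model = object$Q_model, Q_obs = object$Q_obs)
}

#' @export
vcov.dpk_fit <- function(object, ...) object$vcov

#' @export
fitted.dpk_fit <- function(object, ...) object$fitted

#' @export
residuals.dpk_fit <- function(object, ...) object$residuals

#' Confidence intervals for fitted transport parameters
#'
#' @param object a [fit_profile()] fit.
#' @param parm parameters (`"K"`, `"DL2"` or both).
#' @param level confidence level (default 0.90, the conventional level in
#'   bioequivalence work).
#' @param method `"asymptotic"` (t-intervals from the asymptotic covariance)
#'   or `"bootstrap"` (seeded residual-resampling, `B` refits).
#' @param B bootstrap replicates (default 200).
#' @param seed seed for the bootstrap.
#' @param ... unused.
#' @export
confint.dpk_fit <- function(object, parm = c("K", "DL2"), level = 0.90,
                            method = c("asymptotic", "bootstrap"), B = 200,
                            seed = NULL, ...) {
  parm <- match.arg(parm, several.ok = TRUE)
  method <- match.arg(method)
  est <- c(K = object$K, DL2 = object$DL2)
  alpha <- 1 - level
  if (method == "asymptotic") {
    n <- length(object$profile$conc)
    tq <- stats::qt(1 - alpha / 2, df = max(n - 2, 1))
    ci <- cbind(est - tq * object$se, est + tq * object$se)
  } else {
    prof <- object$profile
    boot <- with_seed(seed, {
      t(replicate(B, {
        yb <- object$fitted + sample(object$residuals, replace = TRUE)
        pb <- prof; pb$conc <- pmax(yb, 0)
        fb <- tryCatch(fit_profile(pb, n_starts = 4), error = function(e) NULL)
        if (is.null(fb)) c(NA_real_, NA_real_) else c(fb$K, fb$DL2)
      }))
    })
    ci <- t(apply(boot, 2, stats::quantile,
                  probs = c(alpha / 2, 1 - alpha / 2), na.rm = TRUE))
    rownames(ci) <- c("K", "DL2")
  }
  colnames(ci) <- paste0(format(100 * c(alpha / 2, 1 - alpha / 2)), " %")
  ci[parm, , drop = FALSE]
}

#' Predict SC concentrations from a fitted uptake model
#'
#' @param object a [fit_profile()] fit.
#' @param x_rel relative depths in \[0, 1\]; default: midpoints of the
#'   fitted profile's intervals.
#' @param t exposure time (h); default: the profile's.
#' @param ... unused.
#' @return concentrations (ug/cm3).
#' @export
predict.dpk_fit <- function(object, x_rel = NULL, t = NULL, ...) {
  if (is.null(x_rel)) x_rel <- rowMeans(object$profile$intervals)
  if (is.null(t)) t <- object$profile$t_exposure
  concentration_profile(object$params, x_rel, t)
}

#' Simulate noisy replicate profiles from a fitted uptake model
#'
#' Parametric simulation: model interval-average concentrations plus
#' Gaussian noise with the fit's residual standard deviation, truncated
#' at zero.
#'
#' @param object a [fit_profile()] fit.
#' @param nsim number of simulated profiles.
#' @param seed seed.
#' @param ... unused.
#' @return a matrix (`length(conc)` x `nsim`) of simulated concentrations.
#' @export
simulate.dpk_fit <- function(object, nsim = 1, seed = NULL, ...) {
  m <- object$fitted
  with_seed(seed, {
    matrix(pmax(stats::rnorm(length(m) * nsim, mean = m, sd = object$sigma), 0),
           ncol = nsim)
  })
}

#' @export
plot.dpk_fit <- function(x, ...) {
  prof <- x$profile
  mid <- rowMeans(prof$intervals)
  graphics::plot(mid, prof$conc, xlim = c(0, 1),
                 xlab = "relative depth x/L", ylab = "C (ug/cm3)", ...)
  graphics::segments(prof$intervals[, 1], prof$conc, prof$intervals[, 2],
                     prof$conc, col = "grey60")
  u <- seq(0, 1, length.out = 200)
  graphics::lines(u, concentration_profile(x$params, u, prof$t_exposure),
                  col = "steelblue")
  invisible(x)
}

#' Summarise transport parameters across replicate fits
#'
#' Per-parameter mean, SD and n over a set of replicate [fit_profile()]
#' fits: K, D/L^2, kp, Jss and the total uptake at the exposure time,
#' both model-derived (`Q_model`) and observed as the sum of strip amounts
#' (`Q_obs`).
#'
#' @param fits list of `dpk_fit` objects (>= 2).
#' @return a `data.frame` with columns `parameter`, `mean`, `sd`, `n`.
#' @export
summarize_replicates <- function(fits) {
  if (length(fits) < 2) stop("need >= 2 replicate fits", call. = FALSE)
  stopifnot(all(vapply(fits, inherits, logical(1), "dpk_fit")))
  M <- do.call(rbind, lapply(fits, coef))
  keep <- c("K", "DL2", "kp", "Jss", "Q_model", "Q_obs")
  data.frame(parameter = keep,
             mean = colMeans(M[, keep, drop = FALSE]),
             sd = apply(M[, keep, drop = FALSE], 2, stats::sd),
             n = nrow(M), row.names = NULL)
}
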
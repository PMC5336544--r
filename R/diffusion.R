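# Closed-form series solution of Fick's second law in a finite membrane
# (constant-activity donor at x = 0, perfect sink at x = L, initially
# drug-free). Relative depth u = x/L in [0, 1] is used throughout.
#
#   C(u, t) = K * Cveh * { (1 - u)
#             - (2/pi) * sum_{n>=1} sin(n pi u)/n * exp(-DL2 n^2 pi^2 t) }

# Smallest number of series terms such that the truncation tail is below
# `tol` relative to K*Cveh.  For a = DL2 * pi^2 * t > 0 the tail of
# (2/pi) sum_{n>N} exp(-a n^2)/n is bounded by a geometric series.
# Near t = 0 convergence is slow; a floor of 50 terms is always applied.
n_terms_adaptive <- function(a, tol = 1e-8, n_min = 50L, n_max = 100000L) {
  if (a <= 0) return(n_max)
  n <- n_min
  repeat {
    m <- n + 1
    tail <- (2 / pi) * exp(-a * m^2) / (m * (1 - exp(-2 * a * m)))
    if (tail < tol || n >= n_max) return(n)
    n <- min(n_max, ceiling(n * 1.5))
  }
}

check_time_depth <- function(t, x_rel) {
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t) || t < 0)
    stop("exposure time 't' must be a single number >= 0 (h)", call. = FALSE)
  if (any(!is.finite(x_rel)) || any(x_rel < 0) || any(x_rel > 1))
    stop("relative depths 'x_rel' must lie in [0, 1]", call. = FALSE)
}

#' Drug concentration-depth profile in the SC
#'
#' Evaluates the series solution of Fick's second law for uptake into an
#' initially drug-free SC from a vehicle of constant concentration, at
#' relative depths `x_rel` = x/L after exposure time `t`.
#'
#' @param params a [diffusion_params()] object (`K`, `Cveh` used; `DL2`
#'   sets the time scale).
#' @param x_rel numeric vector of relative depths in \[0, 1\] (0 = SC
#'   surface in contact with the vehicle, 1 = SC/viable-epidermis sink).
#' @param t exposure time (h), >= 0.
#' @param n_terms number of series terms, or `NULL` (default) for an
#'   adaptive choice with truncation tail below `1e-8 * K * Cveh`
#'   (minimum 50 terms).
#' @return concentrations (ug/cm3) at each `x_rel`; small negative values
#'   from truncation (Gibbs oscillation) are clamped to 0.
#' @examples
#' p <- diffusion_params(K = 2, DL2 = 0.05, Cveh = 10)
#' concentration_profile(p, x_rel = c(0, 0.5, 1), t = 6)
#' @export
concentration_profile <- function(params, x_rel, t, n_terms = NULL) {
  stopifnot(inherits(params, "dpk_params"))
  check_time_depth(t, x_rel)
  scale <- params$K * params$Cveh
  if (t == 0) return(ifelse(x_rel == 0, scale, 0))
  a <- params$DL2 * pi^2 * t
  if (is.null(n_terms)) n_terms <- n_terms_adaptive(a)
  if (n_terms < 1) stop("'n_terms' must be >= 1", call. = FALSE)
  n <- seq_len(n_terms)
  damp <- exp(-a * n^2)
  keep <- damp > 0           # underflowed terms contribute nothing
  series <- if (any(keep)) {
    n <- n[keep]
    # sin(n pi u) matrix: length(x_rel) x length(n)
    (2 / pi) * as.vector(outer(x_rel, n, function(u, k) sin(k * pi * u)) %*%
                           (damp[keep] / n))
  } else 0
  pmax(scale * ((1 - x_rel) - series), 0)
}

#' Drug amount per unit area contained in a depth interval of the SC
#'
#' Term-by-term analytic integral of the concentration profile over the
#' relative-depth slab \[`x1_rel`, `x2_rel`\], multiplied by the SC
#' thickness. This is the quantity a tape strip (or a pool of strips)
#' spanning that slab removes.
#'
#' @inheritParams concentration_profile
#' @param x1_rel,x2_rel slab bounds, 0 <= x1 < x2 <= 1. Vectorised over
#'   slabs of equal length.
#' @return amount per unit area (ug/cm2) in each slab.
#' @export
slab_amount <- function(params, x1_rel, x2_rel, t, n_terms = NULL) {
  stopifnot(inherits(params, "dpk_params"))
  if (length(x1_rel) != length(x2_rel))
    stop("'x1_rel' and 'x2_rel' must have equal length", call. = FALSE)
  check_time_depth(t, c(x1_rel, x2_rel))
  if (any(x1_rel >= x2_rel))
    stop("slab bounds must satisfy x1_rel < x2_rel", call. = FALSE)
  if (is.na(params$L))
    stop("SC thickness 'L' is required for slab amounts", call. = FALSE)
  L_cm <- um_to_cm(params$L)
  scale <- params$K * params$Cveh * L_cm
  if (t == 0) return(rep(0, length(x1_rel)))
  a <- params$DL2 * pi^2 * t
  if (is.null(n_terms)) n_terms <- n_terms_adaptive(a)
  n <- seq_len(n_terms)
  damp <- exp(-a * n^2)
  keep <- damp > 0
  linear <- (x2_rel - x1_rel) - (x2_rel^2 - x1_rel^2) / 2
  series <- if (any(keep)) {
    n <- n[keep]
    cosdiff <- outer(x2_rel, n, function(u, k) cos(k * pi * u)) -
      outer(x1_rel, n, function(u, k) cos(k * pi * u))
    (2 / pi^2) * as.vector(cosdiff %*% (damp[keep] / n^2))
  } else 0
  pmax(scale * (linear + series), 0)
}

#' Total drug uptake into the SC
#'
#' Q(t), the amount of drug per unit area contained in the whole SC after
#' exposure time `t`:
#' `Q(t) = K * Cveh * L * [1/2 - (4/pi^2) * sum_{n odd} exp(-DL2 n^2 pi^2 t)/n^2]`.
#' As t grows, Q approaches the steady-state value `K * Cveh * L / 2`
#' (area under the linear profile).
#'
#' @inheritParams concentration_profile
#' @param t exposure time (h); vectorised.
#' @return amount per unit area (ug/cm2) at each `t`.
#' @export
total_uptake <- function(params, t, n_terms = NULL) {
  stopifnot(inherits(params, "dpk_params"))
  if (any(t < 0)) stop("exposure time 't' must be >= 0", call. = FALSE)
  if (is.na(params$L))
    stop("SC thickness 'L' is required for total uptake", call. = FALSE)
  scale <- params$K * params$Cveh * um_to_cm(params$L)
  vapply(t, function(ti) {
    if (ti == 0) return(0)
    a <- params$DL2 * pi^2 * ti
    nt <- if (is.null(n_terms)) n_terms_adaptive(a) else n_terms
    n <- seq(1, nt, by = 2)          # odd terms only
    s <- sum(exp(-a * n^2) / n^2)
    max(scale * (0.5 - (4 / pi^2) * s), 0)
  }, numeric(1))
}
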
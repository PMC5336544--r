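# Internal helpers: unit conversions and seeded RNG scoping.
# Package-wide unit convention: depth um, area cm2, time h, amount ug,
# concentration ug/cm3, TEWL g m-2 h-1. All conversions live here.

UM_PER_CM <- 1e4

um_to_cm <- function(x) x / UM_PER_CM

# mass of SC per area (ug/cm2) at density rho (g/cm3) -> depth (um):
# depth_cm = (m * 1e-6 g/cm2) / rho; depth_um = depth_cm * 1e4 = m / (rho * 100)
#' Convert SC mass removed per area into a depth increment
#'
#' Tape strips are weighed; the SC mass removed per unit area is converted to
#' the thickness of the SC layer removed assuming a constant SC density.
#' At a density of 1 g/cm3, 100 ug/cm2 corresponds to 1 um.
#'
#' @param mass_ug_per_cm2 SC mass removed per unit area (ug/cm2), >= 0.
#' @param sc_density SC density (g/cm3), > 0. Default 1.0.
#' @return Depth increment in um.
#' @export
mass_to_depth <- function(mass_ug_per_cm2, sc_density = 1.0) {
  if (!is.numeric(sc_density) || length(sc_density) != 1L || sc_density <= 0)
    stop("'sc_density' must be a single positive number (g/cm3)", call. = FALSE)
  if (any(mass_ug_per_cm2 < 0)) stop("'mass_ug_per_cm2' must be >= 0", call. = FALSE)
  mass_ug_per_cm2 / (sc_density * 100)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

# lognormal with median m and coefficient of variation cv (cv = 0 -> constant)
rlnorm_cv <- function(n, median, cv) {
  if (cv <= 0) return(rep(median, n))
  sdlog <- sqrt(log(1 + cv^2))
  median * exp(stats::rnorm(n, 0, sdlog))
}

stopifnot_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0) stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  if (nonneg && x < 0) stop(sprintf("'%s' must be >= 0", name), call. = FALSE)
  invisible(x)
}
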
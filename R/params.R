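#' Transport parameters for drug diffusion in the stratum corneum
#'
#' Container for the parameters of the finite-membrane Fickian transport
#' model: the SC-vehicle partition coefficient `K` (dimensionless), the
#' first-order diffusivity parameter `DL2` = D/L^2 (1/h), the SC thickness
#' `L` (um) and the drug concentration in the vehicle `Cveh` (ug/cm3).
#' The derived quantities -- permeability coefficient `kp = K * DL2 * L`
#' (cm/h, with L in cm), steady-state flux `Jss = kp * Cveh`
#' (ug cm-2 h-1) and lag time `tlag = 1/(6 * DL2)` (h) -- are filled by
#' [derive_transport()] whenever `L` (and `Cveh`, for `Jss`) is available.
#'
#' @param K SC-vehicle partition coefficient, > 0.
#' @param DL2 diffusivity parameter D/L^2 (1/h), > 0.
#' @param L SC thickness (um), > 0, or `NA` if not yet determined (supply it
#'   later, e.g. from [fit_tewl_thickness()]).
#' @param Cveh drug concentration in the vehicle (ug/cm3), >= 0.
#' @return An object of class `"dpk_params"`: a list with fields `K`, `DL2`,
#'   `L`, `Cveh` and derived `kp`, `Jss`, `tlag` (NA until derivable).
#' @examples
#' p <- diffusion_params(K = 2, DL2 = 0.05, L = 15, Cveh = 9300)
#' p$Jss
#' @export
diffusion_params <- function(K, DL2, L = NA_real_, Cveh = NA_real_) {
  stopifnot_scalar(K, "K", positive = TRUE)
  stopifnot_scalar(DL2, "DL2", positive = TRUE)
  K <- unname(K); DL2 <- unname(DL2); L <- unname(L); Cveh <- unname(Cveh)
  if (!is.na(L)) stopifnot_scalar(L, "L", positive = TRUE)
  if (!is.na(Cveh)) stopifnot_scalar(Cveh, "Cveh", nonneg = TRUE)
  p <- structure(
    list(K = K, DL2 = DL2, L = L, Cveh = Cveh,
         kp = NA_real_, Jss = NA_real_, tlag = NA_real_),
    class = "dpk_params")
  derive_transport(p, require_L = FALSE)
}

#' Fill in derived transport quantities (kp, Jss, lag time)
#'
#' @param params a [diffusion_params()] object with `K`, `DL2` set.
#' @param require_L if `TRUE` (default), a missing thickness `L` is an error;
#'   thickness must then be supplied directly or estimated from TEWL data
#'   with [fit_tewl_thickness()].
#' @return the params object with `kp`, `Jss` and `tlag` filled where
#'   their inputs are available.
#' @export
derive_transport <- function(params, require_L = TRUE) {
  stopifnot(inherits(params, "dpk_params"))
  params$tlag <- 1 / (6 * params$DL2)
  if (is.na(params$L)) {
    if (require_L)
      stop("SC thickness 'L' is not set: supply it, or estimate it from a ",
           "TEWL series with fit_tewl_thickness()", call. = FALSE)
    return(params)
  }
  params$kp <- unname(params$K * params$DL2 * um_to_cm(params$L))
  if (!is.na(params$Cveh)) params$Jss <- unname(params$kp * params$Cveh)
  params
}

#' @export
print.dpk_params <- function(x, digits = 4, ...) {
  cat("SC transport parameters\n")
  cat(sprintf("  K     (SC/vehicle partition)  %s\n", format(x$K, digits = digits)))
  cat(sprintf("  D/L^2 (1/h)                   %s\n", format(x$DL2, digits = digits)))
  cat(sprintf("  L     (um)                    %s\n", format(x$L, digits = digits)))
  cat(sprintf("  Cveh  (ug/cm3)                %s\n", format(x$Cveh, digits = digits)))
  if (!is.na(x$kp))
    cat(sprintf("  kp    (cm/h)                  %s\n", format(x$kp, digits = digits)))
  if (!is.na(x$Jss))
    cat(sprintf("  Jss   (ug cm-2 h-1)           %s\n", format(x$Jss, digits = digits)))
  cat(sprintf("  tlag  (h)                     %s\n", format(x$tlag, digits = digits)))
  invisible(x)
}
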
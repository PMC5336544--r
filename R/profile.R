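# Tape-strip records -> concentration-depth profile.

#' Tape-strip records for one replicate
#'
#' Validates and orders the per-strip measurements from a single
#' tape-stripping experiment: the SC mass removed on each strip (by
#' weighing) and the drug amount recovered from it. Strips assayed
#' together (deeper strips are often pooled in groups of up to 4 to
#' optimise assay sensitivity) share a `pool_id`; the drug amount of a
#' pool is recorded on each of its rows as the pool total divided by the
#' number of strips, or on one row with the others `NA` -- either way the
#' pool total is what is used.
#'
#' @param strip_index 1-based order of removal; unique and contiguous.
#' @param mass_ug_per_cm2 SC mass removed per area (ug/cm2), >= 0.
#' @param drug_ug_per_cm2 drug recovered per area (ug/cm2), >= 0 (or `NA`
#'   on non-leading rows of a pool).
#' @param pool_id optional pool identifier (`NA` = assayed individually);
#'   pooled strips must be consecutive.
#' @return a `data.frame` of class `"tape_strips"`, sorted by `strip_index`.
#' @export
tape_strips <- function(strip_index, mass_ug_per_cm2, drug_ug_per_cm2,
                        pool_id = NULL) {
  n <- length(strip_index)
  if (is.null(pool_id)) pool_id <- rep(NA_character_, n)
  if (length(mass_ug_per_cm2) != n || length(drug_ug_per_cm2) != n ||
      length(pool_id) != n)
    stop("all record columns must have equal length", call. = FALSE)
  o <- order(strip_index)
  strip_index <- strip_index[o]
  mass_ug_per_cm2 <- mass_ug_per_cm2[o]
  drug_ug_per_cm2 <- drug_ug_per_cm2[o]
  pool_id <- as.character(pool_id)[o]
  if (anyDuplicated(strip_index))
    stop("duplicate strip_index", call. = FALSE)
  if (!all(strip_index == seq_len(n)))
    stop("strip_index must be contiguous starting at 1", call. = FALSE)
  if (any(mass_ug_per_cm2 < 0)) stop("negative SC mass", call. = FALSE)
  if (any(drug_ug_per_cm2 < 0, na.rm = TRUE)) stop("negative drug amount", call. = FALSE)
  for (pid in unique(pool_id[!is.na(pool_id)])) {
    idx <- strip_index[!is.na(pool_id) & pool_id == pid]
    if (!all(diff(idx) == 1))
      stop(sprintf("pooled strips must be consecutive (pool '%s')", pid),
           call. = FALSE)
  }
  structure(data.frame(strip_index = strip_index,
                       mass_ug_per_cm2 = mass_ug_per_cm2,
                       drug_ug_per_cm2 = drug_ug_per_cm2,
                       pool_id = pool_id,
                       stringsAsFactors = FALSE),
            class = c("tape_strips", "data.frame"))
}

#' Build a concentration-depth profile from tape-strip records
#'
#' Converts cumulative SC mass removed into depth (via [mass_to_depth()]),
#' normalises by the SC thickness `L`, merges pooled strips into single
#' depth intervals with their summed drug amounts, and expresses each
#' interval's content as a drug concentration per SC volume.
#'
#' @param records a [tape_strips()] object (one replicate).
#' @param L SC thickness (um), e.g. from [fit_tewl_thickness()].
#' @param t_exposure application time (h), > 0.
#' @param Cveh drug concentration in the vehicle (ug/cm3).
#' @param sc_density SC density (g/cm3), default 1.0.
#' @param discard_first_n drop the first `n` strips from the fitted profile
#'   (their depth is still accounted for); guards against residual surface
#'   formulation when cleaning was less rigorous. Default 0.
#' @return an object of class `"strip_profile"`: list with `intervals`
#'   (2-column matrix of relative depths), `conc` (ug/cm3), `amount`
#'   (ug/cm2 per interval), `t_exposure`, `Cveh`, `L`.
#' @export
build_profile <- function(records, L, t_exposure, Cveh, sc_density = 1.0,
                          discard_first_n = 0) {
  stopifnot(inherits(records, "tape_strips"))
  stopifnot_scalar(L, "L", positive = TRUE)
  stopifnot_scalar(t_exposure, "t_exposure", positive = TRUE)
  stopifnot_scalar(Cveh, "Cveh", nonneg = TRUE)
  depth_inc <- mass_to_depth(records$mass_ug_per_cm2, sc_density)
  depth_hi <- cumsum(depth_inc)
  depth_lo <- c(0, depth_hi[-length(depth_hi)])
  if (depth_hi[length(depth_hi)] > 1.2 * L)
    stop(sprintf(paste0("total mass-derived depth (%.1f um) exceeds 1.2 x L ",
                        "(L = %.1f um): check the supplied thickness or SC ",
                        "density"), depth_hi[length(depth_hi)], L), call. = FALSE)
  # group key: pool_id where present, otherwise the strip itself
  key <- ifelse(is.na(records$pool_id),
                paste0(".strip", records$strip_index), records$pool_id)
  key <- factor(key, levels = unique(key))
  x1 <- tapply(depth_lo, key, min) / L
  x2 <- tapply(depth_hi, key, max) / L
  amt <- tapply(records$drug_ug_per_cm2, key, sum, na.rm = TRUE)
  first_strip <- tapply(records$strip_index, key, min)
  # the final strip's mass-derived depth may overshoot L slightly (it removes
  # whatever SC remains); the profile lives on [0, 1]
  x1 <- pmin(x1, 1); x2 <- pmin(x2, 1)
  keep <- first_strip > discard_first_n & x1 < 1
  x1 <- x1[keep]; x2 <- x2[keep]; amt <- amt[keep]
  width <- x2 - x1
  if (any(width == 0)) {
    warning("zero-mass strip(s) merged with the following interval", call. = FALSE)
    nz <- which(width == 0)
    for (i in rev(nz)) {
      j <- if (i < length(width)) i + 1L else i - 1L
      amt[j] <- amt[j] + amt[i]
    }
    x1 <- x1[-nz]; x2 <- x2[-nz]; amt <- amt[-nz]; width <- width[-nz]
  }
  conc <- amt / (width * um_to_cm(L))   # ug/cm2 per cm of depth -> ug/cm3
  structure(list(intervals = cbind(x1 = as.numeric(x1), x2 = as.numeric(x2)),
                 conc = as.numeric(conc), amount = as.numeric(amt),
                 t_exposure = t_exposure, Cveh = Cveh, L = L),
            class = "strip_profile")
}

#' @export
print.strip_profile <- function(x, ...) {
  cat(sprintf("SC tape-strip profile: %d intervals, t = %g h, L = %.1f um, Cveh = %g ug/cm3\n",
              nrow(x$intervals), x$t_exposure, x$L, x$Cveh))
  cat(sprintf("  depth covered: %.2f of SC; total drug %.3g ug/cm2\n",
              max(x$intervals[, 2]), sum(x$amount)))
  invisible(x)
}
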
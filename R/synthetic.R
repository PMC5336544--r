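# Virtual tape-stripping / TEWL / clearance / IVRT experiments with known
# ground truth. Noise model: multiplicative log-normal for drug amounts and
# replicate-level parameters (amounts are positive and their spread is
# asymmetric), additive Gaussian for TEWL readings and receptor
# concentrations.

#' Specification of a virtual tape-stripping cohort
#'
#' Defines the study conditions a simulated cohort emulates: replicate
#' count, true transport parameters, between-replicate variability
#' (log-normal, applied to K and D/L^2 with median preserved), strip-mass
#' distribution, pooling rule for deep strips, assay noise, and the
#' inverse-thickness TEWL law.
#'
#' @param n_replicates number of replicates (skin samples).
#' @param true_params a [diffusion_params()] object (K, DL2, L, Cveh all set).
#' @param t_exposure application time (h), default 6.
#' @param between_replicate_cv log-normal CV of replicate-level K and D/L^2
#'   around their true values; default 0.20.
#' @param strip_mass_mean,strip_mass_cv log-normal median and CV of SC mass
#'   removed per strip (ug/cm2); defaults 75 and 0.30.
#' @param pool_after strip index beyond which strips are pooled in groups
#'   of up to `pool_size`; default 8.
#' @param pool_size maximum pool size, default 4.
#' @param assay_cv multiplicative log-normal CV of the drug assay (applied
#'   per assayed unit, i.e. per pool or individual strip); default 0.15.
#' @param tewl_baseline pre-stripping TEWL (g m-2 h-1), default 7.
#' @param tewl_kw constant of the inverse-thickness law
#'   `TEWL = Kw / (H - x)` (g m-2 h-1 um), default `tewl_baseline * L` so
#'   the intact-SC reading equals the baseline.
#' @param tewl_noise relative SD of additive Gaussian TEWL noise, default 0.05.
#' @param tewl_endpoint stripping stops once TEWL >= this (g m-2 h-1),
#'   default 100.
#' @param sc_density SC density (g/cm3), default 1.
#' @return an object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_replicates, true_params, t_exposure = 6,
                        between_replicate_cv = 0.20,
                        strip_mass_mean = 75, strip_mass_cv = 0.30,
                        pool_after = 8, pool_size = 4, assay_cv = 0.15,
                        tewl_baseline = 7, tewl_kw = NULL, tewl_noise = 0.05,
                        tewl_endpoint = 100, sc_density = 1) {
  stopifnot(inherits(true_params, "dpk_params"))
  if (is.na(true_params$L) || is.na(true_params$Cveh))
    stop("'true_params' must have L and Cveh set", call. = FALSE)
  if (n_replicates < 1) stop("'n_replicates' must be >= 1", call. = FALSE)
  for (cv in c(between_replicate_cv, strip_mass_cv, assay_cv, tewl_noise))
    if (cv < 0) stop("CVs must be >= 0", call. = FALSE)
  if (is.null(tewl_kw)) tewl_kw <- tewl_baseline * true_params$L
  structure(list(n_replicates = n_replicates, true_params = true_params,
                 t_exposure = t_exposure,
                 between_replicate_cv = between_replicate_cv,
                 strip_mass_mean = strip_mass_mean,
                 strip_mass_cv = strip_mass_cv,
                 pool_after = pool_after, pool_size = pool_size,
                 assay_cv = assay_cv, tewl_baseline = tewl_baseline,
                 tewl_kw = tewl_kw, tewl_noise = tewl_noise,
                 tewl_endpoint = tewl_endpoint, sc_density = sc_density),
            class = "cohort_spec")
}

#' Named cohort presets
#'
#' Ready-made [cohort_spec()]s whose magnitudes match the two study designs
#' the package targets: a potent corticosteroid applied for 6 h in two
#' vehicles of equal thermodynamic activity but very different strength
#' (microemulsion, `"BMV-ME-like"`, Cveh = 9300 ug/cm3, vs medium-chain
#' triglyceride, `"BMV-MCT-like"`, Cveh = 1700 ug/cm3; n = 6; their true
#' steady-state fluxes differ ~8.7-fold), and an antifungal 1% cream
#' cohort (`"EN-like"`, Cveh = 10000 ug/cm3, n = 14) whose true 6-h SC
#' uptake is ~2 ug/cm2 with a ~13 h lag time.
#'
#' @param name one of `"BMV-ME-like"`, `"BMV-MCT-like"`, `"EN-like"`.
#' @param ... overrides passed to [cohort_spec()].
#' @return a [cohort_spec()].
#' @export
cohort_preset <- function(name = c("BMV-ME-like", "BMV-MCT-like", "EN-like"),
                          ...) {
  name <- match.arg(name)
  base <- switch(name,
    "BMV-ME-like" = list(n_replicates = 6,
      true_params = diffusion_params(K = 2, DL2 = 0.02, L = 15, Cveh = 9300)),
    "BMV-MCT-like" = list(n_replicates = 6,
      true_params = diffusion_params(K = 2, DL2 = 0.0126, L = 15, Cveh = 1700)),
    "EN-like" = list(n_replicates = 14,
      true_params = diffusion_params(K = 0.43, DL2 = 1 / 78, L = 15, Cveh = 10000)))
  do.call(cohort_spec, utils::modifyList(base, list(...)))
}

# drug amounts per strip from the diffusion model, pooling + assay noise
simulate_replicate <- function(spec, K_i, DL2_i) {
  H <- spec$true_params$L
  p_i <- diffusion_params(K = K_i, DL2 = DL2_i, L = H,
                          Cveh = spec$true_params$Cveh)
  masses <- numeric(0)
  repeat {
    masses <- c(masses, rlnorm_cv(5, spec$strip_mass_mean, spec$strip_mass_cv))
    if (sum(mass_to_depth(masses, spec$sc_density)) >= H) break
    if (length(masses) > 200) stop("strip masses too small to traverse the SC",
                                   call. = FALSE)
  }
  depth <- cumsum(mass_to_depth(masses, spec$sc_density))
  n_strips <- which(depth >= H)[1]
  masses <- masses[seq_len(n_strips)]
  depth <- depth[seq_len(n_strips)]
  if (n_strips < 4) stop("cohort spec yields < 4 strips; increase thickness ",
                         "or reduce strip mass", call. = FALSE)
  x2 <- pmin(depth / H, 1)
  x1 <- c(0, x2[-n_strips])
  drug_true <- numeric(n_strips)
  pos <- x2 > x1
  drug_true[pos] <- slab_amount(p_i, x1[pos], x2[pos], spec$t_exposure)
  # pooling of deep strips in consecutive groups of up to pool_size
  pool_id <- rep(NA_character_, n_strips)
  if (n_strips > spec$pool_after) {
    deep <- seq(spec$pool_after + 1, n_strips)
    grp <- (seq_along(deep) - 1) %/% spec$pool_size
    pool_id[deep] <- sprintf("P%d", grp + 1)
  }
  key <- ifelse(is.na(pool_id), paste0(".s", seq_len(n_strips)), pool_id)
  key <- factor(key, levels = unique(key))
  pool_totals <- tapply(drug_true, key, sum)
  noise <- rlnorm_cv(length(pool_totals), 1, spec$assay_cv)
  noisy_totals <- pool_totals * noise
  # spread each pool total evenly over its member rows (pool sum preserved)
  per_row <- as.numeric(noisy_totals[key] / tabulate(key)[as.integer(key)])
  rec <- tape_strips(seq_len(n_strips), masses, per_row, pool_id)
  # TEWL series: reading before each strip and after the last
  xs <- c(0, depth)
  tewl_true <- ifelse(xs < H, spec$tewl_kw / (H - xs), Inf)
  tewl_true <- pmin(tewl_true, 10 * spec$tewl_endpoint)
  tewl <- pmax(tewl_true * (1 + stats::rnorm(length(xs), 0, spec$tewl_noise)),
               0.1)
  stop_at <- which(tewl >= spec$tewl_endpoint)[1]
  if (is.na(stop_at)) stop_at <- length(tewl)
  series <- tewl_series(xs[seq_len(stop_at)], tewl[seq_len(stop_at)],
                        baseline = spec$tewl_baseline)
  list(records = rec, tewl = series,
       truth = data.frame(K = K_i, DL2 = DL2_i, n_strips = n_strips,
                          Q_true = total_uptake(p_i, spec$t_exposure),
                          total_drug = sum(drug_true)))
}

#' Generate a virtual tape-stripping cohort
#'
#' For each replicate: draws replicate-level K and D/L^2 (log-normal around
#' the truth), draws strip masses until the cumulative depth reaches the SC
#' thickness, assigns each strip its slab drug amount from the diffusion
#' model at the exposure time, pools deep strips, applies multiplicative
#' assay noise, and emits a TEWL series following the inverse-thickness law
#' truncated at the stripping endpoint. The generator is a pure function of
#' `(spec, seed)`.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer seed.
#' @return an object of class `"dpk_cohort"`: list with `replicates` (each
#'   holding `records` ([tape_strips()]) and `tewl` ([tewl_series()])),
#'   `truth` (per-replicate ground-truth data.frame) and the `spec`.
#' @export
generate_tape_strip_cohort <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(seed, {
    K_r <- rlnorm_cv(spec$n_replicates, spec$true_params$K,
                     spec$between_replicate_cv)
    D_r <- rlnorm_cv(spec$n_replicates, spec$true_params$DL2,
                     spec$between_replicate_cv)
    reps <- lapply(seq_len(spec$n_replicates),
                   function(i) simulate_replicate(spec, K_r[i], D_r[i]))
    truth <- do.call(rbind, lapply(reps, `[[`, "truth"))
    truth <- cbind(replicate = seq_len(spec$n_replicates), truth)
    structure(list(replicates = lapply(reps, function(r) r[c("records", "tewl")]),
                   truth = truth, spec = spec, seed = seed,
                   phase = "uptake"),
              class = "dpk_cohort")
  })
}

#' @export
print.dpk_cohort <- function(x, ...) {
  cat(sprintf("Virtual tape-strip cohort (%s phase): n = %d replicates, %d-%d strips\n",
              x$phase, length(x$replicates), min(x$truth$n_strips),
              max(x$truth$n_strips)))
  invisible(x)
}

#' Generate the clearance arm of a cohort
#'
#' Simulates the tape-stripping carried out after a post-removal waiting
#' period. With `clearance_mode = "none"` the SC load is unchanged up to
#' noise (the behaviour of excised skin, which lacks the microcirculation
#' needed to clear a lipophilic drug); with `"first-order"` every amount is
#' scaled by `exp(-k_clear * t_clear)` (in-vivo-like elimination).
#' Clearance replicates are fresh, independent skin samples.
#'
#' @param spec a [cohort_spec()].
#' @param clearance_mode `"none"` (default) or `"first-order"`.
#' @param k_clear first-order elimination constant (1/h), >= 0.
#' @param t_clear clearance period (h), default 17.
#' @param seed integer seed.
#' @return a `"dpk_cohort"` with `phase = "clearance"` and drug amounts
#'   scaled accordingly (ground truth scaled too).
#' @export
generate_clearance_arm <- function(spec, clearance_mode = c("none", "first-order"),
                                   k_clear = 0, t_clear = 17, seed = NULL) {
  clearance_mode <- match.arg(clearance_mode)
  if (k_clear < 0) stop("'k_clear' must be >= 0", call. = FALSE)
  surv <- if (clearance_mode == "first-order") exp(-k_clear * t_clear) else 1
  cohort <- generate_tape_strip_cohort(spec, seed = seed)
  cohort$replicates <- lapply(cohort$replicates, function(r) {
    r$records$drug_ug_per_cm2 <- r$records$drug_ug_per_cm2 * surv
    r
  })
  cohort$truth$total_drug <- cohort$truth$total_drug * surv
  cohort$phase <- "clearance"
  cohort$clearance <- list(mode = clearance_mode, k_clear = k_clear,
                           t_clear = t_clear, survival = surv)
  cohort
}

#' Total SC amounts of a cohort as a bioequivalence input table
#'
#' @param cohort a `"dpk_cohort"`.
#' @param product product label.
#' @return a [replicate_totals()] table (one row per replicate, phase taken
#'   from the cohort).
#' @export
cohort_totals <- function(cohort, product) {
  stopifnot(inherits(cohort, "dpk_cohort"))
  amounts <- vapply(cohort$replicates,
                    function(r) sum(r$records$drug_ug_per_cm2, na.rm = TRUE),
                    numeric(1))
  replicate_totals(id = seq_along(amounts), product = product,
                   phase = cohort$phase, amount = amounts)
}

#' Generate IVRT release curves with known square-root-of-time truth
#'
#' Builds true cumulative release `Q = slope * sqrt(t)`, perturbs it with
#' additive Gaussian noise (made non-decreasing, as cumulative release is),
#' and inverts the withdrawal/replacement mass balance so that the emitted
#' per-sample receptor concentrations round-trip exactly through
#' [cumulative_from_samples()].
#'
#' @param true_slope release-rate constant (ug cm-2 h^-1/2).
#' @param times sampling times (h), strictly increasing.
#' @param noise_sd SD of additive Gaussian noise on cumulative amounts
#'   (ug/cm2).
#' @param n_cells number of diffusion cells.
#' @param sample_volumes withdrawn volume(s) (mL), default 1.
#' @param receptor_volume receptor volume (mL), default 7.4.
#' @param area membrane area (cm2), default 2.
#' @param seed integer seed.
#' @return list with `curves` (list of [release_curve()]), `concs`
#'   (times x cells matrix of emitted receptor concentrations, ug/mL),
#'   `sample_volumes`, and the generation constants.
#' @export
generate_release_curves <- function(true_slope, times, noise_sd = 0,
                                    n_cells = 6, sample_volumes = 1,
                                    receptor_volume = 7.4, area = 2,
                                    seed = NULL) {
  if (any(diff(times) <= 0)) stop("'times' must be strictly increasing", call. = FALSE)
  nt <- length(times)
  sample_volumes <- rep_len(sample_volumes, nt)
  with_seed(seed, {
    concs <- matrix(0, nt, n_cells)
    curves <- vector("list", n_cells)
    for (c_i in seq_len(n_cells)) {
      Q <- true_slope * sqrt(times)
      if (noise_sd > 0) Q <- cummax(pmax(Q + stats::rnorm(nt, 0, noise_sd), 0))
      withdrawn <- 0
      C <- numeric(nt)
      for (j in seq_len(nt)) {
        C[j] <- max((Q[j] * area - withdrawn) / receptor_volume, 0)
        withdrawn <- withdrawn + C[j] * sample_volumes[j]
      }
      concs[, c_i] <- C
      curves[[c_i]] <- cumulative_from_samples(C, times, sample_volumes,
                                               receptor_volume, area)
    }
    list(curves = curves, concs = concs, sample_volumes = sample_volumes,
         true_slope = true_slope, receptor_volume = receptor_volume,
         area = area, times = times)
  })
}
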
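# Plain-CSV readers/writers for the pipeline's table schemas, config
# handling, and end-to-end pipeline orchestration with a Markdown report.
#
# Schemas (headers carry units; mismatched headers abort, no silent
# coercion):
#   tape strips : replicate_id, strip_index, mass_ug_per_cm2,
#                 drug_ug_per_cm2, pool_id
#   TEWL        : replicate_id, strip_index, mass_ug_per_cm2, tewl_g_m2_h
#                 (baseline row: strip_index = 0)
#   IVRT        : cell_id, formulation_id, membrane_id, time_h,
#                 conc_ug_per_ml, sample_volume_ml
#   totals      : subject_or_cell_id, product_id, phase, amount_ug_per_cm2

check_columns <- function(d, required, file) {
  missing <- setdiff(required, names(d))
  if (length(missing))
    stop(sprintf("%s: missing column(s): %s", file,
                 paste(missing, collapse = ", ")), call. = FALSE)
}

check_nonneg <- function(d, cols, file) {
  for (col in cols) {
    bad <- which(!is.na(d[[col]]) & d[[col]] < 0)
    if (length(bad))
      stop(sprintf("%s: negative %s at row %d", file, col, bad[1]), call. = FALSE)
  }
}

#' Read tape-strip records from CSV
#'
#' @param file path to a CSV with columns `replicate_id`, `strip_index`,
#'   `mass_ug_per_cm2`, `drug_ug_per_cm2` and optionally `pool_id`.
#' @return named list of [tape_strips()] objects, one per replicate.
#' @export
read_strip_csv <- function(file) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE)
  check_columns(d, c("replicate_id", "strip_index", "mass_ug_per_cm2",
                     "drug_ug_per_cm2"), file)
  check_nonneg(d, c("mass_ug_per_cm2", "drug_ug_per_cm2"), file)
  if (is.null(d$pool_id)) d$pool_id <- NA_character_
  d$pool_id[d$pool_id %in% c("", "NA")] <- NA_character_
  out <- lapply(split(d, d$replicate_id), function(dd) {
    dup <- anyDuplicated(dd$strip_index)
    if (dup)
      stop(sprintf("%s: duplicate strip_index %s in replicate %s", file,
                   dd$strip_index[dup], dd$replicate_id[1]), call. = FALSE)
    tape_strips(dd$strip_index, dd$mass_ug_per_cm2, dd$drug_ug_per_cm2,
                dd$pool_id)
  })
  out[order(names(out))]
}

#' Write a cohort's tape-strip records (and ground truth) to CSV
#'
#' @param cohort a `"dpk_cohort"` from [generate_tape_strip_cohort()].
#' @param file output CSV path.
#' @param truth_file optional path for the ground-truth sidecar table.
#' @return `file`, invisibly.
#' @export
write_strip_csv <- function(cohort, file, truth_file = NULL) {
  stopifnot(inherits(cohort, "dpk_cohort"))
  rows <- do.call(rbind, lapply(seq_along(cohort$replicates), function(i) {
    r <- cohort$replicates[[i]]$records
    data.frame(replicate_id = i, strip_index = r$strip_index,
               mass_ug_per_cm2 = r$mass_ug_per_cm2,
               drug_ug_per_cm2 = r$drug_ug_per_cm2, pool_id = r$pool_id)
  }))
  utils::write.csv(rows, file, row.names = FALSE, na = "")
  if (!is.null(truth_file))
    utils::write.csv(cohort$truth, truth_file, row.names = FALSE)
  invisible(file)
}

#' Read a TEWL series from CSV
#'
#' The baseline (pre-stripping) reading is the `strip_index = 0` row; the
#' reading of row i is taken after the cumulative SC mass of strips
#' `1..i` has been removed.
#'
#' @param file CSV with columns `strip_index`, `mass_ug_per_cm2`,
#'   `tewl_g_m2_h` (and optionally `replicate_id`; then a list is returned).
#' @param sc_density SC density (g/cm3) for the mass-to-depth conversion.
#' @return a [tewl_series()] (or a named list of them).
#' @export
read_tewl_csv <- function(file, sc_density = 1) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE)
  check_columns(d, c("strip_index", "mass_ug_per_cm2", "tewl_g_m2_h"), file)
  check_nonneg(d, c("mass_ug_per_cm2"), file)
  one <- function(dd) {
    dd <- dd[order(dd$strip_index), ]
    if (dd$strip_index[1] != 0)
      stop(sprintf("%s: no baseline row (strip_index = 0)", file), call. = FALSE)
    # row k's reading was taken after strips 1..k were removed; the baseline
    # row carries mass 0
    tewl_series(depth_removed = cumsum(mass_to_depth(dd$mass_ug_per_cm2,
                                                     sc_density)),
                tewl = dd$tewl_g_m2_h, baseline = dd$tewl_g_m2_h[1])
  }
  if (!is.null(d$replicate_id)) {
    out <- lapply(split(d, d$replicate_id), one)
    out[order(names(out))]
  } else one(d)
}

#' Write a cohort's TEWL series to CSV
#' @param cohort a `"dpk_cohort"`.
#' @param file output CSV path.
#' @return `file`, invisibly.
#' @export
write_tewl_csv <- function(cohort, file) {
  stopifnot(inherits(cohort, "dpk_cohort"))
  rows <- do.call(rbind, lapply(seq_along(cohort$replicates), function(i) {
    s <- cohort$replicates[[i]]$tewl
    # per-row mass from depth increments (density per the generating spec)
    data.frame(replicate_id = i,
               strip_index = seq_along(s$tewl) - 1L,
               mass_ug_per_cm2 = c(0, diff(s$depth_removed)) *
                 cohort$spec$sc_density * 100,
               tewl_g_m2_h = s$tewl)
  }))
  utils::write.csv(rows, file, row.names = FALSE)
  invisible(file)
}

#' Read IVRT receptor samples from CSV
#'
#' @param file CSV with columns `cell_id`, `formulation_id`, `membrane_id`,
#'   `time_h`, `conc_ug_per_ml`, `sample_volume_ml`.
#' @param receptor_volume receptor volume (mL), default 7.4.
#' @param area membrane area (cm2), default 2.
#' @param correct_replacement apply the withdrawal correction, default TRUE.
#' @return list of [release_curve()] objects, one per cell.
#' @export
read_release_csv <- function(file, receptor_volume = 7.4, area = 2,
                             correct_replacement = TRUE) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE)
  check_columns(d, c("cell_id", "formulation_id", "membrane_id", "time_h",
                     "conc_ug_per_ml", "sample_volume_ml"), file)
  check_nonneg(d, c("conc_ug_per_ml", "sample_volume_ml"), file)
  lapply(split(d, d$cell_id), function(dd) {
    dd <- dd[order(dd$time_h), ]
    cumulative_from_samples(dd$conc_ug_per_ml, dd$time_h, dd$sample_volume_ml,
                            receptor_volume, area,
                            correct_replacement = correct_replacement,
                            formulation_id = dd$formulation_id[1],
                            membrane_id = dd$membrane_id[1])
  })
}

#' Read per-replicate total SC amounts from CSV
#'
#' @param file CSV with columns `subject_or_cell_id`, `product_id`, `phase`
#'   (`uptake`/`clearance`), `amount_ug_per_cm2`.
#' @return a [replicate_totals()] table.
#' @export
read_totals_csv <- function(file) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE)
  check_columns(d, c("subject_or_cell_id", "product_id", "phase",
                     "amount_ug_per_cm2"), file)
  check_nonneg(d, "amount_ug_per_cm2", file)
  bad <- which(!d$phase %in% c("uptake", "clearance"))
  if (length(bad))
    stop(sprintf("%s: invalid phase '%s' at row %d", file, d$phase[bad[1]],
                 bad[1]), call. = FALSE)
  replicate_totals(d$subject_or_cell_id, d$product_id, d$phase,
                   d$amount_ug_per_cm2)
}

#' @rdname read_totals_csv
#' @param totals a [replicate_totals()] table.
#' @param file output CSV path.
#' @export
write_totals_csv <- function(totals, file) {
  stopifnot(inherits(totals, "replicate_totals"))
  utils::write.csv(data.frame(subject_or_cell_id = totals$id,
                              product_id = totals$product,
                              phase = totals$phase,
                              amount_ug_per_cm2 = totals$amount),
                   file, row.names = FALSE)
  invisible(file)
}

#' Read a pipeline run configuration (YAML or JSON)
#'
#' Recognised keys: input paths (`strip_file`, `tewl_file`, `release_file`,
#' `totals_file`), formulation metadata (`Cveh_ug_per_cm3`, `t_exposure_h`,
#' `t_clearance_h`, `L_um`), analysis options (`density_g_cm3`,
#' `discard_first_n`, `ci_method`, `seed`, `test_products`,
#' `reference_product`, `receptor_volume_ml`, `area_cm2`) and `output_dir`.
#'
#' @param file path to a `.yaml`/`.yml` or `.json` file.
#' @param overrides named list of values overriding the file's.
#' @return a validated config list of class `"run_config"`.
#' @export
read_run_config <- function(file, overrides = list()) {
  cfg <- if (grepl("\\.ya?ml$", file, ignore.case = TRUE))
    yaml::read_yaml(file)
  else jsonlite::fromJSON(file, simplifyVector = TRUE)
  cfg <- utils::modifyList(cfg, overrides)
  defaults <- list(density_g_cm3 = 1, discard_first_n = 0, seed = 1,
                   receptor_volume_ml = 7.4, area_cm2 = 2,
                   ci_method = "bootstrap", output_dir = ".")
  cfg <- utils::modifyList(defaults, cfg)
  for (key in grep("_file$", names(cfg), value = TRUE))
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]]))
      stop(sprintf("config: %s '%s' does not exist", key, cfg[[key]]),
           call. = FALSE)
  structure(cfg, class = "run_config")
}

#' Run a full analysis pipeline and write a report bundle
#'
#' Orchestrates the three pipelines over validated CSV inputs:
#' `"dpk"` (tape strips + thickness -> per-replicate model fits -> parameter
#' summary), `"ivrt"` (receptor samples -> cumulative release ->
#' square-root-of-time fits -> formulation/membrane comparison) and
#' `"be"` (uptake/clearance totals -> per-phase and combined summaries ->
#' test/reference ratios with 90% CI and verdicts). Writes CSV tables and
#' a Markdown summary (with a provenance block: package version, seed,
#' config hash) into `output_dir`; deterministic given inputs and seed.
#'
#' @param config a `"run_config"` (see [read_run_config()]) or named list.
#' @param which `"dpk"`, `"ivrt"` or `"be"`.
#' @return named list of result objects (also serialised to `output_dir`),
#'   invisibly.
#' @export
run_pipeline <- function(config, which = c("dpk", "ivrt", "be")) {
  which <- match.arg(which)
  if (!inherits(config, "run_config")) class(config) <- "run_config"
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  md <- c(sprintf("# DPK pipeline report (%s)", which), "")
  res <- switch(which,
    dpk = {
      strips <- read_strip_csv(config$strip_file)
      L <- if (!is.null(config$L_um)) rep(config$L_um, length(strips)) else {
        if (is.null(config$tewl_file))
          stop("dpk pipeline needs 'L_um' or 'tewl_file'", call. = FALSE)
        tw <- read_tewl_csv(config$tewl_file, config$density_g_cm3)
        if (inherits(tw, "tewl_series")) tw <- list(tw)
        vapply(tw, function(s) fit_tewl_thickness(s)$H, numeric(1))
      }
      fits <- lapply(seq_along(strips), function(i) {
        prof <- build_profile(strips[[i]], L = L[i],
                              t_exposure = config$t_exposure_h,
                              Cveh = config$Cveh_ug_per_cm3,
                              sc_density = config$density_g_cm3,
                              discard_first_n = config$discard_first_n)
        fit_profile(prof)
      })
      summ <- summarize_replicates(fits)
      utils::write.csv(summ, file.path(config$output_dir, "dpk_parameters.csv"),
                       row.names = FALSE)
      md <- c(md, "Per-formulation transport parameters (mean +/- SD):", "",
              "| parameter | mean | sd | n |", "|---|---|---|---|",
              sprintf("| %s | %.4g | %.4g | %d |", summ$parameter, summ$mean,
                      summ$sd, summ$n))
      list(fits = fits, summary = summ, thickness = L)
    },
    ivrt = {
      curves <- read_release_csv(config$release_file,
                                 config$receptor_volume_ml, config$area_cm2)
      hf <- lapply(curves, higuchi_fit)
      ends <- vapply(curves, function(cv) cv$cumulative[length(cv$cumulative)],
                     numeric(1))
      form <- vapply(curves, `[[`, character(1) , "formulation_id")
      memb <- vapply(curves, `[[`, character(1), "membrane_id")
      cmp <- tryCatch(compare_release(ends, form, memb), error = function(e) NULL)
      tab <- data.frame(cell_id = names(curves), formulation_id = form,
                        membrane_id = memb, Q_end_ug_per_cm2 = ends,
                        higuchi_k = vapply(hf, `[[`, numeric(1), "k"),
                        r_squared = vapply(hf, `[[`, numeric(1), "r.squared"))
      utils::write.csv(tab, file.path(config$output_dir, "ivrt_fits.csv"),
                       row.names = FALSE)
      md <- c(md, sprintf("%d cells; mean Higuchi slope %.4g ug cm-2 h^-1/2",
                          length(curves), mean(tab$higuchi_k, na.rm = TRUE)))
      list(curves = curves, higuchi = hf, comparison = cmp, table = tab)
    },
    be = {
      totals <- read_totals_csv(config$totals_file)
      products <- unique(totals$product)
      tab2 <- do.call(rbind, lapply(products, function(p) {
        do.call(rbind, lapply(c("uptake", "clearance"), function(ph) {
          s <- phase_summary(totals, p, ph, method = "logt")
          data.frame(product = p, phase = ph, mean = s$mean,
                     ci_low_90 = s$ci[1], ci_high_90 = s$ci[2], n = s$n)
        }))
      }))
      utils::write.csv(tab2, file.path(config$output_dir, "be_phase_summary.csv"),
                       row.names = FALSE)
      ref <- config$reference_product
      tests <- config$test_products
      if (is.null(ref) || is.null(tests))
        stop("be pipeline needs 'reference_product' and 'test_products'",
             call. = FALSE)
      tab3 <- do.call(rbind, lapply(unlist(tests), function(p) {
        r <- be_ratio(totals, p, ref, seed = config$seed,
                      ci_method = if (config$ci_method == "logt") "logt" else "bootstrap",
                      scale = if (config$ci_method == "logt") "log" else "raw")
        summary(r)
      }))
      utils::write.csv(tab3, file.path(config$output_dir, "be_assessment.csv"),
                       row.names = FALSE)
      md <- c(md, "Bioequivalence assessment:", "",
              "| test | reference | ratio | 90% CI | verdict |", "|---|---|---|---|---|",
              sprintf("| %s | %s | %.3f | [%.3f, %.3f] | %s |", tab3$test,
                      tab3$reference, tab3$ratio, tab3$ci_low, tab3$ci_high,
                      tab3$verdict))
      list(phase_summary = tab2, assessment = tab3)
    })
  cfg_tmp <- tempfile(fileext = ".json")
  jsonlite::write_json(unclass(config), cfg_tmp, auto_unbox = TRUE, null = "null")
  md <- c(md, "", "---",
          sprintf("provenance: dpkfit %s | seed %s | config sha %s",
                  as.character(utils::packageVersion("dpkfit")),
                  config$seed, unname(tools::md5sum(cfg_tmp))))
  unlink(cfg_tmp)
  writeLines(md, file.path(config$output_dir, "report.md"))
  invisible(res)
}
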
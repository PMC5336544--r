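Package: dpkfit
Title: Dermatopharmacokinetic Analysis of Topical Drug Products
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the dermatopharmacokinetic (DPK) assessment of topical
    drug products. Implements the closed-form series solution of Fick's second
    law for drug uptake into the stratum corneum (SC) from a constant-activity
    vehicle, nonlinear least-squares fitting of tape-strip concentration-depth
    profiles to recover the SC-vehicle partition coefficient K and the
    diffusivity parameter D/L^2 (with derived permeability coefficient,
    steady-state flux, lag time and 6-h uptake), SC thickness estimation by
    inverse extrapolation of transepidermal water loss (TEWL) against
    cumulative SC removed, in vitro release test (IVRT) cumulative-release
    bookkeeping with sampling-replacement correction and square-root-of-time
    (Higuchi) release kinetics, and average-bioequivalence assessment of
    test versus reference products (ratio of combined uptake + clearance
    means with 90% confidence intervals against the 0.8-1.25 limits).
    A synthetic-data module generates complete virtual tape-stripping, TEWL,
    clearance and IVRT experiments with known ground truth so that every
    stage of the pipeline can be validated by simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    graphics,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
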
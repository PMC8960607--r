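#' Degradation parameters for one scaffold-degradation modality
#'
#' Rates follow the study's convention: volume-fraction erosion rates `k_N`
#' are stored as fraction of element volume per day (a table entry of
#' "4%/day" is stored as 0.04), modulus rates `k_E` in MPa/day, exponential
#' rates `k_e` in 1/day. For autocatalytic bulk degradation, elements in the
#' strut bulk degrade at `bulk_multiplier` times the surface rates.
#' Erosion of bulk-degrading scaffolds starts when the material modulus
#' falls to `onset_fraction` of its initial value (the 10%-of-initial-
#' molecular-weight rule, with modulus proportional to molecular weight).
#'
#' @param modality one of `"surface_erosion"`, `"bulk"`,
#'   `"bulk_autocatalytic"`, `"exponential"`.
#' @param k_N volume-fraction erosion rate (fraction/day).
#' @param k_E linear modulus degradation rate (MPa/day).
#' @param k_e exponential modulus degradation rate (1/day).
#' @param E0 initial scaffold material modulus (MPa).
#' @param N0 initial scaffold volume fraction of a strut element.
#' @param bulk_multiplier autocatalytic acceleration of bulk elements.
#' @param onset_fraction modulus fraction at which erosion of bulk-degrading
#'   scaffolds begins.
#' @return object of class `degradation_params`.
#' @seealso [degradation_preset()] for the rate presets of the study.
#' @export
degradation_params <- function(modality = c("surface_erosion", "bulk",
                                            "bulk_autocatalytic",
                                            "exponential"),
                               k_N = 0, k_E = 0, k_e = 0,
                               E0 = 1000, N0 = 0.5,
                               bulk_multiplier = 2, onset_fraction = 0.1) {
  modality <- match.arg(modality)
  if (any(c(k_N, k_E, k_e) < 0)) stop("degradation rates must be >= 0")
  if (onset_fraction <= 0 || onset_fraction >= 1)
    stop("onset_fraction must lie in (0, 1)")
  structure(
    list(modality = modality, k_N = k_N, k_E = k_E, k_e = k_e,
         E0 = E0, N0 = N0, bulk_multiplier = bulk_multiplier,
         onset_fraction = onset_fraction),
    class = "degradation_params"
  )
}

#' @export
print.degradation_params <- function(x, ...) {
  cat(sprintf(
    "<degradation_params> %s: k_N = %g/day, k_E = %g MPa/day, k_e = %g/day\n",
    x$modality, x$k_N, x$k_E, x$k_e))
  invisible(x)
}

#' Degradation-rate presets of the study
#'
#' The linear modalities come in three speeds, calibrated so that complete
#' scaffold degradation takes 25 (fast), 50 (matched, equal to the expected
#' repair time) or 100 (slow) days. The exponential modality uses the
#' experimentally derived rates: `slow` models porous PCL/PDLLA scaffolds
#' (k_e = 0.003/day, erosion onset beyond two years) and `fast` porous PLGA
#' (k_e = 0.022/day, k_N = 5%/day, complete degradation at day 115).
#'
#' @param modality degradation modality (see [degradation_params()]).
#' @param speed `"fast"`, `"matched"` or `"slow"` (`"matched"` is undefined
#'   for the exponential modality).
#' @return a [degradation_params()] object.
#' @export
degradation_preset <- function(modality = c("surface_erosion", "bulk",
                                            "bulk_autocatalytic",
                                            "exponential"),
                               speed = c("fast", "matched", "slow")) {
  modality <- match.arg(modality)
  speed <- match.arg(speed)
  if (modality == "exponential") {
    if (speed == "matched")
      stop("the exponential modality has only 'fast' and 'slow' presets")
    return(switch(speed,
      fast = degradation_params("exponential", k_e = 0.022, k_N = 0.05),
      slow = degradation_params("exponential", k_e = 0.003, k_N = 0.05)))
  }
  idx <- match(speed, c("fast", "matched", "slow"))
  if (modality == "surface_erosion")
    return(degradation_params("surface_erosion",
                              k_N = c(0.04, 0.02, 0.01)[idx]))
  degradation_params(modality,
                     k_E = c(40, 20, 10)[idx],
                     k_N = c(0.20, 0.10, 0.05)[idx])
}

#' Run configuration for the repair simulation
#'
#' Collects geometry, loading, mechanoregulation and cell-rule constants.
#' Defaults reproduce the study conditions: a 0.637 MPa pressure applied as
#' a 1 s compression ramp followed by a 0.5 s consolidation step; stimulus
#' constants a = 3.75% and b = 3e-3 mm/s; an element cell capacity of 100;
#' differentiation 5%, tissue mitosis 5%, apoptosis 15%, MSC mitosis 15%
#' and bone resorption 10% per day; and a 125-day run.
#'
#' @param total_days number of daily iterations.
#' @param load_pressure applied pressure (MPa).
#' @param compression_duration,consolidation_duration load-step durations (s).
#' @param cell_cap maximum cells per lattice element.
#' @param a stimulus strain constant (%).
#' @param b stimulus fluid-speed constant (mm/s).
#' @param rates named list of daily cell rates.
#' @param n_rows,n_cols,element_size,radius,depth lattice geometry
#'   (see [defect_lattice()]).
#' @param strut_center_radii,strut_thickness scaffold geometry
#'   (see [scaffold_layout()]).
#' @param K0 reference initial scaffold stiffness (N/mm).
#' @param delta_x compressive strain applied in the standalone stiffness
#'   evaluation (fraction).
#' @param fe finite-element stage controls: `fe_factor` (lattice elements
#'   per FE element edge in the defect), `outer_radius`, `total_height`,
#'   `cartilage_thickness`, `subchondral_thickness`, `meniscus_thickness`
#'   (mm, 0 removes the meniscus layer and supports the articular surface
#'   directly), `coarse_spacing` (mm), `n_compression_steps`,
#'   `n_consolidation_steps`.
#' @param failure failure-surrogate controls: `gamma_cap` (octahedral shear
#'   strain, fraction), `buckle_max_cols` (maximum width, in lattice
#'   columns, of a load-bearing strut wall checked against Euler buckling),
#'   `effective_length_factor` (buckling effective length of a freed wall,
#'   as a multiple of the strut height).
#' @param rng_seed optional integer seed, reserved for perturbation studies;
#'   the core daily loop is deterministic.
#' @return object of class `run_config`.
#' @export
run_config <- function(total_days = 125L,
                       load_pressure = 0.637,
                       compression_duration = 1.0,
                       consolidation_duration = 0.5,
                       cell_cap = 100,
                       a = 3.75, b = 3e-3,
                       rates = list(differentiation = 0.05,
                                    tissue_mitosis = 0.05,
                                    apoptosis = 0.15,
                                    msc_mitosis = 0.15,
                                    resorption = 0.10),
                       n_rows = 40L, n_cols = 40L, element_size = 0.125,
                       radius = 5, depth = 5,
                       strut_center_radii = c(1.25, 2.5, 3.75),
                       strut_thickness = 0.5,
                       K0 = 2445, delta_x = 0.03,
                       fe = list(),
                       failure = list(),
                       rng_seed = NULL) {
  stopifnot(all(unlist(rates) >= 0), all(unlist(rates) <= 1))
  fe_defaults <- list(fe_factor = 4L, outer_radius = 10, total_height = 10,
                      cartilage_thickness = 2, subchondral_thickness = 3,
                      meniscus_thickness = 1.5, coarse_spacing = 0.625,
                      n_compression_steps = 5L, n_consolidation_steps = 5L)
  failure_defaults <- list(gamma_cap = 1.0, buckle_max_cols = 1L,
                           effective_length_factor = 2)
  fe <- utils::modifyList(fe_defaults, fe)
  failure <- utils::modifyList(failure_defaults, failure)
  structure(
    list(total_days = as.integer(total_days),
         load_pressure = load_pressure,
         compression_duration = compression_duration,
         consolidation_duration = consolidation_duration,
         cell_cap = cell_cap, a = a, b = b, rates = rates,
         n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         element_size = element_size, radius = radius, depth = depth,
         strut_center_radii = strut_center_radii,
         strut_thickness = strut_thickness,
         K0 = K0, delta_x = delta_x,
         fe = fe, failure = failure, rng_seed = rng_seed),
    class = "run_config"
  )
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf(
    "<run_config> %d days, %g MPa load, %dx%d lattice, fe_factor %d\n",
    x$total_days, x$load_pressure, x$n_rows, x$n_cols, x$fe$fe_factor))
  invisible(x)
}

#' Read a run configuration and degradation parameters from a YAML file
#'
#' The file may contain top-level sections `geometry`, `mechanics`, `cells`,
#' `run` (merged into [run_config()] arguments) and `degradation` (either
#' `modality` plus `speed` naming a preset, or explicit rate fields for
#' [degradation_params()]). Every default is overridable; omitted sections
#' fall back to the study defaults.
#'
#' @param path path to a YAML file.
#' @return list with elements `config` ([run_config()]) and `params`
#'   ([degradation_params()], or `NULL` if no degradation section given).
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("geometry", "mechanics", "cells", "run", "degradation")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown configuration section(s): ", paste(unknown, collapse = ", "))
  args <- c(raw$geometry, raw$mechanics, raw$cells, raw$run)
  args <- args[names(args) != ""]
  config <- do.call(run_config, args)
  params <- NULL
  d <- raw$degradation
  if (!is.null(d)) {
    params <- if (!is.null(d$speed)) {
      degradation_preset(d$modality, d$speed)
    } else {
      do.call(degradation_params, d)
    }
  }
  list(config = config, params = params)
}
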
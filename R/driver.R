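#' Failure surrogate for the degrading scaffold
#'
#' The reference model flags mechanical failure when the finite-element
#' analysis stops converging because of excessive deformation of scaffold
#' elements; convergence behaviour is solver-specific, so this simulator
#' uses an explicit surrogate with configurable thresholds:
#' \itemize{
#' \item excessive strain: any element still holding scaffold material
#'   exceeds the octahedral shear strain cap (`failure$gamma_cap`,
#'   default 100%);
#' \item thin-wall buckling: degradation has reduced a strut's load-bearing
#'   cross-section to a contiguous wall of at most `failure$buckle_max_cols`
#'   lattice columns (autocatalysis hollows the struts into two
#'   single-column walls) and the wall's mean axial strain exceeds the Euler
#'   critical strain `pi^2 t^2 / (12 (kL)^2)` of a plate column of thickness
#'   t and height L with effective length factor k
#'   (`failure$effective_length_factor`, default 2: the freed wall is
#'   restrained at the defect base but laterally braced only by compliant
#'   granulation tissue above, i.e. a sway column).
#' }
#' Solver divergence is caught separately by the driver.
#'
#' @param state a [scaffold_state()].
#' @param stimulus a stimulus field from [extract_stimulus()].
#' @param config a [run_config()].
#' @return `NULL`, or a list with `cause` describing the failure.
#' @export
detect_failure <- function(state, stimulus, config) {
  layout <- state$layout
  lat <- layout$lattice
  h <- lat$element_size
  L <- layout$strut_height
  # excessive strain in scaffold-bearing elements
  for (k in seq_along(state$col)) {
    if (state$N[k] <= 0) next
    idx <- which(lat$col == state$col[k])
    if (any(stimulus$gamma_pct[idx] / 100 > config$failure$gamma_cap))
      return(list(cause = "excessive scaffold element strain"))
  }
  # thin-wall Euler buckling of freed strut walls
  for (s in seq_len(layout$n_struts)) {
    cols <- sort(state$col[state$strut == s & state$N > 0])
    if (!length(cols)) next
    grp <- cumsum(c(1L, diff(cols) != 1L))
    for (g in unique(grp)) {
      gc <- cols[grp == g]
      if (length(gc) > config$failure$buckle_max_cols) next
      t_wall <- length(gc) * h
      kL <- config$failure$effective_length_factor * L
      eps_cr <- pi^2 * t_wall^2 / (12 * kL^2)
      idx <- which(lat$col %in% gc)
      if (mean(abs(stimulus$eps_zz[idx])) > eps_cr)
        return(list(cause = "thin strut wall buckling"))
    }
  }
  NULL
}

#' Run the iterative repair simulation
#'
#' Executes the daily loop: poroelastic finite-element solve of the
#' compression/consolidation load case, stimulus extraction and tissue
#' classification, failure check, MSC diffusion and population update,
#' scaffold degradation step, and property homogenisation feeding the next
#' day. One iteration corresponds to one day; the loop is deterministic
#' given the configuration. The run stops at `total_days` or at the first
#' detected mechanical failure.
#'
#' @param config a [run_config()].
#' @param params a [degradation_params()].
#' @param verbose print a one-line summary per day.
#' @return object of class `simulation_result` with per-day `records`
#'   (stiffness in N/mm, mean scaffold material modulus in MPa, scaffold
#'   volume fraction as % of the defect, tissue-class area fractions in %,
#'   total cells per phenotype), the `failure` entry (`NULL` or
#'   `list(day, cause)`), the analytic `milestones` report, the final
#'   fields, and the configuration echo.
#' @export
run_simulation <- function(config, params, verbose = FALSE) {
  lattice <- defect_lattice(config$n_rows, config$n_cols,
                            config$element_size, config$radius,
                            config$depth, config$fe$cartilage_thickness)
  layout <- scaffold_layout(lattice, config$strut_center_radii,
                            config$strut_thickness)
  tt <- load_tissue_table()
  state <- scaffold_state(layout, params)
  cells <- init_cells(lattice, config, scaffold_field(state)$N)
  mesh <- condyle_mesh(config, lattice)
  smodel <- stiffness_model(layout, config$K0, config$delta_x)

  n_days <- config$total_days
  rec <- data.frame(
    day = seq_len(n_days), stiffness = NA_real_, mean_E = NA_real_,
    scaffold_volume_fraction_pct = NA_real_,
    resorption_pct = NA_real_, bone_pct = NA_real_, cartilage_pct = NA_real_,
    fibrous_pct = NA_real_, msc = NA_real_, osteoblast = NA_real_,
    chondrocyte = NA_real_, fibroblast = NA_real_)
  failure <- NULL
  stim <- NULL
  props <- NULL
  last_day <- 0L
  for (d in seq_len(n_days)) {
    sf <- scaffold_field(state)
    props <- homogenize(cells, sf$N, config, tt)
    system <- assemble_poroelastic_system(mesh, fe_properties(mesh, props, tt))
    fields <- tryCatch(solve_load_case(system, config),
                       strutsim_mechanical_failure = function(e) e)
    if (inherits(fields, "strutsim_mechanical_failure")) {
      failure <- list(day = d, cause = conditionMessage(fields))
      last_day <- d
      break
    }
    stim <- extract_stimulus(fields, mesh, config)
    fail <- detect_failure(state, stim, config)
    if (!is.null(fail)) {
      failure <- list(day = d, cause = fail$cause)
      rec[d, -1] <- day_record(state, stim, cells, smodel, lattice)
      last_day <- d
      break
    }
    cap <- effective_capacity(config$cell_cap, sf$N)
    cells <- diffuse_msc(cells, props$cell_diffusivity, lattice, config, cap)
    cells <- update_populations(cells, stim$tissue_class, config, cap)
    state <- degrade_step(state)
    rec[d, -1] <- day_record(state, stim, cells, smodel, lattice)
    last_day <- d
    if (verbose)
      message(sprintf(
        "day=%d stiffness=%.0f mean_E=%.0f bone=%.1f cartilage=%.1f fibrous=%.1f",
        d, rec$stiffness[d], rec$mean_E[d], rec$bone_pct[d],
        rec$cartilage_pct[d], rec$fibrous_pct[d]))
  }
  rec <- rec[seq_len(last_day), , drop = FALSE]
  structure(
    list(records = rec, failure = failure,
         milestones = milestones(params, layout),
         final = list(cells = cells, scaffold = state, stimulus = stim,
                      lattice_props = props),
         config = config, params = params, lattice = lattice,
         layout = layout),
    class = "simulation_result")
}

day_record <- function(state, stim, cells, smodel, lattice) {
  frac <- classify_repair_map(stim)$area_fraction_pct
  c(scaffold_stiffness(state, smodel),
    mean(state$E),
    sum(state$N * lattice$n_rows) / lattice$n_elements * 100,
    frac[["resorption"]], frac[["bone"]], frac[["cartilage"]],
    frac[["fibrous"]],
    sum(cells$msc), sum(cells$osteoblast), sum(cells$chondrocyte),
    sum(cells$fibroblast))
}

#' @export
print.simulation_result <- function(x, ...) {
  n <- nrow(x$records)
  cat(sprintf("<simulation_result> %d day(s), modality %s\n",
              n, x$params$modality))
  if (!is.null(x$failure)) {
    cat(sprintf("  mechanical failure at day %d: %s\n",
                x$failure$day, x$failure$cause))
  } else if (n) {
    last <- x$records[n, ]
    cat(sprintf(
      "  day %d: K = %.0f N/mm, classes (R/B/C/F) = %.1f/%.1f/%.1f/%.1f %%\n",
      last$day, last$stiffness, last$resorption_pct, last$bone_pct,
      last$cartilage_pct, last$fibrous_pct))
  }
  invisible(x)
}

#' Reference run setups
#'
#' `make_fixture("full")` returns the study configuration (40 x 40 lattice,
#' three 0.5 mm struts, 125 days). `make_fixture("small")` returns a reduced
#' setup for fast tests: an 8 x 8 defect lattice (0.625 mm elements), one
#' two-column strut, a 5-day horizon and rates scaled so every stage of the
#' pipeline is exercised within seconds.
#'
#' @param scale `"full"` or `"small"`.
#' @return list with `config`, `lattice`, `layout` and (for `"small"`) a
#'   matching fast `params`; for `"full"`, `params` is `NULL` and a
#'   degradation preset should be chosen explicitly.
#' @export
make_fixture <- function(scale = c("small", "full")) {
  scale <- match.arg(scale)
  if (scale == "full") {
    config <- run_config()
    lattice <- defect_lattice()
    layout <- scaffold_layout(lattice)
    return(list(config = config, lattice = lattice, layout = layout,
                params = NULL))
  }
  config <- run_config(
    total_days = 5L, n_rows = 8L, n_cols = 8L, element_size = 0.625,
    strut_center_radii = 2.5, strut_thickness = 1.25,
    fe = list(fe_factor = 1L, coarse_spacing = 1.25,
              cartilage_thickness = 2.5, subchondral_thickness = 2.5))
  lattice <- defect_lattice(8L, 8L, 0.625, 5, 5, 2.5)
  layout <- scaffold_layout(lattice, 2.5, 1.25)
  # consistent fast rates: modulus and volume fraction vanish together on day 5
  params <- degradation_params("bulk", k_E = 200, k_N = 1)
  list(config = config, lattice = lattice, layout = layout, params = params)
}
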
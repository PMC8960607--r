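#' Axisymmetric condyle mesh around the osteochondral defect
#'
#' Builds a structured quadrilateral mesh of a simplified femoral condyle:
#' the defect region (radius x depth, resolved with `fe_factor` lattice
#' elements per FE element edge so the defect sub-mesh maps exactly onto the
#' cell lattice) surrounded by healthy tissue meshed at the coarse spacing.
#' Global coordinates put the articular surface at z = 0; below it lies a
#' meniscus layer (transversely isotropic, `meniscus_thickness` mm) whose
#' lower face rests on the rigid tibial plateau, replaced by a fixed
#' vertical support (the hard frictionless contacts of the reference
#' geometry are approximated as bonded interfaces). The loaded top cut of
#' the cancellous bone sits at `z = total_height`.
#' Outside the defect the material is layered: hyperelastic (linearised)
#' cartilage up to `cartilage_thickness`, subchondral bone up to
#' `cartilage_thickness + subchondral_thickness`, cancellous bone above.
#' Drainage (zero pore pressure during consolidation) acts on the free
#' cartilage edge at the outer boundary.
#'
#' @param config a [run_config()].
#' @param lattice the [defect_lattice()] of the same configuration.
#' @return object of class `condyle_mesh`, carrying the grid, precomputed
#'   element kernels, boundary sets, per-element material labels and the
#'   two-way defect/lattice element maps.
#' @export
condyle_mesh <- function(config, lattice = defect_lattice(
                           config$n_rows, config$n_cols,
                           config$element_size, config$radius,
                           config$depth, config$fe$cartilage_thickness)) {
  f <- config$fe$fe_factor
  if (config$n_cols %% f != 0L || config$n_rows %% f != 0L)
    stop("fe_factor must divide the lattice dimensions")
  h <- config$element_size * f
  nd_r <- config$n_cols %/% f
  nd_z <- config$n_rows %/% f
  cs <- config$fe$coarse_spacing
  r_ext <- config$fe$outer_radius - config$radius
  z_ext <- config$fe$total_height - config$depth
  r_lines <- c(seq(0, config$radius, length.out = nd_r + 1L),
               seq(config$radius, config$fe$outer_radius,
                   length.out = max(1L, ceiling(r_ext / cs)) + 1L)[-1])
  tm <- config$fe$meniscus_thickness
  men_lines <- if (tm > 0) {
    ml <- seq(-tm, 0, length.out = max(1L, ceiling(tm / cs)) + 1L)
    ml[-length(ml)]
  } else numeric(0)
  z_lines <- c(men_lines,
               seq(0, config$depth, length.out = nd_z + 1L),
               seq(config$depth, config$fe$total_height,
                   length.out = max(1L, ceiling(z_ext / cs)) + 1L)[-1])
  grid <- poro_grid(r_lines, z_lines)
  el <- grid$elements
  zc1 <- config$fe$cartilage_thickness
  zc2 <- zc1 + config$fe$subchondral_thickness
  material <- ifelse(el$zc < 0, "meniscus",
              ifelse(el$rc < config$radius & el$zc < config$depth, "defect",
              ifelse(el$zc < zc1, "hyperelastic cartilage",
              ifelse(el$zc < zc2, "subchondral bone", "cancellous bone"))))
  # defect element indices within the FE grid (row 1 = defect base)
  defect <- which(material == "defect")
  fe_col <- el$i[defect]
  fe_row <- nd_z - as.integer(round(el$zc[defect] / h + 0.5)) + 1L
  defect_id <- integer(grid$nel)
  defect_id[defect] <- seq_along(defect)
  # lattice element -> FE element
  lat_fe_col <- (lattice$col - 1L) %/% f + 1L
  lat_fe_row <- (lattice$row - 1L) %/% f + 1L
  fe_lookup <- matrix(0L, nd_z, nd_r)
  fe_lookup[cbind(fe_row, fe_col)] <- defect
  lattice_to_fe <- fe_lookup[cbind(lat_fe_row, lat_fe_col)]

  kern <- poro_kernels(grid)
  mesh <- structure(
    list(grid = grid, kernels = kern,
         material = material, defect_elements = defect,
         lattice_to_fe = lattice_to_fe, lattice = lattice,
         bc = list(fix_all_radial = FALSE, fix_outer_radial = FALSE,
                   drain_p_nodes = condyle_drain_nodes(grid, config))),
    class = c("condyle_mesh", "poro_mesh"))
  mesh$ops <- centre_operators(grid, kern)
  mesh
}

condyle_drain_nodes <- function(grid, config) {
  # pressure nodes on the outer boundary within the cartilage layer
  zc1 <- config$fe$cartilage_thickness
  z_nodes <- grid$z_lines
  outer_col <- grid$np_r
  rows <- which(z_nodes >= -1e-9 & z_nodes <= zc1 + 1e-9)
  (rows - 1L) * grid$np_r + outer_col
}

#' @export
print.poro_mesh <- function(x, ...) {
  cat(sprintf("<%s> %d x %d elements, %d displacement dofs, %d pressure nodes\n",
              class(x)[1], x$grid$nr, x$grid$nz, x$grid$n_u_dofs,
              x$grid$n_p_nodes))
  invisible(x)
}

#' Uniaxial column mesh for solver verification
#'
#' A confined axisymmetric column (radial displacement fixed everywhere,
#' vertical support at the base, pressure load on top, drainage at the top
#' surface). Used as the geometry for oedometer and one-dimensional
#' consolidation benchmarks of the poroelastic solver.
#'
#' @param height column height (mm).
#' @param n_z number of elements along the height.
#' @param radius column radius (mm).
#' @param n_r number of elements across the radius.
#' @return object of class `column_mesh`.
#' @export
column_mesh <- function(height = 1, n_z = 16L, radius = 0.2, n_r = 1L) {
  grid <- poro_grid(seq(0, radius, length.out = n_r + 1L),
                    seq(0, height, length.out = n_z + 1L))
  kern <- poro_kernels(grid)
  top_nodes <- (grid$np_z - 1L) * grid$np_r + seq_len(grid$np_r)
  mesh <- structure(
    list(grid = grid, kernels = kern,
         material = rep("uniform", grid$nel),
         bc = list(fix_all_radial = TRUE, fix_outer_radial = FALSE,
                   drain_p_nodes = top_nodes)),
    class = c("column_mesh", "poro_mesh"))
  mesh$ops <- centre_operators(grid, kern)
  mesh
}

#' Per-FE-element material properties for the condyle mesh
#'
#' Healthy-tissue elements take their constants from the tissue table
#' (healthy cartilage uses the small-strain linearisation of its
#' neo-Hookean constants); defect elements average the homogenised
#' per-lattice-element properties of the lattice cells they cover.
#'
#' @param mesh a [condyle_mesh()].
#' @param lattice_props data frame of homogenised properties per lattice
#'   element (see [homogenize()]).
#' @param tissue_table a [load_tissue_table()] result.
#' @return data frame with one row per FE element: `E`, `nu`,
#'   `permeability`, `void_ratio`, `grain_bulk_modulus`.
#' @export
fe_properties <- function(mesh, lattice_props,
                          tissue_table = load_tissue_table()) {
  nel <- mesh$grid$nel
  out <- data.frame(E = numeric(nel), nu = numeric(nel),
                    permeability = numeric(nel), void_ratio = numeric(nel),
                    grain_bulk_modulus = numeric(nel))
  ti <- vector("list", nel)
  for (m in setdiff(unique(mesh$material), "defect")) {
    tp <- tissue_table[[m]]
    idx <- mesh$material == m
    out$E[idx] <- tp$elastic_modulus
    out$nu[idx] <- tp$poisson_ratio
    out$permeability[idx] <- tp$permeability
    out$void_ratio[idx] <- tp$void_ratio
    out$grain_bulk_modulus[idx] <- tp$grain_bulk_modulus
    if (tp$is_transversely_isotropic)
      ti[which(idx)] <- list(tp$transversely_isotropic)
  }
  out$ti <- ti
  fe_of <- mesh$lattice_to_fe
  for (ch in c("elastic_modulus", "poisson_ratio", "permeability",
               "void_ratio", "grain_bulk_modulus")) {
    agg <- tapply(lattice_props[[ch]], fe_of, mean)
    col <- c(elastic_modulus = "E", poisson_ratio = "nu",
             permeability = "permeability", void_ratio = "void_ratio",
             grain_bulk_modulus = "grain_bulk_modulus")[[ch]]
    out[[col]][as.integer(names(agg))] <- as.numeric(agg)
  }
  out
}

#' Map per-element stimulus inputs from the FE mesh to the lattice
#'
#' Each lattice element inherits the octahedral shear strain and fluid
#' speed of the FE element covering it, the strain is expressed in percent,
#' and the mechanoregulatory stimulus `S = gamma/a + v/b` is evaluated and
#' classified into the tissue-formation classes.
#'
#' @param fields result of [solve_load_case()].
#' @param mesh the [condyle_mesh()] used for the solve.
#' @param config a [run_config()].
#' @return data frame (class `stimulus_field`) with one row per lattice
#'   element: `gamma_pct`, `v` (mm/s), `S`, `tissue_class`, `eps_zz`.
#' @export
extract_stimulus <- function(fields, mesh, config) {
  fe_of <- mesh$lattice_to_fe
  gamma <- fields$gamma[fe_of]
  v <- fields$v[fe_of]
  S <- gamma * 100 / config$a + v / config$b
  out <- data.frame(gamma_pct = gamma * 100, v = v, S = S,
                    tissue_class = stimulus_class(S),
                    eps_zz = fields$eps_zz[fe_of])
  class(out) <- c("stimulus_field", class(out))
  out
}
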
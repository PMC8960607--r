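#' Properties of a single tissue or material
#'
#' Constructs the per-material constant set used by the poroelastic stage and
#' the property homogenisation rule. Units follow the conventions of the
#' simulator: moduli in MPa, permeability as hydraulic conductivity in mm/s,
#' cell diffusivity in mm^2/day.
#'
#' @param name material label.
#' @param elastic_modulus drained elastic modulus (MPa).
#' @param poisson_ratio drained Poisson ratio, in (-1, 0.5].
#' @param permeability hydraulic conductivity (mm/s).
#' @param void_ratio pore volume over solid volume (dimensionless).
#' @param grain_bulk_modulus bulk modulus of the solid grains (MPa); 0 is
#'   read as "incompressible grains".
#' @param cell_diffusivity diffusion coefficient of migrating cells
#'   (mm^2/day).
#' @param transversely_isotropic optional named list with directional
#'   constants `E1,E2,E3` (MPa, 1 = axial, 2 = radial, 3 = circumferential),
#'   `nu12,nu23,nu31` and `G12,G23,G31` (MPa).
#' @param hyperelastic optional named list with neo-Hookean constants
#'   `C10` (MPa) and `D1`; `D1` is interpreted with the convention that the
#'   initial bulk modulus is `2/D1`.
#' @return an object of class `tissue_properties`.
#' @export
tissue_properties <- function(name, elastic_modulus, poisson_ratio,
                              permeability, void_ratio, grain_bulk_modulus,
                              cell_diffusivity,
                              transversely_isotropic = NULL,
                              hyperelastic = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  if (elastic_modulus < 0) stop("elastic modulus must be >= 0")
  if (poisson_ratio <= -1 || poisson_ratio > 0.5)
    stop("poisson ratio must lie in (-1, 0.5]")
  if (permeability < 0) stop("permeability must be >= 0")
  structure(
    list(
      name = name,
      elastic_modulus = elastic_modulus,
      poisson_ratio = poisson_ratio,
      permeability = permeability,
      void_ratio = void_ratio,
      grain_bulk_modulus = grain_bulk_modulus,
      cell_diffusivity = cell_diffusivity,
      is_transversely_isotropic = !is.null(transversely_isotropic),
      transversely_isotropic = transversely_isotropic,
      is_hyperelastic = !is.null(hyperelastic),
      hyperelastic = hyperelastic
    ),
    class = "tissue_properties"
  )
}

#' @export
print.tissue_properties <- function(x, ...) {
  cat(sprintf("<tissue_properties> %s: E = %g MPa, nu = %g, k = %g mm/s\n",
              x$name, x$elastic_modulus, x$poisson_ratio, x$permeability))
  invisible(x)
}

# Specific weight of the wetting liquid (N/mm^3) and bulk modulus of the
# pore fluid (MPa), shared by all poroelastic tissues.
fluid_constants <- function() {
  list(specific_weight = 9.74e-6, bulk_modulus = 2300)
}

#' Table of biological tissue and scaffold material properties
#'
#' Returns the per-material constants for all tissues represented in the
#' condyle model: the poroelastic tissues of the defect and surrounding bone,
#' the transversely isotropic meniscus, the hyperelastic healthy cartilage,
#' and the porous scaffold material (50% porosity, 1,000 MPa material
#' modulus). Cell diffusivities drive mesenchymal stromal cell migration;
#' granulation tissue is the fastest medium (0.8 mm^2/day) and the scaffold
#' material the slowest (0.01 mm^2/day).
#'
#' @return named list of [tissue_properties()] objects, keyed by label:
#'   `"subchondral bone"`, `"cancellous bone"`, `"poroelastic cartilage"`,
#'   `"fibrous tissue"`, `"granulation tissue"`, `"meniscus"`,
#'   `"hyperelastic cartilage"`, `"scaffold material"`.
#' @export
load_tissue_table <- function() {
  tt <- list(
    tissue_properties("subchondral bone",
      elastic_modulus = 17000, poisson_ratio = 0.3,
      permeability = 9.74e-11, void_ratio = 0.042,
      grain_bulk_modulus = 13920, cell_diffusivity = 0.01),
    tissue_properties("cancellous bone",
      elastic_modulus = 6000, poisson_ratio = 0.3,
      permeability = 3.63e-8, void_ratio = 4,
      grain_bulk_modulus = 13920, cell_diffusivity = 0.01),
    tissue_properties("poroelastic cartilage",
      elastic_modulus = 10, poisson_ratio = 0.167,
      permeability = 4.87e-8, void_ratio = 4,
      grain_bulk_modulus = 3700, cell_diffusivity = 0.05),
    tissue_properties("fibrous tissue",
      elastic_modulus = 2, poisson_ratio = 0.167,
      permeability = 9.74e-8, void_ratio = 4,
      grain_bulk_modulus = 2300, cell_diffusivity = 0.10),
    tissue_properties("granulation tissue",
      elastic_modulus = 0.2, poisson_ratio = 0.167,
      permeability = 9.74e-8, void_ratio = 4,
      grain_bulk_modulus = 2300, cell_diffusivity = 0.80),
    tissue_properties("meniscus",
      elastic_modulus = 0.5, poisson_ratio = 0.5,
      permeability = 4.87e-8, void_ratio = 4,
      grain_bulk_modulus = 3700, cell_diffusivity = 0,
      transversely_isotropic = list(
        E1 = 0.5, E2 = 0.5, E3 = 100,
        nu12 = 0.5, nu23 = 0.0015, nu31 = 0.0015,
        G12 = 0.167, G23 = 0.05, G31 = 0.05)),
    tissue_properties("hyperelastic cartilage",
      elastic_modulus = hyperelastic_linearised(2.14, 0.399)$E,
      poisson_ratio = hyperelastic_linearised(2.14, 0.399)$nu,
      permeability = 4.87e-8, void_ratio = 4,
      grain_bulk_modulus = 3700, cell_diffusivity = 0,
      hyperelastic = list(C10 = 2.14, D1 = 0.399)),
    tissue_properties("scaffold material",
      elastic_modulus = 1000, poisson_ratio = 0.3,
      permeability = 3.63e-8, void_ratio = 4,
      grain_bulk_modulus = 0, cell_diffusivity = 0.01)
  )
  stats::setNames(tt, vapply(tt, `[[`, "", "name"))
}

#' Small-strain linearisation of a neo-Hookean solid
#'
#' The neo-Hookean constants are mapped to equivalent small-strain elastic
#' constants about the undeformed state: shear modulus `mu = 2 C10` and bulk
#' modulus `K = 2 / D1`. For the healthy-cartilage constants (C10 = 2.14 MPa,
#' D1 = 0.399) this yields E of about 10 MPa and nu of about 0.168, matching
#' the poroelastic cartilage constants used for newly formed cartilage.
#'
#' @param C10,D1 neo-Hookean material constants.
#' @return list with elements `E`, `nu`, `mu`, `K`.
#' @export
hyperelastic_linearised <- function(C10, D1) {
  mu <- 2 * C10
  K <- 2 / D1
  E <- 9 * mu * K / (3 * K + mu)
  nu <- (3 * K - 2 * mu) / (2 * (3 * K + mu))
  list(E = E, nu = nu, mu = mu, K = K)
}
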
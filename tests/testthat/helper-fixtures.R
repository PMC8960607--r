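# Shared fixtures and a cross-file cache for the expensive full-lattice runs,
# so driver regressions and the acceptance suite reuse the same simulations.

.run_cache <- new.env(parent = emptyenv())

cached_run <- function(modality, speed, config = run_config()) {
  key <- paste(modality, speed, config$total_days, config$n_rows, sep = "|")
  if (!exists(key, envir = .run_cache)) {
    res <- run_simulation(config, degradation_preset(modality, speed))
    assign(key, res, envir = .run_cache)
  }
  get(key, envir = .run_cache)
}

default_layout <- function() scaffold_layout(defect_lattice())

# small uniform-property poroelastic column system for solver checks
uniform_column_system <- function(n_z = 16L, E = 10, nu = 0, k = 1e-7,
                                  fluid_bulk = Inf) {
  mesh <- column_mesh(height = 1, n_z = n_z, radius = 0.2, n_r = 1L)
  props <- data.frame(E = E, nu = nu, permeability = k, void_ratio = 4,
                      grain_bulk_modulus = 0)[rep(1, mesh$grid$nel), ]
  assemble_poroelastic_system(mesh, props, fluid_bulk_modulus = fluid_bulk)
}

# classical single-drainage consolidation series solution: normalised excess
# pore pressure at depth fraction x below the drained surface, time factor Tv
terzaghi_series <- function(x, Tv, n_terms = 200) {
  m <- 0:n_terms
  vapply(x, function(xi)
    sum(4 / ((2 * m + 1) * pi) * sin((2 * m + 1) * pi * xi / 2) *
          exp(-((2 * m + 1) * pi / 2)^2 * Tv)), 0)
}
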
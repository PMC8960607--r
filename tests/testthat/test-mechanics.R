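test_that("octahedral shear strain matches the principal-strain definition", {
  # hydrostatic strain has no shear
  expect_equal(octahedral_shear_strain(c(0.01, 0.01, 0.01, 0)), 0)
  # uniaxial extension
  expect_equal(octahedral_shear_strain(c(0.01, 0, 0, 0)),
               (2 / 3) * sqrt(2) * 0.01, tolerance = 1e-12)
  # arbitrary states against an eigen-decomposition oracle
  set.seed(42)
  for (i in 1:25) {
    e <- stats::rnorm(4, sd = 0.02)
    tens <- matrix(c(e[1], e[4] / 2, 0,
                     e[4] / 2, e[2], 0,
                     0, 0, e[3]), 3, 3)
    ev <- eigen(tens, symmetric = TRUE, only.values = TRUE)$values
    oracle <- (2 / 3) * sqrt((ev[1] - ev[2])^2 + (ev[2] - ev[3])^2 +
                               (ev[3] - ev[1])^2)
    expect_equal(octahedral_shear_strain(e), oracle, tolerance = 1e-12)
  }
  # simple tensor shear eps_rz = s: eigenvalues +/- s
  s <- 0.01
  got <- octahedral_shear_strain(c(0, 0, 0, 2 * s))  # engineering gamma = 2s
  expect_equal(got, (2 / 3) * sqrt(6) * s, tolerance = 1e-12)
})

test_that("elasticity matrices are symmetric positive definite", {
  D <- strutsim:::d_matrix(10, 0.3)
  expect_equal(D, t(D))
  expect_true(all(eigen(D, symmetric = TRUE)$values > 0))
  ti <- load_tissue_table()[["meniscus"]]$transversely_isotropic
  Dt <- strutsim:::d_matrix(NA, NA, ti)
  expect_equal(Dt, t(Dt))
  expect_true(all(eigen(Dt, symmetric = TRUE)$values > 0))
  # transversely isotropic constants collapsing to isotropy
  E <- 7; nu <- 0.25; G <- E / (2 * (1 + nu))
  iso <- list(E1 = E, E2 = E, E3 = E, nu12 = nu, nu23 = nu, nu31 = nu,
              G12 = G, G23 = G, G31 = G)
  expect_equal(strutsim:::d_matrix(NA, NA, iso), strutsim:::d_matrix(E, nu),
               tolerance = 1e-12)
})

test_that("confined compression reproduces the oedometric solution", {
  # patch test: uniform strain field exact to near machine precision
  sys <- uniform_column_system(n_z = 4L, E = 10, nu = 0.3)
  p_app <- 0.5
  res <- poro_solve(sys, p_app, phases = list(
    list(duration = 1e12, n_steps = 2, load_start = 1, load_end = 1,
         drained = TRUE)))
  eps <- strutsim:::element_strains(sys, res$u)
  M <- 10 * (1 - 0.3) / ((1 + 0.3) * (1 - 2 * 0.3))
  expect_lt(max(abs(eps[2, ] + p_app / M)) / (p_app / M), 1e-8)
  expect_lt(max(abs(eps[c(1, 3, 4), ])), 1e-12)
  # single-element drained column: axial strain p / E_oedometric
  sys1 <- uniform_column_system(n_z = 1L, E = 4, nu = 0.167)
  res1 <- poro_solve(sys1, 0.2, phases = list(
    list(duration = 1e12, n_steps = 2, load_start = 1, load_end = 1,
         drained = TRUE)))
  eps1 <- strutsim:::element_strains(sys1, res1$u)
  M1 <- 4 * (1 - 0.167) / ((1 + 0.167) * (1 - 2 * 0.167))
  expect_equal(-eps1[2, 1], 0.2 / M1, tolerance = 1e-6)
})

test_that("zero load produces identically zero fields", {
  sys <- uniform_column_system(n_z = 4L)
  res <- poro_solve(sys, 0, phases = list(
    list(duration = 1, n_steps = 3, load_start = 0, load_end = 0,
         drained = FALSE),
    list(duration = 1, n_steps = 3, load_start = 0, load_end = 0,
         drained = TRUE)))
  expect_equal(max(abs(res$u)), 0)
  expect_equal(max(abs(res$p)), 0)
})

test_that("transient consolidation matches the Terzaghi series within 1%", {
  E <- 10; nu <- 0; k <- 1e-7; gw <- 9.74e-6
  sys <- uniform_column_system(n_z = 20L, E = E, nu = nu, k = k,
                               fluid_bulk = Inf)
  cv <- (k / gw) * E        # oedometric modulus = E at nu = 0
  p0 <- 0.5
  Tvs <- c(0.1, 0.3, 0.5)
  t_of <- function(Tv) Tv / cv
  phases <- list(
    list(duration = t_of(0.001), n_steps = 5, load_start = 1, load_end = 1,
         drained = TRUE),
    list(duration = t_of(0.099), n_steps = 60, load_start = 1, load_end = 1,
         drained = TRUE),
    list(duration = t_of(0.2), n_steps = 60, load_start = 1, load_end = 1,
         drained = TRUE),
    list(duration = t_of(0.2), n_steps = 60, load_start = 1, load_end = 1,
         drained = TRUE))
  res <- poro_solve(sys, p0, phases)
  grid <- sys$mesh$grid
  for (i in 1:3) {
    p_num <- res$phase_end[[i + 1]]$p[seq(1, grid$n_p_nodes, by = grid$np_r)]
    x <- 1 - grid$z_lines          # depth fraction below the drained top
    p_ref <- p0 * terzaghi_series(x, Tvs[i])
    expect_lt(max(abs(p_num - p_ref)) / p0, 0.01)
  }
})

test_that("the stimulus maps strain and fluid speed onto tissue classes", {
  cfg <- run_config()
  # gamma = 3.75%, v = 0 -> S = 1, the cartilage boundary is included
  S <- 3.75 / cfg$a + 0 / cfg$b
  expect_equal(S, 1)
  expect_equal(as.character(stimulus_class(S)), "cartilage")
  expect_equal(as.character(stimulus_class(0)), "resorption")
  S2 <- 7.5 / cfg$a + 0.003 / cfg$b
  expect_equal(S2, 3)
  expect_equal(as.character(stimulus_class(S2)), "fibrous")
})

test_that("every non-negative stimulus falls in exactly one class", {
  set.seed(7)
  S <- c(0, 0.01, 1, 3, 10^stats::runif(300, -4, 2))
  cls <- stimulus_class(S)
  expect_false(any(is.na(cls)))
  expect_setequal(levels(cls), c("resorption", "bone", "cartilage", "fibrous"))
  expect_error(stimulus_class(-0.1), "finite")
})

test_that("a stiffer defect fill does not increase the average shear strain", {
  fx <- make_fixture("small")
  mesh <- condyle_mesh(fx$config, fx$lattice)
  tt <- load_tissue_table()
  cells <- init_cells(fx$lattice, fx$config)
  base <- homogenize(cells, numeric(fx$lattice$n_elements), fx$config, tt)
  gamma_for <- function(props) {
    sys <- assemble_poroelastic_system(mesh, fe_properties(mesh, props, tt))
    mean(solve_load_case(sys, fx$config)$gamma[mesh$defect_elements])
  }
  g0 <- gamma_for(base)
  stiffer <- base
  stiffer$elastic_modulus <- base$elastic_modulus * 5
  g1 <- gamma_for(stiffer)
  much_stiffer <- base
  much_stiffer$elastic_modulus <- base$elastic_modulus * 50
  g2 <- gamma_for(much_stiffer)
  expect_lte(g1, g0)
  expect_lte(g2, g1)
})

test_that("the condyle mesh maps one-to-one onto the defect lattice", {
  cfg <- run_config()
  lat <- defect_lattice()
  mesh <- condyle_mesh(cfg, lat)
  f <- cfg$fe$fe_factor
  expect_equal(length(mesh$defect_elements),
               (cfg$n_rows / f) * (cfg$n_cols / f))
  expect_true(all(mesh$lattice_to_fe %in% mesh$defect_elements))
  # every defect FE element covers exactly f^2 lattice elements
  expect_true(all(table(mesh$lattice_to_fe) == f^2))
  # covered lattice elements lie inside their FE element's extent
  el <- mesh$grid$elements
  for (probe in c(1L, 820L, 1600L)) {
    fe <- mesh$lattice_to_fe[probe]
    expect_true(lat$r[probe] > el$r0[fe] && lat$r[probe] < el$r1[fe])
    z_glob <- lat$depth - lat$z[probe]
    expect_true(z_glob > el$z0[fe] && z_glob < el$z1[fe])
  }
  expect_setequal(unique(mesh$material),
                  c("defect", "meniscus", "hyperelastic cartilage",
                    "subchondral bone", "cancellous bone"))
})

test_that("assembly rejects non-positive moduli", {
  fx <- make_fixture("small")
  mesh <- condyle_mesh(fx$config, fx$lattice)
  tt <- load_tissue_table()
  props <- fe_properties(
    mesh, homogenize(init_cells(fx$lattice, fx$config),
                     numeric(fx$lattice$n_elements), fx$config, tt), tt)
  props$E[3] <- 0
  expect_error(assemble_poroelastic_system(mesh, props), "element")
})
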
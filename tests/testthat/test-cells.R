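test_that("MSCs seed the cancellous-base elements at capacity", {
  lat <- defect_lattice()
  cfg <- run_config()
  cells <- init_cells(lat, cfg)          # no scaffold: cap 100 everywhere
  base <- lat$boundary_tag == "cancellous_base"
  expect_equal(sum(base), 40L)
  expect_true(all(cells$msc[base] == 100))
  expect_true(all(cells$msc[!base] == 0))
  expect_equal(sum(cells$msc), 4000)
  expect_true(all(cells$osteoblast == 0))
  # strut elements in the base row are filled to their reduced capacity
  lay <- scaffold_layout(lat)
  st <- scaffold_state(lay, degradation_preset("bulk", "slow"))
  cells2 <- init_cells(lat, cfg, scaffold_field(st)$N)
  in_strut <- base & lat$col %in% unlist(lay$strut_cols)
  expect_true(all(cells2$msc[in_strut] == 50))
  expect_true(all(cells2$msc[base & !in_strut] == 100))
  # scaled fixture
  fx <- make_fixture("small")
  cf <- init_cells(fx$lattice, fx$config)
  expect_equal(sum(cf$msc > 0), 8L)
})

test_that("implicit diffusion preserves uniform states and total mass", {
  fx <- make_fixture("small")
  lat <- fx$lattice
  cfg <- fx$config
  D <- rep(0.8, lat$n_elements)
  # uniform field with closed boundaries stays uniform
  cells <- init_cells(lat, cfg)
  cells$msc <- rep(37.5, lat$n_elements)
  out <- diffuse_msc(cells, D, lat, cfg, source = FALSE)
  expect_equal(out$msc, rep(37.5, lat$n_elements), tolerance = 1e-12)
  # mass conservation with closed boundaries, heterogeneous diffusivity
  set.seed(11)
  cells$msc <- stats::runif(lat$n_elements, 0, 80)
  D2 <- stats::runif(lat$n_elements, 0.01, 0.8)
  out <- diffuse_msc(cells, D2, lat, cfg, source = FALSE)
  expect_equal(sum(out$msc), sum(cells$msc), tolerance = 1e-10)
  expect_true(all(out$msc >= 0))
  expect_error(diffuse_msc(cells, D, lat, cfg, dt = 0), "positive")
})

test_that("the base source keeps every element non-decreasing", {
  fx <- make_fixture("small")
  lat <- fx$lattice
  cfg <- fx$config
  cells <- init_cells(lat, cfg)
  D <- rep(0.8, lat$n_elements)
  prev <- cells$msc
  for (d in 1:10) {
    cells <- diffuse_msc(cells, D, lat, cfg)
    expect_true(all(cells$msc >= prev - 1e-9))
    prev <- cells$msc
  }
  expect_true(all(cells$msc <= 100 + 1e-9))
})

test_that("population rules follow the mechanoregulation rates", {
  cfg <- run_config()
  mk <- function(msc = 0, ob = 0, ch = 0, fb = 0) {
    structure(list(msc = msc, osteoblast = ob, chondrocyte = ch,
                   fibroblast = fb), class = "cell_field")
  }
  # cartilage element: 5 cells differentiate, MSC mitosis clipped at cap
  out <- update_populations(mk(msc = 100), "cartilage", cfg, capacity = 100)
  expect_equal(out$chondrocyte, 5)
  expect_equal(out$msc, 95)               # 95 * 1.15 clipped to cap - 5
  expect_equal(out$osteoblast, 0)
  # resorption: 10% osteoblast loss, others untouched
  out <- update_populations(mk(ob = 50, ch = 8), "resorption", cfg,
                            capacity = 100)
  expect_equal(out$osteoblast, 45)
  expect_equal(out$chondrocyte, 8)
  # bone element: mitosis acts on the pre-transfer count, apoptosis on others
  out <- update_populations(mk(msc = 40, ob = 20, ch = 10, fb = 4), "bone",
                            cfg, capacity = 100)
  expect_equal(out$osteoblast, 20 * 1.05 + 0.05 * 40)
  expect_equal(out$chondrocyte, 10 * 0.85)
  expect_equal(out$fibroblast, 4 * 0.85)
  expect_equal(out$msc, 38 * 1.15)
  # empty element stays empty
  out <- update_populations(mk(), "fibrous", cfg, capacity = 100)
  expect_equal(unlist(out[c("msc", "osteoblast", "chondrocyte",
                            "fibroblast")]),
               c(msc = 0, osteoblast = 0, chondrocyte = 0, fibroblast = 0))
})

test_that("differentiation alone conserves cells", {
  cfg <- run_config(rates = list(differentiation = 0.05, tissue_mitosis = 0,
                                 apoptosis = 0, msc_mitosis = 0,
                                 resorption = 0))
  cells <- structure(list(msc = c(60, 80), osteoblast = c(5, 0),
                          chondrocyte = c(0, 3), fibroblast = c(1, 1)),
                     class = "cell_field")
  tot0 <- sum(unlist(cells))
  out <- update_populations(cells, c("bone", "cartilage"), cfg,
                            capacity = c(100, 100))
  expect_equal(sum(unlist(out[c("msc", "osteoblast", "chondrocyte",
                                "fibroblast")])), tot0)
  expect_equal(out$osteoblast[1], 5 + 3)       # gained exactly the MSC loss
  expect_equal(out$msc[1], 57)
})

test_that("osteoblasts decay as 0.9^d under sustained resorption", {
  fx <- make_fixture("small")
  lat <- fx$lattice
  cfg <- fx$config
  cells <- init_cells(lat, cfg)
  cells$osteoblast <- rep(64, lat$n_elements)
  cells$msc <- numeric(lat$n_elements)
  cls <- rep("resorption", lat$n_elements)
  for (d in 1:6) {
    cells <- diffuse_msc(cells, rep(0, lat$n_elements), lat, cfg,
                         source = FALSE)
    cells <- update_populations(cells, cls, cfg,
                                capacity = rep(100, lat$n_elements))
    expect_equal(cells$osteoblast, rep(64 * 0.9^d, lat$n_elements),
                 tolerance = 1e-12)
  }
})

test_that("counts stay non-negative and within capacity for random stimuli", {
  fx <- make_fixture("small")
  lat <- fx$lattice
  cfg <- fx$config
  lay <- fx$layout
  st <- scaffold_state(lay, degradation_params("bulk", k_E = 100, k_N = 0.2))
  set.seed(99)
  cells <- init_cells(lat, cfg, scaffold_field(st)$N)
  for (d in 1:12) {
    N <- scaffold_field(st)$N
    cap <- effective_capacity(cfg$cell_cap, N)
    D <- stats::runif(lat$n_elements, 0.01, 0.8)
    cls <- sample(c("resorption", "bone", "cartilage", "fibrous"),
                  lat$n_elements, replace = TRUE)
    cells <- diffuse_msc(cells, D, lat, cfg, cap)
    cells <- update_populations(cells, cls, cfg, cap)
    total <- cells$msc + cells$osteoblast + cells$chondrocyte +
      cells$fibroblast
    expect_true(all(cells$msc >= 0 & cells$osteoblast >= 0 &
                      cells$chondrocyte >= 0 & cells$fibroblast >= 0))
    expect_true(all(total <= cap + 1e-9))
    st <- degrade_step(st)
  }
})
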
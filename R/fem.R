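# Axisymmetric Biot poroelastic finite elements on structured quadrilateral
# meshes. Displacements are biquadratic (9-node Lagrange), pore pressure
# bilinear (Taylor-Hood pairing, LBB stable). Strain components are ordered
# (eps_rr, eps_zz, eps_theta, gamma_rz) with engineering shear.

gauss3 <- function() {
  g <- sqrt(3 / 5)
  list(x = c(-g, 0, g), w = c(5, 8, 5) / 9)
}

# 1D quadratic Lagrange basis on [-1, 1] and derivative
lag2 <- function(x) c(x * (x - 1) / 2, 1 - x^2, x * (x + 1) / 2)
dlag2 <- function(x) c(x - 0.5, -2 * x, x + 0.5)

# bilinear basis and derivatives, node order (-,-), (+,-), (-,+), (+,+)
bilin <- function(xi, eta) {
  c((1 - xi) * (1 - eta), (1 + xi) * (1 - eta),
    (1 - xi) * (1 + eta), (1 + xi) * (1 + eta)) / 4
}
dbilin <- function(xi, eta) {
  rbind(c(-(1 - eta), (1 - eta), -(1 + eta), (1 + eta)) / 4,
        c(-(1 - xi), -(1 + xi), (1 - xi), (1 + xi)) / 4)
}

#' Octahedral shear strain of a small-strain tensor
#'
#' Computes `gamma_oct = (2/3) * sqrt((e1-e2)^2 + (e2-e3)^2 + (e3-e1)^2)`
#' from the principal strains of an axisymmetric strain state.
#'
#' @param eps numeric vector `c(eps_rr, eps_zz, eps_theta, gamma_rz)` with
#'   engineering shear, or a 4-row matrix of such columns.
#' @return octahedral shear strain(s), dimensionless.
#' @export
octahedral_shear_strain <- function(eps) {
  if (is.null(dim(eps))) eps <- matrix(eps, nrow = 4)
  err <- eps[1, ]; ezz <- eps[2, ]; ett <- eps[3, ]; grz <- eps[4, ]
  m <- (err + ezz) / 2
  rad <- sqrt(((err - ezz) / 2)^2 + (grz / 2)^2)
  e1 <- m + rad; e2 <- m - rad; e3 <- ett
  (2 / 3) * sqrt((e1 - e2)^2 + (e2 - e3)^2 + (e3 - e1)^2)
}

# Isotropic or transversely isotropic elasticity matrix for the strain order
# (rr, zz, theta, rz). Directions: 1 = axial (z), 2 = radial (r),
# 3 = circumferential (theta).
d_matrix <- function(E, nu, ti = NULL) {
  if (is.null(ti)) {
    lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
    mu <- E / (2 * (1 + nu))
    D <- diag(c(2 * mu, 2 * mu, 2 * mu, mu))
    D[1:3, 1:3] <- D[1:3, 1:3] + lam
    return(D)
  }
  # compliance in (zz, rr, theta) = (1, 2, 3)
  S <- matrix(0, 4, 4)
  S[2, 2] <- 1 / ti$E2            # rr
  S[1, 1] <- 1 / ti$E1            # zz
  S[3, 3] <- 1 / ti$E3            # theta
  S[1, 2] <- S[2, 1] <- -ti$nu12 / ti$E1
  S[2, 3] <- S[3, 2] <- -ti$nu23 / ti$E2
  S[3, 1] <- S[1, 3] <- -ti$nu31 / ti$E3
  S[4, 4] <- 1 / ti$G12           # rz shear couples axial-radial
  D <- solve(S)
  # reorder from (zz, rr, theta, rz) to (rr, zz, theta, rz)
  perm <- c(2, 1, 3, 4)
  D[perm, perm]
}

# Build a structured axisymmetric mesh from grid lines. material is a
# character vector per element (filled by the callers).
poro_grid <- function(r_lines, z_lines) {
  nr <- length(r_lines) - 1L
  nz <- length(z_lines) - 1L
  nel <- nr * nz
  i <- rep(seq_len(nr), times = nz)        # radial element index
  j <- rep(seq_len(nz), each = nr)         # axial element index
  el <- data.frame(
    i = i, j = j,
    r0 = r_lines[i], r1 = r_lines[i + 1L],
    z0 = z_lines[j], z1 = z_lines[j + 1L])
  el$rc <- (el$r0 + el$r1) / 2
  el$zc <- (el$z0 + el$z1) / 2
  nu_r <- 2L * nr + 1L
  nu_z <- 2L * nz + 1L
  np_r <- nr + 1L
  np_z <- nz + 1L
  # element connectivity
  u_nodes <- matrix(0L, nel, 9L)
  p_nodes <- matrix(0L, nel, 4L)
  for (e in seq_len(nel)) {
    ia <- 2L * (i[e] - 1L); jb <- 2L * (j[e] - 1L)
    n <- 0L
    for (b in 1:3) for (a in 1:3) {
      n <- n + 1L
      u_nodes[e, n] <- (jb + b - 1L) * nu_r + ia + a
    }
    ci <- i[e]; cj <- j[e]
    p_nodes[e, ] <- c((cj - 1L) * np_r + ci, (cj - 1L) * np_r + ci + 1L,
                      cj * np_r + ci, cj * np_r + ci + 1L)
  }
  u_dofs <- matrix(0L, nel, 18L)
  u_dofs[, seq(1, 17, 2)] <- 2L * u_nodes - 1L
  u_dofs[, seq(2, 18, 2)] <- 2L * u_nodes
  list(r_lines = r_lines, z_lines = z_lines, nr = nr, nz = nz, nel = nel,
       elements = el, u_nodes = u_nodes, p_nodes = p_nodes, u_dofs = u_dofs,
       n_u_nodes = nu_r * nu_z, n_u_dofs = 2L * nu_r * nu_z,
       n_p_nodes = np_r * np_z, nu_r = nu_r, nu_z = nu_z,
       np_r = np_r, np_z = np_z)
}

# Precompute element integration kernels: stacked strain-displacement
# matrices with quadrature weights folded in, the (property-independent)
# coupling blocks Q_e, the geometric kernels of H_e and S_e, and the
# element-centre strain/pressure-gradient extraction operators.
poro_kernels <- function(grid) {
  g <- gauss3()
  nel <- grid$nel
  Bs <- vector("list", nel)       # 36 x 18, weights folded (sqrt not needed:
  Ws <- vector("list", nel)       # per-gp weights to scale D blocks
  Qe <- vector("list", nel)
  Hg <- vector("list", nel)
  Sg <- vector("list", nel)
  Bc <- vector("list", nel)       # 4 x 18 at centre
  Gc <- vector("list", nel)       # 2 x 4 pressure gradient at centre
  fz_top <- numeric(grid$n_u_dofs)  # unit downward pressure on top edge
  el <- grid$elements
  for (e in seq_len(nel)) {
    a <- el$r1[e] - el$r0[e]
    b <- el$z1[e] - el$z0[e]
    detJ <- a * b / 4
    Bstack <- matrix(0, 36, 18)
    w_gp <- numeric(9)
    Q <- matrix(0, 18, 4)
    H <- matrix(0, 4, 4)
    S <- matrix(0, 4, 4)
    gp <- 0L
    for (q2 in 1:3) for (q1 in 1:3) {
      gp <- gp + 1L
      xi <- g$x[q1]; eta <- g$x[q2]
      r <- el$rc[e] + xi * a / 2
      w <- g$w[q1] * g$w[q2] * detJ * 2 * pi * r
      Lx <- lag2(xi); Ly <- lag2(eta)
      dLx <- dlag2(xi) * 2 / a; dLy <- dlag2(eta) * 2 / b
      N <- as.vector(outer(Lx, Ly))            # node order a fast, b slow
      dNr <- as.vector(outer(dLx, Ly))
      dNz <- as.vector(outer(Lx, dLy))
      B <- matrix(0, 4, 18)
      iu <- seq(1, 17, 2); iw <- seq(2, 18, 2)
      B[1, iu] <- dNr
      B[2, iw] <- dNz
      B[3, iu] <- N / r
      B[4, iu] <- dNz
      B[4, iw] <- dNr
      Bstack[(4 * gp - 3):(4 * gp), ] <- B
      w_gp[gp] <- w
      Np <- bilin(xi, eta)
      dNp <- dbilin(xi, eta)
      dNp[1, ] <- dNp[1, ] * 2 / a
      dNp[2, ] <- dNp[2, ] * 2 / b
      bvol <- B[1, ] + B[2, ] + B[3, ]
      Q <- Q + w * tcrossprod(bvol, Np)
      H <- H + w * crossprod(dNp)
      S <- S + w * tcrossprod(Np)
    }
    Bs[[e]] <- Bstack; Ws[[e]] <- w_gp
    Qe[[e]] <- Q; Hg[[e]] <- H; Sg[[e]] <- S
    # centre extraction
    r <- el$rc[e]
    Lx <- lag2(0); dLx <- dlag2(0) * 2 / a
    Ly <- lag2(0); dLy <- dlag2(0) * 2 / b
    N <- as.vector(outer(Lx, Ly))
    dNr <- as.vector(outer(dLx, Ly))
    dNz <- as.vector(outer(Lx, dLy))
    Bce <- matrix(0, 4, 18)
    iu <- seq(1, 17, 2); iw <- seq(2, 18, 2)
    Bce[1, iu] <- dNr; Bce[2, iw] <- dNz
    Bce[3, iu] <- N / r; Bce[4, iu] <- dNz; Bce[4, iw] <- dNr
    Bc[[e]] <- Bce
    dNp <- dbilin(0, 0)
    dNp[1, ] <- dNp[1, ] * 2 / a
    dNp[2, ] <- dNp[2, ] * 2 / b
    Gc[[e]] <- dNp
    # top edge load (unit pressure, downward)
    if (el$j[e] == grid$nz) {
      for (q in 1:3) {
        xi <- g$x[q]
        r <- el$rc[e] + xi * a / 2
        w <- g$w[q] * (a / 2) * 2 * pi * r
        Lx <- lag2(xi)
        nodes <- grid$u_nodes[e, 7:9]          # b = 3 row (eta = +1)
        fz_top[2L * nodes] <- fz_top[2L * nodes] - w * Lx
      }
    }
  }
  list(B = Bs, w = Ws, Q = Qe, Hg = Hg, Sg = Sg, Bc = Bc, Gc = Gc,
       fz_top = fz_top)
}

# Sparse centre-strain extractor (4*nel x n_u_dofs) and pressure-gradient
# extractor (2*nel x n_p_nodes).
centre_operators <- function(grid, kern) {
  nel <- grid$nel
  ib <- rep((seq_len(nel) - 1L) * 4L, each = 72L) + rep(rep(1:4, 18), nel)
  jb <- rep(t(grid$u_dofs), each = 4L)
  xb <- unlist(lapply(kern$Bc, as.vector))
  Bop <- Matrix::sparseMatrix(i = ib, j = as.vector(jb), x = xb,
                              dims = c(4L * nel, grid$n_u_dofs))
  ig <- rep((seq_len(nel) - 1L) * 2L, each = 8L) + rep(rep(1:2, 4), nel)
  jg <- rep(t(grid$p_nodes), each = 2L)
  Gop <- Matrix::sparseMatrix(i = ig, j = as.vector(jg),
                              x = unlist(lapply(kern$Gc, as.vector)),
                              dims = c(2L * nel, grid$n_p_nodes))
  list(B = Bop, G = Gop)
}

#' Assemble the axisymmetric poroelastic system
#'
#' Builds the coupled displacement/pore-pressure (Biot consolidation,
#' small-strain) sparse blocks for a structured mesh and per-element
#' properties: drained stiffness `K`, coupling `Q` (Biot coefficient 1,
#' incompressible grains in the effective-stress law), seepage `H`
#' (hydraulic conductivity converted to mobility with the fluid specific
#' weight) and storage `S` (fluid and grain compressibility).
#'
#' @param mesh a mesh from [condyle_mesh()] or [column_mesh()].
#' @param props data frame with one row per mesh element: `E` (MPa), `nu`,
#'   `permeability` (mm/s), `void_ratio`, `grain_bulk_modulus` (MPa, 0 =
#'   incompressible); optionally a list-column `ti` of transversely
#'   isotropic constant sets.
#' @param fluid_bulk_modulus pore-fluid bulk modulus (MPa); `Inf` gives an
#'   incompressible fluid.
#' @return object of class `poro_system`.
#' @export
assemble_poroelastic_system <- function(mesh, props,
                                        fluid_bulk_modulus =
                                          fluid_constants()$bulk_modulus) {
  grid <- mesh$grid
  kern <- mesh$kernels
  nel <- grid$nel
  if (any(!is.finite(props$E)) || any(props$E <= 0))
    stop("non-positive elastic modulus in element(s) ",
         paste(utils::head(which(props$E <= 0), 5L), collapse = ", "))
  gw <- fluid_constants()$specific_weight
  mob <- props$permeability / gw
  n_por <- props$void_ratio / (1 + props$void_ratio)
  Ks <- ifelse(props$grain_bulk_modulus <= 0, Inf, props$grain_bulk_modulus)
  stor <- n_por / fluid_bulk_modulus + (1 - n_por) / Ks

  # triplet indices: element-major, with matrix entries stored column-major
  # (row index fast), matching as.vector() of each element matrix
  dofs_t <- t(grid$u_dofs)                      # 18 x nel
  pn_t <- t(grid$p_nodes)                       # 4 x nel
  iK <- as.vector(dofs_t[rep(1:18, 18), ])
  jK <- as.vector(dofs_t[rep(1:18, each = 18), ])
  xK <- numeric(nel * 324L)
  iQ <- as.vector(dofs_t[rep(1:18, 4), ])
  jQ <- as.vector(pn_t[rep(1:4, each = 18), ])
  xQ <- numeric(nel * 72L)
  iH <- as.vector(pn_t[rep(1:4, 4), ])
  jH <- as.vector(pn_t[rep(1:4, each = 4), ])
  xH <- numeric(nel * 16L)
  xS <- numeric(nel * 16L)

  has_ti <- !is.null(props$ti)
  for (e in seq_len(nel)) {
    ti <- if (has_ti) props$ti[[e]] else NULL
    D <- d_matrix(props$E[e], props$nu[e], ti)
    Bs <- kern$B[[e]]
    DB <- matrix(0, 36, 18)
    w <- kern$w[[e]]
    for (gp in 1:9) {
      rows <- (4 * gp - 3):(4 * gp)
      DB[rows, ] <- (w[gp] * D) %*% Bs[rows, ]
    }
    Ke <- crossprod(Bs, DB)
    xK[(324 * (e - 1) + 1):(324 * e)] <- as.vector(Ke)
    xQ[(72 * (e - 1) + 1):(72 * e)] <- as.vector(kern$Q[[e]])
    xH[(16 * (e - 1) + 1):(16 * e)] <- as.vector(mob[e] * kern$Hg[[e]])
    xS[(16 * (e - 1) + 1):(16 * e)] <- as.vector(stor[e] * kern$Sg[[e]])
  }
  K <- Matrix::sparseMatrix(i = iK, j = jK, x = xK,
                            dims = c(grid$n_u_dofs, grid$n_u_dofs))
  Q <- Matrix::sparseMatrix(i = iQ, j = jQ, x = xQ,
                            dims = c(grid$n_u_dofs, grid$n_p_nodes))
  H <- Matrix::sparseMatrix(i = iH, j = jH, x = xH,
                            dims = c(grid$n_p_nodes, grid$n_p_nodes))
  S <- Matrix::sparseMatrix(i = iH, j = jH, x = xS,
                            dims = c(grid$n_p_nodes, grid$n_p_nodes))
  structure(
    list(mesh = mesh, K = K, Q = Q, H = H, S = S, mob = mob,
         f_unit = kern$fz_top, props = props),
    class = "poro_system"
  )
}

# free dof bookkeeping -------------------------------------------------------

u_fixed_dofs <- function(mesh) {
  grid <- mesh$grid
  bc <- mesh$bc
  nu_r <- grid$nu_r; nu_z <- grid$nu_z
  node_id <- function(a, b) (b - 1L) * nu_r + a
  fixed <- integer(0)
  if (bc$fix_all_radial) {
    fixed <- c(fixed, 2L * seq_len(grid$n_u_nodes) - 1L)
  } else {
    axis <- node_id(1L, seq_len(nu_z))
    fixed <- c(fixed, 2L * axis - 1L)
    if (bc$fix_outer_radial) {
      outer <- node_id(nu_r, seq_len(nu_z))
      fixed <- c(fixed, 2L * outer - 1L)
    }
  }
  bottom <- node_id(seq_len(nu_r), 1L)
  fixed <- c(fixed, 2L * bottom)
  sort(unique(fixed))
}

#' Solve a compression/consolidation load schedule
#'
#' Backward-Euler time stepping of the coupled Biot system. Dirichlet values
#' are homogeneous: radial displacement is fixed on the symmetry axis (and
#' optionally on the outer boundary), vertical displacement on the support
#' surface, and pore pressure on the drainage nodes of phases marked
#' `drained`. The applied load ramps linearly from `load_start` to
#' `load_end` within each phase.
#'
#' @param system a [assemble_poroelastic_system()] result.
#' @param pressure applied surface pressure (MPa).
#' @param phases list of phases, each a list with `duration` (s), `n_steps`,
#'   `load_start`, `load_end` (load factors), `drained` (logical).
#' @param record optional function `(phase, step, u, p)` called after every
#'   accepted step.
#' @return list with final `u`, `p`, and per-phase end states.
#' @export
poro_solve <- function(system, pressure, phases, record = NULL) {
  grid <- system$mesh$grid
  fixed_u <- u_fixed_dofs(system$mesh)
  free_u <- setdiff(seq_len(grid$n_u_dofs), fixed_u)
  drain <- system$mesh$bc$drain_p_nodes
  u <- numeric(grid$n_u_dofs)
  p <- numeric(grid$n_p_nodes)
  Qt <- Matrix::t(system$Q)
  phase_end <- vector("list", length(phases))
  for (ph in seq_along(phases)) {
    phase <- phases[[ph]]
    dt <- phase$duration / phase$n_steps
    free_p <- if (isTRUE(phase$drained))
      setdiff(seq_len(grid$n_p_nodes), drain) else seq_len(grid$n_p_nodes)
    A <- rbind(
      cbind(system$K[free_u, free_u, drop = FALSE],
            -system$Q[free_u, free_p, drop = FALSE]),
      cbind(Qt[free_p, free_u, drop = FALSE],
            (system$S + dt * system$H)[free_p, free_p, drop = FALSE]))
    fac <- Matrix::lu(A)
    nf <- length(free_u)
    for (k in seq_len(phase$n_steps)) {
      lam <- phase$load_start +
        (phase$load_end - phase$load_start) * k / phase$n_steps
      p[drain] <- if (isTRUE(phase$drained)) 0 else p[drain]
      rhs_u <- pressure * lam * system$f_unit[free_u]
      rhs_p <- (Qt %*% u + system$S %*% p)[free_p]
      sol <- Matrix::solve(fac, c(rhs_u, as.numeric(rhs_p)))
      sol <- as.numeric(sol)
      if (any(!is.finite(sol)))
        stop(mechanical_failure_condition("poroelastic solve diverged"))
      u[free_u] <- sol[seq_len(nf)]
      p[free_p] <- sol[-seq_len(nf)]
      if (isTRUE(phase$drained)) p[drain] <- 0
      if (!is.null(record)) record(ph, k, u, p)
    }
    phase_end[[ph]] <- list(u = u, p = p)
  }
  list(u = u, p = p, phase_end = phase_end)
}

mechanical_failure_condition <- function(msg, day = NA_integer_,
                                         max_gamma = NA_real_) {
  structure(
    class = c("strutsim_mechanical_failure", "error", "condition"),
    list(message = msg, call = NULL, day = day, max_gamma = max_gamma))
}

# element-centre fields ------------------------------------------------------

element_strains <- function(system, u) {
  eps <- as.numeric(system$mesh$ops$B %*% u)
  matrix(eps, nrow = 4)
}

element_darcy_speed <- function(system, p) {
  g <- as.numeric(system$mesh$ops$G %*% p)
  g <- matrix(g, nrow = 2)
  system$mob * sqrt(g[1, ]^2 + g[2, ]^2)
}

#' Solve the daily load case and extract stimulus inputs
#'
#' Runs the 1 s compression ramp (undrained) followed by the 0.5 s
#' consolidation step (drained). The octahedral shear strain is sampled at
#' the end of the compression ramp; the fluid speed is the per-element
#' maximum of the Darcy flux magnitude over the consolidation window, where
#' drainage makes the flow peak.
#'
#' @param system a [assemble_poroelastic_system()] result.
#' @param config a [run_config()].
#' @return list with per-mesh-element `gamma` (octahedral shear strain,
#'   fraction), `v` (mm/s), `eps_zz`, plus final `u` and `p`.
#' @export
solve_load_case <- function(system, config) {
  nel <- system$mesh$grid$nel
  v_max <- numeric(nel)
  gamma <- NULL
  eps_zz <- NULL
  rec <- function(ph, k, u, p) {
    if (ph == 2L) v_max <<- pmax(v_max, element_darcy_speed(system, p))
  }
  res <- poro_solve(
    system, config$load_pressure,
    phases = list(
      list(duration = config$compression_duration,
           n_steps = config$fe$n_compression_steps,
           load_start = 0, load_end = 1, drained = FALSE),
      list(duration = config$consolidation_duration,
           n_steps = config$fe$n_consolidation_steps,
           load_start = 1, load_end = 1, drained = TRUE)),
    record = rec)
  eps <- element_strains(system, res$phase_end[[1]]$u)
  gamma <- octahedral_shear_strain(eps)
  eps_zz <- eps[2, ]
  list(gamma = gamma, v = v_max, eps_zz = eps_zz,
       u = res$u, p = res$p)
}
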
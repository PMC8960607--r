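#' Initial cell field on the defect lattice
#'
#' Elements adjacent to the cancellous bone (the defect base row) start
#' completely filled with mesenchymal stromal cells — filled to their
#' effective capacity, which is the element cell cap reduced by the volume
#' fraction the scaffold material still occupies. All other elements start
#' empty.
#'
#' @param lattice a [defect_lattice()].
#' @param config a [run_config()].
#' @param scaffold_N per-element scaffold volume fraction (defaults to no
#'   scaffold); see [scaffold_field()].
#' @return object of class `cell_field`: list of per-element numeric vectors
#'   `msc`, `osteoblast`, `chondrocyte`, `fibroblast`.
#' @export
init_cells <- function(lattice, config = run_config(),
                       scaffold_N = numeric(lattice$n_elements)) {
  n <- lattice$n_elements
  cap <- effective_capacity(config$cell_cap, scaffold_N)
  msc <- numeric(n)
  base <- lattice$boundary_tag == "cancellous_base"
  msc[base] <- cap[base]
  structure(
    list(msc = msc, osteoblast = numeric(n), chondrocyte = numeric(n),
         fibroblast = numeric(n)),
    class = "cell_field")
}

#' Effective cell capacity of lattice elements
#'
#' The cap of 100 cells applies to the element volume available to tissue;
#' scaffold material excludes its own volume fraction, so an undegraded
#' strut element (N = 0.5) holds at most 50 cells, and capacity grows back
#' as the scaffold erodes.
#'
#' @param cell_cap nominal cap (cells/element).
#' @param scaffold_N per-element scaffold volume fraction.
#' @return numeric vector of capacities.
#' @export
effective_capacity <- function(cell_cap, scaffold_N) {
  cell_cap * (1 - scaffold_N)
}

#' @export
print.cell_field <- function(x, ...) {
  cat(sprintf(
    "<cell_field> totals: MSC %.0f, osteoblast %.0f, chondrocyte %.0f, fibroblast %.0f\n",
    sum(x$msc), sum(x$osteoblast), sum(x$chondrocyte), sum(x$fibroblast)))
  invisible(x)
}

# Conservative finite-volume Laplacian with harmonic-mean face diffusivities
# on the lattice grid; zero-flux outer boundaries. Returns a sparse matrix L
# such that dc/dt = L c.
diffusion_operator <- function(lattice, diffusivity) {
  nr <- lattice$n_rows; nc <- lattice$n_cols
  h <- lattice$element_size
  id <- matrix(seq_len(nr * nc), nr, nc)     # column-major: row fast
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  add_faces <- function(from, to) {
    Df <- 2 * diffusivity[from] * diffusivity[to] /
      pmax(diffusivity[from] + diffusivity[to], 1e-300)
    k <- Df / h^2
    ii <<- c(ii, from, to, from, to)
    jj <<- c(jj, to, from, from, to)
    xx <<- c(xx, k, k, -k, -k)
  }
  if (nr > 1L) add_faces(as.vector(id[-nr, ]), as.vector(id[-1, ]))
  if (nc > 1L) add_faces(as.vector(id[, -nc]), as.vector(id[, -1]))
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(nr * nc, nr * nc))
}

#' One implicit MSC diffusion step on the defect lattice
#'
#' Backward-Euler step of the mass-diffusion problem that models MSC
#' migration, on the defect-only grid with per-element (homogenised)
#' diffusivity. The cancellous-bone edge acts as a persistent source held
#' at capacity; all other boundaries are zero-flux. Concentrations are
#' clipped to the effective capacity after the step.
#'
#' @param cells a [init_cells()] field.
#' @param diffusivity per-element diffusion coefficient (mm^2/day).
#' @param lattice a [defect_lattice()].
#' @param config a [run_config()].
#' @param capacity per-element effective capacity.
#' @param dt time step (day).
#' @param source keep the base-edge Dirichlet source active (default TRUE);
#'   with `FALSE` all boundaries are closed and total mass is conserved.
#' @return the updated cell field.
#' @export
diffuse_msc <- function(cells, diffusivity, lattice, config = run_config(),
                        capacity = rep(config$cell_cap, lattice$n_elements),
                        dt = 1, source = TRUE) {
  if (dt <= 0) stop("dt must be positive")
  n <- lattice$n_elements
  L <- diffusion_operator(lattice, diffusivity)
  A <- Matrix::Diagonal(n) - dt * L
  b <- cells$msc
  if (source) {
    base <- which(lattice$boundary_tag == "cancellous_base")
    A[base, ] <- 0
    A[cbind(base, base)] <- 1
    b[base] <- capacity[base]
  }
  msc <- as.numeric(Matrix::solve(A, b))
  cells$msc <- pmin(pmax(msc, 0), capacity)
  cells
}

#' Mechanics-dependent daily update of the cell populations
#'
#' Applies the mechanoregulation cell rules elementwise from the tissue
#' class of the stimulus: in an element favouring bone, cartilage or
#' fibrous tissue, 5% of the MSCs differentiate into the matching phenotype,
#' the pre-existing cells of that phenotype undergo 5% mitosis, and the two
#' other phenotypes undergo 15% apoptosis; in a resorption element the
#' osteoblast count drops by 10%. MSCs divide by 15% per day independently
#' of mechanics. All multipliers act on the counts at the start of the day.
#' Totals are then clipped to the effective capacity: MSC growth cannot
#' push an element past its cap, and if the differentiated phenotypes alone
#' exceed a (shrunken) cap they are scaled down proportionally.
#'
#' @param cells a cell field.
#' @param tissue_class per-element factor/character with levels
#'   `resorption`, `bone`, `cartilage`, `fibrous`.
#' @param config a [run_config()].
#' @param capacity per-element effective capacity.
#' @return the updated cell field.
#' @export
update_populations <- function(cells, tissue_class, config = run_config(),
                               capacity = rep(config$cell_cap,
                                              length(cells$msc))) {
  r <- config$rates
  cls <- as.character(tissue_class)
  msc0 <- cells$msc
  ob0 <- cells$osteoblast; ch0 <- cells$chondrocyte; fb0 <- cells$fibroblast
  grow <- function(match_cls, ph0) {
    m <- cls == match_cls
    ifelse(m, ph0 * (1 + r$tissue_mitosis) + r$differentiation * msc0,
           ifelse(cls %in% c("bone", "cartilage", "fibrous"),
                  ph0 * (1 - r$apoptosis), ph0))
  }
  ob <- grow("bone", ob0)
  ch <- grow("cartilage", ch0)
  fb <- grow("fibrous", fb0)
  ob <- ifelse(cls == "resorption", ob0 * (1 - r$resorption), ob)
  differentiated <- ifelse(cls %in% c("bone", "cartilage", "fibrous"),
                           r$differentiation * msc0, 0)
  msc <- (msc0 - differentiated) * (1 + r$msc_mitosis)
  # capacity clipping
  others <- ob + ch + fb
  msc <- pmin(msc, pmax(capacity - others, 0))
  over <- others > capacity
  if (any(over)) {
    s <- capacity[over] / others[over]
    ob[over] <- ob[over] * s
    ch[over] <- ch[over] * s
    fb[over] <- fb[over] * s
  }
  cells$msc <- msc
  cells$osteoblast <- ob
  cells$chondrocyte <- ch
  cells$fibroblast <- fb
  cells
}
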
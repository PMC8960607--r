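#' Regular lattice discretising the osteochondral defect
#'
#' The defect is a 5 mm x 5 mm axisymmetric region discretised into square
#' elements (default 0.125 mm, giving the 40 x 40 = 1,600-element lattice).
#' The radial coordinate r runs from the symmetry axis (r = 0) to the defect
#' wall; the axial coordinate z runs from the defect base at the cancellous
#' bone interface (z = 0) up to the articular surface (z = depth).
#'
#' Edge elements carry exactly one boundary tag, assigned with precedence
#' `cancellous_base` > `articular_surface` > `axis` > side tags, the side
#' being split into `cartilage_side` (adjacent to the healthy cartilage
#' layer) and `subchondral_side` below it.
#'
#' @param n_rows,n_cols lattice dimensions (rows along z, columns along r).
#' @param element_size element edge length (mm); must divide `radius` and
#'   `depth` to within rounding.
#' @param radius,depth defect radius and depth (mm).
#' @param cartilage_thickness thickness of the healthy cartilage layer at
#'   the articular surface (mm), used only to split the side tags.
#' @return object of class `defect_lattice` with per-element centroids,
#'   row/column indices, and boundary tags.
#' @export
defect_lattice <- function(n_rows = 40L, n_cols = 40L, element_size = 0.125,
                           radius = 5, depth = 5, cartilage_thickness = 2) {
  if (abs(n_cols * element_size - radius) > 1e-9 ||
      abs(n_rows * element_size - depth) > 1e-9)
    stop("element_size must divide defect radius and depth exactly")
  n <- n_rows * n_cols
  # element (i, j): i = row from base (z), j = column from axis (r),
  # id = (j - 1) * n_rows + i (column-major)
  i <- rep(seq_len(n_rows), times = n_cols)
  j <- rep(seq_len(n_cols), each = n_rows)
  r <- (j - 0.5) * element_size
  z <- (i - 0.5) * element_size

  tag <- character(n)
  tag[j == n_cols] <- ifelse(z[j == n_cols] > depth - cartilage_thickness,
                             "cartilage_side", "subchondral_side")
  tag[j == 1L] <- "axis"
  tag[i == n_rows] <- "articular_surface"
  tag[i == 1L] <- "cancellous_base"

  structure(
    list(n_rows = n_rows, n_cols = n_cols, element_size = element_size,
         radius = radius, depth = depth, n_elements = n,
         row = i, col = j, r = r, z = z, boundary_tag = tag),
    class = "defect_lattice"
  )
}

#' @export
print.defect_lattice <- function(x, ...) {
  cat(sprintf("<defect_lattice> %d x %d elements of %g mm (defect %g x %g mm)\n",
              x$n_rows, x$n_cols, x$element_size, x$radius, x$depth))
  invisible(x)
}

#' Strut-architecture scaffold layout on the defect lattice
#'
#' Places vertical struts (annular walls in the axisymmetric picture) of the
#' given thickness, spanning the full defect depth. Each strut occupies the
#' lattice columns whose centroids fall inside `[centre - t/2, centre + t/2]`.
#' The exterior-facing columns of each strut (the innermost and outermost
#' radial columns) are labelled `surface`; interior columns are `bulk`.
#' A strut one or two columns wide therefore has no bulk.
#'
#' @param lattice a [defect_lattice()].
#' @param strut_center_radii radial centres of the struts (mm). The printed
#'   geometry does not fix these; the default `c(1.25, 2.5, 3.75)` spaces
#'   three struts evenly between axis and defect wall.
#' @param strut_thickness strut wall thickness (mm, default 0.5).
#' @return object of class `scaffold_layout` with per-strut column indices,
#'   per-column labels and per-element membership.
#' @export
scaffold_layout <- function(lattice,
                            strut_center_radii = c(1.25, 2.5, 3.75),
                            strut_thickness = 0.5) {
  h <- lattice$element_size
  col_r <- (seq_len(lattice$n_cols) - 0.5) * h
  strut_cols <- lapply(strut_center_radii, function(cr) {
    which(col_r > cr - strut_thickness / 2 & col_r < cr + strut_thickness / 2)
  })
  if (any(lengths(strut_cols) == 0L))
    stop("a strut lies outside the lattice or is thinner than one element")
  all_cols <- unlist(strut_cols)
  if (anyDuplicated(all_cols)) stop("struts overlap")
  if (min(all_cols) < 1L || max(all_cols) > lattice$n_cols)
    stop("a strut extends beyond the defect")

  col_label <- lapply(strut_cols, function(cols) {
    lab <- rep("bulk", length(cols))
    lab[cols == min(cols) | cols == max(cols)] <- "surface"
    stats::setNames(lab, cols)
  })

  element_ids <- lapply(strut_cols, function(cols) {
    which(lattice$col %in% cols)
  })

  structure(
    list(strut_center_radii = strut_center_radii,
         strut_thickness = strut_thickness,
         strut_height = lattice$depth,
         n_struts = length(strut_cols),
         strut_cols = strut_cols,
         col_label = col_label,
         element_ids = element_ids,
         n_scaffold_elements = length(unlist(element_ids)),
         lattice = lattice),
    class = "scaffold_layout"
  )
}

#' @export
print.scaffold_layout <- function(x, ...) {
  cat(sprintf("<scaffold_layout> %d struts (%g mm thick) on %d columns, %d elements\n",
              x$n_struts, x$strut_thickness, length(unlist(x$strut_cols)),
              x$n_scaffold_elements))
  invisible(x)
}
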
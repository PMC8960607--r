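#' Write simulation outputs to a directory
#'
#' Serialises a completed run: the per-day time series
#' (`timeseries.csv`), final lattice snapshots as CSV grids (one file per
#' cell phenotype, scaffold modulus and volume fraction, stimulus and class
#' code; rows ordered from the defect base upward), and a JSON run manifest
#' echoing the configuration, degradation parameters, milestone calendar
#' and package version for reproducibility.
#'
#' @param result a [run_simulation()] result.
#' @param out_dir output directory (created if missing).
#' @param vtk also write a legacy-ASCII VTK unstructured grid of the final
#'   lattice fields (`fields.vtk`).
#' @return invisibly, the vector of files written.
#' @export
write_outputs <- function(result, out_dir, vtk = FALSE) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  files <- character(0)
  path <- function(f) file.path(out_dir, f)
  utils::write.csv(result$records, path("timeseries.csv"), row.names = FALSE)
  files <- c(files, path("timeseries.csv"))
  lat <- result$lattice
  as_grid <- function(v) {
    m <- matrix(v, lat$n_rows, lat$n_cols)  # row = z from base, col = r
    m
  }
  grids <- list(
    msc = result$final$cells$msc,
    osteoblast = result$final$cells$osteoblast,
    chondrocyte = result$final$cells$chondrocyte,
    fibroblast = result$final$cells$fibroblast,
    scaffold_modulus = scaffold_field(result$final$scaffold)$E,
    scaffold_fraction = scaffold_field(result$final$scaffold)$N)
  if (!is.null(result$final$stimulus)) {
    grids$stimulus <- result$final$stimulus$S
    grids$class_code <- as.integer(result$final$stimulus$tissue_class)
  }
  for (nm in names(grids)) {
    f <- path(sprintf("grid_%s.csv", nm))
    utils::write.table(as_grid(grids[[nm]]), f, sep = ",",
                       row.names = FALSE, col.names = FALSE)
    files <- c(files, f)
  }
  manifest <- list(
    package = "strutsim",
    version = as.character(utils::packageVersion("strutsim")),
    config = result$config[setdiff(names(result$config), "rates")],
    rates = result$config$rates,
    degradation = unclass(result$params),
    milestones = lapply(unclass(result$milestones), function(v)
      if (is.numeric(v) && is.infinite(v)) "never" else v),
    failure = result$failure)
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  files <- c(files, path("manifest.json"))
  if (vtk) {
    f <- path("fields.vtk")
    write_vtk_lattice(f, lat, grids)
    files <- c(files, f)
  }
  invisible(files)
}

#' Write lattice fields as a legacy-ASCII VTK unstructured grid
#'
#' Emits the defect lattice as VTK quad cells in the (r, z) plane with one
#' CELL_DATA scalar array per supplied field, for inspection in standard
#' VTK viewers.
#'
#' @param path output file path.
#' @param lattice a [defect_lattice()].
#' @param fields named list of per-element numeric vectors.
#' @export
write_vtk_lattice <- function(path, lattice, fields) {
  h <- lattice$element_size
  nr <- lattice$n_rows; nc <- lattice$n_cols
  npr <- nc + 1L; npz <- nr + 1L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "defect lattice fields", "ASCII",
               "DATASET UNSTRUCTURED_GRID"), con)
  writeLines(sprintf("POINTS %d double", npr * npz), con)
  for (i in seq_len(npz)) for (j in seq_len(npr))
    writeLines(sprintf("%g %g 0", (j - 1) * h, (i - 1) * h), con)
  nel <- lattice$n_elements
  writeLines(sprintf("CELLS %d %d", nel, 5L * nel), con)
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    n0 <- (i - 1L) * npr + (j - 1L)
    writeLines(sprintf("4 %d %d %d %d", n0, n0 + 1L, n0 + npr + 1L,
                       n0 + npr), con)
  }
  writeLines(sprintf("CELL_TYPES %d", nel), con)
  writeLines(rep("9", nel), con)
  writeLines(sprintf("CELL_DATA %d", nel), con)
  for (nm in names(fields)) {
    writeLines(c(sprintf("SCALARS %s double 1", nm),
                 "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%g", fields[[nm]]), con)
  }
  invisible(path)
}
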
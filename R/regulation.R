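#' Tissue-formation class of the mechanoregulatory stimulus
#'
#' Partitions the stimulus axis into half-open intervals:
#' bone resorption for `0 <= S < 0.01`, bone formation for `0.01 <= S < 1`,
#' cartilage formation for `1 <= S < 3`, fibrous tissue for `S >= 3`.
#'
#' @param S numeric stimulus values (>= 0).
#' @return factor with levels `resorption`, `bone`, `cartilage`, `fibrous`.
#' @export
stimulus_class <- function(S) {
  if (any(S < 0 | !is.finite(S)))
    stop("stimulus values must be finite and >= 0")
  cut(S, breaks = c(0, 0.01, 1, 3, Inf), right = FALSE,
      labels = c("resorption", "bone", "cartilage", "fibrous"),
      include.lowest = TRUE)
}

#' Homogenised composite properties of the defect elements
#'
#' Each lattice element holds a mixture of species — bone (osteoblasts),
#' cartilage (chondrocytes), fibrous tissue (fibroblasts) and scaffold
#' material — with granulation tissue filling the remainder (MSCs carry
#' granulation-tissue properties and are counted in the remainder). Each
#' property channel is the weighted average
#' `X = [(N_MAX - sum N_i) X_gran + sum X_i N_i] / N_MAX`, with cell counts
#' as loads (1 cell = 1 unit) and the scaffold volume fraction converted to
#' `N_scaffold * N_MAX` units. Formed tissues take the subchondral-bone,
#' poroelastic-cartilage and fibrous-tissue rows of the tissue table. The
#' averaged channels are the elastic modulus, Poisson ratio, permeability,
#' grain bulk modulus and cell diffusivity; the void ratio is not part of
#' the weighted average and is taken from the dominant species.
#'
#' @param cells a cell field (see [init_cells()]).
#' @param scaffold_N per-element scaffold volume fraction.
#' @param config a [run_config()] (supplies `N_MAX = cell_cap`).
#' @param tissue_table a [load_tissue_table()] result.
#' @return data frame with one row per element: `elastic_modulus`,
#'   `poisson_ratio`, `permeability`, `grain_bulk_modulus`,
#'   `cell_diffusivity`, `void_ratio`.
#' @export
homogenize <- function(cells, scaffold_N, config = run_config(),
                       tissue_table = load_tissue_table()) {
  nmax <- config$cell_cap
  loads <- cbind(bone = cells$osteoblast,
                 cartilage = cells$chondrocyte,
                 fibrous = cells$fibroblast,
                 scaffold = scaffold_N * nmax)
  total <- rowSums(loads)
  if (any(total > nmax * (1 + 1e-9)))
    stop("species loads exceed the element capacity in element(s) ",
         paste(utils::head(which(total > nmax * (1 + 1e-9)), 5L),
               collapse = ", "))
  remainder <- pmax(nmax - total, 0)
  rows <- c(bone = "subchondral bone", cartilage = "poroelastic cartilage",
            fibrous = "fibrous tissue", scaffold = "scaffold material")
  gran <- tissue_table[["granulation tissue"]]
  channels <- c(elastic_modulus = "elastic_modulus",
                poisson_ratio = "poisson_ratio",
                permeability = "permeability",
                grain_bulk_modulus = "grain_bulk_modulus",
                cell_diffusivity = "cell_diffusivity")
  out <- data.frame(row.names = seq_along(total))
  for (ch in names(channels)) {
    acc <- remainder * gran[[ch]]
    for (sp in colnames(loads))
      acc <- acc + loads[, sp] * tissue_table[[rows[[sp]]]][[ch]]
    out[[ch]] <- acc / nmax
  }
  # void ratio from the dominant species (granulation counts as remainder)
  all_loads <- cbind(loads, granulation = remainder)
  dominant <- colnames(all_loads)[max.col(all_loads, ties.method = "last")]
  vr <- c(vapply(rows, function(r) tissue_table[[r]]$void_ratio, 0),
          granulation = gran$void_ratio)
  out$void_ratio <- as.numeric(vr[dominant])
  out
}

#' Tissue-class map and area fractions of the predicted repair
#'
#' The repair outcome is visualised through the distribution of the
#' stimulus: each defect element is assigned its tissue-formation class and
#' the per-class area fractions (percent of defect elements) summarise the
#' predicted composition.
#'
#' @param stimulus a stimulus field (see [extract_stimulus()]) or a numeric
#'   vector of stimulus values.
#' @return list with `class` (per-element factor) and `area_fraction_pct`
#'   (named numeric, summing to 100).
#' @export
classify_repair_map <- function(stimulus) {
  S <- if (is.data.frame(stimulus)) stimulus$S else stimulus
  cls <- stimulus_class(S)
  frac <- 100 * table(cls) / length(cls)
  list(class = cls,
       area_fraction_pct = stats::setNames(as.numeric(frac), names(frac)))
}
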
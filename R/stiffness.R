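#' Effective modulus of partially degraded scaffold material
#'
#' The load-bearing competence of a scaffold element combines its material
#' modulus and its remaining volume fraction: `E_scaffold = E_t * N_t`.
#' The undegraded strut element has 1000 MPa x 0.5 = 500 MPa.
#'
#' @param E_t material elastic modulus (MPa).
#' @param N_t scaffold volume fraction in the element.
#' @return effective modulus (MPa).
#' @export
effective_modulus <- function(E_t, N_t) {
  if (any(E_t < 0) || any(N_t < 0))
    stop("modulus and volume fraction must be >= 0")
  E_t * N_t
}

#' Ring-stack stiffness model of the standalone scaffold
#'
#' The three struts are concentric annular walls loaded in uniaxial
#' compression. Each lattice column of a strut is a parallel spring of
#' annular cross-section `A_c = 2 pi r_c dr` and height-averaged effective
#' modulus; the stack is calibrated once so that the undegraded scaffold
#' returns the reference stiffness `K0` exactly. Homogeneous degradation
#' therefore reduces to `K = K0 * (E_t N_t) / (E0 N0)`.
#'
#' @param layout a [scaffold_layout()].
#' @param K0 reference initial stiffness (N/mm, default 2445).
#' @param delta_x applied compressive strain (fraction, default 0.03); kept
#'   for reporting, the stiffness itself is strain-independent in the linear
#'   model.
#' @return object of class `stiffness_model`.
#' @export
stiffness_model <- function(layout, K0 = 2445, delta_x = 0.03) {
  if (layout$strut_height <= 0) stop("strut height must be positive")
  h <- layout$lattice$element_size
  cols <- unlist(layout$strut_cols)
  r_c <- (cols - 0.5) * h
  A_c <- 2 * pi * r_c * h
  structure(
    list(K0 = K0, delta_x = delta_x, height = layout$strut_height,
         cols = cols, area = A_c),
    class = "stiffness_model"
  )
}

#' Scaffold stiffness from the current degradation state
#'
#' @param state a [scaffold_state()].
#' @param model a [stiffness_model()]; defaults to one built from the
#'   state's layout with `K0 = 2445` N/mm.
#' @return scaffold stiffness (N/mm).
#' @export
scaffold_stiffness <- function(state, model = stiffness_model(state$layout)) {
  p <- state$params
  eff <- effective_modulus(state$E, state$N)   # uniform along the height
  eff0 <- p$E0 * p$N0
  model$K0 * sum(model$area * eff) / sum(model$area * eff0)
}

#' Stiffness trajectory under daily-stepped degradation
#'
#' @param params a [degradation_params()].
#' @param layout a [scaffold_layout()].
#' @param days number of days to step.
#' @param model optional [stiffness_model()].
#' @return data frame with columns `day` (0..days), `stiffness` (N/mm),
#'   `mean_E` (MPa) and `mean_N`.
#' @export
stiffness_trajectory <- function(params, layout, days,
                                 model = stiffness_model(layout)) {
  state <- scaffold_state(layout, params)
  out <- data.frame(day = 0:days, stiffness = NA_real_,
                    mean_E = NA_real_, mean_N = NA_real_)
  for (d in 0:days) {
    if (d > 0) state <- degrade_step(state)
    out$stiffness[d + 1] <- scaffold_stiffness(state, model)
    out$mean_E[d + 1] <- mean(state$E)
    out$mean_N[d + 1] <- mean(state$N)
  }
  out
}
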
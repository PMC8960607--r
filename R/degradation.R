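#' Initial scaffold degradation state
#'
#' The state tracks, per scaffold column (columns are uniform along the strut
#' height, since none of the degradation laws depend on z), the scaffold
#' material modulus `E` (MPa) and volume fraction `N`, together with the
#' surface/bulk label. Both quantities are non-increasing in time under every
#' modality; an element whose volume fraction reaches zero has its modulus
#' set to zero.
#'
#' @param layout a [scaffold_layout()].
#' @param params a [degradation_params()].
#' @return object of class `scaffold_state`.
#' @export
scaffold_state <- function(layout, params) {
  cols <- unlist(layout$strut_cols)
  strut <- rep(seq_len(layout$n_struts), lengths(layout$strut_cols))
  label <- unlist(lapply(layout$col_label, unname))
  structure(
    list(day = 0L, params = params, layout = layout,
         col = cols, strut = strut, label = label,
         E = rep(params$E0, length(cols)),
         N = rep(params$N0, length(cols)),
         initial_label = label),
    class = "scaffold_state"
  )
}

#' @export
print.scaffold_state <- function(x, ...) {
  cat(sprintf(
    "<scaffold_state> day %d (%s): mean E = %.1f MPa, mean N = %.3f\n",
    x$day, x$params$modality, mean(x$E), mean(x$N)))
  invisible(x)
}

#' Advance the scaffold state by one day
#'
#' Dispatches to the stepping rule of the state's degradation modality:
#' [step_surface_erosion()], [step_bulk()], [step_bulk_autocatalytic()] or
#' [step_exponential()].
#'
#' @param state a [scaffold_state()].
#' @return the state at the next day.
#' @export
degrade_step <- function(state) {
  switch(state$params$modality,
         surface_erosion = step_surface_erosion(state, state$params),
         bulk = step_bulk(state, state$params),
         bulk_autocatalytic = step_bulk_autocatalytic(state, state$params),
         exponential = step_exponential(state, state$params))
}

check_modality <- function(params, expected) {
  if (params$modality != expected)
    stop(sprintf("this stepping rule requires modality '%s' (got '%s')",
                 expected, params$modality), call. = FALSE)
}

# Relabel columns after erosion: among columns that still hold material, the
# radially outermost and innermost of each strut are exposed (surface).
relabel_active <- function(state) {
  for (s in seq_len(state$layout$n_struts)) {
    idx <- which(state$strut == s)
    active <- idx[state$N[idx] > 0]
    if (!length(active)) next
    lab <- rep("bulk", length(active))
    rr <- state$col[active]
    lab[rr == min(rr) | rr == max(rr)] <- "surface"
    state$label[active] <- lab
  }
  state
}

#' One day of hydrolytic degradation by surface erosion
#'
#' Two erosion fronts, one per exposed face of each strut, each remove
#' material at rate `k_N` per day from the outermost column that still holds
#' material; the part of a day's decrement in excess of a column's remaining
#' fraction carries over to the column it newly exposes. Bulk columns keep
#' their modulus untouched until exposed and fully eroded; a fully eroded
#' column has its modulus set to zero.
#'
#' @param state a [scaffold_state()].
#' @param params a [degradation_params()] with modality `surface_erosion`.
#' @return the state one day later.
#' @export
step_surface_erosion <- function(state, params = state$params) {
  check_modality(params, "surface_erosion")
  for (s in seq_len(state$layout$n_struts)) {
    idx <- which(state$strut == s)
    idx <- idx[order(state$col[idx])]
    for (face in list(idx, rev(idx))) {
      budget <- params$k_N
      for (k in face) {
        if (budget <= 0) break
        if (state$N[k] <= 0) next
        eaten <- min(state$N[k], budget)
        state$N[k] <- state$N[k] - eaten
        budget <- budget - eaten
      }
    }
  }
  zero <- state$N <= 1e-12
  state$N[zero] <- 0
  state$E[zero] <- 0
  state <- relabel_active(state)
  state$day <- state$day + 1L
  state
}

# Shared stepping for the modulus-driven (bulk-type) modalities.
# rate_E, k_N are per-column vectors; `expo` switches the modulus law.
step_bulk_core <- function(state, params, rate_E, k_N, expo = FALSE) {
  thr <- params$onset_fraction * params$E0
  E_old <- state$E
  E_new <- if (expo) E_old * exp(-rate_E) else pmax(0, E_old - rate_E)
  # erosion decrement: full k_N once the modulus sits at/below the onset
  # threshold; on the crossing day only the fraction of the day past the
  # continuous crossing erodes, so daily stepping matches the analytic
  # milestone calendar exactly
  dN <- numeric(length(E_old))
  below <- E_old <= thr & state$N > 0
  dN[below] <- k_N[below]
  crossing <- E_old > thr & E_new <= thr & state$N > 0
  if (any(crossing)) {
    tau <- if (expo) {
      log(E_old[crossing] / thr) / rate_E[crossing]
    } else {
      (E_old[crossing] - thr) / rate_E[crossing]
    }
    dN[crossing] <- k_N[crossing] * pmax(0, 1 - tau)
  }
  state$N <- pmax(0, state$N - dN)
  zero <- state$N <= 1e-12
  state$N[zero] <- 0
  E_new[zero] <- 0
  state$E <- E_new
  state$day <- state$day + 1L
  state
}

#' One day of linear bulk degradation
#'
#' The material modulus of every scaffold element decreases by `k_E` MPa/day
#' homogeneously (molecular weight is proportional to modulus). Once the
#' modulus has fallen to the onset threshold (10% of its initial value),
#' erosion also removes volume fraction at `k_N` per day in all elements.
#'
#' @inheritParams step_surface_erosion
#' @export
step_bulk <- function(state, params = state$params) {
  check_modality(params, "bulk")
  n <- length(state$E)
  step_bulk_core(state, params, rep(params$k_E, n), rep(params$k_N, n))
}

#' One day of bulk degradation with autocatalysis
#'
#' Trapped acidic by-products accelerate interior degradation: elements in
#' the strut bulk lose modulus (and, past onset, volume fraction) at twice
#' the surface-element rates.
#'
#' @inheritParams step_surface_erosion
#' @export
step_bulk_autocatalytic <- function(state, params = state$params) {
  check_modality(params, "bulk_autocatalytic")
  m <- ifelse(state$initial_label == "bulk", params$bulk_multiplier, 1)
  step_bulk_core(state, params, m * params$k_E, m * params$k_N)
}

#' One day of exponential bulk degradation
#'
#' The modulus decays as `E0 * exp(-k_e * t)` homogeneously in all scaffold
#' elements; erosion at rate `k_N` begins once the modulus reaches 10% of
#' its initial value.
#'
#' @inheritParams step_surface_erosion
#' @export
step_exponential <- function(state, params = state$params) {
  check_modality(params, "exponential")
  n <- length(state$E)
  step_bulk_core(state, params, rep(params$k_e, n), rep(params$k_N, n),
                 expo = TRUE)
}

#' Analytic degradation milestone calendar
#'
#' Closed-form calendar of the degradation events. A milestone "day X" is the
#' first integer day at or after the continuous-time crossing (ceiling).
#' Linear erosion onset is at `(E0 - 0.1 E0) / rate`; exponential onset at
#' `ln(10) / k_e`; erosion takes `N0 / k_N` per element once started; a
#' surface-eroding strut of width w columns takes `(w/2) * N0 / k_N` in
#' total (two fronts). Rates of zero yield an `Inf` ("never") sentinel.
#'
#' @param params a [degradation_params()].
#' @param layout a [scaffold_layout()].
#' @return object of class `milestone_report`: a list with (per modality,
#'   `NA` where not applicable) `erosion_onset_day_surface`,
#'   `erosion_onset_day_bulk`, `bulk_complete_day`,
#'   `first_surface_layer_complete_day`, `full_degradation_day`.
#' @export
milestones <- function(params, layout) {
  never <- Inf
  r <- list(erosion_onset_day_surface = NA_real_,
            erosion_onset_day_bulk = NA_real_,
            bulk_complete_day = NA_real_,
            first_surface_layer_complete_day = NA_real_,
            full_degradation_day = NA_real_)
  widths <- lengths(layout$strut_cols)
  ceil_or_never <- function(t) if (is.finite(t)) ceiling(t) else never
  thr_drop <- (1 - params$onset_fraction) * params$E0

  if (params$modality == "surface_erosion") {
    if (params$k_N == 0) {
      r$first_surface_layer_complete_day <- never
      r$full_degradation_day <- never
    } else {
      first_layer <- ifelse(min(widths) >= 2,
                            params$N0 / params$k_N,
                            params$N0 / (2 * params$k_N))
      r$first_surface_layer_complete_day <- ceiling(first_layer)
      r$full_degradation_day <-
        ceiling(max(widths) / 2 * params$N0 / params$k_N)
    }
    r$erosion_onset_day_surface <- 0
  } else if (params$modality %in% c("bulk", "bulk_autocatalytic")) {
    m <- if (params$modality == "bulk_autocatalytic") params$bulk_multiplier else 1
    onset_s <- if (params$k_E > 0) thr_drop / params$k_E else never
    onset_b <- if (params$k_E > 0) thr_drop / (m * params$k_E) else never
    r$erosion_onset_day_surface <- ceil_or_never(onset_s)
    r$erosion_onset_day_bulk <- ceil_or_never(onset_b)
    full_s <- if (params$k_N > 0) onset_s + params$N0 / params$k_N else never
    full_b <- if (params$k_N > 0) onset_b + params$N0 / (m * params$k_N) else never
    r$bulk_complete_day <- if (m > 1) ceil_or_never(full_b) else ceil_or_never(full_s)
    r$full_degradation_day <- ceil_or_never(max(full_s, full_b))
  } else { # exponential
    onset <- if (params$k_e > 0) log(1 / params$onset_fraction) / params$k_e else never
    r$erosion_onset_day_surface <- ceil_or_never(onset)
    r$erosion_onset_day_bulk <- r$erosion_onset_day_surface
    full <- if (params$k_N > 0) onset + params$N0 / params$k_N else never
    r$full_degradation_day <- ceil_or_never(full)
  }
  structure(r, class = "milestone_report")
}

#' @export
print.milestone_report <- function(x, ...) {
  cat("<milestone_report>\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    lbl <- if (is.na(v)) "-" else if (is.infinite(v)) "never" else
      sprintf("day %d", as.integer(v))
    cat(sprintf("  %-34s %s\n", nm, lbl))
  }
  invisible(x)
}

#' Daily-stepped degradation trajectory and stepped milestones
#'
#' Steps the scaffold state day by day and records the trajectory of mean
#' material modulus and scaffold volume fraction, plus the milestone days
#' observed during stepping (the independent daily-stepping counterpart of
#' the analytic [milestones()] calendar).
#'
#' @param params a [degradation_params()].
#' @param layout a [scaffold_layout()].
#' @param days number of days to step.
#' @return list with `trajectory` (data frame: day, `mean_E` MPa over
#'   scaffold columns, `mean_N`, `defect_volume_fraction_pct` of the whole
#'   defect) and `stepped_milestones` (same fields as [milestones()]; `Inf`
#'   when not reached within `days`).
#' @export
degrade_trajectory <- function(params, layout, days) {
  state <- scaffold_state(layout, params)
  lat <- layout$lattice
  cols_per_strut <- lengths(layout$strut_cols)
  n_def <- lat$n_elements
  vf <- function(st) sum(st$N * lat$n_rows) / n_def * 100
  thr <- params$onset_fraction * params$E0
  out <- data.frame(day = 0:days, mean_E = NA_real_, mean_N = NA_real_,
                    defect_volume_fraction_pct = NA_real_)
  sm <- list(erosion_onset_day_surface = Inf, erosion_onset_day_bulk = Inf,
             bulk_complete_day = Inf, first_surface_layer_complete_day = Inf,
             full_degradation_day = Inf)
  first_layer_cols <- state$initial_label == "surface"
  bulk_cols <- state$initial_label == "bulk"
  record <- function(st, d) {
    if (params$modality == "surface_erosion") {
      if (d >= 1 && is.infinite(sm$erosion_onset_day_surface))
        sm$erosion_onset_day_surface <<- 0
    } else {
      if (is.infinite(sm$erosion_onset_day_surface) &&
          any(st$E[first_layer_cols] <= thr))
        sm$erosion_onset_day_surface <<- d
      if (any(bulk_cols) && is.infinite(sm$erosion_onset_day_bulk) &&
          any(st$E[bulk_cols] <= thr))
        sm$erosion_onset_day_bulk <<- d
    }
    if (any(bulk_cols) && is.infinite(sm$bulk_complete_day) &&
        all(st$N[bulk_cols] == 0))
      sm$bulk_complete_day <<- d
    if (params$modality %in% c("bulk", "exponential") &&
        is.infinite(sm$bulk_complete_day) && all(st$E == 0))
      sm$bulk_complete_day <<- d
    if (is.infinite(sm$first_surface_layer_complete_day) &&
        all(st$N[first_layer_cols] == 0))
      sm$first_surface_layer_complete_day <<- d
    if (is.infinite(sm$full_degradation_day) && all(st$N == 0))
      sm$full_degradation_day <<- d
  }
  for (d in 0:days) {
    if (d > 0) state <- degrade_step(state)
    out$mean_E[d + 1] <- mean(state$E)
    out$mean_N[d + 1] <- mean(state$N)
    out$defect_volume_fraction_pct[d + 1] <- vf(state)
    record(state, d)
  }
  if (params$modality == "exponential")
    sm$erosion_onset_day_bulk <- sm$erosion_onset_day_surface
  list(trajectory = out, stepped_milestones = sm)
}

#' Per-lattice-element scaffold fields
#'
#' Expands the per-column scaffold state onto the defect lattice.
#'
#' @param state a [scaffold_state()].
#' @return list of numeric vectors `E` and `N` over all lattice elements
#'   (zero outside the struts).
#' @export
scaffold_field <- function(state) {
  lat <- state$layout$lattice
  E <- numeric(lat$n_elements)
  N <- numeric(lat$n_elements)
  for (k in seq_along(state$col)) {
    idx <- which(lat$col == state$col[k])
    E[idx] <- state$E[k]
    N[idx] <- state$N[k]
  }
  list(E = E, N = N)
}
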
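#' Resistance-elastance tidal-volume grid
#'
#' Evaluates the predicted steady-state tidal volume (mL/kg) over a grid of
#' single-compartment mechanics (elastance on one axis, resistance on the
#' other) for a fixed ventilator setting and body weight. This is the
#' R-E contour map used to read off which mechanics land a patient in the
#' 6-8 mL/kg safe zone under a candidate shared setting. Cells are computed
#' with the exact square-wave closed form ([scm_vt_closed_form()]).
#'
#' @param settings A [vent_settings()] object (`rise_time` must be 0).
#' @param weight Body weight, kg.
#' @param e_range,r_range Axis ranges, cmH2O/L and cmH2O.s/L (default 1-50,
#'   the conventional screening range).
#' @param resolution Number of grid points per axis (default 200).
#' @return Object of class `re_grid`: list with `e_axis`, `r_axis`,
#'   `vt_matrix` (rows = resistance, cols = elastance, mL/kg), `weight`,
#'   `settings`.
#' @examples
#' g <- build_re_grid(vent_settings(17, 7, 15, "1:2"), weight = 65,
#'                    resolution = 50)
#' sum(classify_zone(g$vt_matrix)$zone == "green")
#' @export
build_re_grid <- function(settings, weight, e_range = c(1, 50),
                          r_range = c(1, 50), resolution = 200L) {
  stopifnot(inherits(settings, "vent_settings"), weight > 0,
            all(e_range > 0), all(r_range > 0), resolution >= 2L)
  if (settings$rise_time != 0)
    stop("R-E grids use the square-wave closed form; rise_time must be 0")
  tm <- breath_timing(settings)
  e_axis <- seq(e_range[1], e_range[2], length.out = resolution)
  r_axis <- seq(r_range[1], r_range[2], length.out = resolution)
  dP <- settings$PIP - settings$PEEP
  vt_L <- outer(r_axis, e_axis,
                function(R, E) vt_closed_form_num(E, R, dP, tm[["Ti"]], tm[["Te"]]))
  structure(
    list(e_axis = e_axis, r_axis = r_axis,
         vt_matrix = 1000 * vt_L / weight,
         weight = weight, settings = settings),
    class = "re_grid"
  )
}

#' @export
print.re_grid <- function(x, ...) {
  zones <- classify_zone(as.numeric(x$vt_matrix))$zone
  cat(sprintf("<re_grid> %dx%d cells, weight %g kg, E %g-%g, R %g-%g\n",
              length(x$r_axis), length(x$e_axis), x$weight,
              min(x$e_axis), max(x$e_axis), min(x$r_axis), max(x$r_axis)))
  cat(sprintf("  VT %.2f-%.2f mL/kg; %d green cells (%.1f%%)\n",
              min(x$vt_matrix), max(x$vt_matrix), sum(zones == "green"),
              100 * mean(zones == "green")))
  invisible(x)
}

#' @export
as.data.frame.re_grid <- function(x, ...) {
  d <- expand.grid(R_cmH2OsL = x$r_axis, E_cmH2OL = x$e_axis)
  d$VT_mlkg <- as.numeric(x$vt_matrix)
  d$zone <- classify_zone(d$VT_mlkg)$zone
  d
}

#' Plot an R-E tidal-volume map
#'
#' Filled image of predicted VT (mL/kg) over the elastance-resistance plane
#' with the 6 and 8 mL/kg safe-zone boundaries overlaid.
#'
#' @param x An `re_grid` from [build_re_grid()].
#' @param safe_band Tidal-volume band to outline, mL/kg (default `c(6, 8)`).
#' @param ... Passed on to [graphics::image()].
#' @return Invisibly, `x`.
#' @export
plot.re_grid <- function(x, safe_band = c(6, 8), ...) {
  pal <- grDevices::hcl.colors(64, "RdYlGn", rev = FALSE)
  graphics::image(x$e_axis, x$r_axis, t(x$vt_matrix), col = pal,
                  xlab = "Elastance E (cmH2O/L)", ylab = "Resistance R (cmH2O.s/L)",
                  main = sprintf("Predicted VT (mL/kg), %g kg", x$weight), ...)
  graphics::contour(x$e_axis, x$r_axis, t(x$vt_matrix), levels = safe_band,
                    add = TRUE, lwd = 2)
  invisible(x)
}

#' Classify tidal volumes into safety zones
#'
#' Maps predicted tidal volume (mL/kg) to the graded safe-zone colours of
#' the R-E map. The safe ("green") zone is the inclusive 6-8 mL/kg band.
#' The bands outside it are a reporting convention (only the green bound is
#' clinically standardised): by default yellow covers `[5,6)` and `(8,9.6]`,
#' orange `[4,5)` and `(9.6,11.2]`, red everything further out. A direction
#' flag records whether an out-of-band value is under- or over-ventilation.
#'
#' @param vt_ml_per_kg Numeric vector of tidal volumes, mL/kg (>= 0).
#' @param green Safe band, mL/kg (default `c(6, 8)`, inclusive).
#' @param under_steps Widths (mL/kg) of the yellow and orange bands below the
#'   safe zone (default `c(1, 1)`).
#' @param over_factors Multiplicative outer edges of the yellow and orange
#'   bands above the safe zone, as factors of the upper green bound
#'   (default `c(1.2, 1.4)`, i.e. 9.6 and 11.2 for a bound of 8).
#' @return Data frame with columns `vt_ml_per_kg`, `zone` (factor with
#'   levels green/yellow/orange/red) and `direction` (under/in-range/over).
#' @examples
#' classify_zone(c(7, 5.74, 8.5, 12, 0))
#' @export
classify_zone <- function(vt_ml_per_kg, green = c(6, 8),
                          under_steps = c(1, 1), over_factors = c(1.2, 1.4)) {
  vt <- as.numeric(vt_ml_per_kg)
  if (any(vt < 0, na.rm = TRUE)) stop("tidal volume must be >= 0")
  lo <- green[1]; hi <- green[2]
  y_lo <- lo - under_steps[1]; o_lo <- y_lo - under_steps[2]
  y_hi <- hi * over_factors[1]; o_hi <- hi * over_factors[2]
  direction <- ifelse(vt < lo, "under", ifelse(vt > hi, "over", "in-range"))
  zone <- ifelse(vt >= lo & vt <= hi, "green",
          ifelse((vt >= y_lo & vt < lo) | (vt > hi & vt <= y_hi), "yellow",
          ifelse((vt >= o_lo & vt < y_lo) | (vt > y_hi & vt <= o_hi), "orange",
                 "red")))
  data.frame(vt_ml_per_kg = vt,
             zone = factor(zone, levels = c("green", "yellow", "orange", "red")),
             direction = factor(direction, levels = c("under", "in-range", "over")),
             stringsAsFactors = FALSE)
}

#' Screen candidate patients for co-ventilation with an index patient
#'
#' Predicts each candidate's steady-state tidal volume (at the candidate's
#' own body weight) under the index patient's ventilator settings, classifies
#' it into safety zones, and flags as eligible the candidates whose VT falls
#' in the green 6-8 mL/kg band. Eligible candidates are ranked by closeness
#' of VT to the 7 mL/kg band midpoint, ties broken by elastance similarity to
#' the index patient.
#'
#' @param index A [patient_mechanics()] object (the already-ventilated
#'   patient whose settings are shared).
#' @param settings The index patient's [vent_settings()].
#' @param candidates List of [patient_mechanics()] objects.
#' @param limits [safety_limits()] supplying the green band.
#' @return Object of class `match_report`: list with `index_patient_id`,
#'   `index_vt_ml_per_kg`, and `candidates`, a data frame with columns `id`,
#'   `vt_ml_per_kg`, `zone`, `direction`, `eligible`, `rank` (NA when
#'   ineligible).
#' @examples
#' cohort <- preset_cohort()
#' screen_candidates(cohort$P1, vent_settings(17, 7, 15, "1:2"),
#'                   cohort[c("A", "B", "C", "D", "E")])
#' @export
screen_candidates <- function(index, settings, candidates,
                              limits = safety_limits()) {
  stopifnot(inherits(index, "patient_mechanics"), inherits(settings, "vent_settings"))
  green <- c(limits$vt_min, limits$vt_max)
  index_vt <- scm_tidal_volume(index, settings)$vt_ml_per_kg
  if (index_vt < green[1] || index_vt > green[2])
    warning(sprintf("index patient %s is outside the safe band itself (%.2f mL/kg)",
                    index$id, index_vt))
  if (length(candidates) == 0L) {
    tab <- data.frame(id = character(), vt_ml_per_kg = numeric(),
                      zone = character(), direction = character(),
                      eligible = logical(), rank = integer(),
                      stringsAsFactors = FALSE)
  } else {
    vt <- vapply(candidates, function(p) scm_tidal_volume(p, settings)$vt_ml_per_kg,
                 numeric(1))
    z <- classify_zone(vt, green = green)
    eligible <- z$zone == "green"
    tab <- data.frame(id = vapply(candidates, `[[`, character(1), "id"),
                      vt_ml_per_kg = vt,
                      zone = as.character(z$zone),
                      direction = as.character(z$direction),
                      eligible = eligible,
                      rank = NA_integer_,
                      stringsAsFactors = FALSE)
    if (any(eligible)) {
      mid <- mean(green)
      e_cand <- vapply(candidates, `[[`, numeric(1), "E")
      key1 <- abs(vt - mid)
      key2 <- abs(e_cand - index$E)
      idx <- which(eligible)
      tab$rank[idx[order(key1[idx], key2[idx])]] <- seq_along(idx)
    }
    rownames(tab) <- NULL
  }
  structure(list(index_patient_id = index$id, index_vt_ml_per_kg = index_vt,
                 settings = settings, candidates = tab),
            class = "match_report")
}

#' @export
print.match_report <- function(x, ...) {
  cat(sprintf("<match_report> index %s (VT %.2f mL/kg)\n",
              x$index_patient_id, x$index_vt_ml_per_kg))
  print(x$candidates, row.names = FALSE)
  invisible(x)
}

#' Series-resistor correction to pull tidal volume into the safe band
#'
#' An adjustable resistor in a patient's inspiratory limb adds series
#' resistance, which can only lower the delivered tidal volume. Given a
#' patient whose predicted VT exceeds the band, this finds (by bisection on
#' the square-wave closed form, to 0.01 cmH2O.s/L) the minimal added
#' resistance that brings VT down to at most the upper bound. Patients
#' already in the band need no resistor; patients below the band cannot be
#' helped by one.
#'
#' @param patient A [patient_mechanics()] object.
#' @param settings A [vent_settings()] object (square wave).
#' @param target Tidal-volume band `c(vt_min, vt_max)` in mL/kg (default 6-8).
#' @param precision Resolution of the returned resistance, cmH2O.s/L
#'   (default 0.01).
#' @return Object of class `resistor_adjustment`: list with `status` (one of
#'   `"adjusted"`, `"none-needed"`, `"infeasible"`), `delta_R` (cmH2O.s/L;
#'   0 when none needed, NA when infeasible), `vt_before` and `vt_after`
#'   (mL/kg).
#' @examples
#' resistor_adjustment(patient_mechanics("A", 18, 12, 50),
#'                     vent_settings(17, 7, 15, "1:2"))
#' @export
resistor_adjustment <- function(patient, settings, target = c(6, 8),
                                precision = 0.01) {
  stopifnot(inherits(patient, "patient_mechanics"), inherits(settings, "vent_settings"),
            target[1] < target[2])
  tm <- breath_timing(settings)
  dP <- settings$PIP - settings$PEEP
  vt_at <- function(dR) {
    1000 * vt_closed_form_num(patient$E, patient$R + dR, dP,
                              tm[["Ti"]], tm[["Te"]]) / patient$weight
  }
  vt0 <- vt_at(0)
  if (vt0 < target[1]) {
    out <- list(status = "infeasible", delta_R = NA_real_,
                vt_before = vt0, vt_after = vt0)
  } else if (vt0 <= target[2]) {
    out <- list(status = "none-needed", delta_R = 0,
                vt_before = vt0, vt_after = vt0)
  } else {
    hi <- 1
    while (vt_at(hi) > target[2]) hi <- hi * 2  # VT -> 0 as R -> Inf: terminates
    lo <- 0
    while (hi - lo > precision / 2) {
      mid <- (lo + hi) / 2
      if (vt_at(mid) > target[2]) lo <- mid else hi <- mid
    }
    dR <- ceiling(hi / precision) * precision  # round up so VT stays in band
    out <- list(status = "adjusted", delta_R = dR,
                vt_before = vt0, vt_after = vt_at(dR))
  }
  structure(out, class = "resistor_adjustment")
}

#' @export
print.resistor_adjustment <- function(x, ...) {
  cat(sprintf("<resistor_adjustment> %s: VT %.2f -> %.2f mL/kg",
              x$status, x$vt_before, x$vt_after))
  if (x$status == "adjusted") cat(sprintf(" (added R = %.2f cmH2O.s/L)", x$delta_R))
  cat("\n")
  invisible(x)
}
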
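#' Severity profiles for virtual-patient generation
#'
#' Ranges of respiratory elastance and resistance by respiratory-failure
#' severity, matching the literature-based ranges used for the reference
#' virtual cohort: Normal (E 15-22, R 10-15), Mild (E 18-27, R 9-14),
#' Moderate (E 20-32, R 10-14), Obstructive (E 13-23, R 16-33) and Severe
#' (E 22-33, R 9-14), in cmH2O/L and cmH2O.s/L.
#'
#' @return Data frame with columns `label`, `e_min`, `e_max`, `r_min`,
#'   `r_max`.
#' @export
severity_profiles <- function() {
  data.frame(
    label = c("Normal", "Mild", "Moderate", "Obstructive", "Severe"),
    e_min = c(15, 18, 20, 13, 22),
    e_max = c(22, 27, 32, 23, 33),
    r_min = c(10, 9, 10, 16, 9),
    r_max = c(15, 14, 14, 33, 14),
    stringsAsFactors = FALSE
  )
}

#' Reference virtual cohort
#'
#' The six virtual patients of the worked co-ventilation example: index
#' Patient 1 (mild respiratory failure, E = 20, R = 10, 65 kg) and
#' candidates A-E spanning normal to severe and obstructive mechanics. Each
#' entry uses the mean E and R of its severity range.
#'
#' @return Named list of [patient_mechanics()] objects
#'   (`P1`, `A`, `B`, `C`, `D`, `E`).
#' @examples
#' preset_cohort()$P1
#' @export
preset_cohort <- function() {
  list(
    P1 = patient_mechanics("P1", E = 20, R = 10, weight = 65, severity = "Mild"),
    A  = patient_mechanics("A",  E = 18, R = 12, weight = 50, severity = "Normal"),
    B  = patient_mechanics("B",  E = 25, R = 12, weight = 65, severity = "Moderate"),
    C  = patient_mechanics("C",  E = 18, R = 9,  weight = 80, severity = "Mild"),
    D  = patient_mechanics("D",  E = 15, R = 22, weight = 65, severity = "Obstructive"),
    E  = patient_mechanics("E",  E = 30, R = 11, weight = 100, severity = "Severe")
  )
}

#' Reference index-patient ventilator settings
#'
#' The pressure-control setting the index patient of the reference cohort is
#' ventilated on: PIP 17, PEEP 7 cmH2O, RR 15 breaths/min, I:E 1:2.
#'
#' @return A [vent_settings()] object.
#' @export
preset_settings <- function() {
  vent_settings(PIP = 17, PEEP = 7, RR = 15, IE = "1:2")
}

# run code under a local, seeded RNG without disturbing the global stream
with_local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Draw a random virtual patient from a severity profile
#'
#' Samples elastance and resistance uniformly within the profile's ranges
#' and weight uniformly within `weight_range`; reproducible for a fixed
#' seed. Intended for property tests and synthetic cohorts.
#'
#' @param profile A severity label (row of [severity_profiles()]) or a
#'   one-row data frame with `e_min`, `e_max`, `r_min`, `r_max` (and
#'   optionally `label`).
#' @param weight_range Weight range in kg (default `c(50, 100)`).
#' @param seed Optional integer seed (the global RNG state is preserved).
#' @param id Patient identifier (default derived from the label).
#' @return A [patient_mechanics()] object.
#' @examples
#' random_patient("Mild", seed = 42)
#' @export
random_patient <- function(profile, weight_range = c(50, 100), seed = NULL,
                           id = NULL) {
  if (is.character(profile)) {
    sp <- severity_profiles()
    row <- sp[sp$label == profile, , drop = FALSE]
    if (nrow(row) != 1L)
      stop("unknown severity profile: ", profile,
           " (expected one of ", paste(sp$label, collapse = ", "), ")")
    profile <- row
  }
  stopifnot(is.data.frame(profile), nrow(profile) == 1L)
  label <- if ("label" %in% names(profile)) profile$label else "custom"
  with_local_seed(seed, {
    E <- stats::runif(1, profile$e_min, profile$e_max)
    R <- stats::runif(1, profile$r_min, profile$r_max)
    w <- stats::runif(1, weight_range[1], weight_range[2])
    patient_mechanics(
      id = if (is.null(id)) sprintf("%s-%06d", label, sample.int(999999L, 1)) else id,
      E = E, R = R, weight = w, severity = label
    )
  })
}

#' Simulated breath waveform with measurement noise
#'
#' Simulates the single-compartment model for the given patient and adds
#' i.i.d. Gaussian noise to the pressure channel only (flow and volume stay
#' clean), emulating airway-pressure measurement noise. With noise on the
#' regressand only, the least-squares identification in
#' [identify_mechanics()] stays unbiased in expectation.
#'
#' @param patient A [patient_mechanics()] object.
#' @param settings A [vent_settings()] object.
#' @param noise_sd Pressure noise standard deviation, cmH2O (>= 0).
#' @param seed Optional integer seed (the global RNG state is preserved).
#' @param n_cycles Breaths to simulate (default 3).
#' @param dt Sampling step, s.
#' @return A [breath_waveform()].
#' @examples
#' wf <- noisy_waveform(patient_mechanics("P1", 20, 10, 65),
#'                      vent_settings(17, 7, 15, "1:2"),
#'                      noise_sd = 0.5, seed = 1)
#' identify_mechanics(wf)
#' @export
noisy_waveform <- function(patient, settings, noise_sd = 0.5, seed = NULL,
                           n_cycles = 3L, dt = 0.001) {
  stopifnot(noise_sd >= 0)
  wf <- simulate_scm(patient, settings, dt = dt, n_cycles = n_cycles)
  if (noise_sd > 0) {
    wf$pressure <- wf$pressure +
      with_local_seed(seed, stats::rnorm(length(wf$pressure), 0, noise_sd))
  }
  wf
}

#' Generate a synthetic cohort
#'
#' Draws `n` virtual patients across the severity profiles (cycled in
#' order), reproducibly for a fixed seed.
#'
#' @param n Number of patients.
#' @param seed Optional integer seed.
#' @param weight_range Weight range in kg.
#' @return Named list of [patient_mechanics()] objects.
#' @export
synthetic_cohort <- function(n, seed = NULL, weight_range = c(50, 100)) {
  sp <- severity_profiles()
  with_local_seed(seed, {
    out <- lapply(seq_len(n), function(i) {
      row <- sp[((i - 1L) %% nrow(sp)) + 1L, , drop = FALSE]
      random_patient(row, weight_range = weight_range, id = sprintf("S%03d", i))
    })
    names(out) <- vapply(out, `[[`, character(1), "id")
    out
  })
}
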
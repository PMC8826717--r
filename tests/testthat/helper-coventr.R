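# shared fixtures: the reference cohort and index settings
ref_cohort <- preset_cohort()
ref_settings <- preset_settings()
ref_candidates <- ref_cohort[c("A", "B", "C", "D", "E")]

# random but physiologic patient/settings draws for property tests
draw_patient <- function(i) {
  patient_mechanics(sprintf("rp%d", i),
                    E = stats::runif(1, 5, 50),
                    R = stats::runif(1, 2, 40),
                    weight = stats::runif(1, 50, 100))
}

draw_settings <- function() {
  peep <- stats::runif(1, 5, 12)
  vent_settings(PIP = peep + stats::runif(1, 6, 18), PEEP = peep,
                RR = stats::runif(1, 12, 20),
                IE = stats::runif(1, 2, 5))
}
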
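# Shared fixtures: analytic single-compartment patients and small helpers.

# linear RC patient with tau = R * C = 0.5 s
rc_patient <- function(resistance = 10, compliance = 0.05) {
  linear_single_compartment_patient(resistance = resistance,
                                    compliance = compliance)
}

# a moderate-ARDS-like patient from the distribution encoding
ards_patient <- function() {
  g <- c(0.30, 6, 4, 27.5, 1, 0.15, 0.4, 17, 5, 60, 10,
         0.8, 225, 120, 1.5, 100)
  decode_virtual_patient(g, "distribution")
}
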
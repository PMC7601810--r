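# Shared fixtures: small, fast synthetic inputs built in code.

# One-compartment "high-fidelity" stand-in: exact model trajectory with
# optional relative Gaussian noise. Fast enough for design-loop tests where
# the cellular automaton would dominate the runtime.
fake_hf_1c <- function(beta = 0.14, noise = 0, seed = 1,
                       pretreat = default_pretreatment_1c(),
                       schedule = build_schedule(), days = 1:57) {
  set.seed(seed)
  p <- params_one_compartment(pretreat$A, pretreat$B)
  tr <- simulate_one_compartment(p, radiosensitivity(0.14, beta), schedule,
                                 pretreat$V0, days)
  if (noise > 0)
    tr$tumor_volume <- tr$tumor_volume *
      (1 + rnorm(nrow(tr), sd = noise))
  tr
}

# Two-compartment stand-in, with both metrics.
fake_hf_2c <- function(beta = 0.14, noise = 0, seed = 1,
                       pretreat = default_pretreatment_2c(),
                       schedule = build_schedule(), days = 1:57) {
  set.seed(seed)
  p <- params_two_compartment(pretreat$lambda, pretreat$K, pretreat$eta,
                              pretreat$zeta)
  tr <- simulate_two_compartment(p, radiosensitivity(0.14, beta), schedule,
                                 pretreat$V0, pretreat$N0, days)
  if (noise > 0) {
    tr$tumor_volume <- tr$tumor_volume * (1 + rnorm(nrow(tr), sd = noise))
    tr$necrotic_volume <- pmax(
      tr$necrotic_volume * (1 + rnorm(nrow(tr), sd = noise)), 0)
  }
  tr
}

# Tiny CA configuration for unit tests.
tiny_ca <- function(...) {
  ca_params(lattice_n = 60, ...)
}
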
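# Shared fixtures: everything is built in code, nothing read from disk.

FOUR_STATE_KIN <- c(kex_FI1 = 784, kex_FI2 = 406, kex_I1I2 = 1600,
                    kex_I1U = 11000, p_I1 = 0.0027, p_I2 = 0.0083,
                    p_U = 0.0016)

four_state_network <- function(temperature_c = 10)
  make_ff_model("four_state", FOUR_STATE_KIN, temperature_c = temperature_c)

# Multiplicative +/-frac perturbation of a named numeric vector.
perturb <- function(v, frac = 0.3) v * (1 + runif(length(v), -frac, frac))

# Perturb a truth parameter list into fit initials.
perturbed_initials <- function(truth, frac = 0.3, seed = 42) {
  set.seed(seed)
  list(kinetics = perturb(truth$kinetics, frac),
       spins = lapply(truth$spins, function(s) {
         s$dw <- perturb(s$dw, frac)
         s
       }))
}

# A random detailed-balanced network + spin for property tests.
random_network <- function() {
  p_minor <- runif(3, 1e-3, 0.05)
  kin <- c(kex_FI1 = runif(1, 50, 2000), kex_FI2 = runif(1, 50, 2000),
           kex_I1I2 = runif(1, 100, 5000), kex_I1U = runif(1, 500, 2e4),
           p_I1 = p_minor[1], p_I2 = p_minor[2], p_U = p_minor[3])
  make_ff_model("four_state", kin, temperature_c = 10)
}

random_spin <- function() {
  spin_system("X15N", "15N", omega_ppm = 119 + runif(1, -3, 3),
              delta_omega = c(I1 = runif(1, -8, 8), I2 = runif(1, -8, 8),
                              U = runif(1, -8, 8)),
              r1 = runif(1, 1, 3), r2 = runif(1, 10, 40))
}

default_experiment <- function(b1_hz = 52.1, n = 61, span_ppm = 14,
                               temperature_c = 10) {
  lim <- ppm_to_hz(span_ppm, "15N", 700)
  cest_experiment(b1_hz = b1_hz, tex_s = 0.4, sfrq_mhz = 700,
                  carrier_ppm = 119,
                  offsets_hz = seq(-lim, lim, length.out = n),
                  temperature_c = temperature_c)
}
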
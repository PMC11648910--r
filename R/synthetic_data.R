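# Ground-truth scenarios and seeded synthetic CEST datasets.
#
# Scenario parameters are the study conditions the package is validated
# under: published two- and four-state exchange parameters for a small
# helical domain folding via two intermediates (I1, I2) plus the unfolded
# state (U), and a urea series constructed from published m-values.

# Default offset grid: 61 points over +/- 14 ppm about the carrier (15N),
# wide enough to contain every dip of the four-state scenarios.
.default_offsets_hz <- function(nucleus, sfrq_mhz, span_ppm = 14,
                                n = 61) {
  seq(-ppm_to_hz(span_ppm, nucleus, sfrq_mhz),
      ppm_to_hz(span_ppm, nucleus, sfrq_mhz), length.out = n)
}

# Scenario A kinetic truth (four-state fit, no additive, 10 C).
.SCEN_A_KIN <- c(kex_FI1 = 784, kex_FI2 = 406, kex_I1I2 = 1600,
                 kex_I1U = 11000, p_I1 = 0.0027, p_I2 = 0.0083,
                 p_U = 0.0016)

# State and transition-state m-values (kJ mol^-1 M^-1) used to build the
# urea series of Scenario D.  The I1-I2 transition-state value is a
# documented placeholder (no published number).
.SCEN_D_M_STATE <- c(U = 6.6, I1 = 2.8, I2 = -0.1)
.SCEN_D_M_TS <- c(TS_UI1 = 4.0, TS_I1I2 = 1.0, TS_I1F = 2.1, TS_I2F = 0.3)

# Four-state networks along a urea grid: anchor free energies at 0 M come
# from the Scenario A parameters (the slopes, which are what the m-value
# analysis measures, are independent of the anchors), each state's
# delta G varies as dG(urea) = dG(0) - m * urea, and each edge's exchange
# rate follows from the transition-state free energy with prefactor C.
.scenario_d_networks <- function(urea = seq(0, 1, by = 0.2),
                                 temperature_c = 2.5, prefactor_c = 1e7) {
  rt <- .R_GAS * (temperature_c + 273.15) / 1000  # kJ/mol
  anchor <- make_ff_model("four_state", .SCEN_A_KIN,
                          temperature_c = temperature_c)
  p0 <- anchor$populations
  dg0 <- -rt * log(p0[c("I1", "I2", "U")] / p0[["F"]])
  # anchor microscopic rates away from F on each edge (K side: U, I1, I2)
  k_side <- list(TS_UI1 = c("U", "I1"), TS_I1I2 = c("I1", "I2"),
                 TS_I1F = c("I1", "F"), TS_I2F = c("I2", "F"))
  edge_of <- list(TS_UI1 = c("I1", "U"), TS_I1I2 = c("I1", "I2"),
                  TS_I1F = c("F", "I1"), TS_I2F = c("F", "I2"))
  dg_ts0 <- vapply(names(k_side), function(ts) {
    kk <- k_side[[ts]]
    e <- edge_of[[ts]]
    kex <- anchor$edges$kex[anchor$edges$from == e[1] &
                              anchor$edges$to == e[2]]
    mk <- microscopic_rates(kex, p0[[kk[1]]], p0[[kk[2]]])
    dg0_k <- if (kk[1] == "F") 0 else dg0[[kk[1]]]
    dg0_k - rt * log(mk[["k_ab"]] / prefactor_c)
  }, 0)
  lapply(urea, function(u) {
    dg <- dg0 - .SCEN_D_M_STATE[c("U", "I1", "I2")][names(dg0)] * u
    ratio <- exp(-dg / rt)                       # p_K / p_F
    p_f <- 1 / (1 + sum(ratio))
    p <- ratio * p_f
    dg_ts <- dg_ts0 - .SCEN_D_M_TS[names(dg_ts0)] * u
    kex_of <- function(ts) {
      kk <- k_side[[ts]]
      dg_k <- if (kk[1] == "F") 0 else dg[[kk[1]]]
      k_kl <- prefactor_c * exp((dg_k - dg_ts[[ts]]) / rt)
      p_k <- if (kk[1] == "F") p_f else p[[kk[1]]]
      p_l <- if (kk[2] == "F") p_f else p[[kk[2]]]
      k_kl * (1 + p_k / p_l)                     # kex = k_KL (1 + pK/pL)
    }
    kin <- c(kex_FI1 = kex_of("TS_I1F"), kex_FI2 = kex_of("TS_I2F"),
             kex_I1I2 = kex_of("TS_I1I2"), kex_I1U = kex_of("TS_UI1"),
             p_I1 = p[["I1"]], p_I2 = p[["I2"]], p_U = p[["U"]])
    list(urea = u,
         network = make_ff_model("four_state", kin,
                                 temperature_c = temperature_c))
  })
}

#' Ground-truth study scenarios
#'
#' Returns one of the four validation scenarios the synthetic-data module
#' emulates (parameters as published for the A17G FF domain system):
#'
#' * `"A"` -- four-state folding network (F, I1, I2, U) at 10 C, 15N CEST
#'   at B1 = 26, 52.1, 104.1, 208.3 Hz, T_EX = 0.4 s, 16.4 T:
#'   kex_FI1 = 784, kex_FI2 = 406, kex_I1I2 = 1600, kex_I1U = 11000 s^-1,
#'   p_I1 = 0.27\%, p_I2 = 0.83\%, p_U = 0.16\%.
#' * `"B"` -- two-state F/I2 exchange in 20\% glucose at 20 C
#'   (kex_FI2 = 587 s^-1, p_I2 = 2.1\%), B1 = 26.4, 52.9 Hz.
#' * `"C"` -- two-state F/I2 exchange for the S56P variant in 30\% glucose
#'   at 20 C (kex_FI2 = 41.4 s^-1, p_I2 = 27.2\%).
#' * `"D"` -- urea series at 2.5 C: four-state networks on a 0 to 1 M grid
#'   built from state m-values (U 6.6, I1 2.8, I2 -0.1 kJ mol^-1 M^-1)
#'   and transition-state m-values (TS_UI1 4.0, TS_I1F 2.1, TS_I2F 0.3;
#'   TS_I1I2 set to 1.0 as a placeholder), anchored at the Scenario A
#'   parameters at 0 M.
#'
#' @param name scenario name, `"A"`, `"B"`, `"C"` or `"D"`.
#' @return an object of class `cest_scenario`: list with `name`, `level`,
#'   `kinetics`, `temperature_c`, experiment settings (`b1_hz`, `tex_s`,
#'   `sfrq_mhz`, `carrier_ppm`, `nucleus`) and, for `"D"`, `urea_points`
#'   (per-urea networks) and the ground-truth `m_values`.
#' @export
cest_scenario <- function(name = c("A", "B", "C", "D")) {
  name <- match.arg(name)
  base <- list(name = name, nucleus = "15N", sfrq_mhz = 700,
               carrier_ppm = 119, tex_s = 0.4)
  sc <- switch(name,
    A = c(base, list(level = "four_state", kinetics = .SCEN_A_KIN,
                     temperature_c = 10,
                     b1_hz = c(26, 52.1, 104.1, 208.3))),
    B = c(base, list(level = "two_state",
                     kinetics = c(kex_FI2 = 587, p_I2 = 0.021),
                     temperature_c = 20, b1_hz = c(26.4, 52.9))),
    C = c(base, list(level = "two_state",
                     kinetics = c(kex_FI2 = 41.4, p_I2 = 0.272),
                     temperature_c = 20, b1_hz = c(26.4, 52.9))),
    D = c(base, list(level = "four_state", kinetics = .SCEN_A_KIN,
                     temperature_c = 2.5, b1_hz = c(26, 52.1),
                     urea_points = .scenario_d_networks(),
                     m_values = list(states = .SCEN_D_M_STATE,
                                     transition_states = .SCEN_D_M_TS))))
  structure(sc, class = "cest_scenario")
}

#' @export
print.cest_scenario <- function(x, ...) {
  cat(sprintf("<cest_scenario %s> %s, %g C, B1 = %s Hz\n", x$name, x$level,
              x$temperature_c, paste(x$b1_hz, collapse = "/")))
  invisible(x)
}

#' Deterministic synthetic spin set
#'
#' Builds `n` spin systems for a given exchange level.  The first spins
#' are fixed "reporters" with large, distinct shift differences for every
#' minor state (>= 2 ppm for 15N) so all minor-state dips are
#' identifiable; for four-state networks one spin has nearly coincident
#' I1 and U shift differences to emulate the merged dip produced by rapid
#' I1/U interconversion.  Remaining spins draw their shift differences
#' uniformly from `dw_range` (seeded).
#'
#' @param n number of spins (>= 1).
#' @param minor_states minor-state labels needing a delta_omega, e.g.
#'   `c("I1", "I2", "U")`.
#' @param nucleus nucleus type.
#' @param dw_range length-2 range (ppm) for the randomized shift
#'   differences.
#' @param carrier_ppm centre of the major-state shift distribution.
#' @param seed RNG seed; identical seeds give identical spin sets.
#' @param r1,r2 relaxation rates assigned to every spin (s^-1).
#' @return list of [spin_system()] objects.
#' @export
make_spin_set <- function(n, minor_states, nucleus = "15N",
                          dw_range = c(-8, 8), carrier_ppm = 119,
                          seed = 1, r1 = 2.0, r2 = 20.0) {
  stopifnot(n >= 1, length(minor_states) >= 1)
  if (diff(range(dw_range)) <= 0) stop("'dw_range' must be a proper range")
  set.seed(seed)
  reporters <- list(
    c(I1 = -4.0, I2 = 3.5, U = -6.5),
    c(I1 = 2.6, I2 = -4.5, U = 5.8),
    c(I1 = -5.0, I2 = 1.4, U = -4.7))  # merged I1/U dip (within 0.5 ppm)
  spins <- vector("list", n)
  for (i in seq_len(n)) {
    if (i <= length(reporters)) {
      dw <- pmin(pmax(reporters[[i]][minor_states], dw_range[1]),
                 dw_range[2])
    } else {
      dw <- setNames(runif(length(minor_states), dw_range[1], dw_range[2]),
                     minor_states)
    }
    names(dw) <- minor_states
    spins[[i]] <- spin_system(
      spin_id = sprintf("S%02d%s", i, sub("^[0-9]+", "", nucleus)),
      nucleus = nucleus,
      omega_ppm = carrier_ppm + runif(1, -3, 3),
      delta_omega = dw, r1 = r1, r2 = r2)
  }
  spins
}

#' Generate a synthetic CEST dataset for a scenario
#'
#' Forward-simulates one profile per (spin, B1 field) under the scenario's
#' exchange network and optionally adds Gaussian intensity noise of
#' standard deviation `noise_sd` (as a fraction of I0).  Reproducible:
#' identical `(scenario, spins, noise_sd, seed)` give identical data.
#'
#' @param scenario a [cest_scenario()] (for `"D"` supply `urea` to pick a
#'   point of the series).
#' @param spins list of [spin_system()] objects (see [make_spin_set()]).
#' @param noise_sd Gaussian noise SD as a fraction of I0 (>= 0; 0 gives
#'   exact forward simulations with no errors attached).
#' @param seed RNG seed for the noise.
#' @param offsets_hz RF offset grid; default 61 points over +/- 14 ppm.
#' @param urea urea concentration selecting a Scenario D point.
#' @return list with `profiles` (list of [cest_profile()]) and `truth`
#'   (the generating `level`, `kinetics`, `temperature_c` and per-spin
#'   parameters, for recovery testing).
#' @export
generate_profiles <- function(scenario, spins, noise_sd = 0, seed = 1,
                              offsets_hz = NULL, urea = NULL) {
  stopifnot(inherits(scenario, "cest_scenario"))
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (is.null(offsets_hz))
    offsets_hz <- .default_offsets_hz(scenario$nucleus, scenario$sfrq_mhz)
  if (scenario$name == "D") {
    if (is.null(urea)) stop("Scenario D needs a 'urea' concentration")
    idx <- which(vapply(scenario$urea_points, `[[`, 0, "urea") == urea)
    if (length(idx) != 1) stop("no Scenario D point at urea = ", urea)
    network <- scenario$urea_points[[idx]]$network
    kinetics <- c(setNames(network$edges$kex,
                           paste0("kex_", network$edges$from,
                                  network$edges$to)),
                  setNames(network$populations[c("I1", "I2", "U")],
                           c("p_I1", "p_I2", "p_U")))
  } else {
    network <- make_ff_model(scenario$level, scenario$kinetics,
                             temperature_c = scenario$temperature_c)
    kinetics <- scenario$kinetics
  }
  set.seed(seed)
  profiles <- list()
  for (spin in spins) {
    for (b1 in scenario$b1_hz) {
      ex <- cest_experiment(b1_hz = b1, tex_s = scenario$tex_s,
                            sfrq_mhz = scenario$sfrq_mhz,
                            carrier_ppm = scenario$carrier_ppm,
                            offsets_hz = offsets_hz,
                            temperature_c = scenario$temperature_c)
      pr <- simulate_profile(spin, network, ex)
      if (noise_sd > 0) {
        pr$intensities <- pr$intensities +
          rnorm(length(pr$intensities), 0, noise_sd)
        pr$errors <- rep(noise_sd, length(pr$intensities))
      }
      profiles[[length(profiles) + 1]] <- pr
    }
  }
  truth_spins <- lapply(spins, function(s)
    list(omega_ppm = s$omega_ppm, dw = s$delta_omega, r1 = s$r1,
         r2 = s$r2))
  names(truth_spins) <- vapply(spins, `[[`, "", "spin_id")
  list(profiles = profiles,
       truth = list(level = scenario$level, kinetics = kinetics,
                    temperature_c = scenario$temperature_c,
                    noise_sd = noise_sd, seed = seed,
                    spins = truth_spins))
}
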
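#' Convert a chemical shift from ppm to Hz
#'
#' @param shift_ppm chemical shift (or shift difference) in ppm.
#' @param nucleus nucleus label; one of `"15N"`, `"13C"`, `"1H"` or an
#'   alias (`"1HN"`, `"1HA"`, `"13CA"`, `"13CO"`, `"13CB"`, `"methyl-1H"`,
#'   `"methyl-13C"`).
#' @param sfrq_mhz spectrometer 1H frequency in MHz (e.g. 700 at 16.4 T).
#' @return frequency in Hz: `shift_ppm` times the Larmor frequency of the
#'   nucleus in MHz (1H frequency scaled by the relative gyromagnetic
#'   ratio).
#' @examples
#' ppm_to_hz(1, "15N", 700)  # 70.957 Hz
#' @export
ppm_to_hz <- function(shift_ppm, nucleus, sfrq_mhz) {
  base <- .NUCLEUS_BASE[nucleus]
  if (any(is.na(base)))
    stop("unknown nucleus: ",
         paste(unique(nucleus[is.na(base)]), collapse = ", "))
  shift_ppm * sfrq_mhz * unname(.GAMMA_REL[base])
}

#' Define a spin system for CEST simulation
#'
#' One nucleus in the molecule: its major-state chemical shift, the
#' chemical-shift differences \eqn{\Delta\varpi} to every minor state
#' (signed, minor minus major), and its relaxation rates.  The same R1 is
#' used for all states; R2 may be a single shared value or a named
#' per-state vector (minor states default to the major-state R2).
#'
#' @param spin_id label, e.g. `"S56N"`.
#' @param nucleus nucleus type, see [ppm_to_hz()].
#' @param omega_ppm major-state chemical shift (ppm).
#' @param delta_omega named numeric vector of \eqn{\Delta\varpi} (ppm) per
#'   minor state, e.g. `c(I1 = -4, I2 = 3.5, U = -6)`.
#' @param r1 longitudinal relaxation rate (s^-1), shared across states.
#' @param r2 transverse relaxation rate (s^-1); scalar (shared) or a named
#'   vector with an entry per state.
#' @return an object of class `spin_system`.
#' @export
spin_system <- function(spin_id, nucleus, omega_ppm, delta_omega,
                        r1 = 2.0, r2 = 20.0) {
  if (is.null(names(delta_omega)) || any(names(delta_omega) == ""))
    stop("'delta_omega' must be a named vector (one entry per minor state)")
  if (any(r1 <= 0) || any(r2 <= 0)) stop("R1 and R2 must be > 0")
  if (is.na(.NUCLEUS_BASE[nucleus])) stop("unknown nucleus: ", nucleus)
  structure(list(spin_id = spin_id, nucleus = nucleus,
                 omega_ppm = as.numeric(omega_ppm),
                 delta_omega = delta_omega, r1 = r1, r2 = r2),
            class = "spin_system")
}

#' Define a CEST experiment
#'
#' @param b1_hz saturation field strength (Hz), > 0.
#' @param tex_s saturation time (s), >= 0.
#' @param sfrq_mhz spectrometer 1H frequency (MHz).
#' @param carrier_ppm RF carrier position (ppm).
#' @param offsets_hz RF offsets relative to the carrier (Hz); finite and
#'   distinct.
#' @param temperature_c sample temperature (degrees Celsius).
#' @param b1_inhomogeneity relative standard deviation of the B1 field
#'   (0 = ideal field, the default).
#' @return an object of class `cest_experiment`.
#' @export
cest_experiment <- function(b1_hz, tex_s, sfrq_mhz, carrier_ppm, offsets_hz,
                            temperature_c = 25, b1_inhomogeneity = 0) {
  if (b1_hz <= 0) stop("'b1_hz' must be > 0")
  if (tex_s < 0) stop("'tex_s' must be >= 0")
  if (any(!is.finite(offsets_hz)) || anyDuplicated(offsets_hz))
    stop("'offsets_hz' must be finite and distinct")
  if (b1_inhomogeneity < 0) stop("'b1_inhomogeneity' must be >= 0")
  structure(list(b1_hz = b1_hz, tex_s = tex_s, sfrq_mhz = sfrq_mhz,
                 carrier_ppm = carrier_ppm,
                 offsets_hz = as.numeric(offsets_hz),
                 temperature_c = temperature_c,
                 b1_inhomogeneity = b1_inhomogeneity),
            class = "cest_experiment")
}

#' Bundle a measured or simulated CEST profile
#'
#' @param experiment a [cest_experiment()].
#' @param spin_id spin label the profile belongs to.
#' @param nucleus nucleus type of the spin.
#' @param intensities normalized intensities I/I0, one per offset.
#' @param errors optional per-point standard deviations (> 0).
#' @return an object of class `cest_profile`.
#' @export
cest_profile <- function(experiment, spin_id, nucleus, intensities,
                         errors = NULL) {
  stopifnot(inherits(experiment, "cest_experiment"))
  if (length(intensities) != length(experiment$offsets_hz))
    stop("'intensities' length must match the experiment's offsets")
  if (!is.null(errors)) {
    if (length(errors) != length(intensities))
      stop("'errors' length must match 'intensities'")
    if (any(errors <= 0)) stop("'errors' must be > 0 when present")
  }
  structure(list(experiment = experiment, spin_id = spin_id,
                 nucleus = nucleus,
                 intensities = as.numeric(intensities),
                 errors = if (is.null(errors)) NULL else as.numeric(errors)),
            class = "cest_profile")
}

# Per-state resonance offsets from the carrier, in Hz, ordered like the
# network states.  Minor-state shifts are omega_F + delta_omega.
.state_omega_hz <- function(spin, network, sfrq_mhz, carrier_ppm) {
  minors <- setdiff(network$states, network$states[1])
  missing <- setdiff(minors, names(spin$delta_omega))
  if (length(missing) > 0)
    stop("spin ", spin$spin_id, " has no delta_omega for state(s): ",
         paste(missing, collapse = ", "))
  ppm <- c(spin$omega_ppm,
           spin$omega_ppm + unname(spin$delta_omega[minors]))
  ppm_to_hz(ppm - carrier_ppm, spin$nucleus, sfrq_mhz)
}

# Per-state R1/R2 vectors for a spin simulated against a network.
.state_relaxation <- function(spin, network) {
  n <- length(network$states)
  r1 <- rep_len(unname(spin$r1), n)
  if (length(spin$r2) == 1) {
    r2 <- rep(unname(spin$r2), n)
  } else {
    r2 <- rep(unname(spin$r2["F"] %||% spin$r2[1]), n)
    named <- intersect(names(spin$r2), network$states)
    r2[match(named, network$states)] <- spin$r2[named]
  }
  list(r1 = r1, r2 = r2)
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

#' Assemble the Bloch-McConnell evolution matrix
#'
#' Builds the (3N+1) x (3N+1) evolution matrix for one spin, one RF offset
#' and one B1 field under an N-state exchange network.  Variables are
#' ordered `(Mx, My, Mz)` per state followed by a unit augmentation.  Each
#' Bloch block carries transverse relaxation (-R2), longitudinal
#' relaxation (-R1), the z-y RF nutation coupling (2 pi B1, RF phase along
#' x), and x-y precession at the state's offset from the RF in the
#' rotating frame; exchange couples like components of different states
#' with the microscopic rates; the augmented column carries the
#' \eqn{R_1 p_i} return-to-equilibrium terms (its row is all zeros), so
#' equilibrium magnetization is stationary when B1 = 0.
#'
#' @param spin a [spin_system()] defining `delta_omega` for every minor
#'   state of `network`.
#' @param network a [kinetic_network()].
#' @param experiment a [cest_experiment()] (supplies sfrq, carrier and,
#'   by default, B1).
#' @param offset_hz RF offset from the carrier (Hz).
#' @param b1_hz RF field strength (Hz); defaults to the experiment's.
#' @return square numeric matrix of dimension `3 * N + 1`.
#' @export
evolution_matrix <- function(spin, network, experiment, offset_hz,
                             b1_hz = experiment$b1_hz) {
  stopifnot(inherits(spin, "spin_system"),
            inherits(network, "kinetic_network"),
            inherits(experiment, "cest_experiment"))
  n <- length(network$states)
  omega_hz <- .state_omega_hz(spin, network, experiment$sfrq_mhz,
                              experiment$carrier_ppm)
  rel <- .state_relaxation(spin, network)
  K <- build_rate_matrix(network)
  p <- unname(network$populations)
  dim <- 3 * n + 1
  A <- matrix(0, dim, dim)
  w1 <- 2 * pi * b1_hz
  for (i in seq_len(n)) {
    xi <- 3 * i - 2; yi <- 3 * i - 1; zi <- 3 * i
    om <- 2 * pi * (omega_hz[i] - offset_hz)
    A[xi, xi] <- A[xi, xi] - rel$r2[i]
    A[yi, yi] <- A[yi, yi] - rel$r2[i]
    A[zi, zi] <- A[zi, zi] - rel$r1[i]
    A[xi, yi] <- A[xi, yi] - om
    A[yi, xi] <- A[yi, xi] + om
    A[yi, zi] <- A[yi, zi] + w1
    A[zi, yi] <- A[zi, yi] - w1
    A[zi, dim] <- rel$r1[i] * p[i]
    for (j in seq_len(n)) {
      A[xi, 3 * j - 2] <- A[xi, 3 * j - 2] + K[i, j]
      A[yi, 3 * j - 1] <- A[yi, 3 * j - 1] + K[i, j]
      A[zi, 3 * j]     <- A[zi, 3 * j]     + K[i, j]
    }
  }
  A
}

#' Propagate magnetization under a fixed evolution matrix
#'
#' Computes the matrix-exponential action `expm(A * tex) %*% v`.
#'
#' @param A square evolution matrix (e.g. from [evolution_matrix()]).
#' @param v initial magnetization vector, same dimension as `A`.
#' @param tex_s evolution time (s).
#' @return the propagated vector.
#' @export
propagate <- function(A, v, tex_s) {
  if (!is.matrix(A) || nrow(A) != ncol(A)) stop("'A' must be square")
  if (length(v) != nrow(A)) stop("dimension of 'v' does not match 'A'")
  if (tex_s == 0) return(as.numeric(v))
  as.numeric(cpp_expm_vec(A, tex_s, as.numeric(v)))
}

# Equilibrium initial condition (Mz_i = p_i, unit augmentation).
.equilibrium_vector <- function(network) {
  n <- length(network$states)
  v <- numeric(3 * n + 1)
  v[3 * seq_len(n)] <- unname(network$populations)
  v[3 * n + 1] <- 1
  v
}

#' Forward-simulate a CEST profile
#'
#' For each RF offset the spin's magnetization starts from equilibrium
#' (\eqn{M_{z,i} = p_i}), evolves for `tex_s` under saturation, and the
#' major-state longitudinal magnetization is read out and normalized by
#' its `tex_s = 0` value \eqn{p_F}, giving the familiar I/I0 dip profile.
#' If the experiment declares a nonzero `b1_inhomogeneity`, profiles are
#' averaged over 11 B1 values spanning +/- 2 SD with Gaussian weights.
#'
#' @inheritParams evolution_matrix
#' @return a [cest_profile()] (no errors attached).
#' @export
simulate_profile <- function(spin, network, experiment) {
  stopifnot(inherits(spin, "spin_system"),
            inherits(network, "kinetic_network"),
            inherits(experiment, "cest_experiment"))
  if (experiment$tex_s < 0) stop("'tex_s' must be >= 0")
  omega_hz <- .state_omega_hz(spin, network, experiment$sfrq_mhz,
                              experiment$carrier_ppm)
  rel <- .state_relaxation(spin, network)
  K <- build_rate_matrix(network)
  p <- unname(network$populations)
  sim_one <- function(b1) {
    as.numeric(cpp_cest_profile(experiment$offsets_hz, K, p, omega_hz,
                                rel$r1, rel$r2, b1, experiment$tex_s))
  }
  if (experiment$b1_inhomogeneity > 0) {
    sdv <- experiment$b1_inhomogeneity * experiment$b1_hz
    grid <- experiment$b1_hz + seq(-2, 2, length.out = 11) * sdv
    w <- stats::dnorm(grid, experiment$b1_hz, sdv)
    w <- w / sum(w)
    intens <- Reduce(`+`, Map(function(b, wt) wt * sim_one(b), grid, w))
  } else {
    intens <- sim_one(experiment$b1_hz)
  }
  cest_profile(experiment, spin$spin_id, spin$nucleus, intens)
}
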
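#' Construct a kinetic exchange network
#'
#' A kinetic network holds the states of an N-site exchange model, their
#' equilibrium populations, and the pairwise exchange rate constants
#' \eqn{k_{ex,JK} = k_{JK} + k_{KJ}} on the edges of the exchange topology.
#' Microscopic rates are never free quantities: they are always derived from
#' \eqn{k_{ex}} and the equilibrium populations so that detailed balance,
#' \eqn{p_J k_{JK} = p_K k_{KJ}}, holds on every edge by construction.
#'
#' @param states character vector of state labels; the first state is the
#'   observed major state.
#' @param populations numeric vector of fractional equilibrium populations,
#'   same length and order as `states`; must be strictly positive and sum
#'   to 1.
#' @param edges data.frame with columns `from`, `to`, `kex` giving the
#'   exchanged pairs (unordered; `from`/`to` is only a naming convention)
#'   and their exchange rate constants in s^-1.
#' @param temperature_k absolute temperature in Kelvin (used by the free
#'   energy analysis).
#'
#' @return An object of class `kinetic_network`: a list with elements
#'   `states`, `populations` (named), `edges`, `temperature_k`.
#' @seealso [build_rate_matrix()], [make_ff_model()], [microscopic_rates()]
#' @export
kinetic_network <- function(states, populations, edges, temperature_k = 298.15) {
  stopifnot(is.character(states), length(states) >= 1,
            !anyDuplicated(states))
  if (length(populations) != length(states))
    stop("'populations' must have one entry per state")
  bad <- populations <= 0
  if (any(bad))
    stop("nonpositive population for state(s): ",
         paste(states[bad], collapse = ", "))
  if (abs(sum(populations) - 1) > 1e-8)
    stop("populations must sum to 1 (got ", format(sum(populations)), ")")
  if (!is.data.frame(edges) || !all(c("from", "to", "kex") %in% names(edges)))
    stop("'edges' must be a data.frame with columns from, to, kex")
  unknown <- setdiff(c(edges$from, edges$to), states)
  if (length(unknown) > 0)
    stop("edge references unknown state label(s): ",
         paste(unique(unknown), collapse = ", "))
  if (any(edges$kex < 0)) stop("exchange rates must be >= 0")
  if (any(edges$from == edges$to)) stop("self-edges are not allowed")
  if (!is.numeric(temperature_k) || temperature_k <= 0)
    stop("'temperature_k' must be a positive temperature in Kelvin")
  structure(
    list(states = states,
         populations = setNames(as.numeric(populations), states),
         edges = data.frame(from = as.character(edges$from),
                            to = as.character(edges$to),
                            kex = as.numeric(edges$kex)),
         temperature_k = as.numeric(temperature_k)),
    class = "kinetic_network")
}

#' @export
print.kinetic_network <- function(x, ...) {
  cat(sprintf("<kinetic_network> %d states at %.2f K\n",
              length(x$states), x$temperature_k))
  cat("  populations:",
      paste(sprintf("%s=%.4g", x$states, x$populations), collapse = ", "),
      "\n")
  for (i in seq_len(nrow(x$edges)))
    cat(sprintf("  %s <-> %s  kex = %.4g s^-1\n",
                x$edges$from[i], x$edges$to[i], x$edges$kex[i]))
  invisible(x)
}

#' Decompose an exchange rate constant into microscopic rates
#'
#' Splits \eqn{k_{ex}} between two states into the forward and reverse
#' first-order rate constants using the equilibrium condition
#' \eqn{p_A k_{AB} = p_B k_{BA}}:
#' \deqn{k_{AB} = k_{ex} \frac{p_B}{p_A + p_B}, \qquad
#'       k_{BA} = k_{ex} \frac{p_A}{p_A + p_B}.}
#'
#' @param kex exchange rate constant \eqn{k_{AB} + k_{BA}} (s^-1), >= 0.
#' @param p_a,p_b equilibrium populations of the two states (> 0); only
#'   their ratio matters.
#' @param labels optional length-2 state labels used in error messages.
#' @return named numeric vector `c(k_ab, k_ba)` in s^-1.
#' @examples
#' microscopic_rates(406, 0.9874, 0.0083)  # slow F -> I2, fast I2 -> F
#' @export
microscopic_rates <- function(kex, p_a, p_b, labels = c("A", "B")) {
  if (kex < 0) stop("'kex' must be >= 0")
  if (p_a <= 0) stop("nonpositive population for state ", labels[1])
  if (p_b <= 0) stop("nonpositive population for state ", labels[2])
  tot <- p_a + p_b
  c(k_ab = kex * p_b / tot, k_ba = kex * p_a / tot)
}

#' Assemble the microscopic rate matrix of a network
#'
#' Builds the N x N first-order rate matrix `K` in the convention
#' `dp/dt = K %*% p`: the off-diagonal entry `K[i, j]` is the microscopic
#' rate from state j into state i, and each diagonal entry is minus the
#' total outflow of its column, so all columns sum to zero.  Because the
#' microscopic rates are derived from the equilibrium populations, the
#' population vector is always a stationary (null) vector of `K`.
#'
#' @param network a [kinetic_network()].
#' @return N x N numeric matrix (s^-1) with `dimnames` set to the state
#'   labels.
#' @export
build_rate_matrix <- function(network) {
  stopifnot(inherits(network, "kinetic_network"))
  st <- network$states
  n <- length(st)
  K <- matrix(0, n, n, dimnames = list(st, st))
  p <- network$populations
  ed <- network$edges
  for (i in seq_len(nrow(ed))) {
    a <- ed$from[i]; b <- ed$to[i]
    k <- microscopic_rates(ed$kex[i], p[[a]], p[[b]], labels = c(a, b))
    K[b, a] <- K[b, a] + k[["k_ab"]]
    K[a, a] <- K[a, a] - k[["k_ab"]]
    K[a, b] <- K[a, b] + k[["k_ba"]]
    K[b, b] <- K[b, b] - k[["k_ba"]]
  }
  K
}

# Kinetic parameter names required for each exchange model level.
.LEVELS <- list(
  two_state = list(
    states = c("F", "I2"),
    kex = c("kex_FI2"),
    pops = c("p_I2"),
    edges = data.frame(from = "F", to = "I2", kex_name = "kex_FI2")),
  three_state = list(
    states = c("F", "I1", "I2"),
    kex = c("kex_FI1", "kex_FI2", "kex_I1I2"),
    pops = c("p_I1", "p_I2"),
    edges = data.frame(from = c("F", "F", "I1"),
                       to = c("I1", "I2", "I2"),
                       kex_name = c("kex_FI1", "kex_FI2", "kex_I1I2"))),
  four_state = list(
    states = c("F", "I1", "I2", "U"),
    kex = c("kex_FI1", "kex_FI2", "kex_I1I2", "kex_I1U"),
    pops = c("p_I1", "p_I2", "p_U"),
    edges = data.frame(from = c("F", "F", "I1", "I1"),
                       to = c("I1", "I2", "I2", "U"),
                       kex_name = c("kex_FI1", "kex_FI2", "kex_I1I2",
                                    "kex_I1U")))
)

#' Build a folding exchange network from reported parameters
#'
#' Convenience constructor for the exchange models used for a folded domain
#' F exchanging with sparsely populated intermediates I1, I2 and the
#' unfolded state U.  The four-state topology has edges F-I1, F-I2, I1-I2
#' and I1-U (two folding pathways: U <-> I1 <-> F and U <-> I1 <-> I2 <-> F);
#' there is no direct F-U or I2-U exchange.  The major-state population is
#' computed as \eqn{p_F = 1 - \sum p_{minor}}.
#'
#' @param level one of `"two_state"` (states F, I2), `"three_state"`
#'   (F, I1, I2) or `"four_state"` (F, I1, I2, U).
#' @param params named numeric vector/list with the exchange rate constants
#'   (s^-1) and minor-state populations (fractions) for the level, e.g. for
#'   `four_state`: `kex_FI1`, `kex_FI2`, `kex_I1I2`, `kex_I1U`, `p_I1`,
#'   `p_I2`, `p_U`.
#' @param temperature_c sample temperature in degrees Celsius; stored on the
#'   network in Kelvin.
#' @return a validated [kinetic_network()].
#' @examples
#' make_ff_model("two_state", c(kex_FI2 = 587, p_I2 = 0.021),
#'               temperature_c = 20)
#' @export
make_ff_model <- function(level = c("two_state", "three_state", "four_state"),
                          params, temperature_c = 25) {
  level <- match.arg(level)
  spec <- .LEVELS[[level]]
  params <- unlist(params)
  need <- c(spec$kex, spec$pops)
  missing <- setdiff(need, names(params))
  if (length(missing) > 0)
    stop("missing parameter(s) for ", level, ": ",
         paste(missing, collapse = ", "))
  pops_minor <- params[spec$pops]
  if (any(pops_minor <= 0))
    stop("minor-state populations must be > 0")
  if (sum(pops_minor) >= 1)
    stop("minor-state populations sum to ", format(sum(pops_minor)),
         " >= 1; no population left for F")
  populations <- c(1 - sum(pops_minor), unname(pops_minor))
  edges <- data.frame(from = spec$edges$from, to = spec$edges$to,
                      kex = unname(params[spec$edges$kex_name]))
  kinetic_network(spec$states, populations, edges,
                  temperature_k = temperature_c + 273.15)
}

# Minor-state labels of an exchange level (every state but F).
.minor_states <- function(level) setdiff(.LEVELS[[level]]$states, "F")
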
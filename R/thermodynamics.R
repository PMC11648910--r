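# Free energies of states and transition states from fitted populations and
# rates, and urea m-values from their denaturant dependence.

#' Free energy of a minor state relative to the folded state
#'
#' \deqn{\Delta G_{FK} = -RT \ln(p_K / p_F)}
#' with R = 8.314 J mol^-1 K^-1.
#'
#' @param p_k,p_f equilibrium populations of the minor state K and the
#'   folded state F (fractions, > 0).
#' @param temperature_k absolute temperature (K).
#' @return free energy difference in kJ/mol.
#' @examples
#' delta_g_state(0.0083, 0.9874, 283.15)  # ~11.25 kJ/mol
#' @export
delta_g_state <- function(p_k, p_f, temperature_k) {
  if (any(p_k <= 0) || any(p_f <= 0)) stop("populations must be > 0")
  if (any(temperature_k <= 0)) stop("'temperature_k' must be > 0")
  -.R_GAS * temperature_k * log(p_k / p_f) / 1000
}

#' Free energy of a transition state relative to the folded state
#'
#' \deqn{\Delta G_{F-TS_{KL}} = -RT \ln(p_K/p_F) - RT \ln(k_{KL}/C)}
#' where \eqn{k_{KL}} is the microscopic rate from state K toward state L
#' and C is an arbitrary transition-state-theory prefactor.  Because of
#' detailed balance (\eqn{p_K k_{KL} = p_L k_{LK}}) the result does not
#' depend on which side of the barrier it is computed from, and changing C
#' shifts all transition-state free energies by the same additive constant
#' (so denaturant m-values are unaffected by C).
#'
#' @inheritParams delta_g_state
#' @param k_kl microscopic rate constant K -> L (s^-1, > 0); derive it
#'   with [microscopic_rates()].
#' @param prefactor_c the constant C (s^-1); default 1e7.
#' @return free energy difference in kJ/mol.
#' @export
delta_g_transition <- function(p_k, p_f, k_kl, temperature_k,
                               prefactor_c = 1e7) {
  if (any(k_kl <= 0)) stop("'k_kl' must be > 0")
  delta_g_state(p_k, p_f, temperature_k) -
    .R_GAS * temperature_k * log(k_kl / prefactor_c) / 1000
}

#' Fit a linear denaturant dependence of a free energy series
#'
#' Weighted least-squares line \eqn{\Delta G = a + b \cdot [urea]}; the
#' m-value is \eqn{-b}.  Weights are \eqn{1/SE^2} when standard errors are
#' supplied, uniform otherwise.
#'
#' @param urea denaturant concentrations (mol/L, >= 2 distinct values).
#' @param dg free energies (kJ/mol), same length.
#' @param se optional standard errors of `dg` (kJ/mol, > 0).
#' @param target optional label for the state or transition state.
#' @return an object of class `m_value_fit`: list with `target`, `urea`,
#'   `dg`, `se`, `slope`, `intercept`, `slope_se`, `intercept_se` and
#'   `m_value = -slope` (kJ mol^-1 M^-1).
#' @export
fit_m_value <- function(urea, dg, se = NULL, target = NULL) {
  if (length(urea) != length(dg)) stop("'urea' and 'dg' lengths differ")
  if (length(unique(urea)) < 2)
    stop("need >= 2 distinct urea concentrations")
  w <- if (is.null(se)) NULL else {
    if (any(se <= 0)) stop("'se' must be > 0")
    1 / se^2
  }
  fit <- lm(dg ~ urea, weights = w)
  cf <- coef(fit)
  cse <- suppressWarnings(sqrt(diag(vcov(fit))))  # noiseless series fit a line exactly
  structure(list(target = target, urea = urea, dg = dg, se = se,
                 slope = unname(cf[2]), intercept = unname(cf[1]),
                 slope_se = unname(cse[2]), intercept_se = unname(cse[1]),
                 m_value = -unname(cf[2])),
            class = "m_value_fit")
}

#' @export
print.m_value_fit <- function(x, ...) {
  cat(sprintf("<m_value_fit> %s: m = %.3f +/- %.3f kJ mol^-1 M^-1 (intercept %.3f kJ/mol, %d points)\n",
              x$target %||n% "?", x$m_value, x$slope_se, x$intercept,
              length(x$urea)))
  invisible(x)
}

# Transition-state label for an edge of the folding topology, with the
# state further from F named first (U < I1 < I2 < F).
.ts_label <- function(a, b) {
  ord <- c(U = 1, I1 = 2, I2 = 3, F = 4)
  pair <- c(a, b)[order(ord[c(a, b)])]
  paste0("TS_", pair[1], pair[2])
}

#' Urea m-values of every state and transition state of a network series
#'
#' Takes per-urea fitted networks (identical topology and temperature) and
#' returns the m-value of each minor state (from the urea dependence of
#' \eqn{-RT\ln(p_K/p_F)}) and of the transition state on each exchange
#' edge (adding the \eqn{-RT\ln(k_{KL}/C)} term, computed from the side
#' further from F; detailed balance makes the side choice immaterial).
#'
#' @param points list of urea points, each a list with elements `urea`
#'   (mol/L) and `network` (a [kinetic_network()] fitted at that urea).
#' @param prefactor_c transition-state prefactor C (s^-1).
#' @return named list of [fit_m_value()] results, keyed by state label
#'   (`I1`, `I2`, `U`, ...) and transition-state label (`TS_UI1`,
#'   `TS_I1I2`, `TS_I1F`, `TS_I2F`, ...).
#' @export
m_value_profile <- function(points, prefactor_c = 1e7) {
  stopifnot(length(points) >= 2)
  nets <- lapply(points, `[[`, "network")
  urea <- vapply(points, `[[`, 0, "urea")
  if (any(urea < 0)) stop("urea concentrations must be >= 0")
  st <- nets[[1]]$states
  temp <- nets[[1]]$temperature_k
  for (nw in nets) {
    if (!identical(nw$states, st) ||
        !identical(nw$edges[c("from", "to")], nets[[1]]$edges[c("from", "to")]))
      stop("all networks must share one topology")
    if (abs(nw$temperature_k - temp) > 1e-9)
      stop("mixing temperatures in one m-value analysis is not allowed")
  }
  major <- st[1]
  out <- list()
  for (s in setdiff(st, major)) {
    dg <- vapply(nets, function(nw)
      delta_g_state(nw$populations[[s]], nw$populations[[major]], temp), 0)
    out[[s]] <- fit_m_value(urea, dg, target = s)
  }
  edges <- nets[[1]]$edges
  ord <- c(U = 1, I1 = 2, I2 = 3, F = 4)
  for (i in seq_len(nrow(edges))) {
    a <- edges$from[i]; b <- edges$to[i]
    if (!all(c(a, b) %in% names(ord))) {
      warning("no transition-state convention for edge ", a, "-", b,
              "; omitted")
      next
    }
    k_state <- if (ord[a] < ord[b]) a else b   # side further from F
    l_state <- setdiff(c(a, b), k_state)
    dg <- vapply(nets, function(nw) {
      kex <- nw$edges$kex[nw$edges$from == edges$from[i] &
                            nw$edges$to == edges$to[i]]
      mk <- microscopic_rates(kex, nw$populations[[k_state]],
                              nw$populations[[l_state]],
                              labels = c(k_state, l_state))
      delta_g_transition(nw$populations[[k_state]],
                         nw$populations[[major]], mk[["k_ab"]], temp,
                         prefactor_c = prefactor_c)
    }, 0)
    out[[.ts_label(a, b)]] <- fit_m_value(urea, dg,
                                          target = .ts_label(a, b))
  }
  out
}
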
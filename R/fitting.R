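# Global fitting of multi-spin, multi-B1 CEST data.
#
# Kinetic parameters (exchange rate constants, minor-state populations) are
# shared across all spins and B1 fields; each spin contributes its own
# delta_omega per minor state and (optionally free) R1/R2.  The optimizer is
# bounded Levenberg-Marquardt (minpack.lm).

# Default parameter bounds by parameter kind.
.default_bounds <- function(nucleus) {
  dw_lim <- if (.NUCLEUS_BASE[nucleus] == "1H") 3 else 15
  list(kex = c(1e-3, 1e6), p = c(1e-8, 0.499),
       dw = c(-dw_lim, dw_lim), r1 = c(0.01, 100), r2 = c(0.1, 1000))
}

# Flatten a nested parameter list into the optimizer vector + bounds.
# Returns list(par, lower, upper, kin_names, spin_ids, minors, map).
.flatten_params <- function(initial, level, profiles, fix_relaxation,
                            bounds = NULL) {
  spec <- .LEVELS[[level]]
  kin_names <- c(spec$kex, spec$pops)
  minors <- .minor_states(level)
  kin <- unlist(initial$kinetics)
  missing <- setdiff(kin_names, names(kin))
  if (length(missing) > 0)
    stop("initial kinetics missing: ", paste(missing, collapse = ", "))

  spin_ids <- unique(vapply(profiles, `[[`, "", "spin_id"))
  no_par <- setdiff(spin_ids, names(initial$spins))
  if (length(no_par) > 0)
    stop("no initial parameters for spin(s): ",
         paste(no_par, collapse = ", "))
  nucleus <- vapply(profiles, `[[`, "", "nucleus")[
    match(spin_ids, vapply(profiles, `[[`, "", "spin_id"))]

  par <- unname(kin[kin_names])
  names(par) <- kin_names
  lower <- upper <- numeric(0)
  for (nm in kin_names) {
    kind <- if (startsWith(nm, "kex")) "kex" else "p"
    b <- (bounds[[kind]] %||n% .default_bounds("15N")[[kind]])
    lower <- c(lower, b[1]); upper <- c(upper, b[2])
  }
  for (si in seq_along(spin_ids)) {
    s <- spin_ids[si]
    sp <- initial$spins[[s]]
    db <- .default_bounds(nucleus[si])
    for (m in minors) {
      v <- sp$dw[[m]]
      if (is.null(v) || is.na(v))
        stop("spin ", s, " has no initial delta_omega for state ", m)
      par <- c(par, setNames(v, paste("dw", s, m, sep = ".")))
      b <- bounds$dw %||n% db$dw
      lower <- c(lower, b[1]); upper <- c(upper, b[2])
    }
    if (!fix_relaxation) {
      par <- c(par, setNames(sp$r1 %||n% 2, paste0("r1.", s)),
               setNames(unname(sp$r2[1]) %||n% 20, paste0("r2.", s)))
      b1 <- bounds$r1 %||n% db$r1; b2 <- bounds$r2 %||n% db$r2
      lower <- c(lower, b1[1], b2[1]); upper <- c(upper, b1[2], b2[2])
    }
  }
  if (any(par < lower | par > upper))
    stop("initial parameter(s) outside bounds: ",
         paste(names(par)[par < lower | par > upper], collapse = ", "))
  list(par = par, lower = lower, upper = upper, kin_names = kin_names,
       spin_ids = spin_ids, minors = minors)
}

`%||n%` <- function(a, b) if (is.null(a)) b else a

# Residual closure over a set of profiles.  Fixed (non-fitted) per-spin
# quantities -- omega_ppm always, r1/r2 when fix_relaxation -- come from
# 'initial'.
.make_resid_fn <- function(profiles, level, initial, flat, fix_relaxation) {
  spec <- .LEVELS[[level]]
  minors <- flat$minors
  n_states <- length(spec$states)
  # precompute per-profile constants
  pre <- lapply(profiles, function(pr) {
    ex <- pr$experiment
    list(spin_id = pr$spin_id,
         f_hz = ex$sfrq_mhz * unname(.GAMMA_REL[.NUCLEUS_BASE[pr$nucleus]]),
         base_ppm = initial$spins[[pr$spin_id]]$omega_ppm - ex$carrier_ppm,
         offsets = ex$offsets_hz, b1 = ex$b1_hz, tex = ex$tex_s,
         obs = pr$intensities,
         err = if (is.null(pr$errors)) rep(1, length(pr$intensities))
               else pr$errors)
  })
  n_total <- sum(vapply(pre, function(x) length(x$obs), 0L))

  function(par) {
    kin <- par[flat$kin_names]
    p_minor <- kin[spec$pops]
    if (any(p_minor <= 0) || sum(p_minor) >= 0.999)
      return(rep(1e6, n_total))
    network <- make_ff_model(level, kin)
    K <- build_rate_matrix(network)
    p <- unname(network$populations)
    out <- vector("list", length(pre))
    for (i in seq_along(pre)) {
      pp <- pre[[i]]
      s <- pp$spin_id
      dw <- par[paste("dw", s, minors, sep = ".")]
      if (fix_relaxation) {
        r1 <- rep(unname(initial$spins[[s]]$r1 %||n% 2), n_states)
        r2 <- rep(unname(initial$spins[[s]]$r2[1] %||n% 20), n_states)
      } else {
        r1 <- rep(unname(par[paste0("r1.", s)]), n_states)
        r2 <- rep(unname(par[paste0("r2.", s)]), n_states)
      }
      omega_hz <- (pp$base_ppm + c(0, unname(dw))) * pp$f_hz
      sim <- as.numeric(cpp_cest_profile(pp$offsets, K, p, omega_hz,
                                         r1, r2, pp$b1, pp$tex))
      out[[i]] <- (pp$obs - sim) / pp$err
    }
    unlist(out, use.names = FALSE)
  }
}

#' Weighted residuals of an exchange model against CEST profiles
#'
#' Concatenates `(observed - simulated) / error` over every offset of every
#' profile, in profile order.  Points without errors get unit weight.
#'
#' @param params nested parameter list with elements `kinetics` (named
#'   vector of exchange rates and minor populations for the level) and
#'   `spins` (named list per spin: `omega_ppm`, `dw` named per minor
#'   state, `r1`, `r2`).
#' @param profiles list of [cest_profile()] objects.
#' @param level exchange model level, see [make_ff_model()].
#' @param fix_relaxation if `TRUE` (default) R1/R2 are taken from `params`
#'   as fixed values.
#' @return numeric residual vector.
#' @export
cest_residuals <- function(params, profiles, level, fix_relaxation = TRUE) {
  flat <- .flatten_params(params, level, profiles, fix_relaxation)
  fn <- .make_resid_fn(profiles, level, params, flat, fix_relaxation)
  fn(flat$par)
}

#' Globally fit an exchange model to CEST profiles
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt, \pkg{minpack.lm})
#' over all profiles jointly: kinetic parameters are global, chemical-shift
#' differences are per spin and per minor state, and R1/R2 are either fixed
#' at their supplied values (default, the usual practice when they are
#' known from the synthetic truth or independent measurement) or fitted per
#' spin.  Deterministic given identical inputs and options.
#'
#' @inheritParams cest_residuals
#' @param initial nested initial-parameter list (see [cest_residuals()]);
#'   initial values must lie within the bounds.
#' @param bounds optional list overriding default bounds; entries `kex`,
#'   `p`, `dw`, `r1`, `r2`, each a length-2 `c(lower, upper)`.  Defaults:
#'   kex in \[1e-3, 1e6\] s^-1, minor populations in \[1e-8, 0.499\],
#'   delta_omega within +/-15 ppm (15N/13C) or +/-3 ppm (1H).
#' @param n_starts number of optimizer starts (default 5, guarding against
#'   local minima and optimizer stalls in four-state fits); starts beyond
#'   the first perturb the incumbent best parameters by +/-15 percent
#'   (seeded) and the best chi-square is kept.  Starts stop early once a
#'   fit is essentially perfect (reduced chi-square below 1e-8), so clean
#'   recoveries pay for one start only.
#' @param seed seed for the multi-start perturbations (fixed default keeps
#'   the fit deterministic for identical inputs and options).
#' @param ftol,ptol,maxiter optimizer tolerances and iteration cap.
#'
#' @details The Jacobian is computed by central differences (relative step
#'   1e-5).  Multi-state exchange objectives are "sloppy": some parameter
#'   combinations change the residuals by orders of magnitude less than
#'   others, and forward differences at square-root-of-machine-epsilon
#'   steps lose the sloppy columns to rounding noise, stalling the
#'   optimizer far from the optimum.  Accurate central-difference columns
#'   let the trust-region steps track the curved, ill-conditioned valleys
#'   these models produce.  Each start additionally restarts the
#'   minimizer from its own endpoint (fresh trust region) while that
#'   improves the fit by more than 1 percent.  A final "dip reseat" pass
#'   guards against discrete mis-assignments: when one spin's profiles fit
#'   far worse than the rest (its dips locked onto the wrong spectral
#'   features), that spin's shift differences are refit alone from many
#'   randomized positions and the global fit repeated, keeping the result
#'   only if the overall chi-square improves.
#' @return an object of class `cest_fit`: best-fit parameters (flat vector
#'   `par` and nested `parameters`), `chi2`, `chi2_red`, per-profile
#'   residual vectors, convergence metadata (`converged`, `info`,
#'   `message`, `niter`), and a `boundary_hit` flag.
#' @export
fit_cest <- function(profiles, level, initial, fix_relaxation = TRUE,
                     bounds = NULL, n_starts = 5, seed = 1,
                     ftol = 1e-10, ptol = 1e-10, maxiter = 500) {
  stopifnot(length(profiles) >= 1)
  flat <- .flatten_params(initial, level, profiles, fix_relaxation, bounds)
  fn <- .make_resid_fn(profiles, level, initial, flat, fix_relaxation)
  n_points <- length(fn(flat$par))
  n_free <- length(flat$par)
  if (n_free >= n_points)
    stop("more free parameters (", n_free, ") than data points (",
         n_points, ")")
  ctrl <- minpack.lm::nls.lm.control(ftol = ftol, ptol = ptol,
                                     maxiter = maxiter, maxfev = 200000)
  jac <- function(par, ...) {
    J <- matrix(0, n_points, length(par))
    for (j in seq_along(par)) {
      h <- max(abs(par[j]), 1e-4) * 1e-5
      pp <- par; pp[j] <- pp[j] + h
      pm <- par; pm[j] <- pm[j] - h
      J[, j] <- (fn(pp) - fn(pm)) / (2 * h)
    }
    J
  }
  run_one <- function(start) {
    start <- setNames(as.numeric(start), names(flat$par))
    # restart from the endpoint while that still improves the fit: a fresh
    # trust region often escapes stalls on sloppy valley floors
    res <- minpack.lm::nls.lm(par = start, lower = flat$lower,
                              upper = flat$upper, fn = fn, jac = jac,
                              control = ctrl)
    for (round in 1:3) {
      if (res$deviance / (n_points - n_free) < 1e-8) break
      again <- minpack.lm::nls.lm(par = setNames(as.numeric(res$par),
                                                 names(flat$par)),
                                  lower = flat$lower,
                                  upper = flat$upper, fn = fn, jac = jac,
                                  control = ctrl)
      improved <- again$deviance < 0.99 * res$deviance
      if (again$deviance < res$deviance) res <- again
      if (!improved) break
    }
    res
  }
  if (!is.null(seed)) {
    # seed the multi-start draws without disturbing the caller's RNG stream
    old_rng <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old_rng))
      assign(".Random.seed", old_rng, envir = globalenv()), add = TRUE)
    set.seed(seed)
  }
  best <- run_one(flat$par)
  # Dip-reseat pass: a spin whose profiles fit far worse than the rest has
  # typically locked one of its minor-state dips onto the wrong spectral
  # feature (a discrete mis-assignment no local step can undo).  Refit that
  # spin's shift differences alone, over its own profiles with the global
  # kinetics held at the incumbent, from many randomized positions, then
  # refit everything.  Kept only when it improves the overall chi-square.
  sid <- vapply(profiles, `[[`, "", "spin_id")
  lens <- vapply(profiles, function(p) length(p$intensities), 0L)
  for (reseat_round in 1:2) {
    if (best$deviance / (n_points - n_free) < 1e-8) break
    par_b <- setNames(as.numeric(best$par), names(flat$par))
    rms <- vapply(split(fn(par_b), rep(seq_along(profiles), lens)),
                  function(r) sqrt(mean(r^2)), 0)
    spin_rms <- tapply(rms, sid, max)
    flagged <- names(sort(spin_rms[spin_rms > 3 * stats::median(spin_rms)],
                          decreasing = TRUE))
    if (length(flagged) == 0) break
    improved_any <- FALSE
    for (s in utils::head(flagged, 2)) {
      sub <- which(sid == s)
      if (fix_relaxation) {
        r1_b <- initial$spins[[s]]$r1 %||n% 2
        r2_b <- initial$spins[[s]]$r2 %||n% 20
      } else {
        r1_b <- unname(par_b[paste0("r1.", s)])
        r2_b <- unname(par_b[paste0("r2.", s)])
      }
      dw_names <- paste("dw", s, flat$minors, sep = ".")
      ini_sub <- list(kinetics = par_b[flat$kin_names],
                      spins = setNames(list(list(
                        omega_ppm = initial$spins[[s]]$omega_ppm,
                        dw = setNames(par_b[dw_names], flat$minors),
                        r1 = r1_b, r2 = r2_b)), s))
      flat_s <- .flatten_params(ini_sub, level, profiles[sub], TRUE, bounds)
      fn_s <- .make_resid_fn(profiles[sub], level, ini_sub, flat_s, TRUE)
      dw_idx <- (length(flat$kin_names) + 1):length(flat_s$par)
      fn_dw <- function(dw) {
        p <- flat_s$par; p[dw_idx] <- dw; fn_s(p)
      }
      sub_best <- minpack.lm::nls.lm(
        par = flat_s$par[dw_idx], lower = flat_s$lower[dw_idx],
        upper = flat_s$upper[dw_idx], fn = fn_dw, control = ctrl)
      for (draw in 1:25) {
        d0 <- runif(length(dw_idx), flat_s$lower[dw_idx],
                    flat_s$upper[dw_idx])
        r_s <- minpack.lm::nls.lm(par = d0, lower = flat_s$lower[dw_idx],
                                  upper = flat_s$upper[dw_idx], fn = fn_dw,
                                  control = ctrl)
        if (r_s$deviance < sub_best$deviance) sub_best <- r_s
      }
      par_try <- par_b
      par_try[dw_names] <- as.numeric(sub_best$par)
      res <- run_one(par_try)
      if (res$deviance < best$deviance) {
        best <- res
        improved_any <- TRUE
      }
    }
    if (!improved_any) break
  }
  for (k in seq_len(max(n_starts - 1, 0))) {
    if (best$deviance / (n_points - n_free) < 1e-8) break
    pk <- as.numeric(best$par) * (1 + runif(n_free, -0.15, 0.15))
    res <- run_one(pmin(pmax(pk, flat$lower), flat$upper))
    if (res$deviance < best$deviance) best <- res
  }
  par <- setNames(as.numeric(best$par), names(flat$par))
  chi2 <- best$deviance
  chi2_red <- chi2 / (n_points - n_free)
  # nested best-fit parameter list (includes the fixed quantities)
  parameters <- list(kinetics = par[flat$kin_names], spins = list())
  for (s in flat$spin_ids) {
    sp <- initial$spins[[s]]
    dw <- setNames(par[paste("dw", s, flat$minors, sep = ".")], flat$minors)
    r1 <- if (fix_relaxation) sp$r1 else unname(par[paste0("r1.", s)])
    r2 <- if (fix_relaxation) sp$r2 else unname(par[paste0("r2.", s)])
    parameters$spins[[s]] <- list(omega_ppm = sp$omega_ppm, dw = dw,
                                  r1 = r1, r2 = r2)
  }
  resid <- fn(par)
  lens <- vapply(profiles, function(p) length(p$intensities), 0L)
  resid_by_profile <- split(resid, rep(seq_along(profiles), lens))
  tol_b <- 1e-8 * pmax(1, abs(par))
  structure(
    list(level = level, par = par, parameters = parameters,
         lower = flat$lower, upper = flat$upper,
         chi2 = chi2, chi2_red = chi2_red,
         n_points = n_points, n_free = n_free,
         residuals = resid_by_profile,
         converged = best$info %in% 1:3,
         info = best$info, message = best$message, niter = best$niter,
         boundary_hit = any(par - flat$lower < tol_b |
                            flat$upper - par < tol_b),
         profiles = profiles, initial = initial,
         fix_relaxation = fix_relaxation,
         .resid_fn = fn),
    class = "cest_fit")
}

#' @export
print.cest_fit <- function(x, ...) {
  cat(sprintf("<cest_fit> %s model, %d profiles, %d points, %d free\n",
              x$level, length(x$profiles), x$n_points, x$n_free))
  cat(sprintf("  chi2 = %.6g, chi2_red = %.6g, converged: %s (info %d, %d iter)\n",
              x$chi2, x$chi2_red, x$converged, x$info, x$niter))
  cat("  kinetics:",
      paste(sprintf("%s=%.5g", names(x$parameters$kinetics),
                    x$parameters$kinetics), collapse = ", "), "\n")
  invisible(x)
}

# Forward-difference Jacobian of the fit's residual function at 'par'.
.fit_jacobian <- function(fit, par = fit$par) {
  f0 <- fit$.resid_fn(par)
  J <- matrix(0, length(f0), length(par))
  h <- pmax(abs(par), 1e-4) * 1e-7
  for (j in seq_along(par)) {
    pj <- par
    pj[j] <- pj[j] + h[j]
    J[, j] <- (fit$.resid_fn(pj) - f0) / h[j]
  }
  colnames(J) <- names(par)
  J
}

#' Standard errors of fitted CEST parameters
#'
#' Either the asymptotic covariance estimate (scaled inverse of
#' \eqn{J^T J}, with the reduced chi-square as variance scale) or a
#' parametric bootstrap in which Gaussian noise with the profiles' stated
#' errors is re-added to the best-fit curves and the fit repeated.
#'
#' @param fit a [fit_cest()] result.
#' @param method `"covariance"` or `"bootstrap"`.
#' @param n_boot number of bootstrap replicates.
#' @param seed seed for the bootstrap noise (same seed, same SEs).
#' @return named numeric vector of standard errors for the free
#'   parameters; parameters whose information is singular are `NA` (with
#'   a warning).
#' @export
estimate_uncertainties <- function(fit, method = c("covariance", "bootstrap"),
                                   n_boot = 50, seed = NULL) {
  stopifnot(inherits(fit, "cest_fit"))
  method <- match.arg(method)
  if (method == "covariance") {
    J <- .fit_jacobian(fit)
    jtj <- crossprod(J)
    cov <- tryCatch(solve(jtj), error = function(e) NULL)
    if (is.null(cov)) {
      warning("information matrix is singular; undefined SEs reported as NA")
      d <- svd(jtj)
      ok <- d$d > max(d$d) * 1e-12
      inv <- d$v[, ok, drop = FALSE] %*%
        (t(d$u[, ok, drop = FALSE]) / d$d[ok])
      se <- sqrt(pmax(diag(inv), 0) * fit$chi2_red)
      se[!ok] <- NA_real_
    } else {
      se <- sqrt(pmax(diag(cov), 0) * fit$chi2_red)
    }
    return(setNames(se, names(fit$par)))
  }
  # bootstrap
  has_err <- !vapply(fit$profiles, function(p) is.null(p$errors), TRUE)
  if (!all(has_err))
    stop("bootstrap requires profiles with errors")
  if (!is.null(seed)) set.seed(seed)
  fitted_profiles <- fit$profiles
  for (i in seq_along(fitted_profiles)) {
    fitted_profiles[[i]]$intensities <- fit$profiles[[i]]$intensities -
      fit$residuals[[i]] * fit$profiles[[i]]$errors
  }
  boots <- matrix(NA_real_, n_boot, length(fit$par),
                  dimnames = list(NULL, names(fit$par)))
  start <- .nested_from_flat(fit)
  for (b in seq_len(n_boot)) {
    pb <- fitted_profiles
    for (i in seq_along(pb))
      pb[[i]]$intensities <- pb[[i]]$intensities +
        rnorm(length(pb[[i]]$intensities), 0, pb[[i]]$errors)
    fb <- fit_cest(pb, fit$level, start, n_starts = 1,
                   fix_relaxation = fit$fix_relaxation)
    boots[b, ] <- fb$par
  }
  apply(boots, 2, sd)
}

# Rebuild a nested initial list positioned at the fit optimum.
.nested_from_flat <- function(fit) {
  ini <- fit$initial
  ini$kinetics <- fit$parameters$kinetics
  for (s in names(fit$parameters$spins)) {
    ini$spins[[s]]$dw <- fit$parameters$spins[[s]]$dw
    if (!fit$fix_relaxation) {
      ini$spins[[s]]$r1 <- fit$parameters$spins[[s]]$r1
      ini$spins[[s]]$r2 <- fit$parameters$spins[[s]]$r2
    }
  }
  ini
}

#' Rank exchange models fitted to the same data
#'
#' Tabulates chi-square, reduced chi-square and AIC
#' (\eqn{\chi^2 + 2 N_{free}}) for a set of fits of different model levels
#' to identical data; the lowest AIC is marked best.
#'
#' @param fits list of [fit_cest()] results on the same profiles.
#' @return data.frame with columns `level`, `n_free`, `chi2`, `chi2_red`,
#'   `aic`, `best`.
#' @export
compare_models <- function(fits) {
  stopifnot(length(fits) >= 1)
  obs <- lapply(fits, function(f)
    lapply(f$profiles, function(p)
      list(p$spin_id, p$experiment$offsets_hz, p$intensities)))
  for (i in seq_along(fits)[-1])
    if (!identical(obs[[1]], obs[[i]]))
      stop("fits were not performed on identical data")
  out <- data.frame(
    level = vapply(fits, `[[`, "", "level"),
    n_free = vapply(fits, `[[`, 0L, "n_free"),
    chi2 = vapply(fits, `[[`, 0, "chi2"),
    chi2_red = vapply(fits, `[[`, 0, "chi2_red"))
  out$aic <- out$chi2 + 2 * out$n_free
  out$best <- seq_len(nrow(out)) == which.min(out$aic)
  out
}
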
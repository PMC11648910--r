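make_two_state_data <- function(n_spins = 5, n_offsets = 41, noise = 0,
                                seed = 5, b1 = c(26.4, 52.9)) {
  sc <- cest_scenario("B")
  sc$b1_hz <- b1
  spins <- make_spin_set(n_spins, "I2", seed = seed)
  lim <- ppm_to_hz(14, "15N", 700)
  generate_profiles(sc, spins, noise_sd = noise, seed = seed,
                    offsets_hz = seq(-lim, lim, length.out = n_offsets))
}

test_that("residuals vanish at truth, scale with errors, and are local", {
  dat <- make_two_state_data(noise = 0.01)
  truth_pars <- list(kinetics = cest_scenario("B")$kinetics,
                     spins = dat$truth$spins)
  # exactly-zero residuals only for noiseless data
  dat0 <- make_two_state_data(noise = 0)
  r0 <- cest_residuals(list(kinetics = cest_scenario("B")$kinetics,
                            spins = dat0$truth$spins),
                       dat0$profiles, "two_state")
  expect_lt(max(abs(r0)), 1e-12)

  r1 <- cest_residuals(truth_pars, dat$profiles, "two_state")
  prof2 <- lapply(dat$profiles, function(p) { p$errors <- 2 * p$errors; p })
  r2 <- cest_residuals(truth_pars, prof2, "two_state")
  expect_equal(r2, r1 / 2)

  # perturbing one spin's delta_omega only moves that spin's block
  pars_p <- truth_pars
  sid <- names(pars_p$spins)[2]
  pars_p$spins[[sid]]$dw["I2"] <- pars_p$spins[[sid]]$dw["I2"] + 0.5
  rp <- cest_residuals(pars_p, dat$profiles, "two_state")
  lens <- vapply(dat$profiles, function(p) length(p$intensities), 0L)
  block <- rep(vapply(dat$profiles, `[[`, "", "spin_id"), lens)
  changed <- abs(rp - r1) > 1e-12
  expect_true(all(block[changed] == sid))
  expect_true(any(changed))

  expect_error(
    cest_residuals(list(kinetics = truth_pars$kinetics,
                        spins = truth_pars$spins[-1]),
                   dat$profiles, "two_state"),
    "no initial parameters for spin")
})

test_that("noiseless two-state data are recovered from perturbed initials", {
  dat <- make_two_state_data(noise = 0)
  ini <- perturbed_initials(dat$truth, 0.3, seed = 42)
  fit <- fit_cest(dat$profiles, "two_state", ini)
  expect_true(fit$converged)
  expect_lt(abs(fit$parameters$kinetics[["kex_FI2"]] - 587) / 587, 0.01)
  expect_lt(abs(fit$parameters$kinetics[["p_I2"]] - 0.021) / 0.021, 0.01)
  for (s in names(dat$truth$spins))
    expect_lt(abs(fit$parameters$spins[[s]]$dw[["I2"]] -
                  dat$truth$spins[[s]]$dw[["I2"]]), 0.02)
  expect_lt(fit$chi2_red, 1e-12)
  expect_identical(fit$n_points, length(dat$profiles) * 41L)
  # deterministic: same inputs, same result
  fit2 <- fit_cest(dat$profiles, "two_state", ini)
  expect_identical(fit$par, fit2$par)
})

test_that("a no-exchange (flat) profile drives the minor population to its floor", {
  nw <- make_ff_model("two_state", c(kex_FI2 = 1e-3, p_I2 = 1e-8))
  lim <- ppm_to_hz(10, "15N", 700)
  ex <- cest_experiment(26.4, 0.4, 700, 119,
                        seq(-lim, lim, length.out = 41))
  spin <- spin_system("S01N", "15N", 119.8, c(I2 = 3), r1 = 2, r2 = 20)
  flat <- simulate_profile(spin, nw, ex)
  ini <- list(kinetics = c(kex_FI2 = 300, p_I2 = 0.02),
              spins = list(S01N = list(omega_ppm = 119.8, dw = c(I2 = 3),
                                       r1 = 2, r2 = 20)))
  fit <- fit_cest(list(flat), "two_state", ini)
  expect_lt(fit$parameters$kinetics[["p_I2"]], 1e-4)
  expect_true(fit$boundary_hit)
})

test_that("free parameters cannot outnumber data points", {
  dat <- make_two_state_data(n_spins = 1, n_offsets = 3, b1 = 26.4)
  ini <- list(kinetics = cest_scenario("B")$kinetics,
              spins = dat$truth$spins)
  expect_error(fit_cest(dat$profiles, "two_state", ini), "free parameters")
})

test_that("covariance SEs are ~0 on noiseless data; bootstrap is seeded and consistent", {
  dat <- make_two_state_data(n_spins = 3, n_offsets = 31, noise = 0)
  ini <- perturbed_initials(dat$truth, 0.2, seed = 1)
  fit <- fit_cest(dat$profiles, "two_state", ini)
  se <- estimate_uncertainties(fit, "covariance")
  expect_lt(se[["kex_FI2"]] / 587, 1e-6)
  expect_lt(se[["p_I2"]] / 0.021, 1e-6)

  datn <- make_two_state_data(n_spins = 3, n_offsets = 31, noise = 0.005)
  fitn <- fit_cest(datn$profiles, "two_state",
                   perturbed_initials(datn$truth, 0.2, seed = 1),
                   n_starts = 1)
  se_cov <- estimate_uncertainties(fitn, "covariance")
  se_b1 <- estimate_uncertainties(fitn, "bootstrap", n_boot = 10, seed = 9)
  se_b2 <- estimate_uncertainties(fitn, "bootstrap", n_boot = 10, seed = 9)
  expect_identical(se_b1, se_b2)
  for (nm in c("kex_FI2", "p_I2")) {
    ratio <- se_b1[[nm]] / se_cov[[nm]]
    expect_gt(ratio, 0.5)
    expect_lt(ratio, 2)
  }
})

test_that("model comparison by AIC picks the generating level", {
  sc <- cest_scenario("A")
  sc$b1_hz <- c(26, 104.1)
  spins <- make_spin_set(4, c("I1", "I2", "U"), seed = 3)
  lim <- ppm_to_hz(14, "15N", 700)
  dat <- generate_profiles(sc, spins, noise_sd = 0.003, seed = 3,
                           offsets_hz = seq(-lim, lim, length.out = 31))
  ini4 <- perturbed_initials(dat$truth, 0.15, seed = 2)
  fit4 <- fit_cest(dat$profiles, "four_state", ini4, n_starts = 1)
  ini2 <- list(kinetics = c(kex_FI2 = 406, p_I2 = 0.0083),
               spins = lapply(dat$truth$spins, function(s) {
                 s$dw <- s$dw["I2"]; s
               }))
  fit2 <- fit_cest(dat$profiles, "two_state", ini2, n_starts = 1)
  tab <- compare_models(list(fit2, fit4))
  expect_true(tab$best[tab$level == "four_state"])
  expect_lt(tab$aic[tab$level == "four_state"],
            tab$aic[tab$level == "two_state"])

  tab1 <- compare_models(list(fit4))
  expect_true(tab1$best)

  other <- make_two_state_data(n_spins = 2)
  fit_other <- fit_cest(other$profiles, "two_state",
                        list(kinetics = cest_scenario("B")$kinetics,
                             spins = other$truth$spins))
  expect_error(compare_models(list(fit4, fit_other)), "identical data")
})

test_that("noisy replicates stay calibrated and bracket the true rate", {
  # scaled-down four-state replicate study: 4 spins x 2 B1, 1% noise
  sc <- cest_scenario("A")
  sc$b1_hz <- c(26, 104.1)
  spins <- make_spin_set(4, c("I1", "I2", "U"), seed = 21)
  lim <- ppm_to_hz(14, "15N", 700)
  offs <- seq(-lim, lim, length.out = 41)
  kex <- numeric(0); chi2r <- numeric(0)
  for (rep in 1:6) {
    dat <- generate_profiles(sc, spins, noise_sd = 0.01, seed = 100 + rep,
                             offsets_hz = offs)
    fit <- fit_cest(dat$profiles, "four_state",
                    perturbed_initials(dat$truth, 0.15, seed = rep),
                    n_starts = 1)
    kex <- c(kex, fit$parameters$kinetics[["kex_FI1"]])
    chi2r <- c(chi2r, fit$chi2_red)
  }
  expect_lt(abs(median(kex) - 784), 67)
  expect_gte(mean(chi2r >= 0.5 & chi2r <= 1.5), 0.8)
})
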
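test_that("initial rates are recovered from synthetic traces", {
  p <- assay_params(noise_sd = 0)
  tr <- simulate_assay_trace(p)
  r <- extract_initial_rate(tr)
  expect_equal(r$velocity, tr$truth$v0_specific, tolerance = 0.01)

  flat <- simulate_assay_trace(assay_params(v_max = 0, noise_sd = 0))
  expect_equal(extract_initial_rate(flat)$velocity, 0)

  # detected window starts at/after a long instrument lag
  trl <- simulate_assay_trace(assay_params(lag_time = 120, noise_sd = 0.002,
                                           seed = 3))
  rl <- extract_initial_rate(trl)
  expect_gte(rl$window[1], 120 - 2 * 5)

  # pure noise: either flagged flat/no-linear-phase or a near-zero rate
  noise_only <- simulate_assay_trace(assay_params(v_max = 0,
                                                  noise_sd = 0.01, seed = 2))
  res <- tryCatch(extract_initial_rate(noise_only),
                  error = function(e) list(velocity = 0, flagged = TRUE))
  expect_lt(abs(res$velocity), 2)
})

test_that("Michaelis-Menten fits recover exact and k_cat arithmetic", {
  S <- c(1000, 500, 250, 125, 62.5, 31.25)
  exact <- data.frame(substrate_conc = S,
                      velocity = 100.34 * S / (517 + S))
  fit <- fit_michaelis_menten(exact, molar_mass_g_per_mol = 32200)
  expect_equal(fit$v_max, 100.34, tolerance = 1e-6)
  expect_equal(fit$K_M, 517, tolerance = 1e-6)
  # k_cat conversion at the canonical monomer mass
  expect_equal(fit$k_cat, 3.23, tolerance = 1e-2)
  exact2 <- data.frame(substrate_conc = S, velocity = 41.20 * S / (622 + S))
  fit2 <- fit_michaelis_menten(exact2, molar_mass_g_per_mol = 32200)
  expect_equal(fit2$k_cat, 1.33, tolerance = 1e-2)
  # linear, unit-exact: doubling the molar mass doubles k_cat
  fit3 <- fit_michaelis_menten(exact, molar_mass_g_per_mol = 64400)
  expect_equal(fit3$k_cat, 2 * fit$k_cat, tolerance = 1e-12)
  expect_error(fit_michaelis_menten(exact[1:3, ]), "4 distinct")
})

test_that("apparent KIEs reproduce the reported ratios with propagated errors", {
  S <- c(1000, 500, 250, 125, 62.5, 31.25, 15.6, 7.8)
  mk <- function(vmax, km) fit_michaelis_menten(
    data.frame(substrate_conc = S, velocity = vmax * S / (km + S)))
  fit_H <- mk(100.34, 517)
  fit_D <- mk(10.60, 311)
  kie <- apparent_kie(fit_H, fit_D)
  expect_equal(signif(kie$kie_vmax, 2), 9.5)
  expect_equal(signif(kie$kie_vmax_over_km, 2), 5.7)
  self <- apparent_kie(fit_H, fit_H)
  expect_identical(self$kie_vmax, 1)
  expect_identical(self$kie_vmax_over_km, 1)
})

test_that("noisy assay datasets recover the generator kinetics", {
  # a smaller replicate of the acceptance recovery study
  fits <- lapply(1:10, function(d) {
    tab <- make_rate_table(100.34, 517, seed = 3000 + d * 101)
    fit_michaelis_menten(tab)
  })
  vmax <- vapply(fits, function(f) f$v_max, numeric(1))
  km <- vapply(fits, function(f) f$K_M, numeric(1))
  expect_lt(abs(stats::median(vmax) - 100.34),
            2 * stats::median(vapply(fits, function(f) f$v_max_se, numeric(1))))
  expect_lt(abs(stats::median(km) - 517),
            2 * stats::median(vapply(fits, function(f) f$K_M_se, numeric(1))))
})

test_that("pKa fits recover generator titrations", {
  tab <- simulate_titration(4.76, analyte_conc = 10, volume = 75,
                            titrant_conc = 100, noise_sd = 0)
  fit <- fit_pka_titration(tab, 1)
  expect_equal(fit$pka, 4.76, tolerance = 0.01)

  dh <- simulate_titration(c(3.3, 8.6), analyte_conc = 10, volume = 75,
                           titrant_conc = 100, noise_sd = 0.05, seed = 4,
                           charge_fully_protonated = 1)
  fit2 <- fit_pka_titration(dh, 2, charge_fully_protonated = 1)
  expect_lt(abs(fit2$pka[1] - 3.3), 2 * fit2$se[1] + 0.05)
  expect_lt(abs(fit2$pka[2] - 8.6), 2 * fit2$se[2] + 0.05)

  # over-parameterization: a third site in a two-site titration inflates SEs
  fit3 <- fit_pka_titration(dh, 3, charge_fully_protonated = 1)
  expect_true(any(fit3$overparameterized) || max(fit3$se) > max(fit2$se))
})
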
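two_site_dhha <- function() {
  titratable_system(data.frame(label = c("carboxylate", "amino"),
                               pka = c(3.3, 8.6),
                               charge_protonated = c(0, 1)))
}

test_that("microstate energies follow the pH-dependent multi-site formula", {
  sys <- two_site_dhha()
  expect_equal(microstate_energy(sys, c(0, 0), 7), 0)
  one <- titratable_system(data.frame(label = "a", pka = 5.2,
                                      charge_protonated = 0))
  expect_equal(microstate_energy(one, 1, 5.2), 0)
  pair <- titratable_system(data.frame(label = c("a", "b"),
                                       pka = c(6, 6),
                                       charge_protonated = c(0, 0)),
                            matrix(c(0, 1, 1, 0), 2))
  expect_equal(microstate_energy(pair, c(1, 1), 6), 1)
  expect_error(titratable_system(data.frame(label = c("a", "b"),
                                            pka = c(6, 6)),
                                 matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("exact enumeration reproduces Henderson-Hasselbalch and factorizes", {
  one <- titratable_system(data.frame(label = "a", pka = 7.3,
                                      charge_protonated = 0))
  cur <- enumerate_titration(one)
  hh <- 1 / (1 + 10^(cur$pH - 7.3))
  expect_equal(as.numeric(cur$prob[, 1]), hh, tolerance = 1e-12)
  expect_equal(pka_half(cur, 1)$pka, 7.3, tolerance = 0.05)

  # W = 0 multi-site factorizes into independent single-site curves
  multi <- titratable_system(data.frame(label = c("a", "b", "c"),
                                        pka = c(4, 7, 10),
                                        charge_protonated = 0))
  cm <- enumerate_titration(multi)
  for (i in 1:3)
    expect_equal(as.numeric(cm$prob[, i]),
                 1 / (1 + 10^(cm$pH - multi$sites$pka[i])), tolerance = 1e-12)
})

test_that("exact enumeration matches a hand-summed coupled 3-site oracle", {
  pka <- c(4.5, 6.8, 9.1)
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 0.8
  W[2, 3] <- W[3, 2] <- 1.5
  W[1, 3] <- W[3, 1] <- 0.3
  sys <- titratable_system(data.frame(label = c("a", "b", "c"), pka = pka,
                                      charge_protonated = 0), W)
  grid <- c(2, 5, 6.8, 8, 12)
  cur <- enumerate_titration(sys, grid)
  for (k in seq_along(grid))
    expect_equal(as.numeric(cur$prob[k, ]),
                 hand_titration_prob(pka, W, grid[k]), tolerance = 1e-12)
})

test_that("enumeration refuses oversized systems", {
  big <- make_random_site_system(21, seed = 1)
  expect_error(enumerate_titration(big), "20 sites")
})

test_that("Metropolis Monte Carlo agrees with exact enumeration", {
  one <- titratable_system(data.frame(label = "a", pka = 7.3,
                                      charge_protonated = 0))
  ex <- enumerate_titration(one)
  mc <- mc_titrate(one, n_steps = 1e5, seed = 7)
  expect_lt(max(abs(mc$prob - ex$prob)), 0.01)
  expect_true(all(abs(mc$prob - ex$prob) <= 3 * mc$se))

  sys12 <- make_random_site_system(12, coupling_scale = 1, seed = 42)
  ex12 <- enumerate_titration(sys12)
  mc12 <- mc_titrate(sys12, n_steps = 1e5, seed = 7)
  expect_lt(max(abs(mc12$prob - ex12$prob)), 0.02)
  # with calibrated standard errors, ~0.3% of the 1692 grid-point
  # estimates are expected beyond 3 SE; require nominal 3-SE coverage
  # and that nothing strays beyond 5 SE
  ratio <- abs(mc12$prob - ex12$prob) / mc12$se
  expect_gte(mean(ratio <= 3), 0.995)
  expect_true(all(ratio <= 5))

  # bit-reproducible under the seed
  mc12b <- mc_titrate(sys12, n_steps = 1e5, seed = 7)
  expect_identical(mc12$prob, mc12b$prob)

  # uncoupled system matches Henderson-Hasselbalch per site
  free3 <- titratable_system(data.frame(label = c("a", "b", "c"),
                                        pka = c(4, 7, 10),
                                        charge_protonated = 0))
  mcf <- mc_titrate(free3, seq(0, 14, 0.5), n_steps = 5e4, seed = 3)
  for (i in 1:3)
    expect_lt(max(abs(mcf$prob[, i] -
                        1 / (1 + 10^(mcf$pH - free3$sites$pka[i])))), 0.02)
})

test_that("half-protonation points are interpolated, split or rejected", {
  one <- titratable_system(data.frame(label = "a", pka = 7.3,
                                      charge_protonated = 0))
  expect_equal(pka_half(enumerate_titration(one), "a")$pka, 7.3,
               tolerance = 0.05)

  # anticooperative identical pair: repulsion between the protonated
  # forms splits the macroscopic pKas to ~(pKa - W/slope, pKa); the
  # per-site half-point sits between them, below the intrinsic value
  pair <- titratable_system(data.frame(label = c("a", "b"), pka = c(7, 7),
                                       charge_protonated = c(0, 0)),
                            matrix(c(0, 3, 3, 0), 2))
  cur <- enumerate_titration(pair, seq(0, 14, 0.05))
  ph <- pka_half(cur, 1)
  w_units <- 3 / (log(10) * 1.9872e-3 * 298.15)
  expect_lt(ph$pka, 7)
  expect_true(all(ph$crossings >= 7 - w_units - 0.5 &
                    ph$crossings <= 7 + 0.5))

  # a locked site never crosses 0.5 inside the grid
  locked <- titratable_system(data.frame(label = "a", pka = 20,
                                         charge_protonated = 0))
  expect_error(pka_half(enumerate_titration(locked), 1), "outside")
})

test_that("pKa/energy conversions reproduce the canonical anchors and round-trip", {
  # 1.7 kcal/mol deprotonation energy at pH 7.5 corresponds to pKa ~ 9
  pka <- convert_pka_energy(1.7, "energy_to_pka", pH = 7.5, T = 298.15)
  expect_equal(round(pka), 9)
  expect_equal(pka, 8.746, tolerance = 1e-3)
  # a 12.3 pKa-unit gap is ~17 kcal/mol
  gap <- convert_pka_energy(12.3, "gap_to_energy", T = 298.15)
  expect_equal(gap, 16.78, tolerance = 0.01)
  expect_equal(round(gap), 17)
  # pKa = pH gives zero free energy
  expect_equal(convert_pka_energy(7.5, "pka_to_energy", pH = 7.5), 0)
  # round trip to machine precision
  e <- 1.7
  back <- convert_pka_energy(
    convert_pka_energy(e, "energy_to_pka", pH = 7.5),
    "pka_to_energy", pH = 7.5)
  expect_equal(back, e, tolerance = 1e-12)
})

test_that("titration curves are invariant under uniform microstate shifts", {
  # a constant added to every microstate free energy cancels in the
  # Boltzmann average: the enumeration must equal a shifted-G oracle
  pka <- c(5, 8)
  W <- matrix(c(0, 1.2, 1.2, 0), 2)
  sys <- titratable_system(data.frame(label = c("a", "b"), pka = pka,
                                      charge_protonated = 0), W)
  cur <- enumerate_titration(sys, c(4, 6, 8))
  # oracle with all G shifted by +5 kcal/mol
  R <- 1.9872e-3; RT <- R * 298.15; ln10 <- log(10)
  states <- as.matrix(expand.grid(0:1, 0:1))
  for (k in 1:3) {
    pH <- c(4, 6, 8)[k]
    G <- apply(states, 1, function(s)
      sum(s * ln10 * RT * (pH - pka)) + W[1, 2] * s[1] * s[2]) + 5
    w <- exp(-(G - min(G)) / RT)
    p <- c(sum(w[states[, 1] == 1]), sum(w[states[, 2] == 1])) / sum(w)
    expect_equal(as.numeric(cur$prob[k, ]), p, tolerance = 1e-12)
  }
})

test_that("site models built from structures use screened Coulomb couplings", {
  sys <- build_sites_from_structure(fixture_path("synthetic_two_lysines.pdb"),
                                    effective_dielectric = 20,
                                    ionic_strength = 0)
  expect_equal(sys$n_sites, 2)
  # hand evaluation: 332.06 * (+1)(+1) / (20 * 5)
  expect_equal(sys$interaction[1, 2], 332.06 / 100, tolerance = 1e-9)

  act <- build_sites_from_structure(fixture_path("synthetic_active_site.pdb"))
  labs <- act$sites$label
  his <- grep("HIS", labs)
  expect_equal(act$sites$pka[his], 6.5)  # N-epsilon tautomer model pKa
  # the two glutamates, 100 A apart, are uncoupled to < 1e-3 kcal/mol
  glu <- grep("GLU", labs)
  expect_lt(abs(act$interaction[glu[1], glu[2]]), 1e-3)

  bad <- tempfile(fileext = ".pdb")
  writeLines(c("ATOM      1  NZ  LYS A   1       bad coords"), bad)
  expect_error(build_sites_from_structure(bad), "line 1")
})
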
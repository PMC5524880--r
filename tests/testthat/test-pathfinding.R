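test_that("minimize descends to the correct minimum and classifies it", {
  bowl <- make_analytic_surface("quadratic_bowl")
  sp <- minimize(bowl, c(3, 4))
  expect_equal(sp$coordinates, c(0, 0), tolerance = 1e-6)
  expect_identical(sp$order, 0L)

  dw <- make_analytic_surface("double_well_1d")
  sp <- minimize(dw, 0.2)
  expect_equal(sp$coordinates, 1, tolerance = 1e-6)
  expect_equal(sp$energy, 0, tolerance = 1e-10)

  shuttle <- make_mechanism_surface(phzf_surface_spec("shuttle"))
  sp <- minimize(shuttle, c(0.05, 0.02))
  expect_equal(sp$energy, 0, tolerance = 1e-6)
})

test_that("scan_initial_path relaxes orthogonal coordinates and brackets the saddle", {
  dw1 <- make_analytic_surface("double_well_1d")
  p <- scan_initial_path(dw1, 1, c(-1, 1), 21)
  expect_equal(p$energies, (seq(-1, 1, length.out = 21)^2 - 1)^2)

  dw2 <- make_analytic_surface("double_well_2d")
  p2 <- scan_initial_path(dw2, 1, c(-1, 1), 11, start = c(0, 0.5))
  expect_true(all(abs(p2$frames[, 2]) < 1e-6))

  # the scan brackets the saddle from below, within the grid resolution
  shuttle <- make_mechanism_surface(phzf_surface_spec("shuttle"))
  xi_end <- shuttle$info$stationary[[3]]$x[1]
  p3 <- scan_initial_path(shuttle, 1, c(0, xi_end), 41)
  dgrid <- xi_end / 40
  curv <- 1 * (2448 / phzf_constants()$freq_conv)^2
  expect_gte(max(p3$energies), 14.3 - 0.5 * curv * (dgrid / 2)^2)
  expect_lte(max(p3$energies), 14.3 + 1e-9)
})

test_that("climbing NEB converges to the analytic saddle of the 2-D double well", {
  dw <- make_analytic_surface("double_well_2d")
  x <- seq(-1, 1, length.out = 11)
  init <- reaction_path(dw, cbind(x, 0.2 * sin(pi * (x + 1) / 2)))
  neb <- neb_refine(dw, init, climbing = TRUE)
  conv <- attr(neb, "convergence")
  expect_true(conv$converged)
  ci <- conv$climbing_index
  expect_lt(sqrt(sum(neb$frames[ci, ]^2)), 1e-2)
  expect_equal(neb$energies[ci], 1, tolerance = 1e-3)
  # endpoints immovable
  expect_equal(neb$frames[1, ], c(-1, 0))
  expect_equal(neb$frames[11, ], c(1, 0))
})

test_that("NEB leaves an already-optimal straight valley path unchanged", {
  valley <- energy_surface(2, function(x) 0.1 * x[1]^2 + 0.5 * x[2]^2,
                           function(x) c(0.2 * x[1], x[2]),
                           name = "valley")
  frames <- cbind(seq(-0.002, 0.002, length.out = 7), 0)
  init <- reaction_path(valley, frames)
  out <- neb_refine(valley, init, climbing = FALSE, tolerance = 1e-6)
  expect_lt(max(abs(out$frames[, 2])), 1e-6)
})

test_that("NEB finds the sigmatropic barrier on the canonical surface", {
  sig <- make_mechanism_surface(phzf_surface_spec("sigmatropic"))
  xi_end <- sig$info$stationary[[3]]$x[1]
  init <- scan_initial_path(sig, 1, c(0, xi_end), 15)
  neb <- neb_refine(sig, init, tolerance = 1e-3, max_iter = 8000)
  expect_equal(max(neb$energies), 32.5, tolerance = 0.1)
})

test_that("CPR refines path peaks into first-order saddles matching brute force", {
  dw <- make_analytic_surface("double_well_2d")
  x <- seq(-1, 1, length.out = 15)
  init <- reaction_path(dw, cbind(x, 0.3 * sin(pi * (x + 1) / 2)))
  res <- cpr_refine(dw, init)
  expect_length(res$saddles, 1)
  sp <- res$saddles[[1]]
  expect_identical(sp$order, 1L)
  expect_equal(sp$coordinates, c(0, 0), tolerance = 1e-4)
  oracle <- grid_saddle_energy(dw, c(-1, 1))
  expect_equal(sp$energy, oracle$energy, tolerance = 1e-2)
})

test_that("CPR resolves both saddles of a two-barrier landscape", {
  spec <- mechanism_spec("two_step", letters[1:5], c(0, 5, 2, 8, 1),
                         reactive_mode_frequency = 500)
  surf <- make_mechanism_surface(spec)
  xi_end <- surf$info$stationary[[5]]$x[1]
  init <- scan_initial_path(surf, 1, c(0, xi_end), 61)
  res <- cpr_refine(surf, init)
  expect_length(res$saddles, 2)
  en <- sort(vapply(res$saddles, function(s) s$energy, numeric(1)))
  expect_equal(en, c(5, 8), tolerance = 1e-6)
  # dense-grid brute force over each inter-minimum segment
  mins <- vapply(surf$info$minima, function(m) m$x[1], numeric(1))
  o1 <- grid_saddle_energy(surf, mins[1:2])
  o2 <- grid_saddle_energy(surf, mins[2:3])
  expect_equal(en, sort(c(o1$energy, o2$energy)), tolerance = 1e-2)
})

test_that("CPR is a fixed point on a path already through the saddle", {
  dw <- make_analytic_surface("double_well_2d")
  x <- seq(-1, 1, length.out = 11)
  init <- reaction_path(dw, cbind(x, 0))
  res <- cpr_refine(dw, init)
  expect_lt(max(abs(res$path$frames - init$frames)), 1e-6)
})

test_that("NEB with climbing and CPR agree on catalogue saddle energies", {
  for (nm in c("double_well_1d", "double_well_2d")) {
    surf <- make_analytic_surface(nm)
    if (surf$dimension == 1) {
      frames <- matrix(seq(-1, 1, length.out = 11), ncol = 1)
    } else {
      x <- seq(-1, 1, length.out = 11)
      frames <- cbind(x, 0.2 * sin(pi * (x + 1) / 2))
    }
    init <- reaction_path(surf, frames)
    neb <- neb_refine(surf, init, climbing = TRUE)
    cpr <- cpr_refine(surf, init)
    e_neb <- max(neb$energies)
    e_cpr <- max(vapply(cpr$saddles, function(s) s$energy, numeric(1)))
    expect_equal(e_neb, e_cpr, tolerance = 1e-2)
    oracle <- grid_saddle_energy(surf, c(-1, 1))
    expect_equal(e_cpr, oracle$energy, tolerance = 1e-2)
  }
})

test_that("classification reports order, imaginary modes and mass scaling", {
  bowl <- make_analytic_surface("quadratic_bowl")
  expect_identical(classify_stationary(bowl, c(0, 0))$order, 0L)

  dw <- make_analytic_surface("double_well_2d")
  sp <- classify_stationary(dw, c(0, 0))
  expect_identical(sp$order, 1L)
  expect_identical(sum(sp$frequencies$imaginary), 1L)

  # wavenumber of a diagonal mode scales as 1/sqrt(mass)
  s1 <- classify_stationary(bowl, c(0, 0), masses = c(1, 1))
  s2 <- classify_stationary(bowl, c(0, 0), masses = c(2, 1))
  expect_equal(min(s2$frequencies$wavenumber) /
                 min(s1$frequencies$wavenumber), 1 / sqrt(2),
               tolerance = 1e-6)

  expect_error(classify_stationary(dw, c(0.5, 0.3)), "not stationary")
})

test_that("barriers follow max-saddle semantics and shift invariance", {
  dw <- make_analytic_surface("double_well_1d")
  p <- reaction_path(dw, matrix(seq(-1, 1, length.out = 21), ncol = 1))
  expect_equal(barrier(p), 1)
  # monotone downhill path
  downhill <- energy_surface(1, function(x) -x, function(x) -1,
                             name = "downhill")
  pd <- reaction_path(downhill, matrix(seq(0, 1, length.out = 5), ncol = 1))
  expect_equal(barrier(pd), 0)
  expect_equal(barrier(list()), 0)
  expect_equal(barrier(c(5, 8), reactant_energy = 2), 6)
  # rigid shift leaves path barriers unchanged
  shifted <- energy_surface(1, function(x) (x[1]^2 - 1)^2 + 100,
                            name = "shifted")
  ps <- reaction_path(shifted, matrix(seq(-1, 1, length.out = 21), ncol = 1))
  expect_equal(barrier(ps), barrier(p))
})
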
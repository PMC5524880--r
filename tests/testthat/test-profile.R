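test_that("profile assembly applies the deprotonation correction to flagged states", {
  states <- list(
    cycle_state("E.S", "minimum", 0, correct = FALSE),
    cycle_state("TS1", "transition-state", 14.3, correct = TRUE))
  pr <- assemble_profile(states, global_correction = 1.7)
  expect_equal(pr$energy, c(0, 16.0))

  # zero correction is the identity
  pr0 <- assemble_profile(states, global_correction = 0)
  expect_equal(pr0$energy, c(0, 14.3))

  # tautomerization segment: minimum at -11.5 with the TS 9.2 above it
  seg <- assemble_profile(list(
    cycle_state("E.S", "minimum", 0, correct = FALSE),
    cycle_state("TS1", "transition-state", 14.3, correct = FALSE),
    cycle_state("E.AHCDC", "minimum", -11.5, correct = FALSE),
    cycle_state("TS2", "transition-state", -11.5 + 9.2, correct = FALSE)))
  expect_equal(seg$energy[3:4], c(-11.5, -2.3))

  expect_error(assemble_profile(list(
    cycle_state("a", "minimum", 0),
    cycle_state("b", "minimum", 1))), "alternate")
  expect_error(assemble_profile(list(
    cycle_state("a", "minimum", 2))), "energy 0")
})

test_that("the canonical profile has a 16.0 kcal/mol C3-deprotonation barrier", {
  pr <- phzf_profile()
  ob <- overall_barrier(pr)
  expect_equal(ob$barrier, 16.0)
  expect_match(ob$limiting_step, "C3 deprotonation")
})

test_that("overall_barrier follows max semantics with stable ties", {
  pr <- assemble_profile(list(
    cycle_state("m0", "minimum", 0, correct = FALSE),
    cycle_state("t1", "transition-state", 5, correct = FALSE),
    cycle_state("m1", "minimum", -2, correct = FALSE),
    cycle_state("t2", "transition-state", 8, correct = FALSE)))
  ob <- overall_barrier(pr)
  expect_equal(ob$barrier, 8)
  expect_equal(ob$limiting_step, "t2")

  tie <- assemble_profile(list(
    cycle_state("m0", "minimum", 0, correct = FALSE),
    cycle_state("t1", "transition-state", 8, correct = FALSE),
    cycle_state("m1", "minimum", -2, correct = FALSE),
    cycle_state("t2", "transition-state", 8, correct = FALSE)))
  obt <- overall_barrier(tie)
  expect_equal(obt$limiting_step, "t1")
  expect_equal(obt$ties, c("t1", "t2"))

  single <- assemble_profile(list(cycle_state("well", "minimum", 0)))
  expect_warning(obs <- overall_barrier(single), "no transition state")
  expect_equal(obs$barrier, 0)
})

test_that("mechanism ranking reproduces both canonical orderings", {
  shift <- rank_mechanisms(phzf_candidates("shift"))
  expect_equal(shift$name, c("shuttle", "concerted", "sigmatropic"))
  expect_equal(shift$overall_barrier, c(16.0, 27.2, 32.5))
  expect_equal(shift$verdict, c("plausible", "ruled out", "ruled out"))

  taut <- rank_mechanisms(phzf_candidates("tautomerization"))
  expect_equal(taut$name[1], "taut_c")
  expect_equal(taut$overall_barrier[1], 9.2)

  # equal barriers keep the input order
  cands <- list(mechanism_candidate("first", data.frame(description = "x",
                                                        barrier = 10)),
                mechanism_candidate("second", data.frame(description = "y",
                                                         barrier = 10)))
  expect_equal(rank_mechanisms(cands)$name, c("first", "second"))

  # ranking order is invariant under a common shift
  shifted <- lapply(phzf_candidates("shift"), function(cand) {
    cand$overall <- cand$overall + 7.3
    cand
  })
  expect_equal(rank_mechanisms(shifted, threshold = Inf)$name, shift$name)
})

test_that("the E45D scenario disfavors the shuttle step", {
  mut <- rank_mechanisms(phzf_candidates("shift", e45d_penalty = 15))
  shuttle <- mut[mut$name == "shuttle", ]
  expect_gte(shuttle$overall_barrier, 16.0 + 15)
  expect_equal(shuttle$verdict, "ruled out")
})

test_that("TST consistency compares Eyring rates with measured turnover", {
  res <- tst_consistency(phzf_profile(), 3.23, 298.15)
  expect_equal(res$ratio, 3.597, tolerance = 0.01)
  expect_equal(res$verdict, "consistent within one order")

  res30 <- tst_consistency(30, 3.23, 298.15)
  expect_equal(res30$verdict, "inconsistent")

  same <- tst_consistency(16.0, eyring_rate(16.0, 298.15), 298.15)
  expect_equal(same$ratio, 1)
})

test_that("profile serialization round-trips losslessly", {
  pr <- phzf_profile()
  dir <- tempfile()
  paths <- export_tables(list(profile = pr), format = "tsv", dir = dir)
  back <- import_table(paths[1])
  expect_equal(back$energy, pr$energy, tolerance = 1e-15)
  expect_identical(back$label, pr$label)
  expect_identical(back$kind, pr$kind)
})
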
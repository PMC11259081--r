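test_that("total mass counts precursors, nucleotides and every residue", {
  p <- rw_params(N = 2L, T_NPB = 82, validate = FALSE)
  s <- rw_state(p, strands = strand_tbl("GAGUCUCU", "linear"))
  s$nucleotides[1, 1, 1] <- 10L
  expect_equal(total_mass(s), 82 + 10 + 8)

  expect_equal(total_mass(rw_state(rw_params(N = 2L, T_NPB = 0,
                                             validate = FALSE))), 0)
  expect_equal(total_mass(rw_state(rw_params())), 1e5)

  # substrates bound in complexes count too
  segs <- list(list(list(substrate = "AG", start = 0L)))
  s <- rw_state(rw_params(N = 2L, T_NPB = 5, validate = FALSE),
                strands = strand_tbl("GAGUCUCU", "linear", segments = segs))
  expect_equal(total_mass(s), 5 + 8 + 2)
})

test_that("state construction enforces the structural invariants", {
  p <- rw_params(N = 3L, T_NPB = 10, validate = FALSE)
  expect_error(rw_state(p, strands = strand_tbl("GA", "circular")),
               "at least 3")
  expect_error(rw_state(p, strands = strand_tbl("GAGU", "linear", row = 9)),
               "outside the grid")
  expect_error(rw_state(p, strands = strand_tbl("GAXU", "linear")),
               "A, C, G, U")
  # overlapping bound segments are rejected
  segs <- list(list(list(substrate = "AGAG", start = 0L),
                    list(substrate = "AG", start = 2L)))
  expect_error(rw_state(p, strands = strand_tbl("GAGUCUCU", "linear",
                                                segments = segs)),
               "overlap")
  # a segment longer than the template is rejected
  segs <- list(list(list(substrate = "AGAGAGAGAG", start = 0L)))
  expect_error(rw_state(p, strands = strand_tbl("GAGUCUCU", "linear",
                                                segments = segs)),
               "past a linear template")
})

test_that("circular strands are stored in canonical rotation", {
  p <- rw_params(N = 2L, T_NPB = 0, validate = FALSE)
  a <- rw_state(p, strands = strand_tbl("GAGUCUCU", "circular"))
  b <- rw_state(p, strands = strand_tbl("UCUGAGUC", "circular"))
  expect_identical(a$entities[[1]]$sequence, b$entities[[1]]$sequence)
})

test_that("mass is conserved across steps, including after inoculation", {
  p <- tiny_params()
  s <- rw_state(p)
  s2 <- rw_step(s, p, steps = 300, seed = 1, record_mass = TRUE)
  expect_identical(unique(attr(s2, "mass_trace")), 800)
  expect_equal(s2$step, 300)

  sc <- rw_scenario(tiny_params(), steps = 500,
                    inoculations = inoculation(
                      10, "GAGUCUCU", count = 3, every = 100),
                    observe_every = 100)
  run <- run_scenario(sc, seed = 3, record_mass = TRUE)
  expect_true(all(run$mass$total_mass == run$mass$expected))
  # 5 firings (steps 10, 110, ..., 410) x 3 molecules x 8 nt
  expect_equal(run$inoculated, 5 * 3 * 8)
})

test_that("stepping is resumable: the generator state travels with the state", {
  p <- tiny_params()
  s <- rw_state(p)
  once <- rw_step(s, p, steps = 40, seed = 9)
  twice <- rw_step(rw_step(s, p, steps = 15, seed = 9), p, steps = 25)
  expect_identical(state_sequences(once), state_sequences(twice))
  expect_identical(once$precursors, twice$precursors)
  expect_identical(once$nucleotides, twice$nucleotides)
  expect_equal(twice$step, 40)
  # a fresh state has no generator state to resume from
  expect_error(rw_step(s, p, steps = 1), "seed")
})
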
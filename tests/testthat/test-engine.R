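# forced-event tests: extreme probabilities make single phases deterministic,
# pinning the engine's event semantics one mechanism at a time

test_that("with all probabilities zero only the step counter moves", {
  p <- null_params()
  s <- rw_state(p, strands = strand_tbl(c("GAGUCUCU", "ACGU"),
                                        c("circular", "linear")))
  s$nucleotides[2, 3, 4] <- 7L
  s2 <- rw_step(s, p, steps = 25, seed = 1)
  expect_equal(s2$step, 25)
  expect_identical(s2$precursors, s$precursors)
  expect_identical(s2$nucleotides, s$nucleotides)
  expect_identical(state_sequences(s2), state_sequences(s))
})

test_that("an empty state stays empty", {
  p <- null_params(T_NPB = 0)
  s2 <- rw_step(rw_state(p), p, steps = 5, seed = 1)
  expect_equal(total_mass(s2), 0)
  expect_length(s2$entities, 0)
})

test_that("without decay or ligation the sequence multiset is invariant", {
  # movement and nucleotide cycling on; nothing that edits strands
  p <- null_params(P_MN = 0.1, P_MNP = 0.1, P_NF = 0.01, P_ND = 0.01,
                   T_NPB = 200)
  seqs <- c("GAGUCUCU", "AGAGACUC", "ACGUACG", "GGGG")
  s <- rw_state(p, strands = strand_tbl(seqs, c("circular", "linear",
                                                "circular", "linear"),
                                        row = c(1, 2, 3, 4)))
  before <- state_sequences(s)
  s2 <- rw_step(s, p, steps = 200, seed = 2)
  expect_identical(state_sequences(s2), before)
  expect_equal(total_mass(s2), total_mass(s))
})

test_that("forced circularization closes long-enough free linear strands", {
  p <- null_params(P_EL = 1)
  s <- rw_state(p, strands = strand_tbl(c("GAGUCUCU", "AC"),
                                        "linear", row = c(1, 2)))
  s2 <- rw_step(s, p, steps = 1, seed = 1)
  topo <- vapply(s2$entities, function(e) e$topology, character(1))
  lens <- vapply(s2$entities, function(e) nchar(e$sequence), integer(1))
  expect_identical(topo[lens == 8], "circular")
  # the 2-mer is below the minimum ring size and stays linear
  expect_identical(topo[lens == 2], "linear")
  # the ring is canonical
  expect_identical(s2$entities[[which(lens == 8)]]$sequence,
                   canonical_rotation("GAGUCUCU"))
})

test_that("a broken ring yields exactly one linear strand of the same length", {
  p <- null_params(P_BB = 1)
  s <- rw_state(p, strands = strand_tbl("GAGUCUCU", "circular"))
  s2 <- rw_step(s, p, steps = 1, seed = 4)
  expect_length(s2$entities, 1)
  e <- s2$entities[[1]]
  expect_identical(e$topology, "linear")
  expect_equal(nchar(e$sequence), 8)
  # the linear form is some rotation of the ring
  expect_true(contains_any_rotation("GAGUCUCU", e$sequence))
})

test_that("rings are immune to end decay; linear strands are not", {
  p <- null_params(P_NDE = 1, T_NPB = 0)
  s <- rw_state(p, strands = strand_tbl(c("GAGUCUCU", "ACGUA"),
                                        c("circular", "linear"),
                                        row = c(1, 2)))
  s2 <- rw_step(s, p, steps = 1, seed = 1)
  topo <- vapply(s2$entities, function(e) e$topology, character(1))
  lens <- vapply(s2$entities, function(e) nchar(e$sequence), integer(1))
  expect_true(any(topo == "circular" & lens == 8))      # untouched
  expect_true(all(lens[topo == "linear"] == 3))         # lost both ends
  # and the residues returned to the precursor pool
  expect_equal(total_mass(s2), total_mass(s))
  expect_equal(sum(s2$precursors), 2)
})

test_that("forced attraction binds a complementary nucleotide on a template", {
  p <- null_params(P_AT = 1, P_SP = 0, F_DA = 1, T_NPB = 0)   # de novo unpenalised
  s <- rw_state(p, strands = strand_tbl("GGGG", "circular"))
  s$nucleotides[1, 1, 2] <- 1L          # one C in the template's room
  s2 <- rw_step(s, p, steps = 1, seed = 1)
  e <- s2$entities[[1]]
  expect_length(e$segments, 1)
  expect_identical(e$segments[[1]]$substrate, "C")   # Watson-Crick G-C
  expect_equal(sum(s2$nucleotides), 0)
  expect_equal(total_mass(s2), 5)
})

test_that("P_FP = 1 forces every bound residue to mismatch", {
  p <- null_params(P_AT = 1, P_FP = 1, P_SP = 0, F_DA = 1)
  s <- rw_state(p, strands = strand_tbl("GGGG", "circular"))
  s$nucleotides[1, 1, 2] <- 4L
  s2 <- rw_step(s, p, steps = 2, seed = 8)
  for (sg in s2$entities[[1]]$segments) {
    expect_false(grepl("C", sg$substrate))   # never the complement of G
    expect_true(all(sg$mismatch))
  }
  # and P_FP = 0 never mismatches
  p0 <- null_params(P_AT = 1, P_FP = 0, P_SP = 0, F_DA = 1)
  s <- rw_state(p0, strands = strand_tbl("GGGG", "circular"))
  s$nucleotides[1, 1, 2] <- 4L
  s2 <- rw_step(s, p0, steps = 2, seed = 8)
  for (sg in s2$entities[[1]]$segments) {
    expect_identical(unique(strsplit(sg$substrate, "")[[1]]), "C")
    expect_false(any(sg$mismatch))
  }
})

test_that("adjacent segments ligate and a full-circle complement is released", {
  # circular 8-mer template with two adjacent 4-mer complements bound;
  # forced ligation merges them and then closes and releases the ring
  p <- null_params(P_TL = 1, P_SP = 0, T_NPB = 0)
  tpl <- "GAGUCUCU"   # already canonical? use canonical form for certainty
  tpl <- canonical_rotation(tpl)
  sub1 <- reverse_complement(substr(tpl, 1, 4))   # pairs positions 0..3
  sub2 <- reverse_complement(substr(tpl, 5, 8))   # pairs positions 4..7
  segs <- list(list(list(substrate = sub1, start = 0L),
                    list(substrate = sub2, start = 4L)))
  s <- rw_state(p, strands = strand_tbl(tpl, "circular", segments = segs))
  s2 <- rw_step(s, p, steps = 1, seed = 1)
  topo <- vapply(s2$entities, function(e) e$topology, character(1))
  expect_identical(sort(topo), c("circular", "circular"))
  nseg <- vapply(s2$entities, function(e) length(e$segments), integer(1))
  expect_true(all(nseg == 0))           # complement released, template empty
  seqs <- vapply(s2$entities, function(e) e$sequence, character(1))
  expect_true(canonical_rotation(reverse_complement(tpl)) %in% seqs)
  expect_equal(total_mass(s2), 16)

  # gaps on both sides of each segment admit no ligation
  segs <- list(list(list(substrate = substr(sub1, 1, 2), start = 0L),
                    list(substrate = substr(sub2, 1, 2), start = 5L)))
  s <- rw_state(p, strands = strand_tbl(tpl, "circular", segments = segs))
  s2 <- rw_step(s, p, steps = 1, seed = 1)
  expect_length(s2$entities[[1]]$segments, 2)
})

test_that("forced separation releases substrates as free strands", {
  p <- null_params(P_SP = 1, T_NPB = 0)
  segs <- list(list(list(substrate = "AGAG", start = 0L),
                    list(substrate = "AC", start = 5L)))
  s <- rw_state(p, strands = strand_tbl("GAGUCUCU", "linear",
                                        segments = segs))
  s2 <- rw_step(s, p, steps = 1, seed = 1)
  nseg <- vapply(s2$entities, function(e) length(e$segments), integer(1))
  expect_true(all(nseg == 0))
  seqs <- vapply(s2$entities, function(e) e$sequence, character(1))
  expect_setequal(seqs, c("GAGUCUCU", "AGAG", "AC"))
  expect_equal(total_mass(s2), 14)
})

test_that("a double-stranded break severs template and substrate together", {
  # full-cover duplex on a ring: breaking linearizes the template and the
  # covering substrate stays bound, split where the duplex was cut
  p <- null_params(P_BB = 1, T_NPB = 0)
  tpl <- canonical_rotation("GAGUCUCU")
  segs <- list(list(list(substrate = reverse_complement(tpl), start = 0L)))
  s <- rw_state(p, strands = strand_tbl(tpl, "circular", segments = segs))
  s2 <- rw_step(s, p, steps = 1, seed = 6)
  expect_length(s2$entities, 1)
  e <- s2$entities[[1]]
  expect_identical(e$topology, "linear")
  expect_equal(nchar(e$sequence), 8)
  submass <- sum(vapply(e$segments, function(sg) nchar(sg$substrate),
                        integer(1)))
  expect_equal(submass, 8)
  expect_equal(total_mass(s2), 16)
})

test_that("random ligation joins two free species left-to-right", {
  p <- null_params(P_RL = 1, T_NPB = 0)
  s <- rw_state(p, strands = strand_tbl(c("AAAA", "CCCC"), "linear"))
  s2 <- rw_step(s, p, steps = 1, seed = 1)
  expect_length(s2$entities, 1)
  e <- s2$entities[[1]]
  expect_equal(nchar(e$sequence), 8)
  expect_true(e$sequence %in% c("AAAACCCC", "CCCCAAAA"))
  expect_equal(total_mass(s2), 8)
})

test_that("mass conservation holds under randomized parameter mixes", {
  set.seed(77)
  for (i in 1:6) {
    draws <- stats::runif(14) * c(1, 0.05, 0.01, 0.2, 0.2, 0.2, 0.3, 0.05,
                                  0.1, 1, 0.01, 1, 0.3, 1)
    names(draws) <- c("P_AT", "P_BB", "P_EL", "P_FP", "P_MN", "P_MNP",
                      "P_ND", "P_NDE", "P_NF", "P_NFR", "P_RL", "P_SP",
                      "P_TL", "P_TLR")
    p <- do.call(rw_params, c(as.list(draws),
                              list(N = 3L, T_NPB = 300, validate = FALSE)))
    s <- rw_state(p, strands = strand_tbl(
      c("GAGUCUCU", "AGAGACUC", "ACGAACUG"),
      c("circular", "linear", "linear"), row = c(1, 2, 3)))
    s2 <- rw_step(s, p, steps = 150, seed = i, record_mass = TRUE)
    expect_identical(unique(attr(s2, "mass_trace")), 300 + 24,
                     label = paste("parameter mix", i))
  }
})

test_that("identical scenario and seed reproduce the run exactly", {
  sc <- rw_scenario(tiny_params(), steps = 600,
                    inoculations = inoculation(5, c("GAGUCUCU", "ACGAACUG"),
                                               count = 5),
                    observe_every = 100)
  r1 <- run_scenario(sc, seed = 123)
  r2 <- run_scenario(sc, seed = 123)
  expect_identical(r1$census, r2$census)
  expect_identical(r1$genome_lengths, r2$genome_lengths)
  expect_identical(r1$events, r2$events)
  r3 <- run_scenario(sc, seed = 124)
  expect_false(identical(r1$census, r3$census))
})

test_that("the engine census agrees with the R census on the final state", {
  sc <- rw_scenario(tiny_params(P_FP = 0.05), steps = 400,
                    inoculations = inoculation(5, c("GAGUCUCU", "UGAUGCAG"),
                                               count = 6),
                    observe_every = 400)
  run <- run_scenario(sc, seed = 21, keep_state = TRUE)
  cen_engine <- run$census[nrow(run$census), ]
  cen_r <- census(run$final_state, sc$params)
  for (cat in c(CENSUS_CATEGORIES, paste0(CENSUS_CATEGORIES, "_occ"),
                "total_mass", "n_precursors", "n_nucleotides", "n_strands")) {
    expect_equal(cen_r[[cat]], cen_engine[[cat]], label = cat)
  }
  gl_engine <- run$genome_lengths[
    run$genome_lengths$step == run$census$step[nrow(run$census)], ]
  gl_engine <- gl_engine[order(gl_engine$length), ]
  gl_r <- genome_lengths(run$final_state, sc$params)
  expect_equal(as.integer(gl_r$length), as.integer(gl_engine$length))
  expect_equal(as.numeric(gl_r$count), as.numeric(gl_engine$count))
})
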
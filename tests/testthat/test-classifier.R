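test_that("reverse complement is the antiparallel Watson-Crick mate", {
  expect_identical(reverse_complement("GAGUCUCU"), "AGAGACUC")
  expect_identical(reverse_complement("A"), "U")
  expect_error(reverse_complement("GAXU"), "A, C, G, U")

  # involution on random sequences
  set.seed(42)
  for (i in 1:20) {
    x <- random_rna(sample(1:25, 1))
    expect_identical(reverse_complement(reverse_complement(x)), x)
  }
})

test_that("reverse complement agrees with the Biostrings oracle", {
  skip_if_not_installed("Biostrings")
  set.seed(7)
  for (i in 1:20) {
    x <- random_rna(sample(1:30, 1))
    oracle <- as.character(Biostrings::reverseComplement(Biostrings::RNAString(x)))
    expect_identical(reverse_complement(x), oracle)
  }
})

test_that("containment is rotation-invariant on circular strands only", {
  expect_true(rna_contains("UCUGAGUC", "GAGUCUCU", topology = "circular"))
  expect_false(rna_contains("UCUGAGUC", "GAGUCUCU", topology = "linear"))
  # two-gene ring: each 8-nt gene is found in the 16-mer ring
  expect_true(rna_contains("GAGUCUCUUGAUGCAG", "UGAUGCAG", "circular"))
  expect_true(rna_contains("GAGUCUCUUGAUGCAG", "GAGUCUCU", "circular"))
  # motif longer than the ring can never be contained
  expect_false(rna_contains("ACG", "ACGACG", "circular"))

  # brute-force all-rotations oracle for random rings up to length 20
  set.seed(11)
  for (i in 1:60) {
    ring <- random_rna(sample(3:20, 1))
    motif <- random_rna(sample(1:6, 1))
    expect_identical(rna_contains(ring, motif, "circular"),
                     contains_any_rotation(ring, motif),
                     label = paste(ring, motif))
  }
})

test_that("canonical rotation gives equal rings equal representations", {
  set.seed(5)
  for (i in 1:30) {
    x <- random_rna(sample(3:15, 1))
    n <- nchar(x)
    k <- sample(n, 1)
    rot <- paste0(substring(x, k, n), substring(x, 1, k - 1))
    expect_identical(canonical_rotation(x), canonical_rotation(rot))
    # the canonical form is itself a rotation of the input
    expect_true(contains_any_rotation(x, canonical_rotation(x)))
  }
})

test_that("ribozyme function needs linear form, the motif, and length < 1.5x", {
  cs <- "GAGUCUCU"
  expect_true(is_functional_ribozyme("GAGUCUCU", cs))
  expect_true(is_functional_ribozyme("AGAGUCUCUAA", cs))      # 11-mer
  expect_false(is_functional_ribozyme("AGAGUCUCUAAA", cs))    # 12-mer
  expect_false(is_functional_ribozyme("GAGUCUCU", cs, "circular"))
  expect_false(is_functional_ribozyme("AAAAAAA", cs))          # no motif

  # the exclusive bound is exactly 1.5 x |cs| = 12 for an 8-nt motif
  lens <- 8:16
  seqs <- vapply(lens, function(L) {
    paste0(cs, paste(rep("A", L - 8), collapse = ""))
  }, character(1))
  expect_identical(is_functional_ribozyme(seqs, cs), lens < 12)
})

test_that("census classifies strands into the figure-legend categories", {
  p <- rw_params(N = 3L, T_NPB = 0, validate = FALSE)

  s <- rw_state(p, strands = strand_tbl("GAGUCUCU", "circular"))
  cen <- census(s, p)
  expect_equal(cen$cir_rep, 1)
  expect_equal(sum(cen[CENSUS_CATEGORIES]), 1)
  gl <- genome_lengths(s, p)
  expect_identical(gl$length, 8L)
  expect_identical(gl$count, 1L)

  # the complement ring counts in the *_com category
  s <- rw_state(p, strands = strand_tbl("AGAGACUC", "circular"))
  expect_equal(census(s, p)$cir_repcom, 1)

  # empty state: all zeros
  s <- rw_state(p)
  expect_true(all(census(s, p)[CENSUS_CATEGORIES] == 0))

  # two-gene ring counts once, in cir_repnr; histogram covers it
  s <- rw_state(p, strands = strand_tbl("GAGUCUCUUGAUGCAG", "circular"))
  cen <- census(s, p)
  expect_equal(cen$cir_repnr, 1)
  expect_equal(cen$cir_rep, 0)
  expect_equal(cen$cir_nr, 0)
  expect_equal(sum(genome_lengths(s, p)$count), cen$cir_rep + cen$cir_repnr)

  # functional-length rule separates lin_rep from lin_rep_rib
  s <- rw_state(p, strands = strand_tbl(
    c("GAGUCUCU", "GAGUCUCUAAAA"), "linear", row = c(1, 2)))
  cen <- census(s, p)
  expect_equal(cen$lin_rep, 2)
  expect_equal(cen$lin_rep_rib, 1)
})

test_that("complement-mirrored states give category-swapped censuses", {
  p <- rw_params(N = 3L, T_NPB = 0, validate = FALSE)
  set.seed(19)
  swap <- c(cir_rep = "cir_repcom", cir_repcom = "cir_rep",
            lin_rep = "lin_repcom", lin_repcom = "lin_rep",
            cir_ct = "cir_ctcom", cir_ctcom = "cir_ct")
  for (i in 1:10) {
    seqs <- c(p$CS_REP, reverse_complement(p$CS_REP), p$CS_CT,
              replicate(4, random_rna(sample(4:12, 1))))
    topo <- sample(c("linear", "circular"), length(seqs), replace = TRUE)
    topo[nchar(seqs) < 3] <- "linear"
    st <- rw_state(p, strands = strand_tbl(seqs, topo))
    st_m <- rw_state(p, strands = strand_tbl(reverse_complement(seqs), topo))
    cen <- census(st, p)
    cen_m <- census(st_m, p)
    for (cat in names(swap)) {
      expect_equal(cen_m[[swap[[cat]]]], cen[[cat]],
                   label = paste("mirror", cat, "rep", i))
    }
  }
})

test_that("bound strands are counted and flagged as occupied", {
  p <- rw_params(N = 2L, T_NPB = 0, validate = FALSE)
  segs <- list(list(list(substrate = "AGAG", start = 4L,
                         mismatch = rep(FALSE, 4))))
  s <- rw_state(p, strands = strand_tbl("GAGUCUCU", "circular",
                                        segments = segs))
  cen <- census(s, p)
  expect_equal(cen$cir_rep, 1)
  expect_equal(cen$cir_rep_occ, 1)     # the template is engaged
  expect_equal(cen$n_strands, 2)       # template + substrate
  expect_equal(cen$total_mass, 12)
})
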
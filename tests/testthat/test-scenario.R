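test_that("presets cover every documented experiment, full and desk scale", {
  tb <- rw_presets()
  base <- c("fig2a", "fig2b", "fig3", "fig4a", "fig4b", "fig5a", "fig5b",
            "fig5c", "fig5d", "fig7a", "fig7b", "s1", "s2")
  expect_setequal(tb$name, c(base, paste0(base, "_scaled")))
  expect_error(rw_preset("fig99"), "available")
})

test_that("fig2a inoculates 50 REP and 50 control linear molecules at 1e4", {
  sc <- rw_preset("fig2a")
  expect_equal(sc$params$N, 30L)
  ino <- sc$inoculations
  expect_equal(nrow(ino), 2)
  expect_setequal(ino$sequence, c("GAGUCUCU", "ACGAACUG"))
  expect_true(all(ino$step == 1e4))
  expect_true(all(ino$count == 50))
  expect_true(all(ino$topology == "linear"))
  expect_true(all(ino$every == 0))
})

test_that("fig2b inoculates single molecules periodically until spread", {
  sc <- rw_preset("fig2b")
  ino <- sc$inoculations
  expect_true(all(ino$count == 1))
  expect_true(all(ino$every == 1e4))
  expect_true(all(ino$until_stop))
  expect_equal(sc$stop_rule$category, "cir_rep")
  expect_equal(sc$stop_rule$threshold, 20)
  expect_equal(sc$stop_rule$consecutive, 10L)
})

test_that("fig3 scopes F_LT to REP carriers and their complements; fig4a does not", {
  iv3 <- rw_preset("fig3")$interventions
  fl3 <- iv3[iv3$parameter == "F_LT", ]
  expect_equal(fl3$step, 2.5e6)
  expect_equal(fl3$value, 0)
  expect_identical(fl3$scope_topology, "linear")
  expect_identical(fl3$scope_motif, "GAGUCUCU")
  expect_true(fl3$scope_revcomp)
  tlr <- iv3[iv3$parameter == "P_TLR", ]
  expect_equal(tlr$step, 5e6)
  expect_equal(tlr$value, 0)
  expect_false(tlr$scoped)

  iv4 <- rw_preset("fig4a")$interventions
  expect_true(all(iv4$parameter == "F_LT"))
  expect_equal(iv4$value, c(0.2, 0.1, 0))
  expect_false(any(iv4$scope_revcomp))     # complements keep templating
  expect_true(all(iv4$scope_motif == "GAGUCUCU"))
})

test_that("fig4b additionally forbids circularization from the start", {
  sc <- rw_preset("fig4b")
  expect_equal(sc$params$P_EL, 0)
  expect_equal(nrow(sc$interventions), 3)
})

test_that("fig7 presets carry the published overrides and 16-mer genomes", {
  sc <- rw_preset("fig7a")
  ino <- sc$inoculations
  expect_setequal(ino$sequence,
                  c("GAGUCUCUUGAUGCAG", "ACGAACUGAACGCUCG"))
  expect_true(all(ino$topology == "circular"))
  expect_true(all(ino$count == 100))

  sc <- rw_preset("fig7b")
  p <- sc$params
  expect_equal(p$T_NPB, 2e5)
  expect_equal(p$P_BB, 2e-5)
  expect_equal(p$P_FP, 0.01)
  expect_equal(p$P_NDE, 0.002)
  expect_equal(p$P_NF, 0.001)
  # one-gene genome = REP + noncoding, one substitution from CS_NR
  expect_true("GAGUCUCUUGACGCAG" %in% sc$inoculations$sequence)
  ncd <- "UGACGCAG"
  d <- mapply(function(a, b) a != b,
              strsplit(ncd, "")[[1]], strsplit(p$CS_NR, "")[[1]])
  expect_equal(sum(d), 1)
})

test_that("s2 redefines CS_NR one substitution away from CS_REP", {
  sc <- rw_preset("s2")
  p <- sc$params
  d <- mapply(function(a, b) a != b,
              strsplit(p$CS_NR, "")[[1]], strsplit(p$CS_REP, "")[[1]])
  expect_equal(sum(d), 1)
  expect_equal(p$P_FP, 0.01)
  expect_true(paste0(p$CS_REP, p$CS_REP) %in% sc$inoculations$sequence)
})

test_that("scaled variants shrink the system proportionally", {
  a <- rw_preset("fig2a")
  b <- rw_preset("fig2a_scaled")
  expect_equal(b$params$N, 15L)
  expect_equal(b$params$T_NPB, a$params$T_NPB / 4)
  expect_equal(b$steps, a$steps / 10)
  expect_equal(b$inoculations$step, a$inoculations$step / 10)

  c2 <- rw_preset("fig2b_scaled")
  expect_equal(c2$inoculations$every, c(2000, 2000))
  expect_equal(c2$steps, 3e5)

  # the long intervention experiments carry an extra factor of two in time
  f4 <- rw_preset("fig4a_scaled")
  expect_equal(f4$steps, 4e5)
  expect_equal(f4$interventions$step, c(1e5, 2e5, 3e5))
})

test_that("scenario validation rejects malformed configurations", {
  expect_error(rw_scenario(tiny_params(), steps = 0), "steps")
  expect_error(rw_scenario(tiny_params(), steps = 10, observe_every = 0),
               "observe_every")
  expect_error(inoculation(10, "GAGUCUCU", count = 0), "count")
  expect_error(inoculation(10, "GA", topology = "circular"), "3 nt")
  expect_error(intervention(5, "T_NPB", 10), "cannot intervene")
  expect_error(intervention(5, "P_AT", 1.5), "outside")
  expect_error(intervention(5, "P_TLR", 0, scope_topology = "linear"),
               "F_LT only")
  expect_error(stop_rule("not_a_category"), "category")
})

test_that("a one-step run of an empty scenario yields one all-zero census", {
  sc <- rw_scenario(rw_params(N = 3L, T_NPB = 0, validate = FALSE), steps = 1,
                    observe_every = 1)
  run <- run_scenario(sc, seed = 1)
  expect_equal(nrow(run$census), 1)
  expect_true(all(run$census[CENSUS_CATEGORIES] == 0))
})

test_that("scenarios round-trip through the config file", {
  sc <- rw_scenario(
    tiny_params(P_FP = 1 / 3), steps = 5000, seed = 7L,
    inoculations = dplyr::bind_rows(
      inoculation(10, "GAGUCUCU", count = 5),
      inoculation(100, "ACGAACUG", count = 1, every = 50, until_stop = TRUE)),
    interventions = dplyr::bind_rows(
      intervention(1000, "P_TLR", 0),
      intervention(2000, "F_LT", 0.25, scope_topology = "linear",
                   scope_motif = "GAGUCUCU", scope_revcomp = TRUE)),
    stop_rule = stop_rule("cir_rep", 10, 3),
    observe_every = 250, snapshot_steps = c(1000, 5000), name = "round")
  path <- withr::local_tempfile(fileext = ".yaml")
  write_scenario(sc, path)
  sc2 <- read_scenario(path)
  expect_identical(unclass(sc2$params), unclass(sc$params))
  expect_equal(sc2$steps, sc$steps)
  expect_identical(sc2$seed, sc$seed)
  expect_equal(as.data.frame(sc2$inoculations), as.data.frame(sc$inoculations))
  expect_equal(as.data.frame(sc2$interventions),
               as.data.frame(sc$interventions))
  expect_identical(sc2$stop_rule, sc$stop_rule)
  expect_equal(sc2$observe_every, sc$observe_every)
  expect_equal(sc2$snapshot_steps, sc$snapshot_steps)
})

test_that("an intervention leaves the trajectory before its step untouched", {
  base <- rw_scenario(tiny_params(), steps = 600,
                      inoculations = inoculation(5, "GAGUCUCU", count = 10),
                      observe_every = 50)
  with_iv <- base
  with_iv$interventions <- intervention(301, "P_TLR", 0)
  r0 <- run_scenario(base, seed = 5)
  r1 <- run_scenario(with_iv, seed = 5)
  pre <- r0$census$step <= 300
  expect_identical(r1$census[pre, ], r0$census[pre, ])
})

test_that("with circularization off no ring ever appears", {
  sc <- rw_scenario(tiny_params(P_EL = 0), steps = 2000,
                    inoculations = inoculation(5, c("GAGUCUCU", "ACGAACUG"),
                                               count = 10),
                    observe_every = 100)
  run <- run_scenario(sc, seed = 2)
  circ_cols <- c("cir_rep", "cir_repcom", "cir_ct", "cir_ctcom",
                 "cir_repnr", "cir_nr")
  expect_true(all(run$census[circ_cols] == 0))
  expect_equal(nrow(run$genome_lengths), 0)
})
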
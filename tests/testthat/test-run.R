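# a small scenario with enough going on to exercise every output surface
run_fixture <- function(seed = 31, ...) {
  sc <- rw_scenario(
    tiny_params(N = 5L, T_NPB = 1500), steps = 1500,
    inoculations = inoculation(5, c("GAGUCUCU", "ACGAACUG"), count = 10),
    observe_every = 300, snapshot_steps = c(600, 1500))
  run_scenario(sc, seed = seed, ...)
}

test_that("the run object is internally consistent", {
  run <- run_fixture()
  cen <- run$census
  expect_s3_class(cen, "tbl_df")
  expect_identical(cen$step, seq(300, 1500, by = 300) + 0)
  # occupied counts never exceed raw counts
  for (cat in CENSUS_CATEGORIES) {
    expect_true(all(cen[[paste0(cat, "_occ")]] <= cen[[cat]]), label = cat)
  }
  # histogram total equals the circular REP-carrier count at each observation
  gl <- run$genome_lengths
  by_step <- tapply(gl$count, gl$step, sum)
  for (st in names(by_step)) {
    i <- match(as.numeric(st), cen$step)
    expect_equal(unname(by_step[[st]]), cen$cir_rep[i] + cen$cir_repnr[i])
  }
  expect_true(all(cen$total_mass == cen$total_mass[1]))
})

test_that("snapshot channels sum to the global census", {
  run <- run_fixture()
  expect_length(run$snapshots, 2)
  for (sn in run$snapshots) {
    i <- match(sn$step, run$census$step)
    expect_false(is.na(i))
    for (cat in CENSUS_CATEGORIES) {
      m <- sn$channels[[cat]]
      expect_identical(dim(m), c(5L, 5L))
      expect_equal(sum(m), run$census[[cat]][i], label = cat)
    }
    expect_equal(sum(sn$channels$precursors), run$census$n_precursors[i])
    expect_equal(sum(sn$channels$free_nucleotides),
                 run$census$n_nucleotides[i])
  }
})

test_that("tidy and glance summarise a run in the broom idiom", {
  run <- run_fixture()
  long <- tidy(run)
  expect_s3_class(long, "tbl_df")
  expect_identical(names(long), c("step", "category", "count"))
  expect_equal(nrow(long), nrow(run$census) * 10)
  wide_back <- tidyr::pivot_wider(long, names_from = "category",
                                  values_from = "count")
  expect_equal(as.data.frame(wide_back[CENSUS_CATEGORIES]),
               as.data.frame(run$census[CENSUS_CATEGORIES]))

  long_occ <- tidy(run, occupied = TRUE)
  expect_true("occupied" %in% names(long_occ))

  g <- glance(run)
  expect_equal(nrow(g), 1)
  expect_equal(g$steps, 1500)
  expect_equal(g$total_mass, run$census$total_mass[nrow(run$census)])
})

test_that("autoplot and the companion plots return ggplots", {
  run <- run_fixture()
  expect_s3_class(autoplot(run), "ggplot")
  expect_s3_class(plot_snapshot(run, 600, "precursors"), "ggplot")
  expect_error(plot_snapshot(run, 999), "recorded")
  if (nrow(run$genome_lengths)) {
    expect_s3_class(plot_genome_lengths(run), "ggplot")
  }
})

test_that("replicate batches summarise spread across seeds", {
  sc <- rw_scenario(tiny_params(N = 4L, T_NPB = 600), steps = 400,
                    inoculations = inoculation(5, "GAGUCUCU", count = 5),
                    observe_every = 100)
  res <- run_replicates(sc, seeds = 1:3)
  expect_equal(nrow(res), 3)
  expect_identical(res$seed, 1:3)
  expect_true(all(c("spread", "modal_genome_length") %in% names(res)))
  expect_true(attr(res, "spread_fraction") >= 0 &&
              attr(res, "spread_fraction") <= 1)
})

test_that("the modal genome length breaks ties towards the smaller length", {
  fake <- structure(list(genome_lengths = tibble::tibble(
    step = c(10, 10, 10), length = c(8L, 9L, 12L), count = c(5, 5, 2)
  )), class = "rw_run")
  expect_identical(modal_genome_length(fake), 8L)
  expect_identical(modal_genome_length(fake, at = 10), 8L)
  empty <- structure(list(genome_lengths = tibble::tibble(
    step = numeric(0), length = integer(0), count = numeric(0)
  )), class = "rw_run")
  expect_true(is.na(modal_genome_length(empty)))
})
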
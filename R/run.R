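#' Run a scenario
#'
#' Executes a scenario: seeds the generator, scatters the `T_NPB` nucleotide
#' precursors over uniformly chosen rooms, then iterates Monte Carlo steps,
#' firing inoculations and interventions at their scheduled steps, recording
#' a species census every `observe_every` steps (and at the final step) and
#' spatial snapshots at the requested steps.  Identical `(scenario, seed)`
#' pairs produce identical output, byte for byte.
#'
#' @param scenario an [rw_scenario] (e.g. from [rw_preset()]).
#' @param seed integer RNG seed; defaults to the scenario's own `seed`.
#' @param record_mass if `TRUE`, record [total_mass()] (and the running
#'   material budget including inoculations) after every step -- the mass
#'   tibble appears as `$mass`.
#' @param keep_state if `TRUE`, return the final [rw_state] as
#'   `$final_state`.
#' @param verbose 0 (silent), 1 (final summary line to stderr), or 2
#'   (summary at every observation).
#'
#' @return An object of class `"rw_run"`: a list with
#'   * `census`: tibble, one row per observation -- `step`, the ten category
#'     counts, `*_occ` companions, `total_mass`, `n_precursors`,
#'     `n_nucleotides`, `n_strands`;
#'   * `genome_lengths`: long tibble (`step`, `length`, `count`) of
#'     REP-carrying circular genome lengths;
#'   * `snapshots`: list of per-step channel matrices;
#'   * `events`: named cumulative event counts;
#'   * `manifest`: everything needed to replay the run (see
#'     [write_manifest()]);
#'   * `stopped_at`: observation step at which the stop rule fired (or `NA`);
#'   * optionally `mass` and `final_state`.
#' @examples
#' sc <- rw_scenario(rw_params(N = 6, T_NPB = 3000), steps = 2000,
#'                   inoculations = inoculation(10, "GAGUCUCU", count = 20),
#'                   observe_every = 500)
#' run <- run_scenario(sc, seed = 1)
#' run$census
#' @export
run_scenario <- function(scenario, seed = NULL, record_mass = FALSE,
                         keep_state = FALSE, verbose = 0) {
  stopifnot(inherits(scenario, "rw_scenario"))
  seed <- seed %||% scenario$seed
  if (is.null(seed)) abort("no seed: pass `seed` or set it in the scenario")
  seed <- as.integer(seed)
  validate_parameters(scenario$params, quiet = TRUE)

  ino <- scenario$inoculations
  cfg <- list(
    params = unclass(scenario$params),
    steps = scenario$steps,
    seed = seed,
    observe_every = scenario$observe_every,
    snapshot_steps = scenario$snapshot_steps,
    inoculations = if (is.null(ino) || !nrow(ino)) NULL else as.list(ino),
    interventions = if (is.null(scenario$interventions) ||
                        !nrow(scenario$interventions)) NULL
                    else as.list(scenario$interventions),
    stop_rule = scenario$stop_rule,
    record_mass = isTRUE(record_mass),
    keep_state = isTRUE(keep_state),
    verbose = as.integer(verbose)
  )
  res <- cpp_run(cfg)

  census <- as_tibble(cbind(step = res$step, as.data.frame(res$census)))
  gl <- tibble(step = res$hist_step, length = as.integer(res$hist_length),
               count = res$hist_count)
  out <- list(
    census = census,
    genome_lengths = gl,
    snapshots = res$snapshots,
    events = res$counters,
    stopped_at = if (res$stopped_at < 0) NA_real_ else res$stopped_at,
    inoculated = res$inoculated,
    manifest = list(
      package = "rwsim",
      version = as.character(packageVersion("rwsim")),
      scenario = scenario,
      seed = seed,
      steps = scenario$steps,
      created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    )
  )
  if (isTRUE(record_mass)) {
    out$mass <- tibble(step = seq_along(res$mass_trace),
                       total_mass = res$mass_trace,
                       expected = res$mass_expected)
  }
  if (isTRUE(keep_state)) {
    st <- structure(res$final_state, class = "rw_state")
    st$base_mass <- scenario$params$T_NPB
    out$final_state <- st
  }
  structure(out, class = "rw_run")
}

#' @export
print.rw_run <- function(x, ...) {
  n <- nrow(x$census)
  cat(sprintf("<rw_run> %s observations to step %s (seed %d)\n",
              format(n, big.mark = ","),
              format(x$census$step[n], big.mark = ","), x$manifest$seed))
  fin <- x$census[n, CENSUS_CATEGORIES]
  nz <- fin[, vapply(fin, function(v) v > 0, logical(1)), drop = FALSE]
  if (ncol(nz)) {
    cat("  final counts:",
        paste(names(nz), unlist(nz), sep = "=", collapse = "  "), "\n")
  } else cat("  final counts: all categories zero\n")
  ml <- modal_genome_length(x)
  if (!is.na(ml)) cat("  modal circular REP genome length:", ml, "nt\n")
  invisible(x)
}

#' Tidy a run into long format
#'
#' One row per observation x category, ready for `ggplot2` or dplyr
#' summaries.
#'
#' @param x an `rw_run`.
#' @param occupied include the bound-inside-a-complex (`*_occ`) companion
#'   counts as an extra `occupied` column?
#' @param ... unused.
#' @return tibble with columns `step`, `category`, `count` (and optionally
#'   `occupied`).
#' @method tidy rw_run
#' @export
tidy.rw_run <- function(x, occupied = FALSE, ...) {
  long <- tidyr::pivot_longer(
    x$census[, c("step", CENSUS_CATEGORIES)],
    cols = all_of(CENSUS_CATEGORIES),
    names_to = "category", values_to = "count")
  if (occupied) {
    occ <- tidyr::pivot_longer(
      x$census[, c("step", paste0(CENSUS_CATEGORIES, "_occ"))],
      cols = -"step", names_to = "category", values_to = "occupied")
    occ$category <- sub("_occ$", "", occ$category)
    long <- left_join(long, occ, by = c("step", "category"))
  }
  long$category <- factor(long$category, levels = CENSUS_CATEGORIES)
  long
}

#' One-row summary of a run
#'
#' @param x an `rw_run`.
#' @param spread_threshold count defining "the genome has spread" for the
#'   `spread` flag and `spread_step`.
#' @param ... unused.
#' @return one-row tibble: final step, final category counts, the modal
#'   circular REP genome length, whether/when `cir_rep` first reached the
#'   spread threshold, and the stop-rule step.
#' @method glance rw_run
#' @export
glance.rw_run <- function(x, spread_threshold = 20, ...) {
  n <- nrow(x$census)
  fin <- x$census[n, ]
  sp <- x$census$step[x$census$cir_rep >= spread_threshold]
  tibble(
    steps = fin$step,
    cir_rep = fin$cir_rep, cir_repcom = fin$cir_repcom,
    cir_repnr = fin$cir_repnr, cir_nr = fin$cir_nr,
    lin_rep = fin$lin_rep, lin_rep_rib = fin$lin_rep_rib,
    lin_nr_rib = fin$lin_nr_rib, cir_ct = fin$cir_ct,
    total_mass = fin$total_mass,
    modal_genome_length = modal_genome_length(x),
    spread = length(sp) > 0,
    spread_step = if (length(sp)) sp[1] else NA_real_,
    stopped_at = x$stopped_at
  )
}

#' Modal circular genome length
#'
#' The most abundant length among REP-carrying circular genomes at an
#' observation step (default: the final one).  Ties break towards the
#' smaller length; `NA` if no such genome exists.
#'
#' @param run an `rw_run`.
#' @param at observation step (default final).
#' @return integer length in nt, or `NA`.
#' @export
modal_genome_length <- function(run, at = NULL) {
  gl <- run$genome_lengths
  if (!nrow(gl)) return(NA_integer_)
  at <- at %||% max(gl$step)
  gl <- gl[gl$step == at, ]
  if (!nrow(gl)) return(NA_integer_)
  gl <- gl[order(-gl$count, gl$length), ]
  as.integer(gl$length[1])
}

#' Run a scenario under several seeds
#'
#' Convenience wrapper for replicate batches: runs the scenario once per
#' seed and binds the [glance.rw_run()] rows, attaching a small summary --
#' the fraction of runs in which the circular REP genome spread and the
#' modal final genome length across seeds.
#'
#' @param scenario an [rw_scenario].
#' @param seeds integer vector of seeds.
#' @param spread_threshold passed to [glance.rw_run()].
#' @param verbose passed to [run_scenario()].
#' @return tibble with one row per seed (column `seed` first); attributes
#'   `spread_fraction` and `modal_length` carry the batch summary.
#' @export
run_replicates <- function(scenario, seeds, spread_threshold = 20,
                           verbose = 0) {
  rows <- lapply(seeds, function(s) {
    g <- glance(run_scenario(scenario, seed = s, verbose = verbose),
                spread_threshold = spread_threshold)
    cbind(tibble(seed = as.integer(s)), g)
  })
  out <- as_tibble(bind_rows(rows))
  attr(out, "spread_fraction") <- mean(out$spread)
  ml <- out$modal_genome_length[!is.na(out$modal_genome_length)]
  attr(out, "modal_length") <- if (length(ml)) majority_value(ml) else NA_integer_
  out
}

# the value held by the most seeds; ties break towards the smaller value
majority_value <- function(x) {
  tb <- sort(table(x), decreasing = TRUE)
  top <- as.integer(names(tb)[tb == tb[1]])
  min(top)
}
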
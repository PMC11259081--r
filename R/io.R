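#' Write and read the census time series
#'
#' The time series is a TSV with a header row -- `step`, the ten category
#' columns named exactly as in the figure legends (`cir_rep`, `cir_repcom`,
#' `lin_rep`, `lin_repcom`, `cir_ct`, `cir_ctcom`, `cir_repnr`, `cir_nr`,
#' `lin_rep_rib`, `lin_nr_rib`), their `*_occ` companions, and the
#' diagnostic columns -- and one row per observation.  Formatting is
#' deterministic: replaying a run with the same seed reproduces the file
#' byte for byte.
#'
#' @param x an `rw_run` or a census tibble.
#' @param path destination file.
#' @return `write_timeseries()` returns `path` invisibly;
#'   `read_timeseries()` returns a tibble.
#' @export
write_timeseries <- function(x, path) {
  census <- if (inherits(x, "rw_run")) x$census else x
  if (!is.data.frame(census) || !nrow(census)) {
    abort("no census observations to write")
  }
  readr::write_tsv(census, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_timeseries
#' @export
read_timeseries <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Write the genome-length histogram series
#'
#' Long-format TSV: `step`, `length`, `count` for REP-carrying circular
#' genomes at every observation.
#'
#' @inheritParams write_timeseries
#' @export
write_genome_lengths <- function(x, path) {
  gl <- if (inherits(x, "rw_run")) x$genome_lengths else x
  readr::write_tsv(gl, path, progress = FALSE)
  invisible(path)
}

#' Write a spatial snapshot
#'
#' Each snapshot channel (nucleotide precursors, free nucleotides, and the
#' ten census categories) is an `N x N` integer matrix of per-room counts;
#' every channel is written as a plain-matrix TSV (no header) to
#' `<stem>.<channel>.tsv`.  Summing a category channel over rooms
#' reproduces that category's global census count at the snapshot step.
#'
#' @param snapshot one element of an `rw_run`'s `$snapshots` list (a list
#'   with `step` and `channels`).
#' @param stem path stem for the channel files.
#' @return invisibly, the written file paths.
#' @export
write_snapshot <- function(snapshot, stem) {
  chans <- snapshot$channels
  paths <- character(0)
  for (nm in names(chans)) {
    p <- paste0(stem, ".", nm, ".tsv")
    readr::write_tsv(as.data.frame(chans[[nm]]), p, col_names = FALSE,
                     progress = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Run manifest
#'
#' A JSON record sufficient to replay a run exactly: package version, the
#' full scenario (parameters, schedules, stop rule, observation plan), the
#' seed, and the output files written alongside.  `read_manifest()` rebuilds
#' the [rw_scenario] so that `run_scenario(read_manifest(p)$scenario,
#' read_manifest(p)$seed)` reproduces the outputs byte for byte.
#'
#' @param run an `rw_run`.
#' @param path manifest path.
#' @param outputs optional character vector of output file names recorded in
#'   the manifest.
#' @export
write_manifest <- function(run, path, outputs = character(0)) {
  m <- run$manifest
  sc <- m$scenario
  doc <- list(
    package = m$package, version = m$version, created = m$created,
    seed = m$seed, steps = sc$steps, name = sc$name,
    observe_every = sc$observe_every, snapshot_steps = sc$snapshot_steps,
    params = unclass(sc$params),
    inoculations = sc$inoculations, interventions = sc$interventions,
    stop_rule = sc$stop_rule,
    stopped_at = run$stopped_at, inoculated = run$inoculated,
    outputs = outputs
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  pv <- doc$params
  for (f in names(pv)) {
    if (!f %in% c("CS_REP", "CS_NR", "CS_CT")) pv[[f]] <- as.numeric(pv[[f]])
  }
  for (f in c("N", "T_REP", "T_NR")) pv[[f]] <- as.integer(pv[[f]])
  params <- do.call(rw_params, c(pv, list(validate = FALSE)))
  validate_parameters(params, quiet = TRUE)
  ino <- if (!is.null(doc$inoculations) && length(doc$inoculations)) {
    as_tibble(doc$inoculations)
  }
  iv <- if (!is.null(doc$interventions) && length(doc$interventions)) {
    v <- as_tibble(doc$interventions)
    # JSON drops NA strings to NULL; restore absent scope columns
    for (f in c("scope_topology", "scope_motif")) {
      if (is.null(v[[f]])) v[[f]] <- NA_character_
    }
    v
  }
  sr <- if (!is.null(doc$stop_rule)) {
    stop_rule(doc$stop_rule$category, doc$stop_rule$threshold,
              doc$stop_rule$consecutive)
  }
  sc <- rw_scenario(params = params, steps = doc$steps, seed = doc$seed,
                    inoculations = ino, interventions = iv, stop_rule = sr,
                    observe_every = doc$observe_every,
                    snapshot_steps = doc$snapshot_steps %||% numeric(0),
                    name = doc$name)
  list(scenario = sc, seed = doc$seed, version = doc$version,
       outputs = doc$outputs)
}

#' Write all outputs of a run
#'
#' Writes `timeseries.tsv`, `genome_lengths.tsv`, one snapshot file set per
#' recorded snapshot (`snapshot_<step>.<channel>.tsv`) and `manifest.json`
#' into a directory.
#'
#' @param run an `rw_run`.
#' @param dir destination directory (created if missing).
#' @return invisibly, the directory.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- c("timeseries.tsv", "genome_lengths.tsv")
  write_timeseries(run, file.path(dir, "timeseries.tsv"))
  write_genome_lengths(run, file.path(dir, "genome_lengths.tsv"))
  for (sn in run$snapshots) {
    stem <- file.path(dir, sprintf("snapshot_%d", as.integer(sn$step)))
    write_snapshot(sn, stem)
    outputs <- c(outputs, sprintf("snapshot_%d.*.tsv", as.integer(sn$step)))
  }
  write_manifest(run, file.path(dir, "manifest.json"), outputs = outputs)
  invisible(dir)
}
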
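#' Scenario building blocks
#'
#' `inoculation()` describes molecules added to the system at uniformly
#' chosen random rooms, either once (at `step`) or periodically (`every`
#' steps starting at `step`).  A periodic inoculation with
#' `until_stop = TRUE` ceases once the scenario's stop rule triggers.
#'
#' `intervention()` describes a timed parameter change.  An unscoped
#' intervention rewrites a global parameter at `step`, before that step
#' executes.  A species-scoped intervention (supported for the
#' linear-template factor `F_LT`, the one per-template parameter) installs a
#' resolver: templates matching the scope -- a topology plus a required
#' motif, optionally "or its reverse complement" -- use the new value, with
#' later interventions taking precedence.
#'
#' `stop_rule()` declares when "spread is evident": a census category
#' staying at or above `threshold` for `consecutive` consecutive
#' observations.  Its only effect is to end `until_stop` inoculations.
#'
#' @param step 1-based Monte Carlo step at which the event fires (step 0 is
#'   treated as "before the first step").
#' @param sequence RNA string(s) of the inoculated molecules.
#' @param topology `"linear"` or `"circular"` (recycled).
#' @param count copies per firing (recycled).
#' @param every period in steps; 0 means fire once.
#' @param until_stop stop this periodic inoculation when the stop rule fires?
#' @param parameter name of an [rw_params] field (not `N`, `T_NPB` or a
#'   characteristic sequence).
#' @param value new value, within the parameter's legal range.
#' @param scope_topology,scope_motif,scope_revcomp species scope: topology
#'   (`"linear"`, `"circular"` or `NA` for any), required motif, and whether
#'   the motif's reverse complement also matches.  All `NA`/`FALSE` means an
#'   unscoped (global) intervention.
#' @param category census category watched by the stop rule.
#' @param threshold count that must be reached.
#' @param consecutive number of consecutive observations at or above
#'   `threshold`.
#' @return a tibble with one row per event.
#' @examples
#' inoculation(1e4, c("GAGUCUCU", "ACGAACUG"), "linear", count = 50)
#' intervention(2.5e6, "F_LT", 0, scope_topology = "linear",
#'              scope_motif = "GAGUCUCU", scope_revcomp = TRUE)
#' stop_rule()
#' @name scenario_events
NULL

#' @rdname scenario_events
#' @export
inoculation <- function(step, sequence, topology = "linear", count = 1,
                        every = 0, until_stop = FALSE) {
  check_rna(sequence)
  n <- length(sequence)
  out <- tibble(
    step = as.numeric(rep_len(step, n)),
    sequence = sequence,
    topology = rep_len(topology, n),
    count = as.numeric(rep_len(count, n)),
    every = as.numeric(rep_len(every, n)),
    until_stop = rep_len(until_stop, n)
  )
  if (any(out$step < 0)) abort("inoculation step must be >= 0")
  if (any(out$count < 1)) abort("inoculation count must be >= 1")
  if (!all(out$topology %in% c("linear", "circular"))) {
    abort("topology must be \"linear\" or \"circular\"")
  }
  if (any(out$topology == "circular" & nchar(out$sequence) < 3)) {
    abort("a circular molecule must be at least 3 nt")
  }
  out
}

#' @rdname scenario_events
#' @export
intervention <- function(step, parameter, value, scope_topology = NA,
                         scope_motif = NA, scope_revcomp = FALSE) {
  out <- tibble(
    step = as.numeric(step), parameter = parameter, value = as.numeric(value),
    scope_topology = as.character(scope_topology),
    scope_motif = as.character(scope_motif),
    scope_revcomp = as.logical(scope_revcomp)
  )
  out$scoped <- !is.na(out$scope_topology) | !is.na(out$scope_motif)
  allowed <- c(PROB_FIELDS, "F_DA", "F_LT", "T_REP", "T_NR")
  for (i in seq_len(nrow(out))) {
    pn <- out$parameter[i]
    if (!pn %in% allowed) {
      abort(paste0("cannot intervene on parameter '", pn, "'"))
    }
    v <- out$value[i]
    if (pn %in% PROB_FIELDS && (v < 0 || v > 1)) {
      abort(paste0(pn, " intervention value outside [0, 1]"))
    }
    if (pn == "F_DA" && v < 1) abort("F_DA intervention value must be >= 1")
    if (pn == "F_LT" && (v < 0 || v > 1)) {
      abort("F_LT intervention value outside [0, 1]")
    }
    if (out$scoped[i] && pn != "F_LT") {
      abort("species-scoped interventions are supported for F_LT only")
    }
    if (!is.na(out$scope_topology[i]) &&
        !out$scope_topology[i] %in% c("linear", "circular")) {
      abort("scope_topology must be \"linear\", \"circular\" or NA")
    }
    if (!is.na(out$scope_motif[i])) check_rna(out$scope_motif[i])
  }
  out
}

#' @rdname scenario_events
#' @export
stop_rule <- function(category = "cir_rep", threshold = 20, consecutive = 10) {
  if (!category %in% CENSUS_CATEGORIES) {
    abort(paste0("unknown census category '", category, "'"))
  }
  stopifnot(threshold >= 1, consecutive >= 1)
  list(category = category, threshold = as.numeric(threshold),
       consecutive = as.integer(consecutive))
}

#' Declare a simulation scenario
#'
#' A scenario bundles everything a run needs: the parameter record, the run
#' length, the seed, inoculation and intervention schedules, an optional
#' stop rule, the census observation interval and the steps at which spatial
#' snapshots are taken.  A `(scenario, seed)` pair determines the run
#' exactly.
#'
#' @param params an [rw_params] record.
#' @param steps run length in Monte Carlo steps (>= 1).
#' @param seed default RNG seed for [run_scenario()] (overridable there).
#' @param inoculations tibble from [inoculation()] (rows may be
#'   `dplyr::bind_rows()`-ed together), or `NULL`.
#' @param interventions tibble from [intervention()], or `NULL`.
#' @param stop_rule list from [stop_rule()], or `NULL`.
#' @param observe_every census observation interval in steps (>= 1).
#' @param snapshot_steps steps at which to record spatial snapshots.
#' @param name optional label (presets set it to the preset name).
#' @return a list with class `"rw_scenario"`.
#' @examples
#' sc <- rw_scenario(rw_params(N = 10, T_NPB = 2000), steps = 1000,
#'                   inoculations = inoculation(10, "GAGUCUCU", count = 5),
#'                   observe_every = 100)
#' @export
rw_scenario <- function(params = rw_params(), steps, seed = NULL,
                        inoculations = NULL, interventions = NULL,
                        stop_rule = NULL, observe_every = 1000,
                        snapshot_steps = numeric(0), name = NULL) {
  stopifnot(inherits(params, "rw_params"))
  if (!is.numeric(steps) || length(steps) != 1 || steps < 1) {
    abort("steps must be >= 1")
  }
  if (!is.numeric(observe_every) || observe_every < 1) {
    abort("observe_every must be >= 1")
  }
  if (!is.null(inoculations)) {
    needed <- c("step", "sequence", "topology", "count", "every", "until_stop")
    if (!all(needed %in% names(inoculations))) {
      abort("inoculations must come from inoculation()")
    }
  }
  if (!is.null(interventions)) {
    needed <- c("step", "parameter", "value", "scope_topology", "scope_motif",
                "scope_revcomp", "scoped")
    if (!all(needed %in% names(interventions))) {
      abort("interventions must come from intervention()")
    }
  }
  structure(list(
    params = params, steps = as.numeric(steps),
    seed = if (is.null(seed)) NULL else as.integer(seed),
    inoculations = inoculations, interventions = interventions,
    stop_rule = stop_rule, observe_every = as.numeric(observe_every),
    snapshot_steps = as.numeric(snapshot_steps), name = name
  ), class = "rw_scenario")
}

#' @export
print.rw_scenario <- function(x, ...) {
  cat(sprintf("<rw_scenario>%s\n",
              if (!is.null(x$name)) paste0(" \"", x$name, "\"") else ""))
  cat(sprintf("  grid %dx%d, T_NPB %s, %s steps, observe every %s\n",
              x$params$N, x$params$N, format(x$params$T_NPB, big.mark = ","),
              format(x$steps, big.mark = ","),
              format(x$observe_every, big.mark = ",")))
  cat(sprintf("  inoculations: %d  interventions: %d  stop rule: %s  seed: %s\n",
              if (is.null(x$inoculations)) 0L else nrow(x$inoculations),
              if (is.null(x$interventions)) 0L else nrow(x$interventions),
              if (is.null(x$stop_rule)) "none" else
                paste0(x$stop_rule$category, " >= ", x$stop_rule$threshold),
              if (is.null(x$seed)) "unset" else x$seed))
  invisible(x)
}

#' Read and write scenario files
#'
#' Scenarios serialize to a YAML document: a flat `params` block (see
#' [write_params()]), scalar run settings, and lists of inoculation /
#' intervention records.  Numbers use 17 significant digits so the
#' round-trip is exact.
#'
#' @param scenario an [rw_scenario].
#' @param path file path.
#' @return `read_scenario()` returns an [rw_scenario]; `write_scenario()`
#'   returns `path` invisibly.
#' @export
write_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "rw_scenario"))
  ln <- character(0)
  add <- function(...) ln <<- c(ln, paste0(...))
  if (!is.null(scenario$name)) add("name: ", scenario$name)
  add("steps: ", yaml_scalar(scenario$steps))
  if (!is.null(scenario$seed)) add("seed: ", scenario$seed)
  add("observe_every: ", yaml_scalar(scenario$observe_every))
  if (length(scenario$snapshot_steps)) {
    add("snapshot_steps: [",
        paste(vapply(scenario$snapshot_steps, yaml_scalar, character(1)),
              collapse = ", "), "]")
  }
  add("params:")
  for (f in names(scenario$params)) {
    add("  \"", f, "\": ", yaml_scalar(scenario$params[[f]]))
  }
  ino <- scenario$inoculations
  if (!is.null(ino) && nrow(ino)) {
    add("inoculations:")
    for (i in seq_len(nrow(ino))) {
      add("  - step: ", yaml_scalar(ino$step[i]))
      add("    sequence: ", ino$sequence[i])
      add("    topology: ", ino$topology[i])
      add("    count: ", yaml_scalar(ino$count[i]))
      add("    every: ", yaml_scalar(ino$every[i]))
      add("    until_stop: ", tolower(as.character(ino$until_stop[i])))
    }
  }
  iv <- scenario$interventions
  if (!is.null(iv) && nrow(iv)) {
    add("interventions:")
    for (i in seq_len(nrow(iv))) {
      add("  - step: ", yaml_scalar(iv$step[i]))
      add("    parameter: ", iv$parameter[i])
      add("    value: ", yaml_scalar(iv$value[i]))
      if (!is.na(iv$scope_topology[i])) {
        add("    scope_topology: ", iv$scope_topology[i])
      }
      if (!is.na(iv$scope_motif[i])) add("    scope_motif: ", iv$scope_motif[i])
      add("    scope_revcomp: ", tolower(as.character(iv$scope_revcomp[i])))
    }
  }
  sr <- scenario$stop_rule
  if (!is.null(sr)) {
    add("stop_rule:")
    add("  category: ", sr$category)
    add("  threshold: ", yaml_scalar(sr$threshold))
    add("  consecutive: ", sr$consecutive)
  }
  writeLines(ln, path)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  y <- yaml::read_yaml(path)
  pv <- y$params %||% list()
  int_fields <- c("N", "T_REP", "T_NR")
  for (f in int_fields) if (!is.null(pv[[f]])) pv[[f]] <- as.integer(pv[[f]])
  params <- do.call(rw_params, c(pv, list(validate = FALSE)))
  validate_parameters(params, quiet = TRUE)   # range errors only
  ino <- NULL
  if (!is.null(y$inoculations)) {
    ino <- bind_rows(lapply(y$inoculations, function(r) {
      inoculation(r$step, r$sequence, r$topology %||% "linear",
                  r$count %||% 1, r$every %||% 0,
                  isTRUE(r$until_stop))
    }))
  }
  iv <- NULL
  if (!is.null(y$interventions)) {
    iv <- bind_rows(lapply(y$interventions, function(r) {
      intervention(r$step, r$parameter, r$value,
                   r$scope_topology %||% NA, r$scope_motif %||% NA,
                   isTRUE(r$scope_revcomp))
    }))
  }
  sr <- NULL
  if (!is.null(y$stop_rule)) {
    sr <- stop_rule(y$stop_rule$category %||% "cir_rep",
                    y$stop_rule$threshold %||% 20,
                    y$stop_rule$consecutive %||% 10)
  }
  rw_scenario(params = params, steps = y$steps,
              seed = y$seed, inoculations = ino, interventions = iv,
              stop_rule = sr, observe_every = y$observe_every %||% 1000,
              snapshot_steps = unlist(y$snapshot_steps) %||% numeric(0),
              name = y$name)
}
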
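#' Build a system state by hand
#'
#' A system state is the complete configuration of the toroidal grid:
#' per-room nucleotide-precursor counts, free-nucleotide counts (per base),
#' and the RNA entities (plain strands, or template complexes carrying bound
#' substrate segments), plus the step counter and -- once the state has been
#' stepped -- the generator state for exact replay.  `rw_state()` is mainly a
#' test and exploration tool; scenario runs build their own fresh state
#' internally (see [run_scenario()]), placing each of the `T_NPB` precursors
#' in an independently, uniformly chosen room.  Here, by contrast, the
#' default precursor layout is a deterministic even split so hand-built
#' states need no generator.
#'
#' @param params an [rw_params] record; supplies `N` and `T_NPB`.
#' @param strands optional data frame (or tibble) of strands with columns
#'   `sequence`, `topology` (`"linear"`/`"circular"`), and 1-based room
#'   coordinates `row`, `col`.  An optional list-column `segments` attaches
#'   bound substrate segments, each a list with elements `substrate` (linear
#'   RNA string), `start` (0-based template position paired by the
#'   substrate's 3'-most residue) and optionally `mismatch` (logical vector).
#' @param precursors either `NULL` (distribute `params$T_NPB` evenly), a
#'   single count (distributed evenly), or an `N x N` matrix of counts.
#' @param nucleotides optional `N x N x 4` array of free-nucleotide counts
#'   in base order A, C, G, U; defaults to all zero.
#'
#' @return A list with class `"rw_state"`: elements `N`, `step`,
#'   `precursors`, `nucleotides`, `entities`, `inoculated`, `rng`.
#' @examples
#' p <- rw_params(N = 4, T_NPB = 100)
#' s <- rw_state(p, strands = tibble::tibble(
#'   sequence = "GAGUCUCU", topology = "circular", row = 1, col = 1))
#' total_mass(s)
#' @export
rw_state <- function(params, strands = NULL, precursors = NULL,
                     nucleotides = NULL) {
  stopifnot(inherits(params, "rw_params"))
  N <- params$N
  if (is.null(precursors)) precursors <- params$T_NPB
  if (is.matrix(precursors)) {
    stopifnot(all(dim(precursors) == c(N, N)), all(precursors >= 0))
    pre <- precursors
  } else {
    stopifnot(length(precursors) == 1, precursors >= 0)
    total <- as.integer(precursors)
    base <- total %/% (N * N)
    rem <- total %% (N * N)
    v <- rep(base, N * N)
    if (rem > 0) v[seq_len(rem)] <- v[seq_len(rem)] + 1
    pre <- matrix(v, N, N, byrow = TRUE)   # row-major fill, documented
  }
  storage.mode(pre) <- "integer"
  if (is.null(nucleotides)) {
    nuc <- array(0L, dim = c(N, N, 4))
  } else {
    stopifnot(all(dim(nucleotides) == c(N, N, 4)), all(nucleotides >= 0))
    nuc <- nucleotides
    storage.mode(nuc) <- "integer"
  }

  entities <- list()
  if (!is.null(strands) && nrow(as.data.frame(strands)) > 0) {
    strands <- as_tibble(strands)
    if (!"segments" %in% names(strands)) {
      strands$segments <- rep(list(list()), nrow(strands))
    }
    for (i in seq_len(nrow(strands))) {
      seq <- strands$sequence[i]
      topo <- strands$topology[i]
      check_rna(seq)
      if (!topo %in% c("linear", "circular")) {
        abort("topology must be \"linear\" or \"circular\"")
      }
      if (topo == "circular" && nchar(seq) < 3) {
        abort("a circular strand must be at least 3 nt")
      }
      if (topo == "linear" && nchar(seq) < 1) abort("empty strand")
      row <- as.integer(strands$row[i]); col <- as.integer(strands$col[i])
      if (row < 1 || row > N || col < 1 || col > N) {
        abort("strand room coordinates outside the grid")
      }
      segs <- strands$segments[[i]]
      if (length(segs)) validate_segments(seq, topo, segs)
      if (topo == "circular") seq <- canonical_rotation(seq)
      entities[[length(entities) + 1]] <- list(
        sequence = seq, topology = topo, row = row, col = col,
        segments = segs %||% list())
    }
  }
  st <- structure(list(
    N = N, step = 0, precursors = pre, nucleotides = nuc,
    entities = entities, inoculated = 0, rng = ""
  ), class = "rw_state")
  st$base_mass <- total_mass(st)
  st
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_segments <- function(seq, topo, segs) {
  L <- nchar(seq)
  covered <- rep(FALSE, L)
  total <- 0
  for (sg in segs) {
    check_rna(sg$substrate)
    len <- nchar(sg$substrate)
    if (len < 1) abort("a bound segment must pair at least one position")
    if (sg$start < 0 || sg$start >= L) abort("segment start outside template")
    pos <- sg$start + seq_len(len) - 1
    if (topo == "circular") pos <- pos %% L
    else if (any(pos >= L)) abort("segment extends past a linear template")
    if (any(covered[pos + 1])) abort("bound segments overlap on the template")
    covered[pos + 1] <- TRUE
    total <- total + len
    if (!is.null(sg$mismatch) && length(sg$mismatch) != len) {
      abort("mismatch flags must match substrate length")
    }
  }
  if (total > L) abort("total paired positions exceed template length")
  invisible(TRUE)
}

#' Total material in a state
#'
#' The conserved quantity of the model: the sum over all rooms of nucleotide
#' precursors, free nucleotides, and every RNA residue -- counting both
#' templates and the substrates bound to them.  Every event converts
#' material between these pools without creating or destroying it, so for a
#' run without inoculations `total_mass()` equals `T_NPB` after every step;
#' inoculated molecules add their residues to the budget (tracked in the
#' state's `inoculated` field, see [expected_mass()]).
#'
#' @param state an `rw_state`.
#' @return a single number (nucleotide-equivalents).
#' @examples
#' p <- rw_params(N = 2, T_NPB = 82)
#' s <- rw_state(p, strands = tibble::tibble(
#'   sequence = "GAGUCUCU", topology = "linear", row = 1, col = 1))
#' s$nucleotides[1, 1, 1] <- 10L
#' total_mass(s)   # 82 + 10 + 8 = 100
#' @export
total_mass <- function(state) {
  stopifnot(inherits(state, "rw_state"))
  m <- sum(state$precursors) + sum(state$nucleotides)
  for (e in state$entities) {
    m <- m + nchar(e$sequence)
    for (sg in e$segments) m <- m + nchar(sg$substrate)
  }
  m
}

#' @rdname total_mass
#' @export
expected_mass <- function(state) {
  # material at construction plus everything inoculated since
  base <- state$base_mass %||% (total_mass(state) - state$inoculated)
  base + state$inoculated
}

#' Advance a state by Monte Carlo steps
#'
#' Applies the full event set to every eligible molecule, once per phase per
#' step, in the fixed phase order: nucleotide formation, nucleotide decay,
#' random ligation, circularization, substrate attraction, template-directed
#' ligation (enzymatic attempts first, while REP turnovers last), duplex
#' separation, bond breaking, end decay, movement.  All randomness comes
#' from the single generator carried in the state; pass `seed` to (re)seed
#' it on the first call.
#'
#' @param state an `rw_state`.
#' @param params an [rw_params] record.
#' @param steps number of Monte Carlo steps to advance (>= 0).
#' @param seed optional integer; required if the state has never been
#'   stepped (it then carries no generator state).
#' @param record_mass if `TRUE`, attach a `mass_trace` attribute with
#'   [total_mass()] after every step.
#' @return the advanced `rw_state`.
#' @examples
#' p <- rw_params(N = 3, T_NPB = 500)
#' s <- rw_state(p)
#' s2 <- rw_step(s, p, steps = 10, seed = 1)
#' s2$step
#' @export
rw_step <- function(state, params, steps = 1, seed = NULL,
                    record_mass = FALSE) {
  stopifnot(inherits(state, "rw_state"), inherits(params, "rw_params"))
  if (steps == 0) return(state)
  res <- cpp_step_state(unclass(state), unclass(params), as.integer(steps),
                        if (is.null(seed)) NULL else as.integer(seed),
                        isTRUE(record_mass))
  out <- structure(res$state, class = "rw_state")
  out$base_mass <- state$base_mass %||% (total_mass(state) - state$inoculated)
  if (isTRUE(record_mass)) attr(out, "mass_trace") <- res$mass_trace
  out
}

#' @export
print.rw_state <- function(x, ...) {
  cat(sprintf("<rw_state> %dx%d grid, step %s\n", x$N, x$N,
              format(x$step, big.mark = ",")))
  cat(sprintf("  precursors: %d  free nucleotides: %d  entities: %d\n",
              sum(x$precursors), sum(x$nucleotides), length(x$entities)))
  cat(sprintf("  total mass: %d\n", total_mass(x)))
  invisible(x)
}
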
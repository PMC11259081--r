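#' Species census of a system state
#'
#' Counts every strand in the state -- free strands, templates engaged in
#' complexes, and bound substrates -- into the categories used throughout
#' the figure legends of this model family:
#'
#' * `cir_repnr`: circular RNA containing both the REP and the NR sequence;
#' * `cir_rep` / `cir_nr`: circular RNA containing only one of the two;
#' * `cir_repcom`: circular RNA containing the reverse complement of the REP
#'   sequence (and not the sense sequence -- a strand carrying both counts in
#'   the sense category only);
#' * `cir_ct` / `cir_ctcom`: the control sequence, same conventions;
#' * `lin_rep` / `lin_repcom`: linear carriers of the REP sequence and of its
#'   complement;
#' * `lin_rep_rib` / `lin_nr_rib`: linear carriers short enough to act as the
#'   corresponding ribozyme (see [is_functional_ribozyme()]).
#'
#' "Containing" is rotation-invariant on circular strands.  Strands bound
#' inside complexes are included in the raw counts and additionally reported
#' in parallel `*_occ` columns; subtracting gives free-only counts, since
#' the plotted convention of this model family is ambiguous on that point.
#'
#' @param state an [rw_state].
#' @param params an [rw_params] record (supplies the characteristic
#'   sequences).
#' @return A one-row tibble: `step`, the ten category counts, ten `*_occ`
#'   companions, `total_mass`, `n_precursors`, `n_nucleotides`, `n_strands`.
#' @seealso [genome_lengths()] for the genome-length histogram.
#' @examples
#' p <- rw_params(N = 2, T_NPB = 0)
#' s <- rw_state(p, strands = tibble::tibble(
#'   sequence = "GAGUCUCU", topology = "circular", row = 1, col = 1))
#' census(s, p)$cir_rep
#' @export
census <- function(state, params) {
  stopifnot(inherits(state, "rw_state"), inherits(params, "rw_params"))
  counts <- setNames(rep(0, 10), CENSUS_CATEGORIES)
  occ <- counts
  nstrand <- 0
  for (e in state$entities) {
    occupied <- length(e$segments) > 0
    k <- classify_strand(e$sequence, e$topology, params)
    counts <- counts + k
    if (occupied) occ <- occ + k
    nstrand <- nstrand + 1
    for (sg in e$segments) {
      k <- classify_strand(sg$substrate, "linear", params)
      counts <- counts + k
      occ <- occ + k
      nstrand <- nstrand + 1
    }
  }
  as_tibble(c(
    list(step = state$step), as.list(counts),
    as.list(setNames(occ, paste0(CENSUS_CATEGORIES, "_occ"))),
    list(total_mass = total_mass(state),
         n_precursors = sum(state$precursors),
         n_nucleotides = sum(state$nucleotides),
         n_strands = nstrand)
  ))
}

classify_strand <- function(seq, topology, params) {
  k <- setNames(rep(0, 10), CENSUS_CATEGORIES)
  circ <- topology == "circular"
  hasR <- rna_contains(seq, params$CS_REP, topology)
  hasN <- rna_contains(seq, params$CS_NR, topology)
  hasC <- rna_contains(seq, params$CS_CT, topology)
  if (circ) {
    if (hasR && hasN) k["cir_repnr"] <- 1
    else if (hasR) k["cir_rep"] <- 1
    else if (hasN) k["cir_nr"] <- 1
    if (!hasR && rna_contains(seq, reverse_complement(params$CS_REP), topology)) {
      k["cir_repcom"] <- 1
    }
    if (hasC) k["cir_ct"] <- 1
    else if (rna_contains(seq, reverse_complement(params$CS_CT), topology)) {
      k["cir_ctcom"] <- 1
    }
  } else {
    if (hasR) {
      k["lin_rep"] <- 1
      if (nchar(seq) < 1.5 * nchar(params$CS_REP)) k["lin_rep_rib"] <- 1
    } else if (rna_contains(seq, reverse_complement(params$CS_REP), topology)) {
      k["lin_repcom"] <- 1
    }
    if (hasN && nchar(seq) < 1.5 * nchar(params$CS_NR)) k["lin_nr_rib"] <- 1
  }
  k
}

#' Genome-length histogram
#'
#' The length distribution of REP-carrying circular strands (the circular
#' genomes), the quantity whose drift from 8 nt towards 9-12 nt signals the
#' takeover of a genome with a noncoding insertion.
#'
#' @inheritParams census
#' @return tibble with columns `length` and `count`; its `count` total
#'   equals `cir_rep + cir_repnr` of [census()].
#' @export
genome_lengths <- function(state, params) {
  stopifnot(inherits(state, "rw_state"), inherits(params, "rw_params"))
  lens <- integer(0)
  for (e in state$entities) {
    if (e$topology != "circular") next
    if (rna_contains(e$sequence, params$CS_REP, "circular")) {
      lens <- c(lens, nchar(e$sequence))
    }
  }
  if (!length(lens)) return(tibble(length = integer(0), count = integer(0)))
  tb <- table(lens)
  tibble(length = as.integer(names(tb)), count = as.integer(tb))
}
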
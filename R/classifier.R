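#' Sequence utilities: complement, rotation, containment
#'
#' Sequences are RNA strings over `{A, C, G, U}`, written 5'->3'.
#' `reverse_complement()` returns the antiparallel Watson-Crick complement
#' (A-U, G-C), also 5'->3'.  `canonical_rotation()` returns the
#' lexicographically smallest rotation of a string -- the canonical form
#' under which two circular strands built from rotations of the same ring
#' compare equal.  `rna_contains()` tests motif containment: a plain
#' substring test for linear topology, and a rotation-invariant test (the
#' motif is searched in the doubled sequence) for circular topology.
#'
#' @param x,seq,motif RNA strings (vectorised).
#' @param topology `"linear"` or `"circular"` (recycled).
#' @return `reverse_complement()` and `canonical_rotation()` return character
#'   vectors; `rna_contains()` a logical vector.
#' @examples
#' reverse_complement("GAGUCUCU")           # "AGAGACUC"
#' rna_contains("UCUGAGUC", "GAGUCUCU", topology = "circular")  # TRUE
#' rna_contains("UCUGAGUC", "GAGUCUCU", topology = "linear")    # FALSE
#' canonical_rotation("UCUGAGUC")
#' @export
reverse_complement <- function(x) {
  check_rna(x)
  comp <- chartr("ACGU", "UGCA", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

#' @rdname reverse_complement
#' @export
canonical_rotation <- function(x) {
  check_rna(x)
  vapply(x, cpp_canonical_rotation, character(1), USE.NAMES = FALSE)
}

#' @rdname reverse_complement
#' @export
rna_contains <- function(seq, motif, topology = "linear") {
  check_rna(seq)
  check_rna(motif)
  if (any(nchar(motif) < 1)) abort("motif must be non-empty")
  n <- max(length(seq), length(motif), length(topology))
  seq <- rep_len(seq, n)
  motif <- rep_len(motif, n)
  topology <- rep_len(topology, n)
  if (!all(topology %in% c("linear", "circular"))) {
    abort("topology must be \"linear\" or \"circular\"")
  }
  mapply(function(s, m, t) cpp_contains(s, t == "circular", m),
         seq, motif, topology, USE.NAMES = FALSE)
}

check_rna <- function(x) {
  if (!is.character(x) || any(is.na(x)) || any(grepl("[^ACGU]", x))) {
    abort("sequences must be character strings over {A, C, G, U}")
  }
  invisible(x)
}

#' Is a strand a functional ribozyme?
#'
#' A strand can act as the ribozyme whose characteristic sequence it carries
#' only if it is linear (a circular strand is topologically hindered from
#' folding), contains the characteristic sequence, and is shorter than 1.5
#' times that sequence -- redundant residues beyond that interfere with the
#' folding of the catalytic domain.  With the default 8-nt characteristic
#' sequences, the functional length bound is therefore 12 nt (exclusive):
#' an 11-mer carrying the motif is functional, a 12-mer is not.
#'
#' @param sequence RNA string(s), 5'->3'.
#' @param cs the characteristic sequence to test against.
#' @param topology `"linear"` or `"circular"` (recycled).
#' @return logical vector.
#' @examples
#' is_functional_ribozyme("GAGUCUCU", "GAGUCUCU")              # TRUE
#' is_functional_ribozyme("GAGUCUCUAAAA", "GAGUCUCU")          # 12-mer: FALSE
#' is_functional_ribozyme("GAGUCUCU", "GAGUCUCU", "circular")  # FALSE
#' @export
is_functional_ribozyme <- function(sequence, cs, topology = "linear") {
  check_rna(sequence)
  check_rna(cs)
  n <- max(length(sequence), length(topology))
  sequence <- rep_len(sequence, n)
  topology <- rep_len(topology, n)
  topology == "linear" &
    nchar(sequence) < 1.5 * nchar(cs) &
    rna_contains(sequence, cs, topology = "linear")
}
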
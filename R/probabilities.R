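#' Event-probability formulas
#'
#' The elementary per-event probabilities of the model are modified by the
#' local molecular context through a small set of closed-form rules.  These
#' helpers are the reference implementations of those rules; the compiled
#' step engine applies the identical arithmetic.
#'
#' * `separation_probability()`: a duplex of `n` base pairs separates with
#'   probability `P_SP^sqrt(n)` -- self-folding of the single chains aids
#'   dissociation, hence the 1/2 exponent rather than `P_SP^n`.
#' * `break_probability()`: a phosphodiester bond in a single-stranded region
#'   breaks with `P_BB`; at a double-stranded site the two parallel bonds
#'   break together with `P_BB^(3/2)` (a synergistic, not independent, pair
#'   of events).
#' * `end_decay_probability()`: a terminal residue decays with `P_NDE` when
#'   unpaired, and with `P_NDE^(3/2)` when base-paired (both paired residues
#'   go together).
#' * `movement_probability()`: a molecule of mass `m` nucleotide-equivalents
#'   moves with `P_MN / sqrt(m)`, the Zimm-model size scaling of polymer
#'   diffusion.  A template complex weighs the template plus every bound
#'   substrate.
#' * `attraction_probability()`: substrate attraction onto a template is
#'   `P_AT` for a primer-adjacent site on a circular template, divided by
#'   `F_DA` for a de novo site, and multiplied by `F_LT` on a linear
#'   template; the de novo linear case is `P_AT * F_LT / F_DA`.
#'
#' @param P_SP,P_BB,P_NDE,P_MN,P_AT base per-event probabilities.
#' @param n number of base pairs in the duplex (>= 1).
#' @param double_stranded is the breaking site in a double-stranded region?
#' @param paired_end is the terminal residue base-paired?
#' @param m molecular mass in nucleotide-equivalents (>= 1).
#' @param F_DA de novo attraction penalty factor (>= 1).
#' @param F_LT linear-template efficiency factor (in \[0, 1\]).
#' @param template_is_linear is the template a linear (not circular) RNA?
#' @param de_novo is the site isolated (no adjacent bound substrate)?
#'
#' @return A numeric probability (vectorised over the first argument and the
#'   context argument).
#' @examples
#' separation_probability(0.5, 1)    # 0.5
#' separation_probability(0.5, 4)    # 0.25
#' break_probability(5e-6, double_stranded = TRUE)
#' movement_probability(0.002, m = 16)
#' attraction_probability(0.5, 5, 0.5, template_is_linear = TRUE, de_novo = TRUE)
#' @name event_probabilities
NULL

#' @rdname event_probabilities
#' @export
separation_probability <- function(P_SP, n) {
  if (any(n < 1)) abort("n (base-pair count) must be >= 1")
  if (any(P_SP < 0 | P_SP > 1)) abort("P_SP must lie in [0, 1]")
  P_SP^sqrt(n)
}

#' @rdname event_probabilities
#' @export
break_probability <- function(P_BB, double_stranded = FALSE) {
  if (any(P_BB < 0 | P_BB > 1)) abort("P_BB must lie in [0, 1]")
  ifelse(double_stranded, P_BB^1.5, P_BB)
}

#' @rdname event_probabilities
#' @export
end_decay_probability <- function(P_NDE, paired_end = FALSE) {
  if (any(P_NDE < 0 | P_NDE > 1)) abort("P_NDE must lie in [0, 1]")
  ifelse(paired_end, P_NDE^1.5, P_NDE)
}

#' @rdname event_probabilities
#' @export
movement_probability <- function(P_MN, m) {
  if (any(m < 1)) abort("m (mass in nucleotide-equivalents) must be >= 1")
  if (any(P_MN < 0 | P_MN > 1)) abort("P_MN must lie in [0, 1]")
  P_MN / sqrt(m)
}

#' @rdname event_probabilities
#' @export
attraction_probability <- function(P_AT, F_DA, F_LT,
                                   template_is_linear = FALSE,
                                   de_novo = FALSE) {
  if (any(P_AT < 0 | P_AT > 1)) abort("P_AT must lie in [0, 1]")
  if (any(F_DA < 1)) abort("F_DA must be >= 1")
  if (any(F_LT < 0 | F_LT > 1)) abort("F_LT must lie in [0, 1]")
  p <- P_AT
  p <- ifelse(template_is_linear, p * F_LT, p)
  ifelse(de_novo, p / F_DA, p)
}
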
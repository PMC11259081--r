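#' Model parameters
#'
#' `rw_params()` builds the full parameter record of the simulation with the
#' published default values; any field can be overridden by name.  The record
#' collects every per-event probability, the grid size, the material budget,
#' ribozyme turnover numbers, the two attraction factors and the three
#' characteristic sequences.
#'
#' Probabilities are per event-opportunity per Monte Carlo step and must lie
#' in \[0, 1\].  `F_DA` (>= 1) penalises de novo substrate attraction relative
#' to primer-adjacent attraction; `F_LT` (in \[0, 1\]) is the templating
#' efficiency of a linear RNA relative to a circular one.  `T_NPB` is the
#' total number of nucleotide precursors introduced at the start (the
#' conserved material budget, in nucleotide equivalents); `T_REP` and `T_NR`
#' are the number of catalytic turnovers a replicase (REP) or
#' nucleotide-synthetase (NR) ribozyme can perform per step.  `CS_REP`,
#' `CS_NR` and `CS_CT` are the characteristic sequences whose presence in a
#' short linear strand confers (or, for the control, deliberately does not
#' confer) ribozyme function.
#'
#' @param ... named overrides of individual fields, e.g. `rw_params(P_TLR = 0)`.
#' @param validate if `TRUE` (default) range-check the record and emit
#'   ordering warnings via [validate_parameters()].
#'
#' @return A named list with class `"rw_params"`.
#' @examples
#' p <- rw_params()
#' p$P_SP
#' p$CS_REP
#' rw_params(P_FP = 0.01, T_NPB = 2e5)$P_FP
#' @export
rw_params <- function(..., validate = TRUE) {
  defaults <- list(
    P_AT  = 0.5,     # template attracting a substrate
    P_BB  = 5e-6,    # phosphodiester bond breaking within a chain
    P_EL  = 1e-7,    # end-to-end ligation (circularization)
    P_FP  = 0.001,   # false base-pairing at attraction
    P_MN  = 0.002,   # movement of nucleotides (and, mass-scaled, RNA)
    P_MNP = 0.01,    # movement of nucleotide precursors
    P_ND  = 0.05,    # nucleotide decaying into its precursor
    P_NDE = 0.001,   # residue decaying at a chain end
    P_NF  = 0.005,   # nucleotide forming non-enzymatically
    P_NFR = 0.9,     # nucleotide forming catalysed by NR
    P_RL  = 1e-7,    # random intermolecular ligation
    P_SP  = 0.5,     # separation of a base pair
    P_TL  = 0.01,    # template-directed ligation, non-enzymatic
    P_TLR = 0.9,     # template-directed ligation catalysed by REP
    N     = 30L,     # grid side length
    T_NPB = 1e5,     # nucleotide precursors introduced at the start
    T_REP = 10L,     # REP turnovers per step
    T_NR  = 10L,     # NR turnovers per step
    F_DA  = 5,       # de novo attraction penalty factor
    F_LT  = 0.5,     # linear-template efficiency factor
    CS_REP = "GAGUCUCU",
    CS_NR  = "UGAUGCAG",
    CS_CT  = "ACGAACUG"
  )
  overrides <- list(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(defaults))
    if (length(bad)) {
      abort(paste0("unknown parameter(s): ", paste(bad, collapse = ", ")))
    }
    defaults[names(overrides)] <- overrides
  }
  p <- structure(defaults, class = c("rw_params", "list"))
  p$N <- as.integer(p$N)
  p$T_REP <- as.integer(p$T_REP)
  p$T_NR <- as.integer(p$T_NR)
  if (validate) validate_parameters(p)
  p
}

PROB_FIELDS <- c("P_AT", "P_BB", "P_EL", "P_FP", "P_MN", "P_MNP", "P_ND",
                 "P_NDE", "P_NF", "P_NFR", "P_RL", "P_SP", "P_TL", "P_TLR")

#' Validate a parameter record
#'
#' Hard range violations (a probability outside \[0, 1\], `F_DA < 1`, `F_LT`
#' outside \[0, 1\], `N < 1`, negative counts, an invalid characteristic
#' sequence) are errors naming the offending field.  Violations of the
#' soft ordering relations the model is normally run under are returned --
#' and emitted -- as warnings, because scenario interventions legitimately
#' break them (e.g. switching a ribozyme off with `P_TLR = 0`):
#' `P_TLR >> P_TL`, `P_NFR >> P_NF`, `P_TL >> P_RL` (with `P_RL` of the same
#' order as `P_EL`), `P_NDE < P_ND`, and `P_MN < P_MNP`.
#'
#' @param p an [rw_params] record.
#' @param quiet if `TRUE`, do not emit `warning()`s, only return them.
#' @return (invisibly) a tibble of ordering warnings with columns `rule` and
#'   `detail`; zero rows when all orderings hold.
#' @examples
#' validate_parameters(rw_params())                    # no warnings
#' w <- validate_parameters(rw_params(P_TL = 1e-9, validate = FALSE),
#'                          quiet = TRUE)
#' w$rule
#' @export
validate_parameters <- function(p, quiet = FALSE) {
  for (f in PROB_FIELDS) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1) {
      abort(paste0("parameter ", f, " must be a probability in [0, 1], got ",
                   format(v)))
    }
  }
  if (!is.numeric(p$F_DA) || p$F_DA < 1) {
    abort("parameter F_DA must be >= 1")
  }
  if (!is.numeric(p$F_LT) || p$F_LT < 0 || p$F_LT > 1) {
    abort("parameter F_LT must lie in [0, 1]")
  }
  if (!is.numeric(p$N) || p$N < 1) abort("parameter N must be >= 1")
  if (!is.numeric(p$T_NPB) || p$T_NPB < 0) abort("parameter T_NPB must be >= 0")
  if (p$T_REP < 0) abort("parameter T_REP must be >= 0")
  if (p$T_NR < 0) abort("parameter T_NR must be >= 0")
  for (f in c("CS_REP", "CS_NR", "CS_CT")) {
    s <- p[[f]]
    if (!is.character(s) || length(s) != 1 || nchar(s) < 1 ||
        grepl("[^ACGU]", s)) {
      abort(paste0("parameter ", f,
                   " must be a non-empty RNA string over {A, C, G, U}"))
    }
  }

  ord <- list(
    list("P_TLR >> P_TL",  p$P_TLR > p$P_TL,
         "ribozyme-catalysed ligation should far exceed the non-enzymatic rate"),
    list("P_NFR >> P_NF",  p$P_NFR > p$P_NF,
         "ribozyme-catalysed nucleotide synthesis should far exceed the non-enzymatic rate"),
    list("P_TL >> P_RL",   p$P_TL > p$P_RL,
         "template-directed ligation should far exceed random ligation"),
    list("P_TL >> P_EL",   p$P_TL > p$P_EL,
         "template-directed ligation should far exceed end-to-end ligation"),
    list("P_NDE < P_ND",   p$P_NDE < p$P_ND,
         "semi-protected chain-end residues should decay slower than free nucleotides"),
    list("P_MN < P_MNP",   p$P_MN < p$P_MNP,
         "nucleotides should move slower than their smaller precursors")
  )
  bad <- ord[!vapply(ord, function(x) isTRUE(x[[2]]), logical(1))]
  out <- tibble(
    rule = vapply(bad, function(x) x[[1]], character(1)),
    detail = vapply(bad, function(x) x[[3]], character(1))
  )
  if (!quiet && nrow(out)) {
    for (i in seq_len(nrow(out))) {
      warn(paste0("parameter ordering '", out$rule[i], "' violated: ",
                  out$detail[i]))
    }
  }
  invisible(out)
}

#' @export
print.rw_params <- function(x, ...) {
  cat("<rw_params>\n")
  for (f in names(x)) {
    v <- x[[f]]
    cat(sprintf("  %-6s %s\n", f,
                if (is.character(v)) v else format(v, scientific = NA)))
  }
  invisible(x)
}

# full-precision scalar formatting so YAML round-trips are bit-exact;
# doubles keep a decimal marker so they parse back as doubles
yaml_scalar <- function(v) {
  if (is.character(v)) return(v)
  if (is.integer(v)) return(as.character(v))
  out <- sprintf("%.17g", v)
  if (!grepl("[.eE]", out)) out <- paste0(out, ".0")
  out
}

#' Read and write parameter files
#'
#' Parameters serialize to a flat `key: value` YAML file whose keys are the
#' parameter symbols (`P_AT`, ..., `CS_CT`).  Numbers are written with 17
#' significant digits so a read-back reproduces the record bit-exactly.
#'
#' @param p an [rw_params] record.
#' @param path file path.
#' @return `read_params()` returns an [rw_params] record; `write_params()`
#'   returns `path` invisibly.
#' @export
write_params <- function(p, path) {
  stopifnot(inherits(p, "rw_params"))
  lines <- vapply(names(p), function(f) {
    paste0("\"", f, "\": ", yaml_scalar(p[[f]]))   # quoted: bare N is YAML for FALSE
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  vals <- yaml::read_yaml(path)
  int_fields <- c("N", "T_REP", "T_NR")
  for (f in int_fields) if (!is.null(vals[[f]])) vals[[f]] <- as.integer(vals[[f]])
  do.call(rw_params, vals)
}
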
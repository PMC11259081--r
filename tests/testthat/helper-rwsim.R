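# shared fixtures: everything is generated in code, nothing is stored

# a small, fast parameter set for engine tests (same event structure,
# desk-sized material)
tiny_params <- function(...) {
  rw_params(N = 4L, T_NPB = 800, validate = FALSE, ...)
}

# a parameter set with every event switched off
null_params <- function(...) {
  rw_params(
    P_AT = 0, P_BB = 0, P_EL = 0, P_FP = 0, P_MN = 0, P_MNP = 0, P_ND = 0,
    P_NDE = 0, P_NF = 0, P_NFR = 0, P_RL = 0, P_SP = 0, P_TL = 0, P_TLR = 0,
    N = 4L, T_NPB = 100, validate = FALSE, ...
  )
}

strand_tbl <- function(sequence, topology = "linear", row = 1, col = 1,
                       segments = NULL) {
  tb <- tibble::tibble(sequence = sequence,
                       topology = rep_len(topology, length(sequence)),
                       row = rep_len(row, length(sequence)),
                       col = rep_len(col, length(sequence)))
  if (!is.null(segments)) tb$segments <- segments
  tb
}

# independent brute-force oracle: rotation-invariant containment by
# explicitly testing every rotation
contains_any_rotation <- function(seq, motif) {
  n <- nchar(seq)
  if (nchar(motif) > n) return(FALSE)
  rots <- vapply(seq_len(n) - 1L, function(k) {
    paste0(substring(seq, k + 1, n), substring(seq, 1, k))
  }, character(1))
  any(vapply(rots, function(r) grepl(motif, r, fixed = TRUE), logical(1)))
}

# random RNA string under the ambient RNG
random_rna <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

# sequences of every strand in a state (templates and bound substrates),
# as a sorted multiset label for invariance checks
state_sequences <- function(state) {
  out <- character(0)
  for (e in state$entities) {
    out <- c(out, paste0(substr(e$topology, 1, 3), ":", e$sequence))
    for (sg in e$segments) out <- c(out, paste0("sub:", sg$substrate))
  }
  sort(out)
}
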
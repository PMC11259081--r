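#' Named scenario presets
#'
#' Ready-made scenarios reproducing the canonical experiments of the model:
#' the spread of a one-gene circular genome from a bulk or intermittent
#' inoculation of linear replicase (REP) molecules, the mid-run
#' interventions probing the roles of the circular genome and the ribozyme,
#' the circularization-rescue contrast, the emergence of genomes carrying a
#' noncoding insertion, and the two-gene (REP + NR) genome experiments.
#' Every preset also has a `"<name>_scaled"` variant for desk-scale work:
#' the grid side is halved and the material budget quartered (leaving the
#' per-room precursor density unchanged), step counts, one-shot event steps
#' and observation intervals are divided by 10, and periodic-inoculation
#' intervals by 5 (so inoculant per step per unit material roughly matches
#' the full-scale runs).
#'
#' @details
#' | name  | experiment |
#' |-------|------------|
#' | `fig2a` | 50 linear REP + 50 linear control molecules at step 1e4; the circular REP genome emerges and spreads |
#' | `fig2b` | 1 linear REP + 1 control every 1e4 steps until spread (stop rule); long run |
#' | `fig3`  | `fig2b`, then F_LT -> 0 for linear REP carriers *and their complements* at 2.5e6, P_TLR -> 0 at 5e6 |
#' | `fig4a` | `fig2b`, F_LT -> 0.2 / 0.1 / 0 at 2e6 / 4e6 / 6e6 for linear REP carriers only (complements untouched) |
#' | `fig4b` | `fig4a` with P_EL = 0 from the start: no circular RNA can ever form |
#' | `fig5a`, `fig5d` | `fig2a` with different seeds (noncoding-insertion cases) |
#' | `fig5b` | `fig2a` run longer |
#' | `fig5c` | alias of `fig2b` |
#' | `fig7a` | 100 circular 16-nt REP+NR genomes + 100 circular 16-nt controls at 1e4 |
#' | `fig7b` | 100 circular 16-nt REP+noncoding genomes (noncoding one substitution from CS_NR) + controls; T_NPB = 2e5, P_BB = 2e-5, P_FP = 0.01, P_NDE = 0.002, P_NF = 0.001 |
#' | `s1`    | NR-first: 50 linear NR + 50 control molecules at 1e4 |
#' | `s2`    | gene duplication: 100 circular 16-nt REP-REP genomes + controls; CS_NR redefined one substitution from CS_REP; P_FP = 0.01 |
#'
#' @param name a preset name; see [rw_presets()] for the list.
#' @return `rw_preset()` returns an [rw_scenario]; `rw_presets()` a tibble
#'   with columns `name` and `description`.
#' @examples
#' rw_presets()
#' sc <- rw_preset("fig2a_scaled")
#' sc$params$N
#' @export
rw_preset <- function(name) {
  base_names <- rw_presets()$name
  if (!is.character(name) || length(name) != 1 || !name %in% base_names) {
    abort(paste0("unknown preset '", paste0(name, collapse = ","),
                 "'; available: ", paste(base_names, collapse = ", ")))
  }
  scaled <- grepl("_scaled$", name)
  base <- sub("_scaled$", "", name)
  sc <- build_preset(base)
  if (scaled) {
    # the two long intervention experiments take an extra factor of two in
    # time scaling so a desk-scale batch stays affordable; the intervention
    # staircase keeps its proportions
    sc <- scale_scenario(sc, step_div = if (base %in% c("fig4a", "fig4b")) 20 else 10)
  }
  sc$name <- name
  sc
}

#' @rdname rw_preset
#' @export
rw_presets <- function() {
  base <- tibble(
    name = c("fig2a", "fig2b", "fig3", "fig4a", "fig4b",
             "fig5a", "fig5b", "fig5c", "fig5d", "fig7a", "fig7b",
             "s1", "s2"),
    description = c(
      "one-gene spread: 50 linear REP + 50 controls inoculated at step 1e4",
      "one-gene spread from intermittent single-molecule inoculation (stop rule on spread)",
      "role analysis: scoped F_LT -> 0 (REP and complement) at 2.5e6, P_TLR -> 0 at 5e6",
      "linear-template decline: scoped F_LT 0.5 -> 0.2 -> 0.1 -> 0 for REP carriers only",
      "as fig4a but P_EL = 0: circularization impossible",
      "as fig2a, different seed (noncoding insertion takes over)",
      "as fig2a, longer run (8nt -> 10nt genome transition)",
      "alias of fig2b (the ultimately spreading genome is 9nt)",
      "as fig2a, different seed (8nt -> 9nt -> 12nt)",
      "two-gene genome: 100 circular REP+NR 16-mers + 16-mer controls",
      "second gene from a noncoding sequence one substitution from CS_NR, high error rate",
      "NR-first one-gene spread: 50 linear NR + 50 controls",
      "REP-REP gene duplication; CS_NR one substitution from CS_REP, high error rate"
    )
  )
  bind_rows(base, tibble(name = paste0(base$name, "_scaled"),
                         description = paste0(base$description,
                                              " (desk scale)")))
}

build_preset <- function(base) {
  p <- rw_params()
  switch(base,
    fig2a = rw_scenario(
      params = p, steps = 2e6, seed = 1L,
      inoculations = inoculation(1e4, c(p$CS_REP, p$CS_CT), "linear",
                                 count = 50),
      observe_every = 2000,
      snapshot_steps = c(1e4, 3e4, 8e4, 1.3e5, 2.2e5, 9e5)),
    fig2b = rw_scenario(
      params = p, steps = 3e6, seed = 1L,
      inoculations = inoculation(1e4, c(p$CS_REP, p$CS_CT), "linear",
                                 count = 1, every = 1e4, until_stop = TRUE),
      stop_rule = stop_rule("cir_rep", 20, 10),
      observe_every = 2000),
    fig3 = {
      sc <- build_preset("fig2b")
      sc$steps <- 6e6
      sc$interventions <- bind_rows(
        intervention(2.5e6, "F_LT", 0, scope_topology = "linear",
                     scope_motif = p$CS_REP, scope_revcomp = TRUE),
        intervention(5e6, "P_TLR", 0))
      sc
    },
    fig4a = {
      sc <- build_preset("fig2b")
      sc$steps <- 8e6
      sc$interventions <- bind_rows(
        intervention(2e6, "F_LT", 0.2, scope_topology = "linear",
                     scope_motif = p$CS_REP, scope_revcomp = FALSE),
        intervention(4e6, "F_LT", 0.1, scope_topology = "linear",
                     scope_motif = p$CS_REP, scope_revcomp = FALSE),
        intervention(6e6, "F_LT", 0, scope_topology = "linear",
                     scope_motif = p$CS_REP, scope_revcomp = FALSE))
      sc
    },
    fig4b = {
      sc <- build_preset("fig4a")
      sc$params <- rw_params(P_EL = 0, validate = FALSE)
      sc
    },
    fig5a = { sc <- build_preset("fig2a"); sc$seed <- 2L; sc },
    fig5b = { sc <- build_preset("fig2a"); sc$steps <- 4e6; sc },
    fig5c = build_preset("fig2b"),
    fig5d = { sc <- build_preset("fig2a"); sc$seed <- 4L; sc$steps <- 3e6; sc },
    fig7a = rw_scenario(
      params = p, steps = 3e6, seed = 1L,
      inoculations = inoculation(
        1e4,
        c(paste0(p$CS_REP, p$CS_NR),          # two-gene genome, 16 nt
          paste0(p$CS_CT, "AACGCUCG")),       # 16-nt control
        "circular", count = 100),
      observe_every = 2000),
    fig7b = {
      pp <- rw_params(T_NPB = 2e5, P_BB = 2e-5, P_FP = 0.01,
                      P_NDE = 0.002, P_NF = 0.001)
      noncoding <- "UGACGCAG"                 # one substitution from CS_NR
      rw_scenario(
        params = pp, steps = 3e6, seed = 1L,
        inoculations = inoculation(
          1e4,
          c(paste0(pp$CS_REP, noncoding),
            paste0("ACUGACGU", noncoding)),   # 8-nt control + noncoding
          "circular", count = 100),
        observe_every = 2000,
        snapshot_steps = c(1e4, 1.5e5, 5.3e5, 8.8e5, 1.1e6, 3e6))
    },
    s1 = {
      sc <- build_preset("fig2a")
      sc$inoculations <- inoculation(1e4, c(p$CS_NR, p$CS_CT), "linear",
                                     count = 50)
      sc
    },
    s2 = {
      pp <- rw_params(P_FP = 0.01, CS_NR = "GAGUCUCA")  # one sub from CS_REP
      rw_scenario(
        params = pp, steps = 3e6, seed = 1L,
        inoculations = inoculation(
          1e4,
          c(paste0(pp$CS_REP, pp$CS_REP),     # duplicated gene, 16 nt
            paste0(pp$CS_CT, "AACGCUCG")),
          "circular", count = 100),
        observe_every = 2000)
    },
    abort(paste0("unknown preset '", base, "'"))
  )
}

# desk-scale transform: N/2, T_NPB/4 (same per-room density), steps and
# one-shot event steps /step_div, periodic intervals /5, observation
# interval /10
scale_scenario <- function(sc, step_div = 10) {
  pars <- unclass(sc$params)
  pars$N <- max(1L, as.integer(pars$N / 2))
  pars$T_NPB <- pars$T_NPB / 4
  sc$params <- do.call(rw_params, c(pars, list(validate = FALSE)))
  sc$steps <- max(1, sc$steps / step_div)
  sc$observe_every <- max(1, sc$observe_every / 10)
  sc$snapshot_steps <- unique(pmax(1, sc$snapshot_steps / step_div))
  if (!is.null(sc$inoculations)) {
    sc$inoculations$step <- pmax(1, sc$inoculations$step / step_div)
    sc$inoculations$every <- ifelse(sc$inoculations$every > 0,
                                    pmax(1, sc$inoculations$every / 5), 0)
  }
  if (!is.null(sc$interventions)) {
    sc$interventions$step <- pmax(1, sc$interventions$step / step_div)
  }
  sc
}
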
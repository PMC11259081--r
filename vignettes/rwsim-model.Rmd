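---
title: "The rwsim model: circular genomes and linear ribozymes on a lattice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The rwsim model: circular genomes and linear ribozymes on a lattice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rwsim)
```

## The scientific question

In an RNA world, one polymer must carry both heredity and catalysis.  A
ribozyme has to fold; a replication template is better off not folding.  One
resolution available *before* cells is a division of labour by topology: a
circular RNA, topologically hindered from folding and immune to
end-degradation, serves as the genome, while short linear strands carrying
the same sequence act as the ribozymes.  `rwsim` simulates this precellular
("naked") scene: individual molecules on a spatial lattice, replicating,
degrading and diffusing, with selection emerging from nothing but chemistry
and dispersal limitation.

## State and events

The system is an `N x N` grid of rooms with toroidal (wrap-around)
adjacency.  A room holds nucleotide *precursors* (a count), free activated
*nucleotides* (counts per base A, C, G, U), and RNA molecules: plain strands
-- linear or circular, 5'->3', with circular sequences kept in their
lexicographically smallest rotation so equal rings compare equal -- and
*template complexes*, a template strand with one or more substrate segments
base-paired to it.  Every quantity is integer-valued; the total material,
in nucleotide equivalents, is conserved exactly (energy is left implicit:
substrates are assumed activated, so species compete for matter, not
energy).

Each Monte Carlo step applies ten event phases in a fixed order:

1. *nucleotide formation* -- a precursor becomes a random nucleotide with
   `P_NF`, or via a nucleotide-synthetase ribozyme (NR) turnover with
   `P_NFR`;
2. *nucleotide decay* back to a precursor (`P_ND`);
3. *random ligation* of two free linear species (`P_RL`), sequence = left +
   right;
4. *circularization*: a free linear strand of at least 3 nt closes
   end-to-end with `P_EL`;
5. *substrate attraction* onto templates (below);
6. *template-directed ligation* of adjacently bound segments -- `P_TLR` while
   a replicase (REP) turnover is available in the room, `P_TL` otherwise;
   when a segment comes to cover a circular template entirely, the same rule
   closes it into a circular complement, which is released;
7. *separation* of each bound segment with `P_SP^sqrt(n)` for `n` base
   pairs (self-folding of the single chains aids dissociation);
8. *bond breaking*: a single-stranded phosphodiester bond breaks with
   `P_BB`, a double-stranded site severs both strands with `P_BB^(3/2)`
   (the 3/2 rather than 2 reflects the synergy of the two scissions); a
   broken ring yields one linear strand, a broken linear strand two
   fragments, and bound segments stay with the fragment they pair with;
9. *end decay* of terminal residues -- `P_NDE` unpaired, `P_NDE^(3/2)`
   paired (both paired residues are lost when the partner is itself a chain
   end; a residue internal to a chain is protected and never decays);
   circular strands, having no ends, are immune -- one of the two selective
   advantages of the circular genome;
10. *movement* to a uniformly chosen neighbouring room -- `P_MNP` for
    precursors, `P_MN` for nucleotides, and `P_MN/sqrt(m)` for an RNA of
    mass `m` (Zimm scaling of polymer diffusion); a complex moves whole.

Only molecules in the same room interact, which is what lets a ribozyme's
benefits accrue to its own neighbourhood -- the dispersal limitation that
makes selection possible in a naked system.

### Attraction in detail

A template attracts substrates -- nucleotides or free linear oligomers -- at
its *empty sites*, the maximal unpaired runs.  Each empty site receives one
attraction attempt per step; when a substrate lands, the uncovered
remainders of that run become sites of their own and are attempted in the
same phase.  The attempt succeeds with `P_AT` (primer-adjacent placement on
a circular template), divided by `F_DA >= 1` for a de novo placement, and
multiplied by `F_LT <= 1` on a linear template.  The (substrate, position)
placement is uniform over everything that fits; a substrate must fit
entirely within one empty site.  Each newly paired residue is recorded as
the Watson-Crick complement of its template residue, or, with the error
rate `P_FP`, as a uniformly chosen non-complementary base -- substitution at
copying time is the model's only mutation mechanism, and it is what lets a
noncoding sequence drift into a second gene.

Two consequences of this contract are worth stating plainly.  First, an
oligomer recruited as a substrate has its residues set by templating: bound
material is raw material, and a strand's identity is only safe while it is
free.  Second, a site-level attempt rate is essential: with at most one
attraction attempt per template per step, a bound monomer (separation
probability `P_SP = 0.5` per step) detaches faster than neighbours can
arrive, and template-directed synthesis never outruns dissociation at the
published parameter values.  We therefore treat each empty site, not each
template molecule, as the unit of opportunity in this phase; all other
phases give each molecule (or each reaction site: junction, bond, chain
end) one attempt per step.

### Ribozymes

A linear strand containing a characteristic sequence acts as the
corresponding ribozyme only if it is shorter than 1.5 times that sequence
(residues beyond that interfere with the folding of the catalytic domain);
for the 8-nt default motifs the bound is 12 nt, exclusive.  Circular
strands never function -- that is the labour division under study.  A strand
engaged in a complex (as template or substrate) is not free to fold and
contributes no turnovers that step.  Each functional REP contributes
`T_REP` template-ligation attempts per step to its room, each consuming one
turnover and succeeding with `P_TLR`; NR contributes `T_NR` nucleotide-
synthesis attempts with `P_NFR`.

## Parameters

`rw_params()` carries the full published default set; `validate_parameters()`
enforces the hard ranges and warns -- without failing -- when the soft
orderings the model normally assumes are broken (`P_TLR >> P_TL`,
`P_NFR >> P_NF`, `P_TL >> P_RL ~ P_EL`, `P_NDE < P_ND`, `P_MN < P_MNP`),
because scenario interventions legitimately break them, e.g. switching the
replicase off with `P_TLR = 0`.

```{r}
p <- rw_params()
unlist(p[c("P_AT", "P_SP", "P_TLR", "P_TL", "F_DA", "F_LT")])
```

## Scenarios, presets and interventions

A scenario (`rw_scenario()`) bundles parameters, run length, seed,
inoculation schedules (one-shot or periodic, at uniformly chosen rooms),
timed interventions, an optional stop rule, and the observation plan.
Interventions rewrite a global parameter mid-run or install a
species-scoped override; scoping is supported for `F_LT`, the one
per-template factor the experiments scope -- e.g. "linear strands containing
the REP motif" with or without its reverse complement, which is exactly the
difference between the role-analysis and template-decline experiments.

The presets (`rw_presets()`) encode the canonical experiments: bulk and
intermittent inoculation of linear REP, the mid-run `F_LT`/`P_TLR`
switch-offs, the circularization-rescue contrast (`P_EL = 0`), the
two-gene genome, the noncoding-to-second-gene transition, and the NR-first
and gene-duplication variants.  Choices the sources leave open, fixed here
once:

* **Run lengths** not printed anywhere: 2e6 steps for the bulk-inoculation
  runs, 3e6 for intermittent-inoculation and two-gene runs, 6e6 and 8e6 for
  the two intervention experiments (staged `F_LT` reductions at 2e6, 4e6,
  6e6 where only the final "off after 6e6" is printed).
* **Stop rule** for "inoculation stops once spread is evident":
  `cir_rep >= 20` sustained over 10 consecutive observations; threshold and
  window are configurable.
* **Gene-duplication preset**: the second motif is `GAGUCUCA`, one
  substitution from the REP motif, as the construction requires but no
  source spells out.
* **Desk-scale variants** (`*_scaled`): grid side halved and material
  quartered -- per-room precursor density is then unchanged (~111 per room)
  -- step counts, one-shot event steps and observation intervals divided by
  10, periodic-inoculation intervals by 5 so the inoculant supply per step
  per unit material roughly matches full scale.  The two longest
  experiments, the staged linear-template interventions with and without
  circularization, take an extra factor of two in time (steps and the
  intervention staircase divided by 20) so that a replicate batch stays
  affordable on a desk machine.  These are the presets the test suite and
  the acceptance script run.

## Outputs

`run_scenario()` returns a tidy census time series (the ten figure-legend
categories -- `cir_rep`, `cir_repcom`, `lin_rep`, `lin_repcom`, `cir_ct`,
`cir_ctcom`, `cir_repnr`, `cir_nr`, `lin_rep_rib`, `lin_nr_rib` -- with
parallel `*_occ` columns counting strands currently bound inside
complexes, since the plotted convention of this model family does not say
whether duplexed strands are included; both readings are recoverable), a
long genome-length table for REP-carrying circular strands, optional
per-room spatial snapshots whose channel sums reproduce the global census,
cumulative event counts, and a manifest sufficient to replay the run byte
for byte.  A strand containing both a motif and its reverse complement is
counted on the sense side only, so the sense/antisense categories never
double-count.

```{r, fig.width = 6, fig.height = 3.5}
sc <- rw_scenario(rw_params(N = 8, T_NPB = 7000), steps = 6000,
                  inoculations = inoculation(50, "GAGUCUCU", count = 25),
                  observe_every = 250)
run <- run_scenario(sc, seed = 101)
autoplot(run)
```

The trajectory above shows the one-gene dynamic at toy scale: linear REP
replicates first (`lin_rep` tracks `lin_repcom`, the sense/antisense
symmetry inherent to template-directed replication), and circular forms
appear only on the slow `P_EL` timescale.

## Numerical and design notes

* **Determinism.**  One 64-bit Mersenne Twister per run, seeded from the
  scenario seed; fixed iteration order (rooms row-major, molecules in
  insertion order).  Identical (scenario, seed) reproduce all outputs byte
  for byte, and the generator state travels inside `rw_state` so stepping
  is resumable.
* **Aggregated sampling.**  Phases whose per-molecule probabilities are
  identical (free-nucleotide formation/decay/movement, random-ligation
  initiation, circularization, free-strand end decay) draw a binomial count
  and then choose molecules uniformly -- distributionally identical to
  per-molecule Bernoulli trials, at a fraction of the cost.  Bond breaking
  draws one event per molecule against the summed per-bond hazard and picks
  the bond hazard-weighted; at `P_BB = 5e-6` this is indistinguishable from
  independent per-bond trials.
* **Degenerate cases.**  Length-1 linear strands are returned to the
  free-nucleotide pool; rings require >= 3 nt (a 1-2 nt ring is chemically
  implausible, and no event here can make one); an empty template or an
  empty room simply yields no events.
* **Paired-end decay.**  The decaying strand's terminal residue always
  decays; its pairing partner decays with it only when that partner is
  itself a chain end -- internal residues are protected.  For a duplex
  flush with a template end this reproduces the "two paired residues decay
  together" rule exactly; a substrate end paired to the middle of a
  template loses only the substrate residue.
* **Mass accounting.**  `total_mass()` equals the initial precursor count
  plus everything inoculated since; the engine asserts nothing silently --
  the conservation test recomputes the sum after every step.

## What the desk-scale runs do and do not show

The scaled presets preserve per-room densities and rate constants, so the
qualitative selection phenomena -- spread of REP but not of the control,
dependence on `P_TLR`, rescue by circularization, drift of the genome
length beyond the bare motif -- reproduce at a tenth of the steps and a
quarter of the material.  Absolute counts and waiting times do not
transfer: a quarter-sized system holds proportionally fewer molecules, rare
events (first circularization, first beneficial insertion) have longer
relative waiting times, and single-seed trajectories are noisy -- which is
why the stochastic checks are majority votes over seed panels, and why any
one seed can honestly fail.  The generator emulates the model's own
idealisations, not real chemistry: no secondary structure beyond the
length rule, no energy bookkeeping, no strand displacement or
rolling-circle replication, substitution-only mutation at copying time.
Conclusions about real prebiotic chemistry rest on the model's assumptions,
not on these simulations alone.
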
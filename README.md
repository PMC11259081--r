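# rwsim

A spatial Monte Carlo simulator of the earliest, precellular stage of the
RNA world, built around one hypothesis: the first genomes were *circular*.
With a single polymer type carrying both heredity and catalysis, a division
of labour by topology is available before cells exist — a circular RNA,
topologically hindered from folding and immune to end-degradation, acts as
the genome, while short linear strands carrying the same sequence fold and
act as ribozymes. `rwsim` lets you run that scene as a computational
experiment and watch whether such a genome can spread, what it costs, and
how it grows.

The package is for origin-of-life researchers and students of evolutionary
dynamics who want a reproducible, scriptable instrument: every run is
exactly determined by a scenario configuration and a seed, every quantity
is observable, and all outputs are plain tables.

## The model in brief

Molecules live in the rooms of an *N* × *N* toroidal lattice: nucleotide
precursors, activated nucleotides, linear and circular RNA strands, and
template–substrate complexes. Per Monte Carlo step, each molecule is
offered the full event set with configured probabilities — nucleotide
formation (*P*<sub>NF</sub>, or *P*<sub>NFR</sub> via a
nucleotide-synthetase ribozyme), decay (*P*<sub>ND</sub>), random ligation
(*P*<sub>RL</sub>), end-to-end circularization (*P*<sub>EL</sub>),
substrate attraction with false pairing (*P*<sub>AT</sub>,
*P*<sub>FP</sub>), template-directed ligation (*P*<sub>TL</sub>, or
*P*<sub>TLR</sub> via a replicase ribozyme), duplex separation, bond
breaking, end decay, and diffusion. Context modifies the base rates in
closed form:

* separation of an *n*-pair duplex: *P*<sub>SP</sub><sup>√n</sup>;
* breaking at a double-stranded site: *P*<sub>BB</sub><sup>3/2</sup>
  (both strands sever);
* decay of a paired terminal residue: *P*<sub>NDE</sub><sup>3/2</sup>;
* movement of a molecule of mass *m*: *P*<sub>MN</sub>/√m;
* attraction: *P*<sub>AT</sub>, ÷ *F*<sub>DA</sub> de novo,
  × *F*<sub>LT</sub> on a linear template.

A linear strand containing a characteristic sequence acts as the
corresponding ribozyme only while shorter than 1.5× that sequence (folding
needs room); circular strands never function — that is the labour division.
Total material is conserved exactly; species compete for matter.

## A worked example

Inoculate 25 linear replicase (REP) molecules into a small fresh system and
watch selection do its work:

```r
library(rwsim)

sc <- rw_scenario(rw_params(N = 8, T_NPB = 7000), steps = 6000,
                  inoculations = inoculation(50, "GAGUCUCU", count = 25),
                  observe_every = 250)
run <- run_scenario(sc, seed = 101)
run
#> <rw_run> 24 observations to step 6,000 (seed 101)
#>   final counts: lin_rep=156  lin_repcom=163  lin_rep_rib=156

run$census[c(4, 12, 24), c("step", "lin_rep", "lin_repcom", "cir_rep",
                           "n_precursors")]
#>    step lin_rep lin_repcom cir_rep n_precursors
#> 1  1000       3          1       0         5877
#> 2  3000      17         23       0         5691
#> 3  6000     156        163       0         2644
```

The 25 inoculated ribozymes replicate through template-directed synthesis:
by step 6,000 there are 156 REP-carrying linear strands and — the signature
of replication by base-pairing — almost exactly as many strands carrying
the *complement* (163). Material drains from the precursor pool into RNA;
total mass stays at 7,000 + 200 inoculated residues throughout. Circular
genomes appear only on the much slower *P*<sub>EL</sub> timescale: run the
`fig2a_scaled` preset (a quarter-material, 2×10⁵-step system) to watch the
circular REP genome take over while an inoculated control sequence dies
out.

`tidy()` and `glance()` give long-format and one-row summaries,
`autoplot()` plots the trajectories, `plot_genome_lengths()` the genome
length structure, `plot_snapshot()` the spatial distribution. Presets for
all the canonical experiments — bulk and intermittent inoculation, mid-run
ribozyme knock-outs, the circularization-rescue contrast, two-gene genomes
and gene duplication — are listed by `rw_presets()`, each with a `_scaled`
desk-size variant.

There is also a thin command-line interface:

```sh
Rscript inst/cli/rwsim run --preset fig2a_scaled --seed 1 --out out/
Rscript inst/cli/rwsim presets
Rscript inst/cli/rwsim replicates --preset fig2a_scaled --seeds 1..5 --out rep/
```

Every run directory contains `timeseries.tsv` (the census: `cir_rep`,
`cir_repcom`, `lin_rep`, … exactly as in the standard figure legends),
`genome_lengths.tsv`, per-channel snapshot matrices, and a `manifest.json`
from which `read_manifest()` rebuilds the scenario for byte-identical
replay.

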
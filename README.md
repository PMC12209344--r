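# scatdiet

Carnivore diet analysis from scat DNA-metabarcoding read counts.

Field studies of carnivore diet increasingly collect scats, amplify a short
vertebrate marker (e.g. 12S) in triplicate PCR, sequence the amplicons, and
assign reads to taxa. What comes out of that upstream pipeline is a long
table of per-scat, per-PCR-replicate, per-taxon read counts. `scatdiet`
implements everything downstream of that table for a two-(or more-)predator
diet comparison:

1. **Replicate-consensus filtering.** A PCR replicate counts as successfully
   amplified only when its total reads exceed 1,000 (strict `>`). A taxon is
   retained only when its relative read abundance (RRA — its reads divided by
   the replicate total) is ≥ 1% in at least 2 of the valid replicates; taxa
   passing only at 0.5% are flagged for manual exploration and excluded from
   all summaries. This consensus rule suppresses tag-jumping and other
   low-abundance false detections.
2. **Defecator assignment.** The scat's own depositor must be identified
   from its DNA: a scat is assigned to a carnivore if it is the only
   candidate carnivore detected, or if it dominates and all other carnivore
   reads jointly make up < 10% of the sample's retained reads (those are
   treated as contamination). Ties and heavier mixtures are
   `ambiguous_defecator`. Scats with only defecator DNA, or whose diet items
   all fall below 1% of sample reads, are excluded.
3. **Diet composition.** For each predator species, frequency of occurrence
   (FOO_k = proportion of scats containing taxon *k*) and weighted percent
   of occurrence (wPOO_k = (1/N) Σ_i 1{k ∈ diet_i}/T_i, each scat
   contributing equally across its T_i items; Σ_k wPOO_k = 1).
4. **Dietary overlap.** Pianka's index
   O = Σ p_i q_i / √(Σ p_i² · Σ q_i²) ∈ [0, 1], computed on FOO and wPOO
   utilization vectors, with (a) a niche-breadth-retaining randomization
   null (each species' utilization values permuted across resource
   categories, zeros included, 10,000 iterations, add-one one-tailed
   p-value) and (b) a scat-bootstrap percentile CI for the observed value.
5. **Richness rarefaction.** Sample-based (incidence) rarefaction
   Ŝ(t) = Σ_i [1 − C(T−Y_i, t)/C(T, t)], Chao2 asymptote
   S_obs + ((T−1)/T)·Q1²/(2Q2) (bias-corrected when Q2 = 0), extrapolation
   beyond T, and bootstrap confidence bands.
6. **A synthetic scat generator** with full ground truth (true defecators,
   prey sets, contamination log, true FOO/wPOO profiles) emulating the
   triplicate design — defecator-dominated multinomial read counts,
   log-normal depths, rare-taxon dropout, tag jumping, second-carnivore
   contamination — so the whole pipeline is testable without any sequencing
   data.

## Worked example

```r
library(scatdiet)

sim <- simulate_scats(simulation_params(n_scats_per_species = 30, seed = 11))
res <- run_pipeline(sim$counts, sim$taxonomy,
                    filter_config(null_iterations = 10000,
                                  bootstrap_iterations = 2000, seed = 11))
str(res$manifest$accounting)
#> List of 6
#>  $ n_input               : int 60
#>  $ n_failed_amplification: int 1
#>  $ n_no_carnivore        : int 0
#>  $ n_ambiguous_defecator : int 0
#>  $ n_excluded_no_diet    : int 1
#>  $ n_assigned            : int 58

res$overlaps[["Canis latrans|Vulpes vulpes|wpoo"]]
#> Pianka overlap (wpoo): 0.77 [0.47-0.85]
#>   null: 0.51 [0.31-0.76], one-tailed p = 0.0204 (10000 iterations)
res$overlaps[["Canis latrans|Vulpes vulpes|foo"]]
#> Pianka overlap (foo): 0.83 [0.56-0.87]
#>   null: 0.55 [0.35-0.78], one-tailed p = 0.006499 (10000 iterations)

res$curves[["Vulpes vulpes"]]
#> Rarefaction over 29 scats: S_obs = 16, Chao2 = 24.69 (Q1 = 6, Q2 = 2)
#>   grid t = 1..58; S(2T) = 20.30
```

Reading the output: of 60 simulated scats, one failed amplification (fewer
than 2 replicates over 1,000 reads) and one was excluded for containing no
diet item above 1%; the remaining 58 were assigned to a defecator. The two
simulated predators share most of their prey pool, so observed wPOO overlap
(0.77) sits above the randomization null's 95% interval (0.31–0.76,
p ≈ 0.02): more overlap than expected if each species spread the same niche
breadth randomly across prey. The red-fox rarefaction says 16 prey taxa were
observed in 29 scats and an estimated ~25 exist in the sampled diet, i.e.
sampling is not yet saturated.

`run_pipeline(..., out_dir = "out")` additionally writes `scat_status.csv`,
one `diet_<species>.csv` per predator, `results.json`, and a seed-echoing
`manifest.json`; identical inputs and seed give a byte-identical bundle.

A command-line interface wrapping every stage
(`simulate`, `filter`, `assign`, `diet`, `overlap`, `rarefy`, `run`,
`validate`) is installed at `system.file("cli", "scatdiet.R", package = "scatdiet")`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","scatdiet.R",package="scatdiet"))')" \
    simulate --seed 5 --n-scats 30 --out-dir demo
```

## Validation study

`run_validation()` simulates datasets whose two predators have analytically
constructed prey-availability vectors with known Pianka overlap
(θ/√(θ² + (1−θ)²) for mixing weight θ), runs the full pipeline under
default noise, and reports defecator-assignment accuracy, wPOO estimation
error, and overlap recovery error per θ. Under defaults (150 scats/species),
recovery error stays within ±0.07 across θ ∈ {0, 0.25, 0.5, 0.75, 1} and
assignment accuracy is ≥ 98%.

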
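---
title: "Diet analysis from scat metabarcoding read counts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diet analysis from scat metabarcoding read counts: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scatdiet)
```

# The analysis problem

A scat collected in the field contains DNA of the animal that deposited it
(the *defecator*) alongside DNA of what it ate. After marker amplification
in triplicate PCR, sequencing and taxonomic assignment, the data are
per-scat, per-replicate, per-taxon read counts. Three inferential problems
stand between those counts and an ecological statement about diet:

1. **Which detections are real?** Tag jumping, low-level cross-contamination
   and PCR stochasticity produce spurious low-abundance taxa.
2. **Who deposited the scat?** Multiple carnivores can appear in one sample
   (contamination, or consumption of another carnivore).
3. **How do two predators' diets compare?** Composition, overlap, and
   whether observed richness has saturated with sample size.

`scatdiet` implements one coherent, field-standard answer to each, plus a
generative model of the data so every stage can be validated against known
truth.

# Replicate-consensus filtering

A replicate is *valid* iff its total reads strictly exceed
`min_reads_per_replicate` (default 1000; "over 1000" is read as `>`). A
scat with fewer than `min_replicates` (default 2) valid replicates fails
amplification. A taxon is retained iff its relative read abundance (RRA)
within a replicate is at least `min_rra` (default 1%, inclusive) in at
least `min_replicates` valid replicates. Its combined reads are then summed
over valid replicates only — an invalid replicate contributes neither to
qualification nor to counts.

Two deliberate interpretation choices, both configurable:

- "found in ≥ 2 of 3 replicates with ≥ 1% RRA" is read as *RRA ≥ 1% in each
  of ≥ 2 valid replicates*, not "detected twice and ≥ 1% once". This is the
  standard replicate-consensus reading and the stricter,
  contamination-robust one. A pooled-RRA variant (threshold applied to reads
  pooled across valid replicates, detection in `min_replicates` replicates
  still required) is available via `rra_scope = "pooled"`.
- The 1000-read rule defines *per-replicate validity* rather than requiring
  all three replicates to pass; scats with fewer than three replicates
  present follow the same `min_replicates`-of-valid rule.

Taxa qualifying at `exploration_rra` (default 0.5%) but not at `min_rra`
are reported as exploration-only flags for manual review and never enter
any downstream summary. Defecator taxa are filtered by the same rule as
prey: the consensus filter operates on sequences, not on diet items.

# Defecator assignment and exclusions

Among retained taxa, the candidate carnivores (taxonomy flag
`candidate_defecator`, constrained to order Carnivora) decide the scat's
fate: none → `no_carnivore`; exactly one → it is the defecator; several →
the read-dominant carnivore is the defecator provided the *combined* reads
of all others are below `max_other_carnivore_share` (default 10%) of the
sample's total retained reads, else `ambiguous_defecator`. A tie for
dominance is always ambiguous — never broken arbitrarily.

Design choices made where the rule leaves room:

- "DNA of other carnivores" is read collectively (summed), matching the
  plural phrasing of the rule as used in the field; a per-carnivore variant
  is available (`other_carnivore_scope = "each"`).
- Sub-threshold carnivores are removed as presumed contamination rather
  than counted as prey, since sub-10% carnivore reads are indistinguishable
  from cross-contamination; `carnivores_as_prey = TRUE` restores them
  (predators do scavenge carnivore carcasses).
- The denominator is the post-filter total of retained reads — the only
  total the pipeline has after consensus filtering.
- Diet-item shares are fixed once, against that one sample total, and are
  *not* renormalized after any removal; the < 1% item rule is therefore a
  statement about share of sample reads, and wPOO downstream uses
  presence/absence only, so renormalization would be moot.

A scat whose diet is empty, or whose items all fall below `min_item_share`
(default 1%), becomes `excluded_no_diet`; in mixed cases sub-threshold items
are dropped individually and the scat kept. Every scat ends in exactly one
of five statuses (`assigned`, `ambiguous_defecator`, `no_carnivore`,
`failed_amplification`, `excluded_no_diet`), and the pipeline manifest
checks the accounting identity across them.

# Diet metrics

For the N assigned scats of one species with diet sets $D_i$:

$$\mathrm{FOO}_k = \frac{1}{N}\sum_i \mathbf{1}\{k \in D_i\}, \qquad
  \mathrm{wPOO}_k = \frac{1}{N}\sum_i \frac{\mathbf{1}\{k \in D_i\}}{|D_i|}.$$

wPOO gives each scat equal weight split uniformly over its items —
occurrence-based, not read-share-based, because read counts are a poor
analog of biomass. An RRA-weighted variant is provided for sensitivity
analysis (`wpoo_weighting = "rra"`). Profiles keep sparse support: a taxon
absent from every scat is omitted, not zero-valued. Items are summarized at
their reported identity (mixed ranks: some genus-level like "Tamias sp.",
some species-level); `aggregate_rank()` provides rank-consistent views,
rolling empty labels up to the nearest nonempty coarser rank.

# Overlap and the null model

Pianka's index $O = \sum_i p_i q_i / \sqrt{\sum_i p_i^2 \sum_i q_i^2}$ is
scale-invariant in each argument, so FOO vectors need not be normalized
(tested property). Two uncertainty statements accompany the observed value:

- **Randomization null.** Each iteration permutes each species' utilization
  values independently across resource categories, *zeros included*: the
  multiset of values — the species' dietary niche breadth — is retained
  exactly (the RA3-style niche-breadth-retaining scheme). 10,000 iterations
  by default; summarized by mean and 2.5/97.5 percentiles; one-tailed
  p-value via the add-one estimator $(1 + \#\{O_\mathrm{null} \ge
  O_\mathrm{obs}\})/(n+1)$, which can never be zero.
- **Scat bootstrap.** Scats are resampled with replacement within each
  species, profiles and Pianka recomputed per replicate, 2.5/97.5
  percentiles reported. This is this package's documented construction for
  a CI around the *observed* value; a permutation null cannot bracket the
  observed value, and published CIs produced by unstated constructions are
  not promised to match numerically.

The null mean for small vectors is tested against full enumeration of all
$3! \times 3!$ permutation pairs, and both constructions are seeded and
deterministic.

# Richness rarefaction

The sampling unit is the scat (incidence framework — the natural x-axis is
"if more samples were collected"). With incidence frequencies $Y_i$ over
$T$ scats, interpolation uses the hypergeometric identity
$\hat S(t) = \sum_i [1 - \binom{T-Y_i}{t}/\binom{T}{t}]$ (computed in log
space to avoid overflow; $\hat S(T) = S_\mathrm{obs}$ exactly), the Chao2
asymptote uses $\hat Q_0 = \frac{T-1}{T}\frac{Q_1^2}{2Q_2}$ with the
bias-corrected branch when $Q_2 = 0$, and extrapolation uses
$\hat S(T+t^*) = S_\mathrm{obs} + \hat Q_0\,[1-(1-\frac{Q_1}{Q_1+T\hat
Q_0})^{t^*}]$. Confidence bands resample scats with replacement and
recompute the whole curve — simpler and more assumption-light than the
analytic bootstrap of detection probabilities used by dedicated richness
software, with which exact band agreement is not promised. Endpoint
defaults ($2T$, unit-step grid, 200 bootstrap replicates) are documented
choices, not inferred ones.

# The synthetic-data generator

`simulate_scats()` states a world and draws from it:

| parameter | default | meaning |
|---|---|---|
| `n_scats_per_species` | 30 | per-species sample size of the emulated survey |
| `n_replicates` | 3 | triplicate PCR |
| `lambda_richness` | 1.5 | prey richness per scat is 1 + Poisson(λ) |
| `dirichlet_alpha` | 1.0 | within-scat prey proportion concentration |
| `defecator_beta` | (8, 2) | defecator read fraction ~ Beta(a, b), mean 0.8 |
| `depth_median`, `depth_log_sd` | 20000, 0.5 | log-normal replicate depth |
| `dropout_d0`, `dropout_r0` | 0.5, 0.02 | detection failure prob. d0·exp(−r/r0) |
| `contamination_prob`, `contamination_fmax` | 0.1, 0.08 | second-carnivore reads |
| `tagjump_rate` | 0.002 | reads reassigned uniformly across the taxonomy |
| `failed_replicate_prob` | 0.05 | depth resampled below 1000 reads |

Rationale for the non-obvious pieces:

- **Dropout decays with true proportion** (rare taxa drop out more), the
  very failure mode the 2-of-3 consensus rule exists to absorb.
- **Tag-jump reads are reassigned, not added**, conserving replicate depth
  so depth semantics stay simple; destinations are uniform over the full
  taxonomy, so defecator reads can leak across scats as in real multiplexed
  runs.
- **Per-(species, scat) substreams** are derived deterministically from the
  seed, so enlarging either species' sample never perturbs previously
  generated scats.
- **Prey sets are drawn without replacement** proportional to availability
  weights. The selection mechanism was an open choice; this one is the
  simplest defensible sampling model. Its known consequence: for multi-item
  scats the occurrence process slightly flattens extreme availability
  ratios, so occurrence-based wPOO is a mildly compressed image of the
  availability vector. At the validation design (k = 4 blocks, λ = 1.5)
  this bias is small relative to the stated ±0.07 overlap-recovery
  tolerance and was budgeted analytically before the tests were run.
- `failed_replicate_depth_max` (default 1000) pins down what "a failed
  replicate's depth is resampled low" means; it intentionally coincides
  with the default validity threshold.

What the generator does **not** emulate: sequence-level error (chimeras,
polymerase error, pseudogenes), primer bias, reference-database gaps,
between-scat spatial or temporal correlation, nonvertebrate diet, and
biomass–read-count relationships. A green validation run therefore
establishes that the *statistical pipeline* recovers truth under the stated
count-level noise model — not that any wet-lab protocol is unbiased.

The closed-form overlap construction (`make_profiles_with_overlap()`)
builds `p` uniform on k categories, `r` uniform on the k disjoint ones and
`q = θp + (1−θ)r`, giving $O = \theta/\sqrt{\theta^2 + (1-\theta)^2}$
exactly; `run_validation()` wires these into the generator as per-species
prey availabilities and reports assignment accuracy, wPOO error and overlap
recovery per θ.

# Numerical and degenerate-input choices

- Proportions live in [0, 1] internally; percentages appear only in
  rendered reports (whole percent for FOO/wPOO, two decimals for Pianka).
- Thresholds: validity is strict (`>` 1000); RRA and share thresholds are
  inclusive (`≥` 1%).
- Binomial coefficients in log space (`lchoose`), with
  $\binom{a}{b} = 0$ for $a < b$ handled by `lchoose` returning `-Inf`.
- All-zero replicates have no defined RRA (hard error; the caller treats
  the replicate as absent). Zero-read input rows are legal and dropped with
  a logged count.
- Bootstrap replicates with empty union support are discarded and counted,
  never silently imputed.
- A read-count tie for the dominant carnivore is `ambiguous_defecator` by
  construction.
- `run_pipeline()` writes to a staging directory and copies on success;
  output bundles carry no timestamps, so a seed fully determines the bytes.

# Known limitations

- The per-replicate RRA reading of the retention rule and the collective
  reading of the other-carnivore rule are interpretations; both have
  config-switch alternatives, but only the defaults are exercised by the
  acceptance suite.
- The scat bootstrap is a different construction from published
  null-model-derived intervals; observed-CI agreement with any specific
  published analysis is out of scope.
- Rarefaction bands are resampling-based, not the analytic incidence
  bootstrap; bands (not point estimates) may differ from dedicated
  richness software.
- The exclusion rule drops sub-1% items individually and excludes a scat
  only when *all* items fail; analyses that excluded whole scats on any
  sub-threshold item would differ for mixed scats.
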
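# seedbankcoevo

Molecular-evolution analysis of bacteria–phage coevolution experiments
with a dormancy seed bank.

When a spore-forming bacterium coevolves with a virulent phage under
serial transfer, dormant endospores form a refuge: phages cannot adsorb to
them, so a seed bank stores both phage-susceptible phenotypes and
low-frequency alleles that selection or drift would otherwise purge. This
package implements, for pooled population sequencing (Pool-seq) allele
frequency trajectories from such an experiment (2×2 factorial: ±seed bank
× ±phage, replicate communities, sequencing at transfers 1, 4, 7, 10, 14):

- **Gene multiplicity** — the frequency-weighted per-gene mutational
  burden
  `m[i,j] = (L̄ / L[i]) · Σ_k f_med[j,k]`,
  where `L[i]` is gene *i*'s nonsynonymous target size, `L̄` the genome
  average, and `f_med` each mutation's median nonzero trajectory
  frequency; its normalised form `m̃ = m / Σ m` (summing to 1 per
  population) and rank-abundance views.
- **Permutation statistics** — self-contained two-sample
  Kolmogorov–Smirnov tests with value- or block-level label permutation,
  Bray–Curtis dissimilarity, principal coordinates analysis, and two-way
  PERMANOVA (seed bank × phage, sequential SS, Euclidean distance on the
  leading coordinates explaining >90% of variation).
- **Coevolution signal** — Pearson correlations between all eligible
  host×phage mutation-trajectory pairs per community (both members
  detected at ≥3 timepoints), tested against a null built by permuting
  each trajectory's time labels independently, with a direction
  diagnostic that is negative when observed correlations skew negative.
- **Design arithmetic** — serial-transfer generation counts, single-hit
  phage adsorption kinetics, and the pure-dilution expectation for the
  external seed bank refreshed at a 4:1 (new:old) volumetric ratio.
- **A synthetic Pool-seq generator** — replicator-dynamics trajectories
  with arms-race coupling, seed-bank buffering, binomial coverage noise
  and a breseq-like reporting floor, so the full pipeline runs and is
  testable without any sequencing download.

## Worked example

```r
library(seedbankcoevo)

cfg <- synthetic_config(seed = 1)      # the 2x2 x 3-replicate experiment
exp <- generate_experiment(cfg)

mult <- run_multiplicity_stage(exp, n_perm = 10000, seed = 1)
mutated_gene_ratio(mult$gene_counts)
#> [1] 1.669355
mult$ks$phage_plus
#> Permutation test: KS D (relative multiplicity)
#>   observed = 0.351654
#>   p = 9.999e-05 (10000 permutations, seed 7920)

coev <- run_coevolution_stage(exp, n_null = 50, n_perm = 999, seed = 1)
coev$obs_vs_null$minus
#> Permutation test: KS D (observed vs permuted-time null)
#>   observed = 0.270606
#>   p = 0.001 (999 permutations, seed 253409)
coev$obs_vs_null$minus$direction
#> [1] -0.2032809
coev$treatment_comparison$observed
#> [1] 0.1419535
```

Read: host populations evolving with a seed bank carry ~1.7× as many
mutated genes as those without (the generator's condition is ~2×); their
relative-multiplicity distributions differ (permutation KS at the
add-one floor); without a seed bank the host–phage trajectory
correlations skew negative relative to the permuted-time null
(direction −0.20, p = 0.001), and the two seed-bank treatments' pooled
correlation distributions differ with D ≈ 0.14.

The numbered scripts in `analysis/` (01 simulate → 05 design arithmetic)
run these stages end to end and write figure-ready tables under
`results/`. The methods vignette (`vignettes/methods.Rmd`) documents the
model, the permutation schemes and their calibration, and every generator
default.

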
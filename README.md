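# a3gclust

Detection of APOBEC3G-induced germline mutation clusters in comparative
genomic data.

## The problem

APOBEC3G (A3G) is a primate cytidine deaminase that attacks single-stranded
DNA, deaminating cytosines in CC/CCC contexts (the 3′ C is the mutated
base). A processive engagement deaminates several nearby same-strand
cytosines in one generation, so an inherited A3G event surfaces in
comparative data as a **coordinated cluster**: a group of closely spaced
substitutions that all arose from ancestral C (or all from G, for the
reverse strand). `a3gclust` is for evolutionary genomicists who want to
screen lineage-specific substitution sets for this signature and
characterize where in the genome it lands.

The pipeline:

1. **Parsimony calling** — lineage-specific substitutions from a
   ((target,sister),outgroup1,outgroup2) alignment: the sister allele,
   confirmed by at least one outgroup, is the ancestral state; positional
   filters and exclusion masks define the callable genome.
2. **Cluster detection** — maximal chains of ≥ 2 mutations with consecutive
   spacing ≤ 50 bp; clusters with a pair ≤ 10 bp apart are removed as
   potential complex mutations; clusters are typed by their shared ancestral
   base (mixed clusters are `N`). Each cluster's significance is the
   negative-binomial probability of its density, with π the per-bp mutation
   probability:

   p(k, x) = Σ_{j=0}^{x−k} C(k−2+j, j) (1−π)^j π^{k−1}
           = pnbinom(x − k, size = k − 1, prob = π)

3. **Motif enrichment** — E = signal/background for the deaminase motif
   panel (A3G CC/CCC, A3B TC/TCW, A3F TTC, AID WRC, mouse TYC) against four
   backgrounds (genomic composition, randomized mutations, randomized
   clusters, 10-kb local context), with one-tailed Fisher tests, Bonferroni
   correction, a 48-trinucleotide scan and CpG-deamination controls.
4. **Functional regions** — fold-change of the A3G-induced mutation set
   versus all other mutations across annotation tracks, expression-decile
   correlation, and branch-vs-branch differential accumulation.
5. **Block bootstrap** — standard errors from resampling contiguous genomic
   blocks (90 kb default) with replacement.
6. **Synthetic data** — a four-taxon alignment generator with planted A3G
   events and full ground truth, so every stage is testable end to end.

## Worked example

```r
library(a3gclust)

cfg <- simulation_config(genome_length = 5e5, seed = 42,
  branch_rates = c(target = 1e-3, sister = 1e-3, internal = 2e-3,
                   outgroup1 = 0.02, outgroup2 = 0.06),
  a3g_event_rate = 1e-4)              # ~50 planted A3G events
sim <- simulate_dataset(cfg)
ms  <- call_mutations(sim$alignment, masks = sim$annotations["repeat_mask"])
#> mutation_set: 757 mutations on chr1, callable length 488000 of 500000 bp

cs <- classify_clusters(exclude_complex(detect_clusters(ms, max_spacing = 50)))
#> cluster_set: 60 clusters (150 mutations clustered of 757), max_spacing=50
#>  C  G  N  T
#> 21 16 22  1

pan <- motif_enrichment(filter_by_pvalue(cs, 0.01), a3g_motif_panel())
pan[, c("label", "signal", "background", "E", "q")]
#>     label signal background    E        q
#> 1  A3G-CC  0.983     0.2250 4.37 1.75e-36
#> 2 A3G-CCC  0.383     0.0511 7.50 4.40e-14
#> 3  A3B-TC  0.000     0.2829 0.00 1.00e+00
#> 4 A3B-TCW  0.000     0.2058 0.00 1.00e+00
#> 5 A3F-TTC  0.000     0.0768 0.00 1.00e+00
#> 6 AID-WRC  0.000     0.3051 0.00 1.00e+00
```

Reading this: of the 60 mutations inside significant C/G-coordinated
clusters, 98% sit 3′ of a C (the lenient A3G motif CC; 4.4-fold over the
genomic expectation) and 38% complete a CCC (7.5-fold); no other deaminase
motif shows any signal. The planted events drive both:

```r
a3g <- define_a3g_clusters(filter_by_pvalue(cs, 0.01))
#> 16 A3G clusters holding 57 mutations
```

`sim$truth` carries the planted ground truth (positions, lineages, event
ids), which is how the test suite verifies recovery.

## The analysis

Numbered drivers under `analysis/` run the full study on synthetic data and
write their tables under `results/`:

| script | what it does |
|---|---|
| `01_simulate.R` | 2 Mb four-taxon fixture with 300 planted A3G events |
| `02_call_mutations.R` | parsimony calling, truth benchmark, lineage partition |
| `03_clusters.R` | chaining, complex exclusion, typing, P-values, expected counts |
| `04_motif_enrichment.R` | motif panel × 4 backgrounds, 48-triplet scan, CpG controls, confidence correlation |
| `05_regions.R` | region fold-changes, expression deciles, branch comparison |
| `06_bootstrap.R` | block-bootstrap standard errors |

Run them in order from the repository root, e.g.
`Rscript analysis/01_simulate.R`.

The methods vignette (`vignettes/a3g-cluster-detection.Rmd`) documents the
models, parameter defaults, generator assumptions and known limitations.

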
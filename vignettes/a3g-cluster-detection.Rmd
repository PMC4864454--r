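---
title: "Detecting APOBEC3G-induced germline mutation clusters: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting APOBEC3G-induced germline mutation clusters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(a3gclust)
```

# The scientific problem

APOBEC3G (A3G) is a primate cytidine deaminase that converts cytosine to
uracil on single-stranded DNA, preferring CC and CCC contexts with the 3'
cytosine as the deaminated base. A processive A3G engagement deaminates
several nearby cytosines of the *same* strand in a single generation, so an
inherited A3G event should surface, millions of years later, as a cluster of
closely spaced substitutions that all arose from ancestral C (or all from G,
when the enzyme acted on the reverse strand) — unlike independent point
mutations, which mix ancestral states.

`a3gclust` implements the comparative-genomic screen for such events: call
lineage-specific substitutions from a four-taxon alignment, chain them into
clusters, classify clusters by shared ancestral nucleotide, score them
against a null of independent mutations, and test the clustered mutations for
enrichment of deaminase motifs against several backgrounds, with
CpG-deamination controls, functional-region contrasts and block-bootstrap
errors. A synthetic alignment generator with planted A3G events provides
ground truth, so every stage is testable without external genome downloads.

# Mutation calling by outgroup-confirmed parsimony

The input is a gap-free alignment of a target genome, a sister species, and
two outgroups, mirroring the (human, chimpanzee, orangutan, rhesus) design.
At each position the sister allele is taken as the ancestral state of the
target–sister ancestor *iff* it is a plain base (A/C/G/T) and matches at
least one non-missing outgroup allele; a target-lineage substitution is
called wherever the target allele differs from that ancestral state.
Positions with a missing target or sister allele, with both outgroups
missing, or inside user-supplied exclusion masks (repeats, segmental
duplications) are removed first; the count of surviving positions is the
*callable length*.

Three choices here were genuinely open:

* **Context haplotype.** Motif evaluation needs the sequence as it was
  *before* the mutations. We reconstruct an ancestral haplotype by
  substituting the inferred ancestral allele at **every** called position,
  so the context of one cluster member is not corrupted by its neighbours'
  derived alleles. (A flagless reference-allele mode was considered and
  rejected: with 11–50 bp spacings, neighbouring derived alleles would
  frequently sit inside each other's trinucleotides.)
* **Ambiguity.** Any non-ACGT symbol counts as missing; soft-masked
  lowercase is uppercased rather than filtered, since repeat handling is
  delegated to explicit masks.
* **Homoplasy.** A target allele that differs from the ancestral state but
  equals one outgroup is still called, as in plain parsimony. On synthetic
  data this produces a small false-call rate (visible in stage 2 of the
  analysis scripts as calls absent from the truth table), which is why
  branch rates are capped at 0.1 — beyond that the low-homoplasy assumption
  collapses.

Mutations can be partitioned among descendant lineages (e.g. modern human /
Neandertal / Denisovan) with per-lineage allele tracks: carried by all
lineages → `common`; carried by exactly one → that lineage; a strict subset
or missing data → `unassigned` and excluded from branch-specific sets.

# Clusters and the negative-binomial P-value

A cluster is a maximal chain of at least two mutations on one chromosome in
which every consecutive pair is separated by at most 50 bp (transitive
chaining; 100/300/1000 bp supported for sensitivity analyses, and an
all-within-window mode is available behind a flag). Clusters containing a
pair ≤ 10 bp apart are removed entirely — multi-nucleotide replication
errors ("complex mutations") mimic clusters at that scale. Clusters whose
members share one ancestral base are *coordinated* (C-, G-, A-,
T-coordinated); mixed clusters are typed `N` and kept in a side table, never
silently dropped.

With $\pi$ the genome-wide per-bp mutation probability (total mutations over
callable length; computed per lineage by default, since branch lengths
differ), the probability of observing the remaining $k-1$ mutations of a
cluster within its $x-1$ bp is the lower tail of a negative binomial with
$k-1$ successes of probability $\pi$, evaluated at $x-k$ failures:

$$p(k, x) \;=\; \sum_{j=0}^{x-k} \binom{k-2+j}{j}\,(1-\pi)^j\,\pi^{k-1},$$

implemented as `pnbinom(x - k, size = k - 1, prob = pi)`. For $k=2$ this is
the closed form $1-(1-\pi)^{x-1}$. The binomial coefficient is the standard
negative-binomial one, $\binom{k-2+j}{j}$: the coefficient sometimes typeset
as $\binom{(k-1)+(j-1)}{j}$ is inconsistent with the verbal definition of
the statistic ("$k-1$ mutations in $x-1$ bp") and with the $k=2$ closed
form; the tests pin the implementation to a term-by-term summation, the
closed form, and a $10^7$-replicate Monte-Carlo simulation of per-bp
Bernoulli mutation.

Two expected-count formulas quantify coordination excess under the null of
independent mutations, with $N_i$ the number of clusters with $i$ mutations:

* expected same-ancestor clusters for a state of prevalence $p$:
  $\sum_i N_i\,p^i$;
* expected clusters carrying ≥ 1 motif mutation when each clustered mutation
  falls in the motif with probability $p$: $\sum_i N_i\,(1-(1-p)^i)$, the
  closed form of the printed binomial sum.

# Motif enrichment

The *signal* of a motif is the fraction of clustered mutations at its
mutated position among all mutations in C- and G-coordinated clusters:
C-clusters are matched on the plus strand, G-clusters against the
reverse-complement pattern at the mirrored register, so a free enzyme's
strand symmetry is built in (reverse-complementing the entire dataset leaves
every enrichment unchanged — a tested invariant). Enrichment is
$E = \text{signal}/\text{background}$ with four background models:

1. **genomic** — motif occurrences (both strands) over genomic C+G counts;
   both-strand counting keeps numerator and denominator on the same footing
   as the pooled C/G signal;
2. **randomized mutations** — each mutation re-placed uniformly at a
   callable position of its own chromosome and (by default) its own
   ancestral base, the set re-clustered and re-filtered with the observed
   parameters, and the clustered motif fraction averaged over 100 sets.
   Base-matched placement is the default because signal and background are
   defined per ancestral base; unconstrained placement is available;
3. **randomized clusters** — every observed C/G cluster relocated to a
   uniform locus with its length, member offsets and strand preserved;
4. **local context** — motif frequency among C/G positions in the union of
   10-kb windows centered on cluster midpoints, controlling for local
   composition.

Significance uses a one-tailed Fisher exact test on the 2×2 table of
(in/out of motif) × (clustered mutations / background counts), Bonferroni
corrected within the panel tested in one invocation. The default panel holds
the A3G motifs (CC, CCC; mutated 3' C), A3B (TC, TCW), A3F (TTC), AID (WRC)
and optionally the mouse A3 motif TYC as a negative-control entry — mutated
positions follow the deaminase signature literature and are configurable
per motif.

The **48-trinucleotide scan** tests every triplet with a C at each of its
three positions (16 patterns × 3 registers) the same way, flagging
CG-containing patterns whose enrichment is confounded by CpG deamination.
One honest caveat, documented because it matters for interpreting scans of
strongly clustered data: every A3G mutation carries a 5' C by definition of
the CC/CCC motifs, so when planted (or real) A3G mutations dominate the
clustered set, register-shifted triplets such as CC`A`@middle or `A`CC@3'
are *genuinely* enriched too — uniqueness of CCC among significant triplets
is a property of weak-signal regimes, where the deaminase contributes only a
small fraction of clustered mutations. In this package's planted-signal
tests CCC is asserted to be the top-ranked CpG-free triplet, which is the
scale-invariant form of that observation.

**CpG controls.** Spontaneous deamination of methylated CpG cytosines is the
main confounder of any C-centered motif. Three controls separate it from
deaminase activity: (a) recompute enrichment after removing every mutation
whose mutated base lies in a CpG on its strand, against a CpG-masked genomic
background; (b) exclude CCCG contexts (mutated C followed by G) from the
numerator and the background motif count; (c) decompose per-site mutation
rates over the strata CCC-only, CpG-only, CCC∩CpG and neither — additivity
of the first two in the intersection stratum indicates two superimposed
processes rather than one. A mutation in a CCCG context deliberately counts
in both marginal strata. "Mutated base in a CpG" is defined as the mutated
C being immediately 5' of G on its strand (symmetrically for G mutations);
defining it by any CpG overlap of the triplet was rejected as conflating
neighbour effects with the deamination chemistry.

**Confidence correlation.** `enrichment_vs_confidence()` recomputes E on the
clusters surviving each P-value threshold and correlates E with
$-\log_{10}$(threshold). When the loose-threshold set is dominated by chance
clusters, stricter thresholds purify the deaminase signal and the
correlation is strongly positive; when planted signal dominates every bin
(as under this package's default planted conditions) E is flat and the
correlation is uninformative — the analysis scripts print this explicitly.

# Functional regions

The A3G-induced set is defined as all mutations inside C/G-coordinated
clusters that contain at least one CCC (or GGG) mutation; the control set is
all other mutations. For a region set, the fold-change is the ratio of
in-region fractions, tested two-tailed with Bonferroni correction across the
region panel; a mutation "falls in" a region iff its single-base position
lies in the half-open interval (clusters contribute per mutation, since the
statistic counts mutations). Expression intervals are split into ten
*length-weighted base deciles* by level (a gene-level mode was considered;
base deciles were chosen because the mutation counting is per-base), the
per-decile fold-change is correlated with the decile's mean level over
deciles 1–9, and the top decile is reported separately — the most highly
transcribed regions are under distinct selective constraint and behave as an
outlier. The branch comparison contrasts two branch-labelled A3G sets per
region family with a two-tailed exact test on in/out counts, reporting
nominal and FDR-adjusted values.

# Block bootstrap

Standard errors respect local genomic correlation by resampling contiguous
blocks: the callable genome is tiled into equal blocks (90 kb at production
scale — about 35,000 blocks on a human-sized genome; the pipeline shrinks
the block size to keep at least ~20 blocks on small synthetic genomes),
blocks are drawn with replacement, the data rows in the drawn blocks are
pooled (duplicated when a block is drawn twice) and the statistic is
recomputed. The SE is the standard deviation across replicates; 2.5/97.5
percentiles give the interval. Backgrounds are held fixed during resampling
and cluster memberships are not re-derived — at 90 kb a block is three
orders of magnitude longer than a 50 bp cluster, so resampling blocks
resamples whole clusters; per-replicate background recomputation is
supported but off by default for cost. Production replicate count is
10,000; the packaged tests use a few hundred. A statistic undefined on more
than 1% of replicates raises an error rather than returning a silently
truncated SE.

# The synthetic-data generator

`simulate_dataset()` emulates the mutational structure the screen assumes:

* **Ancestral genome** — iid bases at a target GC (default 0.41,
  human-like), with the CG dinucleotide frequency calibrated to
  `cpg_enrichment` times the independence expectation (default 0.25,
  matching vertebrate CpG depletion). Calibration solves jointly for the
  planting/destruction rate and a compensated base composition, so the final
  GC stays within 2% of target while CG frequency scales with the
  multiplier.
* **Branch mutations** — every site mutates independently per branch
  (`target`, `sister`, `internal`, two outgroups; defaults on the scale of
  great-ape divergences), with CpG sites hypermutable (default 10×, biased
  to transitions).
* **Planted A3G events** — event count is Poisson at `a3g_event_rate` per
  bp (default 1e-4); each event draws a size from a geometric-like
  distribution on 2..5 (the in-vivo processivity distribution is unknown;
  this is a modelling choice, flagged here), a strand (reverse with
  probability 0.5, the symmetry of a free enzyme), and places mutations at
  the 3' C of CCC contexts with probability `motif_fidelity` (default 0.8),
  otherwise at CC-not-CCC, with consecutive spacing uniform on eligible
  positions in (10, 50] bp — above the complex-mutation exclusion, inside
  the chaining window, so planted events exercise the intended detection
  path (a deliberately violating configuration is one parameter away).
  When the drawn class has no eligible position in the window the other
  class is used as a fallback (at fidelity 0 or 1 the fallback is disabled
  so the extremes are exact); realized fidelity therefore deviates slightly
  from the configured value in motif-sparse windows. Derived alleles are
  C→T with probability 0.7 (A3G's transition excess), the rest split
  between C→G and C→A. Optionally, event anchors are sampled inside a
  scored annotation track with probability proportional to interval level,
  emulating transcription-coupled exposure.
* **Annotations** — interval tracks (transcribed, exons, regulatory, a
  repeat mask, a lognormal-scored expression track) placed one-per-slot so
  they never overlap within a track.
* **Lineage tracks** — each target-branch event is assigned to
  `common` or one of three descendant lineages (defaults 0.7/0.1/0.1/0.1),
  and allele tracks are emitted accordingly.

Identical configurations (including the seed) produce byte-identical
fixtures. What the generator does *not* model — and what passing tests
therefore do not establish about real genomes — includes recombination and
linkage breakup of old clusters, indels and alignment error, selection,
mutation-rate heterogeneity beyond CpG, and archaic-genome sequencing error.
The generator's role is to verify the *machinery* (calling, chaining,
scoring, enrichment, resampling) against a known truth, not to reproduce
genome-scale effect sizes.

# Numerical and interface conventions

All internal coordinates are 0-based half-open; BED files are read and
written natively in that convention, and any 1-based export happens only at
an I/O boundary. Interval normalization merges overlaps with
length-weighted level averaging. Ties and zero cells in exact tests are
handled by the exact hypergeometric computation (no continuity correction).
Fisher tables for the randomized backgrounds pool counts across replicate
sets. Analysis problem sizes in the packaged scripts and tests (2–10 Mb
genomes, 100–10,000 bootstrap replicates, 20-seed calibration batches) were
chosen so each stage has enough events for its statistical check while a
full run stays in the minutes range.

# Known limitations

* Long sparse deaminase tracks broken by interleaved mutations are not
  captured (chaining stops at the spacing limit), and linkage breakup makes
  all counts conservative for old events.
* The simple parsimony rule miscalls at homoplasic sites; rates above a few
  percent per branch degrade it quickly (hence the 0.1 cap).
* The 48-triplet scan's register bleed under dominant clustered signal,
  discussed above.
* With a single scored expression track, planting weights are uniform
  within an interval; real transcription-coupled exposure varies within
  genes.
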
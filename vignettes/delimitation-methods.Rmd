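---
title: "Stepwise PCO species delimitation: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stepwise PCO species delimitation: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`crenadelim` delimits candidate species from codominant allozyme genotypes
validated against mitochondrial sequence evidence, following the integrated
workflow used for the *Crenadactylus* gecko complex.  This vignette is the
package's account of the underlying models, the parameters that matter, the
numerical choices made where the method is silent, and what the synthetic
data generator does and does not emulate.

## The delimitation model

The unit of evidence is the **fixed difference** (FD): a locus at which two
population samples share no alleles.  Shared ancestry with ongoing gene flow
keeps alleles shared; a locus that has become fixed for disjoint allele sets
in two populations is strong evidence that they have stopped exchanging
genes.  Because rare alleles leak across otherwise-diagnostic boundaries and
sampling can miss them, the percentage-FD statistic admits a **cumulative
tolerance**: at each locus jointly scorable in both groups the shared-allele
mass

$$m = \sum_{a \,\in\, A \cap B} \frac{p_A(a) + p_B(a)}{2}$$

is computed over the alleles present in both groups, and the locus counts as
fixed iff $m \le t$.  The strict rule is $t = 0$; the conventional reported
statistic uses $t = 0.10$.  Averaging the two taxa makes the rule symmetric
and reduces exactly to the strict rule at $m = 0$.  The comparison is
per-locus; the tolerance is not pooled across loci (an alternative reading of
"cumulative" would sum masses over loci, which would make the rule depend on
the size of the locus panel — we document the choice and expose `tolerance`
as an argument).  The %FD denominator is the number of loci scorable in
*both* groups, not the panel size: published combined tables are internally
inconsistent under any fixed denominator (adjacent cells imply denominators
of 41 and 42), so varying denominators are assumed throughout, which is also
what pairwise deletion of missing gel scores produces naturally.

Two distances complement the FD counts.  **Rogers' distance** is the
per-locus Euclidean distance between allele-frequency vectors scaled to
$[0,1]$, averaged over jointly typed loci — a metric, which matters because
it feeds the PCO embedding.  **Nei's unbiased distance** corrects the
within-group gene identities for sample size,
$\hat J_X = (2n \sum_a p^2 - 1)/(2n - 1)$; the correction can overshoot for
very similar groups, and small negative distances are clamped to zero and
flagged.  Groups sharing no alleles anywhere have zero between-group
identity and infinite distance, returned as `Inf` with a warning rather than
an error, since a printed table can legitimately contain such cells.

## Stepwise PCO

Principal Co-ordinates Analysis embeds the individual-level Rogers' distance
matrix by Gower double-centering of $-\tfrac12 d^2$ and eigendecomposition;
axis $i$ is $\sqrt{\lambda_i}\, v_i$.  The original procedure inspected
scatterplots of the first two axes by eye; the package automates the visual
step deterministically: average-linkage agglomerative clustering on the
first two axes proposes partitions for $k = 2 \dots \min(8, n)$, and a
partition is accepted only if **every** pair of its groups shows at least
`min_fd` fixed differences at the validation tolerance.  The largest
accepted $k$ wins; validated clusters are re-analysed by their own PCO
round, recursively.  This surrogate is a documented stand-in for visual
assessment, not a claim about how the original analysis chose its clusters —
but because every split must survive FD validation, the surrogate can only
differ from a careful visual analysis in clusters that the data cannot
validate anyway.

Parameter defaults, and why:

* `min_fd = 3` — subgroups differing by fewer than three fixed differences
  are treated as non-distinct, the threshold used in the original study.
* `tolerance = 0` for cluster *validation* (the strict rule), `0.10` for
  *reported* %FD.  The tolerance was introduced for the reported statistic,
  not explicitly for validation; both are arguments.
* `max_rounds = 3` — full dataset, regional clusters, within-region
  subgroups; the study performed three rounds.
* The $k$ scan stops at `min(8, n)` rather than `min(8, n - 1)`: a node
  containing exactly two singleton taxa must be allowed the all-singletons
  partition ($k = n = 2$), otherwise two deeply divergent specimens isolated
  together in one node could never be delimited — four of the five Kimberley
  taxa in the motivating study are single-specimen lineages, so this boundary
  case is not hypothetical.

Numerical choices in the PCO: negative eigenvalues (non-Euclidean input)
are discarded from both the coordinates and the percent-variation
denominator, with their count reported — the standard Gower practice.
Per-axis sign is fixed by making the largest-magnitude loading positive, so
plots and tests are reproducible across BLAS implementations.  Distances
are used as-is (not square-root transformed); Rogers' distance is already
metric.  A node whose members are genetically identical yields an all-zero
distance matrix with no positive eigenvalue; such nodes are terminal rather
than errors.

## Sequence divergences and congruence

Uncorrected p-distances and model corrections use pairwise deletion; IUPAC
ambiguity codes are always treated as missing, never partially matched.
JC69, K2P and TN93 use their closed forms (saturated pairs where a logarithm
argument becomes non-positive return `Inf` with a warning).  The default
corrected distance is **GTR+G** — the closest pairwise analogue of the
GTR+I+G tree models used for the sequence data — fitted by maximising the
likelihood of the pairwise site-pattern counts over the branch length, with
empirical base frequencies from the pair, user-suppliable exchangeability
rates (default equal), and 4 discrete gamma categories (`gamma_shape = 1` by
default).  The published divergence table does not name its correction, so
the model is selectable; fixture-based summaries use the printed values
directly and involve no re-correction.

Reciprocal monophyly is assessed on the unrooted topology: a group is
monophyletic iff its tips are separated from all others by a single edge,
i.e. the group or its complement is a clade in an arbitrarily rooted view.
Singleton groups are `"not_assessable"` rather than `TRUE` or `FALSE`.

A terminal cluster is nominated as a **candidate species** when (i) its
minimum strict-FD count against every other cluster is at least `min_fd`,
(ii) it is reciprocally monophyletic or monophyly is not assessable, and
(iii) its minimum between-cluster mitochondrial divergence exceeds its
maximum within-cluster divergence wherever both are computable.  Clusters
with no sequenced member fall back to allozyme-only evidence with a warning.

## The synthetic-data generator

The generator emulates the study design so the pipeline can be exercised
against known truth: 94 diploid individuals in 10 groups at 42 loci — six
primary regional groups, the Kimberley region holding five subgroups, three
of them singletons (sizes 20, 14, 10, 17, 1, 3, 1, 1, 7, 20; sample sizes
per group are not printed in the source study, so these were chosen once to
match the stated totals, the 13 Kimberley specimens, and the singleton-heavy
Kimberley sampling) — plus an 828-site alignment for a 53-sequence subset.

Fixed differences are planted through per-locus **allele-block partitions**:
all groups in a block share that block's allele(s), so a pair of groups is a
strict FD at a locus iff the partition separates them, and planted FD counts
are Hamming distances over the locus plan — exact by construction, not in
expectation.  The study-like plan plants 5–9 FDs among Kimberley subgroups
and 8–20 between primary regions (inside the published 4–14 and 4–21
envelopes).  An arbitrary target FD matrix is realized greedily, separating
every pair with remaining demand each round and coarsening the partition
whenever a full decrement would leave a triangle-violating residual;
infeasible targets (triangle violations, locus-budget overruns) are rejected
before any sampling.  Genotypes are drawn under Hardy–Weinberg within
groups; blocks holding two or more groups carry a secondary shared allele at
frequency 0.15 (mild realistic polymorphism that cannot disturb planted
FDs); two loci carry a universal allele at frequency 0.05 so the 10%
tolerance boundary is exercised; missing scores occur at rate 0.02, in the
range of real gel datasets.

Sequences evolve site-independently under GTR+I+G (transition-biased
exchangeabilities 1,8,1,1,8,1; base frequencies 0.35/0.30/0.10/0.25; gamma
shape 0.8 in 4 discrete categories; 35% invariant sites — chosen to mirror a
protein-coding mitochondrial gene with roughly 46% invariable sites) along
an ultrametric tree whose node heights are obtained by numerically inverting
the model's expected p-distance, so expected between-group uncorrected
divergences land at 0.17–0.26, inside the published 0.14–0.29 span, and
within-group divergences stay near 1%.

What the generator does **not** emulate: linkage between loci, within-group
geographic substructure, mitochondrial introgression (haplotype sharing can
be staged manually in tests, but is not a generator feature),
heterozygote-deficit departures from Hardy–Weinberg, coalescent gene-tree
discordance, and the deep within-lineage mitochondrial diversity (up to
~10%) of the real data, which the generator keeps low so that planted truth
stays unambiguous.  Passing tests therefore show that the pipeline recovers
clean planted structure at realistic problem sizes, not that it would make
the same decisions as the original analysis on the original gels.

## Known limitations

* With only one to three sampled individuals per group, an individual
  homozygous for the 15%-frequency secondary allele at three or more loci is
  — in the sample — indistinguishable from a true singleton taxon, and the
  strict-FD rule will validate a spurious split.  At the study-like
  polymorphism level this happens in a few percent of generator seeds.  The
  vulnerability is inherent to fixed-difference diagnosis of singleton-heavy
  samples, which is why the congruence rule demands independent
  mitochondrial support.
* The mean %FD recomputed from a *printed* table of rounded percentages
  (36.9 in the shipped fixture) differs in the first decimal from a mean
  computed on unrounded data (36.7 in the source study); minima and maxima
  are unaffected by display rounding.
* The FD planner realizes targets expressible as sums of partition metrics
  reachable by its greedy coarsening; it reports — rather than silently
  approximates — anything else.
* `nei_unbiased_distance` excludes loci with fewer than 2 gene copies in
  either group (the unbiased correction is undefined there) with a warning.

## Problem sizes used by the test suite

The suite validates statistics against independent oracles (brute-force
allele-set intersection, naive mismatch loops, bipartition enumeration,
straight-line Nei formulas, `cmdscale`, `ape::dist.dna`) at small sizes
chosen for tight Monte-Carlo error at interactive runtimes: 20-seed
parameter-recovery replicates of the 94-individual scenario, 100–500-case
property sweeps, 10–100 kb two-taxon alignments for estimator consistency,
and single full-pipeline runs with byte-identical-rerun checks.
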
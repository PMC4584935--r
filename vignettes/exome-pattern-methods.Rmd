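---
title: "Methods: exome variant pattern analysis in small familial tumor-control cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exome variant pattern analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exopattern)
```

# The analysis problem

`exopattern` implements a pattern-analysis workflow for very small familial
cohorts of tumor and control exomes — the setting where two related tumor
samples and a handful of related healthy controls are compared without
matched germline sequencing for the cases. The pipeline asks four
questions:

1. **Do affected gene sets carry phenotype structure?** Genes hit by
   qualifying exonic/splice-site variants are encoded as a binary
   gene-affection matrix and embedded by non-metric multidimensional
   scaling (NMDS); hierarchical clustering of the same distance matrix is
   the companion view.
2. **Do novel SNVs carry an editing signature?** An excess of A↔G / C↔T
   transitions among novel substitutions, relative to known ones, is the
   fingerprint expected of enzymatic DNA/RNA editing (e.g. APOBEC/AID
   cytidine deamination). The test is an exact 2×2 comparison of
   transition/transversion counts across novelty strata.
3. **Which variants are somatic and shared between tumors?** Without
   germline calls for the cases, somatic status is inferred by
   identity-by-state set logic: keep variants present in *every* tumor and
   in a positive somatic catalog, and absent from *every* related control.
4. **Is the mutational burden organized?** Hypergeometric
   over-representation of affected gene sets against annotation terms (BH
   FDR), interaction-subnetwork centrality (degree, betweenness,
   closeness), network overlap, and a hub-adjacency contrast between
   nonsynonymously and synonymously affected genes.

# Variant model and normalization

A variant is the normalized tuple `(chrom, pos, ref, alt)` plus annotation
fields (region class, exonic function, gene symbols, known-variant id,
population allele frequency, and a ConDel-like deleteriousness score in
[0, 1]). Normalization trims shared trailing bases, then shared leading
bases (advancing `pos`), always retaining one base per allele. This makes
keys canonical across dialects without a reference genome; it is weaker
than full left-alignment, which would need the genome sequence, and that
trade-off is deliberate: every input the pipeline compares is normalized
by the same rule, so set operations remain internally consistent.

Two dialects are read and written: a minimal single-sample VCF 4.2 whose
INFO keys carry the annotations, and an ANNOVAR-style TSV. Multi-allelic
VCF rows are split before any analysis. BED export is 0-based half-open
with a `ref>alt` name column.

Key thresholds, both surfaced as arguments:

* **Novelty** (`af_threshold = 0.01`): a variant is novel when absent from
  the known-variant catalog, or present with a population allele frequency
  below 1%. A cataloged variant with unknown frequency counts as known —
  the conservative reading when external catalogs disagree.
* **Damaging** (`cutoff = 0.522`): the published ConDel operating point.
  Unscored variants are never damaging (with a counted warning), so
  missing annotation cannot inflate burden.

# Ordination

Gene-affection sets use the exploratory-analysis predicates: SNV sets keep
genes with exonic nonsynonymous/stop-gain/stop-loss or splice-site
changes (synonymous changes are spared); INDEL sets keep genes with any
exonic/splice-site insertion–deletion. The binary matrix marks affected
genes 1 and spared genes 0, with lexicographically ordered columns.

The distance defaults to **Jaccard** (`stats::dist(method = "binary")`),
the conventional choice for asymmetric binary data where joint absence of
a gene hit carries no information; Euclidean is available because the
upstream tooling this workflow descends from defaults to it. The choice is
recorded in the result provenance.

NMDS is Kruskal's method, implemented in the package because its contract
here is stricter than off-the-shelf wrappers expose:

* **Initialization**: classical scaling (Torgerson double-centering, top-k
  spectral coordinates, negative eigenvalues clipped); additional starts
  (default 4 in total) perturb it with seeded Gaussian noise and the best
  final stress wins.
* **Iteration**: configuration distances → pool-adjacent-violators
  (isotonic) disparities in the rank order of the input dissimilarities →
  Kruskal stress-1 → Guttman-transform update. Only stress-decreasing
  steps are kept, so the stress trace is non-increasing by construction.
* **Stopping**: stress change below `tol` (default 1e-6), stress below
  1e-8, or `max_iter` (default 300).
* **Ties** follow Kruskal's primary approach (tied dissimilarities may
  take any disparity order). All-equal dissimilarities are flagged as
  degenerate.
* The dimension bound is `k ≤ n − 1`; five samples admit at most four
  dimensions, and in the full `n − 1` dimensions a monotone embedding
  always exists, so stress near zero there is expected, not impressive.
  The scientific content is in *which* samples dimension 1 separates.

Hierarchical clustering wraps `stats::hclust` (average/UPGMA linkage by
default; the merge heights are validated against a brute-force
set-average oracle in the tests) and exports Newick via `ape`.

# The editing-signature test

Transitions are A↔G and C↔T; everything else off-diagonal in the 4×4
ref×alt count matrix is a transversion, strand as written (no
reverse-complement folding beyond the natural two-class partition). The
novelty-stratified test forms the 2×2 table (transitions, transversions) ×
(novel, known) and computes the two-sided Fisher exact p by the
point-probability rule — the sum of hypergeometric point probabilities at
most that of the observed table, within a relative tolerance of 1e-7 —
with log-factorial accumulation so tables with tens of thousands of
substitutions are handled exactly. The reported odds ratio is the sample
estimate, flagged as such. Whether the known-SNP baseline should be
per-sample or pooled is not a settled convention; the pipeline reports
both.

# Identity-by-state somatic inference

The filter is pure set logic over normalized keys:

```
(∩ tumor keys) ∩ catalog keys − (∪ control keys)
```

with per-stage counts logged (tumor-shared, catalog-matched, after control
removal, genes). Matching requires the exact alternate allele by default;
`match_alleles = FALSE` relaxes to positional matching for catalogs with
divergent allele representations. Controls act as germline references
without genotype-quality weighting — none is available in this design.
The result is monotone in its inputs (more controls never grow it, more
catalog never shrinks it), which the property tests assert directly.

# Networks and enrichment

Subnetworks are induced subgraphs on the query genes (`direct`), or
additionally admit non-query nodes adjacent to at least two query genes
(`plus_bridges`) — the route by which an unmutated hub that interacts
extensively with affected genes becomes visible. Centrality conventions,
chosen because the measures are standard but their normalizations are
not: degree as incident edge count; betweenness by Brandes' algorithm on
unweighted shortest paths, unnormalized, endpoints excluded (igraph's
convention); closeness as the Wasserman–Faust composite
`((r−1)/(n−1)) · ((r−1)/Σ d(v,u))` over the `r` reachable nodes, which is
0 for isolated nodes and well defined on disconnected graphs. Ranks, not
raw values, are the comparison surface. The largest-component percentage
counts query genes in the largest connected component, treating absent
query genes as singletons, so an edgeless query yields `100/|query|`.

Enrichment is the upper-tail hypergeometric (`stats::phyper`) with BH FDR
(`stats::p.adjust`) at `alpha = 0.05`. The default universe is every gene
carrying an exonic/splice variant anywhere in the cohort — enrichment
conclusions are universe-sensitive, so the universe is always an explicit
argument. Terms with fewer than 3 in-universe genes are excluded by
default, mirroring common over-representation-tool practice. The
gene-family contrast (e.g. olfactory receptors vs histone/actin families)
is codified as a two-sided Fisher test on affected counts; the upstream
publication-grade analyses did not name their statistic, so this choice
is the package's own and printed family p-values from other tools are not
treated as reproducible.

# The synthetic cohort generator

The generator is first-class, tested code: it defines the conditions under
which the pipeline's recovery claims are made.

* **Pedigree**: two tumor samples (P17, P61) that are first cousins via a
  common grandparental couple; controls P39 (P61's sibling), P26 (a first
  cousin) and P84 (descended from unrelated founders).
* **Germline variation** has two layers. A *common population panel*
  (70% of SNVs, 50% of INDELs per sample) is carried by every individual
  and always known — real exomes share most common variants across any
  two people, and without this layer the samples would be mutually
  near-disjoint and no control sub-clustering could exist. *Rare
  founder-specific variants* gene-drop through the pedigree with
  probability ½ per meiosis, so first-degree relatives share about half
  of them (a property the tests check on exactly this stratum). All novel
  variants are rare.
* **Scale**: defaults are full study scale — ~45,000 germline SNVs and
  ~9,000 germline INDELs per sample, a 7.2% novel germline SNV fraction,
  1,800 novel somatic SNVs per tumor, and a 2.4-fold tumor INDEL burden
  (somatic INDELs = 1.4 × germline), reproducing the characteristic
  per-sample class-count table. `cohort_config(scale = 0.05)` shrinks the
  gene universe and all counts proportionally for repeated-seed
  experiments; the 100-seed recovery checks in the test suite run at that
  scale.
* **Somatic sharing**: each somatic variant is shared by both tumors with
  probability 0.5. The defining observation in this family design is that
  tumor–tumor sharing *exceeds* sibling-level identical-by-descent sharing
  (which is ½ of the rare germline); a shared-somatic layer of this size
  makes the tumors the tightest pair in the INDEL ordination, which is
  what the dimension-1 separation claim rests on. Shared somatic variants
  enter the positive catalog with probability 0.5 by default (the overlap
  with an external somatic archive is snapshot-dependent; recovery tests
  that need certainty set it to 1).
* **Substitutions** are drawn in two stages — transition vs transversion
  Bernoulli (0.825 novel / 0.68 known), then uniform within the class —
  deliberately *not* a 12-rate or trinucleotide-context model, because the
  statistic under test only sees the two-class partition.
* **Planted structure**: tumor somatic exonic INDEL genes are drawn 50%
  from the pools of two planted annotation terms (40 genes each); an
  unmutated hub gene connects to 40% of somatically nonsynonymous genes
  and 2% of others on top of an Erdős–Rényi background (density 0.002).
  The truth bundle records shared somatic keys, planted terms, the hub,
  and phenotypes.

What the generator does **not** emulate: sequencing error and coverage
variation, mutational spectra beyond the two-class transition model,
linkage disequilibrium, structural variants, and real annotation-term
correlation structure. Passing recovery tests therefore demonstrate that
the *algorithms* recover the planted structure under the stated model,
not that the biological conclusions of any particular study are correct.

# Numerical choices and degenerate inputs

* Fisher and hypergeometric tails are validated against full-enumeration
  oracles for all tables with total ≤ 40 (tolerance 1e-9); betweenness
  against exhaustive shortest-path counting on random graphs ≤ 8 nodes;
  UPGMA heights against an O(n³) recomputation.
* A zero margin in a 2×2 table yields p = 1 with a warning rather than an
  error; an empty substitution spectrum, an empty universe, or an empty
  query is an error.
* Two all-zero affection rows are at Jaccard distance 0 (empty sets are
  identical, not undefined).
* The null-calibration test (both strata at transition probability 0.68,
  500 substitutions each, 1000 replicates) checks the empirical
  rejection rate at 0.05 stays in [0.03, 0.07].
* Determinism: every stochastic routine takes an explicit seed;
  `run_pipeline` reruns byte-identically apart from manifest timestamps.

# Known limitations

* Trim-only normalization cannot reconcile representations that differ by
  alignment against the reference sequence.
* With five samples the ordination is descriptive: stress in four
  dimensions is necessarily near zero and no significance is attached to
  the embedding itself.
* The IBS filter's precision depends entirely on the positive catalog:
  germline variants present in the catalog and absent from the sampled
  controls are indistinguishable from shared somatic variants.
* Centrality ranks depend on the interaction database's degree
  distribution; only the contrast tests (hub adjacency, family
  representation) carry a significance statement.
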
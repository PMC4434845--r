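---
title: "Methods: quantifying molecular convergence of immune-mediated disease gene sets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying molecular convergence of immune-mediated disease gene sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imdconverge)
```

## The question and the overall procedure

Risk-gene lists for immune-mediated diseases overlap only partially, and the
shared genes are exactly the ones that would trivially explain any apparent
molecular similarity. This package measures convergence of a focal disease
gene set (ankylosing spondylitis, AS, in the default design) with eight other
immune-mediated disease sets *after* controlling for that confound, through
five largely independent lenses: set overlap itself, purifying-selection
burden, expression profiling, pathway enrichment, and interaction-network
connectivity. Each stage is a pure function of plain-text inputs (TSV, BED,
GMT) and fixed thresholds, so a run is fully reproducible from its manifest.

Gene identity throughout is the uppercased HGNC-style symbol; no alias
resolution is attempted. That is a real limitation when inputs come from
sources with different annotation vintages (the pathway databases and the
interaction network in particular), and harmonizing symbols is deliberately
left to the user.

## Overlap accounting

For a focal set $F$ and other disease sets $S_1,\dots,S_m$,
`pairwise_overlap()` reports $|F\cap S_d|$ and `sharing_classes()` classifies
each $g \in F$ by $k(g)=\#\{d : g\in S_d\}$: unique ($k=0$), shared with at
most two others ($1\le k\le 2$), shared with more than two ($k\ge 3$). The
three classes partition $F$, which is asserted as an invariant. Whether the
focal set itself should count toward $k$ is genuinely ambiguous; we count
*other* diseases only — this is the reading under which the default
nine-disease design's classes (8/17/5 over 30 focal genes) form a partition —
and expose `include_focal` to flip it.

`deconfounded_pair()` produces the network stage's inputs
$A=F,\;B=S_d\setminus F$ and errors on $B=\emptyset$ rather than silently
testing nothing.

## Burden as a measure of purifying selection

Genes under purifying selection accumulate fewer deleterious variants per
coding base than genes whose loss is tolerated. The observation unit is the
**compound exon**: exon intervals of all isoforms of a gene, merged into
maximal disjoint blocks (0-based, half-open; touching blocks merge, so
duplicated isoforms can never change the model). For each block, the burden
is the count of deleterious variants divided by block length in bp.

*Deleterious* means: missense with allele frequency strictly below the
rarity cutoff, or loss of function (stop-gain, frameshift, canonical splice
donor/acceptor) at any frequency. Non-canonical splice-region annotations
fall in `other` and are excluded — a closed vocabulary keeps the classifier
testable. The rarity cutoff is not dictated by any principle stronger than
convention; the default is 0.01 against the variant table's own AF column
and it is an explicit argument everywhere.

Set-level comparison pools per-exon burdens across all genes of the set
(`set_burden()`, the default) and applies a two-sided two-sample K-S test
against the tolerated-LOF reference pool, with the asymptotic p-value at
effective size $n_an_b/(n_a+n_b)$. Pooling per exon weights long multi-exon
genes more heavily; `per_gene = TRUE` offers gene-level mean burdens
instead. Burden values are counts over lengths, so ties occur; the
asymptotic p is then approximate (slightly conservative), which the
calibration experiment below quantifies.

## Percentile expression profiling

Both expression analyses use one convention, pinned for reproducibility:
the linear-interpolation percentile at index $(q/100)(n-1)$ of the sorted
values (R's quantile type 7), with $q = 75$ by default.

**Transcripts.** A transcript is *highly expressed* when its mean FPKM
across population samples exceeds the genome-wide 75th percentile of
transcript mean FPKM. The summary per gene set is the mean number of highly
expressed transcripts per gene, reported next to the genome-wide mean.
Averaging across samples before thresholding is the simpler of two readings
of "expressed above the 75th percentile in the population"; `per_sample =
TRUE` implements the other (per-sample cutoffs, counts averaged after).

**Proteins.** For a gene-by-tissue spectral-count matrix the cutoff is the
75th percentile of the *pooled* gene-by-tissue values — one global cutoff,
not per tissue — because the quantity of interest is where a set's genes sit
relative to the whole dataset; `per_tissue_cutoff = TRUE` provides the
per-tissue alternative. Per tissue we report the mean spectral count over
set genes and the *ratio* of set genes above the cutoff. The
**hematopoietic fold** is the mean ratio over hematopoietic columns divided
by the mean over all other columns; it is `Inf` when only hematopoietic
tissues carry signal and `NaN` (with a warning) when neither group does.
The per-tissue mean divides by all set genes present in the matrix, not by
the subset detected in that tissue; the alternative denominator would only
raise means in sparsely detected tissues.

Everything here is scale-equivariant: multiplying the matrix by any $c>0$
moves the cutoff with the data and changes no ratio or count (a property
test).

The ΔΔCT utility implements comparative-threshold-cycle arithmetic
($\Delta = CT_{target}-CT_{ref}$, $\Delta\Delta = \Delta -
\Delta_{calibrator}$, $RQ = 2^{-\Delta\Delta}$) for the qPCR follow-up
workflow; wet-lab processing itself is out of scope.

## Pathway enrichment

Pathways with fewer than 15 or more than 1000 genes (measured after
restriction to the background universe) are removed: tiny sets cannot reach
significance, huge sets are biologically vacuous. For a query $Q$ and
pathway $P$ in a universe of $N$ genes, the enrichment p-value is the
one-sided hypergeometric tail $P(X \ge |Q\cap P|)$ — over-representation
only. Benjamini–Hochberg adjustment runs within one disease's scan, not
across diseases jointly (each phenotype is its own family of hypotheses),
and the dual rule $p < 10^{-3}$ and $q < 0.01$ flags significance. Both the
query and every set are intersected with the declared universe first so the
2×2 margins stay consistent. Convergence is then the count of pathway names
significant for both the focal disease and each other disease.

## Seed-connectivity permutation test

The network is a simple undirected graph: self-loops and duplicate /
symmetric pairs are dropped at read time (and counted), so a gene pair
carries exactly one degree of connectivity. The statistic for disjoint sets
$A$, $B$ is the number of edges with one endpoint in each. Because some
genes are heavily studied and over-connected, significance comes from a
node-replacement null: each of $n_{perm}$ replicates redraws $|B|$ genes
uniformly without replacement from the declared background and recomputes
the statistic. Two choices here were ours to make and are exposed as flags:
draws are without replacement within a replicate
(`with_replacement = FALSE`), and the seed set is excluded from the pool
(`allow_seed_overlap = FALSE`) so a replacement set can never manufacture
overlap with the seeds. The background may legitimately contain genes absent
from the network — they contribute zero — mirroring a protein-coding
background larger than the interactome.

The empirical p-value is the add-one estimator $(r+1)/(n_{perm}+1)$, never
exactly zero. When $r=0$ the resolution limit $1/n_{perm}$ is reported as an
upper bound and used for the Bonferroni headline
$\min(1, n_{tests}/n_{perm})$ — with the design's 50,000 permutations and 8
comparisons, $1.6\times10^{-4}$. Candidate ranking counts, for each non-seed
gene, the seed genes it is directly adjacent to; ties break by higher total
degree, then lexicographically, so rankings are deterministic.

Internally the statistic uses the identity
$\mathrm{conn}(B)=\sum_{g\in B}\deg_A(g)$ with the seed-adjacency degrees
$\deg_A$ precomputed once, which makes 50,000 replicates a vector-sampling
exercise rather than a graph traversal.

## The synthetic emulators

The generators exist so every stage has a ground-truth recovery test; they
emulate the *structure* of the real inputs, not their biology.

* **Catalog**: a membership design — a table of (disease-pattern, count)
  rows — is realized exactly, then sets are filled to size with unique
  genes. A purely pairwise design cannot express the default scenario
  (the focal set's pairwise overlaps sum to 38 over only 22 shared genes),
  so patterns may span several diseases; the shipped design uses 5 genes in
  three other diseases, 6 in two and 11 in one, whose column sums are the
  pairwise counts 11/8/5/5/4/4/1/0.
* **Exome**: per gene, 3–8 exons of 80–400 bp (plus a duplicated partial
  isoform to exercise merging); deleterious variants placed by a Poisson
  process per compound-exon bp at the group's rate — tolerated genes 0.02/bp,
  constrained genes 0.01/bp by default, i.e. a twofold depletion —
  with missense AFs drawn below the rarity cutoff from a scaled
  Beta(0.2, 5) (rare-skewed; only the rare/common split matters downstream)
  and LOF AFs unconstrained, plus synonymous and common-missense decoys for
  the classifier to reject.
* **Expression**: log-normal baselines (meanlog 1, sdlog 1); the focal
  genes' spectral counts are multiplied by a boost factor (default 3) in
  the hematopoietic columns of a 30-tissue layout (6 fetal, 18 adult, 6
  hematopoietic cell types); FPKM spans 45 population samples with 1–5
  transcripts per gene.
* **Gene sets**: uniform decoys of size 15–400 plus one planted pathway of
  50 genes containing half the designated query set.
* **Network**: Erdős–Rényi background ($n = 2000$, $p = 0.005$ in the
  default scenario); for planted disease pairs, the bipartite block between
  the two sets is wired at $p_{planted}$ *instead of* $p$ (so
  $p_{planted}=p$ is exactly Erdős–Rényi and the calibration experiment is
  honest), 0.05 in the default scenario.

Identical configurations write byte-identical files, and all files go
through the package's writers so reading them back exercises every reader.

What the emulators do **not** capture: linkage disequilibrium and locus
structure, real genome coordinates, mass-spectrometry missingness and noise,
correlated pathway membership, and the heavy-tailed degree distribution of
real interactomes (the null model is binomial, not scale-free). Passing
recovery tests therefore demonstrates correctness of the statistical
machinery under known truth, not robustness to every pathology of real
data — with one caveat worth naming: the permutation test's motivation
(study-bias in interaction data) is best probed on skewed-degree graphs,
and here it is validated for calibration on Erdős–Rényi nulls only.

## Numerical and degenerate-input choices

* Percentiles: quantile type 7, documented and tested against the hand
  formula.
* Intervals: BED convention (0-based half-open) for exons; variant
  positions 1-based; conversion happens once, at the assignment boundary
  ($start < pos \le end$).
* K-S: asymptotic p only; exact small-sample p is out of scope, but the D
  statistic is pinned against hand-enumerated ECDFs.
* Empty sets: empty burden samples, empty queries, degenerate deconfounded
  pairs and gene sets absent from matrices all raise informative errors
  rather than returning silent zeros.
* Fold with zero denominators: `Inf` when only the hematopoietic group has
  signal, `NaN` with a warning when neither group does.
* Readers hard-fail on malformed rows with line numbers by default
  (`strict = FALSE` downgrades to warn-and-skip); documented cleaning
  (duplicate collapse, self-loop/symmetric-pair removal) is counted, never
  silent.

## Experiment sizes used by the test suite

The stochastic properties are checked at desk scale, chosen to keep the
whole suite around a minute while leaving each check decisively powered:
K-S burden calibration within rejection band [0.02, 0.09] at
$\alpha=0.05$ (500 replicates; 0.066 observed) and power $\ge 80\%$ at the
twofold rate depletion with 100 genes per group and 5×200 bp exons (200
replicates; observed 100%); permutation type-I error within [0.02, 0.09]
on an Erdős–Rényi graph of 500 nodes at $p=0.02$ (200 replicates of 500
permutations) and power $\ge 90\%$ at five-fold planted bipartite density
(100 replicates of 2000 permutations; observed 100%); enrichment null scans
with permuted queries clean of dual-rule hits in $\ge 95$ of 100 runs;
hematopoietic fold $\ge 2$ in $\ge 95$ of 100 seeds at boost 3. Exact-value
oracles (interval bitmaps, edge scans, hypergeometric pmf summation,
step-up FDR, per-gene membership tallies) run on 100+ random small
instances each.

## Known limitations

* Symbol harmonization across sources is absent by design.
* The K-S p-value inherits the usual tie approximation for count-derived
  burdens.
* The enrichment model assumes genes are exchangeable within the universe;
  gene length, LD clustering and pathway overlap violate that in real data,
  which is why the thresholds are strict.
* `n_tests` for the Bonferroni correction defaults to the number of
  comparisons actually run in the session and must be set explicitly when a
  user runs comparisons one at a time.
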
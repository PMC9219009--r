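---
title: "Methods: GO network maps and target inference for auxin response factors"
author: "arfnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: GO network maps and target inference for auxin response factors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arfnet)
```

## The scientific problem

Transgenic expression of the *Agrobacterium rhizogenes* oncogene *rolB*
induces the hairy-root phenotype, and auxin response factors (ARFs) — the
transcription factors that bind auxin-responsive cis-elements (AuxREs) in
gene upstream regions — are prime candidates for mediating that effect.
`arfnet` packages the in-silico side of such a study as a reusable,
fully testable pipeline:

1. **Context mining** — find transcription factors annotated to a context of
   interest (e.g. "root") by keyword search over a GO annotation flat file,
   and take the intersection with a "transcription factor" keyword set.
2. **Family grouping** — cluster the candidate proteins with a
   neighbor-joining tree (p-distance on a supplied alignment, bootstrap
   support), then read off families from anchor taxa.
3. **Target inference** — call a gene a putative downstream target of a
   query ARF when it is (i) co-expressed with the query
   (Pearson r ≥ 0.7, p ≤ 0.05, top 20,000 partners per query) and (ii)
   carries at least one AuxRE motif occurrence in its 3000-bp upstream
   sequence.
4. **Enrichment network maps** — hypergeometric GO "biological process"
   enrichment of the target set with true-path propagation, assembled into
   a network of significant terms plus their ancestors, and compared across
   query sets by counting significant "root"-named nodes.
5. **Wet-data statistics** — ΔΔCt relative quantification of qPCR data with
   Mann–Whitney significance, and chi-square goodness of fit for transgene
   segregation ratios.

Every input format has a synthetic generator, so the full pipeline runs and
is verified offline.

## Models and statistics

### Motif scanning with exact p-values

A motif is a position-weight matrix $P$ (one row per position, columns
A,C,G,T, row-stochastic). A window $w_1 \dots w_k$ scores

$$s = \sum_j \log_2 \frac{P_j(w_j) + \varepsilon}{b(w_j)},$$

with pseudocount $\varepsilon = 0.01$ per cell (renormalized) and a 0-order
background $b$, by default the base composition of the scanned promoter set
(`"uniform"` and explicit vectors are available). The p-value of a score is
the exact tail probability of the score under $b$. To make that computable
at any width, scores are mapped to an integer grid — the widest position's
score range divided into 1000 bins — and the null distribution of the
integer score is built by exact column-wise convolution (dynamic
programming). Both hit classification and the reported p-value live on this
grid, so the p-value is the exact tail of the score actually used, not an
approximation; the raw log2-odds sum is reported alongside as the hit
score. Windows containing `N` are skipped. On the reverse strand the
reverse-complemented window is scored and reported at the forward
coordinate of its leftmost base (all coordinates are 0-based). The default
hit threshold is $p \le 10^{-4}$, the conventional default of
FIMO-style scanners; it is a parameter.

### Co-expression

From an expression matrix, Pearson correlation between query and candidate,
with the two-sided p-value from $t = r\sqrt{(m-2)/(1-r^2)}$ on $m-2$
degrees of freedom. The threshold on $r$ is signed (strong negative
correlation does not qualify a target), self-pairs and exact duplicates of
the query vector are excluded, and constant candidates are skipped with a
logged warning. A precomputed (gene, gene, r, p) table is accepted verbatim
for the case where the co-expression compendium is external; Spearman is
offered as a flag.

### Enrichment maps

Annotations are propagated by the true-path rule over both `is_a` and
`part_of` edges. For a study set of $k$ genes in a population of $N$, a
term annotating $n$ population genes and $x$ study genes scores

$$p = \sum_{i=x}^{\min(n,k)} \frac{\binom{n}{i}\binom{N-n}{k-i}}{\binom{N}{k}},$$

the hypergeometric upper tail. The population defaults to all genes with at
least one biological-process annotation after propagation — the standard
custom-reference choice when no reference list is stated — and is
configurable. Correction defaults to Benjamini–Hochberg with `"bonferroni"`
and `"none"` selectable; the map keeps terms with $q \le 0.05$ and adds
their ancestors as explicitly non-significant context nodes. Keyword node
counts consider significant nodes only: context ancestors are display
scaffolding, and counting them would make the comparison depend on DAG
depth rather than on enriched content.

### Neighbor joining

Saitou–Nei agglomeration on the Q criterion, exact on additive distance
matrices. Two deterministic choices: ties in Q are broken by the lowest
pair position in the current ordering, and negative branch lengths are
clamped to zero with the deficit moved to the sister edge, preserving the
pair's path length. Bootstrap support resamples alignment columns with
replacement and reports the percentage of replicate trees containing each
internal bipartition of the full-alignment tree. Family extraction is
anchor-based rather than cut-height-based: each unlabeled leaf takes the
label of the smallest bipartition side containing it and at least one
anchor, provided that side's anchors are of a single family — leaves whose
smallest anchored side mixes families are reported unassigned. Distances
are p-distances with pairwise gap deletion; model-based protein distances
are out of scope, as the grouping only needs coarse family structure.

### ΔΔCt

Technical replicates are averaged first; per biological replicate
$\Delta Ct = Ct_{target} - Ct_{reference}$, and
$\Delta\Delta Ct = \Delta Ct - \overline{\Delta Ct}_{calibrator}$ within
the same tissue. The reported fold change is $2^{-\overline{\Delta\Delta Ct}}$
— the geometric mean of the per-replicate fold changes — so the calibrator
line is exactly 1 by construction; the arithmetic mean of per-replicate
$2^{-\Delta\Delta Ct}$ would exceed 1 under noise (Jensen's inequality),
which is why the geometric form is used. The standard error and the
two-sided Mann–Whitney test against the calibrator operate on the
per-replicate fold changes. Amplification efficiency is assumed to be 2
(classic ΔΔCt); efficiency estimation from standard curves is out of
scope. Whether replicates should be compared per line or pooled across
lines is not a settled convention; the implementation compares each line's
biological replicates against the calibrator's within a tissue, which is
the finest grouping and the one the per-line significance stars of a
typical expression figure imply.

### Segregation

Observed resistant/sensitive counts against an expected ratio $a\!:\!b$ by
the uncorrected chi-square goodness-of-fit statistic on 1 df, compared with
the upper-0.05 critical value 3.84. No Yates continuity correction is
applied: the uncorrected statistic is what published segregation tables of
this kind report, and it is the one that reproduces such tables from their
counts.

## The synthetic-data module

The generators emulate the statistical structure each stage assumes,
with defaults fixed once as the package's study conditions:

* **Universe**: 120 genes, 40-term single-namespace DAG (average ~1.3
  parents per term, acyclic by construction), 20% of term names containing
  "root". The planted term is the last-generated term — a leaf, so its
  annotation signal stays local instead of being inflated by true-path
  propagation.
* **Co-expression**: 30 samples; a 20-gene block (query included) shares a
  latent factor giving pairwise correlation 0.9; all other genes are
  independent. 30 samples is typical of a small expression compendium and
  makes the sampling noise of $r$ visible but not dominant.
* **Promoters**: 3000 bp of i.i.d. bases at GC 0.40 (plant-like); block
  genes receive one consensus insertion of an 8-bp AuxRE-like PWM
  (core TGTCTC, 0.91 on the consensus base per position) at a uniform
  random offset on a random strand, with a truth sidecar of the planted
  positions.
* **Annotations**: Poisson(2) background terms per gene; block genes carry
  the planted root-named term at 18× the 5% background rate (≈0.9).
* **qPCR**: reference Ct ~ Normal(15, 0.1); target Ct = reference +
  baseline − log2 fold change + Normal(0, 0.1); technical noise
  Normal(0, 0.05) — per-replicate ΔCt noise ≈ 0.11, i.e. a clean assay; 5
  biological × 2 technical replicates; calibrator fold change 1.
* **Segregation**: resistant ~ Binomial(150, a/(a+b)).

Every generator is a pure function of (spec, seed); each draws from a seed
stream derived from the master seed by a stable label hash, so adding a
generator never changes another's output, and `simulate_dataset()` writes
byte-identical files on rerun.

What the generators deliberately do **not** emulate: real promoter
composition beyond 0-order GC content (no CpG/TA structure, no repeats),
annotation evidence-code structure, correlated annotation of related
terms, heavy-tailed expression noise, or amplification-efficiency drift in
qPCR. Passing the recovery tests therefore demonstrates that the
algorithms are correct and calibrated under their own model assumptions —
not that the thresholds are optimal for any particular real compendium.

## The end-to-end benchmark

`synthetic_root_contrast(seed)` runs the whole pipeline on a planted spec
and its matched null (`null_spec()`: block correlation 0, no motif
planting, no term planting, identical sizes) and returns the significant
"root"-keyword node count of each map. Under the defaults the planted run
recovers the planted term (and often further root-named terms annotated to
block genes) while the null's co-expression filter retains essentially
nothing, so the planted count strictly exceeds the null count in ≈100% of
seeded pairs — the synthetic analogue of comparing root-node content
across differently-behaving query sets. The verification suite requires at
least 95% over 100 pairs.

## Numerical choices and degenerate inputs

* PWM rows are renormalized on input; rows of all-equal counts become
  uniform; zero-weight rows are rejected.
* The score grid uses 1000 bins across the widest position range, keeping
  the discretized and raw scores within ~0.1% of each other at width ≤ 20
  while the DP stays a few-thousand-element convolution.
* `hypergeometric_test` evaluates the upper tail via `phyper` (log-space
  internally); the test suite checks it against a direct combinatorial sum
  for every small instance.
* Mann–Whitney switches from exact enumeration to the tie/continuity-
  corrected normal approximation when the pooled size exceeds 12 or ties
  are present; an all-tied input returns p = 1 directly (the corrected
  variance would be 0/0).
* Empty target sets build an empty map (not an error); promoter-less
  co-expressed genes are dropped with a logged tally; annotation records
  referencing unknown terms are logged and skipped; cyclic ontologies are
  rejected.
* Pipeline problem sizes in the shipped tests (120 genes, 40 terms, 100
  replicate pairs) were chosen so the complete verification runs on a
  single desktop core in a few minutes while every rate being tested has a
  tight enough Monte-Carlo error to be meaningful.

## Known limitations

* Keyword mining is substring-based (word-boundary matching is a flag); it
  inherits the imprecision of the method it reproduces — "root" also
  matches, e.g., "square root" should such a term name exist.
* The motif criterion is presence/absence; no per-gene FDR over motif hits
  is computed, matching the two-criterion target definition.
* NJ family grouping depends on anchor choice; with no anchors in a clade
  its leaves stay unassigned rather than being guessed.
* The enrichment population default (all annotated genes) changes p-values
  relative to tools that use a whole-genome reference; published node
  counts obtained with external annotation releases are therefore not
  reproducible quantities, and the package's verification rests on the
  synthetic benchmark instead.
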
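---
title: "Identifying tumor-matching CD8 T cells in blood and marker gates that enrich them"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying tumor-matching CD8 T cells in blood and marker gates that enrich them}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmcell)
```

## The problem

Anti-tumor CD8 T cells circulate in blood, but there is no single surface
marker that picks them out. When paired single-cell RNA + TCR sequencing is
available for a patient's blood and tumor, the TCR itself can serve as a
molecular barcode: a blood CD8 T cell whose full α/β clonotype is also found
among tumor-infiltrating CD8 T cells is called **tumor-matching (TM)**.
`tmcell` implements that matching definition end to end and then asks the
practical follow-up question: *which cell-surface transcripts — alone or as a
small boolean gate — enrich TM cells well enough to sort them by flow
cytometry?*

Because the TM label is derived from the TCR, every discriminative statistic
in the package is computed on cells for which the label is defined: cells
with at least one productive α and one β chain.

## Data model and preprocessing

A sample lives in a `tm_bundle`: a genes × cells sparse UMI count matrix, a
`normalized` layer (`log(1 + 10^4 · c / total)`, "log TP10K"), a `scaled`
layer (per-gene centered, unit variance, computed on the retained cells), a
per-cell metadata table (patient, blood/tumor compartment, external cluster
label), and optional TCR chain records. Blood and tumor cells of one subject
share a bundle.

QC follows the study design it emulates:

* structural filters at load time — genes in ≥ 3 cells, cells with ≥ 400
  expressed genes (the `min.features`-style parameter is applied as
  "at least");
* a housekeeping rule — a cell passes if it expresses strictly more than half
  of a housekeeping gene list;
* a mitochondrial rule — human cells are removed when they express more than
  500 of the 1,158 MitoCarta genes; mouse cells when their expressed
  mitochondrial gene count exceeds the across-cell mean by more than two SDs.
  The source description ("more than two SDs from the mean") does not state a
  direction; we filter **only the high side**, since high mitochondrial
  diversity flags damaged cells and removing low-mito cells would discard the
  healthiest ones. Note the mouse rule recomputes mean and SD on whatever
  cells it is given, so unlike the human rules it is not idempotent: it is a
  one-shot filter, not a fixed threshold.

CD8 cluster retention consumes externally computed cluster labels (this
package does not cluster): human clusters are kept when >30% of cells
co-express ≥2 of CD3E/CD3D/CD3G and either (CD8B or CD8A positive in >30%,
with FOXP3 and CD4 each <5%) or (MKI67 >70% with CD8A or CD8B >20%, for
proliferating clusters); mouse clusters require >30% any-CD3, >30%
Cd3e+Cd8a co-expression and <5% Foxp3. The human rule's middle clause is
grammatically ambiguous in its source; we read CD8B/CD8A as alternatives,
which is the reading under which the worked retention examples come out.

## Clonotype matching

A cell's clonotype key is the **set** of all its detected (chain, CDR3
amino-acid) pairs, deduplicated, sorted, and restricted to productive chains
by default (non-productive chains do not define antigen specificity; a flag
restores them, and another adds V/J segments to the key). Two cells share a
clone only if the sets are identical — a cell with chains {α1, β1} and one
with {α1, α2, β1} are *different* clones. Cells lacking either chain are
excluded. Blood cells are TM when their key occurs in tumor; tumor cells are
blood-matching when their key occurs in blood; for multi-resection subjects
the tumor keys are unioned first. The number of distinct TM keys in blood
always equals the number of distinct blood-matching keys in tumor.

An alternative labelling via TCR-similarity clustering (GLIPH2/iSMART output
tables, not the algorithms) is supported as a consensus: cells on which the
two algorithms agree keep the agreed label, disagreements become `conflicted`
and are dropped from downstream statistics.

Clonal expansion is the size of a cell's clone; TM vs non-TM expansion is
compared with the rank-sum test below, and blood–tumor clone sizes correlate
via Spearman on log10 sizes (the display convention is a log-log scatter;
the statistic is not named in the source, so the rank-based choice is ours).
Clone-collapsed pseudobulk sums raw counts over clone members and drops genes
under 1 count-per-million in the aggregate, as a pre-filter for external
differential-expression tooling.

## Signature scoring and group comparisons

`score_signature()` reproduces the binned-control scoring scheme: all genes
are ranked by their average log TP10K expression and cut into `n_bins = 25`
equal-size bins; each signature gene contributes `ctrl_size = 50` control
genes sampled (seeded, without replacement) from its own bin; the per-cell
score is the mean scaled expression of the signature minus that of the
control set. Two numerical choices matter: bins are built on the
*normalized* layer's gene means (binning on the scaled layer would be
degenerate — every gene's mean is ~0 after centering) while scores are read
from the *scaled* layer; and cells that will be compared must be merged into
one bundle before scaling, because scores are relative quantities. When a
bin is smaller than `ctrl_size` the whole bin serves as control, which makes
the draw deterministic regardless of seed.

Group comparisons use a Wilcoxon rank-sum with midranks and a tie-corrected
normal approximation, switching to exact enumeration when both groups have
≤ 10 observations; paired clone-level comparisons (the same clone's mean
score in blood vs tumor, restricted to clones seen in both) use the signed
rank test, exact by sign-flip enumeration up to 15 nonzero differences.
The thresholds 10 and 15 are our defaults, not source-specified.

## Marker statistics

**AUC grid.** For each gene and direction, 39 candidate thresholds are built:
every fifth percentile of the gene's expression (21 values, 0th–100th, linear
interpolation) plus 18 evenly spaced values strictly between min and max —
the interior points of a 20-point equipartition, there to cover heavily
skewed distributions. Duplicated thresholds are kept (the count stays 39;
duplicate ROC points are harmless under trapezoid integration). Cells above
(positive direction) or below (negation) a threshold are predicted TM; the
trivial points (0,0) and (1,1) are appended and the AUC is the trapezoid
integral over x-sorted points. On discrete counts this grid AUC tracks the
exact midrank AUC within 0.02; a positive-direction AUC below 0.5 flags a
candidate negation ("marker-low") gene.

**XL-mHG test.** Cells are ranked by decreasing expression (negated first for
the negation direction). For a cutoff depth *n*, let *b(n)* be the number of
TM cells in the top *n*; the cutoff's score is the hypergeometric upper-tail
probability of drawing ≥ *b(n)* TM cells in *n* draws from *N* cells of which
*K* are TM. Admissible cutoffs must (i) fall between distinct expression
values, (ii) be at most *L* = min(10·K, ⌊0.35·N⌋) deep — the study's
deliberately permissive cap — and (iii) hold at least ⌈X·K⌉ TM cells with
X = 0.15, which we read as a fraction of K (the source's X semantics are not
spelled out; a fraction matches the "default X parameter (0.15)" of the tool
it parameterizes). The statistic is the minimal score over admissible
cutoffs, and the exact p-value P(statistic ≤ observed) under uniform label
placement is computed by the standard O(N·K) lattice dynamic program that
counts label paths avoiding the rejection region, with periodic rescaling and
a log-space final ratio. Region membership uses a relative tolerance of
1e-9 so mathematically tied tail values land on the same side in both the
statistic and the p-value. The reported p is floored at the statistic
itself — P(S ≤ s) ≥ s holds exactly (the minimizing cutoff alone already
rejects with probability s) — which also guards against underflow for
extreme markers. The reported `cutoff_val` is the midpoint between the
expression values flanking the minimizing cutoff, as an absolute value
(negation thresholds are sign-flipped by convention), so that
"expression > cutoff" (positive) or "expression < cutoff" (negation)
reproduces the selected cell set exactly.

Per sample, every gene × direction pair receives a Benjamini–Hochberg
q-value (the source says only "multiple hypothesis test corrections"; BH is
our choice, applied within sample across genes × both directions). Consensus
ranking keeps markers with q < 0.05 in at least 4 samples, drops an exclusion
list (CD8A as lineage-defining; CCL4, CCL5, MIF as non-surface cytokines) and
ranks by descending mean AUC. Cross-species marker overlap is tested with an
upper-tail hypergeometric on a homolog-mapped universe (the universe size is
configurable; the source does not state the one behind its printed p-value).
Cross-sample similarity correlates per-gene AUCs for all sample pairs, with a
seeded coordinate swap (probability 0.5, seed 27) to avoid x-axis bias,
stratified into within- vs between-patient pairs.

## Boolean gates

A gate literal is `GENE^high` (expression strictly above a threshold) or
`GENE^low` (strictly below); literals combine with `&` and `|` ( `&` binds
tighter). At the universal threshold of 0.001 UMI — any value in (0,1) is
equivalent on count data — `^low` means "zero counts". Gates over up to four
literals are enumerated as all AND/OR expressions deduplicated by truth
table; this is exactly the set of nonconstant monotone boolean functions
(1, 4, 18, 166 for 1–4 literals), each represented canonically by its minimal
DNF. Evaluation reports sensitivity TP/(TP+FN), specificity TN/(TN+FP), and
the penalty

> penalty = √((1−sens)² + (1−spec)²) + |sens − spec|,

the Euclidean distance from the perfect corner plus a balance term. The
balance difference is taken as an *absolute* value: a signed difference would
reward specificity-heavy gates nonsensically. Pareto flags use weak
dominance with at least one strict improvement (points tied on both axes are
both optimal). One design point discovered by property testing: the raw
penalty minimum is **not** guaranteed to be pareto-optimal — the balance term
can prefer (0.5, 0.5) to its dominator (0.51, 0.5) — so `select_best_gate()`
first restricts to the frontier and then minimizes the penalty (ties: fewer
literals, then lexicographic string). A `pareto_only = FALSE` switch
recovers the raw rule; on realistic data the two coincide.

## Uncertainty

`bootstrap_ci()` resamples cells with replacement (same size, thresholds held
fixed) and reports the 2.5th–97.5th percentile interval of B = 10,000
recomputations (scale B down for exploratory runs). `permutation_p()` builds
the null by resampling cells *and* permuting TM labels within each resample
— the reading of "iteratively through each resample" we adopt — and reports
the one-sided upper-tail empirical p as count/B. A zero count is reported as
the bound "< 1/B" ("< 0.0001" at B = 10,000), never as p = 0; the count/B
convention (rather than (count+1)/(B+1)) exists precisely to reproduce that
reporting style. Resamples on which the statistic is undefined (a lost
class) are redrawn so exactly B valid iterations remain, with an error if
more than 10% of draws fail.

## The synthetic world

`simulate_paired_sample()` generates the paired structure every stage needs:

* clone sizes 1 + Geometric(p = 0.5) — many singletons, a tail of expanded
  clones, matching the qualitative clone-size distributions of 10x TCR runs;
* a planted fraction (default 0.1) of blood cells in clones also seeded into
  tumor; the sharing set is chosen greedily to hit the target cell count
  exactly, so the planted fraction is a statement, not a random variable —
  deviations in recovery tests then measure the pipeline, not the generator;
* negative-binomial counts (dispersion 0.5) on log-normal gene means
  (meanlog log 0.3, sdlog 1 — sparse background genes), with 2% extra
  dropout; four planted markers at |log2FC| = 1.5 on a baseline mean of 4
  (negation markers need a visible baseline to lose), two per direction,
  applied in TM blood cells;
* per-cell TCR records with CDR3s of 8–20 residues in the C...F convention;
  10% of *clones* carry a second α or β chain (clone-level, because a
  per-cell extra chain would split the cell off its clone and contradict the
  planted truth), and 10% of cells lose one chain and become unmatched.

The generator does not emulate gene–gene correlation, V(D)J biology,
batch effects, or compartment-specific library sizes; a green recovery test
therefore establishes correctness of the statistics, not robustness to those
real-data features. All randomness flows from one seed through fixed-stream
splitting, so outputs are byte-identical per seed.

`planted_gate_dataset()` plants a known monotone gate: each literal's pass
state is Bernoulli(0.5) per cell, marker counts realize the state exactly at
the 0.001 threshold, and TM labels are the gate value with a configurable
flip probability. At 5% noise the planted gate `M1^low & (M2^low | M3^low)`
is the analytic penalty optimum over all 166 four-literal gates with margin
0.065 over the runner-up (computable exactly from the 16 equiprobable
state rows); recovery tests use 6,000 cells so a single replicate resolves
that margin.

## Numerical and testing conventions

* Exact small-sample tests switch on at n ≤ 10 (rank-sum, per group) and
  n ≤ 15 (signed-rank); XL-mHG p-values are exact at every n by construction.
* Degenerate inputs: constant genes give AUC 0.5 (endpoint-only trapezoid)
  and an XL-mHG p of 1 (no admissible cutoff); zero-variance genes scale to
  all-zero rows; an SD of 0 disables the mouse mitochondrial rule.
* The test suite freezes expected values from independent oracles — full
  enumeration of label placements (XL-mHG), pair counting (AUC), truth-table
  enumeration of all 2^(2^m) boolean functions (gates), quadratic dominance
  scans (pareto) — and runs calibration/coverage simulations at reduced B
  (documented per test) to stay inside CI budgets.

## Limitations

The package consumes, rather than produces, cluster labels and TCR-similarity
clusters; exact matching is conservative for cells with partially recovered
chains; the marker tests treat cells as exchangeable and ignore clonal
pseudo-replication (the paired clone-level comparisons exist for that
reason); and the simulated world is deliberately simple, so headline numbers
from the original patient data are out of reach at desk scale — the
acceptance suite checks properties, not those numbers.
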
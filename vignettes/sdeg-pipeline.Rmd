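---
title: "Sex-dependent expression analysis: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sex-dependent expression analysis: models, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdegtools)
```

## The analysis problem

In dioecious plants such as garden asparagus, female and male flowers
both initiate tepals, pistils and stamens, but pistils cease development
in males and anthers degenerate in females. Bulk RNA-seq of dissected
floral organs from both sexes asks: which genes are expressed
sex-dependently in each organ and developmental stage, and which
functional categories (GO terms, metabolic pathways) are over- or
underrepresented among them? `sdegtools` implements the downstream
arithmetic of that question, starting from a gene-level fragment-count
matrix produced by any upstream mapper/counter.

## Expression model

FPKM is used as the normalized expression unit:

$$\mathrm{FPKM}_{gs} = \frac{c_{gs} \cdot 10^9}{L_g \cdot N_s}$$

with $c_{gs}$ the fragment count of gene $g$ in sample $s$, $L_g$ the
gene length in bp and $N_s$ the library size. **Design choice:** $N_s$
defaults to the column sum of the supplied counts rather than an
externally reported "mapped fragments" figure, which keeps the
computation self-contained and exactly reproducible from the count
matrix alone; `compute_fpkm(cm, library_size = ...)` accepts an override
when an external denominator is preferred. The defining identity
$\sum_g \mathrm{FPKM}_{gs} L_g N_s / 10^9 = \sum_g c_{gs}$ then holds to
floating-point tolerance and is asserted in the test suite at relative
tolerance $10^{-9}$.

## The SDEG rule

A gene is a *sex-dependently expressed gene* (SDEG) favoring sex X
within one (organ, stage) contrast when

* mean FPKM across X's replicates $> 5$, and
* mean FPKM in X $> 5 \times$ mean FPKM in the other sex,

both strict. Strictness follows the "higher than" wording of the rule:
a gene at exactly $5\times$ (e.g. 25 vs 5) is excluded. Only the
contrast's own samples are consulted. The rule is deliberately a
thresholded fold-change criterion, not a count-model test: no dispersion
estimation and no per-gene p-values are involved, so the package does
not wrap DESeq2/edgeR here.

**Replicate combination (open design point).** Replicates could be
averaged, required to pass individually, or pooled at the count level;
the published description does not say. We average FPKM per side before
thresholding — the least conservative stable choice — and expose both
thresholds as parameters (`fpkm_threshold`, `fold_threshold`, defaults
5 and 5) so the criterion itself never has to be edited.

Jaccard indices $|A \cap B| / |A \cup B|$ compare SDEG sets between
organs and stages; the empty/empty case is defined as 0 to keep heat
maps well-defined without special-casing.

## One-to-one homolog assignment

Queries are related to a reference proteome (e.g. Arabidopsis) from
BLASTX tabular hits. Hits with $E \ge 10^{-20}$ are discarded (strict
`<`, following the stated cutoff); the rest are ranked by ascending
E-value and scanned greedily, accepting a hit exactly when both its gene
and its protein are still free. **Design choices:** (i) "one-to-one by
lowest E-values" is read as this greedy sequential assignment, not a
globally optimal bipartite matching — it is deterministic, linear after
sorting, and at $E < 10^{-20}$ the difference from an optimal matching
is negligible; (ii) the tie-break chain (descending bit score, then
query ID, then subject ID) is our own addition purely for determinism,
since E-value ties among distinct hits are otherwise order-dependent.
Annotation transfer then gives each assigned gene exactly its protein's
term set; GO terms are used as flat labels with no graph propagation,
matching how downloaded association lists are structured.

## Enrichment test

For one SDEG set and one term, with $n$ the number of the set's genes
that are *valid* — FPKM $> 5$ in at least one sample and carrying at
least one annotation — and $k$ of those carrying the term, the statistic
is the cumulative binomial probability

$$P = \Pr(X \le k), \quad X \sim \mathrm{Binomial}(n, p_0),$$

where $p_0$ is the term's frequency among all valid genes. Low $P$
indicates underrepresentation; $P$ near 1, overrepresentation. Although
the procedure is traditionally called a "binomial approximation" (it
approximates sampling without replacement from the background by
independent draws), the binomial CDF itself is computed exactly via the
regularized incomplete beta function (`stats::pbinom`), stable to
$n \ge 10^5$ — no normal approximation is layered on top.

**Significance level.** Both one-sided p-values, $\Pr(X \le k)$ and
$\Pr(X \ge k)$ (computed as $1 - \Pr(X \le k-1)$; $\Pr(X \ge 0) = 1$),
for every set and every term of one annotation type are pooled into a
single family. The Benjamini–Hochberg step-up critical value at
$q = 0.01$ — the largest sorted $p_{(i)}$ with $p_{(i)} \le (i/m)q$, or
0 if none qualifies — becomes the single significance level $\alpha$
for that annotation type: underrepresented when $P < \alpha$,
overrepresented when $P > 1 - \alpha$. This mirrors analyses that quote
one FDR-modified $\alpha$ per annotation type. The exact family
composition behind any particular published $\alpha$ (whether both
tails, both annotation types, or all sets were pooled) is generally not
recoverable; pooling both tails within one annotation type is our
choice, applied consistently. Sets with $n = 0$ produce records with
`not_significant` calls and a warning rather than an error, so one
unannotated set cannot abort a run.

## Sample QC: correlation and clustering

Pearson correlations between samples are computed over **all** genes on
raw FPKM, while the clustering heat map first restricts to genes with
FPKM $> 100$ in at least one sample — the two displays deliberately use
different inputs, following the common convention of filtering only the
clustered view. Whether the FPKM > 100 filter should be per-sample
maximum or something else is not specified anywhere we could anchor it;
`filter_min_fpkm(mode = "any_sample")` is the default and
`"all_samples"` is available.

Clustering uses Manhattan ($L_1$) distances of $\log_{10}$(FPKM +
pseudocount) — pseudocount 1 by default so FPKM 0 maps to 0 — with
group-average (UPGMA) linkage for genes and Ward linkage for samples.
**Design choice:** Ward is implemented as `hclust`'s `ward.D2` (the
variant that squares the supplied distances in the update), the standard
modern reading of "Ward's method"; with Manhattan input this is a
generalized Ward criterion, as it is in any pipeline that feeds
non-Euclidean distances to Ward. Heat-map coloration uses per-gene
z-scores with the *uncorrected* (divisor $n$) SD — "normalized" is not
further specified in the sources this convention comes from, and the
z-score is the field default; constant rows map to all-zeros.

## Small utilities

* `relative_expression_ddct()`: $2^{-\Delta\Delta C_t}$ with
  amplification efficiency fixed at 2 (perfect doubling), the assumption
  of the comparative-Ct method; no efficiency correction is applied.
* `uncorrected_sd()`: divisor-$n$ standard deviation, the spread
  statistic quoted with means in stain-quantification and RT-PCR
  summaries.
* `integrated_density()`: Area × Mean Gray Value, the ImageJ "IntDen"
  proxy for nuclear DNA content; segmentation itself is out of scope.

## The synthetic-data generator

`sim_config()` + `write_fixture_bundle()` produce every file the
pipeline reads, with known ground truth, so the whole chain is testable
without downloads. What it emulates:

* the experimental design — by default 2 sexes × 3 floral organs × 2
  replicates at a postmeiotic stage, plus staged whole buds
  (premeiotic/meiotic/postmeiotic, both sexes) and speartips;
* negative-binomial counts with variance $\mu + \mu^2/\theta$
  ($\theta$ = `nb_dispersion`, default 10, a mid-range bulk RNA-seq
  overdispersion); library sizes uniform on 2–4 million fragments;
  per-gene baseline abundances log-uniform over 3.5 decades. No
  library-size or dispersion estimates are available to emulate from the
  motivating study, so these are chosen once as realistic bulk-RNA-seq
  scale values for testability, not fidelity;
* planted sex bias: in each two-sex (organ, stage) cell, 5 % of genes
  (disjoint across contrasts) get a multiplicative fold change drawn
  from 10–50 applied to the favored sex's mean in exactly that cell —
  above the 5-fold detection threshold by construction, so recovery
  measures the noise model, not the threshold;
* homology: an injective gene→protein truth for 60 % of genes; the hit
  table contains every true pair at $E < 10^{-20}$ plus two decoy hits
  per gene with E-values log-uniform on $[10^{-40}, 10^{-5}]$, so both
  the cutoff and the greedy ranking are exercised (decoys can and do
  beat true hits — recovery under the default decoy model is therefore
  deliberately imperfect, while weak-decoy settings recover ≥ 95 %);
* annotation: 40 terms per catalog at ~3 terms/protein background, with
  2 planted terms per contrast assigned to that contrast's biased
  proteins at probability 0.9.

What it does **not** emulate: reads, alignments or mapping artifacts;
organ-specific baseline expression programs (conditions differ only
through planted genes, which is what makes replicate-pairing claims
testable); GC/length biases; batch effects; correlated gene modules.
Passing tests therefore demonstrate correctness of the arithmetic and
recoverability of planted signal under NB noise — not performance on
real tissue transcriptomes.

## Numerical and degenerate-input choices

* Identical seeds reproduce byte-identical fixture bundles; the
  pipeline itself is deterministic, and the run manifest records input
  and output checksums so reruns can be verified bit-for-bit.
* Strict inequalities everywhere a threshold is worded "higher than" /
  "lower than" (FPKM floors, fold ratio, E-value cutoff, α comparisons).
* Jaccard(∅, ∅) = 0; zero-variance samples are an error in correlation
  (named in the message); a sample with zero total counts is an error in
  FPKM; a zero pseudocount with zeros present is an error in the log
  transform.
* Agglomeration determinism is inherited from `stats::hclust`; on
  continuous distances ties occur with probability 0, and the merge
  heights (the quantity we assert on) are permutation-invariant.

## Problem sizes used by the tests

The suite runs entirely on generated data: 300-gene, 8-sample bundles
for round-trips and recovery; a 40 × 4000 draw matrix for the NB moment
check; 500 random bipartite tables (≤ 50 genes/proteins) against an
independent greedy replay; exhaustive binomial enumeration to n = 12;
1000 random p-value families against a brute-force step-up search; 200
null-catalog enrichment replicates; 100 Ward clustering runs of a
150-gene, 8-sample design. These sizes were chosen so the planted
effects dominate sampling noise at the stated tolerances while the whole
suite stays fast.

## Known limitations

* FPKM is the only normalization offered; cross-sample comparability
  inherits FPKM's known limitations (no TPM/TMM alternatives).
* The SDEG rule has no error control per gene; it is a descriptive
  threshold, faithfully so.
* The greedy one-to-one map is not a reciprocal-best-hit or
  orthology-graph method and will happily assign a decoy when it has the
  lowest E-value.
* Enrichment treats terms as flat, independent labels: no GO hierarchy,
  no term-term correlation adjustment beyond the pooled BH level.
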
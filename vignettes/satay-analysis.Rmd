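---
title: "Comparative SATAY fitness analysis and lipidomic adaptation scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative SATAY fitness analysis and lipidomic adaptation scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(satayfit)
```

## The measurement model

SAturated Transposon Analysis in Yeast (SATAY) saturates a population
with millions of independent transposon insertions and lets selection
act over many growth cycles. After sequencing, each library is reduced
to a set of insertion sites: a genomic position, the number of
supporting reads (a proxy for the clone's abundance after selection),
and the library it came from. Genes that tolerate disruption accumulate
insertions; genes required for growth in the assayed condition are
depleted of them. The per-gene transposon count (number of distinct
insertion sites in the ORF) and read count are therefore fitness
readouts, and comparing them across libraries grown in different
conditions exposes *conditional* requirements — the central object of
this package.

`satayfit` consumes the standard interchange formats of that pipeline —
BED (one record per insertion, score = read count), WIG (per-position
read counts) and GFF3 annotation — and holds everything internally in a
single coordinate convention: 0-based, half-open. GFF3 (1-based
inclusive) and WIG (1-based) are converted at the boundary; BED is
taken as-is. A site at position $p$ belongs to gene $[s, e)$ iff
$s \le p < e$. Strand is recorded but ignored in gene assignment,
because transposon disruption is strand-agnostic. When annotation
intervals overlap, a site inside $k$ genes counts toward all $k$; we
chose this over fractional assignment because it keeps counts integral
and the affected gene pairs are rare and obvious downstream. Some
insertion-screen tools exclude a fraction of each ORF's termini, where
insertions may be tolerated; we count the full interval by default and
expose a `truncate_frac` parameter (default 0) for sensitivity
analysis. No repeat or pericentromeric masking is applied.

## Depth normalization

Libraries differ by orders of magnitude in sequencing depth, so counts
are normalized to the total number of transposons (or reads) mapped in
each library — including intergenic sites, which is why the totals are
carried alongside the gene matrix rather than recomputed from it:

$$v_{g\ell} = \frac{c_{g\ell} + a}{T_\ell + aG} \times 10^6$$

with $c_{g\ell}$ the count of gene $g$ in library $\ell$, $T_\ell$ the
library total, $G$ the number of genes and $a$ a pseudocount. The
default $a = 1$ raw count per gene per library keeps log fold changes
finite for genes with zero insertions and shrinks noise in low-coverage
genes. The estimator is exactly invariant to rescaling a library's
counts and totals only at $a = 0$; with $a > 0$ the invariance is
asymptotic in depth. Users comparing libraries of wildly different
depth who need the exact property can set `pseudocount = 0` (and must
then tolerate infinite fold changes at empty genes).

## Library-set comparisons (volcanoes)

A comparison is defined by a *test* set and a *reference* set of
libraries. Per gene, the fold change is the ratio of the mean
normalized count of the test set to that of the reference set, reported
as $\log_2$; the p-value is a two-sided Student's t-test with pooled
variance. Choices worth making explicit:

* **Pooled, not Welch.** The equal-variance form is the classical
  "Student's t-test"; Welch is available behind `welch = TRUE` for
  users worried about heteroscedastic sets.
* **Two-sided.** Both depletion (required genes) and enrichment
  (dispensable genes) are biologically meaningful in the same panel.
* **Degenerate inputs.** Sets with fewer than two libraries get an `NA`
  p-value — the fold change is still reported, as in single-library
  panels — and the classifier marks the gene `untestable` rather than
  dropping it. When both sets have zero variance the statistic is
  undefined; we report $p = 1$ if the means agree (nothing to detect)
  and `NA` otherwise.
* **No multiple-testing correction in the classifier.** Calls use raw
  p-value thresholds, matching common practice for these screens; a
  Benjamini–Hochberg FDR column (`bh_fdr`) is emitted alongside for
  users who prefer it.
* **Transposon counts are the default currency**; read counts are
  supported via `source = "reads"` since both readouts are standard.

Classification defaults are $p < 0.05$ with $\log_2\mathrm{FC} < -0.5$
for `required` and $\log_2\mathrm{FC} > 2$ for `dispensable`; both cuts
are caller-adjustable, since different screen designs use stricter
fold-change thresholds.

## Variable genes, clustering, co-essentiality

Genes that respond to *some* condition are found by ranking the sample
standard deviation of normalized transposon counts across libraries;
ties are broken lexicographically by gene id so results are
reproducible. Libraries are clustered with Ward's criterion
(`hclust`, method `ward.D`) on Euclidean distances over the raw
normalized counts — no feature scaling by default, with a
log2(x+1) flag for users who want variance stabilization. For display,
counts are transformed to $\log_2$ ratios against each gene's mean
across libraries, which centers every gene at zero without erasing the
magnitude of condition effects.

Co-essentiality profiling computes Pearson correlations between gene
profiles across libraries, restricted to a variable-gene subset
(default 500, the larger of the two sizes commonly used) to suppress
correlations driven by small, meaningless fluctuations. The
correlation matrix is clustered on $d = 1 - r$ — the standard
co-fitness distance — with Ward linkage, and the reordered matrix is
returned for clusterogram display. Genes with zero variance have
undefined correlations and are excluded from clustering with a
message, never silently.

## Lipidomics

Three computations accompany the genetic screen:

* **Fraction of total per lane** (`tlc_fractions`): each species'
  quantity over the lane sum, the standard TLC readout.
* **Saturation-pair remodeling** (`saturation_fractions`): membranes
  adapt to cold by shortening acyl chains and adding double bonds
  (homeoviscous adaptation). The readout compares, within each
  phospholipid class, 0- vs 1-double-bond species for lipids with ≤ 30
  total acyl carbons and 1- vs 2-double-bond species for ≥ 32 carbons;
  the summary is the intensity share of the more-unsaturated member.
  The two carbon-range pairs are pooled (intensity-weighted) by
  default so each class yields one number per sample — the only
  reading that produces a single per-class bar — with
  `pool_carbons = FALSE` for per-range fractions. Samples missing both
  pair members yield `NA`, not 0, to avoid biasing remodeling
  estimates. Group contrasts use two-sided two-sample Student's
  t-tests on replicate fractions, uncorrected across classes, matching
  the per-panel convention for such figures.
* **Isotope-labeling flux ratios** (`flux_ratios`): along the CDP-DAG
  route PS → PE → PC, the ¹⁵N-labeled product divided by its
  ¹⁵N-labeled precursor at each timepoint isolates
  conversion-plus-transport efficiency from absolute label uptake
  (which the labeled/unlabeled ratio reports instead). Because the
  chain is linear, all labeled pools scale proportionally with uptake
  and the precursor-normalized traces of two strains differing only in
  uptake are identical — the computational structure behind comparing
  genotypes this way. Raw intensities are used rather than mole
  fractions, which only rescales both numerator and denominator of
  each ratio. Zero denominators give `NA` at that timepoint.

Species nomenclature "CLASS C:D" (total acyl carbons : double bonds)
is parsed by `parse_species_name`; ether and odd-chain species fall
outside the comparison pairs.

## The synthetic-data generator

The generator exists so that every stage can be validated against
known truth without downloading a screen. It emulates:

* a gene-annotated genome with log-normal gene lengths (median
  ~1.4 kb, the yeast ORF scale) and exponential intergenic gaps
  (mean 400 bp);
* uniform insertion positions, with an insertion in gene $g$ surviving
  selection with probability $\min(1, d_g^{\,c/13})$, where $d_g$ is
  the per-gene retention multiplier (1 = neutral, 0 = lethal) and $c$
  the number of growth cycles — selection compounds exponentially over
  cycles, with the exponent normalized to the 13-cycle lower end of a
  typical screen so the published scale maps onto defaults;
* overdispersed reads per retained insertion,
  $1 + \mathrm{NB}(\text{size}=0.5, \mu=19)$, since PCR and
  sequencing jackpots are the norm;
* the 24-library design of a rewiring screen: 12 genotypes (PE
  synthesis targeted to ER/MIM/endosomes/LD × PC synthesis to
  ER/peroxisomes/mitochondrial matrix), each grown with the Kennedy
  pathway ON and OFF;
* a lipidome whose pair fractions shift by a programmed $\delta$ in
  the cold, with a mutant blunting factor $\beta$ and log-normal
  replicate noise, plus a closed-form labeled PS → PE → PC time
  course.

Defaults are desk-scale: $10^5$ insertions per library rather than the
$2\times10^6$–$1.5\times10^7$ of a real screen, 1,000 genes rather than
~6,600. These sizes keep the full validation suite — including 100
random-genome counting oracles, a 1,000-instance t-test oracle with a
100-instance exact permutation cross-check, the 24-library recovery
experiment, and ten-seed calibration loops — at a few minutes on one
CPU while leaving per-gene coverage (~70 insertions for a median gene)
high enough that effect sizes resemble the published regime. All draws
are fixed by a single seed, and per-library seeds are derived from it,
so outputs are byte-identical across reruns.

What the generator does **not** emulate — and hence what passing tests
cannot certify about real data: insertion-site sequence bias
(transposon hotspots; positions are uniform), partial-ORF tolerance at
gene termini, centromeric/repeat artifacts, batch effects between
library preparations, and mapping ambiguity. Recovery rates measured
on the simulation (sensitivity of conditional-essentiality calls,
module contiguity) are therefore best-case statements about the
statistics, not about a sequencing run.

## Numerical notes

* The pooled t-statistic is computed vectorized over genes; its
  p-values are checked in the test suite against `stats::t.test` (to
  $10^{-12}$) and, for rank behavior, against an exact-enumeration
  permutation test.
* `hclust` with `ward.D` on a zero-distance pair merges at height 0;
  duplicated libraries therefore pair first, which the tests assert.
* Top-$k$ selection and leaf orders are deterministic given the input
  (lexicographic tie-breaks; no RNG in any analysis routine — only
  simulators draw random numbers).
* Depth-invariance is exact at pseudocount 0 and holds to first order
  in $1/T_\ell$ otherwise (see above).

## Limitations

Single-library comparisons yield fold changes but no p-values — by
design, not limitation of the data structure. The co-essentiality
module assumes enough conditions (≥ 3 libraries, realistically ≥ 10)
for correlations to be meaningful. The saturation-pair readout ignores
species outside the two comparison windows, so classes dominated by
poly-unsaturated species are summarized by a minority of their signal.
GO-term enrichment of variable genes and genome-browser track
generation are deliberately out of scope; dendrograms, matrices and
tables are exported (Newick/TSV) for external tools instead.
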
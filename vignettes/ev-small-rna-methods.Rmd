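---
title: "Methods: small RNA profiling of plasma EV sequencing libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small RNA profiling of plasma EV sequencing libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evsmallrna)
```

## Scope and model of the data

Plasma extracellular vesicles (EVs) carry a mixture of small non-coding
RNAs — miRNAs, YRNA fragments (dominated by 5'-end fragments of hY4),
tRNA/rRNA/snRNA/snoRNA fragments and piRNAs — whose composition shifts in
lung adenocarcinoma and squamous-cell carcinoma relative to healthy
controls. Sequencing such material gives single-end reads in which a short
insert (17–45 nt) is followed by the 3' sequencing adapter and then
non-informative bases; a sizeable minority of reads are artifacts (missing
3' adapter, empty insert, 5'-adapter carry-over, low quality, sub-17-nt
inserts, homopolymer runs).

This package implements the complete desk side of such a study — read
filtering, annotation, miRNA quantification, and differential expression
between two pooled libraries — together with a generator of synthetic
libraries with per-read ground truth, so that every stage can be verified
exactly even though no real data ships with the package.

## Read filtering

Each read is assigned to exactly one category, in fixed precedence:

1. **3' adapter missing** — no exact occurrence of an adapter prefix with at
   least 6 nt overlap anywhere in the read;
2. **empty insert** — adapter starts at position 1;
3. **5' adapter contaminant** — the trimmed insert contains ≥ 10 consecutive
   bases of the 5' adapter;
4. **inferior quality** — mean Phred score of the insert below 20;
5. **too short** — insert under 17 nt;
6. **homopolymer** — a single base (or N) makes up ≥ 80% of the insert;
7. otherwise **clean**, and the trimmed insert enters the analysis.

Because every read receives exactly one label, the report's category counts
always sum to the total — the same conservation property a disjoint
filtering table relies on. The quality, homopolymer, and contaminant
thresholds are declared package defaults (configurable in
`filter_config()`), not inferences about any particular instrument: typical
small-RNA QC conventions, stated explicitly so that tests can be exact.
Adapter detection is exact-match with minimum overlap 6; overlapping
occurrences are searched (a zero-width lookahead), which matters when an
insert happens to end with a prefix of the adapter.

With the default 50-nt reads and ≥ 6 nt adapter overlap, a clean insert can
be at most 44 nt, so the 45-nt analysis ceiling can never be exceeded under
the defaults; `collapse_reads()` enforces the 17–45 nt contract regardless.

## Annotation by bounded-mismatch matching

Clean inserts are collapsed to unique tags with copy counts, then matched
against a catalog of mature small-RNA reference sequences on both strands
with at most 0–2 substitutions (`align_tags()`). The matcher is a
vectorized bounded-Hamming scan over the concatenated catalog — deliberate
design: the downstream analysis needs only class/feature assignment, so a
dictionary of mature references stands in for full-genome alignment. `N`
never matches on either side (conservative annotation). A tag is **unique**
exactly when a single location attains the minimal mismatch count; ties
make it multi-mapped, and only unique tags (plus unmatched "other" tags)
enter the composition, length-distribution and chromosome-abundance
summaries — mirroring analyses restricted to uniquely aligned reads. When
equally good hits span several classes, the class label follows a
configurable priority (default `miRNA > YRNA > tRNA > rRNA > snRNA >
snoRNA > piRNA`, miRNA first because miRNAs are the usual downstream
focus); the tag still counts as multi-mapped.

Abundances are reported as RPM — reads per million *clean* reads, so the
denominator is the library's clean total, not the mapped total.
Chromosome abundance bins each unique tag's copies at the genomic start of
its alignment (reference locus start + within-reference offset, 0-based
half-open BED convention); references without loci accumulate under
`unplaced`.

## miRNA quantification

Three rules, applied in order:

* **Confirmation** — a tag counts toward a mature miRNA only if it contains
  the entire mature sequence and differs from it in length by at most 4 nt
  (`confirm_tag()`; "within 4" read as ≤ 4, boundary unit-tested). A tag
  containing several matures is assigned to the longest (ties: smallest
  id) — a declared tie-break.
* **isomiR merging** — confirmed tags sharing the same 5' end of the same
  precursor with pairwise length discrepancy strictly below 3 nt (≤ 2) are
  one call; counts sum; the most abundant member represents the call
  (ties: lexicographically smallest sequence). The 5' end is positional:
  with a `mature_offset` metadata column the 5' start in precursor
  coordinates is `mature_offset` minus the mature's position inside the
  tag; without it, the grouping key keeps the mature id, so tags of
  different matures never merge. Within a 5'-anchor group the "pairwise
  ≤ 2 nt" requirement is resolved by deterministic greedy clustering from
  the shortest member.
* **Copy floor** — calls with fewer than 10 copies are dropped (sequencing
  error guard), applied after merging (the order is a declared choice; the
  alternative is not distinguishable from published descriptions).

## Differential expression without replicates

The study design this package targets compares one pooled library per
group, so no within-group variance is estimable. The package implements a
conditional exact test: counts are first equalized to the geometric-mean
library size with deterministic round-half-even scaling; conditional on the
equalized total $s = a' + b'$, each side is modeled as an independent
negative binomial with mean $s/2$ and dispersion $\varphi$, and the
two-sided p-value is the total conditional probability of all splits no
more probable than the observed one (the probability-mass criterion; ties
are included with a $1+10^{-12}$ relative guard, and the symmetric tie
$P(x) = P(s-x)$ is exact in floating point because probabilities are direct
`dnbinom` products). At $\varphi = 0$ the conditional law is
Binomial($s$, 1/2).

$\varphi$ is an explicit, documented parameter (default 0.1) — **not** an
estimate. With unreplicated pools the dispersion is unknowable from the
data, and all significance statements are conditional on the assumed
$\varphi$. The test agrees with edgeR's small-p exact test to machine
precision at equal library sizes, which the test suite uses as an
independent cross-check (the implementation itself never calls edgeR).

Significance requires all three of p < 0.05, Benjamini–Hochberg FDR < 0.05,
and |log2 fold change| ≥ 1. M/A values are computed on RPM with a 0.1
pseudo-count — the same smoothing constant the heatmap transform uses
(`log2(RPM + 0.1)` after dropping features below 1 RPM in every group);
reusing one constant everywhere is a declared simplification. Pearson
correlations between group RPM profiles default to raw RPM with a
log-transform switch, since either convention is common.

A note on power: at $\varphi = 0.1$ the dispersion term dominates the null
conditional variance for deep counts, so a true 4-fold change yields a
conditional z of only ≈ 2.7 *regardless of depth* — under multiplicity
correction such changes are essentially undetectable at that assumed
dispersion. The package's fold-change recovery study therefore pairs the
Poisson sampling model of its own generator with the matched $\varphi = 0$
test; the type-I calibration study uses negative-binomial pairs at
$\varphi = 0.1$ with the matching test dispersion. This is the honest
reading of an unreplicated design: power claims only make sense for a
stated dispersion.

## The synthetic-library generator

`simulate_library()` emulates the statistical structure of pooled EV
libraries:

* a class mixture over the catalog (default YRNA-dominated,
  adenocarcinoma-like: normalized weights ≈ 55% YRNA, 27% miRNA, with
  small rRNA/snRNA/snoRNA/piRNA/tRNA fractions);
* class-specific insert laws — miRNA inserts are full mature sequences
  (18–24 nt), YRNA/tRNA inserts are 5' fragments of 29–34 nt, with
  analogous ranges for the other classes — reproducing the characteristic
  bimodal insert-length profile;
* artifact reads at configurable rates (defaults ≈ 1.9% missing adapter,
  1.0% empty insert, 0.06% 5' contaminant, 0.5% low quality, 3.6% too
  short, 0.02% homopolymer — about 93% clean, typical of a well-behaved
  EV library);
* one integer seed drives all randomness; the same seed reproduces a
  byte-identical FASTQ.

Artifact reads are **unambiguous by construction** (each is generated to
satisfy exactly its own rejection rule under the filter's precedence, e.g.
homopolymer reads do carry the 3' adapter so they reach the homopolymer
rule), which gives the filter tests an exact oracle; an `ambiguous` flag
disables those guards for robustness testing. Clean reads get all insert
bases at Q33–Q40; low-quality reads get insert means near Q10.

What the generator does *not* model: sequencing errors (substitutions or
indels), PCR duplication, 3' non-templated additions, and true genomic
multi-mapping structure. Passing recovery tests therefore demonstrates the
correctness of the bookkeeping and the statistics under the stated sampling
model — not robustness to instrument error profiles.

`simulate_two_group()` plants fold changes by multiplying per-reference
sampling weights in group B. Because each library has a fixed size, planted
changes renormalize all relative abundances (compositional data); the
ground truth therefore records the exact expected copies per group and the
realized log2 fold change, and recovery is always judged against those
recorded expectations. `simulate_count_pairs()` is the count-level
companion used for the calibration and power studies.

## Problem sizes and determinism

The shipped studies use library sizes of 5 000–100 000 reads, catalogs of
~70 references, and 2 000-feature count studies — sizes chosen so the whole
verification suite reruns in minutes on a single core while keeping
binomial sampling error well below the tested tolerances (e.g. class
fractions are checked within 3 binomial standard deviations). All pipeline
outputs are plain TSV with fixed formatting, and a manifest records every
parameter affecting output; identical inputs and seed give byte-identical
files.

## Known limitations

* The matcher searches mature references, not a genome: intergenic or
  precursor-only alignments are invisible, and "unique" means unique within
  the catalog.
* Only substitutions are modeled (0–2); indel isomiRs will not align.
* The dispersion of the exact test is assumed, not estimated; conclusions
  are conditional on it.
* qRT-PCR support covers 2^-ΔCt with an internal control and two-group
  t tests (Student/Welch, optionally F-test-selected), not efficiency
  correction or multi-calibrator ΔΔCt designs.
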
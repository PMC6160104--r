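---
title: "Methods: CNV population genetics from SNP-array signal data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CNV population genetics from SNP-array signal data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvpop)
```

This vignette documents the models, conventions and design choices
behind `cnvpop`. The package analyses copy number variants (CNVs)
called from high-density SNP-array intensity data across populations:
it does not call CNVs itself (callers such as PennCNV do that from the
LRR/BAF signal); it takes per-sample call tables plus the signal
matrices and answers population-level questions.

## Coordinates and core conventions

All in-memory intervals are **1-based inclusive**; `[a, b]` and
`[c, d]` overlap iff `a ≤ d` and `c ≤ b`. Two consequences worth
stating explicitly:

* Book-ended inclusive intervals such as `[100, 200]` and `[200, 300]`
  share one bp and therefore merge; `[100, 200]` and `[201, 300]`
  share zero bp and do not. (This differs from BED-style 0-based
  half-open adjacency.) Only the BED export converts to 0-based
  half-open; the conversion is exactly invertible and a sidecar TSV
  keeps the 1-based coordinates for lossless round-trips.
* Region length is defined as `end − start` bp, the convention under
  which the published region tables this pipeline is modeled on are
  internally consistent (their printed lengths equal end − start, not
  end − start + 1).

Total copy number (tcn) is coded 0 (two-copy deletion), 1 (one-copy
deletion), 2 (neutral — never a call), 3 (single duplication),
4 (double duplication).

## Sample quality control

Four per-sample metrics, applied as a cascade in the order
call rate → DLRS → wave factor → LRR SD; a sample is excluded with the
*first* rule it fails:

| metric | definition | default rule |
|---|---|---|
| call rate | fraction of probes with non-missing LRR | ≥ 0.98 |
| DLRS | SD (n−1) of adjacent-probe LRR differences, pooled within chromosomes, ÷ √2 | ≤ cohort mean + 3 SD |
| wave factor | Pearson correlation of LRR with probe GC fraction | \|r\| ≤ 0.10 |
| LRR SD | genome-wide SD of LRR | < 0.30 |

Call rate and the LRR SD bound are fixed conventional array-QC
cutoffs; no published cutoffs exist for DLRS or waviness in this
setting, so the DLRS rule is cohort-relative (mean + 3 SD, or a fixed
`dlrs_max`) and the wave bound is a conventional 0.10. All four are
configurable via `qc_thresholds()`.

DLRS divides by √2 because the difference of two i.i.d. noise values
has twice their variance; for i.i.d. Gaussian noise of SD σ the
metric recovers σ (the suite checks 5% accuracy at 10,000 probes)
while remaining insensitive to slowly varying CNV signal and to any
constant shift. Note one subtlety: the cascade is idempotent for fixed
cutoffs (re-filtering the kept set excludes nobody), but the
cohort-relative DLRS rule recomputes its cutoff on whatever cohort it
is given, so idempotence is only guaranteed with `dlrs_max` set.

## CNV regions

CNVRs are the connected components of the ≥ 1 bp overlap graph of
calls within a chromosome (transitive closure), with the union extent
as the region span — `bedtools merge` semantics on inclusive
coordinates. The implementation rides on `IRanges::reduce()` with
`min.gapwidth = 0`; the test suite holds it to a quadratic union-find
oracle on random interval sets up to 1,000 calls.

States: *gain* if every member call has tcn > 2, *loss* if every
member has tcn < 2, *complex* otherwise. Length classes are half-open
`[1, 10)`, `[10, 100)`, `[100, ∞)` kb; sub-kb regions are kept in the
first class and counted separately rather than dropped. Frequency
classes partition carrier counts as 1 / 2–4 / 5–15 / ≥ 16, counting
distinct individuals (a subject contributing several adjacent calls
to one region counts once). Genome coverage is Σ region length over
Σ autosome length, which requires an explicit chromosome-size table.

## Cross-population comparison

The counting unit is **focal-set regions**: a region of population A
is shared with B iff ≥ 1 region of B overlaps it by ≥ 1 bp. Counts
are directional (|A shared with B| ≠ |B shared with A| in general)
and both directions are reported, as are shared-length totals and the
per-focal-population Venn cells (which always sum to that
population's region count).

## CNV matrices

Two encodings of the individuals × CNVR matrix: presence/absence
({0,1}) and total copy number ({0..4}, 2 = absent), linked by
`presence == (copy_number != 2)` cell-wise. When one sample has
several calls overlapping one (complex) region, the copy-number code
is resolved deterministically: most covered bp in the region wins,
then larger |tcn − 2|, then the deletion. The rule is a package
choice — any deterministic rule would do for the analyses downstream —
and favors the call with the most evidence inside the region.

The within-population carrier filter (default: ≥ 5 carriers in
*every* population, boundary inclusive) mirrors standard practice for
cross-population CNV analyses: a region too rare in either population
carries no frequency information for that pair. Note its flip side,
visible in the demo: a region *strongly* differentiated downward
(common in one breed, near-absent in the other) is excluded by the
same filter, so the scan addresses frequency shifts among shared
polymorphic regions, not presence/absence fixation.

## Structure summaries

PCA centers columns without scaling and decomposes the centered
matrix by SVD; variance fractions are eigenvalue ratios. On integer
codings this is the natural choice (scaling would inflate rare
regions). A distance-based alternative (`cnv_pcoa()`, classical MDS)
is provided; on Euclidean distances it reproduces the PCA coordinates
up to axis sign, and it is the route to non-Euclidean (Jaccard)
distances.

UPGMA is implemented directly: merge the pair of clusters with the
smallest size-weighted average inter-cluster distance, at ultrametric
node height = distance / 2; ties break deterministically by the
lexicographically smallest pair of cluster representatives (a cluster
is represented by its smallest member label). The suite checks a
hand-worked 3-taxon example, exact recovery of ultrametric inputs,
and topology/height agreement with an independent average-linkage
implementation (phangorn).

Bootstrap support resamples matrix columns (regions) with
replacement; BP of an internal node is the fraction of replicate
UPGMA trees containing the same sample clade. Columns are sorted by
region id before resampling so BP is invariant to input column order
under the same seed. Ordinary BP is reported, not multiscale-bootstrap
AU p-values — AU machinery buys little for cohort-scale sanity checks
and would add a heavy dependency surface.

## The V_ST statistic

At one probe, with n₁, n₂ non-missing LRR values per population,

$$V_{ST} = \frac{V_T - V_S}{V_T}, \qquad
  V_S = \frac{n_1 V_1 + n_2 V_2}{n_1 + n_2},$$

with V_T the pooled variance and all variances divide-by-n
(population) variances. This choice is not cosmetic: with population
variances the law of total variance is exact, so V_T ≥ V_S always,
V_ST is non-negative by construction, and two populations holding the
same multiset of values give exactly 0. (With n−1 variances, small
samples can produce negative values; the raw value is retained as an
attribute and clamped to [0, 1] either way.) V_T = 0 (all values
identical) returns 0. Per-SNP values over the probes inside a
region's closed interval are averaged into the region's mean V_ST;
probes where either population has < 2 non-missing values are skipped
and counted.

Two thresholding rules are implemented and both thresholds are always
reported: `top5pct` (≥ 95th percentile of scanned mean V_ST values)
and `mean2sd` (> mean + 2 SD, strict). `mean2sd` is the default for
region-table-style reporting. A quantile over < 20 regions is
unstable, and the scan warns in that case when `top5pct` is selected.
One structural caveat on `mean2sd`: among k scanned regions a single
outlier's z-score cannot exceed (k−1)/√k, so with k ≤ 6 no single
region can ever be flagged — scans need a reasonable background count
before the rule has power.

The suite verifies the analytic limits (identical populations → 0,
disjoint constant signals → 1), shift/label invariance, the
equal-size identity V_S = (V₁+V₂)/2, agreement with brute-force
variance arithmetic, and monotone recovery: mean V_ST rises strictly
with the between-population carrier-frequency gap over gaps
0 / 0.3 / 0.6 / 0.9 on a seeded 2 × 50-sample synthetic cohort.

## The synthetic cohort generator

`generate_cohort()` emulates the signal layer of a multi-breed
SNP-array study: equally spaced probes per chromosome with GC
fractions Uniform(0.3, 0.7); CNV templates (interval, tcn, per-breed
carrier frequency) carried independently per sample; probe LRR drawn
Normal(mean[tcn], σ) with conventional state means
{0: −3.5, 1: −0.66, 2: 0, 3: +0.40, 4: +0.68}; an optional
GC-correlated wave term `amplitude · (gc − mean gc)`; per-sample call
rates drawn from a configurable range with the complement set
missing; truth calls recorded at exact template bounds. BAF, when
enabled, is a state-dependent mixture over canonical allele ratios
with 0.03 jitter — it exercises I/O only, no statistic consumes it.
Each sample uses an RNG substream seeded `seed + sample index`, so
enlarging a cohort never perturbs existing samples and everything is
byte-reproducible from the master seed.

Default demo conditions: 3 breeds × 25 samples, 3 chromosomes × 5 Mb,
500 probes per chromosome, LRR σ = 0.15, templates covering ~3% of
the toy genome. The coverage fraction matters more than probe count:
genome-wide LRR SD picks up a carried deletion in proportion to the
*fraction* of probes it covers, so a toy genome whose templates cover
tens of percent would push ordinary carriers past the 0.30 QC bound —
an artifact real 777k-probe genomes (CNVRs ≈ 2–3% of the assembly) do
not show. The demo therefore keeps template coverage at the
few-percent scale of real assemblies.

What the generator does **not** emulate — and what passing tests
therefore do not establish about real data: linkage disequilibrium
and correlated noise between probes, GC waves beyond a linear term,
boundary uncertainty of real caller output (truth calls have exact
template bounds), batch effects, and any BAF-driven calling signal.
The suites demonstrate correctness of the downstream statistics under
a controlled signal model, not caller accuracy.

## Degenerate inputs and numerical details

* Empty call tables produce empty (schema-complete) region tables;
  empty region sets export a header-only BED.
* Missing signal values are excluded pairwise from every variance;
  nothing is imputed.
* DLRS with no chromosome holding ≥ 2 non-missing probes, wave factor
  with constant GC, PCA on a constant matrix, V_ST with < 2 values in
  a population, and regions covering no probe all raise informative
  errors rather than returning NaN.
* A single-sample cohort cannot compute the cohort-relative DLRS
  cutoff; the rule degrades to "no DLRS exclusion".
* All stage outputs are plain TSV/BED/JSON/Newick without timestamps,
  so pipeline reruns under the same config and seed are
  byte-identical (checked by checksum in the suite).

## Problem sizes used by the test and acceptance suites

Oracle-backed suites run at deliberately modest sizes: merge
equivalence on 500–1,000 random intervals against a quadratic oracle;
DLRS recovery on 10,000 probes; V_ST recovery on 2 × 50-sample
cohorts (200 probes); a 101-template null-distribution check at 4,000
probes × 100 samples; bootstrap support with 200 replicates over
24 samples × 40 regions; the demo pipeline at 75 samples × 1,500
probes. These sizes put every check within seconds while leaving the
binomial/Monte-Carlo tolerances (3 SD, 5%) comfortably tight.

## Known limitations

* CNV calling itself (HMM segmentation of LRR/BAF) is out of scope by
  design; truth or caller output tables are the input boundary.
* Admixture-style model-based clustering and GO/pathway enrichment
  are hand-off points: the matrix writer and gene lists are the
  integration artifacts.
* The carrier filter excludes presence/absence-fixed differentiated
  regions from the V_ST scan (see above); interpret scan output as
  differentiation among shared polymorphic CNVRs.
* V_ST on intensity data inherits LRR noise; regions covered by very
  few probes (1–2) give noisy means, and the per-region `n_snps` is
  reported so users can weigh them.
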
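---
title: "Methods: molecular profiling of Firehose-style cancer cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: molecular profiling of Firehose-style cancer cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncoprofiler)
```

# Scope and data model

`oncoprofiler` computes four families of molecular profiles from the flat
files that the Broad Firehose pipeline distributes per cancer cohort
("entity"): somatic mutation frequencies from level-2 MAF calls, relative
expression from level-3 RSEM matrices, differential methylation from
level-3 450k beta values, and copy-number category summaries from level-4
GISTIC2.0 thresholded output. Everything downstream consumes the containers
produced by the format readers, and every sample is identified by its TCGA
barcode.

Because Firehose files vary in detail across snapshots, the package pins one
concrete dialect per data type (documented on each reader) so that the
grammar is frozen and the round-trip tests can be bit-exact. Gene identity
is the HUGO symbol throughout; the numeric id from `SYMBOL|NUMID` RSEM rows
is kept as metadata and used only to disambiguate duplicated symbols.
Cross-data-type joins are by symbol. No genomic coordinates are consumed, so
no 0/1-based coordinate ambiguity can arise.

## Barcodes, sample keys, and pairing

A TCGA aliquot barcode (`TCGA-A1-A0SB-01A-11R-A144-07`) is decomposed into
project, tissue source site, participant, sample type + vial, and remainder.
Sample-type codes 1–9 are tumors, 10–19 normals. The package's unit of
identity is the *sample key* — participant id plus two-digit sample type —
so replicate vials and aliquots of one physical sample count once in every
denominator. Tumor/normal pairing joins each participant's tumor and normal
sample; when a participant carries several candidate keys the
lexicographically smallest is taken, which makes pairing deterministic
without reference to input order.

Missing-data policy differs by type on purpose: expression and copy-number
cells must be complete (a missing cell is a format error), whereas
methylation betas may be missing, because level-3 450k data legitimately
contains masked probes. A methylation cell whose probes are all missing
stays missing — it is never coerced to 0, which would read as a biological
"unmethylated".

## Probe aggregation

Level-3 methylation arrives per probe with gene and gene-group annotation
(`TSS1500`, `TSS200`, `5'UTR`, `1stExon`, `Body`, `3'UTR` — the six
Illumina 450k tokens). Probes are aggregated to (gene, region, sample) by
the mean over non-missing probe betas. Mean aggregation is our design
choice (the natural unweighted summary at this resolution); composite
annotations such as `Body;3'UTR` are split so the probe contributes to each
region it overlaps. Aggregation commutes with sample subsetting, which the
test suite checks as a property.

# Mutation profiling

For entity $e$ and gene $g$ the mutation frequency is

$$f_{g,e} = \frac{\#\{\text{distinct tumor sample keys with} \ge 1
\text{ qualifying record}\}}{\#\{\text{assayed tumor samples of } e\}}.$$

Two decisions matter here:

* **Denominator.** MAFs list only mutated samples, so the assayed cohort is
  not recoverable from the file alone. By default the denominator is the set
  of distinct tumor sample keys appearing anywhere in the entity's MAF;
  when the true assayed roster is known it can (and should) be supplied via
  `cohort_index(samples = ...)`. The synthetic generator records its roster
  in the truth sidecar precisely to exercise this override.
* **Variant classes.** All classes emitted by the calling pipeline are
  included by default — silent mutations too — with an exclusion option.
  Frameshift insertions and deletions stay separate in tables even where a
  figure groups them visually.

The class breakdown reports, per class, the slice proportion (share of all
mutation records of the gene; these sum to 1) and the sample percentage
(distinct mutated samples over the cohort). Classes with zero count are
omitted rather than drawn as empty slices.

# Relative expression

With only sparse normal tissue available in such cohorts, each tumor sample
is scored against the remaining tumor samples of its own entity
(leave-one-out). For sample $s$ with expression $x_s$:

$$z_s = \frac{x_s - \bar{x}_{-s}}{\mathrm{sd}(x_{-s})}, \qquad
\mathrm{fc}_s = \frac{x_s + \varepsilon}{\bar{x}_{-s} + \varepsilon},$$

where $\mathrm{sd}$ uses the $n-1$ denominator and $\varepsilon$ (default 1)
keeps all-zero references defined. Normal-tissue columns are excluded from
both the focal and the reference sets. Calls at threshold $t$ (default 2):
over-expressed if $z \ge t$ (fold change $\ge t$), under-expressed if
$z \le -t$ (fold change $\le 1/t$). The reciprocal under-expression cut for
fold changes is our choice: it is the symmetric rule on the ratio scale and
the least surprising counterpart of the z-score's sign symmetry.

Numerical choices:

* A reference with zero spread (e.g. an all-zero RSEM row) makes the
  z-score undefined; such scores are flagged *degenerate* and excluded from
  calls instead of becoming ±Inf. The degeneracy test is relative
  (variance below $10^{-12}$ of the centered second moment), so constant
  references are caught even in floating point.
* The leave-one-out statistics are computed from centered sums in $O(n)$
  per gene; a property test checks them against brute-force removal of the
  focal column.
* Scores are computed on the RSEM scale by default; `log2 = TRUE` applies
  $\log_2(x+1)$ first. Both conventions are common; the log scale is the
  right one when the data generating process is multiplicative (as in the
  bundled simulator).
* Box-plot summaries pin the quartile convention to linear interpolation
  (R's type 7) so they are bit-reproducible; whiskers extend to the most
  extreme observations within 1.5 IQR of the quartiles.

# Differential methylation

Within one entity, each (gene, region) is tested for a tumor–normal shift:

* **Paired mode** uses the two-sided Wilcoxon signed-rank test on
  tumor-minus-normal beta differences over participant-matched pairs. Zero
  differences are dropped before ranking. The exact null distribution is
  used for $n \le 25$ remaining differences without ties in $|d|$;
  otherwise the normal approximation with continuity and tie corrections.
  Fewer than 5 nonzero differences flags the row as underpowered (still
  computed); all-zero differences give $p = 1$ with a degenerate flag.
* **Unpaired mode** uses the two-sided rank-sum test of all tumor vs all
  normal samples of the entity — the only contrast consistent with
  "compared to normal controls". The exact null is used for
  $m + n \le 20$ without ties.

The branch points ($n \le 25$, $m+n \le 20$) keep exact computation where it
is cheap and switch to the corrected approximation where the exact
distribution is both expensive and unnecessary. Both exact branches are
validated against full enumeration oracles (all $2^n$ sign assignments; all
$\binom{m+n}{m}$ group assignments) in the test suite.

P-values are adjusted by the Benjamini–Hochberg step-up across **all
(gene, region) tests of one invocation** (one entity, one mode). The family
could also be defined per gene or per region; per-invocation is
reproducible, conservative relative to per-gene families, and matches how
the results are read (one results table per run). Rows with insufficient
data are reported with a missing p-value and excluded from the family
rather than silently dropped.

The delta-beta, $\Delta\beta = \overline{\beta}_{tumor} -
\overline{\beta}_{normal}$ (means, not medians — the simplest reading of a
"difference between tumor and control methylation"), quantifies the shift,
and its sign alone sets the direction (hyper/hypo): p-values carry no
directional information and are never used for it. Per-pair difference
histograms use fixed width-0.05 bins on $[-1, 1]$, left-closed, so a gene
that is hyper-methylated in some pairs and hypo-methylated in others shows
both flanks. The global methylation view is restricted to one entity per
invocation because the gene × region layout does not compose across
entities.

# Copy-number categories

GISTIC2.0 thresholded values are used as-is: −2 homozygous deletion, −1
heterozygous deletion, 0 normal, +1 low-level gain, +2 high-level
amplification; no re-thresholding of continuous segment means is offered.
Tallies run over tumor samples only (GISTIC matrices occasionally carry
normal-tissue columns). The global profile reports
$f_S = \sum_{c \in S} n_c / n$ for an alteration subset
$S \subseteq \{-2,-1,+1,+2\}$ — by default all four (any gain or loss);
requesting category 0 is an error since normal copy number is not an
alteration. $f_S$ is additive over disjoint subsets and monotone under
subset inclusion, both property-tested.

# The synthetic-cohort generator

`generate_cohort()` stands in for an external cohort download: it writes
all four dialects with one coherent barcode roster and a `truth.json`
sidecar recording every planted parameter and sampled value. The defaults
are the package's reference study conditions, chosen once:

* **60 participants, half with a matched normal** — 30 tumor/normal pairs,
  a typical order of magnitude for 450k normal availability in consortium
  cohorts and the design size at which the paired methylation analysis is
  validated.
* **Mutations**: per-gene per-sample Bernoulli with a realistic class mix
  (missense-dominated); a mutated sample occasionally (rate 0.15) carries a
  second record, exercising distinct-sample counting.
* **Expression**: log-normal (RSEM values are non-negative and
  right-skewed). Outliers are planted by *setting* the sample's log-value
  to `log-mean + offset × log-sd` rather than adding the offset to a noisy
  draw, so a "+4 sd" outlier sits at exactly four reference standard
  deviations and recovery at threshold 2 is a sharp, not a probabilistic,
  expectation.
* **Methylation**: betas from a Beta distribution with region-specific
  baseline mean and precision φ = 20 (beta sd ≈ 0.11 at baseline 0.45);
  the tumor arm is shifted by the planted delta and clipped to $[0,1]$,
  with clip counts recorded since clipping attenuates recoverable deltas.
  Two probes per (gene, region) and a 1% masking rate exercise aggregation
  and missingness.
* **Copy number**: categories drawn from a per-gene 5-probability simplex.
* The default gene panel plants one exemplar per analysis: a frequently
  mutated gene (rate 0.33), a rare one, a mutation-free control, a
  high-level-amplified gene (P(+2) = 0.30), a Body-hypermethylated gene
  (Δβ = +0.30) with an unshifted control, and an expression gene with
  three +4 sd outliers.

One RNG stream per file type is derived from the master seed, so adding or
regenerating one data type never perturbs the draws of another, and equal
spec + seed gives byte-identical files. `truth_check()` re-reads the files
through the package's own readers and verifies them against the sidecar
(exact for integers and categories, $10^{-9}$ relative for reals).

What the simulator does **not** emulate: mutational signatures and hotspot
structure, segment geometry behind GISTIC categories, probe-level chip
artifacts (Infinium I/II chemistry), batch effects, or clinical covariates.
Passing recovery tests therefore demonstrates that the estimators and tests
are correct under the stated sampling models — not that real cohorts meet
those models.

# Batch runs and figures

The command-line layer validates its configuration before touching any
output, writes tables first, renders every figure *from the written
tables*, and records a manifest with input/output MD5 checksums, option
values, versions and collected warnings. Plots being a pure function of
tables means deleting the images and re-rendering reproduces the same
underlying data, and two runs with identical configuration are comparable
checksum-for-checksum. The entity-centric vs gene-centric toggle of the
interactive original becomes a `--view` flag applied at the table level.

# Validation problem sizes

The shipped tests and the acceptance script use: 1,000 random p-value
families (lengths 1–200) against a hand-coded BH oracle; exhaustive
enumeration checks for all paired sizes $n \le 8$ and unpaired sizes
$m, n \le 5$; 200 seeded replicate cohorts at the default study conditions
for mutation/CNV interval coverage and paired-methylation power; 500
all-null tables of 60 features for the realized false-discovery
proportion; 50 random specs for file round-trips; and one
1,000-gene × 500-sample entity for the performance budget, on which each
analysis (read + compute) finishes in a few seconds on one CPU.

# Known limitations

* The MAF-derived cohort denominator over-estimates frequencies whenever
  unmutated samples never appear in the file; supply the assayed roster
  when you have it.
* Exact Wilcoxon p-values are not available under ties; the tie-corrected
  normal approximation is used there even at small $n$.
* Fold-change scoring with small reference means is dominated by the
  pseudocount; the z-score is the more stable default.
* Composite methylation annotations double-count a probe into each region
  it overlaps; regions are therefore not independent tests, which the
  per-invocation BH family absorbs but does not model.
* RNA-SeqV1/RPKM inputs, MAF re-annotation, probe-manifest lookups,
  survival/clinical data and recurrence significance (MutSig-style) are out
  of scope.
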
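---
title: "Calling low-frequency mtDNA heteroplasmies from barcoded read families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling low-frequency mtDNA heteroplasmies from barcoded read families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtstamp)
```

## The problem

Heteroplasmies — minor mtDNA alleles present in a small fraction of a cell's
thousands of mitochondrial genomes — are informative about somatic mutation
accumulation, ageing and disease, but calling them at variant allele
fractions (VAF) down to 0.5% pushes against the sequencing error floor.
`mtstamp` implements the analysis stack for a probe-capture design in which
every captured mtDNA molecule carries a unique molecular barcode: all reads
sharing a barcode (a *read family*) derive from one molecule, so merging
them suppresses sequencing and PCR errors, and true heteroplasmies can be
separated from noise, from nuclear mitochondrial segments (NUMTs) and from
contamination by explicit statistical filters.

The package covers: a circular reference model with coordinate conventions;
a synthetic read-family and cohort simulator providing ground truth; the
Bayesian consensus caller; the NUMT screen; the six-filter variant caller;
region/effect/pathogenicity annotation; and cohort incidence statistics.

## Coordinate conventions

Positions are 1-based inclusive ("m." notation) on a circular genome.
Because reads spanning the replication origin cannot align contiguously to
a linear reference, alignment uses a *shifted* frame in which the final
`shift_bp` bases (default 120) are copied to the front; `unshift_position()`
normalises shifted coordinates immediately at ingestion and everything
downstream is canonical. A consequence of tiling the shifted frame with
capture segments is that the `shift_bp` positions at the end of the circle
are represented twice (by the copied prefix and by the genome tail), so
their pileup depth is roughly doubled; this mirrors the intended behaviour
of the shifted-alignment convention.

The D-loop span is configurable and defaults to the conventional control
region m.16024–m.576 (wrapping the origin) in the bundled full-length
config; the three standard low-complexity stretches (m.302–m.316,
m.512–m.526, m.16184–m.16193) are masked during calling. The source
literature for this design does not print its exact D-loop boundaries, so
region-stratified counts can shift slightly under a different span — hence
the config file, not a constant.

Protein effects are translated with the vertebrate mitochondrial genetic
code (translation table 2), reverse-complementing light-strand genes and
completing incomplete terminal codons with A (polyadenylation convention).
We translate table 2 as-is (ATA = Met everywhere, ATT = Ile), the same
convention ANNOVAR-style annotation uses; alternative start codons are not
special-cased. Only single-nucleotide substitutions are modelled.

## The consensus model

For a pileup column within one family, the posterior probability of true
nucleotide $NT$ given reads $r_1..r_n$ is

$$p(NT \mid r_{1..n}) = \frac{\prod_i p(r_i \mid NT)\, p(NT)}
{\sum_{NT'} \prod_i p(r_i \mid NT')\, p(NT')}$$

with a uniform prior and the per-read likelihood determined by the base
alignment quality (BAQ):

$$p(r_i \mid NT) = \begin{cases} 1 - 10^{-BAQ/10} & r_i = NT \\
\tfrac{1}{3}\,10^{-BAQ/10} & r_i \neq NT \end{cases}$$

The consensus base is the posterior mode with quality
$-10\log_{10}(1-p_{max})$, rounded and clamped to phred 0–93 (the
ASCII-33..126 encodable range). Numerical choices:

* Products are computed in log space; the uniform prior cancels. The
  complement $1-p_{max}$ is obtained as `-expm1(s1 - logsumexp)`, which is
  stable when $p_{max}\to 1$.
* BAQ is floored at 2 before the likelihood so the match branch stays
  positive; BAQ 0/1 bases are effectively uninformative. (The raw formula,
  exposed by `base_likelihood()`, is degenerate at BAQ 0.)
* A posterior tie within $10^{-9}$ yields base `N` with quality 0; `N`
  bases are invisible to every downstream counter.
* Mate overlaps within a read pair are merged first, and the merged pair
  calls are then merged across pairs by the same rule
  (`order = "overlap_first"`). The alternative single-pass order
  (`"joint"`) differs only through rounding of intermediate qualities; the
  test suite asserts both orders agree at high BAQ. Consensus MAPQ is the
  maximum over the family's pairs.

## NUMT screening

A consensus read is flagged as a potential NUMT when its edit distance
(unit-cost Levenshtein, `utils::adist`) to any known NUMT sequence for its
segment is *strictly* lower than its distance to the sample's major
sequence, or when its reads were already NUMT-annotated upstream. Ties are
kept. `N` positions are excluded from all compared strings. Because reads
span their whole capture segment in this design, distances are global over
the shared span; semi-global alignment for truncated reads was considered
and not needed. The NUMT database is an input (FASTA/TSV); discovering
NUMTs from a nuclear genome is out of scope.

## The six variant filters

Consensus reads enter the pileup only with MAPQ ≥ 20, no NUMT flag, and no
mismatch excess versus the sample's major sequence (> 5 mismatches for
reads whose midpoint lies in the coding region, > 8 in the D-loop; the
major sequence is a per-site plurality iterated once so the screen uses the
final major). Bases need quality ≥ 30. A minor-allele call at VAF ≥ 0.5%
must then pass:

1. *depth composition* — ≥ 100× depth with ≥ 70% of covering bases at
   BAQ ≥ 30 (the fraction is computed before the base-quality cut, over
   reads passing the read-level screens; computing it after the cut would
   make the filter vacuous);
2. *low complexity* — site outside the masked intervals;
3. *minor count* — ≥ 5 minor alleles;
4. *log-likelihood score* — a phred-scaled binomial log10 likelihood ratio
   of the observed minor count under allele fraction `max(vaf, rate)`
   versus the error rate alone, required ≥ 5. The functional form of this
   score is not specified by the capture design's description; the binomial
   likelihood-ratio form is this package's documented choice, with the
   threshold kept at 5;
5. *duplicate concordance* — a two-sided Fisher exact test comparing minor
   fractions between duplicate-built and singleton-built consensus reads
   (P ≥ 10⁻⁴), VAF fold-change between the strata ≤ 5 (a zero VAF in a
   covered stratum counts as infinite and fails), and duplicate-stratum
   VAF ≥ 0.2%. Sidedness is not stated in the source description; two-sided
   is the conservative choice;
6. *exact Poisson error test* — the upper-tail probability of the minor
   count under Poisson(rate × depth), with the per-base error rate
   0.02% (2×10⁻⁴) and strict significance P < 0.01/16569, a Bonferroni
   over the full-length genome's sites. The alpha is kept as printed even
   for miniature genomes unless reconfigured, so that filter behaviour is
   comparable across genome sizes.

Samples with ≥ 11 called variants at known polymorphic coding sites are
flagged as likely cross-contaminated. Homoplasmic differences from the
reference are haplotype variants, not mutations: the minor allele is always
defined against the sample's own major sequence.

## What the simulator emulates — and what it does not

`simulate_families()` reproduces the statistical structure the caller
relies on: probe segments tiling the shifted genome (46 for the full-length
genome); one barcode per captured molecule with heteroplasmies assigned
per molecule at their VAF; a truncated-geometric duplicate structure,
`min(1 + Geom(p), 10)` pairs with `p` tuned so that P(≥ 2 pairs) equals the
duplicate rate (~50% by default, matching the design's reported duplicate
share); uniform per-segment depth with ±20% lognormal jitter (real
per-segment unevenness is unreported); per-base BAQ draws (default: mass
0.9 at 30 and 0.1 at 20, reflecting a BAQ-30-filtered library) with
miscalls at rate $10^{-BAQ/10}$ uniform over the other three bases; and
NUMT families drawn from supplied NUMT sequences carrying 2–10 fixed
differences. Reads span their whole segment (2×250 bp chemistry over short
capture products), so mate overlap is complete.

Not emulated: alignment and realignment errors, probe-arm mispriming and
chimeras, strand-specific damage, context-dependent error rates, and
quality mis-calibration. Passing spike-in tests therefore demonstrates the
statistical machinery under calibrated qualities, not robustness to
upstream artefacts — those are handled (or not) by the aligner and
recalibrator that produce the package's input.

Cohort simulation (`simulate_cohort()`) draws per-sample category counts
from Poisson means, optionally log-linear in age around a reference age of
45, and places mutations uniformly among category-compatible substitutions
outside masked intervals. The default design mirrors the studied cohort:
groups of 23/22/21 (control/premanifest/early-stage), ages in the low 30s
to late 50s, D-loop means near 3 per sample, coding means 1–1.7, and a
pathogenic fraction of non-synonymous mutations rising from 0.2 in controls
to 1 in early-stage disease — calibrated once to the reported group means
and not tuned thereafter.

## Cohort statistics

Group contrasts use the two-tailed homoscedastic (pooled-variance) Student
t-test; significant contrasts are followed up with age-adjusted logistic
regression (case ~ count + age) or multinomial logistic regression across
disease stages, reporting Wald odds ratios per unit count; age trends use a
log-linear Poisson regression (count ~ age) whose slope is per year of age.
Wald inference is used throughout because the source reporting style (OR
with p-value) does not state an inference method. No multiple-testing
correction is applied across categories; the Bonferroni correction lives
inside the caller's Poisson filter only. An external comparison cohort is
represented as just another group label on the cohort table.

## Problem sizes used in the checks

The test suite and the acceptance script run everything on the bundled
2,000-bp mini-genome (8 probe segments, shift 120 bp), which preserves all
structural features of the full-length setup — origin-wrapping D-loop,
genes on both strands, masked intervals, doubled coverage in the shifted
prefix — at a size where ultra-deep simulation is comfortable: spike-in
studies use 4000× unique depth with 20 heteroplasmies at VAF 1% (and
1000× at VAF 0.5% for the detectability boundary), NUMT screening is
checked on ~10⁴ families, consensus fidelity on >5×10⁵ merged bases, and
regression calibration on cohorts of 50–200 samples with 100–1000
replicates. The enumeration check of the consensus equations is exhaustive
over all columns of up to 4 reads with BAQ in {10, 20, 30, 40}.

## Known limitations

* Indels, phasing, haplogroup assignment and somatic/inherited
  classification are out of scope.
* Protein features that wrap the origin are rejected; none occur in the
  standard annotation.
* The log-likelihood score (filter 4) is a documented reconstruction; a
  different functional form with the same threshold could admit or reject
  borderline sites differently. Sensitivity to this choice is limited in
  practice because filters 3 and 6 dominate near the detection boundary.
* The published per-sample mutation dataset of the motivating study is not
  redistributable here, so the package's report generators are validated
  on synthetic cohorts; the acceptance suite flags that gap explicitly
  rather than skipping it.
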
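---
title: "Measuring base-editor off-target burden in trio WGS cohorts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring base-editor off-target burden in trio WGS cohorts: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnmtrio)
```

## The measurement problem

CRISPR base editors (cytosine editors such as BE4, adenine editors such as
ABE) chemically convert single bases without double-strand breaks.  Their
deaminase domains can, however, act outside the sgRNA-directed target,
scattering unintended single-nucleotide variants (SNVs) across the genome.
The cleanest in vivo readout of this genome-wide burden is a family-based
trio design: edit zygotes, sequence the founder animals *and their
parents* at high depth, and count the variants present in an offspring but
in neither parent — its *de novo* variants.  Comparing per-animal de novo
counts between edited groups and non-injected controls then separates
editor-induced mutations from the spontaneous germline background, and the
substitution spectrum (a cytosine deaminase should leave a C>T excess)
corroborates the mechanism.

`dnmtrio` implements everything downstream of variant calling for this
design: the multi-stage filtering cascade applied to jointly genotyped
multi-sample calls, parental subtraction with a complete per-variant
decision trace, coincidence of de novo SNVs with in-silico predicted
sgRNA off-target sites, mutational-spectrum tabulation, and the
nonparametric group statistics.  A synthetic cohort generator produces
complete, truth-annotated input bundles so each stage can be validated
end to end.

## The filtering cascade

Candidate variants flow through the following stages, in this order.  A
per-(variant, offspring) trace records each stage's outcome (`pass`,
`fail`, or not reached), so any call can be audited after the fact.

1. **Site-level hard filters.**  SNVs fail when a present annotation
   violates `QD < 2 || FS > 60 || MQ < 40 || MQRankSum < -12.5 ||
   ReadPosRankSum < -8 || SOR > 3`; simple indels use
   `QD < 2 || FS > 200 || ReadPosRankSum < -20 || SOR > 10`.  All
   inequalities are strict; *absent* annotations never fail.  Callers omit
   the rank-sum annotations at homozygous sites, so treating absence as
   failure would discard most 1/1 calls.
2. **Mask exclusion.**  Variants whose reference-spanned bases intersect
   the union of repeat masks and blacklist regions (BED, half-open
   0-based) are removed.  Multi-allelic records are split into bi-allelic
   ones — with per-alternate AD slices and genotype remapping — before any
   filtering, since every downstream threshold is per-allele.
3. **Sample-level filters.**  A call must be genotype 0/1 or 1/1, have
   depth `>= dp_min` (default 10) and `<= d + 3*sqrt(d)` where `d` is the
   average coverage (default 60X, cutoff ~83.2; depths strictly above it
   fail), and — for SNVs — an allele fraction
   `AD_alt / (AD_ref + AD_alt) >= 0.10`.  The AF condition applies to the
   SNV stream only; the indel stream is filtered on genotype and depth,
   matching the separate treatment of indels in this protocol.  A call
   whose AF or depth cannot be evaluated (missing AD or DP) fails the
   corresponding condition: unevaluable evidence is not allowed through.
4. **Indel proximity.**  SNVs within ±5 bp (inclusive) of an indel border
   in the same sample's surviving stream are removed as likely alignment
   artifacts.  Borders are defined as the first and last deleted REF base
   for a deletion, and the two flanking reference positions for an
   insertion — a symmetric, testable convention.
5. **Simple vs complex indels.**  Simple (small-variant caller) indels
   whose REF span intersects a complex indel carried by the same sample
   (from an SV caller, LUMPY/SVTyper style) are excluded; the complex
   record set used here is the carried, pre-quality-filter set, since this
   stage precedes complex-indel filtering.
6. **Complex-indel filtering.**  Carried complex indels are kept when
   QUAL ≥ 100, the sample's coverage does not exceed `d + 3*sqrt(d)`,
   SU (pieces of supporting evidence across samples) ≥ 5, and the interval
   is unmasked.
7. **Parental subtraction.**  A variant survives only if neither parent
   carries the same alternate allele at the same site (exact match on
   chrom, pos, ref, alt).  Matching is allele-level: a parent with a
   *different* alternate allele at the position does not subtract the
   child's variant.  A missing parental genotype does not subtract either
   — only alleles demonstrably present in a parent are removed — but such
   calls are flagged `parent_uncalled` in the trace for scrutiny.

Only stage 4 is order-sensitive (its indel set is the post-stage-3,
pre-subtraction stream); the trace records the stage order so this is
auditable.  Relaxing `af_min` or the SV quality threshold can only grow
the passing set; relaxing `dp_min` is *not* guaranteed monotone, because
additional surviving indels can remove nearby SNVs at stage 4.

## Off-target coincidence

Predicted sgRNA off-target sites (e.g. a CRISPOR export: chrom, half-open
interval over protospacer + PAM, mismatch count) are first filtered with
the same mask as the variants.  De novo SNVs whose position falls inside a
retained site are "coincident"; the module reports the numerator,
denominator and fraction explicitly.  Before counting, variants observed
in any non-edited animal (parent or control offspring) are excluded from
the accounting — an allele circulating in the colony cannot be a
consequence of editing.  We apply this exclusion strictly, to every
sample's set; since parental alleles are already gone after subtraction,
its practical effect is to restrict the accounting to alleles not seen in
controls.  Coincidence is positional, not allele-aware, because site
predictions carry no allele information.

## Group statistics

Per-animal de novo SNV (and, separately, indel) counts are compared with
a tie-corrected Kruskal–Wallis test across the three groups and pairwise
Wilcoxon rank-sum / Mann–Whitney U tests (the same test under two names;
implemented once).  The U statistic uses midranks.  The p-value is exact —
computed by full enumeration of rank assignments — when `n1 + n2 <= 12`
and there are no ties (an `exact` argument can force enumeration for
larger tie-free samples); otherwise a normal approximation with tie and
continuity correction is used, matching the conventions of
`stats::wilcox.test`.  Two-sided p-values double the smaller one-sided
tail, capped at 1.  No multiple-testing correction is applied to the three
pairwise comparisons by default (raw p-values are the convention for this
design); `p_adjust = "bonferroni"` is available for reuse.  Group
summaries are mean ± SD with min/max, and `summarize_groups()` also emits
boxplot tuples in the matching convention — center = mean, box = mean ±
SD, whiskers = min/max — as data, not images.

## The synthetic cohort generator

`cohort_spec()` fixes the study conditions; `simulate_cohort()` writes a
complete input bundle (multi-sample VCF, SV VCF, two mask BEDs, off-target
site table, pedigree, truth table, parameter echo), byte-identical for a
given spec and seed.  Defaults emulate the trio design this package
targets:

* **Cohort structure**: 1 sire + 8 dams; 13 control, 13 ABE and 9 BE4
  offspring (44 samples), each offspring linked to the sire and one dam.
* **Genome**: a 3 × 10 Mb toy genome.  All logic is coordinate-generic,
  so a desk-scale genome exercises it identically to mm10 at a fraction of
  the runtime; the default cohort still carries ~17,000 planted records.
* **Mask**: random intervals (exponential lengths, mean ~0.8 kb) covering
  45% of the genome — mouse-like repeat density — split randomly into a
  "repeats" and a "blacklist" file to exercise the multi-file union.
* **Inherited background**: 300 germline het SNVs + 30 indels per parent;
  each offspring inherits each parental het allele with probability 1/2.
* **De novo counts**: Poisson per mouse with group means 132 (control),
  119 (ABE) and 221 (BE4) SNVs and an equal 12 indels/mouse; a
  `dispersion` parameter switches to a negative binomial for
  over-dispersion experiments.  Poisson is the minimal model consistent
  with reporting only means and between-animal variation.
* **Spectra**: control/ABE use a germline-like background (collapsed
  weights C>A .08, C>G .07, C>T .40, T>A .07, T>C .28, T>G .10, split
  evenly between strands); BE4 is C>T-enriched with minor C>A/C>G
  (C>A .10, C>G .08, C>T .60, T>A .04, T>C .13, T>G .05), reflecting
  cytosine-deaminase chemistry.
* **Calls**: depths are Poisson(60) truncated into the passing range;
  het allele fractions are binomial around 0.5; 10% of edited-group de
  novo SNVs use a mosaic-like fraction near 0.25 (editing after the
  one-cell stage), which exercises the AF-filter boundary while still
  passing.
* **Off-target sites**: 1500 sites of 23 bp (protospacer + PAM), 5%
  deliberately inside the mask (these must be removed by site filtering);
  a fraction `q = 0.02` of each mouse's de novo SNVs is placed inside
  retained sites.  The general placement pool excludes padded site
  footprints, so the realized coincidence fraction is binomial around `q`
  rather than inflated by chance overlaps.
* **Complex deletions**: Poisson(0.8) passing deletions (50–500 bp) per
  BE4 mouse, mirroring the deletion phenotype of cytosine editing.
* **Distractors**: one variant per filter category per offspring
  (site hard filters for SNV and indel, mask, genotype, minimum depth,
  excess depth, allele fraction, indel proximity, simple-vs-complex
  overlap, complex SU), each constructed to violate *exactly* its intended
  predicate while passing all others, so the decision trace can be checked
  against the truth table filter by filter.

Placement uses rejection sampling with ≥ ~40 bp spacing between planted
windows, which guarantees that no passing SNV sits within the ±5 bp
proximity window of any unrelated indel and that no variant lands inside
a complex-deletion interval by accident.  Planted passing calls are drawn
from truncated distributions so that, by construction, the set of planted
"pass" variants is precisely the cascade's expected output — the basis of
the exact truth-recovery tests.

**What the generator does not emulate**: sequence context (no reference
FASTA; REF/ALT strings are synthetic), alignment and calling noise
(annotations for passing variants are drawn comfortably inside the
thresholds rather than near the decision boundary, except for the
distractors), linkage and recombination, shared polymorphism between
parents, and multi-allelic sites (exercised by hand-written fixtures
instead).  Passing tests therefore demonstrate the correctness of the
post-calling logic, not robustness to upstream calling artifacts.

## Numerical and degenerate-input choices

* Excess-depth cutoff `d + 3*sqrt(d)` is compared strictly (`dp` strictly
  above fails); AF is compared inclusively (`>= 0.10` passes).
* Half-open interval semantics everywhere BED/SV intervals appear: an
  indel abutting a complex-indel interval with zero shared bases is not
  an overlap; a site ending where the mask begins is retained.
* `coincidence()` with zero de novo SNVs reports the fraction as
  not-available (`NA`), never 0; with zero sites it reports 0.
* A fully tied Mann–Whitney input (zero rank variance) returns p = 1, as
  does a fully tied Kruskal–Wallis input (H = 0).
* A single-group cohort yields summaries only; tests are skipped with a
  warning.  Empty groups and empty samples are errors.
* VCF parsing validates the header and per-line column counts and names
  the offending line; chromosome names are normalized to the
  `chr`-prefixed convention on read.

## Problem sizes used in validation

The packaged tests validate the cascade against a joint single-pass
brute-force oracle on 500 randomized mini-cohorts, interval operations
against per-base oracles on 1000 random cases, the exact U test against
`wilcox.test` over *all* rank configurations up to `n1 + n2 = 12`
(~8000 cases), the type-I error of the pairwise test on 2000 null
replicates (13/13/9 animals drawn from one Poisson), and parameter
recovery (group means, BE4-vs-control significance, coincidence fraction)
on replicate default cohorts.  `scripts/acceptance.R` repeats the
parameter-recovery analysis from scratch over 10 seeded cohorts.  These
sizes keep a full validation run within a few minutes on a single core
while leaving the Monte-Carlo error of each check well below its decision
threshold.

## Known limitations

* `d` (average read depth) is a configuration input, not estimated from
  the VCF: called-sites-only depth averages are upward-biased, and the
  design value (sequencing coverage) is the right quantity.  Whether `d`
  should be per-sample or cohort-wide is left to the caller; the default
  uses one value for all samples.
* Variants are assumed allele-normalized (left-aligned) by the caller;
  the package does not re-normalize.
* Parental subtraction is exact-match; it does not protect against a
  parent's allele hidden by a local assembly difference or a missed call
  beyond the `parent_uncalled` flag.
* The coincidence module consumes site predictions as given; it does not
  score or re-derive them.
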
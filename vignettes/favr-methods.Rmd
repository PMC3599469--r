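---
title: "Comparator-signature filtering of rare SNVs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparator-signature filtering of rare SNVs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Rare-variant screens start from a candidate SNV list produced by a
conventional caller, which scores each sample against the reference in
isolation. Two classes of unwanted signal survive that step in large
numbers. *Systematic mapping artefacts* arise where reads from similar
sequence elsewhere in the genome mis-map; the same alternate base then
recurs at the same position across unrelated samples prepared with the same
chemistry and pipeline, at widely varying read fractions — but, tellingly,
essentially never at homozygous fractions. *Common variants* recur across
samples for the opposite reason: they are real. Under a rare-variant
disease model neither class is of interest, so a filter need not tell them
apart.

The comparator-signature filter (Rare and True Filter) formalises this.
For a candidate variant with alternate base $b$ at position $x$, and a
panel of $N$ comparator alignment files (unrelated samples, same chemistry
and processing, never the test sample or its relatives), define for
comparator $j$ the count $a_j$ of its reads carrying $b$ at $x$.
Comparator $j$ is *variant-like* when $a_j \ge t$. The variant is
discarded when

$$ 100 \cdot \frac{\#\{j : a_j \ge t\}}{N} \;\ge\; p $$

and kept otherwise. Both parameters are exposed; the reference settings
are $t = 1$, $p = 30$ and $N = 8$. With duplicates removed upstream and a
low-error chemistry, $t = 1$ ("any read") is usable because a recurrent
signature, not sequencing noise, is what the panel detects.

Two companions complete the suite. The *PE Bias Detector* addresses
imbalanced paired-end chemistries (e.g. SOLiD's 50- and 35-base mates):
the short mate is disproportionately artefact-prone, so a called variant
whose alternate support in the test sample's own alignments consists
exclusively of short-mate reads ($a \ge 1$ long-mate support $= 0$) is
discarded. The *Family Annotate Tool* adds, for each relative, the
alternate read count and depth at each candidate site, flagging relatives
with $a \ge t$ (default $t = 1$); because it reads alignments rather than
the relatives' call sets, it recovers shared variants that a rigid
genotype threshold would miss. Annotation never changes the variant count.

## Counting read evidence

All three tools share one evidence-counting routine
(`collect_pileup_evidence()`), so their semantics agree exactly:

* An observation is one aligned, non-gap read base at the locus. A read
  whose alignment places a deletion or reference skip across the locus
  contributes neither depth nor support.
* Unmapped, secondary and supplementary alignments are always excluded.
  Duplicate-flagged reads are excluded by default (duplicate removal is
  expected upstream; a duplicated artefact read must not count twice), and
  can be included via `quality_gates()`.
* The default gates apply no base- or mapping-quality cutoff, matching the
  "any read" semantics of the filter; both cutoffs are configurable.
* Mate classification defaults to *by length*, with the cutoff set to the
  longest read length observed at the locus: in a 50/35 chemistry a
  35-base read is short wherever any 50-base read is present. A fixed
  cutoff, or classification by mate ordinal (`first`/`second` of pair),
  can be chosen instead — chemistries fix which mate is short, but the
  by-length default needs no such knowledge. Unpaired reads are long-mate
  under every mode.

## Decisions where the design was open

* **Boundary of the percent rule.** Variants are kept while the
  variant-like percentage is strictly *below* the threshold; the boundary
  case is discarded. The comparison is done on integers
  (`count * 100 >= p * N`) so floating-point rounding can never flip it.
* **Denominator.** The percentage is over the full panel, including
  comparators with no coverage at the locus (they simply cannot be
  variant-like). A `covered_only` option restricts the denominator to
  covered comparators, which is stricter at poorly covered sites; a
  variant with zero covered comparators is then kept.
* **Exclusion matching.** Database exclusion tables vary in whether they
  record alleles; matching is per (chrom, pos, alt) when the table has
  alleles and per (chrom, pos) otherwise. VCF positions are 1-based
  throughout; BED intervals are converted from their 0-based half-open
  convention at the boundary (via `rtracklayer`).
* **Multi-allelic records** are decomposed into per-allele candidates and
  filtered independently; surviving alleles re-emit as separate records.
* **Zero-support variants in the PE filter** are kept: a variant with no
  observed alternate read is not "evident only in short reads". They are
  flagged `FAVR_PE=no_support_observed` for audit.
* **Annotation serialisation.** Family evidence lives in two INFO keys,
  `FAVR_FAM` (per-relative `sample:alt/depth`, lexicographic sample
  order) and `FAVR_FAM_N`; re-annotation overwrites rather than
  duplicates. Binned variants are written to a sibling VCF with a
  `FAVR_BIN` reason, never dropped silently.
* **Expected sharing between cousins.** First cousins share on average
  12.5% of their DNA. With per-cousin candidate counts $n_a$, $n_b$ and
  observed shared count $s$ (exact (chrom, pos, ref, alt) identity), the
  package uses $E = 0.125 \cdot (n_a + n_b)/2$ and reports $s/E$; the
  kinship coefficient and the aggregation (mean/min/max of the counts) are
  arguments, since the mean-of-counts baseline is an interpretation rather
  than a prescribed formula.
* **Sensitivity projection.** For each known SNV, files with alternate
  frequency $\ge 9\%$ among covered reads are "true carriers" and are
  excluded; if $\ge 30\%$ of the remaining files then show the allele in
  any read, the variant is a projected false negative. Files with zero
  depth cannot be carriers but do count among the remaining files by
  default (configurable); SNVs covered nowhere are excluded from the
  aggregate with a warning.

## The synthetic cohort generator

`simulate_cohort()` emulates the signal structure the filters target, on a
random reference with ungapped perfect-match paired-end reads, so that
pileup semantics rather than alignment are under test:

* `true_rare`: heterozygous variants (alt fraction 0.5) private to one
  carrier; with cousin pairs, each cousin's sites are shared with the
  other with probability 0.125.
* `shared_family`: sites carried by both members of a pair, the second at
  a configurable fraction (set it below the candidate-calling fraction to
  emulate a variant a rigid caller misses in the relative).
* `common`: heterozygous fractions (0.4–0.6) in a 40–80% share of samples.
* `artefact_mapping`: alt fractions 0.1–0.4 — bounded away from
  homozygosity, as recurrent artefact signals are — in a 50–90% share of
  samples. No quantitative artefact prevalence distribution is prescribed
  anywhere; these ranges are this package's assumptions, chosen so that
  artefacts recur broadly but sub-clonally, and they are all free
  parameters of `simulation_config()`.
* `artefact_pe`: as above but with alternate bases confined to short-mate
  reads of the test sample (and other prevalence-drawn carriers).

Planted read counts are the nearest integer to the target fraction times
the eligible depth (half rounds up, so counts do not depend on parity),
with at least one read for any designated carrier; a mate restriction is
honoured exactly, and a site whose restriction cannot be satisfied (no
short-mate read covers it) is relocated to a reserve position and logged.
Unrestricted planting always includes at least one long-mate read when one
covers the site, so planted genuine variants have mate-balanced support.
Candidate VCFs list every site meeting a permissive calling rule (default:
any alternate read), emulating a permissive upstream caller. An optional
read class carries a 2-base internal deletion to exercise the gap rule,
and a per-base substitution error rate is available (default 0, so ground
truth and emitted alignments agree exactly).

Randomness comes from streams keyed by (seed, stage, site, sample):
enlarging the cohort does not reshuffle earlier samples' reads, and a given
configuration reproduces its output byte for byte.

What the generator does *not* emulate: colour-space or GC-dependent error
profiles, mapping (reads are placed, not mapped), capture-region structure,
indels, or genuinely homozygous artefacts. Tests passing on these cohorts
therefore demonstrate the correctness of the counting and threshold logic
and the qualitative behaviour of the evaluation procedures — not
performance on real exomes, where artefact prevalence and coverage are not
under experimental control.

## Problem sizes and test design

The test suite builds all fixtures in code at run time. The standing
cohorts use a 12–15 kb reference at 25-fold coverage with 9–12 samples —
large enough that every planted class is represented tens of times, small
enough that the whole suite runs in minutes. The pileup routine is checked
read-for-read against an independent oracle that parses the plain-text SAM
form from scratch, over 200 loci spread across 10 samples; the filter
decisions are cross-checked against a brute-force re-scan of every
comparator read. The first-cousin O/E analysis uses 20 replicate cohorts
of one cousin pair (100 rare variants each, 60 recurrent artefacts, 8
comparators): per replicate the post-filter O/E is a scaled
Binomial(100, 0.125), so its mean over 20 replicates has standard error
about 0.06 and the asserted [0.8, 1.2] band is a greater-than-3-sigma
margin around 1.

## Known limitations

Only single-nucleotide substitutions are handled; indels, MNVs and
symbolic alleles are skipped (and counted) on input. The filter's
thresholds are fixed per run — they do not adapt to local coverage or
error context. CRAM input is not supported. The comparator panel's
composition (same chemistry and pipeline, no relatives) is the caller's
responsibility; the package verifies only that sample ids are unique and
warns when the declared test sample appears in the panel.
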
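---
title: "Methods: mutation-spectrum analysis and cohort simulation in mnutill"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mutation-spectrum analysis and cohort simulation in mnutill}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mnutill)
```

## Scope and model of the data

`mnutill` analyses whole-genome-sequenced M1 mutant libraries produced by
alkylating mutagens such as N-methyl-N-nitrosourea (MNU). MNU methylates
guanine; O6-methylguanine mispairs with thymine during replication, so the
dominant mutation class is the G/C→A/T transition, and every M1 plant
carries its own private set of heterozygous induced mutations on a shared
reference background. The package starts from the product of joint
genotyping — a multi-sample VCF with one column per plant — and treats
everything upstream (trimming, alignment, duplicate marking, variant
calling) as out of scope.

The analysis chain is:

1. **Curation** (`curate()`): keep records where exactly one plant is
   non-reference *and* that genotype is heterozygous; drop records with
   site quality (QV) at or below a threshold; drop InDels inside
   repeat-masked intervals.
2. **Spectrum statistics** (`compute_spectrum()`, `per_plant_rates()`,
   `window_density()`, `indel_size_histogram()`): the 12-class REF→ALT
   substitution table with its Ts/Tv ratio, per-plant rates, 100-kb window
   densities and signed InDel-size histograms.
3. **Context bias** (`select_mutated_g()`, `profile_context()`,
   `sample_null_g()`, `bias_report()`): base frequencies at offsets −20..+20
   around mutated guanines, against a without-replacement random-G null.
4. **Effect annotation** (`annotate_variants()`): a from-scratch
   variant-effect classifier against longest-isoform gene models.
5. **Library reports** (`build_tilling_index()`, `transmission_summary()`,
   `correlate_seed_setting()`, `saturation_estimate()`).
6. **Cohort simulation** (`cohort_sim_config()`, `simulate_genome()`,
   `simulate_cohort()`): a generative model of the whole data set with
   ground truth, used throughout the test suite.

## Curation rules and their edge cases

*Uniqueness.* A site is assigned to a plant only when that plant is the sole
non-reference carrier; a second carrier of any zygosity disqualifies the
site, and a homozygous-alt sole carrier is also removed (induced M1
mutations are heterozygous; homozygous calls are treated as pre-existing or
artefactual). Missing genotypes in other plants are ignored when counting
carriers: at typical 15× coverage missingness is common, and requiring
complete genotyping would discard most sites.

*Quality threshold.* The QV is the site QUAL of the joint-genotyped VCF,
and the comparison is strict (`qv > threshold`, default 80): a variant at
exactly the threshold is removed. Whether a study filters on site QUAL or
on a per-genotype score is often underdocumented; site QUAL is the default
here and the filter function accepts any numeric column a user prefers to
substitute.

*Repeat mask.* Only InDels are tested against the mask, by their POS
(leftmost base), not their full span — the simplest defensible reading;
SNVs at masked positions are kept. The three filters commute, which the
test suite checks; the shipped order (uniqueness → QV → mask) matches the
discovery protocol.

*Calibration.* `calibrate_qv_threshold()` reproduces the Sanger-validation
view of the threshold choice: for each candidate cutoff, the fraction of
validated variants above it that were confirmed true. On the simulator's
default noise model this curve rises monotonically with the cutoff.

## The substitution spectrum

Classes are the 12 ordered REF→ALT pairs (AC, AG, …, TG) on the plus
strand of the reference; no strand collapsing is performed, so G→A and
C→T are reported separately and their near-symmetry is itself a data
check. Transitions are AG, GA, CT, TC; the Ts/Tv ratio is reported to two
decimals, with an infinity sentinel when no transversions exist. Reported
percentages round half away from zero, matching the convention of the
published tables this format mirrors.

The per-Mb mutation rate needs a genome-size denominator; reference
"length" differs between assembly variants (masked vs unmasked, with or
without organelles), so the denominator is an explicit argument and is
echoed in the output rather than assumed.

"Sliding" window densities are implemented as non-overlapping tiles
(step = width) by default, matching the bar-chart presentation such data
usually gets; a smaller `step` gives a true sliding window.

## Context-bias profiling

All curated SNVs with REF = G enter the observed set, regardless of ALT.
No reverse-complementing of C>N variants is performed: the profile is
defined on the plus strand of the reference around mutated guanines, so
the observed site count equals the GA+GC+GT class counts exactly — an
invariant the suite asserts. Sites near chromosome ends contribute only
their valid offsets (each offset keeps its own denominator), rather than
being dropped wholesale, and N bases are excluded per offset. The null is
a uniform without-replacement sample of G positions with a recorded seed.
`bias_report()` returns observed-minus-null differences in percentage
points and flags offsets beyond a configurable threshold; it does not test
significance — at these site counts any visible difference is far beyond
sampling noise, and the interesting quantity is the effect size.

## Effect annotation from first principles

Gene models are one representative transcript per gene — the longest CDS,
ties broken by the lexicographically smallest transcript id so results are
reproducible. Classification per (variant, gene):

* **Coding SNVs**: the CDS coordinate is computed strand-aware, the
  affected codon extracted from the spliced CDS, and both ref and alt
  codons translated with the standard genetic code (minus-strand alleles
  complemented into transcript frame). Codon 1 losing its ATG is
  `start_lost`; a destroyed stop is `stop_lost`; a created stop
  `stop_gained`; other amino-acid changes `missense`; the rest
  `synonymous`. Models whose CDS length is not divisible by 3 are flagged
  and annotated best-effort (partial codons translate to `X`).
* **Splice sites**: the two canonical intronic bases at each junction,
  donor at the transcript-5' end of the intron, acceptor at the 3' end.
* **Non-coding**: exonic positions outside the CDS become 5'/3' UTR by
  transcript side; other in-gene positions are intronic; positions within
  5,000 bp of the gene span (the default of the annotation tool this
  reimplements) are upstream/downstream, strand-aware; everything else is
  intergenic.

Impact tiers follow the usual map (HIGH: stop gained/lost, start lost,
splice donor/acceptor; MODERATE: missense; LOW: synonymous; MODIFIER: the
rest). A variant overlapping several genes gets one row per gene;
`most_severe_per_variant()` collapses to the highest impact with a fixed
category order as tie-break, and the summary tables report
most-severe-only counts — a variant never counts in two categories.

InDel coding effects (frameshifts) are deliberately out of scope: InDels
receive positional annotation only (`gene` when inside a span, otherwise
upstream/downstream/intergenic), since all coding summary classes here are
SNV-based.

The test suite checks this classifier against an independent brute-force
oracle that rebuilds the entire spliced CDS before and after each variant
and re-translates it with the Biostrings genetic code, on randomly
generated multi-exon genes of both strands.

## The cohort simulator

The simulator is a first-class, tested module, not a fixture. Its defaults
are the study conditions of the MNU library it emulates:

| Parameter | Default | Meaning |
|---|---|---|
| `n_plants` | 266 | cohort size |
| `base_composition` | A .282, C .218, G .218, T .282 | i.i.d. genome composition |
| `snv_count` | lognormal(7.49, 0.9) on [134, 13222] | per-plant SNV count; mean ≈ 2468.7 |
| `class_probs` | 12-class table of the observed cohort | Ts/Tv ≈ 14.81, G/C→A/T ≈ 91.2% |
| `context_bias` | −1: +15.8 pp A, +18.7 pp G; +1: +6.4 pp T | neighbor rewriting around mutated G |
| `indel_fraction` | 0.0047 | InDel share of true variants |
| `deletion_prob` | 2486/3118 | deletions vs insertions |
| `indel_size_geom_p` | 0.555 | geometric sizes; P(<3 bp) ≈ 0.80 |
| `fp_rate` | 0.1 | false-call share of emitted records |
| `fp_qv_range` / `tp_qv_range` | U(30,100) / U(60,500) | overlapping QV distributions |
| `phenotype` | intercept 48, slope −0.006, sd 22.5 | seed-setting model, target r = −0.43 |
| `transmission_loss` | 0.152 | probability a true variant is untransmitted |

Design choices worth recording:

* **REF-conditional placement.** A drawn class (say G→A) is placed at a
  uniformly chosen position whose base is that REF, sampled without
  replacement across the whole cohort, so every true variant is
  heterozygous in exactly one plant and the VCF is consistent with the
  emitted FASTA.
* **Context bias by rewriting.** The −1/+1 neighbors of mutated-G sites
  are resampled from the background composition shifted by the configured
  percentage-point increments (remaining bases renormalized
  proportionally) *before* the reference FASTA is emitted. This gives
  exact control of the deltas at toy scale, at the cost of a slight
  (<1%-point at test densities) composition shift near mutated sites.
  The published ±1 bias values are ambiguous between absolute frequencies
  and increments; the increment reading is adopted, because the absolute
  reading would make the A frequency *decrease*, contradicting the
  direction reported. Neighbor positions that are themselves variant
  sites are never rewritten, so REF alleles stay valid.
* **Count distribution.** No distribution family is reported for per-plant
  counts; a truncated lognormal was chosen as the standard right-skewed
  count model and its parameters fitted once (by moment matching plus a
  small Monte Carlo) to the published mean and range, then frozen.
* **Phenotype model.** Seed setting is linear in mutation count plus
  Gaussian noise, clamped to [0, 100]. Clamping attenuates the
  correlation, so the noise SD was calibrated once by Monte Carlo such
  that the *post-clamp* correlation centers on the −0.43 target (the
  shipped constants give ≈ −0.44 with a per-cohort SD of ≈ 0.04); the
  suite checks recovery within ±0.1 of the target across seeds.
* **Noise model.** False positives are uniform random sites with low,
  overlapping QVs, so that QV-threshold calibration is a non-trivial
  exercise rather than a separable one. With `fp_rate = 0`, an
  unthresholded, unmasked curation returns the truth table exactly — the
  no-noise limit used as an end-to-end test.
* **Determinism.** One integer seed drives genome, cohort and phenotype
  generation (the cohort stage offsets the seed by 1 so the two stages do
  not share a stream); identical configuration and seed give byte-identical
  VCF output.

What the simulator does **not** emulate: read-level errors and coverage
(QV noise is injected directly), M1 chimerism and sectoring, linkage or
clustering between mutations, real repeat structure (the mask is random
intervals), UTRs in simulated gene models (exon = CDS; UTR handling is
tested on hand-built models), and transcript isoform diversity. Passing
tests therefore demonstrate the correctness of the analysis logic under a
faithful statistical cartoon of the data, not robustness to every artefact
of real sequencing.

## Saturation extrapolation

Coverage is the fraction of annotated genes carrying ≥1 high-impact SNV.
The linear model scales cohort size proportionally,
n = n₀ · target/observed — simple, but it cannot represent saturation and
is meaningless for targets near 1. The Poisson alternative treats
per-gene hits as Poisson with per-plant rate λ = −ln(1−observed)/n₀ and
inverts n = −ln(1−target)/λ; it always requires at least as many plants
as the linear model for targets above the observed coverage (a convexity
property the suite checks numerically). Reports label which model
produced each number.

## Numerical conventions and problem sizes

Coordinates are 1-based closed everywhere internally; BED input is
converted at the boundary. Reported percentages and ratios round half
away from zero. Pearson p-values use the t transform with n−2 degrees of
freedom and are descriptive only — a single test per run, no multiplicity
machinery.

The test suite and the acceptance script run the simulator at desk scale —
genomes of 0.1–2 Mb and 10⁴–10⁵ variants, sizes chosen so every
statistical check retains narrow binomial/multinomial error bands while
the whole suite stays fast; the full 266-plant default configuration
(12 × 2.6 Mb genome, ≈ 6.6 × 10⁵ variants) runs in about two minutes and
under a few GB of memory when wanted.

## Known limitations

* Multi-allelic records are split per ALT with the site QUAL retained on
  each split record; per-allele quality is not modelled.
* The InDel mask filter tests POS only; a full-span overlap mode would be
  a one-line change but is not the default.
* The annotation module covers protein-coding, single-isoform models
  only; regulatory features, biotypes and HGVS notation are out of scope.
* The Ts/Tv ratio of a *curated* noisy cohort sits below the configured
  truth value, because surviving false calls have a near-uniform class
  spectrum — visible in any worked example with `fp_rate > 0`, and a
  reminder that the published ratio is itself a post-filtering estimate.
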
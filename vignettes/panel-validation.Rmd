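---
title: "Assessing the analytical validity of a targeted gene panel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing the analytical validity of a targeted gene panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelval)
```

## The problem

A targeted capture panel enriches a few hundred kilobases of cancer
susceptibility genes, sequences them deeply, and calls variants. Before
those calls can support any downstream claim — carrier frequencies,
ancestry contrasts, clinical interpretation — the panel's *analytical
validity* has to be established: which calls are real, which are
artifacts, and whether the call set misses variants that orthogonal
assays (prior clinical gene screening, Sanger re-sequencing) are known
to contain.

`panelval` implements that assessment for the post-VCF portion of a
panel workflow. The package takes four kinds of evidence:

* **per-base depth of coverage** over the captured regions,
* **sample-level variant calls** with genotype, depth and allelic depth,
* **population allele frequencies** per ancestry group, used as a
  rarity filter,
* **orthogonal truth**: Sanger confirmation of called sites, and prior
  clinical screening results (full-gene screens or targeted familial
  variant tests).

and produces coverage profiles, a filtered and triaged call set,
per-gene concordance metrics, and exact 2×2 inference for group
contrasts.

## Concordance model

Calls are classified against orthogonal truth:

* **TP** — a call confirmed by Sanger (or previously known from
  clinical screening and re-detected);
* **FP** — a call that fails Sanger confirmation;
* **FN** — a clinically identified, laboratory-confirmed variant with
  no matching call in the same sample;
* **TN** — a *(sample, gene)* pair with a negative full-gene clinical
  screen and no pathogenic panel call in that gene.

From these: sensitivity = TP/(TP+FN), specificity = TN/(TN+FP), and the
false discovery rate FDR = FP/(TP+FP), the fraction of reported calls
that fail validation. FDR is reported in two modes: over all calls, and
after excluding calls with allele balance ≤ 0.20 (see *Triage* below).
Undefined ratios are reported as `NA`, never coerced to 0.

Two conventions deserve emphasis, because the definitions above do not
force them:

* **The TN unit is a (sample, gene) pair**, pooled over the clinically
  screened gene set. Six negative-screened individuals contribute six
  TNs to *each* of two screened genes (TN = 12), so one FP gives a
  pooled specificity of 12/13 = 92.3%. Treating TNs as individuals
  (TN = 6) cannot reproduce that arithmetic.
* **Only pathogenic calls break TN status.** A clinically negative
  sample that carries VUS or benign calls in the screened gene is still
  a true negative — clinical screening reports *pathogenic* findings,
  so only a pathogenic panel call contradicts a negative screen. A
  sample tested only for a single familial variant is never a TN: a
  negative targeted test does not establish the gene is clean.

Variant matching between calls and truth records uses a normalized key:
`"-"`/`"."` placeholder alleles become empty, the shared prefix is
trimmed first (dropping VCF anchor bases, advancing the position), then
any shared suffix. This makes the anchored VCF spelling of an indel and
its ANNOVAR-style spelling compare equal. Indels inside short tandem
repeats can still carry irreconcilable right-shifted names; resolving
those in general requires the reference sequence, which is out of scope
here.

## Filtering cascade

Three conjunctive predicates, applied in any order with the same
result (a property the test suite asserts):

1. **Gene restriction** to the assessed gene set.
2. **Rarity**: keep a call iff its population MAF is ≤ 2% (inclusive)
   in *every* ancestry group. A variant absent from the control
   repository passes — absence of frequency evidence is read as rarity.
   Both choices are forced by validation tables that retain variants at
   exactly the cutoff and variants missing from one or both control
   populations. MAFs are proportions (0.02), never percentages.
3. **Position**: keep coding calls (nonsynonymous, synonymous,
   frameshift) and intronic calls within 10 bp of an intron–exon
   boundary — the intronic flank such capture designs retain. The
   boundary distance comes from an explicit column, or from the cDNA
   change string (`c.186-7C>T` encodes 7 bp), or from the target exon
   model, in that order of preference.

## Triage by depth and allele balance

The allele balance of a call is `AD_alt / DP` — the fraction of reads
supporting the alternate allele, ≈ 0.5 for a true heterozygote and 1.0
for a homozygote where the alternate allele is the only one detected
(this is what pins the definition: tabulated homozygotes at 1.00).

A call is **high confidence** iff `DP ≥ 100` and `AB ≥ 0.40`, both
boundaries inclusive. The depth boundary is stated inconsistently in
narrative sources ("over 100X" vs "≥ 100X"); the tabular criterion
header is inclusive and no observed call sits exactly at 100X, so the
readings agree on all real data and the inclusive form is used. The
same applies to the 0.40 balance boundary. Classification is a pure
function of (DP, AB, thresholds) and monotone: raising depth or balance
never demotes a call.

Triage uses the call's own reported depth (the VCF sample-field `DP`),
*not* the locus average from the coverage table. Artifact calls sit at
12–63X even inside regions averaging over 400X; using region averages
would hide exactly the calls the triage exists to catch.

The stricter reporting mode drops calls with `AB ≤ 0.20` (strictly:
0.20 itself is excluded, 0.21 survives). On the packaged example data
every excluded call is an FP, so the filtered FDR is never worse.

Genotype quality (GQ) is carried through but not used in any filter:
observed data give it almost no discriminating power (nearly all
confirmed calls sit at GQ 99, and several artifacts do too).

## Exact 2×2 inference

Group contrasts (e.g. individuals with ≥ 1 validated variant per
ancestry) are tested with the Fisher exact test, conditioning on all
margins:

* the two-sided p-value sums hypergeometric probabilities of tables no
  more likely than the observed one (minimum-likelihood rule, with a
  1 + 1e-7 relative tolerance on the comparison — the convention of
  the standard R implementation, required to match published
  p-values);
* the odds-ratio estimate is the **conditional MLE** — the ψ
  maximizing the noncentral hypergeometric likelihood — found by
  root-finding on the conditional mean. This is the estimate standard
  exact-test software reports; it is *not* the sample cross-product
  ratio (18.0 vs 16.8 on the headline table here);
* the 95% bounds invert the exact one-sided tail tests at α = 0.025,
  returning 0 or ∞ when the observed count sits at its attainable
  extreme.

Numerical note: the tail and mean equations are solved to a tolerance
of 1e-10 on log ψ. Reference implementations solve the same equations
with looser default tolerances, so last digits of wide confidence
bounds can differ (e.g. an upper bound of 823.7 here vs a published
819.7 — both satisfy the tail equation to within 5e-5 of α). A
deliberately independent grid-search maximizer (`cmle_oracle()`)
guards the estimate in the test suite to 1e-3 relative on hundreds of
random tables.

Cohort carrier frequency is computed over `2N` chromosomes:
`carrier_maf(het, samples, hom = 0) = (het + 2 hom) / (2 samples)`.
The explicit het/hom split replaces a zygosity-mode flag: it covers the
all-heterozygote convention (`hom = 0`) and allele counting with
homozygotes without a second code path.

## Coverage summaries

Per-region summaries report the arithmetic mean depth, quartiles, and
the percentage of bases at or above 1, 10, 20, 50, 100, 250, 500, 1000
and 10000X. Choices the data do not dictate, fixed here:

* **Quartiles** use linear interpolation between order statistics
  (`stats::quantile` type 7). Published interquartile ranges are not
  reproducible without per-base data, so no convention can be
  validated against them; type 7 is R's default and the least
  surprising.
* **Bases absent from the depth table count as depth 0** — uncovered
  bases are part of the denominator, since "percent of target covered"
  is meaningless otherwise.
* **Depth bins** are closed-left: `[0,100), [100,200), …, [1500, ∞)`.
  Printed labels like "<100" and ">1500" are ambiguous exactly at the
  edges; half-open bins partition the line and keep counts conserved.
* **Per-bin aggregation** is the unweighted mean of region
  percentages; the panel-wide summary, in contrast, pools the per-base
  multiset (equivalently, length-weights the region means — an exact
  identity the suite asserts).
* Per-gene summaries pool bases across samples (the per-sample-average
  depth column of the table), rather than averaging per-sample
  summaries; the alternative is not distinguishable from published
  summaries and the pooled form is simpler.

## The synthetic data generator

Real validation cohorts cannot be redistributed, so the package ships a
generator whose defaults are the study conditions the analysis was
designed around: 43 samples in two ancestry groups (23 + 20), ten genes
in 225 regions (~74 kb), panel mean depth 809X.

* **Region mean depth** is log-normal (`sdlog = 0.5`, `meanlog` set so
  the mean is 809X). Capture panels show a long right tail of region
  depths spanning well over an order of magnitude; a log-normal is the
  simplest law with that shape, as only summary statistics — not a
  generative model — are ever published for such panels.
* **Per-base depth** multiplies the region mean by a per-sample
  log-normal capture factor (`sdlog = 0.2`), stationary AR(1) noise on
  the log scale (`sd = 0.3`, `ρ = 0.9`; capture efficiency is locally
  correlated along a probe footprint), and independent per-base dropout
  (1.8%, matching the fraction of target bases observed to have no
  coverage at all). With all noise at zero the profile degenerates to
  the rounded mean — a corner the tests pin down.
* **Heterozygote allele balance** is `Binomial(DP, 0.5)/DP`, with no
  reference-bias skew: published summaries give het means ≈ 0.5 and no
  distributional detail, so the unbiased binomial is assumed (an open
  question resolved in favor of the simplest model). Homozygotes carry
  `AD = DP` exactly.
* **Artifacts** draw depth uniformly from 12–63 reads and allele
  balance from Beta(2, 4) truncated to (0.05, 0.70), matching the
  observed artifact band (mean ≈ 34X / 0.33, range 0.13–0.68).
  Optionally one region behaves as if shadowed by a processed
  pseudogene: artifacts cluster at a few recurrent sites across many
  samples, the pattern paralogous mis-mapping produces.
* **Ancestry** is a categorical label with group-specific allele
  frequencies — no further population structure, since the analysis
  only consumes per-group frequencies. Planted variants carry separate
  *population* MAFs (what the control repository would show; must be
  rare to survive filtering) and *cohort* carrier frequencies (a
  family-history-enriched cohort can carry a variant at many times its
  population frequency).
* **Determinism**: every component draws from its own substream derived
  from the master seed, one per sample where applicable, so enlarging
  the cohort does not perturb earlier draws; equal configurations
  produce byte-identical output files.

What the generator does **not** emulate: read-level errors, mapping,
indel realignment, strand bias, GC-dependent capture efficiency, and
reference-biased allele balance. Tests passing on synthetic data
therefore demonstrate the *bookkeeping and statistics* of the pipeline
— label conservation, metric identities, recovery of planted artifact
fractions — not robustness to upstream artifacts real data would add.

## Problem sizes and numerical choices

The packaged example dataset (74 calls, 43 samples, 10 genes) runs
through the whole pipeline in well under a second; the test suite uses
scaled-down simulations (two genes, a few hundred bases, 8–14 samples)
except where a law needs volume: the heterozygote-balance check uses
1,000 carriers at 10,000X, and the region-mean law is checked on 10,000
simulated regions. Report files round depth to the whole X, proportions
to two decimals and percentages to one, with a fixed away-from-zero tie
break so reruns are byte-identical across platforms.

## Known limitations

* TN accounting requires gene-level clinical truth; cohorts without
  systematic clinical screening yield specificity `NA`, not an
  optimistic number.
* Key normalization without a reference genome cannot reconcile every
  tandem-repeat indel alias.
* The exclusion boundary (AB ≤ 0.20) and the high-confidence criteria
  are panel-calibrated defaults, not universal constants; both are
  exposed as `triage_thresholds()` and CLI flags.
* Percent-validated is computed per call, not per unique variant;
  recurrent artifacts at one site count once per sample carrying them.
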
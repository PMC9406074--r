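---
title: "Methods: haplotype-based cfDNA variant calling and prognostics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: haplotype-based cfDNA variant calling and prognostics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`plasmavar` analyses ultra-deep amplicon sequencing of plasma cell-free DNA
(cfDNA): short hotspot amplicons (by default 185–216 bp) from a handful of
driver genes, sequenced as overlapping 2 × 150 bp read pairs at depths of
10^4 or more, with the goal of calling single-nucleotide variants down to 1%
frequency and summarising each sample's mutational burden for prognosis.
This vignette documents the model, the parameter choices and their
rationale, the design decisions taken where the procedure was genuinely
open, and what the simulation-based tests do and do not establish.

## Read-level model

**Merging.** Each read pair is assumed to cover the whole amplicon (read 1
from the forward primer, read 2 from the reverse primer), so mates overlap
by `2 * read_length - amplicon_length` bases. Read 2 is reverse-complemented
and candidate overlap lengths are scanned from the longest (`min(len1,
len2)`) downwards; an overlap qualifies when it has at least `min_overlap =
20` bases and a mismatch fraction at most `max_mismatch_frac = 0.10`
(a fraction exactly at the threshold qualifies; `N` counts as a mismatch).
The **longest qualifying overlap wins**. Published merge tools differ in
their selection rule (FLASH, for instance, minimises mismatch density); only
the two thresholds are standard, so we pick a deterministic rule — longest
first, which under the full-coverage fragment model is also the true overlap
whenever it qualifies — and expose it. Within the overlap, disagreeing bases
resolve to the higher-quality mate (quality tie: read 1's base), and the
merged quality at every overlap position is the per-position maximum. The
per-base choices here only affect haplotypes that carry sequencing errors,
which the abundance filters remove downstream.

**Quality filter.** A merged read is discarded when the fraction of its
bases below Phred Q30 is **greater than or equal to** 5% (`q_threshold =
30`, `max_low_q_frac = 0.05`): the boundary is read as "5% or more
discarded", and a read with exactly 5% low-quality bases is removed. `N`
bases count as below threshold.

**Demultiplexing.** "Differences" against a primer are Hamming distances on
the primer-length prefix/suffix — substitutions only, no indel alignment,
consistent with the substitution-only error model; this is a documented
limitation. Each read is tried in both orientations against every amplicon's
forward primer (5' end) and reverse-primer complement (3' end). A candidate
qualifies when **each** primer matches within `max_primer_diff = 3`
differences; the candidate with the fewest total mismatches wins, and a tie
between different amplicons leaves the read unassigned (ambiguous) rather
than guessing. Assigned reads are primer-trimmed and reoriented to the
reference strand. Panels generated by `pv_make_panel()` enforce a pairwise
primer Hamming distance above 6, so a 3-difference demultiplexer cannot be
ambiguous on panel-derived reads.

The stage order is merge → quality filter → demultiplex, and every input
pair lands in exactly one report category (merge failure, quality discard,
unassigned, assigned), which the tests assert as a conservation law.

## Haplotype filters and variant calling

Assigned reads collapse to haplotypes per amplicon and strand, with
abundances relative to all reads assigned to that amplicon+strand. Two
filters then remove error haplotypes:

* **Abundance floor, per strand.** Haplotypes below 0.1% abundance
  (`min_hap_abundance = 0.001`) are discarded. The floor applies on each
  strand separately (the conjunction reading of "below 0.1%, and not common
  to both strands"); an abundance exactly at 0.1% survives, as all
  thresholds here are strict "below".
* **Strand concordance.** A haplotype must be observed on both strands.
  True template molecules are sequenced in both orientations at this depth,
  while polymerase errors and sequencing artifacts are typically
  strand-asymmetric.

Surviving haplotypes get a count-weighted combined abundance,
`(fwd_count + rev_count) / (fwd_total + rev_total)` — count-weighted rather
than an average of the two strand abundances, so unequal strand depths do
not bias it.

**Variant frequencies are relative to the retained consensus.** A call's
frequency is the summed combined abundance of the haplotypes carrying that
allele divided by the total combined abundance of all retained consensus
haplotypes for the amplicon. Two reasons. First, it makes the per-position
allele frequencies — reference allele included — sum to exactly 1, which is
the natural probabilistic reading of a haplotype-frequency table. Second, it
removes a systematic bias: at a per-base error rate of 0.1% over a ~200 bp
amplicon, roughly 15% of the reads of *every* haplotype are scattered into
singleton error haplotypes that the 0.1% floor removes. With raw assigned
totals in the denominator, every call would be deflated by that survival
factor (a 30% variant would read as ~25%); normalising over what is retained
cancels the factor because it hits carrier and reference haplotypes equally.
Calls below `min_variant_freq = 0.01` are dropped (exactly 1% survives).
Haplotypes whose length differs from the reference — putative indels,
outside the SNV-only scope — are excluded from calling and tallied.

**Annotation.** Positions map to genomic coordinates through each amplicon's
anchor (`anchor_start`, strand); reverse-anchored amplicons report
complemented alleles. A local catalog TSV supplies known/novel flags and
field aliases (the TERT promoter `C228T (-124)` style); the package ships a
small synthetic example catalog, and live database queries are deliberately
out of scope. Coding consequence uses the amplicon's reading-frame offset
and the standard genetic code; promoter amplicons (frame `NA`) yield
`noncoding`, as do positions outside a complete codon.

**Burden metrics.** Per sample: `n_mutations` counts nonsynonymous plus
noncoding calls (synonymous calls are excluded), `n_genes` the distinct
genes among them, and `ratio = n_mutations / cfdna_conc` (defined as 0 when
no mutations are detected).

## Cohort statistics

* **Mann–Whitney.** `U = #(a > b) + 0.5 #(a = b)` over cross-group pairs,
  with `U + U' = n_a * n_b`; exact two-sided p by enumeration when both
  groups have ≤ 8 untied observations, otherwise the tie-corrected normal
  approximation (`stats::wilcox.test` supplies both). The reported `U`
  follows R's `W` convention — for `a = {1,2,3}` vs `b = {10,11,12}`,
  `U = 0` with exact p = 0.1.
* **ROC.** AUC is computed by pair counting (`P(pos > neg) + 0.5 P(=)`,
  identical to the Mann–Whitney probability, exact under ties). The optimal
  cut-off maximises Youden's J; no rule is standard here, so Youden was
  chosen and ties resolve to the lower threshold, making the output
  deterministic.
* **Kaplan–Meier / log-rank.** Product-limit curves via
  `survival::survfit` (deaths precede censorings at tied times), two-group
  log-rank via `survival::survdiff`. "Mean survival" is the restricted mean
  — the area under the curve up to the largest observed time — because an
  unrestricted mean is undefined with censoring. With no events the log-rank
  statistic is undefined and reported `NA`.
* **Cox models.** `survival::coxph` with Efron tie handling (accurate with
  few ties; the choice is otherwise inconsequential here), Wald 95%
  intervals and p-values. Dichotomised covariates are binarised with strict
  ">" cut-offs before fitting. Each model uses complete cases for its own
  covariates and reports its `n_obs`. Non-convergence, separation or fewer
  than 10 complete observations produce a diagnostic note on the result row
  instead of an error: tiny fits are legitimate in toy analyses but should
  be visibly flagged.
* **Dichotomies.** cfDNA > 2 ng/µL, > 4 mutations, > 2 mutated genes,
  ratio > 6 (and > 6 tissue mutations). All strict: a value exactly at a
  cut-off is low-risk.
* p-values are reported raw. No multiple-testing correction is applied,
  matching exploratory biomarker practice; the report carries a note saying
  so.

## The synthetic-data generator

The generator exists so that every stage is testable without patient data;
its defaults are the study conditions the package targets.

**Reads** (`pv_simulate_reads`). Full-amplicon pairs (so the merge step has
real work), a ~50/50 strand split, independent per-base substitution errors
(default 0.1%), and Phred scores from a truncated normal (mean 37, sd 3,
clipped to [2, 40]) with an explicit low-quality tail (probability 1% of a
Uniform{10..29} score) so the Q30/5% read filter is exercised. No model for
PCR duplicates, chimeras, index hopping, indels or cfDNA fragment-length
biology — so passing tests say nothing about those artifact classes; on
real data the strand-concordance filter is the main defence against the
first two. The truth table records each spike's realized post-sampling
fraction, which is the correct oracle for recovery tests (a 1% spike can
legitimately realize below 1% and then be correctly filtered).

**Cohorts** (`pv_simulate_cohort`). Patients fall into two latent covariate
groups. cfDNA concentrations are log-normal per group with medians 2.90 and
0.98 ng/µL and spreads matched to interquartile ranges of 2.23–3.26 and
0.70–2.44 — the reported levels for deceased vs surviving early-HCC
patients. Mutation burdens are negative-binomial (medians near 4.5 vs 1.5),
spread uniformly over the five panel genes to derive `n_genes`. Survival and
recurrence times are exponential proportional-hazards draws with per-burden
coefficients defaulting to the reported univariate estimates (HR 1.11 per
mutation for death, 1.16 for recurrence), plus a latent-group frailty
(default log-HR log 4 for death, log 3 for recurrence) standing in for the
unmeasured tumour aggressiveness that links high cfDNA and high burden to
poor outcome. Baseline hazards (0.0025 and 0.006 per month) and the frailty
were calibrated once, a priori, so that a 50-month horizon yields roughly
23% deaths and 40% recurrences and the deceased group's cfDNA distribution
approaches its target median. Setting all coefficients and the frailty to
zero gives an exact null model, which the calibration tests rely on. The
generator does not model competing risks, time-varying hazards or informative
censoring; the only censoring is administrative at the horizon.

**Seeding.** One master seed; child streams per amplicon and per patient
(derived by a fixed integer recurrence) keep outputs byte-identical under
the same seed and stable under partial re-runs.

## Numerical and degenerate-input choices

* Threshold comparisons are exact (`>=` on abundances, `<` on "below");
  the only floating-point guard is a `1e-9` slack when converting the
  overlap mismatch fraction to an integer mismatch budget.
* An amplicon with one strand entirely absent yields no consensus
  haplotypes and a classed warning (`pv_amplicon_dropout`).
* A follow-up horizon of 0 censors everyone at 0 with zero events; the
  log-rank on an event-free dataset is `NA`, not an error.
* Analyses whose preconditions fail on a given cohort (single outcome
  class, empty group, no events) are skipped with a recorded reason in the
  prognostic report rather than aborting the batch.
* Problem sizes in the routine tests were chosen to keep the full suite
  around a minute while leaving no stage untested at realistic depth: depth
  10,000 per amplicon for the recovery check, 100 × n = 2000 Cox replicates
  for coverage, 500 × n = 80 replicates for null calibration, and a
  6-patient demo at depth 300 for end-to-end determinism.

## Known limitations

* Substitution-only error and variant model: indels are neither simulated
  nor called, and length-discordant haplotypes are only counted.
* Hamming-distance demultiplexing cannot rescue reads with primer indels.
* Strand concordance assumes both strands are sequenced at comparable
  depth; heavily unbalanced runs will drop real haplotypes.
* The frequency renormalisation assumes errors hit carrier and reference
  haplotypes at equal rates; variant-dependent error hotspots would break
  that symmetry.
* The cohort generator's frailty construction induces realistic marginal
  associations but is not a mechanistic tumour model; absolute hazard ratios
  from simulated cohorts should be read as plumbing checks, not biology.
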
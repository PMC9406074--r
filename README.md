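# plasmavar

Haplotype-based low-frequency variant calling and prognostics for plasma
cell-free DNA (cfDNA) amplicon panels.

## The problem

In early hepatocellular carcinoma (HCC), a small fraction of circulating
cfDNA is tumour-derived and carries somatic hotspot mutations in a handful of
driver genes (TERT promoter, TP53, CTNNB1, AXIN1, ARID1A). Detecting those
mutations at frequencies around 1% from ultra-deep amplicon sequencing
requires aggressive error suppression, and the resulting per-patient
mutational burden — together with the cfDNA concentration itself — is a
candidate prognostic biomarker for survival and recurrence after curative
treatment.

`plasmavar` implements that full workflow for panels of short
(185–216 bp) amplicons sequenced as overlapping 2 × 150 bp read pairs:

1. **Read reconstruction** — each pair is merged into a full amplicon
   (minimum 20 overlapping bases, at most 10% differences in the overlap;
   conflicting bases resolve to the higher-quality mate).
2. **Quality filter** — merged reads with ≥ 5% of bases below Phred Q30 are
   discarded.
3. **Primer demultiplexing** — reads are assigned to the amplicon/strand
   whose primers match with at most 3 differences each; ambiguous reads are
   dropped.
4. **Haplotype collapsing** — identical reads collapse to haplotypes with
   per-strand abundances. Haplotypes below 0.1% abundance on either strand,
   or absent from one strand, are discarded (strand concordance filters out
   polymerase/sequencing artifacts, which are strand-asymmetric).
5. **SNV calling** — per position and alternate allele, the aggregate
   frequency over the retained consensus haplotypes; calls below 1% are
   filtered. Calls are annotated with genomic coordinates (via the panel's
   anchors), catalog aliases (e.g. TERT `C228T (-124)`), and their coding
   consequence.
6. **Prognostic layer** — per-sample burden metrics (number of mutations,
   number of mutated genes, mutations/cfDNA ratio), Mann–Whitney group
   comparisons, ROC with Youden-optimal cut-offs, Kaplan–Meier / log-rank
   analyses and Cox proportional-hazards models, including the standard
   dichotomizations (cfDNA > 2 ng/µL, > 4 mutations, > 2 mutated genes,
   ratio > 6 — all strict).

A seeded simulator (`pv_make_panel()`, `pv_simulate_reads()`,
`pv_simulate_cohort()`) generates panels, paired-end FASTQ reads with
spiked-in variants, and clinical cohorts, so the entire pipeline is testable
without patient data.

## Worked example

Simulate one sample with a 5% TERT-promoter spike at read depth 4,000 and
call variants with the default thresholds:

```r
library(plasmavar)

panel <- pv_make_panel(2, seed = 7)
pos   <- nchar(panel$forward_primer[1]) + 40L
alt   <- setdiff(c("A","C","G","T"),
                 substr(panel$reference_seq[1], pos, pos))[1]
specs <- pv_variant_specs(panel, panel$amplicon_id[1], pos, alt, 0.05)
sim   <- pv_simulate_reads(panel, specs, depth_per_amplicon = 4000,
                           substitution_error_rate = 0.001, seed = 42)

stage <- pv_run_read_stage(sim$reads, panel)
stage$report
#> # A tibble: 1 × 6
#>   pairs_in merged merge_failures quality_discards assigned unassigned
#>      <int>  <int>          <int>            <int>    <int>      <int>
#> 1     8000   8000              0                0     8000          0

res <- pv_call_stage(stage$assigned, panel)
dplyr::select(res$calls, gene, position, ref_base, alt_base,
              frequency, genomic_label, synonymy)
#> # A tibble: 1 × 7
#>   gene  position ref_base alt_base frequency genomic_label     synonymy
#>   <chr>    <int> <chr>    <chr>        <dbl> <chr>             <chr>
#> 1 TERT        62 A        C           0.0515 ctg01:1195258 A>C noncoding
```

The 5% spike is recovered at 5.15% (within binomial sampling error of the
truth at this depth) and nothing else is called: the strand-concordance and
abundance filters remove all substitution-error haplotypes.

On the cohort side, simulate 200 patients and run the prognostic analyses:

```r
cohort <- pv_simulate_cohort(n_patients = 200, seed = 1)
cohort$vital <- factor(ifelse(cohort$death_event == 1, "dead", "alive"),
                       levels = c("dead", "alive"))
pv_mann_whitney(cohort, "cfdna_conc", "vital")
#> # A tibble: 1 × 8
#>   group_a group_b   n_a   n_b     u u_prime p_value method
#>   <chr>   <chr>   <int> <int> <dbl>   <dbl>   <dbl> <chr>
#> 1 dead    alive      43   157  4265    2486 0.00820 normal approximation

pv_roc(cohort, "cfdna_conc", "death_event")
#> <pv_roc> AUC = 0.632, Youden-optimal cutoff = 1.90171 (43 pos / 157 neg)

cx <- pv_cox(cohort, "os_time", "death_event",
             c("n_mutations", "n_genes", "ratio"),
             dichotomies = pv_dichotomies())
tidy(cx)[, c("term", "hr", "ci_low", "ci_high", "p_value")]
#> # A tibble: 3 × 5
#>   term               hr ci_low ci_high p_value
#>   <chr>           <dbl>  <dbl>   <dbl>   <dbl>
#> 1 n_mutations_gt4 1.88   0.870    4.04 0.108
#> 2 n_genes_gt2     2.70   1.44     5.06 0.00194
#> 3 ratio_gt6       0.968  0.300    3.13 0.957
```

Baseline cfDNA separates the patients who die during follow-up (Mann–Whitney
p = 0.008), the ROC's Youden-optimal cut-off lands near the conventional
2 ng/µL, and mutations in more than two genes carry a hazard ratio of 2.7
for death in this simulated cohort.

`pv_run_demo()` chains everything — panel, cohort, per-patient FASTQ
simulation, read processing, variant calling, burden metrics and the full
prognostic report — deterministically from one seed. Result objects have
`tidy()` / `glance()` / `autoplot()` methods.

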
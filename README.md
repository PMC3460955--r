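# gbmcna

Integrative copy-number analysis for glioblastoma (GBM) cohorts profiled
on SNP arrays. The package implements, as tested and reusable R
functions, the full analysis chain for a tumor-vs-normal copy-number (CN)
study:

1. **CN calling** — probe-level CN values (arbitrary units, diploid ≈ 2)
   are classified with fixed cutoffs — loss ≤ 1.30, gain ≥ 2.50,
   amplification > 5, homozygous deletion < 0.8 — then smoothed with a
   per-chromosome running median and segmented into contiguous per-sample
   events.
2. **Recurrence** — events are aggregated across tumors into recurrence
   frequencies and **minimal common regions** (MCRs): for each event kind
   the per-base pileup of per-case coverage is computed, and the maximal
   sub-interval at each local coverage maximum is reported with its
   contributing cases and overlapping genes.
3. **Dosage integration** — per-gene CN (mean of overlapping probes) is
   correlated with RMA-scale mRNA expression across paired samples using
   the Pearson coefficient; genes pass the dosage filter when
   *R*² > 0.70 **and** *p* < 5×10⁻⁷, with *p* from
   *t* = *r*·√(n−2)/√(1−*r*²) on n−2 degrees of freedom. At the study's
   n = 23 the two conditions nearly coincide (*t* = 7.00 at *R*² = 0.70,
   *p* ≈ 6×10⁻⁷). A Spearman utility supports RT-PCR-style validation.
4. **Survival** — Kaplan–Meier curves, medians (smallest *t* with
   S(*t*) ≤ 0.5) and the log-rank test compare carriers vs non-carriers
   of an amplification at a query gene or region.
5. **iFISH concordance** — interphase-FISH spot-count fractions are
   classified with percent-of-nuclei cutoffs (gain ≥ 5 %, loss ≥ 10 %,
   amplification when the locus:centromere ratio > 2 or clusters in
   > 10 % of nuclei, homozygous deletion ≥ 5 %) and cross-tabulated
   against the array calls.

Because the original tumor arrays were never deposited, the package
ships a **synthetic cohort generator** that reproduces the statistical
structure of the study cohort — 46 tumors with segmental amplicons on
chromosomes 7 (50 %), 12 (22 %), 1 (11 %), 4 (9 %), 11 (4 %) and 17
(4 %), homozygous deletions at 9p21 (52 %) and 10q (22 %), expression
linearly coupled to CN for a configurable gene subset, and exponential
survival with a 6.5-fold hazard for carriers of the 4q12 amplicon — plus
the study's published clinical table and 46-gene correlation table as
verbatim fixtures. Every stage is therefore testable end-to-end without
downloads.

Intended users: cancer-genomics analysts who want a small, transparent,
fully scripted re-implementation of this style of amplicon/deletion
analysis, and methods developers needing a ground-truthed simulator of
segmental CN cohorts.

## Worked example

Simulate a 46-tumor cohort at the default (study-condition) event
frequencies, call events, and measure recurrence:

```r
library(gbmcna)

cohort <- generate_cohort(cohort_config(seed = 1))
events <- call_events(cohort$cn)

chr7 <- list(chrom = "chr7", start = 1, end = 158.6e6)
recurrence_frequency(events, chr7, "amplification", cohort_size = 46)
#> # A tibble: 1 × 2
#>   n_cases frequency_pct
#>     <int>         <int>
#> 1      26            57
```

26/46 tumors (57 %) carry a chromosome-7 amplicon in this draw; the
implanted prevalence is 50 %, so single-cohort draws scatter around it
with binomial error (±7 % SE at n = 46). Minimal common regions of the
homozygous deletions, annotated with the bundled synthetic hg17-like
gene models:

```r
mcr <- minimal_common_region(events, "homozygous_deletion",
                             min_cases = 2, cohort_size = 46)
annotate_regions(mcr, load_gene_models())
#> # A tibble: 2 × 6
#>   chrom    start      end n_cases frequency_pct genes
#>   <chr>    <dbl>    <dbl>   <int>         <int> <chr>
#> 1 chr9  20600000 22800000      20            43 IFNA4,...,MTAP,CDKN2A,CDKN2B
#> 2 chr10 88600000 90900000       9            20 ATAD1,PTEN,LIPA,FAS
```

The survival worked example uses the packaged 46-case clinical table:
the four tumors named as 4q12/PDGFRA-amplified form one group, the rest
the other.

```r
table1 <- load_table1_fixture()
grp <- stratify_by_event(table1,
                         positive_ids = c("G12", "G73", "G82", "G88"))
km_median(km_estimate(grp$positive))
#> [1] 2
km_median(km_estimate(grp$negative))   # warns: one case has 0-month follow-up
#> [1] 13
glance(logrank_test(grp$positive, grp$negative, drop_zero_followup = TRUE))
#> # A tibble: 1 × 5
#>   chisq    df  p_value   n_a   n_b
#>   <dbl> <int>    <dbl> <int> <int>
#> 1  12.5     1 0.000397     4    41
```

Median overall survival is 2 months in the amplified group vs 13 months
in the rest, and the difference is highly significant. The published
46-gene dosage table is also packaged and can be re-filtered:

```r
t2 <- load_table2_fixture()
sum(apply_dosage_filter(t2, filter_config(r2_min = 0.70))$passes_filter)
#> [1] 46
```

A thin CLI over the same functions is installed at
`system.file("exec", "cna", package = "gbmcna")` with subcommands
`simulate | call | recur | dosage | survival | ifish | run`.

## Documentation

The methods vignette (`vignettes/cna-pipeline-methods.Rmd`) describes
the model assumptions, the calling and filter thresholds, what the
synthetic generator does and does not emulate, and the numerical
conventions (coordinate system, rounding, tie-breaks, degenerate
inputs).
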
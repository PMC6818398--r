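# TCRcompare

Downstream analysis of bulk TCR-beta CDR3 clonotype tables from **paired
tumor / matched normal tissue** samples, for immunogenomics analysts
working with AIRR-seq-style repertoire data.

Given one clonotype table per sample (CDR3 nucleotide and amino-acid
sequence, V segment, J segment, read count) and a per-patient clinical
table, the package computes the standard paired-repertoire comparison:

* **Clone accounting** — productive-only filtering, unique clones at
  `nt+VJ`, `nt` and `aa` key levels, frequency spectra, highly expanded
  clone (HEC) rates (share of unique clones with frequency > 0.1%), and
  top-N cumulative frequencies;
* **Diversity** — the inverse Simpson index
  `DI = 1 / Σ p_i²`, the effective number of equally abundant clones
  (`DI = N` for a uniform N-clone repertoire);
* **Overlap** — within-patient tumor/normal clonotype sharing at nt and
  aa resolution, with per-tissue denominators
  (`100 · |A∩B| / |A|` for tissue A);
* **V/J usage** — read- or clone-weighted segment and family profiles,
  and paired differential usage (two-tailed paired t-test with a
  fold-change gate: significant iff FC > 1.5 or FC < 1/1.5 and p < 0.05);
* **Cohort statistics** — exact small-sample Wilcoxon signed-rank and
  Mann-Whitney U tests (enumeration-verified), clinical-covariate
  comparisons, and median-DI-stratified Kaplan-Meier survival with the
  log-rank test;
* **Synthetic cohorts** — a seeded generator of paired tumor/normal
  repertoires (Zipf clone abundances flatter in tumor, partial clone
  sharing, skewed TRBV/TRBJ usage, CDR3 lengths 8–23 peaking at 15,
  survival tied to the diversity group) so the whole pipeline is testable
  without any sequencing data.

## Worked example

```r
library(TCRcompare)

cohort <- generatePairedCohort(syntheticCohortConfig(seed = 1))
res <- runPipeline(cohort$repertoires, metadata = cohort$metadata,
                   outDir = "report")

res$summary[c("mean_di_tumor", "mean_di_normal",
              "p_di_wilcoxon", "mean_hec_rate_pct_tumor",
              "mean_hec_rate_pct_normal")]
#> $mean_di_tumor
#> [1] 35.24437
#> $mean_di_normal
#> [1] 13.96127
#> $p_di_wilcoxon
#> [1] 6.103516e-05
#> $mean_hec_rate_pct_tumor
#> [1] 0.2694225
#> $mean_hec_rate_pct_normal
#> [1] 0.3688151
```

Tumor diversity is higher than normal-tissue diversity (35.2 vs 14.0
effective clones; the paired signed-rank p of 6.1e-05 is the exact floor
`2/2^15` for 15 concordant pairs), while the HEC rate runs the other way
(0.27% vs 0.37% of unique clones expanded) — the normal tissue
concentrates more of its repertoire in large clones. `report/` holds one
tidy TSV per stage plus `summary.json` and a parameter-echoing `run.log`.

Individual stages are plain functions over the `Repertoire` container:

```r
rep <- readClonotypeTable("P01_tumor.tsv", dialect = "vdjtools")
inverseSimpson(rep)            # DI, n_unique, key level
hecRate(rep)                   # fraction of unique clones > 0.1 %
overlapRate(repTumor, repNormal, level = "aa")
usageProfile(rep, locus = "V", level = "family")
```

A thin command-line wrapper lives at `inst/scripts/repseq-compare.R`
(`simulate` and `run` subcommands).

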
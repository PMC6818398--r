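---
title: "Comparing paired tumor/normal TCR-beta repertoires"
author: "TCRcompare"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Comparing paired tumor/normal TCR-beta repertoires}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TCRcompare)
```

## The problem

Bulk TCR-beta CDR3 sequencing of a tissue sample yields a *clonotype
table*: one row per unique rearrangement (CDR3 nucleotide sequence, its
translation, the V and J segments used, and a read count that proxies the
clone's size). When tumor tissue and matched distant normal tissue are
sequenced for the same patients, a set of standard questions follows:

* Is the clone-size distribution different between the tissues — in
  particular, the share of *highly expanded clones* (HECs, clones above
  0.1% of reads) and the read mass concentrated in the largest clones?
* Is clonal *diversity* (the inverse Simpson index) different?
* How many clonotypes are *shared* between the two tissues of a patient,
  at nucleotide and at amino-acid resolution?
* Is any V or J segment used differentially between the tissues?
* Do clinical covariates (age, stage, differentiation) associate with
  diversity, and does diversity stratify survival?

TCRcompare implements this downstream analysis as composable, tested
functions over a validated S4 `Repertoire` container, plus a synthetic
paired-cohort generator so that every stage can be exercised and
calibrated without access to patient-level sequencing data.

## The statistics and their conventions

**Productivity filter.** A clonotype is analysed only if its CDR3 is in
frame (nucleotide length three times the amino-acid length) and stop-free.
Failing rows are dropped and tallied, not fatal — mirroring a
productive-only analysis where upstream tools emit mixed tables.

**Clone frequencies and diversity.** With counts $c_i$ and
$p_i = c_i/\sum_j c_j$, the inverse Simpson diversity index is
$DI = 1/\sum_i p_i^2$, the effective number of equally abundant clones.
$DI = N$ exactly for a uniform $N$-clone repertoire, and moving reads from
a rarer to a commoner clone always lowers it (majorization
monotonicity) — both are enforced by tests. The plug-in estimate is used,
without rarefaction or Chao-type correction: at the sequencing depths this
analysis targets the dominant clones that control $\sum p_i^2$ are
saturated, and the plug-in value is what practitioners report.

**HEC rate and spectrum.** The HEC rate is the fraction of *unique*
clones whose frequency strictly exceeds 0.1%. The strict inequality and
the unique-clone denominator are deliberate: reported HEC rates in deep
repertoires are on the order of $10^{-4}$, which is only consistent with
counting expanded clones against $10^5$–$10^6$ unique clones, not against
reads. The frequency spectrum bins unique clones by frequency with edges
in percent (default 0.0001, 0.001, 0.01, 0.1); a clone exactly at an edge
goes to the lower bin so that the top bin coincides with the strict HEC
definition.

**Top-N statistics.** The cumulative frequency of the N most abundant
clones (default N = 100) uses a deterministic tie rule — count
descending, then clonotype key ascending — so repeated runs and platforms
agree byte-for-byte.

**Key levels and overlap.** Clonotypes can be keyed at `nt+VJ`
(finest), `nt`, or `aa` (coarsest; translation is many-to-one).
Re-aggregation only coarsens, sums counts, and preserves totals. Overlap
between the paired tissues is presence/absence intersection of keys, with
a *per-tissue* denominator: $100\,|A \cap B|/|A|$ for tissue A. This
convention makes the tissue with more unique clones show the smaller
rate for a fixed intersection, which is the behaviour reported for
tumor/normal pairs (tumors carry more unique clones and lower overlap
rates). Overlap defaults to plain `nt` keys; V/J-qualified intersection
is available.

**V/J usage.** Usage profiles are read-weighted by default (the share of
repertoire mass carried by clones using a segment); clone-weighted
profiles are available because published analyses do not always state the
weighting. Families are segment names truncated before the sub-family
number (TRBV6-5 → TRBV6), after stripping any allele suffix; family
profiles are exact sums of member-segment profiles. Differential usage
between tissues is a per-segment two-tailed paired t-test across
patients combined with a fold-change gate: a segment is flagged only if
FC > 1.5 or FC < 1/1.5 *and* p < 0.05. No multiple-testing correction is
applied by default (matching how such screens are usually reported); a
Benjamini–Hochberg option exists. A pseudo-frequency floor of $10^{-6}$ —
below any plausibly reported usage — keeps FC finite for segments absent
from one tissue.

**Cohort tests.** The Wilcoxon signed-rank test (paired) and
Mann-Whitney U test (unpaired) are implemented from their defining
formulas so that small-sample p-values are exact and verifiable by
brute-force enumeration: the signed-rank null is enumerated over all
$2^n$ sign assignments (with zeros dropped and midranks for ties) up to
n = 25, and the rank-sum null over all $\binom{n_A+n_B}{n_A}$ labelings
up to a combined n of 20 without ties; beyond that, tie-corrected normal
approximations with continuity correction take over. Two-tailed p-values
are $\min(1, 2\min(P_{\le}, P_{\ge}))$. Both tests are reported for each
paired quantity because published repertoire comparisons have used either
on the same design; the output labels them explicitly.

**Survival.** Patients are split at the median of tumor DI (ties and the
odd-n median go to the "low" group, giving an 8/7 split for 15
patients); Kaplan-Meier curves use the product-limit estimator and the
groups are compared with the standard $O-E$ log-rank chi-square on 1 df.
Right censoring only; no Cox modelling or confidence bands.

## The synthetic cohort generator

`generatePairedCohort()` emulates the study design the analysis assumes.
Per patient:

* a *normal* clone pool and a *tumor* pool that shares a configurable
  fraction of the normal pool (default 15%; sharing is presence/absence —
  abundances are drawn independently in each tissue);
* CDR3s built codon-wise from the 61 sense codons, so every sequence is
  productive by construction; amino-acid lengths follow a discretised
  bell over 8–23 residues with mode 15;
* V/J segments drawn from skewed default profiles over the 46 functional
  TRBV segments (23 families) and 13 TRBJ segments (2 families), headed
  by the segments that dominate bulk TCR-beta data (TRBV11-2 15.25%,
  TRBV29-1 10.08%, TRBV20-1 8.16%, TRBV6-5 7.07%, TRBV12-3 6.81%;
  TRBJ2-1 18.78%, TRBJ2-7 17.58%, TRBJ2-3 11.67%, TRBJ2-5 9.95%);
* Zipf (rank$^{-\alpha}$) clone abundances, flatter in tumor
  ($\alpha = 1.05$) than in normal tissue ($\alpha = 1.25$), multinomial
  read sampling at 5×10⁵ reads over 5×10⁴-clone pools by default;
  clones drawing zero reads are absent from the output, as in real data;
* an age effect (+0.1 on the tumor exponent for patients over 60,
  i.e. lower diversity in older patients), clinical covariates with an
  adenocarcinoma-dominated case mix, and exponential survival with
  hazard ratio 3 for the high-diversity group under independent
  exponential censoring.

The default pool size and depth are roughly a tenth of the unique-clone
counts and read depths of deep tissue repertoires; the *laws*, not the
scale, carry the structure the tests probe. Effect sizes for the
tumor/normal difference are not published as a quantitative model
anywhere, so the defaults are calibrated qualitatively: they reproduce
the reported *directions* (higher DI in tumor, higher HEC rate and top-100
mass in normal, higher overlap rate in normal) with paired significance
across seeds, at desk-scale magnitudes (mean DI ≈ 35 vs 14 rather than
431 vs 166).

What the generator does **not** emulate — and what passing tests
therefore do not certify about real data:

* biophysical V(D)J recombination (insertion/deletion profiles, codon
  bias, convergent recombination). One visible consequence: amino-acid
  level sharing between tissues is essentially equal to nucleotide-level
  sharing in synthetic cohorts, whereas real repertoires show visibly
  higher aa-level overlap driven by convergence. The invariant
  aa ≥ nt sharing still holds, but rarely strictly.
* sequencing error and PCR amplification noise;
* the HEC-rate tissue contrast at *small* scale: with pools of ~2×10³
  clones at 2×10⁴ reads the contrast is lost in sampling noise (the
  steep normal-tissue law loses many rare clones from the unique-clone
  denominator), so it is asserted only at the full default scale.

## Numerical and design choices

* **Boundary conventions**: HEC strictly above threshold; spectrum edges
  close on the lower side; median-split ties go low; top-N ties break by
  key. All chosen once, deterministic, and covered by tests.
* **Zipf exponent 0** is allowed (the uniform limit, useful for
  calibration); negative exponents are rejected.
* **Duplicate table rows** are merged by summing counts rather than
  rejected, since upstream tools aggregate at different levels;
  frequency columns in input files are ignored and recomputed.
* **Degenerate inputs**: all-zero paired differences, empty groups,
  all-censored survival and empty repertoires raise typed errors at the
  function level; the pipeline converts the one case that arises
  routinely in simulation (a quantity identical in every pair, e.g.
  fixed sequencing depth) into an NA rather than aborting the run.
* **Aggregation keeps** columns outside the new key only when they are
  constant within every merged group, otherwise NA — so an aa-level
  repertoire never carries a misleading single V call.
* **Problem sizes** used by the shipped tests: pools of 4×10²–5×10⁴
  clones, depths of 4×10³–5×10⁵ reads, 20 recovery seeds, 40 null seeds;
  these sizes keep a full run in minutes while leaving every assertion at
  the scale where its property is stable.

## A worked run

```{r example, eval = FALSE}
cohort <- generatePairedCohort(syntheticCohortConfig(seed = 1))
res <- runPipeline(cohort$repertoires, metadata = cohort$metadata,
                   outDir = "report")
res$summary$mean_di_tumor      # ~35.2
res$summary$mean_di_normal     # ~14.0
res$summary$p_di_wilcoxon      # 6.1e-05, the exact floor for n = 15
subset(res$differential_v, significant)
```

The `report/` directory then holds tidy TSVs per stage (`metrics.tsv`,
`overlap.tsv`, `usage.tsv`, differential usage per locus,
`cohort_tests.tsv`, `covariates.tsv`, survival tables) plus
`summary.json` and a `run.log` echoing the parameters.

## Known limitations

Beyond the generator caveats above: diversity values are plug-in
estimates and depth-dependent, so cross-study DI comparisons require
comparable depth; the overlap statistic is presence/absence (no
abundance-weighted index such as Morisita–Horn); the differential-usage
t-test is applied per segment without correction by default, exactly
because that is how such results are usually reported — switch on the
BH option for a conservative screen; and the survival stratification is
a two-group log-rank without covariate adjustment, appropriate for
15-patient cohorts but not a substitute for regression at scale.
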
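---
title: "Methods: screening-cascade classification, founder-variant association and the translocation scan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening-cascade classification, founder-variant association and the translocation scan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmrscreen)
```

## What this package models

Universal tumour screening for Lynch syndrome (LS) stains every colorectal
tumour for the four mismatch-repair (MMR) proteins MLH1, MSH2, MSH6 and
PMS2. A tumour that has lost staining is MMR-deficient (dMMR), and the
deficiency has a small set of possible causes: somatic hypermethylation of
the *MLH1* promoter (MLH1-hm), a germline LS mutation (with a somatic second
hit in the tumour), two somatic hits without any germline mutation
("double somatic"), or — rarely — nothing identifiable. `mmrscreen`
implements the full decision cascade that assigns one of these etiologies to
every case, the diagnostic-performance and prevalence arithmetic built on
top of it, the case-control logistic machinery used to estimate cancer risks
for rare founder mutations, and a discordant read-pair scanner able to find
a germline translocation that disrupts an MMR gene without any point
mutation.

## The screening cascade

**IHC scoring and panels.** Stains are scored present, absent, or
weak-but-present; a weak stain must be backed by a percent-positive
annotation above 1%, and a stain without a positive internal control carries
no information. Resections receive the four-protein panel. Biopsies start
with MSH6 and PMS2 only: the MMR proteins work as heterodimers
(MLH1–PMS2, MSH2–MSH6) whose obligate partners degrade when the primary is
lost, so an intact PMS2 certifies MLH1 and an intact MSH6 certifies MSH2.
Reflex stains are added only when a partner is lost. For the same reason a
case whose MSH6 and PMS2 stains are both scored (directly) is treated as
fully informative even when MLH1/MSH2 were never stained; `incomplete` is
reserved for cases where the informative stains themselves are missing.

**Loss patterns** follow the dimer biology: MLH1 loss presents as
MLH1/PMS2, MSH2 loss as MSH2/MSH6, and isolated MSH6 or PMS2 loss points at
the secondary partner itself. Weak stains count as present for pattern
purposes and are carried as a flag — the weak-stain LS cases are exactly the
ones a pattern-only reading would miss.

**Methylation.** The pyrosequencing assay reports per-CpG methylation
percentages; the test value is their arithmetic mean and the call is
positive at **≥ 15%**, inclusive. The assay description averages the sites
into a single reaction-level value, so the threshold is applied to the mean
rather than per site; this is an interpretation, recorded here, and the
threshold is configurable (`screening$methylation_threshold`).

**BRAF-V600E reflex.** When methylation testing fails on a biopsy (too
little DNA), positive BRAF-V600E IHC substitutes as evidence of sporadic
hypermethylation. The work-up data also contain a case rescued by BRAF at a
*tested* methylation level of 14% — one point under threshold — so the
reflex additionally fires on negative results within
`screening$braf_rescue_margin` (default 2) percentage points of the
threshold when BRAF is positive. The margin is the smallest round value
consistent with that case and is configurable.

**Tumour sequencing.** Somatic work-up of the remaining dMMR cases uses
three rules:

* *MSI call:* the instability score is the fraction of assayed
  microsatellite loci that are unstable; the call is MSI-high at
  **≥ 0.2**, inclusive. The source material prints scores and calls but no
  cut-off; 0.2 is the published convention for this score type and cleanly
  separates the printed MSS maximum (0.1587) from the MSI-H minimum
  (0.2188). Configurable as `somatic$msi_threshold`.
* *LOH banding:* for a germline heterozygous variant whose wild-type allele
  is lost in the tumour, every cell contributes one variant allele and only
  normal cells contribute reference alleles, so the expected variant allele
  fraction at purity $p$ is $1/(2-p)$. The observed/expected ratio is
  banded: ≥ 0.95 definite, ≥ 0.85 likely, ≥ 0.60 maybe, else none. The
  bands were chosen so that a balanced heterozygous VAF (ratio 0.5) is
  never called, a near-saturated VAF at high purity is definite, and a
  VAF of 0.60 at purity 0.6 (ratio 0.84) lands in the maybe band —
  the configuration that reproduces the printed likely/maybe annotations.
  Configurable as `somatic$loh_bands`.
* *Resolution:* a tumour is **solved double somatic** with two
  pathogenic/likely-pathogenic somatic hits in one gene, or one hit plus
  LOH graded at least likely; **possibly double somatic** with one hit and
  maybe-grade LOH. A qualifying germline mutation pre-empts the somatic
  verdict: with a somatic second hit (mutation in the same gene or
  likely-or-better LOH) the case is LS; without one, the carrier developed
  a sporadic tumour. "Pathogenic" means class 4/5, predicted truncation,
  or designation by study-level evidence; a plain class-3 variant
  qualifies as the germline hit only when the tumour shows a second hit —
  the same second-hit logic that justifies upgrading such variants.

**Cascade order.** Normal/incomplete patterns resolve first (carrier with
tumour evidence → LS or sporadic-tumour-in-carrier; otherwise proficient).
MLH1/PMS2 loss checks methylation (direct or BRAF-inferred) before
anything germline — hypermethylation explains the overwhelming majority of
that pattern. Remaining patterns look for a concordant-gene germline hit
(MSH2/MSH6 pattern → MSH2 or MSH6; isolated MSH6 → MSH6; isolated PMS2 →
PMS2 or MLH1, the partner pairings of the dimers), then fall through to the
somatic resolution, then to unexplained.

**Screening metrics.** Sensitivity/specificity/PPV/NPV are computed on the
genotyped subset only, since germline truth is unknowable elsewhere.
*Screen positive* is an abnormal stain pattern **not explained by
MLH1-hm**: hypermethylated tumours are true sporadic findings that the
screening programme correctly sets aside, and this is also the only
definition under which the four published percentages are simultaneously
consistent (21/27, 905/926, 21/42, 905/911). Sporadic-tumour carriers
count as LS (they are carriers the programme wants to find). Percentages
are rounded half away from zero to one decimal at report time only; all
internal arithmetic is full precision.

## The synthetic cohort and the fixture

`generate_cohort()` draws per-etiology counts (multinomial, or
largest-remainder apportionment in exact mode) and builds cases whose
stain/methylation/variant evidence is consistent with their etiology, so
that the cascade round-trips the configured mixture exactly. Defaults are
the study conditions: 1,182 cases mixed 1044/27/90/16/5, 78.2% of
normal-IHC cases genotyped, founder carrier frequencies 0.234%/0.092%/
0.080%, a one-third weak-stain rate among MSH6-mutation LS cases (3 of 9
in the study), and two sporadic-tumour carriers. Ages, sex, stage and
location are decorated from the per-etiology descriptive distributions and
are never read by the classifier.

`fixture_cohort()` is deterministic and reproduces the published marginals
cell by cell, including all 30 tumour-sequencing work-up rows as somatic
profiles. Two joint assignments are under-determined by the published
tables and were fixed as follows: the PMS2 frameshift carriers split 9
abnormal + 3 normal-IHC and the MSH6 p.Leu585Pro carriers 6 abnormal + 3
weak-stain, with the private MSH6 mutations split 1 isolated-MSH6 + 2
MSH2/MSH6 — the only assignment consistent with the pattern-by-etiology
cross-tab row totals. The sixth normal-IHC LS case, whose gene the tables
do not name, is assigned the PMS2 frameshift (the most frequent founder
allele); this is an assumption, flagged here. The possibly-double-somatic
case with isolated MSH6 loss but an MSH2-gene somatic hit is attributed to
MSH6 (its stain pattern) in the gene-share report; that attribution is the
only one consistent with the published 13/16 MLH1+MSH2 share, and reflects
that stain loss, not the candidate hit, names the deficient protein.

What the generator does *not* emulate: pedigree structure, genotyping
error, stain-interpretation noise, tumour-content variation, or any
correlation between etiology and demographics beyond the printed
marginals. Green tests therefore certify the decision logic and the
arithmetic, not robustness to noisy real-world inputs.

## Association and penetrance

Case-control fits use maximum-likelihood logistic regression
(`stats::glm`, binomial). With 0/1 carrier dosages the identical binomial
likelihood is fitted on the aggregated 2×2 counts, where the ML odds ratio
equals the cross-product ratio; confidence intervals are Wald (the
convention for GWAS-style output), and complete separation returns a
flagged estimate with an infinite bound rather than an error. Inflation
correction divides the χ² statistic by a per-trait LD-score-regression
intercept shipped as a 17-trait configuration table; the package does not
estimate these factors. The 16-test Bonferroni threshold is α/m.

Rare-variant simulation is retrospective: carrier status is drawn given
the fixed case/control totals, with carrier odds among cases equal to
control carrier odds times the true OR — the case-control duality of the
logistic model — because the published designs fix those totals. At the
sparsest published designs the expected carrier-case count is in the
single digits, which makes the median of the OR estimate count-discrete;
parameter-recovery checks therefore use 1,000 replicates (the median is
stable there, and the estimand is unchanged).

Odds ratios convert to carrier lifetime risks on the odds scale by
default — carrier odds = OR × baseline odds, the scale on which logistic
estimates live — with `1-(1-K)^OR` available as a hazard-scale
alternative. The registry baselines behind the published risk columns are
not printed anywhere, so those columns are reproducible only conditional
on user-supplied baselines; the package asserts instead that the
conversion is exact under inversion (to 1e-9 away from floating-point
saturation) and strictly monotone in both arguments.

## The translocation scan

Reads are taken from the gene ± 100 kb, then filtered: mapping quality 0
or mean PHRED base quality ≤ 25 (inclusive) drops a read. The library
fragment distribution is estimated from same-chromosome FR pairs with
1%/99% quantile trimming (an addition, to resist contamination from
mis-paired reads; up to 100,000 pairs). A read is discordant when its mate
is unaligned or on another chromosome, the pair orientation is not FR, or
the pair span deviates from the mean insert by more than three standard
deviations — evaluated in that order. Discordant pairs cluster by
single-linkage when within `max_gap` (default 500 bp) on *both* sides;
clusters die if they overlap a user-supplied repeat mask, have fewer than
`min_support` pairs (default 3 — a floor standing in for the manual
curation step), or appear in more than 1% of a control catalogue.
Translocation calls are made from interchromosomal clusters only:
same-chromosome discordance classes (orientation, insert size) are flagged
but belong to other SV types.

Breakpoints come from soft-clipped reads: the modal clip boundary per side
and direction (ties toward the smaller coordinate) gives the last/first
retained base on each chromosome, and the four boundaries determine the
target-site anatomy — overlap on a side is a duplication present on both
derivative haplotypes, a gap is a deletion missing from both. Clipped
tails are aligned to the partner reference at the opposing junction with a
mismatch-minimising offset (mismatch fraction ≤ 0.25, at least 8 aligned
bases); the unaligned prefix is the inserted motif, and both strands of
both references within 200 bp of the breakpoints are searched to decide
whether it was templated in reverse-complement orientation. With no
spanning soft-clips the call degrades to cluster-interval resolution with
the anatomy unset rather than guessing.

The read simulator emits FR pairs from both derivative chromosomes plus
concordant background from the unrearranged references (a heterozygous
carrier's normal haplotypes); junction-crossing reads are soft-clipped by
construction with the clip placed at the junction. Because alignment is
simulated rather than recomputed, base-calling errors perturb the
inserted-motif inference but not clip placement; the error-rate tests
accordingly exercise the sequence-matching stages.

## Numerical and testing choices

Problem sizes were chosen so the full suite runs comfortably on one CPU:
references of a few kb at depth 15–30 for scanner tests (100 seeds for the
null-scan check), 1,000 replicates per published design for parameter
recovery, and population simulations of ≤ 240,000 individuals. Report-time
rounding is half away from zero, one decimal. All generators take explicit
integer seeds and are byte-reproducible.

Known limitations: the classifier consumes abstracted stain calls, not
images; MSH2 promoter methylation is a categorical pass-through; the
scanner handles reciprocal two-chromosome translocations in gene
orientation (no inversions of the translocated segment, no copy-number
inference); and the possibly-double-somatic gene attribution rule is a
reporting convention, not a biological claim.
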
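---
title: "Methods: paired-compartment triage of clonal hematopoiesis"
author: "chtriage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired-compartment triage of clonal hematopoiesis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chtriage)
```

## The problem and the model

Plasma cell-free DNA (cfDNA) of a cancer patient is a mixture of
tumor-derived and hematopoietic fragments. A somatic mutation carried by an
expanded blood clone — clonal hematopoiesis (CH) — is present at matched
allele fraction in both the white-blood-cell compartment (PBL) and cfDNA,
while a tumor-derived mutation is essentially cfDNA-only and a germline
variant sits near 50% VAF in both. The triage exploits exactly this
compartment structure. Writing $(a, b)$ for alt/ref read counts in cfDNA
and $(c, d)$ in PBL, the implicit generative model is binomial sampling of
reads at a true per-compartment allele fraction; the null hypothesis "same
allele fraction in both compartments" is tested by Fisher's exact test on
the 2×2 count table. CH candidacy requires both a non-significant test
($p \ge$ `ch_min_p`) and a sample odds ratio inside an explicit window
(`ch_or_low`, `ch_or_high`) around 1, so the call is a *consistency*
criterion rather than a mere failure to reject.

The decision procedure is ordered and exhaustive: cfDNA-only variants go
down the somatic branch with its depth/VAF/population-frequency filters;
PBL variants at ≥ 20% VAF are germline (retained only when ClinVar calls
them pathogenic — the package deliberately applies no population-frequency
rule here because the class is consumed only as a label for downstream
cross-tabulation); PBL variants below 20% VAF at depth ≥ 30× enter the
paired test; low-depth PBL variants are set aside as unclassifiable. Two
outcomes are defined by neither candidate rule: significant *PBL-enriched*
counts, and non-significant counts with an odds ratio outside the window.
Both become `DISCORDANT_DISCARD` with an explicit reason rather than being
silently folded into a class; calling them CH would contradict the test's
own logic, and calling them somatic is stated only for the
cfDNA-enriched significant case.

## Thresholds

| parameter | default | meaning |
|---|---|---|
| `somatic_min_depth` | 100 | minimum cfDNA depth (×) for a somatic call |
| `min_alt_reads` | 2 | alt-read floor (cfDNA for somatic; both compartments for CH) |
| `somatic_min_vaf` | 0.003 | minimum cfDNA VAF (fraction) |
| `max_pop_maf` | 0.002 | gnomAD/ExAC MAF ceiling; unknown MAF counts as 0 |
| `germline_min_depth` | 30 | PBL depth (×) to evaluate the germline/CH branches |
| `germline_min_vaf` | 0.20 | PBL VAF at or above which a call is germline |
| `ch_min_p` | 0.05 | Fisher p floor for CH candidacy |
| `ch_or_low`, `ch_or_high` | 0.5, 1.5 | open OR window for CH candidacy |
| `carrier_ratio_max` | 0.0025 | carrier-ratio ceiling for recurrent artifacts |

Boundary semantics are literal: "not smaller than" thresholds are `>=`,
the 20% germline VAF cut is strict `<` on the CH side, the OR window is
open at both ends, and a carrier ratio exactly at the ceiling is retained.
The dbSNP/COSMIC and HLA filters belong to the somatic branch only. The OR
window is evaluated on the sample cross-product estimate with a
Haldane–Anscombe 0.5 added to every cell when any cell is zero; the
conditional-MLE OR is computed and reported alongside but does not gate any
rule — the two estimands differ noticeably in small tables, and rules that
consume one are documented as such.

## Exact-test conventions

The two-sided p-value is the point-probability ("sum of less-likely
tables") definition, with point probabilities compared under a relative
tolerance of 1e-7 so floating-point ties land on the inclusive side — the
convention of the standard statistical implementations this field uses.
The conditional MLE of the noncentral hypergeometric odds ratio solves
$E[a \mid \text{margins}, \psi] = a$ by bisection on $\log\psi$ to a
relative tolerance of 1e-8, returning 0 and $\infty$ at the ends of the
support. An independent enumeration oracle (`fisher_oracle`, log-gamma
arithmetic, no shared code with the `dhyper`-based implementation) exists
for verification; the test suite sweeps randomized tables against it and
against `stats::fisher.test`. Pearson correlation and Benjamini–Hochberg
adjustment delegate to `stats::cor` and `stats::p.adjust`.

## The cohort funnel

Candidate CH flows through three filters, once each, in a fixed order:
the min-alt-read rule, the carrier-ratio filter, and the matched-tumor
crosscheck. The carrier-ratio denominator — patients with at least one
candidate after the min-alt rule — is computed once and not iterated after
removals; iterating to a fixed point would progressively shift the
denominator and make the filter's meaning depend on its own output. Stage
counts satisfy the conservation identity
`candidates_in = ch_final + removed_min_alt + removed_carrier_ratio +
removed_tumor`, asserted in the tests and echoed in every run summary.
Note the scale-dependence of the carrier-ratio filter: at 0.25%, a cohort
needs at least 400 CH-positive patients before even a private (single
carrier) variant can survive. The filter is a large-cohort instrument and
`ch_pipeline()` applies it as specified regardless of cohort size.

## Cohort analytics choices

* **Age bins** are right-closed, `[0,40], (40,50], …, (90,∞)`; the
  correlation uses the equally spaced group index as the x-variable
  (midpoints give the identical r for equal spacing), with empty groups
  excluded and r undefined below three nonempty groups.
* **Prevalence comparison** reports the prevalence *ratio*
  $(c_A/t_A)/(c_B/t_B)$ and the Fisher result on the carrier 2×2 as two
  distinct, separately named quantities — they are close for rare carriers
  but are different estimands, and conflating them is a known source of
  confusion in cohort reports.
* **Preferred classes**: a polymorphic CH mutation (CH in ≥ 1 patient,
  germline or somatic in ≥ 1 other) takes the class holding a strict
  majority of its patient-level determinations; gene labels derive from
  labeled mutations only, and ties — equal germline- and somatic-preferred
  counts with CH-preferred present — stay unlabeled because no rule covers
  them. Occurrences are patient-level: one determination per patient per
  variant per class.
* **Actionable overlap** matches on genomic position and alternate allele
  exactly (no ref check beyond the key, no proximity window). The per-gene
  concentration test compares the gene distribution of hit patients with
  that of CH-positive non-hit patients; this definition is the package's
  own and is stated in the function documentation.
* **Gene-set over-representation** takes user-supplied GMT collections and
  an explicit background; no ontology content ships with the package.

## The synthetic cohort: what it emulates, and what it does not

The generator reproduces the statistical structure the triage assumes, with
defaults fixed at the study conditions the pipeline was designed around:

* ages uniform on 30–90; P(carrier) logistic in age with intercept −2.23
  and slope 0.0338 — obtained by fitting the logistic curve to a published
  pan-cancer age-prevalence reference (≈ 26% below 40 rising to ≈ 71%
  above 90) and then frozen;
* CH burden per carrier: 1 with probability 0.60, 2 with 0.25, geometric
  tail beyond; shared blood VAF log-uniform on [0.005, 0.20);
* two germline variants per patient, VAF ~ Beta(50, 50); three somatic
  variants, cfDNA VAF log-uniform on [0.003, 0.30], tumor VAF 10× capped
  at 0.5, true PBL VAF 0;
* depths Poisson with means 200× (PBL) and 1000× (cfDNA, tumor); alt reads
  binomial at VAF + e(1−VAF), e = 0.001; a zero-alt-read compartment is
  "not called" there;
* three recurrent artifact variants, each planted in 2% of CH carriers —
  recurrence is the artifacts' role: true CH sites are drawn from a pool
  large enough (5 × 10⁵) that chance recurrence is negligible at these
  cohort sizes, mirroring the observed structure that real candidate CH
  overwhelmingly sits below the 0.25% carrier ceiling;
* the actionable knowledge base is a random subset of planted CH sites, so
  overlap analytics have signal.

Not emulated: UMI/duplex error structure and sequence-context-specific
artifacts (the planted artifacts are statistical, not mechanistic),
overdispersed counts (a beta-binomial `dispersion` knob exists, default
off, because the exact test's model is plain binomial), indels and their
normalization, real panel footprints, tumor fraction dynamics, and any
linkage between CH burden and cancer type. Passing recovery tests
therefore demonstrates correctness of the decision logic under its own
model, not robustness to the full error structure of real panel data.

Problem sizes in the tests and acceptance runs — 2000 patients per seed,
ten seeds, one 4000-patient age-trend check — were chosen as the smallest
cohorts at which the carrier-ratio filter and the age trend are
well-behaved (see the scale note above).

## A known limitation: the OR window at low VAF

With PBL at 200× mean depth, a CH variant at 2% VAF yields ~4 alt reads in
PBL; the sample OR then has $\mathrm{sd}(\log \mathrm{OR}) \approx 0.5$, so
even under the exact null the estimate falls outside $(0.5, 1.5)$ for a
substantial fraction of true CH, and near the 20% VAF boundary some true CH
routes to the germline branch. The recovery metrics computed by
`scripts/acceptance.R` quantify this: high-VAF (≥ 2%) CH sensitivity is
about 0.81 under the default conditions, while somatic-to-CH leakage stays
near 0.002, germline-to-CH at 0, and artifact removal at 1.0. The
sensitivity loss is a property of the published decision rule at these
depths, not of this implementation — raising PBL depth or widening the OR
window recovers it, at the cost of leaving the published operating point.

## Degenerate inputs and determinism

All-zero 2×2 tables error; zero-depth compartments are filtered with an
explicit reason, never a crash; empty cohorts, empty candidate sets, empty
gene panels and header-only files return empty, well-typed results.
The analysis path is fully deterministic — identical inputs and thresholds
give byte-identical output tables — and all randomness lives in the
simulator behind a single recorded seed. Variant identity is the exact
four-field key (chrom, pos, ref, alt); inputs are assumed left-aligned and
normalized upstream, and no liftover or re-normalization is attempted.
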
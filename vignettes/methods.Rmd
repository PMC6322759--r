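---
title: "Methods: variant triage and carrier-burden testing on a cardiac gene panel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: variant triage and carrier-burden testing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Scope and model

`cardioburden` analyses annotated single-nucleotide variant observations
from a case cohort screened on a 70-gene cardiac panel (23 channelopathy,
47 cardiomyopathy genes). It does not call variants, compute CADD or
conservation scores, or query ClinVar/HGMD: those enter as pre-computed
columns and boolean evidence flags, which keeps the triage engine
deterministic and auditable. The analysis chain is

triage → case-level carrier aggregation → exact burden comparisons →
(optionally) Monte Carlo permutation of pathogenic proportions.

## Triage rules and precedence

Filters run in a fixed order and the first failure records the fate:

1. **Frequency filter.** A variant is excluded if any reference-population
   MAF exceeds `maf_exclusion_threshold` (default 0.01). Missing
   frequencies never exclude: absence from a reference catalogue is
   evidence of rarity, not commonness. A configuration switch
   (`any_population_excludes = FALSE`) instead requires all non-missing
   populations to exceed the threshold; the default is the strict reading.
   An input MAF above 0.5 is rejected as not being a *minor* allele
   frequency.
2. **Consequence filter.** Synonymous variants are excluded, as are
   intronic variants not predicted to affect splicing. An intronic variant
   with a splice-prediction hit is retained and reclassified `splice_site`,
   making it loss-of-function downstream.
3. **Classification.** Precedence LoF/evidence > benign > VUS:
   loss-of-function (nonsense, frameshift, splice site) or evidence-backed
   variants (prior reports in affected individuals, functional studies) are
   *putative pathogenic*; an unsupported missense that is both at a poorly
   conserved position **and** has scaled CADD < `cadd_low_threshold` is
   *likely benign*; everything else is a *VUS*. The benign rule is a
   conjunction: requiring both signals keeps the benign call conservative.

"Low CADD" has no canonical definition; the default threshold 10 marks the
top-10% rank cutoff of the phred-like scaled score
(`cadd_rank_fraction(10) = 0.1`) and is deliberately low so that only
clearly unremarkable missense variants can be dismissed.

### Simplified ACMG class

Clinical five-tier ACMG classification needs criteria (segregation, de
novo status, per-variant literature) that are not recomputable from the
annotation columns, so the package uses the two tiers that occur in this
setting: 3 (uncertain significance) and 4 (likely pathogenic). The default
rule assigns class 4 to loss-of-function variants with no prior disease
report and class 3 otherwise. Curated tables are not always consistent
with any mechanical rule (e.g. a known stop-gain may be class 3 because of
a nonzero population frequency, while a frameshift with similar frequency
is class 4), so a per-row published class, when present in the input,
overrides the rule and the override is recorded in the decision trace.
Output flagged by `acmg_published_override` should be read as "curator
wins over heuristic".

## Carrier aggregation and burden tests

A **carrier** is a case with at least one retained putative-pathogenic
variant; counting is by distinct case, and a case with variants in both
disease categories counts once overall but in both category totals. On the
allele scale a heterozygote contributes one alternate allele and a
homozygote two, over `2N` chromosomes.

Reference populations provide only frequencies, so reference carrier
counts are **expected** counts under a one-carrier assumption: no
reference individual carries more than one of the cohort's variants, i.e.
`E = round(sum_v MAF_v × 2N)`, each distinct variant counted once, capped
at N. The sum is rounded to the nearest integer before table construction
(a contingency table needs integer cells). This assumption is safe for
rare variants (sum of MAFs ≪ 1) and errs upward — it maximises the
reference carrier count and is therefore conservative for the cohort-
enrichment comparison. Where a genotype-derived carrier count for a
population is known, it can be supplied directly (`ref_carriers`) and
overrides the MAF sum.

All 2×2 comparisons use a **two-sided Fisher's exact test** with the
point-probability rule: p is the total probability of tables in the
hypergeometric support whose point probability does not exceed that of the
observed table, with a `1e-7` relative tolerance guarding against
floating-point ties. This matches mainstream implementations; note that
published p-values computed under other two-sided conventions (e.g.
doubling the smaller tail) can differ for skewed margins. Probabilities
are accumulated from log-scale hypergeometric densities for numerical
stability at allele-scale denominators (~10^5). The odds ratio is the
sample cross-product `(ad)/(bc)`, `Inf` when only the denominator product
is zero, `NaN` when both are. A gene-level allele comparison with zero
alternate alleles on both sides is refused as degenerate (there is nothing
to compare).

The gestational-age comparison is a goodness-of-fit chi-square of the
carrier bin counts against expectations scaled from the complete cohort
(`E_i = n_carriers × all_i / all_total`, statistic `Σ(O−E)²/E`, `bins − 1`
degrees of freedom); an expected zero cell is an error advising bin
merging. Sex uses the exact 2×2 test. Gestational ages parse from
`weeks+days` notation; the token `full_term` maps to 40 weeks by
convention (term ≥ 37 weeks; 40 is the midpoint of term deliveries), and a
case recorded twice with discrepant ages resolves to its first row
(`case_table()`).

## Permutation comparison

`permute_proportions()` draws `sample_size` variants (default 50) from
each of two cohorts per iteration (default 10,000 iterations) and reports
the mean pathogenic proportion per cohort. Sampling is **without
replacement** within an iteration — the natural reading of "randomly
selected variants" — with a with-replacement switch. Draws are independent
between cohorts (unpaired). The cohort's flag vector is indexed after a
canonical sort by variant key, so results at a fixed seed are invariant to
input row order. As a labelled extension the result also reports the
fraction of iterations in which cohort A's pathogenic count exceeds
cohort B's; it is descriptive, not a calibrated test. The expected mean
proportion equals each cohort's true pathogenic fraction (the
hypergeometric sample proportion is unbiased), which is what the
property tests assert.

## Gene panel choices

Some panel genes have disease associations spanning both families (PKP2
is ARVC- and Brugada-associated). A gene takes the single category of its
row in the panel file, and `load_panel(category_override = ...)` reassigns
symbols without editing the file — exposed rather than hard-coded because
category assignment for such genes is a curation decision, not a fact
derivable from the association codes. Symbols are compared after
uppercasing; no alias resolution is attempted (the panel is closed and
small).

## Synthetic data: what it emulates and what it does not

`simulate_cohort()` generates the stated world of the packaged cohort:
290 cases, carrier prevalence 0.12, a second variant for 4/35 of carriers,
23/35 of pathogenic variants in channelopathy genes, reference MAFs
log-uniform on [1e-5, 10^-2.3] (0.001%–0.5%, safely under the 1% filter),
plus decoys — VUS (Poisson, mean 0.5/case), likely-benign, synonymous and
5%-MAF common variants — that the filters must remove. Pathogenic variants
are constructed to classify as putative pathogenic by design (evidence
missense or LoF), so truth recovery is exact by construction and asserted
per run; gestational age and sex are association-free (uniform weeks
22–41, Bernoulli(0.5)) since no demographic association is being modelled.
All variants are heterozygous and keys are distinct across cases;
recurrent variants, homozygosity, linkage and population stratification
are **not** emulated. A green synthetic test therefore establishes that
the pipeline recovers a known signal under clean sampling assumptions, not
that those assumptions hold in real cohorts.

`end_to_end_recovery()` aligns the simulator's null with the burden test's
null: the reference carrier count is `round(prevalence × ref_n)` under the
same one-carrier convention, so with `enrichment = 1` the rejection rate
estimates the test's empirical type-I error (Fisher's exact test is
discrete and mildly conservative; rates slightly off 0.05 in either
direction at 200 replicates are expected, and the acceptance band is
[0.02, 0.08]).

## Known limitations

- Evidence flags are inputs; the triage is only as good as the curation
  that produced them.
- Expected reference carriers inherit any error in catalogued MAFs, and a
  small cohort overestimates the MAF of singletons — a cohort-vs-reference
  comparison at n ≈ 290 has wide uncertainty on per-variant frequencies.
- No multiple-testing correction is applied anywhere (none is part of the
  analysis being reproduced); interpret per-gene and per-variant p-values
  accordingly.
- The simplified two-tier ACMG mapping is a stand-in for full clinical
  classification and is flagged as such in the decision trace.
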
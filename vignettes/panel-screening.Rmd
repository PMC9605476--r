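---
title: "Methods: candidate-gene panel screening for tooth agenesis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: candidate-gene panel screening for tooth agenesis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelscreen)
```

## The analysis this package implements

Non-syndromic tooth agenesis (ns-TA) — the congenital absence of one or
more permanent teeth, third molars excluded — is one of the most common
dental anomalies, classified as hypodontia (1–5 missing teeth) or
oligodontia (6 or more). Targeted panel sequencing of candidate genes in a
case/control cohort is a standard study design for it: rare coding variants
in the cases are filtered down to a pathogenic/likely-pathogenic set by a
rule cascade, carriers are phenotyped tooth by tooth, and common variants
in the implicated genes are tested for case/control association.

`panelscreen` implements that full analysis as reusable, tested components:

1. **Filtering cascade** (`run_cascade()`): rarity filter, likely-gene-
   disrupting rules with an in-silico consensus vote, gene-level
   prioritization and pathogenicity labelling, with a per-variant audit
   trail.
2. **Dentition accounting** (`count_missing()`, `classify_agenesis()`,
   `carrier_phenotype_summary()`, `detect_oligogenic()`): FDI-coded
   missing-teeth sets, carrier summaries and multilocus co-occurrence.
3. **Association** (`cochran_armitage()`, `allelic_odds_ratio()`,
   `trend_scan()`): Cochran–Armitage trend test, allelic odds ratios and
   Bonferroni control.
4. **Synthetic cohorts** (`simulate_cohort()`): a seeded generator with
   known ground truth so every stage is testable without patient data.

The package ships fixture tables (`ps_fixture()`) encoding a published
27-variant screen of a 65-case / 127-control cohort, so the whole pipeline
runs offline.

## The filtering cascade and its thresholds

A variant enters the retained set by passing three stages; every stage
records pass/fail/exempt plus a human-readable detail in the audit trail.

**Stage 1 — rare and non-synonymous.** Synonymous (and unclassified
"other") variants always fail. Otherwise the variant passes when its
population frequency (gnomAD European non-Finnish, `af_nfe`) is *strictly
below* `maf_threshold` (default 0.001). An absent frequency means the
variant was never observed in the reference population and passes. Genes on
the `exempt_genes` allowlist (default `WNT10A`) pass this stage regardless
of frequency: for a gene in which common hypomorphic alleles are
established risk factors, a rarity filter would discard exactly the alleles
of interest.

**Stage 2 — likely gene disrupting.** Stop-gain, stop-loss and frameshift
variants qualify unconditionally. Splice variants qualify when their ADA
splice-impact score is present and at least `ada_threshold` (default 0.9,
`>=`). Missense variants qualify when CADD is present and strictly above
`cadd_threshold` (default 20) *and* at least `vote_rule` (default one half)
of the available in-silico verdicts call the variant damaging. ADA is
applied only to variants classified as splicing, not to missense variants
with incidental splice predictions.

**Consensus vote.** Sixteen predictors are scored in a fixed order. A tool
counts as damaging when *any* of its verdict tokens is in {D, Dc, P};
multi-token verdicts such as "T, D" therefore count damaging. The
denominator is the number of tools that produced a verdict, not 16: several
fixture variants have only 12–13 verdicts, and a fixed denominator would
conflate "no prediction" with "benign". Both choices are forced by the
fixture data: with any-damaging counting the LRP6 p.Asp543Glu row reaches
exactly 8/16 — retained under "at least half" — while benign-biased
counting would discard a variant the screen keeps. A vote with zero
available verdicts cannot pass (truncating variants do not need it).

**Stage 3 — prioritization.** The gene must be an established ns-TA risk
gene (`known_ta`), have a documented role in odontogenesis, or carry a pLi
score of at least `pli_threshold` (default 0.95). Category and pLi are
disjunctive: a known risk gene with pLi 0.00 (e.g. *LAMA3*) is still
prioritized.

**Exemptions are flagged, never silent.** Passing the rarity stage through
the gene allowlist is part of the printed selection criteria and still
counts as a strict pass (the nonsense variant WNT10A p.Cys107Ter, at
frequency 1.6e-3, is such a case). A variant-level exemption flag is set
only when the allowlist rescues a variant that fails a *downstream* stage —
in the fixtures exactly WNT10A p.Arg113Cys, whose CADD of 16.2 fails the
missense rule. Variants retained by expert judgement against the rules
(fixture: TP63 p.Pro532Ala, CADD 18.8, vote 7/16) are configured explicitly
via `manual_exceptions`, never hard-coded, and are retained unconditionally:
a judgement call is a judgement call, the engine does not second-guess
which rule it violated. On the fixtures this yields 25 strict passes plus 2
flagged exemptions = 27 retained variants.

**Labelling.** Retained variants are `pathogenic` when ClinVar reports them
pathogenic/likely-pathogenic or HGMD lists them as disease mutations, else
`likely_pathogenic`. A ClinVar *uncertain significance* record does not set
the flag; the conflict stays visible in `db_note`. The fixture LAMA3
p.Glu306Ter is therefore labelled likely-pathogenic with its VUS note
attached, because the evidence that drove any stronger published label is
not stated in the source material.

## Dentition accounting

Teeth are addressed by two-digit FDI codes (quadrant 1–4, position 1–8).
All summary counts exclude third molars by default — every printed cohort
statistic does — and the flag is overridable per call. Peg-shaped
(microdont) teeth are *present* teeth: they are carried in their own column
and never counted as missing. Agenesis severity is derived solely from the
third-molar-excluded count (0 none, 1–5 hypodontia, ≥6 oligodontia), so any
case cohort partitions exactly into hypodontia and oligodontia.

Tooth-class tallies pool the four quadrants (12, 22, 32 and 42 are all
lateral incisors); the maxillary/mandibular split is kept available as a
separate view rather than baked into the class counts, since published
summary tables pool jaws while the running text sometimes distinguishes
them.

`carrier_phenotype_summary()` supports an *exclusive* mode restricting to
subjects whose only retained variants match the selector — this is how
"patients harbouring only the recurrent missense variant" summaries are
formed. Exclusive summaries are by construction sub-summaries of the
inclusive ones. Family-history rates keep unknown entries in the
denominator (yes / all subjects), matching how the reproduced cohort
percentages were computed (11/18 = 61.11%).

`detect_oligogenic()` reports every subject with two or more retained
variants: `cross_gene` when at least two genes are involved (the signature
of possible oligogenic inheritance), `same_gene_multi` for multiple
variants of one gene (e.g. compound heterozygotes).

## Association stage

The Cochran–Armitage trend test is computed from its closed form with
additive scores (0, 1, 2); the scores are configurable but defaulted, and
the statistic is invariant under affine score transformations. The p-value
is the upper tail of the 1-df chi-square distribution — two-sided in the
usual sense for this statistic; the reproduced study does not state
sidedness. Degenerate tables (all subjects in one genotype class) return
chi-square 0 and p 1 rather than an error. X-linked markers are excluded
from the scan with a warning, because additive genotype scores are
ill-defined for hemizygous males; the packaged common-variant table
contains no X-linked markers, so this never triggers on fixtures.

The allelic odds ratio uses the Woolf log-scale interval with the
Haldane–Anscombe 0.5-per-cell correction when any cell is zero; the method
and the correction are both flagged in the output, since the reproduced
study names neither. Multiplicity is controlled by Bonferroni over the
number of *tested* (case-MAF ≥ 0.1) variants.

Two printed association numbers are deliberately **not** reproduced: the
odds ratio 47.86 and p 9.15e-7 for the recurrent WNT10A variant. No integer
allele table consistent with the printed per-patient genotypes (8 HET + 7
HOM of 65 cases → case MAF 22/130 = 0.169) or with the printed group MAFs
(0.16 / 0.004) yields exactly those values; the formula-derived values from
the reconstructed genotypes are OR 48.74 and p 2.9e-7. The package reports
what it computes; the discrepancy is documented rather than imitated. The
cohort-wide median of 6 missing teeth is likewise out of scope: 28 of the
65 cases have no printed dentition grid.

## Numerical and validation choices

* **Asymptotic vs exact p.** The closed-form p is validated in the test
  suite against a 20,000-draw permutation oracle that permutes case labels
  at fixed genotype margins. The permutation distribution is a lattice with
  large atoms, so the oracle reports the mid-p (half weight on ties) — the
  quantity a continuous tail approximation estimates. On random tables with
  every genotype class populated (cells 5–40), agreement is within 3
  Monte-Carlo standard errors plus a 0.05 allowance for residual
  finite-sample error; the gap shrinks with sample size.
* **Type-I error.** Over 2,000 null cohorts of 200 subjects the empirical
  rejection rate at α = 0.05 is required to sit inside the 99% binomial
  band.
* **Absent values.** Absent annotation cells are a distinct state end to
  end (`NA` scalars, empty verdict sets) and are never imputed as 0; each
  filter rule decides explicitly what absence means (absent frequency
  passes rarity; absent CADD/ADA fails the corresponding rule; absent
  verdicts leave the denominator).
* **Boundaries.** Threshold senses are exactly as printed and tested at
  the boundary: MAF strictly `<`, CADD strictly `>`, ADA and pLi `>=`,
  vote "at least", case-MAF selection `>=`.
* **Determinism.** `run_cascade()` is a pure function of its inputs;
  outputs are sorted by (gene, DNA change); reruns are byte-identical, and
  `run_all()` manifests carry checksums of every output.

## The synthetic cohort generator

`simulate_cohort()` emulates the screened study's structure with defaults
fixed to its conditions: 65 cases, 127 controls; a recurrent focal missense
variant at minor allele frequency 0.16 in cases and 0.004 in controls
(Hardy–Weinberg sampling per group); 28 common background markers at
frequencies 0.10–0.45 identical in both groups; and a planted rare-variant
panel that exercises every cascade path — truncating and splice passes, a
boundary 8/16 vote, an allowlisted low-CADD rescue, plus decoys failing
each stage (a synonymous variant, a too-common variant, a failed vote, a
sub-threshold splice score, a non-prioritized gene).

Rare variants are planted by exact carrier counts rather than frequencies
so the ground truth is deterministic; controls carry none unless
configured. The expected retained set in `truth` is derived from the
configured parameters by direct rule arithmetic, independently of the
cascade implementation it is later checked against. Missing-teeth counts
are drawn from truncated negative binomials per carrier class (mean 12 for
biallelic-focal/truncating carriers, 8 for other carriers, 4 for
non-carrier cases; all clamped to 1–28), which lands the generated
oligodontia fraction near the reproduced cohort's one half. The published
study reports only means and ranges, so the distribution family is a
generator choice, recorded in the truth output. Tooth positions are drawn
with class weights mirroring the reproduced distribution (second premolars
and lateral incisors most frequently missing).

What the generator does *not* emulate — and what passing tests on it
therefore cannot show about real data: linkage disequilibrium between
markers (markers are independent), relatedness and population structure
(subjects are exchangeable), annotation errors (scores are exactly as
configured), variable sequencing coverage, and segregation within families.

## Problem sizes used in the checks

The validation suite runs at sizes chosen to make each statistical check
informative at interactive cost: 20,000 permutation draws per oracle table,
2,000 replicates for the type-I error band, 200 replicates for the
family-wise error check over 29 markers, 20 generator seeds for exact
planted-truth recovery, and power checks at tenfold cohort size
(650/1,270), where the focal enrichment is detected below the Bonferroni
threshold in every replicate.

## Known limitations

* The cascade consumes annotations; it does not compute CADD/ADA scores or
  tool verdicts, and it does not re-implement ACMG/AMP classification.
* Copy-number and structural variants are out of scope, as in the
  reproduced screening design.
* The trend test is asymptotic; for very sparse tables an exact test would
  be preferable. The package flags rather than solves the hemizygote
  problem for X-linked common markers.
* `from_vcf()` accepts only normalized bi-allelic records by design.
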
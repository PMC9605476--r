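# panelscreen

Candidate-gene panel screening for non-syndromic tooth agenesis (ns-TA):
an R implementation of the complete analysis used in targeted-sequencing
case/control studies of congenitally missing teeth — rare-variant
filtering and classification, tooth-by-tooth phenotype accounting, and
common-variant association — together with a seeded synthetic cohort
generator so that every stage is testable without patient data.

## What it computes

**Rare-variant cascade.** Candidate variants are filtered by a rule
cascade with an auditable per-variant trail:

* rarity: gnomAD non-Finnish-European MAF < 0.001 (strict), with a gene
  allowlist (default *WNT10A*) whose variants are evaluated regardless of
  frequency;
* likely gene disrupting: stop-gain/stop-loss/frameshift unconditionally;
  splicing with ADA ≥ 0.9; missense with CADD > 20 *and* a damaging
  consensus from at least half of the available in-silico predictors
  (16 tools; a tool is damaging when any of its verdict tokens is in
  {D, Dc, P}, and the denominator is the number of tools with a verdict);
* prioritization: established ns-TA risk gene, documented odontogenesis
  role, or pLi ≥ 0.95;
* labelling: `pathogenic` when annotated in ClinVar/HGMD, else
  `likely_pathogenic`.

**Dentition phenotyping.** Missing teeth in FDI notation; hypodontia
(1–5) / oligodontia (≥6) classification excluding third molars;
tooth-class distributions; carrier summaries (including exclusive-carrier
mode); detection of subjects carrying retained variants in two or more
genes (oligogenic co-occurrence).

**Association.** Cochran–Armitage trend test from its closed form

```
chi2 = N (N Σ w_i r_i − R Σ w_i n_i)² / [ R (N−R) (N Σ w_i² n_i − (Σ w_i n_i)²) ]
```

with additive scores w = (0, 1, 2) and a 1-df upper-tail p-value; allelic
odds ratios with Woolf confidence intervals and Haldane–Anscombe zero-cell
correction; Bonferroni control over the tested (case-MAF ≥ 0.1) variants.

The package ships plain-text fixtures (`ps_fixture()`) encoding a
published 27-variant screen of 65 ns-TA cases and 127 controls, so the
whole pipeline runs offline.

## Worked example

```r
library(panelscreen)

variants   <- read_variant_table(ps_fixture("table2_variants.tsv"))
panel      <- read_panel(ps_fixture("gene_panel.tsv"))
phenotypes <- read_phenotype_table(ps_fixture("table34_phenotypes.tsv"))
genotypes  <- read_genotypes(ps_fixture("table34_genotypes.tsv"),
                             panel = panel, phenotypes = phenotypes)

cfg <- cascade_config(manual_exceptions = variant_key("TP63", "c.1594C>G"))
res <- run_cascade(variants, panel, cfg)
res
#> Variant filtering cascade
#>   27 variants in; 25 pass strictly; 27 retained (2 exempt)
#>     likely_pathogenic: 22
#>     pathogenic: 5

carrier_rate(genotypes, 65, keys = retained_keys(res))$fraction
#> [1] 0.5692308

carrier_phenotype_summary(phenotypes, genotypes, genes = "WNT10A")
#> Dentition summary over 18 subject(s)
#>   total missing 174; mean 9.67; range 2-20
#>   hypodontia 6; oligodontia 12

detect_oligogenic(retained_keys(res), genotypes)[, c("subject_id", "kind")]
#> # A tibble: 7 x 2
#>   subject_id kind
#>   <chr>      <chr>
#> 1 TA_21      same_gene_multi
#> 2 TA_22      same_gene_multi
#> 3 TA_28      same_gene_multi
#> 4 TA_33      cross_gene
#> 5 TA_34      cross_gene
#> 6 TA_36      cross_gene
#> 7 TA_37      same_gene_multi

assoc <- read_assoc_table(ps_fixture("table5_common.tsv"))
plan  <- multiplicity_plan(0.05, nrow(assoc))
sum(flag_significance(assoc$p_trend, plan)$significant_bonferroni)
#> [1] 1
```

So 27 pathogenic/likely-pathogenic variants are retained (25 strictly, 2
via documented exemptions), carried by 56.9% of the 65 cases; the 18
*WNT10A* carriers miss 174 permanent teeth (mean 9.67 per person, range
2–20); seven subjects carry two retained variants; and one of the 29
common variants survives Bonferroni correction.

The same pipeline runs end to end on synthetic data with known truth:

```r
sim <- simulate_cohort(simulation_config(seed = 7))
out <- run_all(sim$variants, sim$genotypes, sim$phenotypes, sim$panel,
               out_dir = tempfile())
identical(sort(out$cascade$classified$key[out$cascade$classified$retained]),
          sim$truth$expected_retained)
#> [1] TRUE
```

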
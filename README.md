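# famseg

Family-based rare-variant segregation analysis for cancer predisposition
studies, built around the design used for familial glioma in founder
populations: a handful of multiplex families (2–3 generations, several brain
tumor cases each), whole-exome discovery in a subset, targeted genotyping of
the shared candidates plus literature risk variants in the remaining
families, and criterion-based prioritization rather than formal linkage.

## What it does

For whom: statistical geneticists and bioinformaticians analyzing germline
variants in multiplex cancer families where case counts are far too small
for association testing and incomplete penetrance rules out simple
co-segregation filters.

The core procedure is an *all-criteria* prioritization. A variant is a
candidate only if every enabled criterion holds:

- **rare** — Finnish-population allele frequency `AF_fin < 0.01` (strict);
- **shared** — every genotyped affected member of each supporting family
  carries it (missing genotypes drop from the denominator);
- **recurrent** — affected carriers in ≥ 2 distinct families, counted at the
  variant level or pooled over a gene's qualifying variants;
- **tumor-side** — the allele entered each family through the founder
  lineage with reported brain/other tumor history. Inheritance side is
  inferred by tracing the transmitting parent (carrier parents transmit; a
  homozygous-reference parent makes the other parent the obligate
  transmitter; X-linked hemizygous males receive from the mother) under a
  single-founder-entry parsimony assumption — the natural reading of a rare
  allele — with de novo mutation never invoked;
- **damaging** — a consensus over the available in-silico predictors (SIFT,
  PolyPhen, LRT, MutationTaster, MutationAssessor, FATHMM_MKL, MetaSVM,
  MetaLR; majority rule by default);
- **relevant** — curated flags for brain expression / glioma relevance.

Around that core the package provides pedigree I/O with Mendelian checks and
hemizygosity support, VCF/annotation-table input, the discovery
frequency/consequence filter and targeted-panel genotype QC, risk-locus
summaries with a log-additive polygenic risk score
(`PRS = Σ dosage · ln OR`) compared between affected and unaffected by a
within-family label-permutation test, closed-form and gene-drop Monte-Carlo
detection power (`1 − (1 − p)^n` for the any-family rule), a Fisher-exact
loss-of-heterozygosity screen with Benjamini–Hochberg correction, and a
gene-drop simulator of multiplex cohorts with an incompletely penetrant
planted causal allele.

## Worked example

The package ships a deterministic synthetic worked-example cohort of 12
Finnish multiplex brain-tumor families:

```r
library(famseg)

coh <- example_glioma_cohort()
coh
#> <fs_cohort> 12 families, 52 individuals, 17 variants (52 genotyped individuals)

cand <- prioritize_variants(coh)
cand
#> <fs_candidates> 5 candidate variants in 3 genes
#> # A tibble: 3 × 3
#>   gene    n_supporting_families families
#>   <chr>                   <int> <chr>
#> 1 AR                          2 A,Q
#> 2 GALNT13                     2 A,C
#> 3 MYO10                       3 B,F,J
```

Five rare damaging variants in three genes survive all criteria: two GALNT13
missense variants (one family each, combined at the gene level), an X-linked
AR variant carried hemizygously by males, and two MYO10 variants. The known
pathogenic CHEK2 frameshift in the cohort is *excluded* because it entered
its family through the married-in lineage, and the common CCDC26 risk SNP
rs55705857 (AF_fin 0.09) fails the rarity criterion while still appearing in
8 affected individuals across 6 families (7 heterozygous, 1 homozygous) in
the risk-locus summary:

```r
detection_summary(coh) |> dplyr::filter(variant_id == "8:130645692:A:G")
co_occurrence(coh, cand)   # rs55705857 co-occurs with candidates in B, C, Q

glance(prs_compare(coh, seed = 1))
#> # A tibble: 1 × 6
#>   statistic mean_affected mean_unaffected p_value n_perm scheme
#>       <dbl>         <dbl>           <dbl>   <dbl>  <dbl> <chr>
#> 1     0.166          1.13           0.967   0.497    999 within_family
```

The permutation p-value of ~0.5 says the polygenic score of the genotyped
risk loci does not separate affected from unaffected members — risk-allele
dosages are as common on the unaffected side of these pedigrees.

```r
power_closed_form(0.2, 4)
#> [1] 0.5904
```

With four sequenced families, a variant present in 20% of families is
detected (any-family rule) with probability 0.59; the stricter
shared-by-affecteds rule under incomplete penetrance lowers this (see
`power_mc()`).

`run_pipeline()` chains QC → segregation → prioritization → risk-locus /
PRS / power / LOH stages and writes every table as TSV;
`simulate_cohort(sim_config())` generates synthetic cohorts with a known
planted causal gene for end-to-end validation, and `autoplot()` /
`plot_prs()` draw the segregation tile map and score distributions.

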
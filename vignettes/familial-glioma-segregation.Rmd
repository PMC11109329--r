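---
title: "Methods: family-based rare-variant segregation and prioritization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: family-based rare-variant segregation and prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famseg)
```

## The analysis problem

famseg implements the analysis design used for non-syndromic familial glioma
in a founder population: a small set of multiplex families (each with two to
five brain-tumor cases across 2–3 generations), exome discovery in the
best-sampled families, targeted genotyping of the shared candidates plus
previously reported risk variants in the remainder, and a fully
criterion-based prioritization. Nothing here is an association test: with a
handful of families and incompletely penetrant alleles, the meaningful
evidence is *qualitative segregation* — who carries the allele, whether all
genotyped affecteds share it, and which founder lineage it entered through.

## Data model

A cohort bundles four tables: a pedigree (one row per individual, with
affection status, printed age-at-diagnosis bands, a `sampled` flag, and a
founder-only `side_label`), a variant table keyed by `chrom:pos:ref:alt` on
hg19, a genotype matrix over the alphabet `hom_ref/het/hom_alt/
hemi_ref/hemi_alt/missing`, and an annotation table (population frequencies,
eight binarized predictor calls, CADD, three conservation scores, ClinVar at
review status ≥ 2 stars, domain and gene-relevance flags). Predictor calls
are binarized at ingestion because the downstream consensus only consumes
damaging/tolerated/unavailable. Male X genotypes are stored hemizygous;
pseudoautosomal regions are out of scope and would need an explicit autosomal
flag. A missing genotype never counts as carrier *or* non-carrier: the
individual simply drops out of every denominator.

## Inheritance-side inference

`side_label` is an input annotation derived from reported family history —
any reported tumor history (brain or other) marks a founder `tumor_side`,
spouses who joined from outside the tumor-history lineage are `married_in` —
never inferred from genotypes. For a variant, the side is inferred by
tracing each affected carrier's transmitting parent: a genotyped carrier
parent transmits; a genotyped homozygous(-hemizygous)-reference parent makes
the other parent the obligate transmitter; X-linked hemizygous males receive
from the mother. De novo mutation is never invoked to explain a carrier
child of a genotyped non-carrier parent.

Because the alleles of interest are rare, the inference assumes a **single
founder entry point** (parsimony). This is applied jointly: each observed
carrier (affected or not) constrains the possible entry founders, and the
allele is taken to have entered through a minimum-size founder set hitting
every carrier's possibility set. Two consequences are worth noting. First, a
genotyped carrier founder anywhere in the pedigree becomes the preferred
explanation for every other carrier it can reach. Second, on the X
chromosome a genotyped homozygous-reference daughter pins her ungenotyped
father's X, which often resolves sides that a naive upward trace cannot.
The test suite verifies this procedure against brute-force enumeration of
all Mendelian-consistent genotype assignments on pedigrees of up to 8
members. Homozygous carriers arising from consanguinity would violate the
single-entry assumption; the package then reports `undetermined` rather than
guessing. When both founder lineages of a family carried tumor history, or
labels are absent, the side is reported `mixed`/`undetermined` — the
category records the ambiguity instead of resolving it.

## Prioritization criteria and their defaults

`prioritization_criteria()` exposes every threshold:

- `af_fin_max = 0.01`, strict `<`. The discovery filter reuses the same
  bound (`filter_config()`), keeping the two stages consistent; a variant
  absent from the frequency panel counts as frequency 0 (never observed).
- `min_families = 2`, with `gene_level_aggregation = TRUE`: family support
  may be pooled over a gene's qualifying variants, each family counting
  once. This is what lets a gene with two private variants in two families
  qualify.
- `require_shared = TRUE`: in every family with at least one affected
  carrier, *all* genotyped affecteds must carry. A family whose only
  carriers are unaffected contributes nothing either way.
- `require_tumor_side = "all_determinable"`: no supporting family may
  resolve to the non-tumor side; undetermined families do not veto. The
  alternative `"at_least_one"` demands positive evidence in at least one
  family. We default to the weaker mode because in small families with
  unsampled parents the side is frequently undeterminable, and a hard
  requirement would discard variants on missingness rather than evidence.
- `damaging_rule = "majority"` of the *available* predictors. The candidate
  variants in the worked example are called damaging by 6/7–8/8 predictors,
  so majority and all-but-one behave identically there; majority is robust
  to a single discordant tool. A variant with no available predictor fails
  the criterion (non-coding variants cannot pass on pathogenicity they
  cannot show).
- `require_gene_relevance = TRUE`: the brain-expression/glioma-relevance
  flags are curated inputs, not computed — the criterion is intrinsically
  literature-based.

All criteria are ANDed; candidates are reported sorted by gene and position,
and no ranking score is invented beyond the binary criteria.

## Caller merging, panel assembly and QC

Two caller sets are merged by union by default (sensitivity at the discovery
stage; intersection is available). The targeted panel keeps discovery
variants shared by the affecteds of at least one sequenced family and
carries literature variants and gene regions through with provenance labels.
Genotype QC drops panel variants with call rate < 0.9 (over sequenced
samples only — individuals without genotype data are not failed attempts) or
median depth < 10 when depths are present; both thresholds are
config-exposed, and every drop is logged with its reason.

## Risk loci and the polygenic score

The PRS is the standard log-additive score `Σ dosage × ln(OR)` with
user-supplied per-locus odds ratios; no OR is ever estimated from the
cohort. Hemizygous male X dosage is 1 per risk allele (no doubling — the
conservative choice, config-exposed through the data model). Missing
genotypes contribute 0 and are reported through a completeness fraction; an
individual genotyped at no locus is not scored. The affected/unaffected
comparison uses the difference of group means with a label-permutation null,
permuting **within families** by default so each family's affected count is
preserved exactly and relatedness cannot manufacture significance; p-values
are `(1 + #extreme)/(n_perm + 1)`, so the smallest attainable value is
`1/(n_perm+1)`. The test's type-I error is verified at ~5% over 1000 null
simulations in the test suite.

## Detection power

For the any-family-carries rule the closed form `1 − (1 − p)^n` applies. The
Monte-Carlo estimator also implements the stricter rule actually used at
discovery — detection requires a carrier family in which every affected is a
carrier — via gene-drop through a configurable nuclear family with
penetrance `f1` and phenocopy rate `f0`. With `f1 = 1, f0 = 0` the two rules
provably coincide, which the tests exploit as an analytical reduction. The
two rules bracket realistic designs: at `p = 0.2, n = 4` the any-family rule
gives 59.0%, while the sharing rule under the simulator's default penetrance
model (`f1 = 0.6`, `f0 = 0.001`, three children) gives ≈ 53%. No exact
published figure is asserted for the stricter rule because the family
structures behind such figures are rarely fully specified.

## LOH screen

At each germline-heterozygous site the tumor/normal ref/alt read counts form
a 2×2 table tested with a two-sided Fisher exact test (exact at low depth),
plus the allele-fraction shift; flags are assigned after Benjamini–Hochberg
correction across the tested loci at `alpha = 0.05`. The test is symmetric
in allele labels. Purity/ploidy-aware models are out of scope.

## The synthetic cohort generator

`simulate_cohort()` emulates the study conditions: 19 multiplex families of
2–3 generations (sibships of 2–4, one lineage continuing to a third
generation), a causal gene with two rare variants (`AF_fin = 5e-5`) planted
one copy each in the tumor-side founder of two carrier families, penetrance
0.6 for carriers and a sporadic rate of 0.001, a 10⁴-variant exome-like
background with a rare-shifted Beta(0.2, 2) frequency spectrum and 79%
protein-altering consequences, per-predictor false damaging calls at 10%,
15 common risk loci led by one at frequency 0.09 with OR 3.4 (the rest OR
1.2–1.5 at frequencies 0.10–0.80), 5% genotype missingness and 80% founder
sampling. Founders draw from Hardy–Weinberg; transmission is fair meiosis
over independent loci with X-linked rules.

Because the emulated families are *ascertained* multiplex, affection cannot
be purely sporadic in non-carrier families. Each non-carrier family
therefore carries a private latent liability allele — gene-dropped like any
locus but never genotyped — and families are redrawn until they reach two
affected members (capped retries). This gives every family a familial cause
while only the planted gene is visible to the pipeline, which is exactly the
situation the prioritization faces in practice.

What the generator does *not* model: linkage disequilibrium, recombination
maps, sequence context, relatedness between families, population
stratification, genotyping error beyond missingness, and age-dependent
penetrance. Passing the recovery suite therefore demonstrates that the
criteria logic isolates a planted signal under the assumed sampling model,
not that the pipeline is robust to correlated real-world artifacts.

The deterministic worked-example cohort (`example_glioma_cohort()`) is a
hand-encoded synthetic stand-in: 12 families whose genotypes at 17 loci
reproduce the qualitative carrier patterns the package's documentation
discusses. Where a printed total constrains several families jointly (eight
rs55705857 affected carriers in six families, seven heterozygous and one
homozygous), the per-family allocation not individually printed was fixed
once (two heterozygous carriers in each of families E and L). Genotypes of
relatives without stated data are missing, never imputed; exact positions
not printed for a few non-coding loci are plausible synthetic values. The
low-risk GWAS loci are encoded family-uniform, which is Mendelian-consistent
and carries no affected/unaffected contrast — the cohort's PRS null result
is a design property of the fixture, matching the null finding it encodes.

## Numerical choices and degenerate inputs

Strict inequalities at both frequency thresholds (a variant *at* 0.01 is
removed); sharing requires `all()` over genotyped affecteds with at least
one carrier; a family with no genotyped affected returns `NA` (uninformative)
rather than false; consensus over zero available predictors is an error at
the operation level and a criterion failure inside prioritization;
permutation p-values never reach 0 by construction; Monte-Carlo power
reports a normal-approximation CI; empty cohorts write valid headers.
Problem sizes in the test suite — 200 recovery simulations at 10⁴ background
variants, 1000 PRS null simulations at 199 permutations, 10⁵-draw power
comparisons, enumeration oracles on ≤ 8-member pedigrees — were chosen as
the smallest sizes at which the stochastic assertions are stable.

## Known limitations

Half-sibling structures are permitted but consanguinity loops defeat the
single-entry parsimony; the package then reports `undetermined`. The
tumor-side criterion inherits the subjectivity of reported family history.
Gene-relevance flags are curated inputs, so the corresponding criterion is
only as good as its curation. The prioritization is binary by design — no
co-segregation likelihoods or Bayes factors are computed, matching the
procedure it implements rather than extending it.
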
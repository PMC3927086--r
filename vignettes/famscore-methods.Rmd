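---
title: "Methods: family-based prioritization and liability-scale genetic scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: family-based prioritization and liability-scale genetic scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famscore)
```

`famscore` implements a two-cohort design for common-variant discovery in
multiplex families: a liberal family-based association scan, a
functional-genomics scoring filter, and a sex-specific genetic score whose
discrimination in an independent validation cohort is converted to the
proportion of genetic variance explained on the liability scale. This
vignette is the package's account of each modelling decision: the
generative model behind the simulator, the statistics at each stage, the
numerical conventions, and what the passing test suite does and does not
demonstrate about real data.

## The generative model

`simulate_families()` draws nuclear families with two parents and (by
default) two to four children. Parents' genotypes at each diallelic SNP are
independent Hardy-Weinberg draws at a minor allele frequency sampled from
`maf_range`; each child receives one allele from each parent by fair
Mendelian transmission, so child genotypes are Mendel-consistent by
construction. A child's liability is

> liability = centred causal-genotype term + sibling-shared N(0, c²) +
> independent residual,

standardized to total variance 1. Each causal SNP contributes `beta` per
unit of its genetic-model coding (additive/dominant/recessive), centred at
the Hardy-Weinberg mean so the threshold calculation stays exact; the
residual variance is `1 − Σ beta²·Var(coding) − c²` and must be positive.
A child is affected when liability exceeds the sex-specific threshold
`qnorm(1 − K_sex)`. Families are ascertained on a minimum number of
affected children (two, the multiplex criterion) by rejection sampling;
if a pilot batch estimates the acceptance probability below 10⁻⁶ the
generator aborts with a diagnostic rather than loop forever.

Default parameters and their provenance:

* `male_prevalence = 1/54`, `female_prevalence = 1/252` — the US childhood
  autism prevalences (1 in 88 overall with the observed sex split). The
  roughly 4:1 affected male:female ratio is *emergent*: children's sexes
  are drawn 50:50 and only the thresholds differ, i.e. differential
  penetrance rather than sex-specific loci.
* `shared_sib_var = 0.643` — calibrated once with
  `calibrate_shared_sib_var(0.259, 1/54)` (a `uniroot` solve of the
  bivariate-normal tail integral in `sibling_recurrence()`) so that, with
  no causal SNPs, the recurrence among brothers of affected boys equals
  the reported 25.9%.
* `children_per_family = 2:4` — family-size distributions for multiplex
  cohorts are rarely published; 2–4 children is a realistic modelling
  choice, and it matters only through the count of unaffected siblings
  available as controls.
* Missingness and genotype-error injection default to 0 and exist to
  exercise QC; an injected error replaces a genotype with a fresh
  Hardy-Weinberg draw, which Mendel checking then catches at a realistic
  (not 100%) rate.

For speed, ascertainment is decided from liabilities (which involve only
causal SNPs); null-SNP genotypes, independent of affection by
construction, are filled in afterwards for accepted families only — the
joint distribution is identical to generating everything up front.

What the generator deliberately does **not** emulate: linkage
disequilibrium (every SNP segregates independently, so there is no proxy
structure and no need for LD pruning), copy-number or rare variants,
assortative mating, genotyping-chemistry artefacts, and the literature
curation that produces real evidence tables — `simulate_evidence()` stands
in for the latter with per-field Bernoulli activations (`p_true` for
causal-SNP genes, `p_false` otherwise; when a categorical field activates,
the stronger level is drawn with probability 0.75).

## Quality control

`mendel_mask()` runs first, then `snp_qc_filter()` — masking changes call
rates, so the order matters and is fixed. A (family, SNP) with any child
incompatible with the parental genotypes under biallelic transmission is
set to missing *for every family member* at that SNP; masking is
idempotent. Children with a missing own or parental genotype are not
testable and are left alone.

The SNP filters are Hardy-Weinberg exact p < 10⁻³, call rate < 90%, and
MAF < 5%. HWE and MAF are computed on founders only: siblings are
correlated copies of their parents' alleles, and including them distorts
both the allele-frequency estimate and the exact-test null. Call rate uses
all individuals, since missingness affects every downstream user of the
genotype. The exact test itself sums, over all heterozygote counts
compatible with the observed allele counts, the probabilities of
configurations no more likely than the observed one, computed with the
standard adjacent-heterozygote recurrence in log space (stable for
thousands of founders); the test suite checks it exhaustively against a
direct log-factorial enumeration for every table of up to 50 individuals.

## The transmission test

`fbat_test()` conditions on parental genotypes: for each target child the
coding of the three possible transmitted genotypes has an exact conditional
mean and variance; family contributions add (offspring are independent
transmissions given parents), and `Z = (S − E)/√V` is referred to the
standard normal, two-sided. Conventions:

* Families with a missing parental genotype at a SNP are dropped for that
  SNP. The full sufficient-statistic conditioning for missing parents is
  intentionally out of scope; cohorts of this design have genotyped
  parents, and the restriction is documented rather than approximated.
* Offspring enter with an indicator weight for the stratum's target status
  (affected-only or unaffected-only sums), matching the four discovery
  runs: affected both/male/female, unaffected both. The unaffected run is
  unstratified by default (configurable), since unaffected siblings are
  few once split by sex.
* `Z` is computed for the coding of the A1 allele. A dominant coding of
  one allele is the complement of the recessive coding of the other, so
  three models tested two-sidedly cover both orientations; `fbat_test()`
  also accepts an explicit `allele` argument.
* The reported risk allele is the overtransmitted allele for affected
  targets. For unaffected targets the overtransmitted allele is
  *protective*, so the designated risk allele is the other one — this
  keeps the downstream concordance rule ("sibling OR > 1 for the risk
  allele") uniform across all four runs.
* A SNP with zero total transmission variance (all informative families
  lost) returns Z = 0, p = 1, flagged by `n_informative = 0`. No exact
  small-sample p is attempted; p-values are normal approximations
  throughout, and the suite verifies the empirical size at α = 0.05 stays
  inside [0.04, 0.06] over 2,000 null cohorts of 300 families.

## Sibling case-control estimating equations

`gee_logistic()` fits ordinary logistic regression by IRLS (tolerance
10⁻¹⁰ on the deviance scale via `glm.fit`, at most 100 iterations) and
replaces the model-based covariance with the cluster sandwich `A⁻¹BA⁻¹`,
`B` accumulated from per-family summed score vectors, with no small-sample
correction — with every cluster of size one this is exactly HC0, an
identity the tests check against the `sandwich` package. A constant
predictor or a diverging coefficient (|β| > 15, the practical signature of
separation) flags the fit non-estimable instead of returning a misleading
interval; other rank deficiencies are errors.

`sibling_case_control()` compares affected with unaffected children
(parents excluded), genotype coded under a genetic model for the
designated risk allele, clustered by family. Sex enters as an adjustment
covariate exactly when it is not the stratification variable.

`select_candidates()` keeps a SNP when some (model, stratum) combination
has family-based p < 10⁻³ *and* the matching sibling test — same model,
same sex stratum, genotype coded for the family-designated risk allele —
has p < 0.05 with OR > 1. "Nominal" is read as two-sided 0.05 on the
robust Wald test. Requiring the *same* model and stratum in both funnels
is the stricter of the plausible readings and is the default; direction
concordance is enforced explicitly since an overtransmitted allele that
*protects* in the sibling comparison is evidence of inconsistency, not
replication. No multiple-testing correction is applied at this stage —
false-positive control is delegated to the evidence score, which is the
point of the design.

## SNP-gene mapping and scoring

`map_snp_to_genes()` pairs a SNP with the nearest gene within 5 kb
(distance 0 inside the 1-based inclusive span; ties return all tied
genes), else with the closest upstream and closest downstream genes within
50 kb (0, 1 or 2 pairs). `score_pair()` allocates:

| category | points | cap |
|---|---|---|
| statistical | 1 if GWAS p < 10⁻⁸, else 0.5 if < 10⁻⁵; +1 if sibling OR ≥ 1.5 | 2 |
| genomic | 1 if within gene ± 5 kb; +1 if eQTL of the gene | 2 |
| previous reporting | 1 autism, 0.5 related neurodevelopmental disorder | 1 |
| physiological | 1 brain expression difference (0.5 lymphoblastoid); +1 CNS-specific role; +1 mouse CNS model; +1 pathway membership | 4 |

Bands are half-open with the stricter side winning (p = 10⁻⁵ earns 0,
p = 10⁻⁸ earns 0.5); the alternative levels within a line are mutually
exclusive maxima, not sums. The total lives on the half-point lattice
0–9 and a pair is selected at total ≥ 4, a closed bound. When a SNP maps
to two genes the SNP is selected if *any* pair clears the cutoff
(max-over-pairs), and the best pair is reported. A candidate missing from
the evidence table scores with all functional flags off (logged), so
statistics alone can never exceed 2 points plus geometry. Only the
threshold rule is enforced; no additional "must mix statistical and
functional points" side condition is imposed.

## Genetic scores and the liability conversion

`select_best_model()` chooses, per SNP and sex stratum, the coding that
maximizes |robust Wald z| in the discovery sibling design. A joint search
over all 3^m model assignments would be combinatorially infeasible and
no more identifiable; the marginal criterion is the package's reading of
"best fitted", and the criterion function is isolated so it can be
swapped. With the direction filter on, codings with OR ≤ 1 for the risk
allele are removed first and SNPs with no admissible coding are dropped.
Ties within 10⁻¹² resolve additive > dominant > recessive — the additive
coding is the conventional, most robust default.

`compute_gs()` sums the per-SNP codings; a missing genotype contributes
the stratum mean coding computed on the cohort being scored (flagged), or
optionally the observed sum is rescaled by the fraction observed
(`impute = "rescale"`). Scores are integers when nothing is missing, and
an individual missing more than half the model SNPs is flagged
low-confidence.

`evaluate_gs()` takes a *fixed* model to the validation cohort — nothing
is re-estimated there — and reports the GRR (GEE odds ratio per score
unit), the case-control AUC (`auc_of_score()`, Mann-Whitney with ties
counted half, oriented ≥ 0.5 with the flip recorded), the implied
liability variance `v`, and `v/h²`. The AUC↔v relation is the
liability-threshold identity implemented in `liability_auc()`; the inverse
is monotone bisection on v ∈ [0, 1) to 10⁻⁸ (the forward map is strictly
increasing, so bisection always converges for AUC < 1; AUC = 1 is a
boundary and rejected). `h²` is Falconer's `2(t − t_R)/i` for full
siblings, with a Reich-corrected variant behind `reich = TRUE`. With the
default autism parameters the male estimate exceeds 1 — the
liability-scale ceiling — and is returned *flagged*, with `v/h²` clamped
to [0, 1] and the clamping flagged, rather than silently renormalized:
an out-of-range Falconer estimate is information about the inputs, not a
nuisance to hide.

## Bootstrap machinery

`bootstrap_statistic()` resamples families (never individuals) with
replacement to the original family count, rebuilding duplicated families
as distinct clusters. The 95% CI is percentile with the adjacent-rank
convention: lower = ⌈0.025·B⌉-th, upper = ⌈0.975·B⌉-th order statistic —
no interpolation, so the endpoints are always realized replicate values.
Non-estimable replicates are redrawn and counted; more than 20% aborts.
`inflation_check()` compares the bootstrap mean to the observed value:
when a selection step (such as the direction filter) is re-run inside
each replicate, the bootstrap mean exceeds the observed GRR under the
null — the suite demonstrates this selection-inflation effect directly.
`reproducibility_index()` re-runs model selection on B family-bootstrap
replicates of each of two cohorts; a replicate that drops the SNP counts
as non-reproducing, and "highly reproducible" means RI > 0.80 in both.
The full B = 1000 is a configuration default; the test suite runs reduced
B (100–200) to keep runtimes proportionate.

## What the tests show — and the sibling-control caveat

The suite validates each stage against independent oracles: exhaustive
HWE enumeration, TDT algebra on enumerated trios, the 2×2 cross-product
identity, HC0/cluster-sandwich identities, forward/inverse liability
round-trips, Falconer parameter recovery from simulated sibling pairs,
bootstrap coverage of a known GRR, and the Monte-Carlo size of both tests.
Problem sizes were chosen to make Monte-Carlo error small relative to the
asserted bands: 2,000 null transmission cohorts of 300 families, 1,000
GEE null replicates of 500 families, 200 outer coverage replicates at
B = 200, 20 end-to-end pipeline replicates at 500 discovery / 400
validation families.

One structural property deserves emphasis. The validation design measures
the score's AUC between affected children and their *unaffected siblings*.
Siblings share half their alleles and come from families ascertained for
high liability, so the unaffected controls are genetically enriched
relative to population controls: roughly, only the within-family
segregation variance (half the score's variance) separates the groups, and
the effective case-control liability contrast is further compressed by the
family-conditional prevalence. The AUC→v inversion, however, assumes
population cases and controls. The package follows the design faithfully
and documents rather than corrects this bias, and the generative-recovery
experiment in the suite shows its consequence: the estimated proportion of
genetic variance explained from sibling-control AUCs falls substantially
below the generative ratio v/h² even at large validation sizes. Estimates
produced by this design should therefore be read as conservative
lower bounds, and compared only with estimates from the same design. The
deterministic direction of the effect is easy to see from the forward map:

```{r}
lp <- liability_params(1 / 54, sibling_recurrence(0.4, 1 / 54))
# population AUC implied by a score explaining 10% of liability variance
liability_auc(0.10, lp)
```

An observed sibling-design AUC materially below this value inverts to a
correspondingly smaller v.

Other known limitations: no X-chromosome-specific transmission rules, no
haplotype or trait-offset FBAT variants, no exchangeable/AR working
correlations (independence only, as in the design), and the evidence
table is an input — the package does not query eQTL or model-organism
databases.
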
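# famscore

Family-based GWAS prioritization and sex-specific genetic scores under a
liability-threshold model.

## The problem

Genome-wide association studies of autism in multiplex families (two
parents, two or more children, ascertained on at least two affected
siblings) rarely yield genome-wide-significant SNPs: common risk variants
have small effects, and affected cohorts of practical size are
underpowered. One productive response is convergent functional genomics:
run the association scan liberally (several genetic models, sex strata,
transmission to affected *and* unaffected children), accept many weak
statistical signals, then filter them by scoring each SNP-gene pair on
independent functional-genomics evidence. SNPs that survive are combined
into a sex-specific genetic score (GS), whose case-control discrimination
in an independent validation cohort is converted into the proportion of
genetic variance explained on the liability scale.

`famscore` implements that entire pipeline as tested, reusable R code, plus
a synthetic-data generator so every stage runs end to end with no external
data. It is aimed at statistical geneticists who want to study the
behaviour of this class of prioritization designs (power, selection
inflation, model reproducibility) under a known generative truth.

## The statistics at the core

* **Transmission test (FBAT/TDT form).** For children of genotyped parents,
  `S = Σ x(g_child)` is the sum of a genetic-model coding
  (additive 0/1/2, dominant 0/1/1, recessive 0/0/1) over target children;
  `E[S]` and `Var[S]` come from the exact conditional distribution of
  offspring genotypes given parental genotypes under Mendelian
  transmission, and `Z = (S − E[S])/√Var[S]` is referred to the normal.
  For one-heterozygous-parent trios under the additive coding, `Z²`
  reduces to the classical TDT McNemar statistic `(b − c)²/(b + c)`.
* **Sibling case-control GEE.** Affected vs unaffected children, logistic
  point estimates (independence working correlation) with the
  cluster-robust sandwich `A⁻¹BA⁻¹`, `B` accumulated from per-family summed
  scores. The exponentiated genotype coefficient is the odds ratio / GRR.
* **Evidence scoring.** Each SNP-gene pair earns points in four capped
  categories — statistical (≤2), genomic (≤2), previous reporting (≤1),
  physiological (≤4) — total ≤ 9, selected when total ≥ 4.
* **Liability conversion.** With prevalence `K`, threshold
  `t = Φ⁻¹(1−K)`, mean case liability `i = φ(t)/K`, a score explaining a
  fraction `v` of liability variance implies
  `AUC = Φ( v(i−i_c) / √( v(1−v·i(i−t)) + v(1−v·i_c(i_c−t)) ) )`;
  the package inverts this by bisection, and divides by the Falconer
  heritability `h² = 2(t − t_R)/i` from the sibling recurrence risk `K_R`
  to report the proportion of *genetic* variance explained.
* **Family bootstrap.** Families are the resampling unit for empirical 95%
  percentile CIs, selection-inflation checks, and a per-SNP genetic-model
  reproducibility index (RI).

## Worked example

Simulate a discovery/validation pair with three additive causal SNPs, run
the whole pipeline, and inspect the female genetic score:

```r
library(famscore)

causal <- data.frame(snp = 1:3, model = "additive", beta = 0.27)
sim <- function(n) list(n_families = n, n_snps = 25, maf_range = c(0.25, 0.35),
                        causal = causal, shared_sib_var = 0.35)
cfg <- pipeline_config(
  simulate = list(discovery = sim(200), validation = sim(150),
                  evidence = list(p_true = 0.9, p_false = 0.1)),
  bootstrap_B = 200, seed = 42)
art <- run_pipeline(cfg, out_dir = "famscore_demo")
#> simulate: 200 discovery families, 150 validation families, 25 SNPs
#> qc[discovery]: 0 Mendel-error family-SNPs masked; 0/25 SNPs removed
#> qc[validation]: 0 Mendel-error family-SNPs masked; 0/25 SNPs removed
#> fbat: 300 tests (25 SNPs x 3 models x 4 strata)
#> select: 16 family hits -> 4 candidate SNPs
#> score: 3 SNPs at score >= 4
#> gs-eval[male]: 3 SNPs, GRR = 1.35 (p = 0.0027), AUC = 0.586, genetic variance explained = 0.0129
#> bootstrap[male]: GRR 95% CI [1.14, 1.69]
#> gs-eval[female]: 3 SNPs, GRR = 1.81 (p = 0.00026), AUC = 0.641, genetic variance explained = 0.032
#> bootstrap[female]: GRR 95% CI [1.32, 2.51]

art$gs_model_female
#> # A tibble: 3 × 5
#>   snp     risk_allele model        or     z
#>   <chr>   <chr>       <chr>     <dbl> <dbl>
#> 1 snp0001 A           dominant   3.04  3.58
#> 2 snp0002 A           additive   1.74  2.95
#> 3 snp0003 A           recessive  1.83  1.63
```

Reading the log: of 25 SNPs, the family-based GWAS (3 models × 4 strata)
plus the sibling case-control funnel keeps 4 candidates; 3 of them carry
enough functional evidence to clear the score cutoff of 4. In validation
females the resulting 3-SNP score has odds ratio 1.81 per score unit
(robust p = 2.6×10⁻⁴), AUC 0.641 against unaffected sisters, and explains
about 3% of the Falconer genetic variance. Note that AUCs measured against
*sibling* controls are attenuated relative to population controls, because
siblings share half their alleles — see the methods vignette
(`vignettes/famscore-methods.Rmd`) for the quantitative discussion.

Every stage also works on its own (`simulate_families()`,
`snp_qc_filter()`, `mendel_mask()`, `fbat_test()`, `run_family_gwas()`,
`sibling_case_control()`, `select_candidates()`, `prioritize()`,
`select_best_model()`, `compute_gs()`, `evaluate_gs()`,
`bootstrap_statistic()`, `reproducibility_index()`), takes and returns
tibbles, and has `tidy()`/`glance()`/plot helpers. Real genotype data enter
through `read_ped_map()` (PLINK text PED/MAP).

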
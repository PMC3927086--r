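test_that("pre-ascertainment prevalence matches the sex-specific threshold", {
  set.seed(101)
  p <- sim_params(n_families = 25000, children_per_family = 2, n_snps = 2,
                  causal = NULL, shared_sib_var = 0,
                  male_prevalence = 0.0185, female_prevalence = 0.0185,
                  seed = 101)
  co <- simulate_families(p, ascertain = FALSE)
  kids <- is_child(co)
  n <- sum(kids)
  frac <- mean(co$individuals$status[kids] == "affected")
  se <- sqrt(0.0185 * (1 - 0.0185) / n)
  expect_lt(abs(frac - 0.0185), 3 * se)
})

test_that("every ascertained family has at least the required affected children", {
  co <- random_cohort(n_fam = 60, seed = 7)
  aff <- tapply(co$individuals$status == "affected" & is_child(co),
                co$individuals$family, sum)
  expect_true(all(aff >= 2))
})

test_that("parental allele frequencies match the drawn MAF within binomial error", {
  p <- sim_params(n_families = 2000, children_per_family = 2, n_snps = 4,
                  male_prevalence = 0.4, female_prevalence = 0.4,
                  shared_sib_var = 0, seed = 33)
  co <- simulate_families(p, ascertain = FALSE)
  maf <- attr(co, "maf")
  gf <- co$genotypes[is_founder(co), ]
  freq <- colMeans(gf) / 2
  se <- sqrt(maf * (1 - maf) / (2 * nrow(gf)))
  expect_true(all(abs(freq - maf) < 4 * se))
})

test_that("shared sibling variance calibration reproduces the target recurrence", {
  # generator default was calibrated so brother recurrence is 25.9% at the
  # male prevalence of 1/54
  rho <- calibrate_shared_sib_var(0.259, 1 / 54)
  expect_equal(sibling_recurrence(rho, 1 / 54), 0.259, tolerance = 1e-6)
  expect_equal(rho, 0.643, tolerance = 0.001)
  # Monte-Carlo: recurrence among brothers of affected boys (sib pairs,
  # pre-ascertainment, elevated K to keep the sample informative)
  K <- 0.05
  rho2 <- calibrate_shared_sib_var(0.259, K)
  p <- sim_params(n_families = 60000, children_per_family = 2, n_snps = 1,
                  male_prevalence = K, female_prevalence = K,
                  shared_sib_var = rho2, seed = 57)
  co <- simulate_families(p, ascertain = FALSE)
  kids <- co$individuals[is_child(co), ]
  sib <- dplyr::summarise(dplyr::group_by(kids, family),
                          a1 = status[1] == "affected",
                          a2 = status[2] == "affected")
  rec <- with(sib, (sum(a1 & a2) * 2) / (sum(a1) + sum(a2)))
  expect_lt(abs(rec - 0.259), 0.02)
})

test_that("ascertained cohorts show inflated sibling recurrence (lambda_s > 1)", {
  p <- sim_params(n_families = 400, children_per_family = 3, n_snps = 2,
                  male_prevalence = 0.05, female_prevalence = 0.05,
                  shared_sib_var = 0.4, seed = 21)
  co <- simulate_families(p)
  kids <- co$individuals[is_child(co), ]
  rec <- mean(tapply(kids$status == "affected", kids$family, mean))
  expect_gt(rec / 0.05, 1)
})

test_that("the generator is deterministic given its seed", {
  p <- sim_params(n_families = 15, n_snps = 4, male_prevalence = 0.3,
                  female_prevalence = 0.3, shared_sib_var = 0.1, seed = 99)
  a <- simulate_families(p)
  b <- simulate_families(p)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$individuals, b$individuals)
})

test_that("non-convergent ascertainment aborts with a diagnostic", {
  p <- sim_params(n_families = 5, children_per_family = 2, n_snps = 1,
                  male_prevalence = 1e-5, female_prevalence = 1e-5,
                  shared_sib_var = 0, ascertainment_min_affected = 2,
                  seed = 3)
  expect_error(simulate_families(p), "acceptance probability")
})

test_that("causal variance bookkeeping rejects an over-unit liability", {
  p <- sim_params(n_families = 5, n_snps = 1,
                  causal = data.frame(snp = 1, model = "additive", beta = 2),
                  shared_sib_var = 0.5, maf_range = c(0.49, 0.5), seed = 1)
  expect_error(simulate_families(p), "< 1")
})

test_that("evidence simulation honours p_true/p_false extremes and the seed", {
  co <- random_cohort(n_fam = 10, n_snps = 20, seed = 11)
  causal <- co$map$snp[1:5]
  ev <- simulate_evidence(co, causal, p_true = 1, p_false = 0, seed = 4)
  is_causal <- ev$snp %in% causal
  on <- function(x) if (is.logical(x)) x else x != "none"
  flags <- c("within_gene", "is_eqtl", "prior_report", "expression_diff",
             "cns_specific", "mouse_cns_model", "pathway_member")
  for (f in flags) {
    expect_true(all(on(ev[[f]][is_causal])), info = f)
    expect_false(any(on(ev[[f]][!is_causal])), info = f)
  }
  expect_identical(ev, simulate_evidence(co, causal, 1, 0, seed = 4))
  expect_error(simulate_evidence(co, "nope", 1, 0, seed = 1), "unknown SNP")
})

test_that("causal genes accumulate more functional points than null genes", {
  co <- random_cohort(n_fam = 10, n_snps = 200, seed = 12)
  causal <- co$map$snp[1:20]
  ev <- simulate_evidence(co, causal, p_true = 0.8, p_false = 0.1, seed = 9)
  prof <- dplyr::mutate(ev, gwas_p = 0.5, sibling_or = 1)
  cards <- score_pair(prof)
  m_causal <- mean(cards$total[cards$snp %in% causal])
  m_null <- mean(cards$total[!cards$snp %in% causal])
  expect_gt(m_causal, m_null)
})

test_that("simulated annotation places genes consistently with the evidence", {
  co <- random_cohort(n_fam = 10, n_snps = 30, seed = 13)
  ev <- simulate_evidence(co, co$map$snp[1:10], 0.9, 0.2, seed = 5)
  ann <- simulate_annotation(ev, co$map, seed = 6)
  pairs <- map_snp_to_genes(co$map, ann)
  hit <- dplyr::inner_join(ev, pairs, by = c("snp", "gene"))
  expect_true(all((hit$distance == 0) == hit$within_gene))
})

test_that("odds-ratio-to-liability helper is monotone and vanishes at OR 1", {
  expect_equal(liability_effect_from_or(1, 0.01), 0)
  b <- liability_effect_from_or(c(1.2, 1.5, 2), 0.01)
  expect_true(all(diff(b) > 0))
  expect_lt(b[3], 1)
})
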
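test_that("genetic scores apply model codings by hand rules", {
  # two SNPs: s1 additive with risk A, s2 recessive with risk G (= a2)
  ind <- tibble::tibble(
    id = c("F1_P1", "F1_P2", "F1_C1", "F1_C2"), family = "F1",
    father = c("0", "0", "F1_P1", "F1_P1"),
    mother = c("0", "0", "F1_P2", "F1_P2"),
    sex = c("male", "female", "male", "male"),
    status = c("unknown", "unknown", "affected", "unaffected")
  )
  # counts of A1 = A: C1 is AA at s1 (2) and Aa at s2 (1 -> 1 copy of G)
  geno <- rbind(c(1L, 1L), c(1L, 1L), c(2L, 1L), c(0L, 0L))
  map <- tibble::tibble(snp = c("s1", "s2"), chrom = 1, pos = c(100L, 200L),
                        a1 = "A", a2 = "G")
  co <- family_cohort(ind, geno, map)
  gsm <- structure(
    tibble::tibble(snp = c("s1", "s2"), risk_allele = c("A", "G"),
                   model = c("additive", "recessive")),
    class = c("gs_model", class(tibble::tibble())), sex = "male",
    direction_filtered = FALSE
  )
  sc <- compute_gs(co, gsm)
  # C1: additive(AA)=2 + recessive(1 copy of G)=0 -> 2
  expect_equal(sc$gs[sc$id == "F1_C1"], 2)
  # C2: additive(aa)=0 + recessive(GG)=1 -> 1
  expect_equal(sc$gs[sc$id == "F1_C2"], 1)
  # homozygous non-risk everywhere scores 0
  co0 <- co; co0$genotypes[3, ] <- c(0L, 2L)
  expect_equal(compute_gs(co0, gsm)$gs[1], 0)
  # missing genotypes take the cohort mean coding and are flagged
  com <- co; com$genotypes[3, 1] <- NA
  scm <- compute_gs(com, gsm)
  # C2 is the only other scored child, so the s1 mean coding is additive(0) = 0
  expect_equal(scm$gs[scm$id == "F1_C1"], 0 + 0)
  expect_true(scm$imputed[scm$id == "F1_C1"])
  # one of two SNPs is exactly half, not "more than half": not low confidence
  expect_false(scm$low_confidence[scm$id == "F1_C1"])
  com$genotypes[3, 2] <- NA
  scm2 <- compute_gs(com, gsm)
  expect_true(scm2$low_confidence[scm2$id == "F1_C1"])
  # both SNPs imputed from C2: additive(0) = 0 and recessive(GG) = 1
  expect_equal(scm2$gs[scm2$id == "F1_C1"], 1)
  expect_error(compute_gs(co, gsm[0, ]), "no SNPs")
  # rescale imputation: observed sum scaled up by m / n_observed
  scr <- compute_gs(com, gsm, impute = "rescale")
  # C1 has both SNPs missing -> undefined under rescaling
  expect_true(is.na(scr$gs[scr$id == "F1_C1"]))
  com2 <- co; com2$genotypes[3, 2] <- NA   # only s2 missing for C1
  scr2 <- compute_gs(com2, gsm, impute = "rescale")
  expect_equal(scr2$gs[scr2$id == "F1_C1"], 2 * 2 / 1)
})

test_that("integer scores when nothing is missing", {
  co <- random_cohort(n_fam = 25, n_snps = 6, seed = 24)
  gsm <- structure(
    tibble::tibble(snp = co$map$snp[1:4], risk_allele = "A",
                   model = c("additive", "dominant", "recessive", "additive")),
    class = c("gs_model", class(tibble::tibble())), sex = "both",
    direction_filtered = FALSE
  )
  sc <- compute_gs(co, gsm)
  expect_true(all(sc$gs == round(sc$gs)))
  expect_false(any(sc$imputed))
})

test_that("best-model selection recovers a strong recessive architecture", {
  hits <- vapply(1:5, function(s) {
    p <- sim_params(n_families = 400, children_per_family = 2:3, n_snps = 2,
                    maf_range = c(0.4, 0.5),
                    causal = data.frame(snp = 1, model = "recessive",
                                        beta = 0.7),
                    shared_sib_var = 0.2, male_prevalence = 0.08,
                    female_prevalence = 0.08, seed = 300 + s)
    co <- simulate_families(p)
    gsm <- select_best_model(co, tibble::tibble(snp = "snp0001",
                                                risk_allele = "A"),
                             sex = "male")
    nrow(gsm) == 1 && gsm$model == "recessive"
  }, logical(1))
  expect_gte(sum(hits), 3)
})

test_that("direction filtering drops SNPs with no risk-increasing coding", {
  # protective allele: code the WRONG allele as risk -> all ORs <= 1
  p <- sim_params(n_families = 300, n_snps = 1, maf_range = c(0.3, 0.4),
                  causal = data.frame(snp = 1, model = "additive", beta = 0.5),
                  shared_sib_var = 0.2, male_prevalence = 0.1,
                  female_prevalence = 0.1, seed = 26)
  co <- simulate_families(p)
  gsm <- select_best_model(co, tibble::tibble(snp = "snp0001",
                                              risk_allele = "G"),
                           sex = "both")
  expect_equal(nrow(gsm), 0)
  off <- select_best_model(co, tibble::tibble(snp = "snp0001",
                                              risk_allele = "G"),
                           sex = "both", direction_filter = FALSE)
  expect_equal(nrow(off), 1)
  expect_error(select_best_model(co, tibble::tibble(snp = character(),
                                                    risk_allele = character()),
                                 sex = "male"), "empty")
})

test_that("evaluation on validation data reports the full variance decomposition", {
  beta <- sqrt(0.025 / 0.42)
  causal <- data.frame(snp = 1:4, model = "additive", beta = beta)
  mk <- function(seed, n) sim_params(
    n_families = n, n_snps = 8, maf_range = c(0.25, 0.35), causal = causal,
    shared_sib_var = 0.35, seed = seed
  )
  disc <- simulate_families(mk(27, 250))
  vali <- simulate_families(mk(28, 250))
  gsm <- select_best_model(disc, tibble::tibble(snp = disc$map$snp[1:4],
                                                risk_allele = "A"),
                           sex = "male")
  expect_gt(nrow(gsm), 0)
  lp <- liability_params(1 / 54, sibling_recurrence(0.4, 1 / 54))
  vr <- evaluate_gs(vali, gsm, lp)
  expect_s3_class(vr, "variance_result")
  expect_gte(vr$auc, 0.5)
  expect_gte(vr$v, 0)
  expect_lt(vr$v, 1)
  expect_gte(vr$genetic_variance_explained, 0)
  expect_lte(vr$genetic_variance_explained, 1)
  expect_gt(vr$grr, 0)
  # evaluation never re-selects: the model passed in is used verbatim
  expect_identical(attr(gsm, "sex"), "male")
})

test_that("a null score explains approximately nothing", {
  p <- sim_params(n_families = 250, n_snps = 6, male_prevalence = 0.1,
                  female_prevalence = 0.05, shared_sib_var = 0.4, seed = 29)
  vali <- simulate_families(p)
  gsm <- structure(
    tibble::tibble(snp = vali$map$snp[1:3], risk_allele = "A",
                   model = "additive"),
    class = c("gs_model", class(tibble::tibble())), sex = "both",
    direction_filtered = FALSE
  )
  lp <- liability_params(0.1, 0.3)
  vr <- evaluate_gs(vali, gsm, lp)
  expect_lt(vr$genetic_variance_explained, 0.05)
})
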
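test_that("SNP-gene mapping follows the 5 kb / 50 kb window rules", {
  ann <- tibble::tibble(
    gene = c("near", "up", "down", "far"),
    chrom = 1,
    start = c(103000, 60000, 120000, 300000),
    end = c(110000, 70000, 130000, 310000)
  )
  # 3 kb away: the single nearest proximal gene
  p1 <- map_snp_to_genes(tibble::tibble(snp = "s1", chrom = 1, pos = 100000), ann)
  expect_equal(p1$gene, "near")
  expect_equal(p1$distance, 3000)
  # no gene within 5 kb; nearest upstream 30 kb and downstream 20 kb: both
  ann2 <- ann[ann$gene != "near", ]
  p2 <- map_snp_to_genes(tibble::tibble(snp = "s2", chrom = 1, pos = 100000), ann2)
  expect_setequal(p2$gene, c("up", "down"))
  expect_setequal(p2$distance, c(30000, 20000))
  # nearest gene 60 kb away: no pair
  p3 <- map_snp_to_genes(tibble::tibble(snp = "s3", chrom = 1, pos = 180000),
                         ann[ann$gene == "far", , drop = FALSE])
  expect_equal(nrow(p3), 0)
  # inside a span: distance 0
  p4 <- map_snp_to_genes(tibble::tibble(snp = "s4", chrom = 1, pos = 105000), ann)
  expect_equal(p4$distance, 0)
  expect_equal(p4$side, "within")
  # chromosome mismatch: empty
  p5 <- map_snp_to_genes(tibble::tibble(snp = "s5", chrom = 2, pos = 105000), ann)
  expect_equal(nrow(p5), 0)
})

test_that("proximal ties return all tied genes", {
  ann <- tibble::tibble(gene = c("a", "b"), chrom = 1,
                        start = c(96000, 102000), end = c(98000, 104000))
  p <- map_snp_to_genes(tibble::tibble(snp = "s", chrom = 1, pos = 100000), ann)
  expect_setequal(p$gene, c("a", "b"))
})

test_that("the score card reproduces the printed point lattice", {
  expect_equal(score_pair(maximal_profile())$total, 9)
  expect_equal(score_pair(empty_profile())$total, 0)
  # 0.5 + 1 + 1 + 0.5 + 0.5 = 3.5, then brain + eQTL -> 5.0
  p <- empty_profile()
  p$gwas_p <- 1e-6; p$sibling_or <- 1.6; p$within_gene <- TRUE
  p$prior_report <- "related_disorder"; p$expression_diff <- "lymphoblastoid"
  c1 <- score_pair(p)
  expect_equal(c1$total, 3.5)
  expect_false(c1$selected)
  p$expression_diff <- "brain"; p$is_eqtl <- TRUE
  c2 <- score_pair(p)
  expect_equal(c2$total, 5.0)
  expect_true(c2$selected)
})

test_that("band boundaries are half-open with the stricter side winning", {
  p <- empty_profile()
  p$gwas_p <- 1e-5
  expect_equal(score_pair(p)$statistical_points, 0)
  p$gwas_p <- 1e-8
  expect_equal(score_pair(p)$statistical_points, 0.5)
  p$gwas_p <- 1e-9
  expect_equal(score_pair(p)$statistical_points, 1)
  p$sibling_or <- 1.5   # >= is inclusive
  expect_equal(score_pair(p)$statistical_points, 2)
})

test_that("scoring is monotone, capped, pure and lands on the half-point lattice", {
  set.seed(9)
  rand_profile <- function() tibble::tibble(
    gwas_p = 10^runif(1, -10, 0), sibling_or = runif(1, 0.5, 3),
    within_gene = runif(1) < 0.5, is_eqtl = runif(1) < 0.5,
    prior_report = sample(c("none", "related_disorder", "autism"), 1),
    expression_diff = sample(c("none", "lymphoblastoid", "brain"), 1),
    cns_specific = runif(1) < 0.5, mouse_cns_model = runif(1) < 0.5,
    pathway_member = runif(1) < 0.5
  )
  upgrades <- list(
    function(p) { p$gwas_p <- p$gwas_p / 1e4; p },
    function(p) { p$sibling_or <- p$sibling_or + 1; p },
    function(p) { p$within_gene <- TRUE; p },
    function(p) { p$is_eqtl <- TRUE; p },
    function(p) { p$prior_report <- "autism"; p },
    function(p) { p$expression_diff <- "brain"; p },
    function(p) { p$cns_specific <- TRUE; p },
    function(p) { p$mouse_cns_model <- TRUE; p },
    function(p) { p$pathway_member <- TRUE; p }
  )
  for (i in 1:50) {
    p <- rand_profile()
    card <- score_pair(p)
    expect_lte(card$statistical_points, 2)
    expect_lte(card$genomic_points, 2)
    expect_lte(card$previous_points, 1)
    expect_lte(card$physiological_points, 4)
    expect_equal(card$total,
                 card$statistical_points + card$genomic_points +
                   card$previous_points + card$physiological_points)
    expect_true(card$total %in% seq(0, 9, by = 0.5))
    up <- upgrades[[sample(9, 1)]](p)
    expect_gte(score_pair(up)$total, card$total)
    expect_identical(score_pair(p), card)   # pure function
  }
})

test_that("the cutoff is a closed bound and any pair can qualify a SNP", {
  p4 <- empty_profile()
  p4$sibling_or <- 1.5; p4$within_gene <- TRUE; p4$is_eqtl <- TRUE
  p4$prior_report <- "autism"
  card <- score_pair(p4)
  expect_equal(card$total, 4)
  expect_true(card$selected)   # exactly 4 selects

  co <- random_cohort(n_fam = 10, n_snps = 2, seed = 19)
  snp <- co$map$snp[1]
  cand <- tibble::tibble(snp = snp, family_p = 1e-4, or = 1.6)
  ann <- tibble::tibble(gene = c("g1", "g2"), chrom = co$map$chrom[1],
                        start = c(co$map$pos[1] - 1000, co$map$pos[1] + 20000),
                        end = c(co$map$pos[1] + 1000, co$map$pos[1] + 22000))
  # g1 within gene; give g2 strong functional evidence reachable at 20 kb
  # only when no proximal gene exists, so test the any-pair rule via g1 alone
  ev <- tibble::tibble(
    snp = snp, gene = c("g1", "g2"),
    within_gene = c(TRUE, FALSE), is_eqtl = c(TRUE, FALSE),
    prior_report = c("autism", "none"), expression_diff = c("none", "none"),
    cns_specific = FALSE, mouse_cns_model = FALSE, pathway_member = FALSE
  )
  cards <- prioritize(cand, ev, ann, co$map)
  expect_true(any(cards$selected))
  expect_equal(cards$gene[cards$best_pair], "g1")
})

test_that("candidates missing from the evidence table score on statistics alone", {
  co <- random_cohort(n_fam = 10, n_snps = 2, seed = 20)
  snp <- co$map$snp[1]
  cand <- tibble::tibble(snp = snp, family_p = 1e-9, or = 2.0)
  ann <- tibble::tibble(gene = "g1", chrom = co$map$chrom[1],
                        start = co$map$pos[1] - 500, end = co$map$pos[1] + 500)
  ev <- tibble::tibble(snp = character(), gene = character(),
                       within_gene = logical(), is_eqtl = logical(),
                       prior_report = character(), expression_diff = character(),
                       cns_specific = logical(), mouse_cns_model = logical(),
                       pathway_member = logical())
  expect_message(cards <- prioritize(cand, ev, ann, co$map), "absent")
  # p < 1e-8 (1) + OR >= 1.5 (1) + within gene (1): functional flags off
  expect_equal(cards$total, 3)
  expect_false(any(cards$selected))
})
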
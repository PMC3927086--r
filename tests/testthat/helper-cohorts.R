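# Cohort builders used across the suite. All fixtures are constructed in
# code; nothing is read from disk.

# One-SNP cohort of trios: vectors fa, mo, ch give copies of allele A per
# family (one child each unless ch is a list of per-family child vectors).
trios_cohort <- function(fa, mo, ch, status = "affected", sex = "male") {
  n <- length(fa)
  ch <- if (is.list(ch)) ch else as.list(ch)
  status <- rep_len(status, n)
  sex <- rep_len(sex, n)
  rows <- list(); geno <- list()
  for (i in seq_len(n)) {
    k <- length(ch[[i]])
    fam <- sprintf("F%04d", i)
    rows[[i]] <- tibble::tibble(
      id = paste0(fam, c("_P1", "_P2", paste0("_C", seq_len(k)))),
      family = fam,
      father = c("0", "0", rep(paste0(fam, "_P1"), k)),
      mother = c("0", "0", rep(paste0(fam, "_P2"), k)),
      sex = c("male", "female", rep_len(sex[i], k)),
      status = c("unknown", "unknown", rep_len(status[i], k))
    )
    geno[[i]] <- c(fa[i], mo[i], ch[[i]])
  }
  family_cohort(
    dplyr::bind_rows(rows),
    matrix(unlist(geno), ncol = 1),
    tibble::tibble(snp = "s1", chrom = 1, pos = 100L, a1 = "A", a2 = "G")
  )
}

# Null transmission cohort: parents at HWE, children by Mendelian
# transmission, ALL children labelled affected (affection independent of
# genotype — the exact null of the transmission test). Vectorized.
null_trio_cohort <- function(n_fam, maf = 0.3, kids = 2) {
  fa <- rbinom(n_fam, 2, maf)
  mo <- rbinom(n_fam, 2, maf)
  tr <- function(g) (g == 2L) * 1L + (g == 1L) * rbinom(length(g), 1, 0.5)
  ch <- lapply(seq_len(kids), function(j) tr(fa) + tr(mo))
  fam <- sprintf("F%05d", seq_len(n_fam))
  ind <- tibble::tibble(
    id = c(paste0(fam, "_P1"), paste0(fam, "_P2"),
           unlist(lapply(seq_len(kids), function(j) paste0(fam, "_C", j)))),
    family = rep(fam, 2 + kids),
    father = c(rep("0", 2 * n_fam), rep(paste0(fam, "_P1"), kids)),
    mother = c(rep("0", 2 * n_fam), rep(paste0(fam, "_P2"), kids)),
    sex = rep("male", (2 + kids) * n_fam),
    status = c(rep("unknown", 2 * n_fam), rep("affected", kids * n_fam))
  )
  family_cohort(ind, matrix(c(fa, mo, unlist(ch)), ncol = 1),
                tibble::tibble(snp = "s1", chrom = 1, pos = 100L,
                               a1 = "A", a2 = "G"))
}

# Small multi-SNP cohort for round-trip properties (fast: high prevalence
# so ascertainment is cheap).
random_cohort <- function(n_fam = 20, n_snps = 5, seed = 1, missing_rate = 0) {
  simulate_families(sim_params(
    n_families = n_fam, n_snps = n_snps, children_per_family = 2:3,
    male_prevalence = 0.4, female_prevalence = 0.3,
    shared_sib_var = 0.2, missing_rate = missing_rate, seed = seed
  ))
}

# A full evidence profile with every field at its strongest level.
maximal_profile <- function() {
  tibble::tibble(
    gwas_p = 1e-9, sibling_or = 1.5, within_gene = TRUE, is_eqtl = TRUE,
    prior_report = "autism", expression_diff = "brain", cns_specific = TRUE,
    mouse_cns_model = TRUE, pathway_member = TRUE
  )
}

empty_profile <- function() {
  tibble::tibble(
    gwas_p = 0.5, sibling_or = 1.0, within_gene = FALSE, is_eqtl = FALSE,
    prior_report = "none", expression_diff = "none", cns_specific = FALSE,
    mouse_cns_model = FALSE, pathway_member = FALSE
  )
}

# Independent HWE oracle: direct log-factorial multinomial formula
# (conditional on allele counts), summing probabilities <= observed.
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  het <- seq(min(nA, na) %% 2, min(nA, na), by = 2)
  lp <- vapply(het, function(h) {
    naa_h <- (na - h) / 2
    nAA_h <- (nA - h) / 2
    lfactorial(n) - lfactorial(nAA_h) - lfactorial(h) - lfactorial(naa_h) +
      h * log(2) + lfactorial(nA) + lfactorial(na) - lfactorial(2 * n)
  }, numeric(1))
  p <- exp(lp - max(lp)); p <- p / sum(p)
  obs <- match(n_Aa, het)
  min(1, sum(p[p <= p[obs] * (1 + 1e-9)]))
}
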
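#' Simulation parameters for multiplex-family cohorts
#'
#' Defines the generative model: nuclear families (two parents, several
#' children), diallelic SNPs in Hardy-Weinberg proportions without linkage
#' disequilibrium, and a standard-normal liability for each child composed of
#' a causal-SNP genetic component, a sibling-shared Gaussian component and an
#' independent residual. A child is affected when liability exceeds the
#' sex-specific threshold \eqn{\Phi^{-1}(1-K_{sex})}. Families are
#' ascertained on a minimum number of affected children (multiplex design).
#'
#' Defaults mirror a multiplex autism cohort: prevalence 1/54 in males and
#' 1/252 in females (about a 4:1 affected sex ratio emerges from the two
#' thresholds, with children's sexes drawn 50:50), ascertainment on two or
#' more affected children, and a sibling-shared variance of 0.643, calibrated
#' with [calibrate_shared_sib_var()] so that, with no causal SNPs, the
#' recurrence risk among brothers of affected boys is 25.9%.
#'
#' @param n_families Number of ascertained families to emit.
#' @param children_per_family Integer vector; each family's number of
#'   children is drawn uniformly from it (default `2:4`).
#' @param n_snps Number of independent diallelic SNPs.
#' @param maf_range Range the per-SNP minor allele frequency is drawn from.
#' @param causal Data frame with columns `snp` (index into the SNP panel),
#'   `model` (`"additive"`, `"dominant"` or `"recessive"`) and `beta`
#'   (liability effect per risk-genotype unit on the standardized liability
#'   scale, risk allele = A1). `NULL` for no causal SNPs.
#' @param shared_sib_var Variance fraction in `[0, 1)` of the sibling-shared
#'   Gaussian liability component.
#' @param male_prevalence,female_prevalence Lifetime prevalences `K` in (0,1).
#' @param ascertainment_min_affected Minimum affected children per family.
#' @param missing_rate,genotype_error_rate Per-genotype rates (default 0) of
#'   missingness and of replacement by a fresh Hardy-Weinberg draw, applied
#'   after family assembly to exercise quality control.
#' @param seed Integer seed; the generator is fully reproducible given it.
#'
#' @return A list of class `sim_params`.
#' @seealso [simulate_families()]
#' @export
sim_params <- function(n_families = 545,
                       children_per_family = 2:4,
                       n_snps = 100,
                       maf_range = c(0.1, 0.5),
                       causal = NULL,
                       shared_sib_var = 0.643,
                       male_prevalence = 1 / 54,
                       female_prevalence = 1 / 252,
                       ascertainment_min_affected = 2,
                       missing_rate = 0,
                       genotype_error_rate = 0,
                       seed = NULL) {
  if (is.null(causal)) {
    causal <- tibble(snp = integer(), model = character(), beta = double())
  }
  causal <- as_tibble(causal)
  stopifnot(
    n_families >= 1, n_snps >= 1,
    all(children_per_family >= 1),
    length(maf_range) == 2, all(maf_range > 0), all(maf_range < 1),
    male_prevalence > 0, male_prevalence < 1,
    female_prevalence > 0, female_prevalence < 1,
    shared_sib_var >= 0, shared_sib_var < 1,
    ascertainment_min_affected >= 0,
    missing_rate >= 0, missing_rate < 1,
    genotype_error_rate >= 0, genotype_error_rate < 1
  )
  if (nrow(causal) > 0) {
    stopifnot(all(causal$snp >= 1), all(causal$snp <= n_snps),
              all(causal$model %in% c("additive", "dominant", "recessive")))
    if (anyDuplicated(causal$snp)) abort("duplicate causal SNP indices")
  }
  p <- list(
    n_families = as.integer(n_families),
    children_per_family = as.integer(children_per_family),
    n_snps = as.integer(n_snps),
    maf_range = maf_range,
    causal = causal,
    shared_sib_var = shared_sib_var,
    male_prevalence = male_prevalence,
    female_prevalence = female_prevalence,
    ascertainment_min_affected = as.integer(ascertainment_min_affected),
    missing_rate = missing_rate,
    genotype_error_rate = genotype_error_rate,
    seed = seed
  )
  class(p) <- "sim_params"
  p
}

# genotype coding: copies of the risk allele -> model score
code_genotype <- function(g, model) {
  switch(model,
    additive  = g,
    dominant  = (g >= 1L) * 1L,
    recessive = (g == 2L) * 1L,
    abort(paste0("unknown genetic model: ", model))
  )
}

# mean/variance of the coded genotype under HWE at risk-allele frequency p
coding_moments <- function(p, model) {
  pr <- c((1 - p)^2, 2 * p * (1 - p), p^2)
  x <- code_genotype(0:2, model)
  m <- sum(pr * x)
  list(mean = m, var = sum(pr * x^2) - m^2)
}

#' Simulate an ascertained multiplex-family cohort
#'
#' Parents are drawn at Hardy-Weinberg proportions per SNP; each child's
#' genotype arises from independent Mendelian transmission, so child
#' genotypes are Mendel-consistent with parents by construction. The child
#' liability is the centred sum of causal effects plus a sibling-shared
#' Gaussian and an independent residual, with total variance 1. Families are
#' regenerated until `n_families` meet the ascertainment rule.
#'
#' For efficiency, ascertainment is decided from liabilities (which involve
#' only the causal SNPs); genotypes at the remaining null SNPs, being
#' independent of affection status, are filled in for accepted families only
#' — the joint distribution is identical to generating everything up front.
#'
#' @param params A [sim_params()] object.
#' @param ascertain If `FALSE`, emit the first `n_families` generated without
#'   applying the ascertainment rule (useful for prevalence checks).
#' @return A [family_cohort()]. The drawn minor allele frequencies are
#'   attached as `attr(, "maf")`.
#' @export
simulate_families <- function(params, ascertain = TRUE) {
  stopifnot(inherits(params, "sim_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  n_snps <- params$n_snps
  maf <- runif(n_snps, params$maf_range[1], params$maf_range[2])
  causal <- params$causal
  ci <- causal$snp
  # variance bookkeeping on the liability scale
  g_var <- 0
  if (nrow(causal) > 0) {
    mom <- purrr::map2(maf[ci], causal$model, coding_moments)
    g_mean <- map_dbl(mom, "mean")
    g_var <- sum(causal$beta^2 * map_dbl(mom, "var"))
  }
  resid_var <- 1 - g_var - params$shared_sib_var
  if (resid_var <= 0) {
    abort("causal liability variance + shared_sib_var must be < 1")
  }
  thr <- c(male = qnorm(1 - params$male_prevalence),
           female = qnorm(1 - params$female_prevalence))

  kmax <- max(params$children_per_family)
  draw_batch <- function(m) {
    kk <- params$children_per_family
    nk <- if (length(kk) == 1L) rep(kk, m) else sample(kk, m, replace = TRUE)
    # parents at causal SNPs only (ascertainment needs just these)
    nc <- length(ci)
    fa <- matrix(rbinom(m * nc, 2L, rep(maf[ci], each = m)), m, nc)
    mo <- matrix(rbinom(m * nc, 2L, rep(maf[ci], each = m)), m, nc)
    shared <- rnorm(m, 0, sqrt(params$shared_sib_var))
    kid_g <- vector("list", kmax)
    kid_sex <- matrix(sample(c("male", "female"), m * kmax, replace = TRUE), m, kmax)
    kid_aff <- matrix(FALSE, m, kmax)
    for (j in seq_len(kmax)) {
      g <- transmit(fa) + transmit(mo)
      kid_g[[j]] <- g
      lia <- shared + rnorm(m, 0, sqrt(resid_var))
      if (nc > 0) {
        coded <- g
        for (k in seq_len(nc)) coded[, k] <- code_genotype(g[, k], causal$model[k])
        lia <- lia + drop(sweep(coded, 2, g_mean) %*% causal$beta)
      }
      kid_aff[, j] <- lia > thr[kid_sex[, j]]
    }
    active <- matrix(vapply(seq_len(kmax), function(j) j <= nk, logical(m)), m, kmax)
    list(nk = nk, fa = fa, mo = mo, kid_g = kid_g, kid_sex = kid_sex,
         kid_aff = kid_aff & active, active = active)
  }

  keep <- list()
  accepted <- 0L
  tried <- 0L
  target <- params$n_families
  repeat {
    m <- if (tried == 0L) max(1000L, 2L * target) else {
      acc <- max(accepted / tried, 1 / tried)
      min(200000L, max(2000L, ceiling(1.3 * (target - accepted) / acc)))
    }
    if (!ascertain) m <- target
    b <- draw_batch(m)
    ok <- if (ascertain) {
      rowSums(b$kid_aff) >= params$ascertainment_min_affected
    } else rep(TRUE, m)
    tried <- tried + m
    accepted <- accepted + sum(ok)
    if (any(ok)) keep[[length(keep) + 1L]] <- lapply(
      list(nk = b$nk, fa = b$fa, mo = b$mo, kid_sex = b$kid_sex,
           kid_aff = b$kid_aff, active = b$active),
      function(x) if (is.matrix(x)) x[ok, , drop = FALSE] else x[ok]
    )
    if (any(ok)) {
      keep[[length(keep)]]$kid_g <- lapply(b$kid_g, function(g) g[ok, , drop = FALSE])
    }
    if (accepted >= target) break
    if ((accepted + 1) / (tried + 2) < 1e-6) {
      abort(paste0("ascertainment acceptance probability estimated below 1e-6 (",
                   accepted, "/", tried, " families accepted); ",
                   "check prevalences and ascertainment_min_affected"))
    }
  }

  nk <- unlist(lapply(keep, `[[`, "nk"))[seq_len(target)]
  pick <- function(name) do.call(rbind, lapply(keep, `[[`, name))[seq_len(target), , drop = FALSE]
  fa_c <- pick("fa"); mo_c <- pick("mo")
  kid_sex <- pick("kid_sex"); kid_aff <- pick("kid_aff"); active <- pick("active")
  kid_g_c <- lapply(seq_len(kmax), function(j) {
    do.call(rbind, lapply(keep, function(b) b$kid_g[[j]]))[seq_len(target), , drop = FALSE]
  })

  # fill genotypes at the null SNPs for accepted families only
  null_i <- setdiff(seq_len(n_snps), ci)
  nn <- length(null_i)
  fa_full <- matrix(NA_integer_, target, n_snps)
  mo_full <- matrix(NA_integer_, target, n_snps)
  fa_full[, ci] <- fa_c; mo_full[, ci] <- mo_c
  if (nn > 0) {
    fa_full[, null_i] <- rbinom(target * nn, 2L, rep(maf[null_i], each = target))
    mo_full[, null_i] <- rbinom(target * nn, 2L, rep(maf[null_i], each = target))
  }
  kid_full <- lapply(seq_len(kmax), function(j) {
    g <- matrix(NA_integer_, target, n_snps)
    g[, ci] <- kid_g_c[[j]]
    if (nn > 0) {
      g[, null_i] <- transmit(fa_full[, null_i, drop = FALSE]) +
        transmit(mo_full[, null_i, drop = FALSE])
    }
    g
  })

  fam_id <- sprintf("F%04d", seq_len(target))
  rows <- list(); geno <- list()
  for (i in seq_len(target)) {
    k <- nk[i]
    ids <- c("P1", "P2", paste0("C", seq_len(k)))
    rows[[i]] <- tibble(
      id = paste0(fam_id[i], "_", ids),
      family = fam_id[i],
      father = c("0", "0", rep(paste0(fam_id[i], "_P1"), k)),
      mother = c("0", "0", rep(paste0(fam_id[i], "_P2"), k)),
      sex = c("male", "female", kid_sex[i, seq_len(k)]),
      status = c("unknown", "unknown",
                 if_else(kid_aff[i, seq_len(k)], "affected", "unaffected"))
    )
    geno[[i]] <- rbind(fa_full[i, ], mo_full[i, ],
                       do.call(rbind, lapply(seq_len(k), function(j) kid_full[[j]][i, ])))
  }
  individuals <- bind_rows(rows)
  genotypes <- do.call(rbind, geno)

  if (params$genotype_error_rate > 0) {
    hit <- which(runif(length(genotypes)) < params$genotype_error_rate)
    col <- (hit - 1L) %/% nrow(genotypes) + 1L
    genotypes[hit] <- rbinom(length(hit), 2L, maf[col])
  }
  if (params$missing_rate > 0) {
    genotypes[runif(length(genotypes)) < params$missing_rate] <- NA_integer_
  }

  map <- tibble(
    snp = sprintf("snp%04d", seq_len(n_snps)),
    chrom = ((seq_len(n_snps) - 1L) %% 22L) + 1L,
    pos = 1000000L + 200000L * ((seq_len(n_snps) - 1L) %/% 22L),
    a1 = "A", a2 = "G"
  )
  out <- family_cohort(individuals, genotypes, map)
  attr(out, "maf") <- maf
  out
}

# one transmitted allele per parent genotype (copies of A1 in the gamete)
transmit <- function(g) {
  t <- (g == 2L) * 1L
  het <- g == 1L
  t[het] <- rbinom(sum(het), 1L, 0.5)
  t
}

#' Simulate a SNP-gene evidence table
#'
#' Emits one synthetic gene per SNP with the functional-genomics evidence
#' fields used by the prioritization score. Each field is "on" with
#' probability `p_true` for genes of causal SNPs and `p_false` otherwise;
#' when a categorical field is on, its stronger level (autism prior, brain
#' expression) is drawn with probability 0.75 and the weaker level
#' (related-disorder prior, lymphoblastoid expression) otherwise.
#'
#' @param cohort A [family_cohort()].
#' @param causal_ids Character vector of causal SNP ids (must exist in the
#'   cohort map).
#' @param p_true,p_false Per-field activation probabilities,
#'   `0 <= p_false < p_true <= 1`.
#' @param seed Integer seed; same seed gives an identical table.
#' @return A tibble with columns `snp`, `gene`, `within_gene`, `is_eqtl`,
#'   `prior_report`, `expression_diff`, `cns_specific`, `mouse_cns_model`,
#'   `pathway_member`.
#' @export
simulate_evidence <- function(cohort, causal_ids, p_true, p_false, seed = NULL) {
  stopifnot(p_false >= 0, p_true <= 1, p_false < p_true)
  unknown <- setdiff(causal_ids, cohort$map$snp)
  if (length(unknown) > 0) {
    abort(paste0("unknown SNP ids: ", paste(head(unknown, 5), collapse = ", ")))
  }
  if (!is.null(seed)) set.seed(seed)
  snp <- cohort$map$snp
  p <- if_else(snp %in% causal_ids, p_true, p_false)
  n <- length(snp)
  flag <- function() runif(n) < p
  lvl <- function(on, hi, lo) {
    pick <- if_else(runif(n) < 0.75, hi, lo)
    if_else(on, pick, "none")
  }
  tibble(
    snp = snp,
    gene = paste0("g.", snp),
    within_gene = flag(),
    is_eqtl = flag(),
    prior_report = lvl(flag(), "autism", "related_disorder"),
    expression_diff = lvl(flag(), "brain", "lymphoblastoid"),
    cns_specific = flag(),
    mouse_cns_model = flag(),
    pathway_member = flag()
  )
}

#' Simulate a gene annotation consistent with an evidence table
#'
#' Places one gene span per evidence row: containing the SNP when the
#' evidence says the SNP is within the gene (+/- 5 kb), otherwise 8-45 kb
#' away so the pair is still reachable through the extended 50 kb window.
#'
#' @param evidence Output of [simulate_evidence()].
#' @param map SNP map (`snp`, `chrom`, `pos`).
#' @param seed Integer seed.
#' @param gene_length Span length in bp.
#' @return A tibble with columns `gene`, `chrom`, `start`, `end`.
#' @export
simulate_annotation <- function(evidence, map, seed = NULL, gene_length = 4000) {
  if (!is.null(seed)) set.seed(seed)
  df <- left_join(evidence[, c("snp", "gene", "within_gene")], map, by = "snp")
  n <- nrow(df)
  inside_off <- floor(runif(n, 0, gene_length))
  gap <- floor(runif(n, 8000, 45000))
  upstream <- runif(n) < 0.5
  start <- if_else(df$within_gene,
                   df$pos - inside_off,
                   if_else(upstream, df$pos + gap, df$pos - gap - gene_length))
  start <- pmax(start, 1)
  tibble(gene = df$gene, chrom = df$chrom,
         start = as.integer(start), end = as.integer(start + gene_length))
}

#' Sibling recurrence risk under a shared liability correlation
#'
#' Probability that a sibling of an affected individual is affected, for a
#' bivariate standard-normal liability with correlation `rho` and prevalence
#' `K` (same threshold for both siblings).
#'
#' @param rho Liability correlation between siblings.
#' @param prevalence Prevalence `K`.
#' @return Recurrence risk `P(L2 > t | L1 > t)`.
#' @export
sibling_recurrence <- function(rho, prevalence) {
  t <- qnorm(1 - prevalence)
  if (rho == 0) return(prevalence)
  f <- function(x) dnorm(x) * pnorm((rho * x - t) / sqrt(1 - rho^2))
  integrate(f, t, Inf, rel.tol = 1e-10)$value / prevalence
}

#' Calibrate the sibling-shared liability variance
#'
#' Finds the sibling liability correlation (equal to the shared-component
#' variance when no causal SNPs contribute) that reproduces a target
#' same-sex sibling recurrence risk at a given prevalence. The package
#' default `shared_sib_var = 0.643` comes from
#' `calibrate_shared_sib_var(0.259, 1/54)`.
#'
#' @param target_recurrence Target sibling recurrence risk.
#' @param prevalence Prevalence `K`.
#' @return The calibrated variance fraction.
#' @export
calibrate_shared_sib_var <- function(target_recurrence, prevalence) {
  uniroot(function(r) sibling_recurrence(r, prevalence) - target_recurrence,
          c(1e-6, 1 - 1e-6), tol = 1e-9)$root
}

#' Convert a per-genotype odds ratio to an approximate liability effect
#'
#' Uses the standard logit-to-liability slope approximation
#' \eqn{\beta \approx \log(OR) \, K(1-K)/\phi(\Phi^{-1}(1-K))}, exact in the
#' limit of small effects.
#'
#' @param or Target odds ratio per unit of the coded genotype.
#' @param prevalence Prevalence `K`.
#' @return Approximate effect per coded-genotype unit on the standardized
#'   liability scale.
#' @export
liability_effect_from_or <- function(or, prevalence) {
  stopifnot(or > 0, prevalence > 0, prevalence < 1)
  K <- prevalence
  log(or) * K * (1 - K) / dnorm(qnorm(1 - K))
}
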
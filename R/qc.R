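#' QC thresholds
#'
#' Default SNP-level filters: Hardy-Weinberg exact p < 1e-3, call rate
#' < 90%, minor allele frequency < 5%.
#'
#' @param hwe_p_min,call_rate_min,maf_min Thresholds, all in (0, 1).
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(hwe_p_min = 1e-3, call_rate_min = 0.90, maf_min = 0.05) {
  stopifnot(hwe_p_min > 0, hwe_p_min < 1, call_rate_min > 0, call_rate_min < 1,
            maf_min > 0, maf_min < 1)
  structure(list(hwe_p_min = hwe_p_min, call_rate_min = call_rate_min,
                 maf_min = maf_min), class = "qc_thresholds")
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact conditional test on genotype counts: the p-value is the sum of
#' probabilities, over all heterozygote counts compatible with the observed
#' allele counts, of configurations no more probable than the observed one.
#' Probabilities are computed with the standard recurrence over adjacent
#' heterozygote counts, which is numerically stable for large samples.
#' A monomorphic sample has a single possible configuration and p = 1.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (nonnegative, total > 0).
#' @return The exact p-value in \[0, 1\].
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n == 0) abort("all genotype counts are zero")
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  rare <- min(nA, na)
  if (rare == 0) return(1)
  # heterozygote counts share the parity of the rare allele count
  het <- seq(rare %% 2, rare, by = 2)
  lp <- numeric(length(het))
  # recurrence: P(h+2)/P(h) = 4 * nAA(h) * naa(h) / ((h+2)(h+1))
  for (k in seq_along(het)[-1]) {
    h <- het[k - 1]
    hom_r <- (rare - h) / 2
    hom_c <- (max(nA, na) - h) / 2
    lp[k] <- lp[k - 1] + log(4 * hom_r * hom_c) - log((h + 2) * (h + 1))
  }
  lp <- lp - max(lp)
  p <- exp(lp) / sum(exp(lp))
  obs <- match(n_Aa, het)
  if (is.na(obs)) abort("heterozygote count inconsistent with allele counts")
  min(1, sum(p[p <= p[obs] * (1 + 1e-9)]))
}

#' SNP-level quality-control filter
#'
#' Computes, per SNP, the founder-based Hardy-Weinberg exact p-value, the
#' call rate over all individuals, and the founder minor allele frequency,
#' and removes SNPs failing any threshold. Founders (the parents) are used
#' for HWE and MAF to avoid the distortion relatedness among siblings would
#' introduce.
#'
#' @param cohort A [family_cohort()].
#' @param thresholds A [qc_thresholds()].
#' @return A list with `cohort` (filtered) and `report`, a tibble with one
#'   row per SNP: `snp`, `maf`, `call_rate`, `hwe_p`, `pass`, `reasons`
#'   (comma-separated among `"maf"`, `"call_rate"`, `"hwe"`).
#' @export
snp_qc_filter <- function(cohort, thresholds = qc_thresholds()) {
  stopifnot(inherits(cohort, "family_cohort"))
  g <- cohort$genotypes
  if (nrow(g) == 0) abort("empty cohort")
  fnd <- is_founder(cohort)
  gf <- g[fnd, , drop = FALSE]
  call_rate <- colMeans(!is.na(g))
  p_a1 <- colMeans(gf, na.rm = TRUE) / 2
  maf <- pmin(p_a1, 1 - p_a1)
  maf[is.nan(maf)] <- 0
  hwe_p <- vapply(seq_len(ncol(gf)), function(j) {
    x <- gf[, j]
    x <- x[!is.na(x)]
    if (length(x) == 0) return(1)
    hwe_exact_test(sum(x == 2L), sum(x == 1L), sum(x == 0L))
  }, numeric(1))
  fail_maf <- maf < thresholds$maf_min
  fail_cr <- call_rate < thresholds$call_rate_min
  fail_hwe <- hwe_p < thresholds$hwe_p_min
  reasons <- vapply(seq_along(maf), function(j) {
    paste(c("maf", "call_rate", "hwe")[c(fail_maf[j], fail_cr[j], fail_hwe[j])],
          collapse = ",")
  }, character(1))
  report <- tibble(snp = cohort$map$snp, maf = maf, call_rate = call_rate,
                   hwe_p = hwe_p, pass = reasons == "", reasons = reasons)
  list(cohort = subset_cohort(cohort, snps = report$pass), report = report)
}

# 3x3x3 lookup: is child genotype c possible given parents f, m (copies of A1)?
mendel_compatible <- local({
  comp <- array(FALSE, c(3, 3, 3))
  for (f in 0:2) for (m in 0:2) for (cc in 0:2) {
    ft <- unique(c((f >= 1) * 1L, (f == 2) * 1L))  # transmissible from father
    mt <- unique(c((m >= 1) * 1L, (m == 2) * 1L))
    comp[f + 1, m + 1, cc + 1] <- cc %in% outer(ft, mt, `+`)
  }
  comp
})

#' Mask Mendelian-inconsistent genotypes family-wide
#'
#' For every (family, SNP) where any child's genotype is incompatible with
#' the parental genotypes under biallelic Mendelian transmission, the
#' genotype is set to missing for every member of that family at that SNP.
#' Children with a missing own or parental genotype cannot be tested and are
#' skipped. Masking is idempotent: a second pass finds no errors.
#'
#' @param cohort A [family_cohort()].
#' @return A list with `cohort` (masked) and `errors`, a tibble with
#'   `family`, `snp` and `n_inconsistent` (children flagged).
#' @export
mendel_mask <- function(cohort) {
  stopifnot(inherits(cohort, "family_cohort"))
  g <- cohort$genotypes
  pid <- parent_index(cohort)
  kid <- which(!is.na(pid$father) & !is.na(pid$mother))
  if (length(kid) == 0) {
    return(list(cohort = cohort,
                errors = tibble(family = character(), snp = character(),
                                n_inconsistent = integer())))
  }
  gf <- g[pid$father[kid], , drop = FALSE]
  gm <- g[pid$mother[kid], , drop = FALSE]
  gc <- g[kid, , drop = FALSE]
  ok <- !is.na(gf) & !is.na(gm) & !is.na(gc)
  bad <- matrix(FALSE, length(kid), ncol(g))
  bad[ok] <- !mendel_compatible[cbind(gf[ok] + 1L, gm[ok] + 1L, gc[ok] + 1L)]
  if (!any(bad)) {
    return(list(cohort = cohort,
                errors = tibble(family = character(), snp = character(),
                                n_inconsistent = integer())))
  }
  idx <- which(bad, arr.ind = TRUE)
  fam <- cohort$individuals$family[kid[idx[, 1]]]
  snp <- cohort$map$snp[idx[, 2]]
  errors <- tibble(family = fam, snp = snp) |>
    dplyr::count(.data$family, .data$snp, name = "n_inconsistent") |>
    arrange(.data$family, .data$snp)
  snp_col <- match(errors$snp, cohort$map$snp)
  for (r in seq_len(nrow(errors))) {
    members <- cohort$individuals$family == errors$family[r]
    g[members, snp_col[r]] <- NA_integer_
  }
  out <- cohort
  out$genotypes <- g
  list(cohort = out, errors = errors)
}
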
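#' Genetic model codings
#'
#' Copies of the risk allele are mapped to a score: additive 0/1/2,
#' dominant 0/1/1, recessive 0/0/1. All model codings are monotone
#' nondecreasing in risk-allele copies.
#'
#' @format Character vector of the three model names.
#' @export
genetic_models <- c("additive", "dominant", "recessive")

#' The four discovery analysis strata
#'
#' Affected children analysed together and by sex, plus the transmission to
#' unaffected children (unstratified), mirroring the four genome-wide runs
#' of the discovery design.
#'
#' @return A tibble with columns `target` and `sex`.
#' @export
analysis_strata <- function() {
  tibble(target = c("affected", "affected", "affected", "unaffected"),
         sex = c("both", "male", "female", "both"))
}

# per-child conditional transmission moments given parental genotypes
# f, m: vectors of parental copies of A1; returns P(child = 0/1/2 copies)
child_geno_probs <- function(f, m) {
  pf <- f / 2; pm <- m / 2
  cbind(p0 = (1 - pf) * (1 - pm),
        p1 = pf * (1 - pm) + (1 - pf) * pm,
        p2 = pf * pm)
}

#' Family-based transmission test for one SNP
#'
#' Computes the transmission score S (sum of the model coding of the target
#' children's genotypes, coded as copies of the A1 allele), its expectation
#' and variance under the exact conditional distribution of offspring
#' genotypes given parental genotypes under Mendelian transmission
#' (offspring treated as independent transmissions, family contributions
#' summed), and the normal-approximation two-sided p-value of
#' Z = (S - E\[S\])/sqrt(V\[S\]). Families in which no child's coding has
#' conditional variance (for example both parents homozygous) are
#' non-informative and excluded from `n_informative`. Families with a
#' missing parental genotype at the SNP are dropped for that SNP.
#'
#' @param cohort A [family_cohort()].
#' @param snp SNP id.
#' @param model One of `"additive"`, `"dominant"`, `"recessive"` (coding of
#'   copies of the A1 allele).
#' @param target Children analysed: `"affected"` or `"unaffected"`.
#' @param sex `"both"`, `"male"` or `"female"`.
#' @param allele Which allele's copies the coding counts (default the SNP's
#'   A1). Testing the three models two-sidedly for one allele spans both
#'   orientations (a dominant coding of one allele is the complement of the
#'   recessive coding of the other).
#' @return A one-row tibble: `snp`, `model`, `target`, `sex`, `S`, `E_S`,
#'   `V_S`, `Z`, `p`, `n_informative`, `direction` (sign of `S - E_S`) and
#'   `risk_allele` (the overtransmitted allele for affected targets; the
#'   undertransmitted — protective-complement — allele for unaffected
#'   targets). Zero total variance gives `Z = 0`, `p = 1`.
#' @export
fbat_test <- function(cohort, snp, model = "additive",
                      target = "affected", sex = "both", allele = NULL) {
  j <- match(snp, cohort$map$snp)
  if (is.na(j)) abort(paste0("SNP not in cohort: ", snp))
  if (!is.null(allele) && !identical(allele, cohort$map$a1[j])) {
    if (!identical(allele, cohort$map$a2[j])) {
      abort(paste0("allele '", allele, "' is neither allele of ", snp))
    }
    old_a1 <- cohort$map$a1[j]
    cohort$genotypes[, j] <- 2L - cohort$genotypes[, j]
    cohort$map$a1[j] <- allele
    cohort$map$a2[j] <- old_a1
  }
  res <- fbat_engine(cohort, j, model, target, sex)
  res$snp <- cohort$map$snp[j]
  res[, c("snp", setdiff(names(res), "snp"))]
}

# vectorised over a set of SNP columns; returns one row per SNP
fbat_engine <- function(cohort, snp_cols, model, target, sex) {
  ind <- cohort$individuals
  pid <- parent_index(cohort)
  sel <- !is.na(pid$father) & !is.na(pid$mother) & ind$status == target
  if (sex != "both") sel <- sel & ind$sex == sex
  kid <- which(sel)
  g <- cohort$genotypes
  x <- code_genotype(0:2, model)
  nsnp <- length(snp_cols)
  out <- tibble(model = model, target = target, sex = sex,
                S = NA_real_, E_S = NA_real_, V_S = NA_real_, Z = 0,
                p = 1, n_informative = 0L, direction = 0,
                risk_allele = NA_character_)
  out <- out[rep(1, nsnp), ]
  if (length(kid) == 0) {
    out$S <- out$E_S <- out$V_S <- 0
    return(out)
  }
  gf <- g[pid$father[kid], snp_cols, drop = FALSE]
  gm <- g[pid$mother[kid], snp_cols, drop = FALSE]
  gc <- g[kid, snp_cols, drop = FALSE]
  use <- !is.na(gf) & !is.na(gm) & !is.na(gc)
  fam <- ind$family[kid]
  S <- E <- V <- numeric(nsnp)
  n_inf <- integer(nsnp)
  for (k in seq_len(nsnp)) {
    u <- use[, k]
    if (!any(u)) { n_inf[k] <- 0L; next }
    pr <- child_geno_probs(gf[u, k], gm[u, k])
    ex <- drop(pr %*% x)
    ex2 <- drop(pr %*% x^2)
    va <- pmax(ex2 - ex^2, 0)
    S[k] <- sum(x[gc[u, k] + 1L])
    E[k] <- sum(ex)
    V[k] <- sum(va)
    n_inf[k] <- length(unique(fam[u][va > 0]))
  }
  out$S <- S; out$E_S <- E; out$V_S <- V
  inf <- V > 0
  out$Z[inf] <- (S[inf] - E[inf]) / sqrt(V[inf])
  out$p[inf] <- 2 * pnorm(-abs(out$Z[inf]))
  out$n_informative <- n_inf
  out$direction <- sign(S - E)
  a1 <- cohort$map$a1[snp_cols]; a2 <- cohort$map$a2[snp_cols]
  over <- if_else(out$direction >= 0, a1, a2)
  under <- if_else(out$direction >= 0, a2, a1)
  # overtransmission to unaffected children marks the OTHER allele as risk
  out$risk_allele <- if (target == "affected") over else under
  out
}

#' Run the family-based GWAS over all SNPs, models and strata
#'
#' One test per (SNP, genetic model, stratum); the default strata are the
#' four discovery runs of [analysis_strata()].
#'
#' @param cohort A [family_cohort()] (QC already applied).
#' @param models Genetic models to test.
#' @param strata Data frame of strata (`target`, `sex`).
#' @return A tibble of class `fbat_results` with one row per combination
#'   (columns as in [fbat_test()]).
#' @export
run_family_gwas <- function(cohort, models = genetic_models,
                            strata = analysis_strata()) {
  cols <- seq_len(ncol(cohort$genotypes))
  res <- purrr::map_dfr(seq_len(nrow(strata)), function(s) {
    purrr::map_dfr(models, function(m) {
      r <- fbat_engine(cohort, cols, m, strata$target[s], strata$sex[s])
      r$snp <- cohort$map$snp
      r
    })
  })
  res <- res[, c("snp", "model", "target", "sex", "S", "E_S", "V_S", "Z", "p",
                 "n_informative", "direction", "risk_allele")]
  class(res) <- c("fbat_results", class(res))
  res
}

#' Best association per SNP
#'
#' The minimum p across models and strata, with its argmin, used for
#' downstream candidate selection and score points.
#'
#' @param results Output of [run_family_gwas()].
#' @return A tibble with one row per SNP (ties broken by model order then
#'   stratum order).
#' @export
best_association <- function(results) {
  results |>
    group_by(.data$snp) |>
    slice_min(.data$p, n = 1, with_ties = FALSE) |>
    ungroup()
}
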
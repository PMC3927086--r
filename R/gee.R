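#' Cluster-robust logistic regression (GEE, independence working correlation)
#'
#' Point estimates are the ordinary logistic maximum-likelihood fit
#' (independence working correlation, IRLS to tolerance 1e-10, at most 100
#' iterations); the covariance is the sandwich A^-1 B A^-1, where A is the
#' Fisher information and B accumulates the outer products of the
#' per-cluster summed score vectors. Wald z statistics and two-sided normal
#' p-values use the robust standard errors.
#'
#' A constant (non-intercept) predictor or a diverging coefficient
#' (|beta| > 15, logistic separation) yields a fit flagged non-estimable;
#' other rank deficiencies are rejected.
#'
#' @param data Data frame with the outcome, predictors and cluster column.
#' @param formula Model formula; the outcome must be 0/1 or logical.
#' @param cluster Name of the cluster-id column (a string).
#' @param or_term Term whose exponentiated coefficient is reported as the
#'   odds ratio; defaults to the first non-intercept term.
#' @return An object of class `gee_fit`.
#' @export
gee_logistic <- function(data, formula, cluster, or_term = NULL) {
  stopifnot(is.data.frame(data), is.character(cluster), length(cluster) == 1)
  if (!cluster %in% names(data)) abort(paste0("no cluster column '", cluster, "'"))
  vars <- all.vars(formula)
  data <- data[complete.cases(data[, c(vars, cluster)]), , drop = FALSE]
  cl <- as.character(data[[cluster]])
  if (length(unique(cl)) < 2) abort("need at least 2 clusters")
  X <- model.matrix(formula, data)
  y <- model.response(stats::model.frame(formula, data))
  y <- as.numeric(y)
  stopifnot(all(y %in% c(0, 1)))
  terms_all <- colnames(X)
  non_int <- setdiff(terms_all, "(Intercept)")
  if (is.null(or_term)) or_term <- if (length(non_int) > 0) non_int[1] else NA
  const <- vapply(non_int, function(tm) length(unique(X[, tm])) == 1, logical(1))
  n_est <- FALSE
  if (any(const)) {
    co <- tibble(term = terms_all, estimate = NA_real_, robust_se = NA_real_,
                 z = NA_real_, p = NA_real_)
    return(new_gee_fit(co, vcov = NULL, n_obs = nrow(X),
                       n_clusters = length(unique(cl)), converged = FALSE,
                       non_estimable = TRUE, or_term = or_term, or = NA_real_,
                       or_p = NA_real_))
  }
  if (qr(X)$rank < ncol(X)) abort("design matrix is rank deficient")
  fit <- glm.fit(X, y, family = binomial(),
                 control = glm.control(epsilon = 1e-10, maxit = 100))
  beta <- fit$coefficients
  if (any(abs(beta) > 15)) n_est <- TRUE
  mu <- fit$fitted.values
  w <- mu * (1 - mu)
  A <- crossprod(X, X * w)
  U <- X * (y - mu)
  Us <- rowsum(U, cl)
  B <- crossprod(Us)
  Ainv <- solve(A)
  V <- Ainv %*% B %*% Ainv
  V <- (V + t(V)) / 2
  se <- sqrt(pmax(diag(V), 0))
  z <- beta / se
  co <- tibble(term = terms_all, estimate = unname(beta),
               robust_se = unname(se), z = unname(z),
               p = 2 * pnorm(-abs(unname(z))))
  orv <- if (!is.na(or_term)) exp(beta[[or_term]]) else NA_real_
  orp <- if (!is.na(or_term)) co$p[co$term == or_term] else NA_real_
  new_gee_fit(co, vcov = V, n_obs = nrow(X), n_clusters = length(unique(cl)),
              converged = fit$converged, non_estimable = n_est,
              or_term = or_term, or = orv, or_p = orp)
}

new_gee_fit <- function(coefficients, vcov, n_obs, n_clusters, converged,
                        non_estimable, or_term, or, or_p) {
  structure(list(coefficients = coefficients, vcov = vcov, n_obs = n_obs,
                 n_clusters = n_clusters, converged = converged,
                 non_estimable = non_estimable, or_term = or_term,
                 or = or, or_p = or_p),
            class = "gee_fit")
}

#' @export
print.gee_fit <- function(x, ...) {
  cat("<gee_fit> cluster-robust logistic fit: ", x$n_obs, " obs in ",
      x$n_clusters, " clusters", if (x$non_estimable) " [non-estimable]",
      "\n", sep = "")
  print(x$coefficients)
  if (!is.na(x$or_term)) {
    cat("OR(", x$or_term, ") = ", format(x$or, digits = 4),
        ", p = ", format(x$or_p, digits = 3), "\n", sep = "")
  }
  invisible(x)
}

#' Sibling case-control association for one SNP
#'
#' Compares affected with unaffected children (parents excluded), clustered
#' by family, with the genotype coded under a genetic model for a designated
#' risk allele. Sex is an adjustment covariate when it is not the
#' stratification variable (`sex = "both"`).
#'
#' @param cohort A [family_cohort()].
#' @param snp SNP id.
#' @param model Genetic model coding.
#' @param sex `"both"`, `"male"` or `"female"`.
#' @param risk_allele Which allele the coding counts; defaults to A1.
#' @return A `gee_fit` (the genotype term's exponentiated coefficient is the
#'   odds ratio).
#' @export
sibling_case_control <- function(cohort, snp, model = "additive",
                                 sex = "both", risk_allele = NULL) {
  j <- match(snp, cohort$map$snp)
  if (is.na(j)) abort(paste0("SNP not in cohort: ", snp))
  if (is.null(risk_allele)) risk_allele <- cohort$map$a1[j]
  ind <- cohort$individuals
  kid <- is_child(cohort) & ind$status %in% c("affected", "unaffected")
  if (sex != "both") kid <- kid & ind$sex == sex
  g <- cohort$genotypes[kid, j]
  df <- tibble(
    y = as.integer(ind$status[kid] == "affected"),
    geno = code_genotype(risk_count(g, risk_allele, cohort$map$a1[j]), model),
    sex = ind$sex[kid],
    family = ind$family[kid]
  )
  df <- df[!is.na(df$geno), , drop = FALSE]
  if (sum(df$y == 0) == 0 || sum(df$y == 1) == 0) {
    abort(paste0("stratum '", sex, "' lacks both affected and unaffected ",
                 "children with genotypes at ", snp))
  }
  form <- if (sex == "both") y ~ geno + sex else y ~ geno
  gee_logistic(df, form, cluster = "family", or_term = "geno")
}

# copies of the designated risk allele, given counts of A1
risk_count <- function(g, risk_allele, a1) {
  if (identical(risk_allele, a1)) g else 2L - g
}

#' Run sibling case-control tests for family-based hits
#'
#' For each (SNP, model, sex) combination among the supplied family-based
#' results, fits the sibling case-control GEE with the genotype coded for
#' that result's designated risk allele in the matching sex stratum.
#'
#' @param cohort A [family_cohort()].
#' @param hits Rows of [run_family_gwas()] output to follow up.
#' @return A tibble: `snp`, `model`, `sex`, `risk_allele`, `or`, `sibling_p`,
#'   `non_estimable`.
#' @export
run_sibling_tests <- function(cohort, hits) {
  combos <- distinct(hits, .data$snp, .data$model, .data$sex, .data$risk_allele)
  purrr::map_dfr(seq_len(nrow(combos)), function(i) {
    fit <- sibling_case_control(cohort, combos$snp[i], combos$model[i],
                                combos$sex[i], combos$risk_allele[i])
    tibble(snp = combos$snp[i], model = combos$model[i], sex = combos$sex[i],
           risk_allele = combos$risk_allele[i], or = fit$or,
           sibling_p = fit$or_p, non_estimable = fit$non_estimable)
  })
}

#' Select candidate SNPs from the two association funnels
#'
#' A SNP qualifies when some (model, stratum) combination has a family-based
#' p below `p_family_max` and the matching sibling case-control test (same
#' model and sex stratum, genotype coded for the family-designated risk
#' allele) is significant at `p_sibling_max` with a concordant direction
#' (odds ratio above 1 for the risk allele). All qualifying combinations are
#' returned.
#'
#' @param family_results Output of [run_family_gwas()].
#' @param sibling_results Output of [run_sibling_tests()].
#' @param p_family_max,p_sibling_max Selection thresholds (defaults 1e-3 and
#'   0.05).
#' @return A tibble: `snp`, `model`, `sex`, `target`, `risk_allele`,
#'   `family_p`, `sibling_p`, `or`.
#' @export
select_candidates <- function(family_results, sibling_results,
                              p_family_max = 1e-3, p_sibling_max = 0.05) {
  fam <- family_results |>
    filter(.data$p < p_family_max) |>
    select("snp", "model", "sex", "target", "risk_allele", family_p = "p")
  joined <- inner_join(fam, sibling_results,
                       by = c("snp", "model", "sex", "risk_allele"))
  joined |>
    filter(!.data$non_estimable, .data$sibling_p < p_sibling_max, .data$or > 1) |>
    select("snp", "model", "sex", "target", "risk_allele", "family_p",
           "sibling_p", "or") |>
    arrange(.data$snp, .data$family_p)
}
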
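#' Select each SNP's best-fitted genetic model in a discovery stratum
#'
#' For every SNP, each of the three codings (of the designated risk allele)
#' is fitted in the discovery sibling case-control design for the given sex
#' stratum; the coding that maximizes the magnitude of the cluster-robust
#' Wald z is chosen (a per-SNP marginal criterion). With the direction
#' filter on, codings whose odds ratio for the risk allele is not above 1
#' are excluded before maximization, and SNPs with no admissible coding are
#' dropped. Criterion ties within 1e-12 resolve additive > dominant >
#' recessive.
#'
#' @param cohort Discovery [family_cohort()].
#' @param snp_set Data frame with columns `snp` and `risk_allele`.
#' @param sex `"male"` or `"female"` (the genetic score is sex-specific).
#' @param direction_filter Exclude codings with OR <= 1 (default `TRUE`).
#' @return A tibble of class `gs_model`: `snp`, `risk_allele`, `model`,
#'   `or`, `z`, with attributes `sex` and `direction_filtered`.
#' @export
select_best_model <- function(cohort, snp_set, sex, direction_filter = TRUE) {
  snp_set <- distinct(as_tibble(snp_set), .data$snp, .data$risk_allele)
  if (nrow(snp_set) == 0) abort("empty SNP set")
  stopifnot(sex %in% c("male", "female", "both"))
  rows <- purrr::map_dfr(seq_len(nrow(snp_set)), function(i) {
    fits <- purrr::map_dfr(genetic_models, function(m) {
      fit <- tryCatch(
        sibling_case_control(cohort, snp_set$snp[i], m, sex,
                             snp_set$risk_allele[i]),
        error = function(e) NULL
      )
      if (is.null(fit) || fit$non_estimable || is.na(fit$or)) return(NULL)
      zt <- fit$coefficients$z[fit$coefficients$term == "geno"]
      tibble(snp = snp_set$snp[i], risk_allele = snp_set$risk_allele[i],
             model = m, or = fit$or, z = zt)
    })
    if (nrow(fits) == 0) return(NULL)
    if (direction_filter) fits <- fits[fits$or > 1, , drop = FALSE]
    if (nrow(fits) == 0) return(NULL)
    crit <- abs(fits$z)
    best <- crit >= max(crit) - 1e-12
    fits[which(best)[1], , drop = FALSE]  # model order is the tie-break
  })
  if (nrow(rows) == 0) {
    rows <- tibble(snp = character(), risk_allele = character(),
                   model = character(), or = double(), z = double())
  }
  structure(rows, class = c("gs_model", class(tibble())),
            sex = sex, direction_filtered = direction_filter)
}

#' Compute genetic scores under a fitted model
#'
#' The genetic score of an individual is the sum, over the model's SNPs, of
#' the model coding of the individual's risk-allele count. A missing
#' genotype contributes the mean coding of that SNP over the cohort being
#' scored (within the scored stratum), flagged per individual; an individual
#' missing more than half the model SNPs is flagged low-confidence.
#'
#' @param cohort A [family_cohort()].
#' @param gs_model A [select_best_model()] result.
#' @param children_only Score only children (default `TRUE`).
#' @param impute `"mean"` (default): a missing genotype contributes the
#'   stratum mean coding of that SNP; `"rescale"`: the sum of observed
#'   codings is rescaled by the number of model SNPs over the number
#'   observed.
#' @return A tibble: `id`, `family`, `sex`, `status`, `gs`, `n_missing`,
#'   `imputed`, `low_confidence`.
#' @export
compute_gs <- function(cohort, gs_model, children_only = TRUE,
                       impute = c("mean", "rescale")) {
  impute <- match.arg(impute)
  stopifnot(inherits(gs_model, "gs_model") || is.data.frame(gs_model))
  if (nrow(gs_model) == 0) abort("genetic-score model has no SNPs")
  sex <- attr(gs_model, "sex") %||% "both"
  ind <- cohort$individuals
  sel <- if (children_only) is_child(cohort) else rep(TRUE, nrow(ind))
  if (sex != "both") sel <- sel & ind$sex == sex
  if (!any(sel)) abort(paste0("no individuals to score in stratum '", sex, "'"))
  j <- match(gs_model$snp, cohort$map$snp)
  if (anyNA(j)) abort("gs_model contains SNPs absent from the cohort")
  coded <- matrix(NA_real_, sum(sel), length(j))
  for (k in seq_along(j)) {
    g <- cohort$genotypes[sel, j[k]]
    r <- risk_count(g, gs_model$risk_allele[k], cohort$map$a1[j[k]])
    coded[, k] <- code_genotype(r, gs_model$model[k])
  }
  n_missing <- rowSums(is.na(coded))
  if (impute == "mean") {
    col_mean <- colMeans(coded, na.rm = TRUE)
    col_mean[is.nan(col_mean)] <- 0
    for (k in seq_along(j)) coded[is.na(coded[, k]), k] <- col_mean[k]
    gs <- rowSums(coded)
  } else {
    n_obs <- length(j) - n_missing
    gs <- rowSums(coded, na.rm = TRUE) * length(j) / pmax(n_obs, 1)
    gs[n_obs == 0] <- NA_real_
  }
  tibble(
    id = ind$id[sel], family = ind$family[sel], sex = ind$sex[sel],
    status = ind$status[sel], gs = gs,
    n_missing = as.integer(n_missing), imputed = n_missing > 0,
    low_confidence = n_missing > length(j) / 2
  )
}

#' AUC of a genetic score (Mann-Whitney)
#'
#' The probability that a random affected individual outscores a random
#' unaffected one, ties counted half; oriented so the returned AUC is at
#' least 0.5, with the orientation recorded.
#'
#' @param case_scores,control_scores Numeric score vectors (both nonempty).
#' @return A list: `auc`, `flipped` (`TRUE` when the raw AUC was below 0.5).
#' @export
auc_of_score <- function(case_scores, control_scores) {
  if (length(case_scores) == 0 || length(control_scores) == 0) {
    abort("both groups must be nonempty")
  }
  n1 <- length(case_scores); n0 <- length(control_scores)
  r <- rank(c(case_scores, control_scores))
  auc <- (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  if (auc < 0.5) list(auc = 1 - auc, flipped = TRUE)
  else list(auc = auc, flipped = FALSE)
}

#' Evaluate a genetic score on a validation cohort
#'
#' Computes the score for all validation children of the model's sex,
#' estimates the genetic relative risk (odds ratio per score unit) and its
#' p-value with the cluster-robust logistic fit, measures the case-control
#' AUC, converts it to the proportion of liability variance `v`
#' ([auc_to_liability_v()]), and reports `v / h2` — the proportion of
#' genetic variance explained — with `h2` the Falconer estimate from the
#' supplied prevalence and sibling recurrence. `v / h2` is clamped to
#' \[0, 1\] with a flag. The model must have been fixed on a separate
#' discovery cohort; nothing is re-estimated here.
#'
#' @param cohort Validation [family_cohort()].
#' @param gs_model A [select_best_model()] result.
#' @param params A [liability_params()] for the model's sex.
#' @param reich Use the Reich-corrected heritability.
#' @return A one-row tibble of class `variance_result`: `sex`, `n_affected`,
#'   `n_unaffected`, `grr`, `p`, `auc`, `v`, `h2`, `h2_flagged`,
#'   `genetic_variance_explained`, `clamped`.
#' @export
evaluate_gs <- function(cohort, gs_model, params, reich = FALSE) {
  stopifnot(inherits(params, "liability_params"))
  scores <- compute_gs(cohort, gs_model)
  scores <- scores[scores$status %in% c("affected", "unaffected"), , drop = FALSE]
  n_aff <- sum(scores$status == "affected")
  n_un <- sum(scores$status == "unaffected")
  if (n_aff == 0 || n_un == 0) {
    abort("validation stratum lacks affected or unaffected children")
  }
  df <- tibble(y = as.integer(scores$status == "affected"),
               gs = scores$gs, family = scores$family)
  fit <- gee_logistic(df, y ~ gs, cluster = "family", or_term = "gs")
  a <- auc_of_score(scores$gs[scores$status == "affected"],
                    scores$gs[scores$status == "unaffected"])
  v <- if (a$auc >= 1) NA_real_ else auc_to_liability_v(a$auc, params)
  h <- heritability_from_recurrence(params, reich = reich)
  gve_raw <- v / h$h2
  clamped <- !is.na(gve_raw) && (gve_raw > 1 || gve_raw < 0)
  out <- tibble(
    sex = attr(gs_model, "sex") %||% "both",
    n_affected = n_aff, n_unaffected = n_un,
    grr = fit$or, p = fit$or_p,
    auc = a$auc, auc_flipped = a$flipped, v = v,
    h2 = h$h2, h2_flagged = h$flagged,
    genetic_variance_explained = if (is.na(gve_raw)) NA_real_ else
      min(max(gve_raw, 0), 1),
    clamped = clamped
  )
  class(out) <- c("variance_result", class(out))
  out
}
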
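#' Family-level bootstrap of a cohort statistic
#'
#' Each replicate draws families with replacement up to the original family
#' count (the resampling unit is always the family, never the individual),
#' recomputes the statistic, and the 95% empirical CI is read off the
#' replicate order statistics: lower = ceiling(0.025 B)-th, upper =
#' ceiling(0.975 B)-th. Replicates where the statistic is non-estimable
#' (`NA`/`NaN` or an error) are redrawn and counted; more than 20%
#' non-estimable aborts.
#'
#' @param cohort A [family_cohort()].
#' @param statistic Function `cohort -> scalar`.
#' @param B Number of bootstrap replicates (default 1000).
#' @param seed Integer seed; results are fully reproducible given it.
#' @return An object of class `bootstrap_result`: `observed`, `replicates`,
#'   `ci` (length 2), `boot_mean`, `inflation` (boot mean - observed), `B`,
#'   `n_redrawn`, `seed`.
#' @export
bootstrap_statistic <- function(cohort, statistic, B = 1000, seed = NULL) {
  stopifnot(length(unique(cohort$individuals$family)) >= 2, B >= 2)
  if (!is.null(seed)) set.seed(seed)
  observed <- statistic(cohort)
  reps <- numeric(B)
  n_redrawn <- 0L
  for (b in seq_len(B)) {
    repeat {
      val <- tryCatch(statistic(resample_families(cohort)),
                      error = function(e) NA_real_)
      if (is.finite(val)) break
      n_redrawn <- n_redrawn + 1L
      if (n_redrawn > 0.2 * B) {
        abort(paste0("more than 20% of bootstrap replicates were ",
                     "non-estimable (", n_redrawn, " redraws)"))
      }
    }
    reps[b] <- val
  }
  srt <- sort(reps)
  ci <- c(srt[ceiling(0.025 * B)], srt[ceiling(0.975 * B)])
  structure(list(observed = observed, replicates = reps, ci = ci,
                 boot_mean = mean(reps), inflation = mean(reps) - observed,
                 B = B, n_redrawn = n_redrawn, seed = seed),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat("<bootstrap_result> B = ", x$B, ", observed = ",
      format(x$observed, digits = 4), ", boot mean = ",
      format(x$boot_mean, digits = 4), "\n  95% CI [",
      format(x$ci[1], digits = 4), ", ", format(x$ci[2], digits = 4),
      "], ", x$n_redrawn, " replicate(s) redrawn\n", sep = "")
  invisible(x)
}

#' Selection-inflation summary
#'
#' Compares the bootstrap mean of a statistic (typically the genetic
#' relative risk, with any selection steps re-run inside each replicate) to
#' its observed value; a positive difference indicates inflation induced by
#' selection.
#'
#' @param observed Observed statistic.
#' @param boot A [bootstrap_statistic()] result on the same statistic.
#' @return A one-row tibble: `observed`, `boot_mean`, `inflation`,
#'   `inflation_frac` (fraction of observed).
#' @export
inflation_check <- function(observed, boot) {
  stopifnot(inherits(boot, "bootstrap_result"))
  tibble(observed = observed, boot_mean = boot$boot_mean,
         inflation = boot$boot_mean - observed,
         inflation_frac = (boot$boot_mean - observed) / observed)
}

#' Genetic-model reproducibility index across two cohorts
#'
#' For each SNP and each cohort, the originally selected genetic model
#' ([select_best_model()]) is compared with the model re-selected on each of
#' `B` family-bootstrap replicates; the RI is the fraction of replicates
#' reproducing the original choice (a replicate where the SNP is dropped or
#' non-informative counts as non-reproducing). A SNP's models are highly
#' reproducible when RI exceeds 0.80 in both cohorts.
#'
#' @param cohort1,cohort2 Two [family_cohort()]s (e.g. discovery and
#'   validation).
#' @param snp_set Data frame with `snp` and `risk_allele`.
#' @param sex Stratum passed to [select_best_model()].
#' @param B Bootstrap replicates per cohort.
#' @param seed Integer seed.
#' @param direction_filter Passed to [select_best_model()].
#' @return A tibble: `snp`, `model1`, `model2` (original choices; `NA` when
#'   dropped), `ri1`, `ri2`, `highly_reproducible`.
#' @export
reproducibility_index <- function(cohort1, cohort2, snp_set, sex,
                                  B = 1000, seed = NULL,
                                  direction_filter = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  snp_set <- distinct(as_tibble(snp_set), .data$snp, .data$risk_allele)
  one_cohort <- function(cohort) {
    orig <- select_best_model(cohort, snp_set, sex, direction_filter)
    hits <- matrix(0L, nrow(snp_set), B, dimnames = list(snp_set$snp, NULL))
    for (b in seq_len(B)) {
      res <- tryCatch(
        select_best_model(resample_families(cohort), snp_set, sex,
                          direction_filter),
        error = function(e) NULL
      )
      if (is.null(res) || nrow(res) == 0) next
      m <- res$model[match(snp_set$snp, res$snp)]
      o <- orig$model[match(snp_set$snp, orig$snp)]
      hits[, b] <- as.integer(!is.na(m) & !is.na(o) & m == o)
    }
    list(model = orig$model[match(snp_set$snp, orig$snp)],
         ri = rowMeans(hits))
  }
  c1 <- one_cohort(cohort1)
  c2 <- one_cohort(cohort2)
  tibble(snp = snp_set$snp, model1 = c1$model, model2 = c2$model,
         ri1 = c1$ri, ri2 = c2$ri,
         highly_reproducible = c1$ri > 0.80 & c2$ri > 0.80)
}
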
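#' Tidy a cluster-robust logistic fit
#'
#' @param x A [gee_logistic()] fit.
#' @param ... Unused.
#' @return A tibble with one row per term: `term`, `estimate`, `robust_se`,
#'   `z`, `p.value`, `odds.ratio`.
#' @method tidy gee_fit
#' @export
tidy.gee_fit <- function(x, ...) {
  co <- x$coefficients
  tibble(term = co$term, estimate = co$estimate, robust_se = co$robust_se,
         statistic = co$z, p.value = co$p, odds.ratio = exp(co$estimate))
}

#' @rdname tidy.gee_fit
#' @return For `glance()`: a one-row tibble with `n_obs`, `n_clusters`,
#'   `converged`, `non_estimable`.
#' @method glance gee_fit
#' @export
glance.gee_fit <- function(x, ...) {
  tibble(n_obs = x$n_obs, n_clusters = x$n_clusters,
         converged = x$converged, non_estimable = x$non_estimable)
}

#' Tidy a family-bootstrap result
#'
#' @param x A [bootstrap_statistic()] result.
#' @param ... Unused.
#' @return A one-row tibble: `observed`, `boot_mean`, `ci_lower`, `ci_upper`,
#'   `inflation`, `B`, `n_redrawn`.
#' @method tidy bootstrap_result
#' @export
tidy.bootstrap_result <- function(x, ...) {
  tibble(observed = x$observed, boot_mean = x$boot_mean,
         ci_lower = x$ci[1], ci_upper = x$ci[2],
         inflation = x$inflation, B = x$B, n_redrawn = x$n_redrawn)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
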
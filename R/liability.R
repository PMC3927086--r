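#' Liability-threshold parameters
#'
#' Derived standard-normal quantities for a prevalence `K` and sibling
#' recurrence risk `K_R`: threshold `t = qnorm(1 - K)`, density `z = dnorm(t)`,
#' mean case liability `i = z/K`, mean control liability
#' `i_ctrl = -iK/(1 - K)`, and the recurrence threshold `t_R = qnorm(1 - K_R)`.
#'
#' @param K Prevalence in (0, 1).
#' @param K_R Sibling recurrence risk in (0, 1); for a familial disorder
#'   `K < K_R`.
#' @return A list of class `liability_params`.
#' @export
liability_params <- function(K, K_R) {
  stopifnot(K > 0, K < 1, K_R > 0, K_R < 1)
  t <- qnorm(1 - K)
  z <- dnorm(t)
  i <- z / K
  structure(list(K = K, K_R = K_R, t = t, z = z, i = i,
                 i_ctrl = -i * K / (1 - K), t_R = qnorm(1 - K_R)),
            class = "liability_params")
}

#' Default sex-specific liability parameters for autism
#'
#' Prevalence 1 in 54 for males and 1 in 252 for females (1 in 88 overall),
#' with sibling recurrence risks of 25.9% and 9.6%.
#'
#' @return A list with elements `male` and `female`, each a
#'   [liability_params()].
#' @export
default_liability_params <- function() {
  list(male = liability_params(1 / 54, 0.259),
       female = liability_params(1 / 252, 0.096))
}

#' Forward map: liability variance explained to AUC
#'
#' For a genetic score explaining a proportion `v` of the (unit) liability
#' variance, the expected case-control discrimination is
#' \deqn{AUC = \Phi\!\left(\frac{v\,(i - i_c)}
#'   {\sqrt{v(1 - v\,i(i - t)) + v(1 - v\,i_c(i_c - t))}}\right)}
#' with `i` and `i_c` the mean case and control liabilities and `t` the
#' threshold. Strictly increasing in `v`.
#'
#' @param v Proportion of liability variance in \[0, 1).
#' @param params A [liability_params()].
#' @return The implied AUC.
#' @export
liability_auc <- function(v, params) {
  stopifnot(inherits(params, "liability_params"), all(v >= 0), all(v < 1))
  i <- params$i; ic <- params$i_ctrl; t <- params$t
  num <- v * (i - ic)
  den <- sqrt(v * (1 - v * i * (i - t)) + v * (1 - v * ic * (ic - t)))
  out <- ifelse(v == 0, 0.5, pnorm(num / den))
  out
}

#' Invert the AUC to the liability variance explained
#'
#' Monotone bisection of [liability_auc()] on `v` in \[0, 1) to a tolerance
#' of 1e-8.
#'
#' @param auc Observed AUC in \[0.5, 1).
#' @param params A [liability_params()].
#' @param tol Bisection tolerance on `v`.
#' @return The proportion of liability variance `v`.
#' @export
auc_to_liability_v <- function(auc, params, tol = 1e-8) {
  stopifnot(auc >= 0.5)
  if (auc >= 1) abort("AUC = 1 implies v at the boundary 1; not invertible")
  if (auc == 0.5) return(0)
  lo <- 0; hi <- 1 - 1e-12
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (liability_auc(mid, params) < auc) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Liability-scale heritability from sibling recurrence (Falconer)
#'
#' Falconer's estimate for full siblings (relatedness 1/2):
#' \eqn{h^2 = 2(t - t_R)/i}. Values above 1 — which the default autism
#' parameters produce for males — are returned as-is with a flag rather
#' than truncated. An optional Reich-style correction for the nonlinearity
#' of the threshold model is available.
#'
#' @param params A [liability_params()].
#' @param reich Use the Reich-corrected regression estimate.
#' @return A list: `h2`, `flagged` (`TRUE` when `h2 > 1` or negative).
#' @export
heritability_from_recurrence <- function(params, reich = FALSE) {
  stopifnot(inherits(params, "liability_params"))
  t <- params$t; tR <- params$t_R; i <- params$i
  h2 <- if (!reich) {
    2 * (t - tR) / i
  } else {
    b <- (t - tR * sqrt(1 - (t^2 - tR^2) * (1 - t / i))) / (i + tR^2 * (i - t))
    2 * b
  }
  list(h2 = h2, flagged = h2 > 1 || h2 < 0)
}
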
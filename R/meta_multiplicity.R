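# Cross-stratum meta-analysis and multiplicity control -------------------------

#' Inverse-variance fixed-effect meta-analysis
#'
#' Pools per-stratum coefficient estimates with weights `1/SE^2`:
#' `pooled = sum(w * beta) / sum(w)`, `SE = 1/sqrt(sum(w))`, two-sided normal
#' p from `z = pooled/SE`.
#'
#' @param beta Per-stratum estimates.
#' @param se Per-stratum standard errors (all positive).
#' @param strata Optional stratum labels.
#' @return A `meta_result` list: `beta`, `se`, `z`, `p`, `k` strata.
#' @examples
#' ivw_meta(c(0.48, 0.40), c(0.134, 0.375))  # pooled 0.47, SE 0.126
#' @export
ivw_meta <- function(beta, se, strata = NULL) {
  if (length(beta) != length(se)) stop("beta and se lengths differ")
  if (length(beta) < 2L) stop("need at least 2 strata")
  if (any(!is.finite(se)) || any(se <= 0)) stop("standard errors must be positive")
  w <- 1 / se^2
  pooled <- sum(w * beta) / sum(w)
  pse <- 1 / sqrt(sum(w))
  z <- pooled / pse
  structure(list(kind = "ivw", beta = pooled, se = pse, z = z,
                 p = 2 * stats::pnorm(-abs(z)), k = length(beta),
                 strata = strata),
            class = "meta_result")
}

#' Fisher's method for combining independent p-values
#'
#' `X = -2 * sum(log(p))` referred to a chi-square with `2k` degrees of
#' freedom. Appropriate for the one-sided dispersion-test p-values produced
#' per stratum.
#'
#' @param p P-values in (0, 1].
#' @param strata Optional labels.
#' @return A `meta_result`: `statistic`, `df`, `p`, `k`.
#' @examples
#' fisher_combine(c(0.000636, 0.038))$p  # ~2.8e-4
#' @export
fisher_combine <- function(p, strata = NULL) {
  if (!length(p)) stop("empty p-value vector")
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]; clip zeros before combining")
  X <- -2 * sum(log(p))
  k <- length(p)
  structure(list(kind = "fisher", statistic = X, df = 2L * k,
                 p = stats::pchisq(X, df = 2 * k, lower.tail = FALSE),
                 k = k, strata = strata),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  if (x$kind == "ivw")
    cat(sprintf("<meta_result> IVW fixed-effect over %d strata: beta %.4g, SE %.4g, p %.4g\n",
                x$k, x$beta, x$se, x$p))
  else
    cat(sprintf("<meta_result> Fisher over %d strata: X2 %.4g on %d df, p %.4g\n",
                x$k, x$statistic, x$df, x$p))
  invisible(x)
}

#' Benjamini-Hochberg step-up adjusted p-values (q-values)
#'
#' `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1, returned in the input
#' order; ties keep their input positions (the adjustment depends only on the
#' sorted values, so ties are stable by construction).
#'
#' @param p P-values in (0, 1]; one family per call — family construction is
#'   the caller's responsibility and must never be implicit.
#' @return Adjusted q-values in input order.
#' @export
bh_fdr <- function(p) {
  if (!length(p)) stop("empty p-value family")
  if (any(is.na(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1] with no missing values")
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

#' Bonferroni family-wise threshold
#'
#' @param m Number of tests in the family.
#' @param alpha Family-wise error level.
#' @return `alpha / m`.
#' @examples
#' bonferroni_threshold(9)  # 0.00556
#' @export
bonferroni_threshold <- function(m, alpha = 0.05) {
  if (length(m) != 1L || is.na(m) || m < 1) stop("m must be a positive count")
  alpha / m
}
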
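# Gaussian GEE with cluster-robust (sandwich) covariance ----------------------
#
# Identity link, Gaussian variance, working correlation independence or
# exchangeable. The exchangeable working inverse uses the closed form
# R^{-1} = [I - a/(1+(n-1)a) J] / (1-a), so clusters never need explicit
# matrix inversion and arbitrary cluster sizes are cheap.

#' Fit a marginal mean model by generalized estimating equations
#'
#' Solves the Gaussian identity-link GEE for clustered longitudinal data and
#' returns coefficient estimates with both model-based and cluster-robust
#' (sandwich) covariance matrices. With one observation per subject and
#' independence working correlation the estimates coincide with ordinary
#' least squares and the sandwich equals the HC0 robust covariance.
#'
#' @param formula Mean-model formula (`y ~ ...`).
#' @param data data.frame in long format, one row per subject-exam.
#' @param id Name of the subject-id column in `data` (or a vector of ids).
#' @param working Working correlation: `"independence"` or `"exchangeable"`.
#' @param tol Convergence tolerance on the relative coefficient change.
#' @param maxit Maximum number of Fisher-scoring iterations.
#' @return A `gee_fit`: `coefficients`, `vcov_robust`, `vcov_model`,
#'   `alpha` (estimated exchangeable correlation), `sigma2` (dispersion),
#'   `residuals`, `fitted`, `id`, `n_subjects`, `n_obs`, `converged`.
#' @examples
#' d <- data.frame(y = c(1, 2, 3), id = 1:3)
#' f <- fit_gee(y ~ 1, d, id = "id")
#' coef(f)                      # 2
#' sqrt(diag(f$vcov_robust))    # 0.4714
#' @export
fit_gee <- function(formula, data, id, working = c("exchangeable",
                                                   "independence"),
                    tol = 1e-8, maxit = 100L) {
  working <- match.arg(working)
  ids_full <- if (is.character(id) && length(id) == 1L) data[[id]] else id
  if (is.null(ids_full)) stop(sprintf("id column '%s' not found", id))
  mf <- stats::model.frame(formula, data, na.action = stats::na.omit)
  dropped <- attr(mf, "na.action")
  ids <- if (length(dropped)) ids_full[-dropped] else ids_full
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  n_obs <- nrow(X)
  p <- ncol(X)
  dec <- qr(X)
  if (dec$rank < p) {
    bad <- colnames(X)[dec$pivot[(dec$rank + 1L):p]]
    stop(sprintf("singular design; collinear term(s): %s",
                 paste(bad, collapse = ", ")))
  }
  fid <- factor(ids, levels = unique(ids))
  n_sub <- nlevels(fid)
  if (n_sub < 2L) stop("need at least 2 subjects")
  csize <- as.vector(table(fid))

  beta <- qr.coef(dec, y)
  alpha <- 0
  converged <- (working == "independence")
  sigma2 <- NA_real_
  gls_parts <- function(alpha) {
    # A = sum_i X_i' R^-1 X_i, b = sum_i X_i' R^-1 y_i, closed-form R^-1
    ci <- alpha / (1 + (csize - 1) * alpha)      # per-cluster J coefficient
    Sx <- rowsum(X, fid)                          # cluster column sums of X
    Sy <- rowsum(y, fid)[, 1L]
    A <- (crossprod(X) - crossprod(Sx * ci, Sx)) / (1 - alpha)
    b <- (crossprod(X, y) - crossprod(Sx * ci, Sy)) / (1 - alpha)
    list(A = A, b = b, Sx = Sx, ci = ci)
  }
  if (working == "exchangeable") {
    for (it in seq_len(maxit)) {
      r <- y - X %*% beta
      sigma2 <- sum(r^2) / (n_obs - p)
      Sr <- rowsum(as.vector(r), fid)[, 1L]
      Sr2 <- rowsum(as.vector(r)^2, fid)[, 1L]
      npairs <- sum(csize * (csize - 1)) / 2
      if (npairs > 0) {
        cross <- sum(Sr^2 - Sr2) / 2
        alpha <- cross / (sigma2 * max(npairs - p, 1))
        alpha <- max(min(alpha, 0.99), -0.99 / max(csize - 1, 1))
      }
      gp <- gls_parts(alpha)
      beta_new <- solve(gp$A, gp$b)
      delta <- max(abs(beta_new - beta) / (abs(beta) + 1e-10))
      beta <- beta_new
      if (delta < tol) { converged <- TRUE; break }
    }
  }
  gp <- gls_parts(alpha)
  r <- as.vector(y - X %*% beta)
  sigma2 <- sum(r^2) / (n_obs - p)
  # sandwich: u_i = X_i' R^-1 r_i accumulated per cluster
  Ur <- rowsum(X * r, fid)
  Sr <- rowsum(r, fid)[, 1L]
  U <- (Ur - (gp$ci * Sr) * gp$Sx) / (1 - alpha)
  bread <- solve(gp$A)
  meat <- crossprod(U)
  vr <- bread %*% meat %*% bread
  vr <- (vr + t(vr)) / 2
  beta <- as.vector(beta)
  names(beta) <- colnames(X)
  dimnames(vr) <- list(colnames(X), colnames(X))
  vm <- sigma2 * bread
  dimnames(vm) <- dimnames(vr)
  structure(list(coefficients = beta,
                 vcov_robust = if (converged) vr else NULL,
                 vcov_model = if (converged) vm else NULL,
                 working = working, alpha = alpha, sigma2 = sigma2,
                 residuals = r, fitted = as.vector(X %*% beta),
                 id = as.character(fid), n_subjects = n_sub, n_obs = n_obs,
                 converged = converged, formula = formula,
                 design = X),
            class = "gee_fit")
}

#' @export
print.gee_fit <- function(x, ...) {
  cat(sprintf("<gee_fit> %s working correlation, %d subjects / %d obs%s\n",
              x$working, x$n_subjects, x$n_obs,
              if (x$converged) "" else " [NOT CONVERGED]"))
  print(gee_table(x))
  invisible(x)
}

#' @export
coef.gee_fit <- function(object, ...) object$coefficients

#' @export
vcov.gee_fit <- function(object, ...) object$vcov_robust

#' Robust Wald test of one coefficient
#'
#' @param fit A [fit_gee()] result.
#' @param term Coefficient name.
#' @return List with `estimate`, `se` (sandwich), `z`, `p` (two-sided
#'   standard-normal).
#' @export
robust_test <- function(fit, term) {
  if (!fit$converged) stop("fit did not converge; no inference available")
  if (!term %in% names(fit$coefficients))
    stop(sprintf("term '%s' not in the fit", term))
  est <- unname(fit$coefficients[term])
  se <- sqrt(fit$vcov_robust[term, term])
  if (se <= 0) stop("zero sandwich standard error")
  z <- est / se
  list(estimate = est, se = se, z = z,
       p = 2 * stats::pnorm(-abs(z)))
}

#' All-terms coefficient table with sandwich SEs
#'
#' @param fit A [fit_gee()] result.
#' @return data.frame: term, beta, se, z, p, n_subjects, n_obs.
#' @export
gee_table <- function(fit) {
  se <- sqrt(diag(fit$vcov_robust))
  z <- fit$coefficients / se
  data.frame(term = names(fit$coefficients),
             beta = unname(fit$coefficients), se = unname(se), z = unname(z),
             p = unname(2 * stats::pnorm(-abs(z))),
             n_subjects = fit$n_subjects, n_obs = fit$n_obs,
             row.names = NULL)
}
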
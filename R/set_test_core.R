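# Set-based GEE score ("dispersion") tests ------------------------------------
#
# Interaction test: Y_ij = a'X_ij + f(E_ij) + b'G_i + g'(E_ij * G_i) + e_ij,
# H0: g = 0. Marginal test: Y_ij = a'X_ij + b'G_i + e_ij, H0: b = 0. Both are
# score tests built on a working-independence GEE null fit with subject-level
# sandwich aggregation: the score vector U accumulates tested-block x residual
# products per subject, Q = sum_j w_j^2 U_j^2, and the null distribution of Q
# is a weighted sum of chi-square(1) variables with weights the eigenvalues
# of W V W, V the cluster-level empirical covariance of the per-subject score
# contributions after projecting the tested block off the null design.

#' Standardize a genotype block for set testing
#'
#' Mean-imputes missing dosages per variant, centers each column, and (by
#' default) scales columns to unit variance. Variants with zero variance
#' after imputation are dropped with a warning.
#'
#' @param gm A [genotype_matrix()] or plain dosage matrix (subjects x
#'   variants, rownames = subject ids).
#' @param scale Scale columns to unit variance (default `TRUE`).
#' @return Centered numeric matrix with attributes `"imputed"` (per-variant
#'   imputation counts) and `"dropped"` (ids of zero-variance variants).
#' @export
standardize_genotypes <- function(gm, scale = TRUE) {
  m <- if (inherits(gm, "genotype_matrix")) gm$dosage else as.matrix(gm)
  ids <- colnames(m)
  imputed <- integer(ncol(m))
  for (j in seq_len(ncol(m))) {
    miss <- is.na(m[, j])
    if (all(miss)) stop(sprintf("variant %s has no non-missing dosages",
                                colnames(m)[j]))
    if (any(miss)) {
      m[miss, j] <- mean(m[!miss, j])
      imputed[j] <- sum(miss)
    }
  }
  names(imputed) <- colnames(m)
  sds <- apply(m, 2L, stats::sd)
  drop <- sds == 0
  if (any(drop)) {
    warning(sprintf("dropping %d zero-variance variant(s): %s", sum(drop),
                    paste(colnames(m)[drop], collapse = ", ")))
    m <- m[, !drop, drop = FALSE]
    sds <- sds[!drop]
  }
  out <- scale(m, center = TRUE, scale = if (scale) sds else FALSE)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  attr(out, "imputed") <- imputed
  attr(out, "dropped") <- ids[drop]
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Weighted-PCA adjustment columns for the genotype main effect
#'
#' When the variant count is small relative to the sample size (`p <=
#' p_max`), returns the standardized block itself, i.e. the null model
#' adjusts for every SNP. Otherwise returns the leading principal-component
#' score columns — the fewest whose eigenvalues account for at least `tau` of
#' the total variance — each carrying weight proportional to the square root
#' of its eigenvalue (raw, unstandardized PC scores).
#'
#' @param block Standardized genotype matrix from [standardize_genotypes()].
#' @param tau Variance-explained threshold in (0, 1].
#' @param p_max Revert threshold: adjust for all SNPs when `p <= p_max`.
#' @return Matrix of adjustment columns (named `PC1..PCk` when reduced).
#' @export
weighted_pca_adjustment <- function(block, tau = 0.95,
                                    p_max = min(100, nrow(block) / 10)) {
  if (tau <= 0 || tau > 1) stop("tau must lie in (0, 1]")
  p <- ncol(block)
  if (p < 1L) stop("empty genotype block")
  if (p <= p_max) return(block)
  sv <- svd(block, nu = min(nrow(block), p), nv = 0)
  ev <- sv$d^2 / (nrow(block) - 1)
  ev <- ev[ev > max(ev) * 1e-12]
  k <- which(cumsum(ev) / sum(ev) >= tau)[1L]
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  colnames(scores) <- paste0("PC", seq_len(k))
  rownames(scores) <- rownames(block)
  attr(scores, "eigenvalues") <- ev[seq_len(k)]
  scores
}

make_exposure_basis <- function(E, spline_knots = 3L) {
  vals <- unique(E[!is.na(E)])
  if (length(vals) <= 2L) {
    b <- matrix(E, ncol = 1L, dimnames = list(NULL, "E"))
    attr(b, "type") <- "indicator"
    return(b)
  }
  knots <- stats::quantile(E, probs = seq_len(spline_knots) /
                             (spline_knots + 1), na.rm = TRUE)
  b <- splines::bs(E, knots = unique(knots), degree = 3L)
  colnames(b) <- paste0("E_bs", seq_len(ncol(b)))
  attr(b, "type") <- "spline"
  b
}

#' Fit the set-test null model
#'
#' Working-independence GEE (equivalently, observation-level least squares
#' with subject clustering retained for the sandwich step) of the outcome on
#' the covariates, the exposure main effect `f(E)`, and any genotype
#' main-effect adjustment columns. A binary exposure (at most two distinct
#' values) enters as a single indicator; a continuous exposure enters through
#' a cubic B-spline basis with `spline_knots` interior knots at quantiles,
#' guarding the interaction test against misspecified nonlinear exposure
#' main effects. Basis or adjustment columns collinear with the rest of the
#' design are dropped with a warning.
#'
#' @param data Long-format data.frame (one row per subject-exam).
#' @param outcome,covariates,exposure Column names in `data`; `exposure`
#'   `NULL` for the marginal-test null model.
#' @param g_adjust Optional genotype-adjustment matrix with subject-id
#'   rownames (from [weighted_pca_adjustment()] or [standardize_genotypes()]).
#' @param id Subject-id column name.
#' @param spline_knots Interior knot count for a continuous exposure.
#' @param exposure_form `"auto"` (binary detection as above), `"linear"`
#'   (force a single linear term; mainly for demonstrating type-I inflation),
#'   or `"spline"`.
#' @return A `null_fit`: design `X`, `residuals`, `fitted`, per-observation
#'   subject `id`, used row indices `obs`, exposure values `E`, `converged`.
#' @export
fit_null_model <- function(data, outcome, covariates, exposure = NULL,
                           g_adjust = NULL, id = "subject_id",
                           spline_knots = 3L,
                           exposure_form = c("auto", "linear", "spline")) {
  exposure_form <- match.arg(exposure_form)
  need <- c(outcome, covariates, exposure, id)
  miss <- setdiff(need, names(data))
  if (length(miss)) stop(sprintf("column(s) not in data: %s",
                                 paste(miss, collapse = ", ")))
  cc <- stats::complete.cases(data[, need, drop = FALSE])
  obs <- which(cc)
  d <- data[obs, , drop = FALSE]
  ids <- as.character(d[[id]])
  y <- d[[outcome]]
  Xc <- stats::model.matrix(
    stats::reformulate(covariates),
    d)
  E <- NULL
  if (!is.null(exposure)) {
    E <- d[[exposure]]
    Eb <- switch(exposure_form,
      auto = make_exposure_basis(E, spline_knots),
      linear = matrix(E, ncol = 1L, dimnames = list(NULL, "E")),
      spline = {
        knots <- stats::quantile(E, probs = seq_len(spline_knots) /
                                   (spline_knots + 1))
        b <- splines::bs(E, knots = unique(knots), degree = 3L)
        colnames(b) <- paste0("E_bs", seq_len(ncol(b)))
        b
      })
    Xc <- cbind(Xc, Eb)
  }
  if (!is.null(g_adjust)) {
    g_adjust <- as.matrix(g_adjust)
    if (is.null(rownames(g_adjust)))
      stop("g_adjust needs subject-id rownames")
    ridx <- match(ids, rownames(g_adjust))
    if (anyNA(ridx)) stop("subjects in data missing from g_adjust")
    Ga <- g_adjust[ridx, , drop = FALSE]
    colnames(Ga) <- paste0("G_", colnames(g_adjust) %||%
                             seq_len(ncol(g_adjust)))
    Xc <- cbind(Xc, Ga)
  }
  dec <- qr(Xc)
  if (dec$rank < ncol(Xc)) {
    dropped <- colnames(Xc)[dec$pivot[(dec$rank + 1L):ncol(Xc)]]
    warning(sprintf("dropping collinear null-design column(s): %s",
                    paste(dropped, collapse = ", ")))
    Xc <- Xc[, dec$pivot[seq_len(dec$rank)], drop = FALSE]
    dec <- qr(Xc)
  }
  beta <- qr.coef(dec, y)
  fitted <- as.vector(Xc %*% beta)
  structure(list(X = Xc, y = y, coefficients = beta, fitted = fitted,
                 residuals = y - fitted, id = ids, obs = obs, E = E,
                 qr = dec, converged = TRUE),
            class = "null_fit")
}

# Kauermann-Carroll / CR2-type residual adjustment: per cluster,
# r_i -> (I - H_ii)^{-1/2} r_i with H the working-independence hat matrix of
# the null design. Removes the downward bias of the empirical cluster-score
# covariance caused by fitting the null model (material when the null design
# carries many genotype-adjustment columns). Cluster sizes here are small
# (1-2 exams), so the per-cluster inverse square roots are cheap.
kc_adjust_residuals <- function(null, fid) {
  r <- null$residuals
  Qm <- qr.qy(null$qr, diag(1, nrow = length(r), ncol = null$qr$rank))
  out <- r
  sizes <- tabulate(fid)
  ord <- order(fid)
  # vectorized closed forms for the dominant cluster sizes (1 and 2 exams);
  # 2x2 symmetric inverse square root: M^{-1/2} = [[c+s,-b],[-b,a+s]]/(s*t),
  # s = sqrt(det M), t = sqrt(tr M + 2 s)
  pos <- c(0L, cumsum(sizes))[seq_along(sizes)]   # offset of each cluster in ord
  i1 <- ord[pos[sizes == 1L] + 1L]
  if (length(i1)) {
    h <- rowSums(Qm[i1, , drop = FALSE]^2)
    out[i1] <- r[i1] / sqrt(pmax(1 - h, 1e-10))
  }
  c2 <- which(sizes == 2L)
  if (length(c2)) {
    ia <- ord[pos[c2] + 1L]
    ib <- ord[pos[c2] + 2L]
    Qa <- Qm[ia, , drop = FALSE]
    Qb <- Qm[ib, , drop = FALSE]
    a <- 1 - rowSums(Qa^2)
    c_ <- 1 - rowSums(Qb^2)
    b <- -rowSums(Qa * Qb)
    s <- sqrt(pmax(a * c_ - b^2, 1e-10))
    st <- s * sqrt(pmax(a + c_ + 2 * s, 1e-10))
    ra <- r[ia]; rb <- r[ib]
    out[ia] <- ((c_ + s) * ra - b * rb) / st
    out[ib] <- (-b * ra + (a + s) * rb) / st
  }
  big <- which(sizes > 2L)
  for (ci in big) {
    ix <- ord[pos[ci] + seq_len(sizes[ci])]
    M <- diag(sizes[ci]) - tcrossprod(Qm[ix, , drop = FALSE])
    es <- eigen(M, symmetric = TRUE)
    out[ix] <- es$vectors %*% ((t(es$vectors) %*% r[ix]) /
                                 sqrt(pmax(es$values, 1e-10)))
  }
  out
}

# Affine spectral shrinkage toward the mean eigenvalue, with intensity set so
# that sum(lambda^2) matches the unbiased (U-statistic) estimate of tr(V^2):
#   sum_{i != j} (a_i'a_j)^2 * n/(n-1).
# Sample eigenvalues of a covariance built from n cluster contributions are
# overdispersed, which makes the mixture tail heavier than it should be and
# the test conservative; matching the second spectral moment to its unbiased
# estimate removes exactly that overdispersion. Identity when p = 1.
shrink_spectrum_c2 <- function(A, lambda) {
  n <- nrow(A)
  if (n < 3L || length(lambda) < 2L) return(lambda)
  V <- crossprod(A)
  T2 <- sum(V^2) - sum(rowSums(A^2)^2)
  c2_hat <- T2 * n / (n - 1)
  lbar <- mean(lambda)
  p <- length(lambda)
  denom <- sum(lambda^2) - p * lbar^2
  if (denom <= 0) return(lambda)
  if (c2_hat <= p * lbar^2) return(rep(lbar, p))
  kappa <- min(sqrt((c2_hat - p * lbar^2) / denom), 1)
  lbar + kappa * (lambda - lbar)
}

set_test_engine <- function(null, S, weights, hypothesis, region = NA_character_,
                            method = "auto", correction = c("kc", "none"),
                            shrink = c("c2", "none")) {
  correction <- match.arg(correction)
  shrink <- match.arg(shrink)
  if (!isTRUE(null$converged)) stop("null model did not converge")
  p <- ncol(S)
  if (p < 1L) stop("empty tested block")
  w <- if (is.null(weights)) rep(1, p) else rep_len(weights, p)
  if (any(w < 0)) stop("weights must be non-negative")
  # project tested block off the null design (observation level)
  S_t <- S - qr.fitted(null$qr, S)
  r <- null$residuals
  U <- as.vector(crossprod(S_t, r))
  fid <- factor(null$id, levels = unique(null$id))
  Q <- sum((w * U)^2)
  r_meat <- if (correction == "kc") kc_adjust_residuals(null, fid) else r
  A <- rowsum(S_t * r_meat, fid)     # per-subject score contributions
  A <- sweep(A, 2L, w, "*")          # fold in variant weights: W V W
  lambda <- eigen(crossprod(A), symmetric = TRUE, only.values = TRUE)$values
  # structural (numerically zero) eigenvalues are excluded before shrinkage:
  # they reflect rank deficiency of the block, not sampling noise
  lambda <- lambda[lambda > max(lambda) * 1e-10]
  if (shrink == "c2") lambda <- shrink_spectrum_c2(A, lambda)
  lambda <- lambda[lambda > max(lambda) * 1e-10]
  pv <- quadform_pvalue(Q, lambda, method = method)
  structure(list(region = region, hypothesis = hypothesis, Q = Q,
                 lambda = lambda, p = pv$p, method = pv$method,
                 n_subjects = nlevels(fid), p_variants = p,
                 correction = correction, shrink = shrink),
            class = "set_test_result")
}

#' @export
print.set_test_result <- function(x, ...) {
  cat(sprintf("<set_test_result> %s%s: Q = %.4g, p = %.4g (%s; %d subjects, %d variants)\n",
              x$hypothesis,
              if (!is.na(x$region)) paste0(" [", x$region, "]") else "",
              x$Q, x$p, x$method, x$n_subjects, x$p_variants))
  invisible(x)
}

#' Set-based interaction score test (H0: all interaction coefficients zero)
#'
#' Builds the observation-level interaction block `E_ij * G_i` from the
#' subject-level standardized genotypes and the exposure values stored in the
#' null fit, and tests its joint association with the null-model residuals.
#'
#' @param null A [fit_null_model()] result fitted *with* the exposure main
#'   effect (and usually a genotype main-effect adjustment).
#' @param block Standardized genotype matrix (subjects x variants, rownames =
#'   subject ids), typically [standardize_genotypes()] output.
#' @param weights Optional per-variant weights `w_j` (default all 1; see
#'   [maf_beta_weights()] for rare-variant weighting).
#' @param region Optional region label carried into the result.
#' @param method P-value method passed to [quadform_pvalue()].
#' @param correction Small-sample treatment of the sandwich meat: `"kc"`
#'   (default) applies a Kauermann-Carroll / CR2-type per-cluster residual
#'   adjustment `(I - H_ii)^{-1/2}` that undoes the downward bias induced by
#'   fitting the null model; `"none"` is the plain empirical sandwich.
#' @param shrink Eigenvalue treatment: `"c2"` (default) shrinks the spectrum
#'   affinely toward its mean so its second moment matches the unbiased
#'   U-statistic estimate of `tr(V^2)` (identity when `p = 1`); `"none"`
#'   uses the raw sample eigenvalues.
#' @return A `set_test_result` (`Q`, eigenvalue spectrum, `p`, sizes).
#' @export
interaction_set_test <- function(null, block, weights = NULL,
                                 region = NA_character_, method = "auto",
                                 correction = c("kc", "none"),
                                 shrink = c("c2", "none")) {
  if (is.null(null$E))
    stop("null model has no exposure; fit it with `exposure =` first")
  ridx <- match(null$id, rownames(block))
  if (anyNA(ridx)) stop("subjects in the null fit missing from the block")
  S <- block[ridx, , drop = FALSE] * null$E
  set_test_engine(null, S, weights, "interaction", region, method,
                  correction = correction, shrink = shrink)
}

#' Set-based marginal genetic score test (H0: all genotype coefficients zero)
#'
#' @param null A [fit_null_model()] result fitted with covariates only (no
#'   exposure term, no genotype adjustment).
#' @inheritParams interaction_set_test
#' @return A `set_test_result`.
#' @export
marginal_set_test <- function(null, block, weights = NULL,
                              region = NA_character_, method = "auto",
                              correction = c("kc", "none"),
                              shrink = c("c2", "none")) {
  ridx <- match(null$id, rownames(block))
  if (anyNA(ridx)) stop("subjects in the null fit missing from the block")
  S <- block[ridx, , drop = FALSE]
  set_test_engine(null, S, weights, "marginal", region, method,
                  correction = correction, shrink = shrink)
}

#' Beta-density variant weights
#'
#' `dbeta(maf, a, b)` weights; the common-variant default elsewhere is flat
#' weights, but `a = 1, b = 25` reproduces the usual rare-variant upweighting.
#'
#' @param maf Minor allele frequencies.
#' @param a,b Beta shape parameters.
#' @export
maf_beta_weights <- function(maf, a = 1, b = 25) stats::dbeta(maf, a, b)

# Mixture-of-chi-square tail probabilities -------------------------------------

liu_pvalue <- function(Q, lambda) {
  c1 <- sum(lambda); c2 <- sum(lambda^2)
  c3 <- sum(lambda^3); c4 <- sum(lambda^4)
  s1 <- c3 / c2^1.5
  s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    delta <- s1 * a^3 - a^2
    l <- a^2 - 2 * delta
  } else {
    l <- 1 / s2
    a <- sqrt(l)
    delta <- 0
  }
  tstar <- (Q - c1) / sqrt(2 * c2)
  x <- tstar * sqrt(2) * a + l + delta
  stats::pchisq(x, df = l, ncp = delta, lower.tail = FALSE)
}

imhof_pvalue <- function(Q, lambda, abs_tol = 1e-9) {
  # rescale to unit mean eigenvalue: the integrand lives on scale 1/lambda,
  # which stats::integrate cannot find when lambda is very large or small
  sc <- mean(lambda)
  lambda <- lambda / sc
  Q <- Q / sc
  f <- function(u) {
    theta <- 0.5 * colSums(atan(outer(lambda, u))) - 0.5 * Q * u
    rho <- exp(0.25 * colSums(log1p(outer(lambda^2, u^2))))
    out <- sin(theta) / (u * rho)
    out[u == 0] <- 0.5 * (sum(lambda) - Q)
    out
  }
  it <- stats::integrate(f, 0, Inf, abs.tol = abs_tol, subdivisions = 2000L,
                         stop.on.error = FALSE)
  0.5 + it$value / pi
}

#' Tail probability of a weighted sum of chi-square(1) variables
#'
#' Computes `P(sum_k lambda_k X_k > Q)` for independent chi-square(1) `X_k`,
#' the null distribution of the set-test statistic. `moment_matching` is a
#' four-moment (Liu-type) noncentral chi-square approximation;
#' `numerical_inversion` integrates the characteristic function (Imhof).
#' `auto` uses moment matching and refines by inversion when the approximate
#' p falls below `1e-3` (where moment matching is least accurate).
#'
#' @param Q Observed statistic (non-negative).
#' @param lambda Non-negative eigenvalues, not all zero.
#' @param method `"auto"`, `"moment_matching"`, or `"numerical_inversion"`.
#' @return List with `p` (clipped to `(0, 1]`) and the `method` that produced
#'   it.
#' @export
quadform_pvalue <- function(Q, lambda,
                            method = c("auto", "moment_matching",
                                       "numerical_inversion")) {
  method <- match.arg(method)
  lambda <- lambda[lambda > 0]
  if (!length(lambda)) stop("all eigenvalues are zero")
  if (Q < 0) stop("Q must be non-negative")
  if (method == "numerical_inversion") {
    p <- imhof_pvalue(Q, lambda)
    used <- "numerical_inversion"
  } else {
    p <- liu_pvalue(Q, lambda)
    used <- "moment_matching"
    if (method == "auto" && p < 1e-3) {
      pi_ <- imhof_pvalue(Q, lambda)
      if (is.finite(pi_) && pi_ > 0) {
        p <- pi_
        used <- "numerical_inversion"
      }
    }
  }
  list(p = min(max(p, .Machine$double.xmin), 1), method = used)
}
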
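# Set-based score tests: standardization, PCA adjustment, null model,
# quadratic-form p-values, and the tests' invariances.

test_that("standardize_genotypes centers, scales, imputes, drops", {
  m <- matrix(c(0, 1, 2,
                1, NA, 1,
                0, 0, 2), nrow = 3,
              dimnames = list(c("a", "b", "c"), c("v1", "v2", "v3")))
  expect_warning(z <- standardize_genotypes(m, scale = FALSE), "zero-variance")
  # v2 imputes to all-1 -> zero variance -> dropped
  expect_equal(colnames(z), c("v1", "v3"))
  expect_equal(z[, "v1"], c(a = -1, b = 0, c = 1))
  expect_equal(attr(z, "imputed")[["v2"]], 1L)
  expect_equal(attr(z, "dropped"), "v2")
  zs <- suppressWarnings(standardize_genotypes(m))
  expect_equal(apply(zs, 2, sd), c(v1 = 1, v3 = 1))
})

test_that("weighted PCA adjustment reverts below p_max and honors tau", {
  set.seed(1)
  blk <- make_block(200, 5)
  # revert: block returned unchanged
  expect_identical(weighted_pca_adjustment(blk, p_max = 50), blk)
  # rank-1 block -> exactly one component at any tau
  one <- matrix(rnorm(100), 100, 1)
  rk1 <- scale(one %*% t(c(1, 2, 3)), scale = FALSE)
  rownames(rk1) <- sprintf("S%03d", 1:100)
  for (tau in c(0.2, 0.95, 1)) {
    pc <- weighted_pca_adjustment(rk1, tau = tau, p_max = 0)
    expect_equal(ncol(pc), 1L)
  }
  # component count matches a direct eigendecomposition of the covariance
  set.seed(2)
  big <- make_block(200, 120)
  pc <- weighted_pca_adjustment(big, tau = 0.95, p_max = 100)
  ev <- eigen(cov(big), symmetric = TRUE, only.values = TRUE)$values
  k_expect <- which(cumsum(ev) / sum(ev) >= 0.95)[1]
  expect_equal(ncol(pc), k_expect)
  # score columns carry sqrt(eigenvalue) scale: column var equals eigenvalue
  expect_equal(unname(apply(pc, 2, var)), ev[seq_len(k_expect)],
               tolerance = 1e-8)
  expect_error(weighted_pca_adjustment(big, tau = 1.5), "tau")
})

test_that("null model: binary exposure degenerates to one indicator column,
           continuous exposure gets a spline basis, collinearity is dropped", {
  d <- make_flat_data(150, seed = 3)
  nf <- fit_null_model(d, "bmi", c("age", "age2", "sex"),
                       exposure = "exposure")
  expect_equal(sum(grepl("^E", colnames(nf$X))), 1L)
  # equals a plain linear-term fit for binary E
  nf_lin <- fit_null_model(d, "bmi", c("age", "age2", "sex"),
                           exposure = "exposure", exposure_form = "linear")
  expect_equal(nf$residuals, nf_lin$residuals, tolerance = 1e-10)
  # continuous exposure: cubic B-spline with 3 interior knots -> 6 columns
  d$stress <- rnorm(150)
  nf_s <- fit_null_model(d, "bmi", c("age", "age2", "sex"),
                         exposure = "stress")
  expect_equal(sum(grepl("^E_bs", colnames(nf_s$X))), 6L)
  # residuals orthogonal to the design
  expect_lt(max(abs(crossprod(nf_s$X, nf_s$residuals))), 1e-6)
  # collinear adjustment columns dropped with a warning, fit still returned
  g_adj <- cbind(dup = d$age)
  rownames(g_adj) <- d$subject_id
  expect_warning(
    nf_c <- fit_null_model(d, "bmi", c("age", "age2", "sex"),
                           g_adjust = g_adj),
    "collinear")
  expect_true(nf_c$converged)
})

test_that("p = 1: uncorrected set test equals the brute-force robust score test,
           default corrections stay close", {
  set.seed(4)
  worst_plain <- worst_def <- 0
  for (k in 1:25) {
    n <- 150 + 10 * k
    Z1 <- make_block(n, 1, maf = runif(1, 0.1, 0.5))
    d <- make_flat_data(n)
    nf <- fit_null_model(d, "bmi", c("age", "age2", "sex"),
                         exposure = "exposure")
    S <- Z1[match(nf$id, rownames(Z1)), , drop = FALSE] * nf$E
    X <- nf$X
    St <- S - X %*% solve(crossprod(X), crossprod(X, S))
    U <- sum(St * nf$residuals)
    V <- sum((St[, 1] * nf$residuals)^2)
    p_oracle <- pchisq(U^2 / V, 1, lower.tail = FALSE)
    p_plain <- interaction_set_test(nf, Z1, correction = "none",
                                    shrink = "none")$p
    worst_plain <- max(worst_plain, abs(p_plain - p_oracle))
    worst_def <- max(worst_def,
                     abs(interaction_set_test(nf, Z1)$p - p_oracle))
  }
  expect_lt(worst_plain, 1e-6)
  expect_lt(worst_def, 0.02)   # KC adjustment is a small finite-sample shift
})

test_that("p = 2: uncorrected set test matches a brute-force quadratic-form oracle", {
  set.seed(5)
  for (k in 1:10) {
    n <- 200
    Z <- make_block(n, 2, maf = 0.3)
    d <- make_flat_data(n)
    nf0 <- fit_null_model(d, "bmi", c("age", "age2", "sex"))
    res <- marginal_set_test(nf0, Z, correction = "none", shrink = "none")
    X <- nf0$X
    S <- Z[match(nf0$id, rownames(Z)), , drop = FALSE]
    St <- S - X %*% solve(crossprod(X), crossprod(X, S))
    U <- crossprod(St, nf0$residuals)
    V <- crossprod(St * nf0$residuals)
    lam <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
    # oracle tail probability by Monte Carlo over the 2-eigenvalue mixture
    Qo <- sum(U^2)
    expect_equal(res$Q, Qo, tolerance = 1e-10)
    expect_equal(sort(res$lambda), sort(lam[lam > 0]), tolerance = 1e-8)
  }
})

test_that("allele-flip, column-permutation and weight-scale invariances hold", {
  cc <- make_cohort(n = 250, p = 12, seed = 6, beta_g = 0.1)
  Z <- standardize_genotypes(cc$gm)
  nf <- fit_null_model(cc$pheno, "bmi", c("age", "age2", "sex"),
                       exposure = "exposure", g_adjust = Z)
  base <- interaction_set_test(nf, Z)
  # allele flip (d -> 2-d): centered column negates, Q and p unchanged
  dos2 <- cc$gm$dosage
  dos2[, 3] <- 2 - dos2[, 3]
  Zf <- standardize_genotypes(dos2)
  flip <- interaction_set_test(nf, Zf)
  expect_equal(flip$Q, base$Q, tolerance = 1e-9)
  expect_equal(flip$p, base$p, tolerance = 1e-9)
  # column permutation: Q, spectrum (as multiset) and p unchanged
  perm <- sample(ncol(Z))
  permres <- interaction_set_test(nf, Z[, perm])
  expect_equal(permres$Q, base$Q, tolerance = 1e-9)
  expect_equal(sort(permres$lambda), sort(base$lambda), tolerance = 1e-8)
  expect_equal(permres$p, base$p, tolerance = 1e-9)
  # scaling all weights by c > 0 leaves p unchanged
  w <- rep(1, ncol(Z))
  pw1 <- interaction_set_test(nf, Z, weights = w)$p
  pw2 <- interaction_set_test(nf, Z, weights = 7.3 * w)$p
  expect_equal(pw1, pw2, tolerance = 1e-9)
  # duplicating every variant column leaves the p-value unchanged
  nf0 <- fit_null_model(cc$pheno, "bmi", c("age", "age2", "sex"))
  p_single <- marginal_set_test(nf0, Z)$p
  p_doubled <- marginal_set_test(nf0, cbind(Z, Z))$p
  expect_equal(p_single, p_doubled, tolerance = 1e-6)
})

test_that("quadform_pvalue: chi-square cases, scale equivariance, method accord", {
  expect_equal(quadform_pvalue(qchisq(0.95, 1), 1)$p, 0.05, tolerance = 1e-8)
  expect_equal(quadform_pvalue(2 * qchisq(0.95, 1), 2)$p, 0.05,
               tolerance = 1e-8)
  expect_equal(quadform_pvalue(2 * qchisq(0.95, 1), 2,
                               method = "numerical_inversion")$p,
               0.05, tolerance = 5e-3)
  # scale equivariance across methods and magnitudes;
  # 0.08803 frozen from a 4e6-draw Monte-Carlo tail of the same mixture
  for (sc in c(1e-4, 1, 1e6)) {
    p1 <- quadform_pvalue(4 * sc, c(1, 0.5, 0.25) * sc,
                          method = "numerical_inversion")$p
    expect_equal(p1, 0.08803, tolerance = 5e-3)
  }
  # methods agree within 10% relative on random spectra (p > 1e-4)
  set.seed(7)
  for (k in 1:20) {
    lam <- rexp(sample(2:40, 1))
    Q <- sum(lam) + 2 * sqrt(2 * sum(lam^2)) * runif(1)
    pm <- quadform_pvalue(Q, lam, method = "moment_matching")$p
    pn <- quadform_pvalue(Q, lam, method = "numerical_inversion")$p
    if (pn > 1e-4) expect_lt(abs(pm - pn) / pn, 0.10)
  }
  expect_error(quadform_pvalue(1, c(0, 0)), "zero")
})

test_that("interaction test refuses a null fit without an exposure", {
  d <- make_flat_data(60, seed = 8)
  nf0 <- fit_null_model(d, "bmi", c("age", "sex"))
  Z <- make_block(60, 3)
  expect_error(interaction_set_test(nf0, Z), "no exposure")
})

test_that("power rises with the interaction effect size", {
  set.seed(9)
  rej <- sapply(c(0, 1.2, 2.4), function(g) {
    mean(replicate(60, {
      gm <- simulate_genotypes(600, 10, rho = 0.3)
      gamma <- c(g, rep(0, 9))
      coh <- simulate_cohort(sim_config(n_subjects = 600, p_variants = 10,
                                        gamma = gamma, beta_g = 0.05),
                             gm)
      Z <- standardize_genotypes(gm)
      nf <- fit_null_model(coh, "bmi", c("age", "age2", "sex"),
                           exposure = "exposure", g_adjust = Z)
      interaction_set_test(nf, Z)$p < 0.05
    }))
  })
  expect_true(rej[2] > rej[1] || rej[3] > rej[1])
  expect_gt(rej[3], rej[2] - 0.05)  # monotone up to Monte-Carlo noise
  expect_gt(rej[3], 0.3)
})
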
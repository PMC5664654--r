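# Synthetic cohorts with the structure the analysis assumes --------------------
#
# Forward model: Y_ij = a'X_ij + f(E_ij) + b'G_i + g'(E_ij * G_i) + e_ij with
# e_ij decomposed as a subject random intercept (variance sigma_b^2) plus
# white noise (variance sigma_e^2) — the simplest structure generating
# exchangeable within-subject correlation. Genotypes come from an AR(1)
# Gaussian copula over haplotypes, giving common variants with tunable LD.

#' Simulation configuration
#'
#' Defaults follow an "HRS European-ancestry like" preset at desk scale:
#' 500 subjects (the observed cohort is 7838; pass `n_subjects = 7838` for
#' full size), 58.3% with a second exam four years later, age 66 (SD 10),
#' 56.7% female, one dichotomous adverse exposure with prevalence 0.38, a
#' region of 60 common variants with AR(1) LD 0.5, exposure main effect 0.48
#' on the outcome scale, and no genetic main or interaction effects unless
#' requested. The error SDs (`sigma_b = 4.5`, `sigma_e = 2.5`) give a
#' marginal outcome SD near the observed 5.7 with within-subject correlation
#' about 0.76.
#'
#' @param n_subjects Cohort size.
#' @param two_exam_fraction Share of subjects with a second exam.
#' @param age_mean,age_sd First-exam age distribution (years).
#' @param female_fraction Probability of the sex indicator being 1.
#' @param exposure_prevalence Adverse-category probability.
#' @param p_variants,maf_range,rho Region spec: variant count, MAF bounds
#'   (inside (0.01, 0.5]), AR(1) latent correlation in [0, 1).
#' @param intercept,beta_age,beta_age2,beta_sex Covariate effects.
#' @param exposure_effect Main exposure effect on the outcome.
#' @param beta_g Genotype main effects (scalar recycled or length-p vector;
#'   per-dosage-allele scale).
#' @param gamma Interaction effects (same shape as `beta_g`).
#' @param sigma_b,sigma_e Random-intercept and residual SDs.
#' @param time_varying_exposure Redraw the exposure at each exam.
#' @param confounded_exposure Make exposure prevalence depend on age
#'   (logistic), for robustness experiments.
#' @param exposure_type `"binary"` (the default adverse indicator) or
#'   `"continuous"` (standard-normal score), the latter mainly for studying
#'   nonlinear exposure main effects.
#' @param exposure_effect2 Coefficient on the squared exposure (quadratic
#'   main effect `f(E) = effect * E + effect2 * E^2`); only meaningful for a
#'   continuous exposure.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_subjects = 500L, two_exam_fraction = 0.583,
                       age_mean = 66, age_sd = 10, female_fraction = 0.567,
                       exposure_prevalence = 0.38, p_variants = 60L,
                       maf_range = c(0.05, 0.5), rho = 0.5,
                       intercept = 27, beta_age = 0.1, beta_age2 = -0.001,
                       beta_sex = 0.5, exposure_effect = 0.48,
                       beta_g = 0, gamma = 0, sigma_b = 4.5, sigma_e = 2.5,
                       time_varying_exposure = FALSE,
                       confounded_exposure = FALSE,
                       exposure_type = c("binary", "continuous"),
                       exposure_effect2 = 0) {
  exposure_type <- match.arg(exposure_type)
  stopifnot(two_exam_fraction >= 0, two_exam_fraction <= 1,
            exposure_prevalence >= 0, exposure_prevalence <= 1,
            rho >= 0, rho < 1, sigma_b >= 0, sigma_e >= 0,
            maf_range[1] > 0.01, maf_range[2] <= 0.5)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate an LD-structured common-variant region
#'
#' Draws two haplotypes per subject from a latent AR(1) Gaussian copula
#' thresholded at each variant's MAF quantile; the dosage is the haplotype
#' sum, so adjacent variants are correlated with strength governed by `rho`.
#' Variant positions are equally spaced across a 100 kb span and INFO scores
#' are set to 1 (simulated genotypes are "perfectly imputed").
#'
#' @param n Number of subjects.
#' @param p Number of variants.
#' @param maf Optional vector of target MAFs; drawn uniformly from
#'   `maf_range` when `NULL`.
#' @param maf_range,rho See [sim_config()].
#' @param chrom,start Placement of the simulated span.
#' @param seed Optional seed for reproducibility.
#' @return A [genotype_matrix()].
#' @export
simulate_genotypes <- function(n, p, maf = NULL, maf_range = c(0.05, 0.5),
                               rho = 0.5, chrom = "13", start = 1000000L,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(maf)) maf <- stats::runif(p, maf_range[1], maf_range[2])
  if (any(maf <= 0 | maf > 0.5)) stop("target MAFs must lie in (0, 0.5]")
  nh <- 2L * n
  z <- matrix(stats::rnorm(nh * p), nh, p)
  if (rho > 0 && p > 1L) {
    for (j in 2:p) z[, j] <- rho * z[, j - 1L] + sqrt(1 - rho^2) * z[, j]
  }
  thr <- stats::qnorm(maf)
  hap <- sweep(z, 2L, thr, "<")
  dosage <- hap[seq_len(n), , drop = FALSE] +
    hap[n + seq_len(n), , drop = FALSE]
  storage.mode(dosage) <- "double"
  ids <- sprintf("snp%03d", seq_len(p))
  rownames(dosage) <- sprintf("S%05d", seq_len(n))
  colnames(dosage) <- ids
  pos <- as.integer(round(seq(start, start + 100000L, length.out = p)))
  genotype_matrix(dosage,
                  data.frame(id = ids, chrom = chrom, pos = pos,
                             ref = "A", alt = "G", info = 1,
                             stringsAsFactors = FALSE))
}

#' Simulate a longitudinal cohort over a genotype matrix
#'
#' Applies the forward model described in the package overview: outcome =
#' covariate effects + exposure main effect + genotype main effects +
#' interaction effects + subject random intercept + noise. A
#' `two_exam_fraction` share of subjects receives a second exam with age
#' advanced 4 years (and, when `time_varying_exposure`, a freshly drawn
#' exposure).
#'
#' @param config A [sim_config()].
#' @param gm A [genotype_matrix()] with `config$n_subjects` subjects,
#'   typically from [simulate_genotypes()].
#' @param seed Optional seed.
#' @return Long-format data.frame: `subject_id`, `exam`, `age`, `age2`,
#'   `sex`, `exposure`, `bmi`.
#' @export
simulate_cohort <- function(config, gm, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_subjects
  if (nrow(gm$dosage) != n)
    stop("genotype matrix subject count must equal n_subjects")
  p <- ncol(gm$dosage)
  beta_g <- rep_len(config$beta_g, p)
  gamma <- rep_len(config$gamma, p)
  ids <- rownames(gm$dosage)
  age1 <- stats::rnorm(n, config$age_mean, config$age_sd)
  sex <- stats::rbinom(n, 1L, config$female_fraction)
  b <- stats::rnorm(n, 0, config$sigma_b)
  draw_E <- function(age) {
    if (identical(config$exposure_type, "continuous"))
      return(stats::rnorm(n))
    if (config$confounded_exposure) {
      lp <- stats::qlogis(config$exposure_prevalence) +
        0.05 * (age - config$age_mean)
      stats::rbinom(n, 1L, stats::plogis(lp))
    } else stats::rbinom(n, 1L, config$exposure_prevalence)
  }
  E1 <- draw_E(age1)
  two <- stats::rbinom(n, 1L, config$two_exam_fraction) == 1L
  g_main <- as.vector(gm$dosage %*% beta_g)
  g_int <- as.vector(gm$dosage %*% gamma)
  make_exam <- function(exam, age, E, keep) {
    e2 <- if (is.null(config$exposure_effect2)) 0 else config$exposure_effect2
    mu <- config$intercept + config$beta_age * age +
      config$beta_age2 * age^2 + config$beta_sex * sex +
      config$exposure_effect * E + e2 * E^2 + g_main + E * g_int + b
    data.frame(subject_id = ids, exam = exam, age = age, age2 = age^2,
               sex = sex, exposure = E,
               bmi = mu + stats::rnorm(n, 0, config$sigma_e),
               stringsAsFactors = FALSE)[keep, , drop = FALSE]
  }
  d1 <- make_exam(1L, age1, E1, rep(TRUE, n))
  age2 <- age1 + 4
  E2 <- if (config$time_varying_exposure) draw_E(age2) else E1
  d2 <- make_exam(2L, age2, E2, two)
  out <- rbind(d1, d2)
  out <- out[order(out$subject_id, out$exam), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a cohort, genotypes and config snapshot to disk
#'
#' Emits the formats the pipeline reads: `<prefix>.pheno.csv`,
#' `<prefix>.dosage.tsv` / `<prefix>.variants.tsv`, `<prefix>.vcf`, and a
#' JSON config snapshot.
#'
#' @param cohort [simulate_cohort()] output.
#' @param gm The matching [genotype_matrix()].
#' @param config The [sim_config()] used.
#' @param prefix Output path prefix.
#' @return Invisibly, the vector of written paths.
#' @export
write_simulation <- function(cohort, gm, config, prefix) {
  pheno <- paste0(prefix, ".pheno.csv")
  data.table::fwrite(cohort, pheno)
  tsv <- write_dosage_tsv(gm, prefix)
  vcf <- write_dosage_vcf(gm, paste0(prefix, ".vcf"))
  cfg <- paste0(prefix, ".config.json")
  jsonlite::write_json(unclass(config), cfg, auto_unbox = TRUE, digits = NA)
  invisible(c(pheno, tsv, vcf, cfg))
}
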
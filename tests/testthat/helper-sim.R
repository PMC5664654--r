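# Shared fixture builders (all programmatic; no stored data).

# Cross-sectional table: one exam per subject, pure-noise outcome.
make_flat_data <- function(n, sd = 5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- data.frame(subject_id = sprintf("S%05d", seq_len(n)),
                  exam = 1L,
                  age = stats::rnorm(n, 66, 10),
                  sex = stats::rbinom(n, 1L, 0.5),
                  exposure = stats::rbinom(n, 1L, 0.4),
                  bmi = stats::rnorm(n, 29, sd))
  d$age2 <- d$age^2
  d
}

# Plain standardized block from binomial dosages (independent variants).
make_block <- function(n, p, maf = 0.3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(stats::rbinom(n * p, 2L, maf), n, p,
              dimnames = list(sprintf("S%05d", seq_len(n)),
                              sprintf("v%03d", seq_len(p))))
  standardize_genotypes(m)
}

# Default small cohort + genotypes for end-to-end style tests.
make_cohort <- function(n = 300, p = 15, seed = 1, ...) {
  set.seed(seed)
  cfg <- sim_config(n_subjects = n, p_variants = p, ...)
  gm <- simulate_genotypes(n, p, maf_range = cfg$maf_range, rho = cfg$rho)
  list(cfg = cfg, gm = gm, pheno = simulate_cohort(cfg, gm))
}
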
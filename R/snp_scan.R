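# Single-SNP follow-up within a region -----------------------------------------

#' Single-SNP GEE interaction scan
#'
#' For every variant in the matrix, fits the longitudinal GEE
#' `Y ~ covariates + SNP + E + SNP:E` (additive dosage coding) and records
#' the SNP, exposure, and interaction estimates with sandwich SEs and
#' two-sided p-values. Monomorphic variants are skipped with a reason;
#' non-converged fits are flagged and returned without inference.
#'
#' @param data Long-format data.frame.
#' @param gm A [genotype_matrix()] with subject-id rownames matching
#'   `data[[id]]`.
#' @param exposure,outcome,covariates,id Column names in `data`.
#' @param working Working correlation for [fit_gee()].
#' @return data.frame ordered by position: `rsid`, `pos`, `coded_allele`,
#'   `beta_snp`, `se_snp`, `p_snp`, `beta_exposure`, `se_exposure`,
#'   `p_exposure`, `beta_int`, `se_int`, `p_int`, `n_subjects`, `n_obs`,
#'   `status`.
#' @export
snp_interaction_scan <- function(data, gm, exposure, outcome = "bmi",
                                 covariates = c("age", "age2", "sex"),
                                 id = "subject_id",
                                 working = "exchangeable") {
  v <- gm$variants
  ord <- order(v$pos)
  ridx <- match(as.character(data[[id]]), rownames(gm$dosage))
  if (anyNA(ridx)) stop("subjects in data missing from the genotype matrix")
  res <- lapply(ord, function(j) {
    dos <- gm$dosage[ridx, j]
    rec <- data.frame(rsid = v$id[j], pos = v$pos[j],
                      coded_allele = v$alt[j],
                      beta_snp = NA_real_, se_snp = NA_real_, p_snp = NA_real_,
                      beta_exposure = NA_real_, se_exposure = NA_real_,
                      p_exposure = NA_real_,
                      beta_int = NA_real_, se_int = NA_real_, p_int = NA_real_,
                      n_subjects = NA_integer_, n_obs = NA_integer_,
                      status = "ok", stringsAsFactors = FALSE)
    if (stats::var(dos, na.rm = TRUE) == 0 || all(is.na(dos))) {
      rec$status <- "monomorphic"
      return(rec)
    }
    d <- data
    d$.snp <- dos
    fml <- stats::reformulate(c(covariates, ".snp", exposure,
                                paste0(".snp:", exposure)),
                              response = outcome)
    fit <- tryCatch(fit_gee(fml, d, id = id, working = working),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      rec$status <- paste0("error: ", conditionMessage(fit))
      return(rec)
    }
    if (!fit$converged) {
      rec$status <- "non_converged"
      return(rec)
    }
    int_term <- grep(":", names(fit$coefficients), value = TRUE, fixed = TRUE)[1L]
    ts <- robust_test(fit, ".snp")
    te <- robust_test(fit, exposure)
    ti <- robust_test(fit, int_term)
    rec[c("beta_snp", "se_snp", "p_snp")] <- ts[c("estimate", "se", "p")]
    rec[c("beta_exposure", "se_exposure", "p_exposure")] <-
      te[c("estimate", "se", "p")]
    rec[c("beta_int", "se_int", "p_int")] <- ti[c("estimate", "se", "p")]
    rec$n_subjects <- fit$n_subjects
    rec$n_obs <- fit$n_obs
    rec
  })
  do.call(rbind, res)
}

#' Covariate-adjusted outcome means by genotype and exposure class
#'
#' Computes the adjusted outcome per observation as the residual from a
#' covariate-only GEE (no SNP, no exposure) plus the grand mean, averages it
#' within subject across exams, and tabulates cell means over subjects by
#' hard-call genotype class (dosages rounded to 0/1/2; calls farther than
#' `call_band` from an integer are dropped) and exposure class (the subject's
#' first non-missing exposure value). Empty cells are reported with `NA`
#' means, not errors.
#'
#' @param data Long-format data.frame.
#' @param snp Per-subject dosage vector named by subject id (one column of a
#'   [genotype_matrix()]).
#' @param exposure,outcome,covariates,id Column names in `data`.
#' @param call_band Maximum distance from an integer for a hard call.
#' @param working Working correlation for the adjustment fit; the
#'   independence default makes the adjusted outcome exactly orthogonal to
#'   the covariates.
#' @return data.frame: `genotype`, `exposure`, `mean`, `n`.
#' @export
adjusted_means <- function(data, snp, exposure, outcome = "bmi",
                           covariates = c("age", "age2", "sex"),
                           id = "subject_id", call_band = 0.1,
                           working = "independence") {
  fml <- stats::reformulate(covariates, response = outcome)
  fit <- fit_gee(fml, data, id = id, working = working)
  used <- setdiff(seq_len(nrow(data)),
                  which(!stats::complete.cases(
                    data[, c(outcome, covariates, id), drop = FALSE])))
  adj <- fit$residuals + mean(data[[outcome]][used])
  ids <- fit$id
  subj_adj <- tapply(adj, ids, mean)
  first_e <- tapply(seq_len(nrow(data)), as.character(data[[id]]),
                    function(ix) {
                      e <- data[[exposure]][ix]
                      e <- e[!is.na(e)]
                      if (length(e)) e[1L] else NA
                    })
  subs <- names(subj_adj)
  dos <- snp[subs]
  gcall <- round(dos)
  gcall[abs(dos - gcall) > call_band | gcall < 0 | gcall > 2] <- NA
  eclass <- unlist(first_e[subs])
  grid <- expand.grid(genotype = 0:2, exposure = sort(unique(eclass[!is.na(eclass)])))
  grid$mean <- NA_real_
  grid$n <- 0L
  for (i in seq_len(nrow(grid))) {
    sel <- !is.na(gcall) & gcall == grid$genotype[i] &
      !is.na(eclass) & eclass == grid$exposure[i]
    grid$n[i] <- sum(sel)
    if (any(sel)) grid$mean[i] <- mean(subj_adj[sel])
  }
  grid
}
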
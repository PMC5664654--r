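# Staged inference pipeline -----------------------------------------------------
#
# Stage 1  marginal exposure tests per stratum (GEE) + IVW meta, Bonferroni
#          gating within the exposure family.
# Stage 2  marginal set tests per region (confirmatory).
# Stage 3  interaction set tests for gated exposures only, FDR per exposure
#          family across regions; Fisher meta across strata for exposures
#          that passed gating in the combined meta.
# Stage 4  single-SNP scan + adjusted means for (exposure, region) pairs that
#          survive FDR.

#' Run the staged gene-environment interaction pipeline
#'
#' @param pheno Long-format phenotype data.frame (`subject_id`, exam, outcome,
#'   covariates, 0/1 exposures, optional stratum column).
#' @param regions Named list of [genotype_matrix()] objects, one per
#'   gene/region (already restricted/filtered; see [filter_variants()]).
#' @param exposures Character vector of exposure column names (each 0/1 with
#'   1 = adverse).
#' @param outcome,covariates,id Column names.
#' @param strata Optional stratum column name; strata are analysed fully
#'   separately and combined only by meta-analysis.
#' @param alpha Family-wise level for Stage-1 Bonferroni gating.
#' @param fdr_level FDR level for Stage-3 discovery.
#' @param tau,p_max Weighted-PCA knobs for the interaction null model
#'   (see [weighted_pca_adjustment()]); `p_max = NULL` uses the per-stratum
#'   default `min(100, n_subjects / 10)`.
#' @param weights Optional per-variant weights for the set tests.
#' @param spline_knots Interior knots for a continuous exposure main effect.
#' @param working Working correlation for Stage-1/Stage-4 GEE fits.
#' @param scale_genotypes Unit-variance scaling in [standardize_genotypes()].
#' @param out_dir Optional directory; when given, per-stage TSVs, a JSON
#'   manifest, and a plain-text log of every gating decision are written.
#' @param seed Optional seed recorded in the manifest (the pipeline itself is
#'   deterministic given its inputs).
#' @return List with `stage1`, `stage2`, `stage3`, `stage3_meta`, `stage4`
#'   (scan + adjusted means), `gated_exposures`, `log`, `manifest`.
#' @export
run_pipeline <- function(pheno, regions, exposures, outcome = "bmi",
                         covariates = c("age", "age2", "sex"),
                         id = "subject_id", strata = NULL,
                         alpha = 0.05, fdr_level = 0.05,
                         tau = 0.95, p_max = NULL, weights = NULL,
                         spline_knots = 3L, working = "exchangeable",
                         scale_genotypes = TRUE,
                         out_dir = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(names(regions)) || any(!nzchar(names(regions))))
    stop("regions must be a named list of genotype matrices")
  log <- character()
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log <<- c(log, msg)
    message(msg)
  }
  stratum_of <- if (is.null(strata)) rep("all", nrow(pheno))
                else as.character(pheno[[strata]])
  slevels <- unique(stratum_of)
  bonf <- bonferroni_threshold(length(exposures), alpha)
  say("Stage 1: %d exposure(s) x %d stratum/strata; Bonferroni threshold %.3g (alpha %.3g / %d tests)",
      length(exposures), length(slevels), bonf, alpha, length(exposures))

  # ---- Stage 1: marginal exposure effects -----------------------------------
  s1 <- list()
  for (st in slevels) {
    d <- pheno[stratum_of == st, , drop = FALSE]
    for (e in exposures) {
      fit <- fit_gee(stats::reformulate(c(covariates, e), response = outcome),
                     d, id = id, working = working)
      tt <- robust_test(fit, e)
      s1[[length(s1) + 1L]] <- data.frame(
        stratum = st, exposure = e, beta = tt$estimate, se = tt$se, p = tt$p,
        n_subjects = fit$n_subjects, n_obs = fit$n_obs,
        significant = tt$p < bonf, stringsAsFactors = FALSE)
    }
  }
  stage1 <- do.call(rbind, s1)
  if (length(slevels) > 1L) {
    meta_rows <- lapply(exposures, function(e) {
      sub <- stage1[stage1$exposure == e, ]
      mr <- ivw_meta(sub$beta, sub$se, strata = sub$stratum)
      data.frame(stratum = "meta", exposure = e, beta = mr$beta, se = mr$se,
                 p = mr$p, n_subjects = sum(sub$n_subjects),
                 n_obs = sum(sub$n_obs), significant = mr$p < bonf,
                 stringsAsFactors = FALSE)
    })
    stage1 <- rbind(stage1, do.call(rbind, meta_rows))
  }
  gated <- unique(stage1$exposure[stage1$significant])
  for (e in exposures) {
    hit <- stage1$stratum[stage1$exposure == e & stage1$significant]
    if (length(hit))
      say("Gating: exposure %s passes Bonferroni (p < %.3g) in: %s",
          e, bonf, paste(hit, collapse = ", "))
    else
      say("Gating: exposure %s NOT significant in any stratum or meta; interaction models will not be tested for it",
          e)
  }

  # ---- Stage 2: marginal genetic set tests ----------------------------------
  s2 <- list()
  blocks <- list() # standardized per (stratum, region)
  for (st in slevels) {
    d <- pheno[stratum_of == st, , drop = FALSE]
    null0 <- fit_null_model(d, outcome, covariates, id = id)
    for (rg in names(regions)) {
      Z <- standardize_genotypes(regions[[rg]], scale = scale_genotypes)
      blocks[[paste(st, rg, sep = "\r")]] <- Z
      res <- marginal_set_test(null0, Z, weights = weights, region = rg)
      s2[[length(s2) + 1L]] <- data.frame(
        stratum = st, region = rg, hypothesis = "marginal", Q = res$Q,
        p = res$p, method = res$method, n_subjects = res$n_subjects,
        p_variants = res$p_variants, stringsAsFactors = FALSE)
    }
  }
  stage2 <- do.call(rbind, s2)

  # ---- Stage 3: interaction set tests for gated exposures -------------------
  stage3 <- NULL
  stage3_meta <- NULL
  if (!length(gated)) {
    say("Stage 3 skipped: no exposure passed Stage-1 gating")
  } else {
    s3 <- list()
    for (st in slevels) {
      d <- pheno[stratum_of == st, , drop = FALSE]
      strat_gated <- gated
      for (e in strat_gated) {
        for (rg in names(regions)) {
          Z <- blocks[[paste(st, rg, sep = "\r")]]
          pm <- if (is.null(p_max)) min(100, length(unique(d[[id]])) / 10)
                else p_max
          adj <- weighted_pca_adjustment(Z, tau = tau, p_max = pm)
          nf <- fit_null_model(d, outcome, covariates, exposure = e,
                               g_adjust = adj, id = id,
                               spline_knots = spline_knots)
          res <- interaction_set_test(nf, Z, weights = weights, region = rg)
          s3[[length(s3) + 1L]] <- data.frame(
            stratum = st, exposure = e, region = rg, Q = res$Q, p = res$p,
            method = res$method, n_subjects = res$n_subjects,
            p_variants = res$p_variants, stringsAsFactors = FALSE)
        }
      }
    }
    stage3 <- do.call(rbind, s3)
    stage3$q <- NA_real_
    for (st in unique(stage3$stratum)) for (e in gated) {
      fam <- stage3$stratum == st & stage3$exposure == e
      stage3$q[fam] <- bh_fdr(stage3$p[fam])
    }
    say("Stage 3: %d interaction test(s) = %d gated exposure(s) x %d region(s) per stratum; FDR within each (stratum, exposure) family",
        nrow(stage3), length(gated), length(regions))
    if (length(slevels) > 1L) {
      meta_gated <- if ("meta" %in% stage1$stratum)
        unique(stage1$exposure[stage1$stratum == "meta" & stage1$significant])
      else gated
      if (length(meta_gated)) {
        rows <- list()
        for (e in meta_gated) for (rg in names(regions)) {
          sub <- stage3[stage3$exposure == e & stage3$region == rg, ]
          mr <- fisher_combine(pmax(sub$p, .Machine$double.xmin),
                               strata = sub$stratum)
          rows[[length(rows) + 1L]] <- data.frame(
            exposure = e, region = rg, statistic = mr$statistic, df = mr$df,
            p = mr$p, stringsAsFactors = FALSE)
        }
        stage3_meta <- do.call(rbind, rows)
        stage3_meta$q <- NA_real_
        for (e in meta_gated) {
          fam <- stage3_meta$exposure == e
          stage3_meta$q[fam] <- bh_fdr(stage3_meta$p[fam])
        }
        say("Stage 3 meta: Fisher combination across strata for %d exposure(s) significant in the combined meta",
            length(meta_gated))
      } else say("Stage 3 meta skipped: no exposure significant in combined meta")
    }
  }

  # ---- Stage 4: single-SNP follow-up ----------------------------------------
  stage4 <- list()
  hits <- NULL
  if (!is.null(stage3)) {
    hits <- unique(stage3[stage3$q <= fdr_level, c("exposure", "region")])
    if (!is.null(stage3_meta)) {
      mh <- stage3_meta[stage3_meta$q <= fdr_level, c("exposure", "region")]
      hits <- unique(rbind(hits, mh))
    }
  }
  if (is.null(hits) || !nrow(hits)) {
    say("Stage 4 skipped: no (exposure, region) pair passed FDR <= %.3g",
        fdr_level)
  } else {
    for (i in seq_len(nrow(hits))) {
      e <- hits$exposure[i]; rg <- hits$region[i]
      say("Stage 4: single-SNP scan for exposure %s in region %s (q <= %.3g)",
          e, rg, fdr_level)
      for (st in slevels) {
        d <- pheno[stratum_of == st, , drop = FALSE]
        scan <- snp_interaction_scan(d, regions[[rg]], exposure = e,
                                     outcome = outcome,
                                     covariates = covariates, id = id,
                                     working = working)
        ok <- scan$status == "ok" & !is.na(scan$p_int)
        top <- if (any(ok)) scan$rsid[ok][which.min(scan$p_int[ok])] else NA
        am <- if (!is.na(top))
          adjusted_means(d, regions[[rg]]$dosage[, top], exposure = e,
                         outcome = outcome, covariates = covariates,
                         id = id, working = working)
        else NULL
        stage4[[paste(st, e, rg, sep = ".")]] <-
          list(stratum = st, exposure = e, region = rg, scan = scan,
               top_snp = top, adjusted_means = am)
      }
    }
  }

  manifest <- list(package = "longGxE",
                   version = as.character(utils::packageVersion("longGxE")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   seed = seed, exposures = exposures,
                   regions = names(regions), strata = slevels,
                   alpha = alpha, bonferroni = bonf, fdr_level = fdr_level,
                   tau = tau, p_max = p_max, working = working,
                   gated_exposures = gated)
  out <- list(stage1 = stage1, stage2 = stage2, stage3 = stage3,
              stage3_meta = stage3_meta, stage4 = stage4,
              gated_exposures = gated, log = log, manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(df, f) if (!is.null(df))
      data.table::fwrite(df, file.path(out_dir, f), sep = "\t")
    wr(stage1, "stage1_exposures.tsv")
    wr(stage2, "stage2_marginal.tsv")
    wr(stage3, "stage3_interaction.tsv")
    wr(stage3_meta, "stage3_meta.tsv")
    for (nm in names(stage4)) {
      wr(stage4[[nm]]$scan, sprintf("stage4_scan_%s.tsv", gsub("[^A-Za-z0-9._-]", "_", nm)))
      wr(stage4[[nm]]$adjusted_means,
         sprintf("stage4_means_%s.tsv", gsub("[^A-Za-z0-9._-]", "_", nm)))
    }
    writeLines(log, file.path(out_dir, "pipeline.log"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  out
}

#' Build all regions from an index-SNP table and write a manifest
#'
#' @param index_snps data.frame: `rsid`, `chrom`, `pos`.
#' @param genes Transcript annotation as in [build_region()].
#' @param ... Passed to [build_region()].
#' @return data.frame manifest: region, source, chrom, start, end, index_snp.
#' @export
build_region_manifest <- function(index_snps, genes, ...) {
  rows <- lapply(seq_len(nrow(index_snps)), function(i) {
    r <- build_region(index_snps$rsid[i], index_snps$chrom[i],
                      index_snps$pos[i], genes, ...)
    data.frame(region = r$name, source = r$source, chrom = r$chrom,
               start = r$start, end = r$end, index_snp = r$index_snp,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
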
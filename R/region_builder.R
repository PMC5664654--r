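# Gene/region construction around index SNPs; genotype container + filters ----

#' Genotype dosage matrix with per-variant metadata
#'
#' Container pairing an `n x p` dosage matrix (expected alternate-allele
#' counts in `[0, 2]`, possibly missing) with a variant metadata table.
#' Subject order must match the phenotype table the dosages are analysed
#' against.
#'
#' @param dosage Numeric matrix, subjects in rows, variants in columns.
#'   Row names are subject ids, column names variant ids.
#' @param variants data.frame with one row per variant: `id`, `chrom`, `pos`,
#'   `ref`, `alt`, `info` (imputation quality in (0, 1]); `af`/`maf` are
#'   recomputed from the dosages if absent.
#' @return A `genotype_matrix` object.
#' @export
genotype_matrix <- function(dosage, variants) {
  dosage <- as.matrix(dosage)
  if (ncol(dosage) != nrow(variants))
    stop("dosage column count must equal variant metadata row count")
  if (is.null(colnames(dosage))) colnames(dosage) <- variants$id
  if (ncol(dosage) &&
      !identical(colnames(dosage), as.character(variants$id)))
    stop("dosage column names must match variant ids in order")
  if (ncol(dosage)) {
    rng <- range(dosage, na.rm = TRUE)
    if (rng[1] < 0 || rng[2] > 2) stop("dosages must lie in [0, 2]")
  }
  if (ncol(dosage) && (is.null(variants$af) || is.null(variants$maf))) {
    fr <- vapply(seq_len(ncol(dosage)),
                 function(j) compute_maf(dosage[, j], variants$id[j]),
                 numeric(2))
    variants$af <- fr[1L, ]
    variants$maf <- fr[2L, ]
  }
  structure(list(dosage = dosage, variants = variants),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d subjects x %d variants (chrom %s, %s..%s)\n",
              nrow(x$dosage), ncol(x$dosage),
              paste(unique(x$variants$chrom), collapse = ","),
              format(min(x$variants$pos)), format(max(x$variants$pos))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Alternate-allele frequency and MAF from dosages
#'
#' @param dosages Per-subject dosages for one variant.
#' @param id Variant id used in error messages.
#' @return `c(af, maf)`: alternate-allele frequency `mean(dosage)/2` over
#'   non-missing entries, and `min(af, 1 - af)`.
#' @export
compute_maf <- function(dosages, id = "variant") {
  ok <- !is.na(dosages)
  if (!any(ok)) stop(sprintf("all dosages missing for %s", id))
  f <- mean(dosages[ok]) / 2
  c(af = f, maf = min(f, 1 - f))
}

#' Build a gene/region around a GWAS index SNP
#'
#' If the index SNP lies within any gene span extended by a `buffer` (default
#' 5 kb) on either side, the region is that gene's unbuffered span (multiple
#' transcripts per gene are merged to the most inclusive start/stop first).
#' Otherwise the region is a symmetric window of `window` bp (default 50 kb)
#' around the index position, clamped at position 1. When several genes
#' contain the index SNP within buffer, a gene whose unbuffered span contains
#' it wins; remaining ties go to the gene with the nearest span boundary,
#' then alphabetically by gene id.
#'
#' @param rsid Index SNP identifier (used as the region name for windows).
#' @param chrom,pos Index SNP coordinates (1-based).
#' @param genes data.frame of transcript intervals: `chrom`, `start`, `end`,
#'   `gene` (and optionally `transcript`); 1-based inclusive.
#' @param buffer Containment buffer in bp around each gene span.
#' @param window Half-width in bp of the fallback window.
#' @return A `region` object: `name`, `chrom`, `start`, `end`, `source`
#'   (`"gene"` or `"window"`), `index_snp`.
#' @export
build_region <- function(rsid, chrom, pos, genes, buffer = 5000L,
                         window = 50000L) {
  if (!all(c("chrom", "start", "end", "gene") %in% names(genes)))
    stop("genes must have columns chrom, start, end, gene")
  g <- genes[genes$chrom == chrom, , drop = FALSE]
  if (!nrow(g) && nrow(genes))
    stop(sprintf("chromosome %s absent from gene annotation", chrom))
  # most inclusive transcript union per gene
  spans <- if (nrow(g)) {
    agg <- stats::aggregate(cbind(start, end) ~ gene, data = g,
                            FUN = function(z) z)
    data.frame(gene = agg$gene,
               start = vapply(split(g$start, g$gene), min, 1)[agg$gene],
               end = vapply(split(g$end, g$gene), max, 1)[agg$gene],
               stringsAsFactors = FALSE)
  } else data.frame(gene = character(), start = numeric(), end = numeric())
  hit <- spans[pos >= spans$start - buffer & pos <= spans$end + buffer, ,
               drop = FALSE]
  if (nrow(hit)) {
    inside <- hit[pos >= hit$start & pos <= hit$end, , drop = FALSE]
    pick <- if (nrow(inside)) inside else hit
    if (nrow(pick) > 1L) {
      d <- pmin(abs(pick$start - pos), abs(pick$end - pos))
      pick <- pick[order(d, pick$gene), , drop = FALSE]
    }
    pick <- pick[1L, ]
    out <- list(name = pick$gene, chrom = chrom, start = pick$start,
                end = pick$end, source = "gene", index_snp = rsid)
  } else {
    out <- list(name = rsid, chrom = chrom, start = max(1, pos - window),
                end = pos + window, source = "window", index_snp = rsid)
  }
  structure(out, class = "region")
}

#' @export
print.region <- function(x, ...) {
  cat(sprintf("<region> %s [%s source] chr%s:%s-%s (index %s)\n", x$name,
              x$source, x$chrom, format(x$start), format(x$end), x$index_snp))
  invisible(x)
}

#' Restrict a genotype matrix to a region with quality filters
#'
#' Retains exactly the variants whose position lies inside the region span on
#' the region's chromosome, with imputation INFO strictly above `info_min`
#' and MAF strictly above `maf_min`. Positional order is preserved and a
#' per-variant exclusion reason is attached.
#'
#' @param gm A [genotype_matrix()].
#' @param region A [build_region()] result (or any list with `chrom`,
#'   `start`, `end`).
#' @param info_min,maf_min Strict lower thresholds (defaults 0.5 and 0.01).
#' @return The filtered `genotype_matrix`, with attribute `"exclusions"`, a
#'   data.frame of dropped variant ids and reasons. Zero surviving variants
#'   yields an empty matrix with a warning.
#' @export
filter_variants <- function(gm, region, info_min = 0.5, maf_min = 0.01) {
  v <- gm$variants
  if (is.null(v$info)) stop("variant metadata lacks an 'info' column")
  reason <- rep(NA_character_, nrow(v))
  in_span <- v$chrom == region$chrom & v$pos >= region$start &
    v$pos <= region$end
  reason[!in_span] <- "outside_region"
  low_info <- in_span & v$info <= info_min
  reason[low_info] <- "low_info"
  low_maf <- in_span & !low_info & v$maf <= maf_min
  reason[low_maf] <- "low_maf"
  keep <- is.na(reason)
  ord <- order(v$pos[keep])
  idx <- which(keep)[ord]
  if (!length(idx))
    warning(sprintf("region %s: no variants survive the filters", region$name))
  out <- genotype_matrix(gm$dosage[, idx, drop = FALSE],
                         v[idx, , drop = FALSE])
  attr(out, "exclusions") <- data.frame(id = v$id[!keep],
                                        reason = reason[!keep])
  out
}

# I/O: dosage-matrix TSV + metadata TSV, and a minimal dosage VCF dialect ------

#' Write / read a genotype matrix as TSV
#'
#' The pair of files is the package's primary genotype exchange format:
#' `<prefix>.dosage.tsv` holds `subject_id` plus one column per variant, and
#' `<prefix>.variants.tsv` the metadata (`id`, `chrom`, `pos`, `ref`, `alt`,
#' `info`, `af`, `maf`).
#'
#' @param gm A [genotype_matrix()].
#' @param prefix Output path prefix.
#' @return `write_dosage_tsv` returns the two paths invisibly;
#'   `read_dosage_tsv` returns a `genotype_matrix`.
#' @export
write_dosage_tsv <- function(gm, prefix) {
  dos <- data.table::data.table(subject_id = rownames(gm$dosage))
  dos <- cbind(dos, data.table::as.data.table(gm$dosage))
  p1 <- paste0(prefix, ".dosage.tsv")
  p2 <- paste0(prefix, ".variants.tsv")
  data.table::fwrite(dos, p1, sep = "\t")
  data.table::fwrite(gm$variants, p2, sep = "\t")
  invisible(c(p1, p2))
}

#' @rdname write_dosage_tsv
#' @export
read_dosage_tsv <- function(prefix) {
  dos <- data.table::fread(paste0(prefix, ".dosage.tsv"), sep = "\t")
  v <- as.data.frame(data.table::fread(paste0(prefix, ".variants.tsv"),
                                       sep = "\t"))
  m <- as.matrix(dos[, -1])
  rownames(m) <- as.character(dos[[1L]])
  genotype_matrix(m, v)
}

#' Write / read a minimal dosage VCF
#'
#' Plain-text VCFv4.2 with one `DS` (dosage) value per genotype and `INFO`
#' and `AF` keys per variant; sufficient for round-tripping the synthetic
#' cohorts and for importing externally prepared dosage VCFs of the same
#' shape. Only biallelic SNV records are read; others are skipped with a
#' warning.
#'
#' @param gm A [genotype_matrix()].
#' @param path Output `.vcf` path (uncompressed).
#' @return `write_dosage_vcf` returns `path` invisibly; `read_dosage_vcf`
#'   a `genotype_matrix`.
#' @export
write_dosage_vcf <- function(gm, path) {
  v <- gm$variants
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=INFO,Number=1,Type=Float,Description=\"Imputation quality\">",
               "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Alternate allele frequency\">",
               "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Alternate allele dosage\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(gm$dosage)),
                     collapse = "\t")), con)
  body <- vapply(seq_len(nrow(v)), function(j) {
    ds <- formatC(gm$dosage[, j], format = "g", digits = 6)
    ds[is.na(gm$dosage[, j])] <- "."
    paste(c(v$chrom[j], v$pos[j], v$id[j], v$ref[j], v$alt[j], ".", "PASS",
            sprintf("INFO=%g;AF=%g", v$info[j], v$af[j]), "DS", ds),
          collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' @rdname write_dosage_vcf
#' @export
read_dosage_vcf <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  if (!length(hdr)) stop("not a VCF: missing #CHROM header line")
  cols <- strsplit(lines[hdr], "\t")[[1L]]
  subjects <- cols[-(1:9)]
  body <- lines[-seq_len(hdr)]
  body <- body[nzchar(body)]
  fields <- strsplit(body, "\t", fixed = TRUE)
  snv <- vapply(fields, function(f) nchar(f[4]) == 1L && nchar(f[5]) == 1L &&
                  !grepl(",", f[5], fixed = TRUE), logical(1))
  if (any(!snv)) warning(sprintf("skipping %d non-SNV/multiallelic records",
                                 sum(!snv)))
  fields <- fields[snv]
  get_info <- function(s, key) {
    m <- regmatches(s, regexec(paste0("(?:^|;)", key, "=([^;]+)"), s))[[1L]]
    if (length(m) == 2L) as.numeric(m[2L]) else NA_real_
  }
  v <- data.frame(
    id = vapply(fields, `[`, "", 3L),
    chrom = vapply(fields, `[`, "", 1L),
    pos = as.numeric(vapply(fields, `[`, "", 2L)),
    ref = vapply(fields, `[`, "", 4L),
    alt = vapply(fields, `[`, "", 5L),
    info = vapply(fields, function(f) get_info(f[8L], "INFO"), numeric(1)),
    stringsAsFactors = FALSE)
  ds_idx <- vapply(fields, function(f)
    match("DS", strsplit(f[9L], ":", fixed = TRUE)[[1L]]), integer(1))
  m <- vapply(seq_along(fields), function(j) {
    g <- vapply(strsplit(fields[[j]][-(1:9)], ":", fixed = TRUE),
                `[`, "", ds_idx[j])
    suppressWarnings(as.numeric(ifelse(g == ".", NA, g)))
  }, numeric(length(subjects)))
  m <- matrix(m, nrow = length(subjects),
              dimnames = list(subjects, v$id))
  genotype_matrix(m, v)
}
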
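# Exposure battery scoring, dichotomization, outcome cleaning -----------------

#' Define a questionnaire battery
#'
#' A battery is a fixed set of Likert-type or yes/no items that is aggregated
#' into a single score per subject-exam. Batteries differ in item count,
#' response scale, which items are reverse-coded, whether items are averaged
#' or summed, and how many missing item responses are tolerated before the
#' score itself is set to missing. Multi-domain instruments (social support
#' asked separately about spouse, children, family, friends) score each
#' relationship domain with the same item rules and then average the domain
#' scores.
#'
#' @param name Battery label.
#' @param n_items Number of items (per domain when `domains > 1`).
#' @param scale_min,scale_max Integer response bounds common to all items.
#' @param reverse_items Integer indices (in `1:n_items`) to reverse-code
#'   before aggregation: `v -> scale_min + scale_max - v`.
#' @param aggregation `"mean"` or `"sum"` over non-missing items.
#' @param max_missing Maximum number of missing items tolerated; a score is
#'   missing when the missing count exceeds this (strictly more than).
#' @param domains Number of relationship domains whose domain scores are
#'   averaged; `1` for single-domain batteries.
#' @return A `battery_spec` object.
#' @examples
#' trait_anger <- battery_spec("ANGERIN", n_items = 4, scale_min = 1,
#'                             scale_max = 4, aggregation = "mean",
#'                             max_missing = 2)
#' compute_battery_score(trait_anger, c(1, 2, 3, 4))
#' @export
battery_spec <- function(name, n_items, scale_min, scale_max,
                         reverse_items = integer(), aggregation = c("mean", "sum"),
                         max_missing = 0L, domains = 1L) {
  aggregation <- match.arg(aggregation)
  n_items <- as.integer(n_items)
  max_missing <- as.integer(max_missing)
  domains <- as.integer(domains)
  if (n_items < 1L) stop("n_items must be >= 1")
  if (scale_min >= scale_max) stop("scale_min must be < scale_max")
  if (max_missing < 0L || max_missing >= n_items)
    stop("max_missing must satisfy 0 <= max_missing < n_items")
  if (length(reverse_items) && !all(reverse_items %in% seq_len(n_items)))
    stop("reverse_items must be a subset of 1..n_items")
  if (domains < 1L) stop("domains must be >= 1")
  structure(list(name = name, n_items = n_items, scale_min = scale_min,
                 scale_max = scale_max,
                 reverse_items = as.integer(reverse_items),
                 aggregation = aggregation, max_missing = max_missing,
                 domains = domains),
            class = "battery_spec")
}

#' @export
print.battery_spec <- function(x, ...) {
  cat(sprintf("<battery_spec> %s: %d item(s) on [%g, %g], %s, max %d missing",
              x$name, x$n_items, x$scale_min, x$scale_max, x$aggregation,
              x$max_missing))
  if (x$domains > 1L) cat(sprintf(", %d domains averaged", x$domains))
  cat("\n")
  invisible(x)
}

#' Built-in battery definitions for the nine social/psychosocial exposures
#'
#' Scoring rules for the instruments used in the analyses this package
#' supports: trait anger (ANGERIN; 4 items on 1-4, averaged, missing when
#' more than 2 items missing), state anger (ANGEROUT; 7 items, averaged,
#' missing when more than 3 missing), chronic burden (BURDEN; 8 items on
#' 1-4, summed), stressful life events (SLE; 6 yes/no items, summed),
#' positive social support (PSS; 3 items per relationship domain, all
#' reverse-coded, averaged, domain score missing when more than 1 item
#' missing; 4 domain scores averaged), negative social support (NSS; 4 items
#' per domain, all reverse-coded, averaged, missing when more than 2 items
#' missing), and depressive symptoms (CESD; 8 yes/no items with two
#' positively worded items reverse-coded, summed to a 0-8 score).
#'
#' CSES and ASES (childhood/adult socioeconomic status) are not batteries:
#' they are education years dichotomized by [dichotomize_exposure()] with the
#' `education_cut` rule.
#'
#' @param name One of `"ANGERIN"`, `"ANGEROUT"`, `"BURDEN"`, `"SLE"`,
#'   `"PSS"`, `"NSS"`, `"CESD"`.
#' @return A [battery_spec()].
#' @export
hrs_battery <- function(name = c("ANGERIN", "ANGEROUT", "BURDEN", "SLE",
                                 "PSS", "NSS", "CESD")) {
  name <- match.arg(name)
  switch(name,
    ANGERIN  = battery_spec("ANGERIN", 4L, 1, 4, aggregation = "mean",
                            max_missing = 2L),
    ANGEROUT = battery_spec("ANGEROUT", 7L, 1, 4, aggregation = "mean",
                            max_missing = 3L),
    BURDEN   = battery_spec("BURDEN", 8L, 1, 4, aggregation = "sum"),
    SLE      = battery_spec("SLE", 6L, 0, 1, aggregation = "sum"),
    PSS      = battery_spec("PSS", 3L, 1, 4, reverse_items = 1:3,
                            aggregation = "mean", max_missing = 1L,
                            domains = 4L),
    NSS      = battery_spec("NSS", 4L, 1, 4, reverse_items = 1:4,
                            aggregation = "mean", max_missing = 2L,
                            domains = 4L),
    CESD     = battery_spec("CESD", 8L, 0, 1, reverse_items = c(4L, 6L),
                            aggregation = "sum")
  )
}

reverse_code <- function(spec, responses) {
  if (length(spec$reverse_items))
    responses[spec$reverse_items] <-
      spec$scale_min + spec$scale_max - responses[spec$reverse_items]
  responses
}

score_one_domain <- function(spec, responses) {
  bad <- which(!is.na(responses) &
                 (responses < spec$scale_min | responses > spec$scale_max))
  if (length(bad))
    stop(sprintf("battery '%s': item %d response %g outside scale [%g, %g]",
                 spec$name, bad[1L], responses[bad[1L]],
                 spec$scale_min, spec$scale_max))
  if (sum(is.na(responses)) > spec$max_missing) return(NA_real_)
  responses <- reverse_code(spec, responses)
  if (spec$aggregation == "mean") mean(responses, na.rm = TRUE)
  else sum(responses, na.rm = TRUE) # sum over non-missing items
}

#' Score one battery for one subject-exam
#'
#' Reverse-codes the flagged items, aggregates non-missing responses by the
#' battery's rule, and returns missing when the missing-item count exceeds
#' the battery's tolerance. For multi-domain batteries `responses` is a
#' matrix or list with one row/element per domain; domain scores follow the
#' per-domain missingness rule and the final score averages the non-missing
#' domain scores (a relationship domain that does not apply, e.g. no spouse,
#' is skipped rather than propagating missingness).
#'
#' @param spec A [battery_spec()].
#' @param responses Numeric vector of length `n_items`, or for multi-domain
#'   batteries a `domains x n_items` matrix (or list of vectors).
#' @return The battery score, or `NA` under the missingness rule.
#' @export
compute_battery_score <- function(spec, responses) {
  stopifnot(inherits(spec, "battery_spec"))
  if (spec$domains > 1L) {
    if (is.list(responses)) responses <- do.call(rbind, responses)
    if (!is.matrix(responses) || nrow(responses) != spec$domains ||
        ncol(responses) != spec$n_items)
      stop(sprintf("battery '%s': expected %d x %d response matrix",
                   spec$name, spec$domains, spec$n_items))
    dom <- apply(responses, 1L, function(r) score_one_domain(spec, r))
    if (all(is.na(dom))) return(NA_real_)
    return(mean(dom, na.rm = TRUE))
  }
  if (length(responses) != spec$n_items)
    stop(sprintf("battery '%s': expected %d responses, got %d",
                 spec$name, spec$n_items, length(responses)))
  score_one_domain(spec, as.numeric(responses))
}

#' Score a battery across an item-level table
#'
#' Vectorised wrapper over [compute_battery_score()]: takes one row per
#' subject-exam with one column per item (domain-major order for
#' multi-domain batteries) and returns the score vector.
#'
#' @param spec A [battery_spec()].
#' @param items A data.frame or matrix with `n_items * domains` columns.
#' @return Numeric vector of scores, one per row.
#' @export
score_battery_table <- function(spec, items) {
  items <- as.matrix(items)
  need <- spec$n_items * spec$domains
  if (ncol(items) != need)
    stop(sprintf("battery '%s': expected %d item columns, got %d",
                 spec$name, need, ncol(items)))
  apply(items, 1L, function(r) {
    if (spec$domains > 1L)
      compute_battery_score(spec, matrix(r, nrow = spec$domains, byrow = TRUE))
    else compute_battery_score(spec, r)
  })
}

#' Dichotomize an exposure series (1 = adverse category)
#'
#' All exposures enter the interaction models as 0/1 indicators with 1 the
#' adverse category. Three rules are supported: `group_median` codes 1 when
#' the score strictly exceeds the group-specific median pooled over all exams
#' and subjects (values tied with the median go to the reference category 0);
#' `zero_reference` codes 1 for any positive count (CESD, SLE); and
#' `education_cut` codes 1 when years of education fall below a cutoff
#' (childhood SES: either parent without a high-school degree, `cutoff = 12`,
#' strict; adult SES: at most 12 years, `cutoff = 12`, `inclusive = TRUE`).
#'
#' @param score Numeric vector of raw scores (may contain `NA`, which is
#'   preserved).
#' @param rule `"group_median"`, `"zero_reference"`, or `"education_cut"`.
#' @param group Grouping labels (e.g. ancestry stratum); required for
#'   `group_median`.
#' @param exam Optional exam index; only used when `per_exam = TRUE`.
#' @param per_exam If `TRUE`, medians are computed within (group, exam)
#'   rather than pooling all exams (pooled is the default and the documented
#'   behaviour).
#' @param cutoff Education-years threshold for `education_cut`.
#' @param inclusive For `education_cut`: if `TRUE`, code 1 when
#'   `score <= cutoff`, otherwise when `score < cutoff`.
#' @return Integer vector of 0/1/NA, same length as `score`.
#' @examples
#' dichotomize_exposure(c(0, 2, 0, 5), rule = "zero_reference")
#' dichotomize_exposure(c(1, 2, 3, 4), rule = "group_median",
#'                      group = rep("EA", 4))
#' @export
dichotomize_exposure <- function(score,
                                 rule = c("group_median", "zero_reference",
                                          "education_cut"),
                                 group = NULL, exam = NULL, per_exam = FALSE,
                                 cutoff = 12, inclusive = FALSE) {
  rule <- match.arg(rule)
  if (!is.numeric(score)) stop("score must be numeric")
  out <- rep(NA_integer_, length(score))
  ok <- !is.na(score)
  if (rule == "zero_reference") {
    out[ok] <- as.integer(score[ok] > 0)
    return(out)
  }
  if (rule == "education_cut") {
    out[ok] <- if (inclusive) as.integer(score[ok] <= cutoff)
               else as.integer(score[ok] < cutoff)
    return(out)
  }
  if (is.null(group)) stop("group labels are required for the median rule")
  if (length(group) != length(score)) stop("group length must match score")
  key <- if (per_exam) {
    if (is.null(exam)) stop("per_exam = TRUE requires exam indices")
    interaction(group, exam, drop = TRUE)
  } else factor(group)
  for (g in levels(key)) {
    idx <- which(key == g)
    vals <- score[idx]
    if (all(is.na(vals))) stop(sprintf("group '%s' has no non-missing scores", g))
    med <- stats::median(vals, na.rm = TRUE)
    out[idx] <- as.integer(vals > med) # ties -> reference category
  }
  out
}

#' Flag outcome outliers beyond 6 standard deviations
#'
#' Computes the mean and SD once over all non-missing values (single pass, no
#' iterative re-fitting) and flags observations whose absolute deviation
#' strictly exceeds `k` standard deviations. Values exactly at the boundary
#' are retained.
#'
#' @param y Numeric outcome values (e.g. BMI per subject-exam).
#' @param ids Optional row identifiers used in the exclusion report.
#' @param k SD multiple defining an outlier (default 6).
#' @return A list with `keep` (logical mask, `NA` values kept as `NA`-safe
#'   `TRUE`), `excluded` (data.frame of id/value for dropped rows), and the
#'   `center`, `sd`, `lower`, `upper` used.
#' @export
filter_bmi_outliers <- function(y, ids = seq_along(y), k = 6) {
  ok <- !is.na(y)
  if (sum(ok) < 2L) stop("need at least 2 non-missing outcome values")
  m <- mean(y[ok])
  s <- stats::sd(y[ok])
  keep <- rep(TRUE, length(y))
  keep[ok] <- abs(y[ok] - m) <= k * s
  list(keep = keep,
       excluded = data.frame(id = ids[!keep], value = y[!keep]),
       center = m, sd = s, lower = m - k * s, upper = m + k * s)
}

#' Rank-based inverse-normal transform
#'
#' Maps values to standard-normal quantiles through Blom offsets,
#' `qnorm((rank - 3/8) / (n + 1/4))`, with average ranks for ties and `n` the
#' non-missing count. Used for sensitivity analyses on the residual scale.
#'
#' @param x Numeric vector; `NA` preserved.
#' @return Transformed vector, order-isomorphic to `x`.
#' @export
inverse_normal_transform <- function(x) {
  ok <- !is.na(x)
  v <- x[ok]
  if (length(v) < 2L || length(unique(v)) < 2L)
    stop("need at least 2 distinct non-missing values")
  r <- rank(v, ties.method = "average")
  out <- rep(NA_real_, length(x))
  out[ok] <- stats::qnorm((r - 3 / 8) / (length(v) + 1 / 4))
  out
}
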
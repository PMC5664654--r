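# Battery scoring, dichotomization, outlier filtering, inverse-normal transform

test_that("battery scoring follows the aggregation and missingness rules", {
  anger <- hrs_battery("ANGERIN")
  expect_equal(compute_battery_score(anger, c(1, 2, 3, 4)), 2.5)
  # missing tolerated up to the cap, aggregation over non-missing items
  expect_equal(compute_battery_score(anger, c(2, NA, NA, 4)), 3)
  # more than two missing (out of four) -> missing
  expect_true(is.na(compute_battery_score(anger, c(2, NA, NA, NA))))

  burden <- hrs_battery("BURDEN")
  expect_equal(compute_battery_score(burden, rep(4, 8)), 32)
  expect_equal(compute_battery_score(burden, rep(1, 8)), 8)

  state <- hrs_battery("ANGEROUT")
  expect_true(is.na(compute_battery_score(state, c(1, 1, 1, NA, NA, NA, NA))))
  expect_false(is.na(compute_battery_score(state, c(1, 1, 1, 1, NA, NA, NA))))

  # CESD: two positively worded items reverse-coded; max adverse case sums to 8
  cesd <- hrs_battery("CESD")
  expect_equal(compute_battery_score(cesd, c(1, 1, 1, 0, 1, 0, 1, 1)), 8)
  expect_equal(compute_battery_score(cesd, c(0, 0, 0, 1, 0, 1, 0, 0)), 0)

  expect_error(compute_battery_score(anger, c(1, 2, 3, 9)), "outside scale")
  expect_error(compute_battery_score(anger, c(1, 2, 3)), "expected 4")
})

test_that("multi-domain batteries average domain scores and skip empty domains", {
  pss <- hrs_battery("PSS")
  # all items = 1 ("a lot"), reverse-coded to 4 -> each domain 4 -> final 4
  allsupport <- matrix(1, nrow = 4, ncol = 3)
  expect_equal(compute_battery_score(pss, allsupport), 4)
  # one domain entirely missing (no spouse): averaged over remaining three
  m <- matrix(1, nrow = 4, ncol = 3)
  m[1, ] <- NA
  m[2, ] <- 2   # reverse -> 3
  expect_equal(compute_battery_score(pss, m), mean(c(3, 4, 4)))
  # domain with more than one missing item is dropped, not imputed
  m2 <- matrix(1, nrow = 4, ncol = 3)
  m2[2, 1:2] <- NA
  expect_equal(compute_battery_score(pss, m2), 4)
  # all domains missing -> missing
  expect_true(is.na(compute_battery_score(pss, matrix(NA_real_, 4, 3))))
})

test_that("reverse coding is an involution", {
  spec <- battery_spec("x", 5, 1, 4, reverse_items = c(2, 4),
                       aggregation = "mean", max_missing = 1)
  set.seed(1)
  for (i in 1:20) {
    r <- sample(1:4, 5, replace = TRUE)
    twice <- longGxE:::reverse_code(spec, longGxE:::reverse_code(spec, r))
    expect_equal(twice, r, ignore_attr = TRUE)
  }
})

test_that("score_battery_table vectorises over rows (domain-major layout)", {
  anger <- hrs_battery("ANGERIN")
  items <- rbind(c(1, 2, 3, 4), c(4, 4, NA, NA), c(NA, NA, NA, 2))
  expect_equal(score_battery_table(anger, items), c(2.5, 4, NA))
  nss <- hrs_battery("NSS")
  tab <- matrix(1, nrow = 2, ncol = 16)
  expect_equal(score_battery_table(nss, tab), c(4, 4))
})

test_that("dichotomization rules: zero reference, education cut, group median", {
  expect_equal(dichotomize_exposure(c(0, 2, 0, 5), rule = "zero_reference"),
               c(0L, 1L, 0L, 1L))
  # group median pooled over exams; ties to the reference category
  expect_equal(dichotomize_exposure(c(1, 2, 3, 4), rule = "group_median",
                                    group = rep("EA", 4)),
               c(0L, 0L, 1L, 1L))
  expect_equal(dichotomize_exposure(c(1, 2, 3), rule = "group_median",
                                    group = rep("g", 3)),
               c(0L, 0L, 1L))  # value equal to median -> 0
  # group-specific medians: same score, different category per group
  sc <- c(1, 3, 5, 8, 12, 5)
  gr <- c("a", "a", "a", "b", "b", "b")
  out <- dichotomize_exposure(sc, rule = "group_median", group = gr)
  expect_equal(out[3], 1L)  # 5 > median(a) = 3
  expect_equal(out[6], 0L)  # 5 < median(b) = 8
  # education cuts: CSES strict <12, ASES inclusive <=12
  expect_equal(dichotomize_exposure(c(8, 12, 16), rule = "education_cut",
                                    cutoff = 12),
               c(1L, 0L, 0L))
  expect_equal(dichotomize_exposure(c(8, 12, 16), rule = "education_cut",
                                    cutoff = 12, inclusive = TRUE),
               c(1L, 1L, 0L))
  # missing propagates; empty group errors
  expect_true(is.na(dichotomize_exposure(c(NA, 1), rule = "zero_reference")[1]))
  expect_error(dichotomize_exposure(c(NA, 1), rule = "group_median",
                                    group = c("a", "b")),
               "no non-missing")
})

test_that("group-median rule assigns at most half of observations to adverse", {
  set.seed(42)
  for (i in 1:25) {
    sc <- sample(0:20, 60, replace = TRUE)
    g <- sample(c("x", "y"), 60, replace = TRUE)
    out <- dichotomize_exposure(sc, rule = "group_median", group = g)
    for (gg in c("x", "y"))
      expect_lte(mean(out[g == gg]), 0.5)
  }
})

test_that("6-SD outlier rule is strict, single-pass, and order-invariant", {
  # a value of 70 against mean ~29 / SD ~5.7 (threshold ~63.2) is excluded
  res <- filter_bmi_outliers(c(rep(29 - 5.7, 500), rep(29 + 5.7, 500), 70))
  expect_gt(res$upper, 63)
  expect_equal(res$excluded$value, 70)
  expect_equal(sum(!res$keep), 1L)

  # constant vector: SD 0, nothing excluded
  expect_equal(sum(!filter_bmi_outliers(rep(5, 10))$keep), 0L)

  # boundary: a value exactly at mean + 6 SD is retained (strictly greater)
  v <- rep(c(-1, 1), 50)
  res2 <- filter_bmi_outliers(v)
  expect_true(all(res2$keep))
  expect_true(all(filter_bmi_outliers(c(v, res2$upper))$keep))

  # order invariance of the exclusion count
  set.seed(11)
  y3 <- c(rnorm(500, 29, 5.7), 80, -40)
  r_a <- filter_bmi_outliers(y3)
  perm <- sample(length(y3))
  r_b <- filter_bmi_outliers(y3[perm])
  expect_equal(sum(!r_a$keep), sum(!r_b$keep))
  expect_equal(sort(r_a$excluded$value), sort(r_b$excluded$value))
  # nothing within 6 SD is ever excluded
  expect_true(all(abs(y3[!r_a$keep] - r_a$center) > 6 * r_a$sd))
  expect_error(filter_bmi_outliers(c(NA, NA, 1)), "at least 2")
})

test_that("inverse-normal transform uses Blom offsets and preserves order", {
  # closed form for n = 3 distinct values
  x <- c(10, -5, 3)
  want <- qnorm((rank(x) - 3 / 8) / (3 + 1 / 4))
  expect_equal(inverse_normal_transform(x), want)
  # middle of an odd-length symmetric sample maps to 0
  expect_equal(inverse_normal_transform(c(-9, 0, 9))[2], 0)
  # idempotent on ranks; order isomorphic
  set.seed(5)
  z <- rnorm(50)
  t1 <- inverse_normal_transform(z)
  expect_equal(order(t1), order(z))
  expect_equal(inverse_normal_transform(t1), t1)
  # ties get average ranks -> equal outputs
  tt <- inverse_normal_transform(c(1, 1, 2))
  expect_equal(tt[1], tt[2])
  # moments approximately standard normal for large n
  set.seed(6)
  big <- inverse_normal_transform(rchisq(2000, 1))
  expect_lt(abs(mean(big)), 0.01)
  expect_lt(abs(sd(big) - 1), 0.05)
  # NA preserved, constant input errors
  expect_true(is.na(inverse_normal_transform(c(1, NA, 2))[2]))
  expect_error(inverse_normal_transform(rep(3, 5)), "distinct")
})
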
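# Agreement statistics and contingency-table tests.

test_that("percent agreement counts matching grade pairs", {
  a <- percent_agreement(c("2+", "1+", "0", "2+"), c("2+", "2+", "0", "1+"))
  expect_identical(a$n, 4L)
  expect_identical(a$n_match, 2L)
  expect_equal(a$percent_match, 50)

  g <- sample(c("0", "1+", "2+", "3+"), 20, replace = TRUE)
  expect_equal(percent_agreement(g, g)$percent_match, 100)
  flip <- c("1+", "2+", "3+", "0")[match(g, c("0", "1+", "2+", "3+"))]
  expect_equal(percent_agreement(g, flip)$percent_match, 0)
  expect_error(percent_agreement(character(), character()),
               class = "ihc_empty_input")
  expect_error(percent_agreement(c("0", NA), c("0", "1+")),
               class = "ihc_invalid_input")
})

test_that("the printed 73-of-108 match reports as 68% at integer rounding", {
  manual <- c(rep("2+", 73), rep("1+", 35))
  auto <- c(rep("2+", 73), rep("0", 35))
  a <- percent_agreement(manual, auto)
  expect_identical(a$n_match, 73L)
  expect_equal(a$percent_match, 100 * 73 / 108)
  expect_equal(floor(a$percent_match * 10 + 0.5) / 10, 67.6)  # one decimal
  expect_equal(floor(a$percent_match + 0.5), 68)              # integer
})

test_that("Cohen's kappa matches its defining formula", {
  # perfect agreement over two or more categories
  g <- rep(c("0", "2+"), 10)
  expect_equal(cohens_kappa(g, g), 1)

  # product-marginal independence gives kappa 0 by construction
  manual <- rep(c("0", "1+"), each = 8)
  auto <- rep(rep(c("0", "2+"), each = 4), 2)
  expect_lt(abs(cohens_kappa(manual, auto)), 1e-12)

  # random samples against the direct cross-table formula (and e1071)
  set.seed(12)
  for (k in 1:10) {
    m <- sample(c("0", "1+", "2+", "3+"), 200, replace = TRUE,
                prob = c(0.4, 0.3, 0.2, 0.1))
    a <- ifelse(runif(200) < 0.6, m,
                sample(c("0", "1+", "2+", "3+"), 200, replace = TRUE))
    expect_equal(cohens_kappa(m, a), kappa_oracle(m, a), tolerance = 1e-12)
    if (requireNamespace("e1071", quietly = TRUE)) {
      lv <- c("0", "1+", "2+", "3+")
      tab <- table(factor(m, lv), factor(a, lv))
      expect_equal(cohens_kappa(m, a), e1071::classAgreement(tab)$kappa,
                   tolerance = 1e-9)
    }
  }

  # degenerate: both raters constant and identical
  expect_equal(cohens_kappa(rep("2+", 5), rep("2+", 5)), 1)
  k <- cohens_kappa(rep("2+", 5), c(rep("2+", 4), "1+"))
  expect_true(is.finite(k))  # mixed marginals stay defined
})

test_that("linear-weighted kappa penalizes near-misses less", {
  m <- c(rep("3+", 10), rep("0", 10))
  a <- c(rep("2+", 10), rep("0", 10))  # all errors one step
  expect_gt(cohens_kappa(m, a, weights = "linear"), cohens_kappa(m, a))
})

test_that("chi-square agrees with the direct formula and its symmetries", {
  # proportional rows: no association
  r <- chi_square_2x2(matrix(c(10, 10, 20, 20), 2, byrow = TRUE))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  # ER-status table from the reference cohort counts
  tab <- matrix(c(32, 4, 44, 28), 2, byrow = TRUE)
  r <- chi_square_2x2(tab)
  expect_equal(r$statistic, chisq_oracle(tab), tolerance = 1e-12)
  expect_equal(r$p_value, stats::pchisq(chisq_oracle(tab), 1,
                                        lower.tail = FALSE))
  ry <- chi_square_2x2(tab, yates = TRUE)
  expect_lt(ry$statistic, r$statistic)

  # invariance under row swap, column swap and transpose
  expect_equal(chi_square_2x2(tab[2:1, ])$statistic, r$statistic)
  expect_equal(chi_square_2x2(tab[, 2:1])$statistic, r$statistic)
  expect_equal(chi_square_2x2(t(tab))$statistic, r$statistic)

  # random tables against the oracle
  set.seed(13)
  for (k in 1:15) {
    tt <- matrix(sample(1:60, 4, replace = TRUE), 2)
    expect_equal(chi_square_2x2(tt)$statistic, chisq_oracle(tt),
                 tolerance = 1e-10)
  }
  expect_error(chi_square_2x2(matrix(c(0, 0, 5, 5), 2, byrow = TRUE)),
               class = "ihc_degenerate_table")
})

test_that("cohort summaries recompute from their own counts", {
  rec <- records_from_counts(hnis_reference_counts())
  s <- cohort_summary(rec, "subtype")
  expect_identical(s$n_positive, s$n_grade1 + s$n_grade2 + s$n_grade3)
  expect_equal(s$percent_positive, 100 * s$n_positive / s$n)
  overall <- s[s$stratum == "overall", ]
  expect_identical(overall$n, 108L)
  expect_identical(overall$n_positive, 76L)
  expect_equal(overall$percent_rounded, 70)

  er <- cohort_summary(rec, "er", digits = 1)
  expect_equal(er$percent_rounded[er$stratum == "negative"], 61.1)

  # empty stratum flags missing percentage
  rec2 <- rec; rec2$site <- "A"
  rec2$site[0] <- "B"
  empty <- cohort_summary(rec[rec$er == "nonexistent", , drop = FALSE])
  expect_identical(empty$n, 0L)
  expect_true(is.na(empty$percent_positive))

  expect_error(cohort_summary(rec, "no_such_field"),
               class = "ihc_config_error")
})

test_that("synthetic cohorts with equal graders give perfect concordance", {
  counts <- data.frame(subtype = rep("ER+PgR+HER2-", 3),
                       grade = c("0", "1+", "2+"), n = c(2L, 2L, 2L))
  coh <- generate_cohort(counts, seed = 3, size = c(32, 32), noise_sd = 0)
  a <- percent_agreement(coh$records$manual_grade, coh$records$manual_grade)
  expect_equal(a$percent_match, 100)
  expect_equal(cohens_kappa(coh$records$manual_grade,
                            coh$records$manual_grade), 1)
  # and the pipeline itself recovers every noise-free grade
  expect_identical(coh$records$auto_grade, coh$records$manual_grade)
})
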
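# Zone histogramming, dominance rule, weighted formula, area categories.

test_that("zone boundaries follow the printed closed ranges exactly", {
  # the eight boundary intensities, one pixel each
  dab <- matrix(c(60L, 61L, 120L, 121L, 170L, 171L, 230L, 231L), 2, 4)
  h <- zone_histogram(dab)
  expect_identical(h$n3, 1L)         # 60 closes zone 3+
  expect_identical(h$n2, 2L)         # 61 and 120
  expect_identical(h$n1, 2L)         # 121 and 170
  expect_identical(h$n0, 2L)         # 171 and 230
  expect_identical(h$n_excluded, 1L) # 231 starts the excluded range
  expect_identical(h$total, 8L)

  # the five-pixel example across the printed cut points
  h5 <- zone_histogram(matrix(c(60L, 61L, 170L, 230L, 231L), 1))
  expect_identical(unlist(h5[c("n3", "n2", "n1", "n0", "n_excluded")],
                          use.names = FALSE), rep(1L, 5))
})

test_that("zone counts equal an exhaustive per-pixel classification", {
  set.seed(5)
  for (k in 1:20) {
    d <- matrix(sample(0:255, sample(16:4096, 1), replace = TRUE))
    h <- zone_histogram(d)
    o <- zone_oracle(d)
    expect_identical(unlist(h[names(o)]), o)
    expect_identical(h$total, length(d))  # conservation
  }
  # uniform image concentrates in one zone
  h <- zone_histogram(uniform_dab(40L))
  expect_identical(h$n3, 100L)
  expect_identical(h$n2 + h$n1 + h$n0 + h$n_excluded, 0L)
})

test_that("dominance rule is strict at the 66% threshold", {
  expect_identical(dominance_grade(hist_from_counts(70, 10, 10, 10)), 3L)
  expect_identical(dominance_grade(hist_from_counts(66, 34, 0, 0)),
                   NA_integer_)  # 66% is not "more than 66%"
  expect_identical(dominance_grade(hist_from_counts(67, 33, 0, 0)), 3L)
  expect_identical(dominance_grade(hist_from_counts(0, 0, 0, 100)), 0L)
  # excluded pixels are not part of the denominator
  expect_identical(dominance_grade(hist_from_counts(67, 33, 0, 0,
                                                    n_excluded = 900)), 3L)
  expect_error(dominance_grade(hist_from_counts(0, 0, 0, 0, 10)),
               class = "ihc_no_scoreable_pixels")
})

test_that("weighted score is the zone-weighted mean over scoreable pixels", {
  expect_equal(weighted_score(hist_from_counts(0, 50, 0, 0)), 2)
  expect_equal(weighted_score(hist_from_counts(25, 25, 25, 25)), 1.5)
  set.seed(6)
  for (k in 1:20) {
    n <- sample(0:200, 5, replace = TRUE)
    if (sum(n[1:4]) == 0) n[1] <- 1
    h <- hist_from_counts(n[1], n[2], n[3], n[4], n[5])
    expect_equal(weighted_score(h),
                 (3 * n[1] + 2 * n[2] + n[3]) / sum(n[1:4]))
  }
  expect_error(weighted_score(hist_from_counts(0, 0, 0, 0, 5)),
               class = "ihc_no_scoreable_pixels")
})

test_that("grade assignment applies dominance first, then rounding", {
  g <- assign_grade(hist_from_counts(70, 10, 10, 10))
  expect_identical(g$grade, 3L)
  expect_true(g$dominance_applied)

  g <- assign_grade(hist_from_counts(25, 25, 25, 25))
  expect_identical(g$grade, 2L)  # 1.5 rounds half-up to 2+
  expect_false(g$dominance_applied)
  expect_equal(g$weighted_score, 1.5)

  g <- assign_grade(hist_from_counts(0, 10, 80, 10))
  expect_identical(g$grade, 1L)  # 80% dominance in zone 1+
  expect_true(g$dominance_applied)

  # dominance supremacy: a >66% zone decides regardless of the mean
  set.seed(7)
  for (k in 1:25) {
    zone <- sample(1:4, 1)
    n <- sample(0:30, 4, replace = TRUE)
    n[zone] <- ceiling(sum(n[-zone]) * 2.1) + 1  # > 66% share
    g <- assign_grade(hist_from_counts(n[1], n[2], n[3], n[4]))
    expect_identical(g$grade, c(3L, 2L, 1L, 0L)[zone])
    expect_true(g$dominance_applied)
  }
  expect_equal(sum(assign_grade(hist_from_counts(3, 4, 5, 6))$zone_fractions),
               1)
})

test_that("darkening a pixel never lowers the weighted score", {
  set.seed(8)
  n <- c(10, 20, 30, 40)
  base <- weighted_score(hist_from_counts(n[1], n[2], n[3], n[4]))
  for (from in 2:4) for (to in seq_len(from - 1)) {
    m <- n; m[from] <- m[from] - 1L; m[to] <- m[to] + 1L
    expect_gte(weighted_score(hist_from_counts(m[1], m[2], m[3], m[4])), base)
  }
})

test_that("stained-area categories follow the pathologist bins", {
  make_dab <- function(frac, n = 200L) {
    stained <- round(frac * n)
    matrix(c(rep(100L, stained), rep(200L, n - stained)), 1)
  }
  cases <- list(c(0.05, NA), c(0.15, NA), c(0.50, NA), c(0.85, NA))
  expected <- c("negative", "focal", "patchy", "diffused")
  for (i in seq_along(cases)) {
    r <- stained_area(make_dab(cases[[i]][1]))
    expect_identical(r$category, expected[i])
    expect_equal(r$stained_fraction, cases[[i]][1])
  }
  # bin edges: half-open with 0.70 cut for diffused
  expect_identical(stained_area(make_dab(0.10))$category, "focal")
  expect_identical(stained_area(make_dab(0.20))$category, "patchy")
  expect_identical(stained_area(make_dab(0.70))$category, "diffused")
  # uniform intensity-200 image: nothing at or below 170
  r <- stained_area(matrix(200L, 5, 5))
  expect_equal(r$stained_fraction, 0)
  expect_identical(r$category, "negative")
  # excluded pixels leave the denominator
  d <- matrix(c(rep(100L, 10), rep(240L, 90)), 1)
  expect_equal(stained_area(d)$stained_fraction, 1)
  expect_error(stained_area(matrix(240L, 2, 2)),
               class = "ihc_no_scoreable_pixels")
})

test_that("score_image composes the pipeline and is geometry-invariant", {
  expect_error(score_image(array(255L, c(8, 8, 3))),
               class = "ihc_no_scoreable_pixels")

  img <- render_ihc(grade_region_spec(2L), size = c(48, 48), noise_sd = 0,
                    seed = 3)
  s <- score_image(img$rgb)
  expect_identical(s$grade$grade, 2L)

  rot <- array(0L, dim = dim(img$rgb)[c(2, 1, 3)])
  for (ch in 1:3) rot[, , ch] <- t(img$rgb[, , ch])[, nrow(img$rgb):1]
  s2 <- score_image(rot)
  expect_identical(s2$grade$grade, s$grade$grade)
  expect_identical(unclass(s2$histogram), unclass(s$histogram))
  expect_equal(s2$area$stained_fraction, s$area$stained_fraction)

  # pixel shuffling
  set.seed(9)
  perm <- sample(48 * 48)
  shuf <- array(0L, dim(img$rgb))
  for (ch in 1:3) shuf[, , ch] <- matrix(img$rgb[, , ch][perm], 48)
  expect_identical(score_image(shuf)$grade$grade, s$grade$grade)
})

test_that("average grading pools weighted scores without dominance", {
  expect_identical(average_grade(c(2, 2))$grade, 2L)
  g <- average_grade(c(1.4, 1.8))
  expect_identical(g$grade, 2L)  # mean 1.6 rounds to 2+
  expect_equal(g$weighted_score, 1.6)
  expect_false(g$dominance_applied)
  expect_identical(average_grade(0)$grade, 0L)
  expect_error(average_grade(numeric()), class = "ihc_empty_input")
})
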
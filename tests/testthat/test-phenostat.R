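test_that("comparison-group selection maximizes the smaller strain group", {
  opts <- tibble::tibble(group_key = c("strip_a", "strip_b"),
                         n_N = c(20, 20), n_J = c(22, 13))
  expect_equal(select_comparison_group(opts)$group_key, "strip_a")

  one <- tibble::tibble(group_key = "only", n_N = 5, n_J = 9)
  expect_equal(select_comparison_group(one)$group_key, "only")

  # exhaustive-scan oracle on a small option set
  opts3 <- tibble::tibble(group_key = c("a", "b", "c"),
                          n_N = c(5, 7, 8), n_J = c(9, 7, 6))
  best <- select_comparison_group(opts3)
  scores <- pmin(opts3$n_N, opts3$n_J)
  expect_equal(best$group_key, opts3$group_key[which.max(scores)])
  expect_equal(best$group_key, "b")

  # ties: larger total first, then option order
  tie <- tibble::tibble(group_key = c("x", "y"), n_N = c(10, 10), n_J = c(10, 12))
  expect_equal(select_comparison_group(tie)$group_key, "y")
  tie2 <- tibble::tibble(group_key = c("x", "y"), n_N = c(10, 12), n_J = c(12, 10))
  expect_equal(select_comparison_group(tie2)$group_key, "x")

  expect_error(select_comparison_group(tibble::tibble(group_key = character(),
                                                      n_N = numeric(),
                                                      n_J = numeric())),
               "no comparison groups")
})

test_that("time courses collapse to per-animal means", {
  expect_equal(collapse_timecourse(list(c(2, 4, 6))), 4)
  expect_equal(collapse_timecourse(list(rep(3.7, 8))), 3.7)
  set.seed(5)
  series <- replicate(20, stats::rnorm(10), simplify = FALSE)
  expect_equal(collapse_timecourse(series),
               vapply(series, mean, numeric(1)), tolerance = 1e-12)
  # missing points are skipped; empty animals dropped with a warning
  expect_equal(collapse_timecourse(list(c(1, NA, 3))), 2)
  expect_warning(res <- collapse_timecourse(list(c(1, 2), c(NA, NA))), "dropping")
  expect_equal(res, 1.5)
})

test_that("Mann-Whitney comparison matches its exact examples and symmetry", {
  # identical samples: no separation
  res <- compare_numeric(1:5 + 0.5, 1:5 + 0.5)
  expect_equal(res$p_value, 1)
  expect_equal(res$direction, "none")

  res <- compare_numeric(c(5, 6, 7, 8, 9), c(0, 1, 2, 3, 4))
  expect_equal(res$p_value, 2 / 252, tolerance = 1e-12)
  expect_equal(res$direction, "N_gt_J")
  expect_equal(res$rank_biserial, 1)
  expect_true(res$exact)

  flipped <- compare_numeric(c(0, 1, 2, 3, 4), c(5, 6, 7, 8, 9))
  expect_equal(flipped$p_value, res$p_value, tolerance = 1e-12)
  expect_equal(flipped$direction, "J_gt_N")
  expect_equal(flipped$rank_biserial, -1)

  # exact path agrees with full enumeration across random untied inputs
  set.seed(31)
  for (i in 1:25) {
    n1 <- sample(2:6, 1)
    n2 <- sample(2:6, 1)
    x <- sample(seq(0, 100, by = 0.5), n1)
    y <- sample(setdiff(seq(0.25, 100, by = 0.5), x), n2)
    expect_equal(compare_numeric(x, y)$p_value, mw_enum_p(x, y),
                 tolerance = 1e-12)
  }

  # large/tied samples switch to the corrected normal approximation
  big <- compare_numeric(rnorm(30), rnorm(30))
  expect_false(big$exact)
  tied <- compare_numeric(c(1, 2, 2, 3), c(2, 3, 4, 4))
  expect_false(tied$exact)
  expect_true(tied$p_value >= 0 && tied$p_value <= 1)

  expect_error(compare_numeric(numeric(0), 1:3), "non-empty")
})

test_that("categorical comparison uses Fisher for 2x2 and chi-squared beyond", {
  res <- compare_categorical(rbind(B6N = c(10, 0), B6J = c(0, 10)))
  expect_equal(res$test, "fisher")
  expect_equal(res$p_value, 2 / choose(20, 10), tolerance = 1e-12)
  expect_equal(res$direction, "N_gt_J")

  eq <- compare_categorical(rbind(B6N = c(5, 5), B6J = c(5, 5)))
  expect_equal(eq$p_value, 1)
  expect_equal(eq$direction, "none")

  chi <- compare_categorical(rbind(B6N = c(3, 6, 9), B6J = c(3, 6, 9)))
  expect_equal(chi$test, "chi2")
  expect_equal(chi$p_value, 1)
  expect_equal(chi$direction, "unordered")

  # chi-squared agrees with the closed form on a 2x3 table
  tab <- rbind(B6N = c(16, 4, 10), B6J = c(6, 12, 12))
  exp_counts <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - exp_counts)^2 / exp_counts)
  expect_equal(compare_categorical(tab)$p_value,
               stats::pchisq(stat, df = 2, lower.tail = FALSE),
               tolerance = 1e-12)

  expect_error(compare_categorical(rbind(c(0, 0), c(0, 0))), "all-zero")
})

test_that("cell encoding maps p-values and directions to hue/shade", {
  cell <- function(p, dir = "N_gt_J") list(p_value = p, direction = dir)
  expect_equal(encode_cell(cell(0.2)), list(hue = "null", shade = 0L))
  expect_equal(encode_cell(cell(0.05)), list(hue = "null", shade = 0L))
  expect_equal(encode_cell(cell(0.04)), list(hue = "red", shade = 1L))
  expect_equal(encode_cell(cell(0.004)), list(hue = "red", shade = 2L))
  expect_equal(encode_cell(cell(0.004, "J_gt_N")), list(hue = "green", shade = 2L))
  expect_equal(encode_cell(cell(0.0005, "unordered")), list(hue = "blue", shade = 3L))

  # monotone: smaller p never gives a lighter shade
  set.seed(8)
  p <- sort(stats::runif(50))
  shades <- vapply(p, function(pp) encode_cell(cell(pp))$shade, integer(1))
  expect_true(all(diff(shades) <= 0))

  expect_error(encode_cell(cell(0.01), thresholds = c(0.01, 0.05)), "decreasing")
})
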
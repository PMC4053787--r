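test_that("heat maps assemble with absent combinations flagged", {
  cells <- tidyr::expand_grid(parameter = c("p1", "p2"),
                              center = paste0("c", 1:4),
                              sex = c("male", "female"))
  cells$hue <- "red"
  cells$shade <- 1L
  hm <- build_heatmap(cells)
  expect_equal(nrow(hm), 16)
  expect_false(any(hm$absent))

  # drop one center's female data: the cell comes back flagged absent
  hm2 <- build_heatmap(cells[!(cells$center == "c2" & cells$sex == "female"), ],
                       centers = paste0("c", 1:4))
  missing_cell <- hm2[hm2$center == "c2" & hm2$sex == "female", ]
  expect_true(all(missing_cell$absent))
  expect_true(all(missing_cell$hue == "null"))

  expect_error(build_heatmap(dplyr::bind_rows(cells, cells[1, ])), "duplicate")

  # TSV round trip preserves the map exactly
  path <- tempfile(fileext = ".tsv")
  write_heatmap_tsv(hm2, path)
  back <- read_heatmap_tsv(path)
  expect_equal(as.data.frame(back)[c("parameter", "center", "sex", "hue",
                                     "shade", "absent")],
               as.data.frame(hm2)[c("parameter", "center", "sex", "hue",
                                    "shade", "absent")])
})

test_that("parameters are assigned to the four concordance classes", {
  hues <- function(...) matrix(c(...), nrow = 1, byrow = TRUE)

  hm <- heatmap_from_hues(hues("red", "red", "red", "red"))
  expect_equal(classify_parameter(hm, "p1"), "concordant_3plus")

  hm <- heatmap_from_hues(hues("red", "red", "null", "null"))
  expect_equal(classify_parameter(hm, "p1"), "concordant_2")

  hm <- heatmap_from_hues(hues("red", "red", "green", "null"))
  expect_equal(classify_parameter(hm, "p1"), "contradictory")

  hm <- heatmap_from_hues(hues("null", "null", "null", "null"))
  expect_equal(classify_parameter(hm, "p1"), "no_difference")

  # contradictory outranks strong concordance
  hm <- heatmap_from_hues(hues("red", "red", "red", "green"))
  expect_equal(classify_parameter(hm, "p1"), "contradictory")

  # two matching centers with a third non-null (non-opposite) cell is not the
  # weak class: blue has no opposite and blocks "all others null"
  hm <- heatmap_from_hues(hues("red", "red", "blue", "null"))
  expect_equal(classify_parameter(hm, "p1"), "no_difference")

  # blue concords with blue only
  hm <- heatmap_from_hues(hues("blue", "blue", "blue", "null"))
  expect_equal(classify_parameter(hm, "p1"), "concordant_3plus")

  expect_error(classify_parameter(hm, "nope"), "unknown parameter")

  # classes partition every random map
  set.seed(12)
  for (i in 1:20) {
    hm <- random_heatmap(n_params = 6)
    cls <- vapply(paste0("p", 1:6), function(p) classify_parameter(hm, p),
                  character(1))
    expect_true(all(cls %in% c("concordant_3plus", "concordant_2",
                               "contradictory", "no_difference")))
  }
})

test_that("observed concordance rate counts parameters meeting the k rule", {
  rows <- rbind(
    matrix(rep(c("red", "red", "red", "null"), 3), nrow = 3, byrow = TRUE),
    matrix(rep(c("red", "green", "null", "null"), 7), nrow = 7, byrow = TRUE))
  hm <- heatmap_from_hues(rows)
  expect_equal(observed_concordance_rate(hm, k = 3), 0.3)
  expect_equal(observed_concordance_rate(hm, k = 1), 1.0)
  expect_equal(observed_concordance_rate(hm, k = 4), 0.0)
})

test_that("randomization null matches the exhaustive oracle on small maps", {
  # all cells one non-null hue: permutation-invariant, probability 1
  hm_all <- heatmap_from_hues(matrix("red", nrow = 2, ncol = 3))
  expect_equal(exhaustive_null(hm_all, k = 3), 1)
  rn <- randomize_null(hm_all, k = 3, n_reps = 50, seed = 1)
  expect_equal(rn$probability, 1)

  # all null: probability 0
  hm_null <- heatmap_from_hues(matrix("null", nrow = 2, ncol = 3))
  expect_equal(exhaustive_null(hm_null, k = 3), 0)
  expect_equal(randomize_null(hm_null, k = 3, n_reps = 50, seed = 1)$probability, 0)

  # {red x3, green x3} over 2 parameters x 3 centers: exact null 0.1
  hm_mix <- heatmap_from_hues(rbind(rep("red", 3), rep("green", 3)))
  expect_equal(exhaustive_null(hm_mix, k = 3), 0.1, tolerance = 1e-12)

  # reproducible under seed; parameter relabeling leaves the estimate unchanged
  a <- randomize_null(hm_mix, k = 3, n_reps = 500, seed = 9)
  b <- randomize_null(hm_mix, k = 3, n_reps = 500, seed = 9)
  expect_identical(a$probability, b$probability)
  relabeled <- hm_mix
  relabeled$parameter <- sub("p1", "zz", relabeled$parameter)
  attr(relabeled, "parameters") <- sub("p1", "zz", attr(relabeled, "parameters"))
  c_est <- randomize_null(relabeled, k = 3, n_reps = 500, seed = 9)
  expect_identical(c_est$probability, a$probability)

  # null probability is monotone non-increasing in k
  set.seed(4)
  hm <- heatmap_from_hues(matrix(sample(c("red", "green", "null"), 8, TRUE),
                                 nrow = 2))
  probs <- vapply(1:4, function(k) exhaustive_null(hm, k), numeric(1))
  expect_true(all(diff(probs) <= 1e-12))

  expect_error(randomize_null(hm_mix, k = 5, n_reps = 10), "fewer than k")
  expect_error(exhaustive_null(random_heatmap(n_params = 8), k = 3), "too large")
})

test_that("exhaustive null reduces to the per-parameter chance for P = 1", {
  hm <- heatmap_from_hues(matrix(c("red", "red", "red", "null"), nrow = 1))
  # 3 red among 4 cells, one sex: P(3 same hue among any 3 chosen cells) --
  # every assignment has exactly 3 red, so the criterion always holds
  expect_equal(exhaustive_null(hm, k = 3), 1)
  # 2 red, 2 null: can never reach 3 concordant
  hm2 <- heatmap_from_hues(matrix(c("red", "red", "null", "null"), nrow = 1))
  expect_equal(exhaustive_null(hm2, k = 3), 0)
})

test_that("concordance report contrasts observed and randomized class rates", {
  # strongly structured map: planted concordance must exceed its null
  planted <- rbind(
    matrix(rep(c("red", "red", "red", "red"), 4), nrow = 4, byrow = TRUE),
    matrix(rep(c("null", "null", "null", "null"), 4), nrow = 4, byrow = TRUE))
  hm <- heatmap_from_hues(planted)
  rep <- concordance_report(hm, k = 3, n_reps = 300, seed = 2)
  strong <- rep$rates[rep$rates$class == "concordant_3plus", ]
  expect_equal(strong$observed_rate, 0.5)
  expect_gt(strong$ratio, 1)
  expect_gt(strong$observed_rate, strong$null_rate + 3 * strong$mc_se)

  # report round-trips through JSON
  js <- jsonlite::toJSON(rep, auto_unbox = TRUE, digits = NA, force = TRUE)
  back <- jsonlite::fromJSON(js)
  expect_equal(back$rates$observed_rate, rep$rates$observed_rate)
  expect_equal(back$concordance$probability, rep$concordance$probability)
  expect_equal(back$classes$class, rep$classes$class)
})
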
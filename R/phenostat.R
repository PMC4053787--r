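# Per parameter/center/sex comparison of the two sub-strains.
#
# Numeric parameters are compared with the two-sided Mann-Whitney U test
# (exact enumeration when both groups are small and untied, normal
# approximation with tie and continuity correction otherwise); categorical
# parameters with Fisher's exact test (2 x 2) or Pearson's chi-squared
# (larger tables). Comparisons are always within a center, never pooled
# across centers. Each result is encoded as a heat-map cell color: red when
# B6N exceeds B6J, green for the opposite, blue for unordered categorical
# differences, with darker shades at stronger significance.

#' Select the comparison group among metadata-defined options
#'
#' When a parameter has several comparable measurement groups at a center
#' (split by a metadata difference), the group maximizing the smaller of the
#' two strain sample sizes is used; ties are broken by larger total size,
#' then by option order.
#'
#' @param options Tibble/data frame with columns `group_key`, `n_N`, `n_J`
#'   (one row per option).
#' @return The selected row.
#' @export
#' @examples
#' opts <- tibble::tibble(group_key = c("a", "b"),
#'                        n_N = c(20, 20), n_J = c(22, 13))
#' select_comparison_group(opts)$group_key
select_comparison_group <- function(options) {
  options <- as.data.frame(options)
  if (nrow(options) == 0) stop("no comparison groups available", call. = FALSE)
  min_n <- pmin(options$n_N, options$n_J)
  tot <- options$n_N + options$n_J
  best <- order(-min_n, -tot, seq_len(nrow(options)))[1]
  tibble::as_tibble(options[best, , drop = FALSE])
}

#' Collapse per-animal time courses to scalars
#'
#' Time-course measurements are averaged into a single mean per animal
#' (missing time points skipped). Animals with no non-missing time point are
#' dropped with a warning.
#'
#' @param series List of numeric vectors, one per animal.
#' @return Numeric vector of per-animal means.
#' @export
collapse_timecourse <- function(series) {
  means <- vapply(series, function(v) mean(v, na.rm = TRUE), numeric(1))
  if (anyNA(means) || any(is.nan(means))) {
    warning("dropping animal(s) with no non-missing time points", call. = FALSE)
    means <- means[is.finite(means)]
  }
  means
}

# "1.2,3.4,..." -> numeric vector
parse_series <- function(x) lapply(strsplit(x, ",", fixed = TRUE), as.numeric)

#' Mann-Whitney comparison of a numeric parameter
#'
#' Two-sided Mann-Whitney U test of B6N versus B6J values. The p-value comes
#' from exact enumeration when `min(n) <= 8` and the pooled sample has no
#' ties, otherwise from the normal approximation with tie correction and
#' continuity correction. Direction is the sign of `mean(N) - mean(J)`
#' (`none` when equal); the rank-biserial correlation `2U/(n_N n_J) - 1` is
#' reported alongside the mean difference.
#'
#' @param values_n,values_j Numeric vectors (each of length >= 1).
#' @param exact_max_n Largest `min(n)` for which the exact distribution is
#'   enumerated; default 8.
#' @return A list: `test = "mann_whitney"`, `p_value`, `direction`
#'   (`N_gt_J` / `J_gt_N` / `none`), `effect` (mean difference N - J),
#'   `rank_biserial`, `n_N`, `n_J`, `exact`.
#' @export
#' @examples
#' compare_numeric(c(5, 6, 7, 8, 9), c(0, 1, 2, 3, 4))$p_value  # 2/252
compare_numeric <- function(values_n, values_j, exact_max_n = 8L) {
  n_n <- length(values_n)
  n_j <- length(values_j)
  if (n_n == 0 || n_j == 0) stop("both groups must be non-empty", call. = FALSE)
  ties <- anyDuplicated(c(values_n, values_j)) > 0
  exact <- min(n_n, n_j) <= exact_max_n && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(values_n, values_j, alternative = "two.sided",
                       exact = exact, correct = TRUE)
  )
  u <- unname(wt$statistic)  # number of (N, J) pairs with N > J (+ half-ties)
  mean_diff <- mean(values_n) - mean(values_j)
  direction <- if (mean_diff > 0) "N_gt_J" else if (mean_diff < 0) "J_gt_N" else "none"
  list(test = "mann_whitney", p_value = unname(wt$p.value),
       direction = direction, effect = mean_diff,
       rank_biserial = 2 * u / (n_n * n_j) - 1,
       n_N = n_n, n_J = n_j, exact = exact)
}

#' Categorical comparison of strain-level counts
#'
#' A 2 x 2 table is tested with Fisher's exact test (two-sided: the sum of
#' hypergeometric probabilities of tables no more probable than the observed
#' one); larger tables with Pearson's chi-squared on (r-1)(c-1) degrees of
#' freedom. For binary outcomes the direction compares the per-strain
#' proportion of the designated affected level; with more than two levels the
#' difference is unordered.
#'
#' @param tab Count matrix with rows B6N then B6J and one column per level.
#' @param affected Column name or index of the "affected" level for binary
#'   outcomes; default the first column.
#' @return A list like [compare_numeric()]'s, with `test` one of `"fisher"`,
#'   `"chi2"`, `effect` the proportion difference (N - J) or `NA`, and
#'   `direction` possibly `"unordered"`.
#' @export
compare_categorical <- function(tab, affected = 1L) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) stop("counts must be non-negative", call. = FALSE)
  if (ncol(tab) < 2 || nrow(tab) != 2) {
    stop("need a 2 x k table with k >= 2", call. = FALSE)
  }
  if (sum(tab) == 0) stop("all-zero contingency table", call. = FALSE)
  n_n <- sum(tab[1, ])
  n_j <- sum(tab[2, ])
  if (ncol(tab) == 2) {
    p <- stats::fisher.test(tab)$p.value
    test <- "fisher"
    prop_n <- tab[1, affected] / n_n
    prop_j <- tab[2, affected] / n_j
    effect <- prop_n - prop_j
    direction <- if (isTRUE(effect > 0)) "N_gt_J"
      else if (isTRUE(effect < 0)) "J_gt_N" else "none"
  } else {
    p <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
    if (is.nan(p)) p <- 1  # degenerate table with no variation
    test <- "chi2"
    effect <- NA_real_
    direction <- "unordered"
  }
  list(test = test, p_value = unname(p), direction = direction, effect = effect,
       rank_biserial = NA_real_, n_N = n_n, n_J = n_j)
}

#' Encode a test result as a heat-map cell color
#'
#' Cells at `p >= thresholds[1]` are blank (`null` hue, shade 0). Otherwise
#' the shade counts how many thresholds the p-value passes (1..3 for the
#' defaults 0.05/0.01/0.001 — darker means more significant), and the hue is
#' red when B6N exceeds B6J, green for the opposite, and blue for differences
#' with no order (categorical, or tied means).
#'
#' @param cell Result list from [compare_numeric()] / [compare_categorical()].
#' @param thresholds Strictly decreasing significance thresholds; default
#'   `c(0.05, 0.01, 0.001)`.
#' @return A list with `hue` (`"red"`, `"green"`, `"blue"`, `"null"`) and
#'   integer `shade` (0-3).
#' @export
encode_cell <- function(cell, thresholds = c(0.05, 0.01, 0.001)) {
  if (is.unsorted(rev(thresholds), strictly = TRUE)) {
    stop("thresholds must be strictly decreasing", call. = FALSE)
  }
  p <- cell$p_value
  if (p >= thresholds[1]) return(list(hue = "null", shade = 0L))
  shade <- sum(p < thresholds)
  hue <- switch(cell$direction,
                N_gt_J = "red",
                J_gt_N = "green",
                "blue")
  list(hue = hue, shade = as.integer(shade))
}
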
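# Multi-center heat map, concordance classes, and the randomization null.
#
# Each parameter x center x sex comparison is one colored cell. A parameter's
# evidence is judged across centers, within each sex: replication of the same
# hue in >= 3 centers is the strong concordance class; the same hue in exactly
# 2 centers with all others blank is the weak class; the same hue in >= 2
# centers with the opposite hue elsewhere is contradictory. The chance rate of
# multi-center concordance is estimated by randomizing all heat-map squares
# (permuting the observed color multiset) and recording how often parameters
# still meet the >= k same-hue criterion; an exhaustive enumeration of the
# same expectation is available for small maps as an oracle.

hue_levels <- c("null", "red", "green", "blue")

#' Assemble a multi-center heat map from encoded cells
#'
#' @param cells Tibble with columns `parameter`, `center`, `sex`, `hue`,
#'   `shade` (extra columns are kept). Every combination must appear at most
#'   once; combinations missing from the rectangular design are filled in
#'   with `hue = "null"`, `shade = 0` and flagged `absent`.
#' @param centers,parameters,sexes Optional explicit orderings; defaults are
#'   taken from the data.
#' @return A `substrain_heatmap`: the completed cell tibble with an `absent`
#'   column and `parameters`/`centers`/`sexes` attributes.
#' @export
build_heatmap <- function(cells, centers = NULL, parameters = NULL, sexes = NULL) {
  stopifnot(all(c("parameter", "center", "sex", "hue", "shade") %in% names(cells)))
  if (!all(cells$hue %in% hue_levels)) stop("unknown hue value", call. = FALSE)
  key <- paste(cells$parameter, cells$center, cells$sex, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (parameter, center, sex) cell(s): ",
         key[duplicated(key)][1], call. = FALSE)
  }
  parameters <- parameters %||% unique(cells$parameter)
  centers <- centers %||% unique(cells$center)
  sexes <- sexes %||% unique(cells$sex)
  grid <- tidyr::expand_grid(parameter = parameters, center = centers, sex = sexes)
  cells$absent <- FALSE
  full <- dplyr::left_join(grid, cells, by = c("parameter", "center", "sex"))
  full$absent[is.na(full$absent)] <- TRUE
  full$hue[full$absent] <- "null"
  full$shade[full$absent] <- 0L
  structure(full, class = c("substrain_heatmap", class(full)),
            parameters = parameters, centers = centers, sexes = sexes)
}

# hues as integer codes (null = 0) for fast permutation work
hue_codes <- function(hm) match(hm$hue, hue_levels) - 1L

# per-parameter list of per-sex cell-index vectors (non-absent cells only)
heatmap_groups <- function(hm) {
  live <- !hm$absent
  out <- lapply(attr(hm, "parameters"), function(p) {
    lapply(attr(hm, "sexes"), function(s) {
      which(live & hm$parameter == p & hm$sex == s)
    })
  })
  stats::setNames(out, attr(hm, "parameters"))
}

# classification of one parameter from its per-sex hue-code vectors
classify_codes <- function(sex_hues, k_strong = 3L) {
  contradictory <- FALSE
  strong <- FALSE
  weak <- FALSE
  for (h in sex_hues) {
    h <- h[h > 0L]
    if (!length(h)) next
    cnt <- tabulate(h, nbins = 3L)  # red, green, blue
    if ((cnt[1] >= 2 && cnt[2] >= 1) || (cnt[2] >= 2 && cnt[1] >= 1)) {
      contradictory <- TRUE
    }
    if (any(cnt >= k_strong)) strong <- TRUE
    if (any(cnt == 2L) && length(h) == 2L) weak <- TRUE
  }
  if (contradictory) return("contradictory")
  if (strong) return("concordant_3plus")
  if (weak) return("concordant_2")
  "no_difference"
}

# does any sex show >= k cells of one non-null hue?
meets_k_codes <- function(sex_hues, k) {
  for (h in sex_hues) {
    h <- h[h > 0L]
    if (length(h) && any(tabulate(h, nbins = 3L) >= k)) return(TRUE)
  }
  FALSE
}

#' Assign a parameter to a cross-center concordance class
#'
#' Evaluated per sex over the non-blank hues, then aggregated over sexes with
#' precedence contradictory > concordant_3plus > concordant_2 >
#' no_difference: a sex with >= 2 centers sharing an ordered hue while >= 1
#' center shows the opposite ordered hue makes the parameter `contradictory`;
#' else >= 3 centers sharing a hue in some sex gives `concordant_3plus`; else
#' exactly 2 centers sharing a hue with every other center blank in that sex
#' gives `concordant_2`; otherwise `no_difference`. Blue (unordered) cells
#' concord only with blue and have no opposite.
#'
#' @param hm A [build_heatmap()] object.
#' @param parameter Parameter name.
#' @return One of `"contradictory"`, `"concordant_3plus"`, `"concordant_2"`,
#'   `"no_difference"`.
#' @export
classify_parameter <- function(hm, parameter) {
  stopifnot(inherits(hm, "substrain_heatmap"))
  if (!parameter %in% attr(hm, "parameters")) {
    stop("unknown parameter: ", parameter, call. = FALSE)
  }
  codes <- hue_codes(hm)
  groups <- heatmap_groups(hm)[[parameter]]
  classify_codes(lapply(groups, function(i) codes[i]))
}

#' Observed rate of >= k-center concordance
#'
#' Fraction of parameters for which some sex shows the same non-blank hue in
#' at least `k` centers. This is the same counting rule the randomization
#' null uses, so observed and null rates are directly comparable.
#'
#' @param hm A heat map.
#' @param k Minimum number of concordant centers; default 3.
#' @return Fraction in \[0, 1\].
#' @export
observed_concordance_rate <- function(hm, k = 3L) {
  stopifnot(inherits(hm, "substrain_heatmap"))
  codes <- hue_codes(hm)
  groups <- heatmap_groups(hm)
  mean(vapply(groups, function(g)
    meets_k_codes(lapply(g, function(i) codes[i]), k), logical(1)))
}

#' Randomization null for multi-center concordance
#'
#' Estimates how often >= k centers would share a cell color by chance: every
#' repeat shuffles all heat-map squares (a permutation of the observed hue
#' multiset, blanks included, across all non-absent cells; shades are not
#' part of the matching rule) and counts the parameters for which some sex
#' still shows >= k cells of one non-blank hue. The estimate is the total
#' count divided by (number of parameters x repeats).
#'
#' @param hm A heat map with at least `k` centers.
#' @param k Minimum concordant centers; default 3.
#' @param n_reps Number of randomization repeats.
#' @param seed Integer seed; estimates are reproducible under a fixed seed.
#' @param replace Sample hues with replacement instead of permuting; default
#'   `FALSE` (permutation preserves the observed color composition).
#' @return A `substrain_null_estimate` list: `k`, `n_reps`, `probability`
#'   (the null estimate), `observed`, `se` (Monte-Carlo standard error),
#'   `seed`, `replace`.
#' @export
randomize_null <- function(hm, k = 3L, n_reps = 10000L, seed = 1L,
                           replace = FALSE) {
  stopifnot(inherits(hm, "substrain_heatmap"))
  if (n_reps < 1) stop("n_reps must be >= 1", call. = FALSE)
  if (length(attr(hm, "centers")) < k) {
    stop("map has fewer than k centers", call. = FALSE)
  }
  codes <- hue_codes(hm)
  live <- which(!hm$absent)
  pool <- codes[live]
  n <- length(pool)
  # positions of each live cell within the pool, grouped parameter -> sex
  groups <- lapply(heatmap_groups(hm), function(g)
    lapply(g, function(i) match(i, live)))
  p_total <- length(groups)
  with_seed(seed, {
    counts <- integer(n_reps)
    for (r in seq_len(n_reps)) {
      perm <- if (replace) pool[sample.int(n, n, replace = TRUE)]
              else pool[sample.int(n)]
      counts[r] <- sum(vapply(groups, function(g)
        meets_k_codes(lapply(g, function(i) perm[i]), k), logical(1)))
    }
    frac <- counts / p_total
    structure(list(k = as.integer(k), n_reps = as.integer(n_reps),
                   probability = mean(frac),
                   observed = observed_concordance_rate(hm, k),
                   se = stats::sd(frac) / sqrt(n_reps),
                   seed = as.integer(seed), replace = replace),
              class = "substrain_null_estimate")
  })
}

# all ways to deal `m` cells out of `pool` (named color counts), with the
# multivariate hypergeometric probability of each split
hyper_splits <- function(pool, m) {
  cols <- names(pool)
  grids <- lapply(pool, function(n) 0:min(n, m))
  combos <- expand.grid(grids)
  combos <- combos[rowSums(combos) == m, , drop = FALSE]
  total <- choose(sum(pool), m)
  probs <- apply(combos, 1, function(a) prod(choose(pool, a)) / total)
  list(counts = as.matrix(combos), probs = probs, cols = cols)
}

# exact P(some sex group gets >= k of one non-null color), by recursive
# enumeration of the joint multivariate hypergeometric allocation
param_meets_prob <- function(pool, group_sizes, k) {
  nonnull <- setdiff(names(pool), "0")
  recurse <- function(pool, gi, hit) {
    if (hit) return(1)  # remaining groups cannot undo a hit
    if (gi > length(group_sizes)) return(0)
    sp <- hyper_splits(pool, group_sizes[gi])
    total <- 0
    for (r in seq_along(sp$probs)) {
      a <- sp$counts[r, ]
      hit_here <- any(a[sp$cols %in% nonnull] >= k)
      total <- total + sp$probs[r] *
        recurse(pool - a, gi + 1L, hit_here)
    }
    total
  }
  recurse(pool, 1L, FALSE)
}

#' Exact expectation of the concordant fraction under randomization
#'
#' Exhaustive counterpart of [randomize_null()] for small maps: the exact
#' expected fraction of parameters meeting the >= k same-hue criterion over
#' all equally likely assignments of the observed color multiset to the
#' cells. Intended as an oracle; maps with more than 16 cells are refused.
#'
#' @inheritParams randomize_null
#' @return Exact probability.
#' @export
exhaustive_null <- function(hm, k = 3L) {
  stopifnot(inherits(hm, "substrain_heatmap"))
  codes <- hue_codes(hm)
  live <- which(!hm$absent)
  if (length(live) > 16) {
    stop("map too large for exhaustive enumeration; use randomize_null()",
         call. = FALSE)
  }
  pool <- table(codes[live])
  pool <- stats::setNames(as.integer(pool), names(pool))
  groups <- heatmap_groups(hm)
  probs <- vapply(groups, function(g) {
    sizes <- lengths(g)
    sizes <- sizes[sizes > 0]
    if (!length(sizes)) return(0)
    param_meets_prob(pool, unname(sizes), k)
  }, numeric(1))
  mean(probs)
}

#' Concordance report: class roster and observed vs randomized class rates
#'
#' Classifies every parameter, then compares the observed class composition
#' with its randomization distribution: each repeat permutes all cell hues
#' and re-classifies every parameter. Reported per class: observed count and
#' rate, mean randomized rate, their ratio, and the Monte-Carlo standard
#' error of the randomized rate.
#'
#' @param hm A heat map.
#' @param k Concordance threshold passed through to the >= k null; default 3.
#' @param n_reps Randomization repeats; default 1000.
#' @param seed Integer seed.
#' @return A list: `k`, `seed`, `n_reps`, `classes` (roster tibble:
#'   `parameter`, `class`), `rates` (per-class tibble: `class`, `observed_n`,
#'   `observed_rate`, `null_rate`, `ratio`, `mc_se`), `concordance`
#'   (the [randomize_null()] estimate as a plain list).
#' @export
concordance_report <- function(hm, k = 3L, n_reps = 1000L, seed = 1L) {
  stopifnot(inherits(hm, "substrain_heatmap"))
  params <- attr(hm, "parameters")
  classes <- vapply(params, function(p) classify_parameter(hm, p), character(1))
  class_levels <- c("concordant_3plus", "concordant_2", "contradictory",
                    "no_difference")
  obs <- table(factor(classes, levels = class_levels))

  codes <- hue_codes(hm)
  live <- which(!hm$absent)
  pool <- codes[live]
  groups <- lapply(heatmap_groups(hm), function(g)
    lapply(g, function(i) match(i, live)))
  null_frac <- matrix(0, nrow = n_reps, ncol = length(class_levels),
                      dimnames = list(NULL, class_levels))
  with_seed(seed + 1L, {
    for (r in seq_len(n_reps)) {
      perm <- pool[sample.int(length(pool))]
      cl <- vapply(groups, function(g)
        classify_codes(lapply(g, function(i) perm[i])), character(1))
      null_frac[r, ] <- table(factor(cl, levels = class_levels)) / length(groups)
    }
  })
  null_rate <- colMeans(null_frac)
  rates <- tibble(
    class = class_levels,
    observed_n = as.integer(obs),
    observed_rate = as.numeric(obs) / length(params),
    null_rate = as.numeric(null_rate),
    ratio = ifelse(null_rate > 0, as.numeric(obs) / length(params) / null_rate, NA),
    mc_se = apply(null_frac, 2, stats::sd) / sqrt(n_reps)
  )
  est <- randomize_null(hm, k = k, n_reps = n_reps, seed = seed)
  list(k = as.integer(k), seed = as.integer(seed), n_reps = as.integer(n_reps),
       classes = tibble(parameter = params, class = unname(classes)),
       rates = rates,
       concordance = unclass(est))
}

#' Write / read a heat map as TSV
#'
#' @param hm A heat map (for writing).
#' @param path File path.
#' @return `read_heatmap_tsv()` rebuilds the `substrain_heatmap`.
#' @export
write_heatmap_tsv <- function(hm, path) {
  utils::write.table(as.data.frame(hm)[c("parameter", "center", "sex", "hue",
                                         "shade", "absent")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_heatmap_tsv
#' @export
read_heatmap_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$shade <- as.integer(df$shade)
  build_heatmap(as_tibble(df[!df$absent, setdiff(names(df), "absent")]),
                parameters = unique(df$parameter),
                centers = unique(df$center),
                sexes = unique(df$sex))
}
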
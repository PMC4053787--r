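# Independent oracles used across the suite. Each recomputes the target
# quantity by brute force (enumeration or whole-molecule translation), never
# through the code path it checks.

# Exact two-sided Mann-Whitney p by full enumeration of all C(n1+n2, n1)
# group assignments of the pooled (untied) values.
mw_enum_dist <- function(n1, n2) {
  n <- n1 + n2
  sets <- utils::combn(n, n1)
  # U = number of (group1, group2) pairs with group1 > group2, computed from ranks
  apply(sets, 2, function(s) sum(s) - n1 * (n1 + 1) / 2)
}

mw_enum_p <- function(x, y) {
  stopifnot(!anyDuplicated(c(x, y)))
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  dist <- mw_enum_dist(length(x), length(y))
  p <- 2 * min(mean(dist <= u_obs), mean(dist >= u_obs))
  min(p, 1)
}

# Two-sided Fisher exact p for a 2x2 table by direct hypergeometric
# enumeration over the support, summing probabilities no larger than the
# observed one (with the conventional relative tolerance for float ties).
fisher_enum_p <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ])
  c1 <- sum(tab[, 1])
  n <- sum(tab)
  k <- max(0, c1 - (n - r1)):min(r1, c1)
  lp <- lchoose(r1, k) + lchoose(n - r1, c1 - k) - lchoose(n, c1)
  p_obs <- exp(lp[k == a])
  min(sum(exp(lp)[exp(lp) <= p_obs * (1 + 1e-7)]), 1)
}

revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
}

# Random coding transcript embedded in a random genome string. Exons are
# chosen so the spliced CDS length is divisible by 3.
random_transcript <- function(chrom = "1", n_exons = sample(1:3, 1),
                              strand = sample(c("+", "-"), 1)) {
  repeat {
    starts <- integer(0)
    ends <- integer(0)
    pos <- sample(5:20, 1)
    for (i in seq_len(n_exons)) {
      w <- sample(6:30, 1)
      starts <- c(starts, pos)
      ends <- c(ends, pos + w - 1L)
      pos <- pos + w + sample(10:40, 1)  # intron gap
    }
    if (sum(ends - starts + 1L) %% 3L == 0L) break
  }
  glen <- max(ends) + 20L
  genome <- paste(sample(c("A", "C", "G", "T"), glen, replace = TRUE),
                  collapse = "")
  spliced <- paste(vapply(seq_along(starts), function(i)
    substr(genome, starts[i], ends[i]), character(1)), collapse = "")
  cds <- if (strand == "+") spliced else revcomp(spliced)
  list(tm = transcript_model("g", chrom, strand,
                             data.frame(start = starts, end = ends), cds),
       genome = genome)
}

# Brute-force consequence oracle: apply the SNP to the genome, re-splice both
# haplotypes, translate whole proteins with Biostrings, and compare.
oracle_consequence <- function(pos, alt, tr) {
  tm <- tr$tm
  ex <- tm$exons
  in_exon <- any(pos >= ex$start & pos <= ex$end)
  if (in_exon) {
    g2 <- tr$genome
    substr(g2, pos, pos) <- alt
    splice <- function(g) paste(vapply(seq_len(nrow(ex)), function(i)
      substr(g, ex$start[i], ex$end[i]), character(1)), collapse = "")
    cds_ref <- if (tm$strand == "+") splice(tr$genome) else revcomp(splice(tr$genome))
    cds_alt <- if (tm$strand == "+") splice(g2) else revcomp(splice(g2))
    tr_aa <- function(s) as.character(Biostrings::translate(
      Biostrings::DNAString(s), if.fuzzy.codon = "X"))
    p_ref <- tr_aa(cds_ref)
    p_alt <- tr_aa(cds_alt)
    if (identical(p_ref, p_alt)) return("synonymous")
    ref_stars <- gregexpr("*", p_ref, fixed = TRUE)[[1]]
    alt_stars <- gregexpr("*", p_alt, fixed = TRUE)[[1]]
    if (length(setdiff(alt_stars[alt_stars > 0], ref_stars[ref_stars > 0])) > 0) {
      return("nonsense")
    }
    return("missense")
  }
  if (nrow(ex) > 1) {
    win <- c(outer(ex$end[-nrow(ex)], 1:2, `+`), outer(ex$start[-1], 1:2, `-`))
    if (pos %in% win) return("splice")
  }
  "noncoding"
}

# Random heat-map with iid cell hues; hue_probs ordered (null, red, green, blue).
random_heatmap <- function(n_params = 8, centers = c("c1", "c2", "c3", "c4"),
                           sexes = c("male", "female"),
                           hue_probs = c(0.6, 0.15, 0.15, 0.1)) {
  grid <- expand.grid(parameter = paste0("p", seq_len(n_params)),
                      center = centers, sex = sexes,
                      stringsAsFactors = FALSE)
  grid$hue <- sample(c("null", "red", "green", "blue"), nrow(grid),
                     replace = TRUE, prob = hue_probs)
  grid$shade <- ifelse(grid$hue == "null", 0L, sample(1:3, nrow(grid), TRUE))
  build_heatmap(tibble::as_tibble(grid),
                parameters = paste0("p", seq_len(n_params)),
                centers = centers, sexes = sexes)
}

# tiny heat map from a hue matrix (parameters x centers), one sex
heatmap_from_hues <- function(hues, sexes = "male") {
  df <- expand.grid(center = paste0("c", seq_len(ncol(hues))),
                    parameter = paste0("p", seq_len(nrow(hues))),
                    sex = sexes, stringsAsFactors = FALSE)
  df$hue <- as.vector(t(hues))[rep(seq_len(length(hues)), length(sexes))]
  df$shade <- ifelse(df$hue == "null", 0L, 1L)
  build_heatmap(tibble::as_tibble(df),
                parameters = paste0("p", seq_len(nrow(hues))),
                centers = paste0("c", seq_len(ncol(hues))), sexes = sexes)
}
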
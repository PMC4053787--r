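# The SNP / small-indel hard-filter cascade.
#
# An inbred genome should be homozygous everywhere, so a call with a depressed
# alternate-allele read fraction is an artifact ("heterozygous"), and calls at
# extreme depths sit in collapsed repeats or dropout regions. The cascade is:
# (1) subtract calls shared with an independent short-read assembly of the
# reference strain (these flag reference-assembly errors, not sub-strain
# differences); (2) drop calls with allele ratio < 0.8 or depth outside
# [3, 150]. Boundary values pass: the published thresholds are worded as
# strict inequalities ("less than 0.8", "less than 3 or greater than 150").

#' Filter thresholds for the variant cascade
#'
#' @param min_allele_ratio Calls with allele ratio strictly below this are
#'   removed as heterozygous artifacts; default 0.8.
#' @param min_depth,max_depth Calls with depth strictly below `min_depth` or
#'   strictly above `max_depth` are removed; defaults 3 and 150.
#' @return A `substrain_filter_thresholds` list.
#' @export
filter_thresholds <- function(min_allele_ratio = 0.8, min_depth = 3L,
                              max_depth = 150L) {
  if (min_depth > max_depth) stop("min_depth must be <= max_depth", call. = FALSE)
  if (min_allele_ratio <= 0 || min_allele_ratio > 1) {
    stop("min_allele_ratio must lie in (0, 1]", call. = FALSE)
  }
  structure(list(min_allele_ratio = min_allele_ratio,
                 min_depth = as.integer(min_depth),
                 max_depth = as.integer(max_depth)),
            class = "substrain_filter_thresholds")
}

#' Left-normalize a variant to its minimal representation
#'
#' Call sets carry no genome context, so indels are reduced to a minimal
#' representation by trimming the common suffix and then the common prefix of
#' the allele pair (position advanced past trimmed prefix bases). Identity of
#' a call for keying is `(chrom, pos, ref, alt)` after this normalization;
#' per-sample depth and allele ratio are ignored.
#'
#' @param pos 1-based position.
#' @param ref,alt Allele strings.
#' @return A list with normalized `pos`, `ref`, `alt`.
#' @export
normalize_variant <- function(pos, ref, alt) {
  if (!nzchar(ref) && !nzchar(alt)) stop("empty alleles", call. = FALSE)
  r <- strsplit(ref, "")[[1]]
  a <- strsplit(alt, "")[[1]]
  # trim common suffix
  while (length(r) > 1 && length(a) > 1 && r[length(r)] == a[length(a)]) {
    r <- r[-length(r)]
    a <- a[-length(a)]
  }
  # trim common prefix
  while (length(r) > 1 && length(a) > 1 && r[1] == a[1]) {
    r <- r[-1]
    a <- a[-1]
    pos <- pos + 1L
  }
  list(pos = as.integer(pos), ref = paste(r, collapse = ""),
       alt = paste(a, collapse = ""))
}

# Normalized string key per call; vectorized over a call tibble.
variant_key <- function(calls) {
  if (nrow(calls) == 0) return(character())
  norm <- Map(normalize_variant, calls$pos, calls$ref, calls$alt)
  vapply(seq_len(nrow(calls)), function(i) {
    n <- norm[[i]]
    paste(calls$chrom[i], n$pos, n$ref, n$alt, sep = ":")
  }, character(1))
}

#' Subtract reference-set calls from a focal call set
#'
#' Removes focal calls whose normalized `(chrom, pos, ref, alt)` key also
#' occurs in the reference call set (shared calls flag reference-assembly
#' discrepancies rather than genuine sub-strain differences). Order of the
#' focal calls is preserved. Duplicate keys within the focal set trigger a
#' warning; the first occurrence is kept.
#'
#' @param focal,reference Call tibbles (`chrom`, `pos`, `ref`, `alt`, ...).
#' @return The focal tibble restricted to calls absent from the reference set.
#' @export
subtract_reference_calls <- function(focal, reference) {
  fk <- variant_key(focal)
  if (anyDuplicated(fk)) {
    warning("duplicate variant keys in focal call set; keeping first occurrence",
            call. = FALSE)
    focal <- focal[!duplicated(fk), ]
    fk <- fk[!duplicated(fk)]
  }
  rk <- variant_key(reference)
  focal[!fk %in% rk, ]
}

#' Apply the allele-ratio and depth hard filters
#'
#' A call is removed iff `allele_ratio < min_allele_ratio` OR
#' `depth < min_depth` OR `depth > max_depth` (strict inequalities; boundary
#' values pass). Each removed call is tagged with its first failing reason,
#' allele ratio being checked before depth.
#'
#' @param calls Call tibble.
#' @param thresholds A [filter_thresholds()].
#' @return A list with `retained` (call tibble) and `removed` (call tibble
#'   with a `reason` column: `heterozygous`, `low_depth` or `high_depth`).
#' @export
#' @examples
#' calls <- tibble::tibble(chrom = "1", pos = 1:3, ref = "A", alt = "G",
#'                         depth = c(40L, 2L, 200L),
#'                         allele_ratio = c(0.79, 0.95, 0.95))
#' apply_quality_filters(calls, filter_thresholds())$removed$reason
apply_quality_filters <- function(calls, thresholds = filter_thresholds()) {
  stopifnot(inherits(thresholds, "substrain_filter_thresholds"))
  reason <- rep(NA_character_, nrow(calls))
  reason[is.na(reason) & calls$allele_ratio < thresholds$min_allele_ratio] <- "heterozygous"
  reason[is.na(reason) & calls$depth < thresholds$min_depth] <- "low_depth"
  reason[is.na(reason) & calls$depth > thresholds$max_depth] <- "high_depth"
  removed <- calls[!is.na(reason), ]
  removed$reason <- reason[!is.na(reason)]
  list(retained = calls[is.na(reason), ], removed = removed)
}

#' Optional sequence-context curation rule
#'
#' Manual curation of coding candidates dismissed calls embedded in
#' homopolymer runs or GC-rich windows, where short-read errors concentrate.
#' This exposes that step as an automatic, reproducible rule: a call is
#' removed when the reference base at its position sits inside a homopolymer
#' run of at least `homopolymer_min` bases, or when the GC fraction of the
#' `window`-bp window centred on it exceeds `gc_max`. Off by default in the
#' pipeline; it requires reference sequence context.
#'
#' @param calls Call tibble.
#' @param genome Named character vector of chromosome sequences.
#' @param homopolymer_min Minimum run length to flag; default 8.
#' @param gc_max Maximum window GC fraction; default 0.8.
#' @param window Window size in bp; default 50.
#' @return A list with `retained` and `removed` (with a `reason` column:
#'   `homopolymer` or `gc_rich`).
#' @export
curate_context_artifacts <- function(calls, genome, homopolymer_min = 8L,
                                     gc_max = 0.8, window = 50L) {
  reason <- rep(NA_character_, nrow(calls))
  half <- window %/% 2L
  for (i in seq_len(nrow(calls))) {
    seq <- genome[[calls$chrom[i]]]
    if (is.null(seq)) next
    n <- nchar(seq)
    p <- calls$pos[i]
    if (p < 1 || p > n) next
    run <- 1L
    b <- substr(seq, p, p)
    q <- p - 1L
    while (q >= 1 && substr(seq, q, q) == b) { run <- run + 1L; q <- q - 1L }
    q <- p + 1L
    while (q <= n && substr(seq, q, q) == b) { run <- run + 1L; q <- q + 1L }
    if (run >= homopolymer_min) { reason[i] <- "homopolymer"; next }
    lo <- max(1L, p - half); hi <- min(n, p + half)
    win <- strsplit(substr(seq, lo, hi), "")[[1]]
    if (mean(win %in% c("G", "C")) > gc_max) reason[i] <- "gc_rich"
  }
  removed <- calls[!is.na(reason), ]
  removed$reason <- reason[!is.na(reason)]
  list(retained = calls[is.na(reason), ], removed = removed)
}

#' Assess strain privacy of a variant against a strain panel
#'
#' A variant is private when no other sequenced strain in the panel carries
#' the identical normalized call; otherwise it is shared with every panel
#' strain carrying it.
#'
#' @param v One-row call tibble (or list with `chrom`, `pos`, `ref`, `alt`).
#' @param panel Named list mapping strain name to that strain's call tibble.
#' @param carrier Sub-strain carrying the variant (`"B6J"` or `"B6N"`),
#'   returned when the panel lacks the call.
#' @return `carrier` when private, otherwise `"shared:<strains>"` listing the
#'   panel strains (comma-separated, panel order).
#' @export
assess_privacy <- function(v, panel, carrier) {
  key <- variant_key(tibble(chrom = as.character(v$chrom), pos = v$pos,
                            ref = v$ref, alt = v$alt))
  hits <- names(panel)[vapply(panel, function(calls) key %in% variant_key(calls),
                              logical(1))]
  if (length(hits) == 0) carrier
  else paste0("shared:", paste(hits, collapse = ","))
}
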
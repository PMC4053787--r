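# Synthetic variant call sets with planted filter artifacts.
#
# Emulates the inputs to the hard-filter cascade: a focal call set carrying
# true sub-strain differences plus planted artifact classes (sites shared with
# the independent reference-strain call set, heterozygous-looking calls with
# depressed allele ratio, and calls outside the acceptable depth window), with
# truth labels returned so recovery can be scored exactly.

#' Configure a synthetic variant call-set simulation
#'
#' Planted classes occupy disjoint genomic positions by construction, so every
#' call has exactly one truth label.
#'
#' @param n_true Clean variants that pass every filter.
#' @param n_reference_shared Sites planted in both the focal and the
#'   reference call set (removed by subtraction).
#' @param n_heterozygous Artifacts with allele ratio uniform in \[0.3, 0.8).
#' @param n_low_depth,n_high_depth Artifacts with depth below / above the
#'   acceptable window.
#' @param depth_range Inclusive depth window for clean calls; default `c(3, 150)`.
#' @param seed Integer seed; same seed, identical call sets.
#' @return A `substrain_variant_sim_config` list.
#' @export
variant_sim_config <- function(n_true = 50L, n_reference_shared = 0L,
                               n_heterozygous = 0L, n_low_depth = 0L,
                               n_high_depth = 0L, depth_range = c(3L, 150L),
                               seed = 1L) {
  counts <- c(n_true, n_reference_shared, n_heterozygous, n_low_depth, n_high_depth)
  if (any(counts < 0)) stop("planted class counts must be >= 0", call. = FALSE)
  if (length(depth_range) != 2 || depth_range[1] > depth_range[2] || depth_range[1] < 1) {
    stop("invalid depth_range", call. = FALSE)
  }
  structure(list(n_true = as.integer(n_true),
                 n_reference_shared = as.integer(n_reference_shared),
                 n_heterozygous = as.integer(n_heterozygous),
                 n_low_depth = as.integer(n_low_depth),
                 n_high_depth = as.integer(n_high_depth),
                 depth_range = as.integer(depth_range),
                 seed = as.integer(seed)),
            class = "substrain_variant_sim_config")
}

#' Simulate focal and reference variant call sets with truth labels
#'
#' @param config A [variant_sim_config()].
#' @return A list with tibbles `focal`, `reference` and `truth`. Call tibbles
#'   have columns `chrom`, `pos`, `ref`, `alt`, `depth`, `allele_ratio`;
#'   `truth` additionally has `class` (one of `true`, `reference_shared`,
#'   `heterozygous`, `low_depth`, `high_depth`) and logical `keep` (should the
#'   cascade retain the call).
#' @export
#' @examples
#' sim <- generate_variant_callsets(variant_sim_config(n_true = 10, seed = 3))
#' table(sim$truth$class)
generate_variant_callsets <- function(config) {
  stopifnot(inherits(config, "substrain_variant_sim_config"))
  bases <- c("A", "C", "G", "T")
  dr <- config$depth_range
  n_total <- with(config, n_true + n_reference_shared + n_heterozygous +
                    n_low_depth + n_high_depth)
  with_seed(config$seed, {
    # distinct positions keep the planted classes disjoint by construction
    pos <- sample.int(1e7L, n_total)
    chrom <- as.character(sample.int(19L, n_total, replace = TRUE))
    ref <- sample(bases, n_total, replace = TRUE)
    alt <- unname(vapply(ref, function(b) sample(setdiff(bases, b), 1L),
                         character(1)))
    class <- rep(c("true", "reference_shared", "heterozygous", "low_depth",
                   "high_depth"),
                 times = with(config, c(n_true, n_reference_shared,
                                        n_heterozygous, n_low_depth, n_high_depth)))
    depth <- integer(n_total)
    ar <- numeric(n_total)
    ok <- class %in% c("true", "reference_shared")
    depth[ok] <- sample(seq(dr[1], dr[2]), sum(ok), replace = TRUE)
    ar[ok] <- stats::runif(sum(ok), 0.8, 1.0)
    het <- class == "heterozygous"
    depth[het] <- sample(seq(dr[1], dr[2]), sum(het), replace = TRUE)
    ar[het] <- stats::runif(sum(het), 0.3, 0.8 - 1e-9)
    lo <- class == "low_depth"
    depth[lo] <- sample(seq(0L, dr[1] - 1L), sum(lo), replace = TRUE)
    ar[lo] <- stats::runif(sum(lo), 0.8, 1.0)
    hi <- class == "high_depth"
    depth[hi] <- sample(seq(dr[2] + 1L, dr[2] * 2L), sum(hi), replace = TRUE)
    ar[hi] <- stats::runif(sum(hi), 0.8, 1.0)

    focal <- tibble(chrom = chrom, pos = pos, ref = ref, alt = alt,
                    depth = depth, allele_ratio = ar)
    shared <- class == "reference_shared"
    reference <- focal[shared, ]
    truth <- dplyr::mutate(focal, class = class, keep = class == "true")
    list(focal = focal, reference = reference, truth = truth)
  })
}

#' Write variant calls as a minimal VCF
#'
#' Emits VCF v4.2 with the two INFO keys the cascade consumes: `DP` (total
#' read depth) and `AR` (alternate-allele read fraction).
#'
#' @param calls Call tibble (`chrom`, `pos`, `ref`, `alt`, `depth`,
#'   `allele_ratio`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variant_vcf <- function(calls, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
    "##INFO=<ID=AR,Number=1,Type=Float,Description=\"Alternate allele read fraction\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t.\tDP=%d;AR=%.6f",
                  calls$chrom, calls$pos, calls$ref, calls$alt,
                  calls$depth, calls$allele_ratio)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read variant calls from VCF or the minimal TSV dialect
#'
#' VCF input (`.vcf`) is parsed with \pkg{vcfR}; depth and allele ratio are
#' taken from the `DP` and `AR` INFO keys. TSV input must carry the call
#' columns directly.
#'
#' @param path Input file (`.vcf` or `.tsv`).
#' @return A call tibble (`chrom`, `pos`, `ref`, `alt`, `depth`, `allele_ratio`).
#' @export
read_variant_calls <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
    if (nrow(fix) == 0) {
      return(tibble(chrom = character(), pos = integer(), ref = character(),
                    alt = character(), depth = integer(),
                    allele_ratio = numeric()))
    }
    tibble(
      chrom = fix$CHROM,
      pos = as.integer(fix$POS),
      ref = fix$REF,
      alt = fix$ALT,
      depth = as.integer(vcfR::extract.info(v, "DP")),
      allele_ratio = as.numeric(vcfR::extract.info(v, "AR"))
    )
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("chrom", "pos", "ref", "alt", "depth", "allele_ratio")
    if (!all(need %in% names(df))) {
      stop("TSV call set must have columns: ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    df$chrom <- as.character(df$chrom)
    as_tibble(df[need])
  }
}
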
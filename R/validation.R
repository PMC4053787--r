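# Validation-assay adjudication and ledger bookkeeping.
#
# Each candidate variant was genotyped on a fixed panel of four samples per
# sub-strain. A candidate is confirmed only when all four samples of each
# sub-strain agree (homozygous) within the sub-strain and the two sub-strains
# differ; anything else is eliminated (in order of precedence: PCR failure,
# heterozygous call, within-strain inconsistency) or declared not a variant.

#' Construct a validation assay
#'
#' @param variant_id Identifier of the assayed candidate.
#' @param genotypes Data frame with columns `strain` (`"B6J"` / `"B6N"`) and
#'   `genotype` (diploid call such as `"A/A"`, or `NA` for a failed call);
#'   exactly four rows per sub-strain.
#' @param platform Genotyping platform: `"sequenom"`, `"pyro"` or `"sanger"`.
#' @param category `"coding"` or `"noncoding"` (for the ledger breakdown).
#' @param type `"snp"` or `"indel"`.
#' @return A `substrain_assay` list with `status = NA` (assign via
#'   [adjudicate_assay()] only).
#' @export
validation_assay <- function(variant_id, genotypes,
                             platform = c("sequenom", "pyro", "sanger"),
                             category = c("coding", "noncoding"),
                             type = c("snp", "indel")) {
  platform <- match.arg(platform)
  category <- match.arg(category)
  type <- match.arg(type)
  genotypes <- as.data.frame(genotypes)
  if (!all(c("strain", "genotype") %in% names(genotypes))) {
    stop("genotypes needs 'strain' and 'genotype' columns", call. = FALSE)
  }
  tab <- table(genotypes$strain)
  if (!identical(sort(names(tab)), c("B6J", "B6N")) || !all(tab == 4L)) {
    stop("panel must contain exactly four B6J and four B6N samples", call. = FALSE)
  }
  structure(list(variant_id = variant_id, platform = platform,
                 category = category, type = type,
                 genotypes = genotypes, status = NA_character_),
            class = "substrain_assay")
}

# Alleles of a diploid call string "A/G" -> c("A", "G").
split_gt <- function(gt) strsplit(gt, "/", fixed = TRUE)[[1]]

#' Adjudicate a validation assay
#'
#' Applies the panel-consistency rules in fixed precedence: any missing call
#' is a PCR failure; any heterozygous call eliminates the assay; any
#' within-strain genotype disagreement eliminates it as inconsistent; if both
#' sub-strains are homozygous for the same allele the site is not a variant;
#' otherwise the variant is confirmed.
#'
#' @param a A [validation_assay()].
#' @return The assay with `status` set to one of `confirmed`, `not_variant`,
#'   `eliminated_heterozygous`, `eliminated_inconsistent`,
#'   `eliminated_pcr_failure`.
#' @export
#' @examples
#' gt <- data.frame(strain = rep(c("B6J", "B6N"), each = 4),
#'                  genotype = rep(c("A/A", "G/G"), each = 4))
#' adjudicate_assay(validation_assay("v1", gt))$status
adjudicate_assay <- function(a) {
  stopifnot(inherits(a, "substrain_assay"))
  gt <- a$genotypes$genotype
  status <- if (anyNA(gt)) {
    "eliminated_pcr_failure"
  } else if (any(vapply(gt, function(g) {
    al <- split_gt(g)
    length(unique(al)) > 1L
  }, logical(1)))) {
    "eliminated_heterozygous"
  } else {
    by_strain <- split(gt, a$genotypes$strain)
    if (any(vapply(by_strain, function(g) length(unique(g)) > 1L, logical(1)))) {
      "eliminated_inconsistent"
    } else if (identical(unique(by_strain$B6J), unique(by_strain$B6N))) {
      "not_variant"
    } else {
      "confirmed"
    }
  }
  a$status <- status
  a
}

#' Summarize an adjudicated assay set into the validation ledger
#'
#' @param assays List of adjudicated [validation_assay()] objects.
#' @return A list: `assayed`, `eliminated` (all `eliminated_*` statuses),
#'   `remaining` (= assayed - eliminated), `not_variant`, `confirmed`,
#'   `by_status` (named count vector) and `confirmed_by_category` (count
#'   matrix, coding/noncoding x snp/indel).
#' @export
summarize_validation <- function(assays) {
  statuses <- vapply(assays, function(a) {
    stopifnot(inherits(a, "substrain_assay"))
    if (is.na(a$status)) stop("unadjudicated assay: ", a$variant_id, call. = FALSE)
    a$status
  }, character(1))
  levels <- c("confirmed", "not_variant", "eliminated_heterozygous",
              "eliminated_inconsistent", "eliminated_pcr_failure")
  by_status <- table(factor(statuses, levels = levels))
  eliminated <- sum(by_status[startsWith(levels, "eliminated")])
  confirmed_idx <- statuses == "confirmed"
  cat_tab <- table(
    factor(vapply(assays[confirmed_idx], `[[`, character(1), "category"),
           levels = c("coding", "noncoding")),
    factor(vapply(assays[confirmed_idx], `[[`, character(1), "type"),
           levels = c("snp", "indel"))
  )
  list(assayed = length(assays),
       eliminated = as.integer(eliminated),
       remaining = length(assays) - as.integer(eliminated),
       not_variant = as.integer(by_status[["not_variant"]]),
       confirmed = as.integer(by_status[["confirmed"]]),
       by_status = stats::setNames(as.integer(by_status), levels),
       confirmed_by_category = unclass(cat_tab))
}
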
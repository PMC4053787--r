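#' Load the packaged coding-variant table
#'
#' Reads the packaged transcription of the published table of coding SNP and
#' small-indel differences between C57BL/6J and C57BL/6N (36 records: 32
#' missense, 1 nonsense, 1 splice-site, 2 frameshift 1 bp deletions). Each
#' record carries the 1-based NCBIM37 position, the two sub-strain alleles,
#' the carrier of the derived allele (`private_to`), the gene symbol, the
#' consequence class, and the amino-acid change where printed.
#'
#' One record (Zp2, chromosome 7) is the only non-private variant: its allele
#' is also carried by a wider inbred panel, recorded as
#' `private_to = "B6N_shared"` with the composite label kept verbatim in
#' `strain_label`. One printed row (Stxb4) repeats the gene symbol in the
#' amino-acid column; it is stored with `aa_j` missing and flagged
#' `as_printed_anomaly`.
#'
#' @return A tibble with one row per variant and columns `chrom`, `pos`,
#'   `base_j`, `base_n`, `strain_label`, `private_to`, `gene`, `consequence`,
#'   `aa_j`, `aa_n`, `as_printed_anomaly`.
#' @param path Fixture file path; defaults to the packaged table.
#' @export
#' @examples
#' cv <- load_coding_variant_table()
#' table(cv$consequence)
load_coding_variant_table <- function(path = fixture_path("coding_variants.tsv")) {
  file <- basename(path)
  df <- read_fixture_tsv(path)
  expected_cols <- c("chrom", "pos", "base_j", "base_n", "strain_label",
                     "private_to", "gene", "consequence", "aa_j", "aa_n",
                     "as_printed_anomaly")
  if (!identical(names(df), expected_cols)) {
    stop("corrupt fixture '", file, "': unexpected columns", call. = FALSE)
  }
  classes <- c("missense", "nonsense", "splice", "frameshift")
  for (i in seq_len(nrow(df))) {
    r <- df[i, ]
    if (is.na(r$pos) || r$pos < 1) fixture_row_error(file, i, "pos must be >= 1")
    if (!r$consequence %in% classes) {
      fixture_row_error(file, i, paste0("unknown consequence '", r$consequence, "'"))
    }
    if (!r$private_to %in% c("B6J", "B6N", "B6N_shared")) {
      fixture_row_error(file, i, paste0("unknown private_to '", r$private_to, "'"))
    }
    if (is.na(r$gene) || !nzchar(r$gene)) fixture_row_error(file, i, "missing gene")
  }
  if (nrow(df) != 36) {
    stop("corrupt fixture '", file, "': expected 36 records, got ", nrow(df),
         call. = FALSE)
  }
  if (sum(df$private_to == "B6N_shared") != 1) {
    stop("corrupt fixture '", file,
         "': exactly one record must be shared with the wider panel",
         call. = FALSE)
  }
  df$chrom <- as.character(df$chrom)
  df$pos <- as.integer(df$pos)
  as_tibble(df)
}

#' Load the packaged structural-variant table
#'
#' Reads the packaged transcription of the published table of 43 validated
#' structural variants (SVs) between C57BL/6N and C57BL/6J. Coordinates are
#' stored as 1-based inclusive NCBIM37 positions exactly as printed (rows
#' printed with `stop = start + 1` are kept as printed; no event length is
#' inferred). `ancestral_event` is the printed event label ("LINE Ins",
#' "Del", "VNTR", ...), `strain` the parsed primary carrier of the derived
#' allele, and `overlap` the printed gene-overlap class.
#'
#' @return A tibble with columns `chrom`, `start`, `stop`, `ancestral_event`,
#'   `strain_label`, `strain`, `gene`, `overlap`.
#' @param path Fixture file path; defaults to the packaged table.
#' @export
#' @examples
#' sv <- load_sv_table()
#' table(sv$overlap)
load_sv_table <- function(path = fixture_path("structural_variants.tsv")) {
  file <- basename(path)
  df <- read_fixture_tsv(path)
  expected_cols <- c("chrom", "start", "stop", "ancestral_event",
                     "strain_label", "strain", "gene", "overlap")
  if (!identical(names(df), expected_cols)) {
    stop("corrupt fixture '", file, "': unexpected columns", call. = FALSE)
  }
  for (i in seq_len(nrow(df))) {
    r <- df[i, ]
    if (is.na(r$start) || is.na(r$stop) || r$start > r$stop) {
      fixture_row_error(file, i, "start must be <= stop")
    }
    if (!r$overlap %in% c("intron", "exon", "entire", "none")) {
      fixture_row_error(file, i, paste0("unknown overlap '", r$overlap, "'"))
    }
    # overlap = none iff no gene recorded (the VNTR row has neither).
    if (is.na(r$gene) != (r$overlap == "none")) {
      fixture_row_error(file, i, "gene and overlap columns disagree")
    }
  }
  if (nrow(df) != 43) {
    stop("corrupt fixture '", file, "': expected 43 records, got ", nrow(df),
         call. = FALSE)
  }
  df$chrom <- as.character(df$chrom)
  df$start <- as.integer(df$start)
  df$stop <- as.integer(df$stop)
  as_tibble(df)
}

#' Load the validation-campaign bookkeeping counts
#'
#' The published validation campaign assayed 762 SNPs and 169 small indels on
#' a panel of four C57BL/6J and four C57BL/6N samples; 363 assays were
#' eliminated (heterozygous or inconsistent genotypes, PCR failures), and of
#' the 568 remaining, 236 were confirmed as genuine sub-strain differences
#' (34 coding SNPs, 2 coding indels, 146 non-coding SNPs, 54 non-coding
#' indels). This loader exposes those seed counts so the ledger arithmetic
#' can be replayed by [summarize_validation()]-style bookkeeping.
#'
#' @return A list with elements `assayed_snps`, `assayed_indels`,
#'   `eliminated`, `confirmed` (named vector: `coding_snps`, `coding_indels`,
#'   `noncoding_snps`, `noncoding_indels`), plus derived `assayed_total`,
#'   `remaining` and `confirmed_total`.
#' @param path Fixture file path; defaults to the packaged table.
#' @export
load_validation_summary <- function(path = fixture_path("validation_counts.tsv")) {
  file <- basename(path)
  df <- read_fixture_tsv(path)
  need <- c("assayed_snps", "assayed_indels", "eliminated",
            "confirmed_coding_snps", "confirmed_coding_indels",
            "confirmed_noncoding_snps", "confirmed_noncoding_indels")
  if (!all(need %in% df$key)) {
    stop("corrupt fixture '", file, "': missing keys", call. = FALSE)
  }
  cnt <- stats::setNames(as.integer(df$count), df$key)
  confirmed <- c(coding_snps = cnt[["confirmed_coding_snps"]],
                 coding_indels = cnt[["confirmed_coding_indels"]],
                 noncoding_snps = cnt[["confirmed_noncoding_snps"]],
                 noncoding_indels = cnt[["confirmed_noncoding_indels"]])
  assayed_total <- cnt[["assayed_snps"]] + cnt[["assayed_indels"]]
  list(
    assayed_snps = cnt[["assayed_snps"]],
    assayed_indels = cnt[["assayed_indels"]],
    assayed_total = assayed_total,
    eliminated = cnt[["eliminated"]],
    remaining = assayed_total - cnt[["eliminated"]],
    confirmed = confirmed,
    confirmed_total = sum(confirmed)
  )
}

#' Load the structural-variant triage counts
#'
#' Seed counts for replaying the published SV triage: 551 predicted sites,
#' 470 dismissed as paired-end mapping errors on visual inspection, and 38 of
#' the 81 retained sites removed as reference errors after PCR/Sanger, leaving
#' 43 validated SVs.
#'
#' @return A named list: `predicted`, `false_pe_error`, `reference_error`,
#'   and the derived `retained` and `validated`.
#' @export
load_sv_triage_counts <- function() {
  df <- read_fixture_tsv(fixture_path("sv_triage_counts.tsv"))
  cnt <- stats::setNames(as.integer(df$count), df$key)
  retained <- cnt[["predicted"]] - cnt[["false_pe_error"]]
  list(
    predicted = cnt[["predicted"]],
    false_pe_error = cnt[["false_pe_error"]],
    reference_error = cnt[["reference_error"]],
    retained = retained,
    validated = retained - cnt[["reference_error"]]
  )
}
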
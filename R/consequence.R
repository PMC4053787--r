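# Codon-level consequence classification of small variants against a
# transcript model.

comp_base <- function(x) chartr("ACGTacgt", "TGCAtgca", x)

#' Build a transcript model
#'
#' A minimal coding transcript: ordered, non-overlapping CDS exons on one
#' chromosome plus the spliced CDS sequence (sense strand, length divisible
#' by 3 and equal to the summed exon widths).
#'
#' @param gene Gene symbol.
#' @param chrom Chromosome label.
#' @param strand `"+"` or `"-"`.
#' @param exons Data frame with 1-based inclusive `start`, `end` columns,
#'   in ascending genomic order.
#' @param cds_seq Spliced CDS sequence (character, sense strand).
#' @return A `substrain_transcript` list.
#' @export
transcript_model <- function(gene, chrom, strand, exons, cds_seq) {
  stopifnot(strand %in% c("+", "-"))
  exons <- as.data.frame(exons)[c("start", "end")]
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  if (any(exons$start > exons$end)) stop("exon start > end", call. = FALSE)
  if (nrow(exons) > 1) {
    if (is.unsorted(exons$start, strictly = TRUE) ||
        any(exons$start[-1] <= exons$end[-nrow(exons)])) {
      stop("exons must be ordered and non-overlapping", call. = FALSE)
    }
  }
  cds_seq <- toupper(cds_seq)
  if (grepl("[^ACGT]", cds_seq)) stop("cds_seq must be ACGT only", call. = FALSE)
  widths <- exons$end - exons$start + 1L
  if (sum(widths) != nchar(cds_seq)) {
    stop("CDS length must equal summed exon widths", call. = FALSE)
  }
  if (nchar(cds_seq) %% 3 != 0) {
    stop("CDS length must be divisible by 3", call. = FALSE)
  }
  structure(list(gene = gene, chrom = as.character(chrom), strand = strand,
                 exons = exons, cds_seq = cds_seq),
            class = "substrain_transcript")
}

# Genomic position -> 1-based coordinate in the spliced sense-strand CDS,
# or NA when intronic / outside the span.
cds_coord <- function(tm, pos) {
  ex <- tm$exons
  widths <- ex$end - ex$start + 1L
  hit <- which(pos >= ex$start & pos <= ex$end)
  if (length(hit) == 0) return(NA_integer_)
  if (tm$strand == "+") {
    before <- if (hit > 1) sum(widths[seq_len(hit - 1L)]) else 0L
    before + (pos - ex$start[hit] + 1L)
  } else {
    after <- if (hit < nrow(ex)) sum(widths[seq(hit + 1L, nrow(ex))]) else 0L
    after + (ex$end[hit] - pos + 1L)
  }
}

translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[toupper(codon)]]
  if (is.null(aa)) stop("invalid codon: ", codon, call. = FALSE)
  aa
}

#' Classify the coding consequence of a variant
#'
#' A SNP falling inside the CDS has its codon translated strand-aware: a
#' gained stop is `nonsense`, an amino-acid change `missense`, otherwise
#' `synonymous`. A variant within 2 intronic bases of an exon/intron boundary
#' (the canonical splice donor/acceptor dinucleotide) is `splice`. An indel
#' touching the CDS is `frameshift` when the allele length difference is not
#' divisible by 3, else `inframe_indel`. Everything else, including positions
#' outside the transcript span, is `noncoding`. Checks are applied in that
#' order.
#'
#' Deletion alleles may be written `"-"` (empty). A SNP whose reference
#' allele disagrees with the transcript's CDS sequence is an input error.
#'
#' @param v One-row call (list or tibble row) with `chrom`, `pos`, `ref`, `alt`.
#' @param tm A [transcript_model()].
#' @return One of `"missense"`, `"nonsense"`, `"synonymous"`, `"splice"`,
#'   `"frameshift"`, `"inframe_indel"`, `"noncoding"`.
#' @export
classify_consequence <- function(v, tm) {
  stopifnot(inherits(tm, "substrain_transcript"))
  if (as.character(v$chrom) != tm$chrom) {
    stop("variant lies on a different chromosome than the transcript", call. = FALSE)
  }
  ref <- gsub("-", "", toupper(v$ref))
  alt <- gsub("-", "", toupper(v$alt))
  if (grepl("[^ACGT]", ref) || grepl("[^ACGT]", alt)) {
    stop("malformed alleles: ", v$ref, "/", v$alt, call. = FALSE)
  }
  pos <- as.integer(v$pos)
  is_indel <- nchar(ref) != nchar(alt)
  span <- c(pos, pos + max(nchar(ref), 1L) - 1L)

  # 1. SNP inside the CDS: codon-level call
  if (!is_indel && nchar(ref) == 1L) {
    cp <- cds_coord(tm, pos)
    if (!is.na(cp)) {
      sense_ref <- if (tm$strand == "+") ref else comp_base(ref)
      sense_alt <- if (tm$strand == "+") alt else comp_base(alt)
      if (substr(tm$cds_seq, cp, cp) != sense_ref) {
        stop("reference allele does not match transcript CDS at position ", pos,
             call. = FALSE)
      }
      codon_start <- ((cp - 1L) %/% 3L) * 3L + 1L
      offset <- cp - codon_start + 1L
      ref_codon <- substr(tm$cds_seq, codon_start, codon_start + 2L)
      alt_codon <- ref_codon
      substr(alt_codon, offset, offset) <- sense_alt
      aa_ref <- translate_codon(ref_codon)
      aa_alt <- translate_codon(alt_codon)
      if (aa_alt == "*" && aa_ref != "*") return("nonsense")
      if (aa_alt != aa_ref) return("missense")
      return("synonymous")
    }
  }

  # 2. splice window: 2 intronic bases flanking each internal exon boundary
  ex <- tm$exons
  if (nrow(ex) > 1) {
    donor <- c(outer(ex$end[-nrow(ex)], 1:2, `+`))
    acceptor <- c(outer(ex$start[-1], 1:2, `-`))
    win <- c(donor, acceptor)
    if (any(win >= span[1] & win <= span[2])) return("splice")
  }

  # 3. indel touching the CDS
  if (is_indel) {
    in_cds <- any(span[2] >= ex$start & span[1] <= ex$end)
    if (in_cds) {
      shift <- abs(nchar(ref) - nchar(alt)) %% 3L
      return(if (shift == 0L) "inframe_indel" else "frameshift")
    }
  }

  "noncoding"
}
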
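# Structural-variant triage ledger.
#
# Candidates predicted by several detection methods are merged, then driven
# through an audited state machine: predicted -> (false_pe_error | retained)
# on visual inspection of the paired-end evidence, and retained ->
# (reference_error | validated) after PCR/Sanger. Validated SVs are annotated
# with gene overlap and, using an outgroup species (rat), with the ancestral
# mutational event.

sv_states <- c("predicted", "false_pe_error", "retained", "reference_error",
               "validated")
# legal transitions of the triage state machine
sv_transitions <- list(predicted = c("false_pe_error", "retained"),
                       retained = c("reference_error", "validated"))

retro_classes <- c("LINE", "SINE", "IAP", "MaLR", "MTA")

#' Merge per-method SV calls into candidates
#'
#' Calls of the same type whose intervals reciprocally overlap by at least
#' `reciprocal_overlap` are merged (single linkage, iterated to a fixed point,
#' so merging a merged set changes nothing). A merged candidate spans the
#' union of its members and accumulates the supporting methods. Insertions
#' are represented as (near) zero-length reference intervals, so insertion
#' calls merge only when their breakpoints coincide within the overlap rule.
#'
#' @param method_calls Named list of call tibbles (`chrom`, `start`, `stop`,
#'   `svtype`, optional `repeat_class`), one per detection method, each sorted
#'   by (chrom, start).
#' @param reciprocal_overlap Minimum reciprocal overlap in (0, 1]; default 0.5.
#' @return A candidate tibble: `id`, `chrom`, `start`, `stop`, `svtype`,
#'   `repeat_class`, `supporting_methods` (comma-joined), `n_methods`,
#'   `state = "predicted"`.
#' @export
merge_candidates <- function(method_calls, reciprocal_overlap = 0.5) {
  if (reciprocal_overlap <= 0 || reciprocal_overlap > 1) {
    stop("reciprocal_overlap must lie in (0, 1]", call. = FALSE)
  }
  stopifnot(length(names(method_calls)) == length(method_calls))
  all_calls <- dplyr::bind_rows(lapply(names(method_calls), function(m) {
    x <- method_calls[[m]]
    if (!"repeat_class" %in% names(x)) x$repeat_class <- NA_character_
    dplyr::mutate(x, method = m)
  }))
  if (nrow(all_calls) == 0) {
    return(tibble(id = character(), chrom = character(), start = integer(),
                  stop = integer(), svtype = character(),
                  repeat_class = character(), supporting_methods = character(),
                  n_methods = integer(), state = character()))
  }
  all_calls$methods <- all_calls$method

  merge_pass <- function(df) {
    out <- list()
    for (grp in split(df, list(df$chrom, df$svtype), drop = TRUE)) {
      n <- nrow(grp)
      parent <- seq_len(n)
      find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
      w <- grp$stop - grp$start + 1L
      for (i in seq_len(n)) {
        for (j in seq_len(n)) {
          if (j <= i) next
          ov <- min(grp$stop[i], grp$stop[j]) - max(grp$start[i], grp$start[j]) + 1L
          if (ov >= reciprocal_overlap * w[i] && ov >= reciprocal_overlap * w[j]) {
            ri <- find(i); rj <- find(j)
            if (ri != rj) parent[rj] <- ri
          }
        }
      }
      comp <- vapply(seq_len(n), find, integer(1))
      for (members in split(seq_len(n), comp)) {
        g <- grp[members, ]
        rc <- g$repeat_class[!is.na(g$repeat_class)]
        out[[length(out) + 1L]] <- tibble(
          chrom = g$chrom[1], start = min(g$start), stop = max(g$stop),
          svtype = g$svtype[1],
          repeat_class = if (length(rc)) rc[1] else NA_character_,
          methods = paste(sort(unique(unlist(strsplit(g$methods, ",")))),
                          collapse = ",")
        )
      }
    }
    dplyr::arrange(dplyr::bind_rows(out), chrom, start)
  }

  merged <- merge_pass(all_calls[c("chrom", "start", "stop", "svtype",
                                   "repeat_class", "methods")])
  repeat {
    nxt <- merge_pass(merged)
    if (nrow(nxt) == nrow(merged)) break
    merged <- nxt
  }
  tibble(id = sprintf("sv%03d", seq_len(nrow(merged))),
         chrom = merged$chrom, start = merged$start, stop = merged$stop,
         svtype = merged$svtype, repeat_class = merged$repeat_class,
         supporting_methods = merged$methods,
         n_methods = lengths(strsplit(merged$methods, ",")),
         state = "predicted")
}

#' Apply triage verdicts to an SV candidate ledger
#'
#' Updates candidate states along the legal transition graph
#' (`predicted -> false_pe_error | retained`,
#' `retained -> reference_error | validated`); any other requested transition
#' is an error naming the candidate, so a candidate can never reach
#' `validated` without passing `retained`.
#'
#' @param ledger Candidate tibble with `id` and `state` columns.
#' @param verdicts Named character vector mapping candidate id to the verdict
#'   state.
#' @return A list: `ledger` (updated tibble) and `counts` (named count of
#'   candidates per state).
#' @export
apply_triage_verdicts <- function(ledger, verdicts) {
  stopifnot(all(c("id", "state") %in% names(ledger)))
  if (!all(verdicts %in% sv_states)) {
    stop("unknown verdict state(s): ",
         paste(setdiff(verdicts, sv_states), collapse = ", "), call. = FALSE)
  }
  for (id in names(verdicts)) {
    i <- match(id, ledger$id)
    if (is.na(i)) stop("unknown candidate: ", id, call. = FALSE)
    from <- ledger$state[i]
    to <- verdicts[[id]]
    if (!to %in% (sv_transitions[[from]] %||% character())) {
      stop("illegal state transition for candidate ", id, ": ", from, " -> ", to,
           call. = FALSE)
    }
    ledger$state[i] <- to
  }
  counts <- table(factor(ledger$state, levels = sv_states))
  list(ledger = ledger, counts = stats::setNames(as.integer(counts), sv_states))
}

#' Define a gene model for overlap annotation
#'
#' @param gene Gene symbol.
#' @param chrom Chromosome label.
#' @param strand `"+"` or `"-"` (overlap labels do not depend on it).
#' @param exons Data frame of 1-based inclusive `start`, `end` exon intervals.
#' @return A `substrain_gene` list with the transcribed span attached.
#' @export
gene_model <- function(gene, chrom, strand, exons) {
  exons <- as.data.frame(exons)[c("start", "end")]
  structure(list(gene = gene, chrom = as.character(chrom), strand = strand,
                 exons = exons,
                 span = c(min(exons$start), max(exons$end))),
            class = "substrain_gene")
}

# Overlap label of one SV against one gene; severity entire > exon > intron.
overlap_label_one <- function(start, stop, g) {
  if (stop < g$span[1] || start > g$span[2]) return("none")
  if (start <= g$span[1] && stop >= g$span[2]) return("entire")
  ex <- IRanges::IRanges(g$exons$start, g$exons$end)
  sv <- IRanges::IRanges(start, stop)
  if (sum(IRanges::countOverlaps(ex, sv)) > 0) return("exon")
  "intron"
}

#' Annotate SV candidates with gene overlap
#'
#' Labels each SV `entire` when it contains a gene's full transcribed span,
#' `exon` when it intersects at least one exon base (without containing the
#' gene), `intron` when it overlaps the gene span without touching an exon,
#' and `none` otherwise. When several genes are hit, the most severe label
#' (entire > exon > intron) and its gene are kept.
#'
#' @param svs Tibble with `chrom`, `start`, `stop`.
#' @param genes List of [gene_model()] objects.
#' @return `svs` with `overlap` and `gene` columns replaced/added.
#' @export
annotate_gene_overlap <- function(svs, genes) {
  severity <- c(none = 0L, intron = 1L, exon = 2L, entire = 3L)
  lab <- character(nrow(svs))
  hit_gene <- rep(NA_character_, nrow(svs))
  for (i in seq_len(nrow(svs))) {
    best <- "none"
    for (g in genes) {
      if (g$chrom != svs$chrom[i]) next
      l <- overlap_label_one(svs$start[i], svs$stop[i], g)
      if (severity[[l]] > severity[[best]]) {
        best <- l
        hit_gene[i] <- g$gene
      }
    }
    lab[i] <- best
  }
  svs$overlap <- lab
  svs$gene <- hit_gene
  svs
}

#' Classify the ancestral event of a validated SV
#'
#' The derived allele is the one absent from the outgroup. A derived gain of
#' sequence annotated with a retrotransposon class (LINE, SINE, IAP, MaLR,
#' MTA) is labelled `"<class> Ins"`; an unannotated gain is `"Ins"`; a derived
#' loss is `"Del"`; a copy-number change of a tandem array is `"VNTR"`.
#' Category rollup: any insertion label (retrotransposition or plain) rolls up
#' to `insertion`, deletions to `non_repeat`, tandem-array changes to `vntr`.
#'
#' @param svtype `"insertion"`, `"deletion"` or `"tandem_repeat"`: how the
#'   difference was called in `strain` relative to the other sub-strain.
#' @param strain Sub-strain in which the call was made: the carrier of the
#'   extra sequence for an insertion call, the sub-strain missing sequence
#'   for a deletion call (ignored for tandem repeats).
#' @param outgroup Named logical vector (`B6J`, `B6N`): is each sub-strain's
#'   allele present in the outgroup?
#' @param repeat_class Repeat annotation of the gained sequence, or `NULL`.
#' @return A list with `label` and `rollup`.
#' @export
#' @examples
#' classify_ancestral_event("insertion", "B6J",
#'                          c(B6J = FALSE, B6N = TRUE), "LINE")
classify_ancestral_event <- function(svtype, strain, outgroup,
                                     repeat_class = NULL) {
  svtype <- match.arg(svtype, c("insertion", "deletion", "tandem_repeat"))
  if (svtype == "tandem_repeat") {
    return(list(label = "VNTR", rollup = "vntr"))
  }
  stopifnot(all(c("B6J", "B6N") %in% names(outgroup)))
  if (all(outgroup)) {
    stop("both alleles present in outgroup: ancestral state ambiguous",
         call. = FALSE)
  }
  if (!any(outgroup)) {
    stop("neither allele present in outgroup: at least one must be ancestral",
         call. = FALSE)
  }
  derived <- names(outgroup)[!outgroup]
  # which strain carries the longer allele under this call
  long_strain <- if (svtype == "insertion") strain else {
    setdiff(c("B6J", "B6N"), strain)
  }
  if (derived == long_strain) {
    label <- if (!is.null(repeat_class) && !is.na(repeat_class) &&
                 repeat_class %in% retro_classes) {
      paste(repeat_class, "Ins")
    } else "Ins"
    list(label = label, rollup = "insertion")
  } else {
    list(label = "Del", rollup = "non_repeat")
  }
}

# Printed event label -> rollup category.
rollup_event <- function(label) {
  dplyr::case_when(
    grepl("Ins", label, fixed = TRUE) ~ "insertion",
    grepl("^Del", label) ~ "non_repeat",
    grepl("^VNTR", label) ~ "vntr",
    TRUE ~ NA_character_
  )
}

#' Summarize an SV ledger
#'
#' Tallies candidates by triage state, gene-overlap class, carrier strain and
#' ancestral-event rollup. All tallies are additive and exhaustive over the
#' rows that carry the relevant column.
#'
#' @param ledger SV tibble; recognised columns are `state`, `overlap`,
#'   `strain` and `ancestral_event`.
#' @return A list of named integer vectors: `by_state`, `by_overlap`,
#'   `by_strain`, `by_rollup` (entries present only when the corresponding
#'   column is).
#' @export
#' @examples
#' summarize_svs(load_sv_table())$by_overlap
summarize_svs <- function(ledger) {
  out <- list(n = nrow(ledger))
  tally <- function(x, levels) {
    t <- table(factor(x, levels = levels))
    stats::setNames(as.integer(t), levels)
  }
  if ("state" %in% names(ledger)) {
    out$by_state <- tally(ledger$state, sv_states)
  }
  if ("overlap" %in% names(ledger)) {
    out$by_overlap <- tally(ledger$overlap, c("intron", "exon", "entire", "none"))
  }
  if ("strain" %in% names(ledger)) {
    s <- ledger$strain
    out$by_strain <- tally(ifelse(is.na(s), "unassigned", s),
                           c("B6J", "B6N", "unassigned"))
  }
  if ("ancestral_event" %in% names(ledger)) {
    out$by_rollup <- tally(rollup_event(ledger$ancestral_event),
                           c("insertion", "non_repeat", "vntr"))
  }
  out
}
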
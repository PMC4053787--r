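# End-to-end orchestration: variant cascade, phenotype comparison, and
# replication of the published tallies from the packaged fixtures.

pkg_version <- function() {
  as.character(utils::packageVersion("substrain"))
}

#' Run the variant filter cascade end to end
#'
#' Chains reference-set subtraction and the allele-ratio/depth hard filters
#' over a focal call set, and reports every cascade count.
#'
#' @param focal,reference Call tibbles, or paths to VCF / TSV call files
#'   (read via [read_variant_calls()]).
#' @param thresholds A [filter_thresholds()].
#' @param out_json Optional path; when given, the summary (without the
#'   retained calls) is written as JSON.
#' @return A list: `n_raw`, `n_after_subtraction`, `n_removed_shared`,
#'   `removed_by_reason` (named counts), `n_retained`, `retained` (call
#'   tibble), `thresholds`.
#' @export
run_variant_pipeline <- function(focal, reference,
                                 thresholds = filter_thresholds(),
                                 out_json = NULL) {
  if (is.character(focal)) focal <- read_variant_calls(focal)
  if (is.character(reference)) reference <- read_variant_calls(reference)
  after_sub <- subtract_reference_calls(focal, reference)
  filt <- apply_quality_filters(after_sub, thresholds)
  reasons <- table(factor(filt$removed$reason,
                          levels = c("heterozygous", "low_depth", "high_depth")))
  summary <- list(
    version = pkg_version(),
    n_raw = nrow(focal),
    n_after_subtraction = nrow(after_sub),
    n_removed_shared = nrow(focal) - nrow(after_sub),
    removed_by_reason = stats::setNames(as.integer(reasons), names(reasons)),
    n_retained = nrow(filt$retained),
    thresholds = unclass(thresholds)
  )
  if (!is.null(out_json)) {
    jsonlite::write_json(summary, out_json, auto_unbox = TRUE, digits = NA)
  }
  c(summary, list(retained = filt$retained, removed = filt$removed))
}

# one encoded heat-map cell (or NULL when a group is missing)
compute_cell <- function(sub, kind, affected, shade_thresholds) {
  vals_n <- sub$value[sub$strain == "B6N"]
  vals_j <- sub$value[sub$strain == "B6J"]
  if (!length(vals_n) || !length(vals_j)) return(NULL)
  if (kind == "categorical") {
    levels <- sort(unique(sub$value))
    if (length(levels) < 2) levels <- union(levels, c("affected", "unaffected"))
    tab <- rbind(B6N = table(factor(vals_n, levels = levels)),
                 B6J = table(factor(vals_j, levels = levels)))
    res <- compare_categorical(tab, affected = match(affected, levels))
  } else {
    if (kind == "timecourse") {
      vals_n <- collapse_timecourse(parse_series(vals_n))
      vals_j <- collapse_timecourse(parse_series(vals_j))
    } else {
      vals_n <- as.numeric(vals_n)
      vals_j <- as.numeric(vals_j)
    }
    res <- compare_numeric(vals_n, vals_j)
  }
  color <- encode_cell(res, shade_thresholds)
  tibble(test = res$test, p_value = res$p_value, direction = res$direction,
         effect = res$effect, rank_biserial = res$rank_biserial,
         n_N = res$n_N, n_J = res$n_J, hue = color$hue, shade = color$shade)
}

#' Run the multi-center phenotype comparison end to end
#'
#' For every parameter x center x sex: selects the comparison group (largest
#' minimum strain group size across metadata group keys), collapses time
#' courses to per-animal means, applies the Mann-Whitney or Fisher/chi-squared
#' test, and encodes the heat-map cell. Then assembles the heat map, assigns
#' concordance classes, and estimates the randomization null.
#'
#' @param pheno Phenotype table (tibble from [generate_phenotype_study()] or
#'   a TSV path).
#' @param affected Affected level for categorical parameters; default
#'   `"affected"`.
#' @param shade_thresholds Significance thresholds for cell shades.
#' @param k Concordance threshold (centers); default 3.
#' @param n_reps Randomization repeats for the null; default 1000.
#' @param seed Integer seed (recorded in outputs).
#' @param out_dir Optional output directory; when given, writes `cells.tsv`,
#'   `heatmap.tsv` and `report.json`.
#' @return A list: `cells` (per-cell tibble), `heatmap`, `classes`,
#'   `null` (the `substrain_null_estimate`), `report`
#'   (from [concordance_report()]), `seed`.
#' @export
run_phenotype_pipeline <- function(pheno, affected = "affected",
                                   shade_thresholds = c(0.05, 0.01, 0.001),
                                   k = 3L, n_reps = 1000L, seed = 1L,
                                   out_dir = NULL) {
  if (is.character(pheno)) pheno <- read_phenotype_table(pheno)
  combos <- dplyr::distinct(pheno, parameter, kind)
  centers <- unique(pheno$center)
  sexes <- unique(pheno$sex)
  cells <- list()
  for (i in seq_len(nrow(combos))) {
    par <- combos$parameter[i]
    kind <- combos$kind[i]
    for (ct in centers) {
      for (sx in sexes) {
        sub <- pheno[pheno$parameter == par & pheno$center == ct &
                       pheno$sex == sx, ]
        if (nrow(sub) == 0) next
        # metadata group selection: largest minimum strain group size
        opts <- dplyr::summarise(
          dplyr::group_by(sub, group_key),
          n_N = sum(strain == "B6N"), n_J = sum(strain == "B6J"),
          .groups = "drop")
        chosen <- select_comparison_group(opts)$group_key
        cell <- compute_cell(sub[sub$group_key == chosen, ], kind, affected,
                             shade_thresholds)
        if (is.null(cell)) next
        cells[[length(cells) + 1L]] <- dplyr::bind_cols(
          tibble(parameter = par, center = ct, sex = sx, group_key = chosen),
          cell)
      }
    }
  }
  cells <- dplyr::bind_rows(cells)
  hm <- build_heatmap(cells, centers = centers,
                      parameters = combos$parameter, sexes = sexes)
  classes <- vapply(combos$parameter, function(p) classify_parameter(hm, p),
                    character(1))
  null <- randomize_null(hm, k = k, n_reps = n_reps, seed = seed)
  report <- concordance_report(hm, k = k, n_reps = n_reps, seed = seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    header <- sprintf("# substrain %s seed=%d", pkg_version(), seed)
    cells_path <- file.path(out_dir, "cells.tsv")
    writeLines(header, cells_path)
    suppressWarnings(utils::write.table(cells, cells_path, sep = "\t",
                                        quote = FALSE, row.names = FALSE,
                                        append = TRUE))
    hm_path <- file.path(out_dir, "heatmap.tsv")
    writeLines(header, hm_path)
    suppressWarnings(utils::write.table(
      as.data.frame(hm)[c("parameter", "center", "sex", "hue", "shade",
                          "absent")],
      hm_path, sep = "\t", quote = FALSE, row.names = FALSE, append = TRUE))
    jsonlite::write_json(
      c(list(version = pkg_version(), seed = seed), report),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
      force = TRUE)
  }
  list(cells = cells, heatmap = hm,
       classes = tibble(parameter = combos$parameter, class = unname(classes)),
       null = null, report = report, seed = as.integer(seed))
}

#' Replay the published tallies from the packaged fixtures
#'
#' Recomputes, from the packaged tables and the triage/validation ledgers,
#' every published summary count: the coding-variant consequence tallies, the
#' structural-variant overlap and ancestral-event tallies, the SV triage
#' cascade (551 predicted, 81 retained, 43 validated) and the validation
#' bookkeeping (931 assayed, 363 eliminated, 568 remaining, 236 confirmed).
#' Each recomputed value is compared against the published count.
#'
#' @param out_json Optional path for a JSON copy of the report.
#' @return A tibble with columns `target`, `computed`, `expected`, `pass`.
#' @export
#' @examples
#' rep <- run_table_replication()
#' all(rep$pass)
run_table_replication <- function(out_json = NULL) {
  cv <- load_coding_variant_table()
  cons <- table(factor(cv$consequence,
                       levels = c("missense", "nonsense", "splice", "frameshift")))
  is_snp <- cv$base_n != "-" & cv$base_j != "-" &
    nchar(cv$base_n) == nchar(cv$base_j)

  sv <- load_sv_table()
  svs <- summarize_svs(sv)

  # replay the SV triage state machine from the seed counts
  tc <- load_sv_triage_counts()
  ledger <- tibble(id = sprintf("cand%03d", seq_len(tc$predicted)),
                   state = "predicted")
  v1 <- stats::setNames(
    c(rep("false_pe_error", tc$false_pe_error),
      rep("retained", tc$predicted - tc$false_pe_error)),
    ledger$id)
  step1 <- apply_triage_verdicts(ledger, v1)
  retained_ids <- step1$ledger$id[step1$ledger$state == "retained"]
  v2 <- stats::setNames(
    c(rep("reference_error", tc$reference_error),
      rep("validated", length(retained_ids) - tc$reference_error)),
    retained_ids)
  step2 <- apply_triage_verdicts(step1$ledger, v2)

  vs <- load_validation_summary()

  rows <- tibble(
    target = c("coding_variants_total", "missense", "nonsense", "splice",
               "frameshift", "coding_snps", "coding_indels", "non_private",
               "sv_total", "sv_gene_overlap", "sv_intron", "sv_exon",
               "sv_entire", "sv_rollup_insertion", "sv_rollup_non_repeat",
               "sv_rollup_vntr",
               "sv_predicted", "sv_retained", "sv_validated",
               "validation_assayed", "validation_eliminated",
               "validation_remaining", "validation_confirmed"),
    computed = c(nrow(cv), cons[["missense"]], cons[["nonsense"]],
                 cons[["splice"]], cons[["frameshift"]], sum(is_snp),
                 sum(!is_snp), sum(cv$private_to == "B6N_shared"),
                 svs$n, sum(svs$by_overlap[c("intron", "exon", "entire")]),
                 svs$by_overlap[["intron"]], svs$by_overlap[["exon"]],
                 svs$by_overlap[["entire"]],
                 svs$by_rollup[["insertion"]], svs$by_rollup[["non_repeat"]],
                 svs$by_rollup[["vntr"]],
                 nrow(step1$ledger),
                 sum(step1$ledger$state == "retained"),
                 step2$counts[["validated"]],
                 vs$assayed_total, vs$eliminated, vs$remaining,
                 vs$confirmed_total),
    expected = c(36, 32, 1, 1, 2, 34, 2, 1,
                 43, 15, 12, 2, 1, 27, 15, 1,
                 551, 81, 43,
                 931, 363, 568, 236)
  )
  rows$pass <- rows$computed == rows$expected
  if (!is.null(out_json)) {
    jsonlite::write_json(list(version = pkg_version(), targets = rows),
                         out_json, auto_unbox = TRUE, digits = NA)
  }
  rows
}
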
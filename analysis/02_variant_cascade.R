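#!/usr/bin/env Rscript
# Exercises the SNP/indel hard-filter cascade on synthetic call sets with
# planted artifacts: reference-shared sites (assembly discrepancies),
# heterozygous-looking calls (allele ratio < 0.8), and calls outside the
# [3, 150] depth window. Scores recovery against the planted truth over 20
# seeds and writes the per-seed summary to results/variant_cascade.tsv.

library(substrain)

dir.create("results", showWarnings = FALSE)

rows <- lapply(1:20, function(s) {
  sim <- generate_variant_callsets(variant_sim_config(
    n_true = 60, n_reference_shared = 12, n_heterozygous = 9,
    n_low_depth = 4, n_high_depth = 6, seed = s))
  res <- run_variant_pipeline(sim$focal, sim$reference)
  truth <- sort(with(sim$truth[sim$truth$keep, ], paste(chrom, pos, ref, alt)))
  got <- sort(with(res$retained, paste(chrom, pos, ref, alt)))
  tibble::tibble(seed = s, n_raw = res$n_raw,
                 removed_shared = res$n_removed_shared,
                 removed_heterozygous = res$removed_by_reason[["heterozygous"]],
                 removed_low_depth = res$removed_by_reason[["low_depth"]],
                 removed_high_depth = res$removed_by_reason[["high_depth"]],
                 retained = res$n_retained,
                 perfect_recovery = identical(truth, got))
})
tab <- dplyr::bind_rows(rows)
utils::write.table(tab, "results/variant_cascade.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

cat("Filter cascade on synthetic call sets (60 true + 31 planted artifacts):\n\n")
print(as.data.frame(tab[1:5, ]), row.names = FALSE)
cat("...\n\nPerfect truth recovery in", sum(tab$perfect_recovery), "of",
    nrow(tab), "seeds.\n")

# consequence classification of the packaged coding table is part of the
# fixtures themselves; here we sanity-check the classifier on a constructed
# transcript carrying the canonical stop-gain codon change
tm <- transcript_model("demo", "13", "+", data.frame(start = 101, end = 115),
                       "ATGCGAGGATTTTAA")
cat("\nCGA -> TGA codon change classifies as:",
    classify_consequence(list(chrom = "13", pos = 104, ref = "C", alt = "T"), tm),
    "\n")
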
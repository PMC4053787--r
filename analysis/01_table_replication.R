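#!/usr/bin/env Rscript
# Replays every published summary count from the packaged tables: the 36
# coding variants and their consequence classes, the 43 validated structural
# variants with their gene-overlap and ancestral-event tallies, the SV triage
# cascade (551 predicted -> 81 retained -> 43 validated), and the validation
# ledger (931 assayed - 363 eliminated -> 568 remaining, 236 confirmed).
# Writes the replication report to results/table_replication.tsv.

library(substrain)

dir.create("results", showWarnings = FALSE)

rep <- run_table_replication(out_json = "results/table_replication.json")
utils::write.table(rep, "results/table_replication.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

cat("Replication of published tallies from packaged fixtures:\n\n")
print(as.data.frame(rep), row.names = FALSE)
cat("\n", sum(rep$pass), "of", nrow(rep), "tallies reproduced exactly.\n")
if (!all(rep$pass)) stop("replication mismatch; see results/table_replication.tsv")
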
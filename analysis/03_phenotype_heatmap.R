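#!/usr/bin/env Rscript
# Simulates the default multi-center phenotype study (visual acuity, retinal
# vessel counts, fundus flecking prevalence, a glucose-tolerance time course,
# and a null control; 4 centers, both sexes, 20 animals per group), runs the
# per-cell statistics, builds the heat map, and assigns concordance classes.
# Artifacts land under results/phenotype/.

library(substrain)

dir.create("results", showWarnings = FALSE)

cfg <- default_study_config(n_per_group = 20, seed = 11)
tab <- generate_phenotype_study(cfg)
write_phenotype_table(tab, "results/phenotype_study.tsv")
cat("Simulated", nrow(tab), "measurement rows for",
    length(unique(tab$parameter)), "parameters at",
    length(unique(tab$center)), "centers.\n\n")

res <- run_phenotype_pipeline(tab, k = 3, n_reps = 2000, seed = 11,
                              out_dir = "results/phenotype")

cat("Per-cell comparisons (one row per parameter x center x sex):\n\n")
show <- res$cells[res$cells$sex == "male",
                  c("parameter", "center", "test", "p_value", "direction",
                    "hue", "shade")]
print(as.data.frame(show), row.names = FALSE, digits = 3)

cat("\nConcordance classes:\n\n")
print(as.data.frame(res$classes), row.names = FALSE)

cat(sprintf("\nObserved >=3-center concordance rate: %.3f\n",
            res$null$observed))
cat(sprintf("Randomization null (n_reps = %d, seed = %d): %.3f (SE %.4f)\n",
            res$null$n_reps, res$null$seed, res$null$probability, res$null$se))
cat("\nPer-class observed vs randomized rates:\n\n")
print(as.data.frame(res$report$rates), row.names = FALSE, digits = 3)
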
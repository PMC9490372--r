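#!/usr/bin/env Rscript
# Simulate a balanced multi-environment wheat trial shaped like the
# study design: 13 genotypes x 4 locations x 2 years x 3 replicates,
# with a yield-like trait (kg/plot) and a protein-like trait (%). The
# plot-level records and the implanted ground truth go to results/data/.

library(metgei)

seed <- 20260101L
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

yield <- simulate_met(trait = "yield", seed = seed)
# protein: genotype-dominated signal, weaker environment/interaction,
# mirroring the relative variance shares grain protein content shows
gpc <- simulate_met(grand_mean = 13.5, genotype_sd = 0.9,
                    environment_sd = 0.5, interaction_sds = c(2.2, 1.3),
                    error_sd = 0.25, trait = "gpc", seed = seed + 1L)

met <- met_data(rbind(as.data.frame(yield$data), as.data.frame(gpc$data)))
write_met(met, file.path(out, "met_simulated.tsv"))
write_met_truth(yield$truth, file.path(out, "truth_yield.tsv"))
write_met_truth(gpc$truth, file.path(out, "truth_gpc.tsv"))

cat(sprintf("Simulated %d records (%d genotypes x %d environments x %d reps, 2 traits)\n",
            nrow(met), attr(met, "g"), attr(met, "e"), attr(met, "r")))
cat(sprintf("Implanted yield interaction singular values: %s\n",
            paste(round(yield$truth$singular_values, 3), collapse = ", ")))
cat("Wrote", file.path(out, "met_simulated.tsv"), "and truth sidecars\n")
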
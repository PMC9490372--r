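#!/usr/bin/env Rscript
# Pearson correlation between the simulated traits on the
# genotype x environment cell-mean basis, with t-test p-values.

library(metgei)

met <- read_met("results/data/met_simulated.tsv")
dir.create("results/correlation", showWarnings = FALSE, recursive = TRUE)

cm <- pearson_matrix(met)
print(cm)

rmat <- cbind(trait = rownames(cm$r), as.data.frame(round(cm$r, 4)))
pmat <- cbind(trait = rownames(cm$p), as.data.frame(signif(cm$p, 4)))
utils::write.table(rmat, "results/correlation/r.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(pmat, "results/correlation/p.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat(sprintf("\nyield-gpc correlation r = %.3f (n = %d cell means)\n",
            cm$r["yield", "gpc"], cm$n))
cat("Wrote results/correlation/{r,p}.tsv\n")
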
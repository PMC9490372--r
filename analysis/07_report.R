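#!/usr/bin/env Rscript
# One-shot pipeline: everything the numbered drivers compute, written
# as a single report bundle (per-trait tables plus a plain-text
# summary of the top-ranked stable genotypes).

library(metgei)

met <- read_met("results/data/met_simulated.tsv")
res <- run_report(met, "results/report", quiet = FALSE)
cat("\n")
writeLines(readLines("results/report/summary.txt"))
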
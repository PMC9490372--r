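#!/usr/bin/env Rscript
# GGE biplot geometry per trait: which-won-where mega-environments,
# mean-vs-stability AEC projections, ideal-genotype ranking, and
# environment discriminativeness vs representativeness.

library(metgei)

met <- read_met("results/data/met_simulated.tsv")
dir.create("results/gge", showWarnings = FALSE, recursive = TRUE)

for (tr in met_traits(met)) {
  tw <- cell_means(met, tr)
  www <- which_won_where(fit_gge(tw, svp = "symmetric"))
  gmod <- fit_gge(tw, svp = "genotype")
  ms <- mean_vs_stability(gmod)
  rk <- rank_genotypes(gmod)
  dr <- discrimination_representativeness(fit_gge(tw, svp = "environment"))

  utils::write.table(www$winners,
                     sprintf("results/gge/%s__www_winners.tsv", tr),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(format(ms$scores, digits = 6),
                     sprintf("results/gge/%s__mean_vs_stability.tsv", tr),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(format(rk, digits = 6),
                     sprintf("results/gge/%s__ranking.tsv", tr),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(format(dr, digits = 6),
                     sprintf("results/gge/%s__discrimination.tsv", tr),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  cat(sprintf("\n== %s (PC1+PC2 = %.1f%% of G+GE) ==\n", tr,
              100 * gmod$gof))
  print(www)
  cat("Biplot ranking:", paste(head(rk$genotype, 4), collapse = " > "),
      "...\n")
  cat("Ideal test environment:", dr$environment[dr$ideal], "\n")
}
cat("\nWrote GGE view tables under results/gge/\n")
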
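#!/usr/bin/env Rscript
# Over-representation analysis of the combined biomarker panel against a
# user-supplied GMT library. A synthetic library with one planted enriched
# set stands in for pathway / cell-marker / transcription-factor databases.
#
# Writes: results/analysis/ora.tsv, frequent_genes.tsv

library(larconnect)
out <- "results/analysis"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 2030

panel <- merge_panels(gen_biomarker_panels())$panel
universe <- unique(c(panel, sprintf("BG%04d", 1:800)))

lib <- withr::with_seed(seed, {
  sets <- c(
    list(planted_pathway = c(sample(panel, 30), sample(universe, 10)),
         planted_celltype = c(sample(panel, 20), sample(universe, 20))),
    setNames(lapply(1:40, function(i) sample(universe, sample(20:60, 1))),
             sprintf("random_set_%02d", 1:40))
  )
  gene_set_library("synthetic_library", lapply(sets, unique))
})

res <- suppressMessages(ora(panel, universe, lib, q_threshold = 0.01))
cat(sprintf("ORA: %d of %d sets significant at BH-FDR < 1%%\n",
            sum(res$significant), nrow(res)))
print(head(res[, c("set", "overlap", "set_size", "odds_ratio", "p", "q")], 5),
      row.names = FALSE)
write.table(res, file.path(out, "ora.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

fg <- frequent_genes(res)
write.table(fg, file.path(out, "frequent_genes.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("Most frequent biomarkers across significant sets:\n")
print(head(fg, 5), row.names = FALSE)
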
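#!/usr/bin/env Rscript
# Stage 2: cell-type-specific differential expression of the biomarkers in a
# synthetic endobronchial-biopsy dataset (allergic asthma and allergic
# control groups, 4 subjects each, sampled before and after allergen
# challenge). Up-regulation of a biomarker subset is planted in CD8 and CD4
# T cells of the asthma group only; the control group provides the negative
# control contrast.
#
# Writes: results/analysis/scde.tsv, scde_summary.tsv, signature_up.gmt,
#         signature_down.gmt

library(larconnect)
out <- "results/analysis"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 2028

panel <- merge_panels(gen_biomarker_panels())$panel
planted <- list("CD8 T" = panel[1:30], "CD4 T" = panel[15:40])
sc <- gen_sc_biopsy(planted_sets = planted, effect = 1.5, n_genes = 400,
                    cells_per_stratum = 30, seed = seed)

de_tables <- list()
for (grp in c("allergic_asthma", "allergic_control")) {
  de <- suppressMessages(
    de_by_celltype(sc$dataset, biomarkers = panel, group = grp, fdr = 0.20))
  de$table$group <- grp
  de$summary$group <- grp
  de_tables[[grp]] <- de
  cat(sprintf("%s: significant up-regulated biomarkers per cell type (BH-FDR < 20%%)\n", grp))
  print(de$summary, row.names = FALSE)
}

tab <- rbind(de_tables[[1]]$table, de_tables[[2]]$table)
write.table(tab, file.path(out, "scde.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(rbind(de_tables[[1]]$summary, de_tables[[2]]$summary),
            file.path(out, "scde_summary.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

# disease signatures (asthma group) feed the drug-matching stage
sets <- signature_sets(de_tables$allergic_asthma)
if (length(sets$up))
  write_gmt(gene_set_library("signature_up", sets$up),
            file.path(out, "signature_up.gmt"))
if (length(sets$down))
  write_gmt(gene_set_library("signature_down", sets$down),
            file.path(out, "signature_down.gmt"))
cat(sprintf("Signatures written: %d cell types with up-sets, %d with down-sets\n",
            length(sets$up), length(sets$down)))
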
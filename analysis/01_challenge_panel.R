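#!/usr/bin/env Rscript
# Stage 1a: allergen-challenge cohort -- responder classification, gene
# filtering, sPLSDA keepX tuning and biomarker panel selection.
#
# A synthetic NanoString-like cohort (15 early responders, 20 dual responders,
# 770 genes of which 40 are housekeeping) stands in for the discovery data.
# Writes: results/analysis/responders.tsv, tuning.tsv, panel.tsv, panels_merged.tsv

library(larconnect)
out <- "results/analysis"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 2026

cohort <- gen_challenge_cohort(seed = seed)

calls <- classify_responders(cohort$spirometry)
write.table(calls, file.path(out, "responders.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("Responders: %d ER / %d DR; rescue rule fired for %d subject(s)\n",
            sum(calls$label == "ER"), sum(calls$label == "DR"),
            sum(calls$rule_fired == "ais_rescue")))

kept <- filter_low_abundance(cohort$expression, cohort$genes)
cat(sprintf("Filtering: %d of %d genes retained (housekeeping and low-abundance removed)\n",
            length(kept), 770))

logm <- log2_clip(cohort$expression)
X <- t(logm$values[kept, , drop = FALSE])
y <- factor(cohort$samples$group, levels = c("ER", "DR"))

# keepX grid: 5..30 transcripts per component, two components, 20x5-fold CV
tuning <- repeated_cv_auc(X, y, keepX_grid = c(5, 10, 15, 20, 25, 30),
                          ncomp = 2, repeats = 20, folds = 5, seed = seed)
write.table(tuning[, c("config", "n_transcripts", "mean_auc", "sd_auc")],
            file.path(out, "tuning.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
chosen <- select_panel(tuning, auc_threshold = 0.70)
stopifnot(!is.null(chosen))
cat(sprintf("Chosen configuration: keepX = %s, %d transcripts, CV AUC %.1f +/- %.1f%%\n",
            chosen$config, chosen$n_transcripts, 100 * chosen$mean_auc,
            100 * chosen$sd_auc))

fit <- fit_splsda(X, y, ncomp = 2, keepX = chosen$keepX[[1]])
panel <- panel_genes(fit)
imp <- sort(vip(fit), decreasing = TRUE)
write.table(data.frame(gene = panel, vip = imp[panel],
                       planted = panel %in% cohort$truth$informative),
            file.path(out, "panel.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("Panel: %d genes, %.0f%% of planted informative genes recovered\n",
            length(panel),
            100 * mean(cohort$truth$informative %in% panel)))

# merge with the four published-panel stand-ins
published <- gen_biomarker_panels()
merged <- merge_panels(published)
cat(sprintf("Five-panel merge: %d slots, %d unique biomarkers\n",
            merged$slots, merged$n_unique))
write.table(data.frame(gene = merged$panel),
            file.path(out, "panels_merged.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
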
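test_that("ranking score combines fold change and evidence", {
  expect_equal(ranking_score(1, 0.01), 2)
  expect_equal(ranking_score(-2, 0.001), -6)
  expect_equal(ranking_score(0.5, 1), 0)
  expect_equal(ranking_score(0, 0.5), 0)
  expect_error(ranking_score(1, 0), "p must be")
})

test_that("enrichment score matches hand-computed and oracle values", {
  s <- c(A = 4, B = 3, C = 2, D = 1)
  expect_equal(enrichment_score(s, "A"), 1)
  expect_equal(enrichment_score(s, "D"), -1)
  expect_equal(enrichment_score(s, c("A", "C")), 2 / 3)
  na <- enrichment_score(s, "ZZZ")
  expect_true(is.na(na))
  expect_true(attr(na, "empty_intersection"))
  expect_error(enrichment_score(c(A = 1, A = 2), "A"), "duplicate")

  # brute-force agreement on random instances up to N = 50
  withr::with_seed(51, {
    for (i in 1:40) {
      N <- sample(5:50, 1)
      sc <- stats::setNames(round(rnorm(N), 2), sprintf("G%02d", 1:N))
      set <- sample(names(sc), sample(1:min(8, N), 1))
      expect_equal(enrichment_score(sc, set), es_oracle(sc, set))
    }
  })
})

test_that("enrichment score is antisymmetric and scale invariant", {
  withr::with_seed(52, {
    for (i in 1:20) {
      N <- sample(8:30, 1)
      sc <- stats::setNames(rnorm(N), sprintf("G%02d", 1:N))
      set <- sample(names(sc), 4)
      es <- enrichment_score(sc, set)
      # negating scores reverses the list order, flipping the ES sign
      expect_equal(enrichment_score(-rev(sc), set), -es, tolerance = 1e-12)
      # positive rescaling leaves hit weights (normalised) unchanged
      expect_equal(enrichment_score(sc * 7.3, set), es, tolerance = 1e-12)
    }
  })
})

test_that("normalised ES calibrates to about 1 and flags undefined cases", {
  withr::with_seed(53, {
    sc <- stats::setNames(rnorm(60), sprintf("G%02d", 1:60))
    top <- names(sort(sc, decreasing = TRUE))[1:5]
  })
  r <- normalized_es(sc, top, n_perm = 300, seed = 2)
  expect_gt(r$nes, 1)
  # a random set has |NES| near 1 on average
  withr::with_seed(54, {
    vals <- sapply(1:20, function(i)
      abs(normalized_es(sc, sample(names(sc), 5), n_perm = 200, seed = i)$nes))
  })
  expect_gt(mean(vals), 0.6)
  expect_lt(mean(vals), 1.8)
  expect_error(normalized_es(sc, top, n_perm = 10), "100")
})

test_that("connectivity score is the up-down difference", {
  expect_equal(connectivity_score(0.8, -0.5), 1.3)
  expect_equal(connectivity_score(0.4, 0.4), 0)
  expect_equal(connectivity_score(-0.6, 0.7), -1.3)
  expect_true(is.na(connectivity_score(NA, 0.5)))
})

test_that("drug signatures recover planted shifts and the two-group identity", {
  sets <- list(up = list("CD8 T" = sprintf("LARB%03d", 1:15)),
               down = list("CD8 T" = sprintf("LARB%03d", 16:25)))
  scr <- gen_perturbation(n_compounds = 6, target_sets = sets, n_genes = 80,
                          cells_per_stratum = 10, effect = 1.5, seed = 8)
  sig <- build_drug_signatures(scr$dataset, min_cells = 3)
  rev_id <- scr$truth$reversers
  d <- sig$table[sig$table$compound == rev_id & sig$table$cell_type == "CD8 T", ]
  up <- d[d$gene %in% sets$up[["CD8 T"]], ]
  expect_gte(mean(up$log2fc < 0 & up$p < 0.05), 25 / 30)  # planted down-shift found
  expect_true(all(sign(d$score) == sign(d$log2fc) | d$score == 0))

  # two-group identity: coefficient equals the pseudobulk mean difference
  cd <- scr$dataset$cell_data
  keep <- cd$compound %in% c("DMSO", rev_id) & cd$cell_type == "CD8 T"
  sub <- single_cell_dataset(scr$dataset$counts[keep, ], cd[keep, ],
                             gene_ids = scr$dataset$gene_ids)
  sig2 <- build_drug_signatures(sub, min_cells = 3, trend = FALSE)
  nsub <- normalize_cells(sub, scale_factor = NULL)
  pb <- pseudobulk_mean(nsub, cell_type_col = "cell_type", sample_col = "compound",
                        min_cells = 3)
  diff <- pb$means[pb$strata$sample_id == rev_id, ] -
    pb$means[pb$strata$sample_id == "DMSO", ]
  d2 <- sig2$table[sig2$table$compound == rev_id, ]
  expect_equal(unname(stats::setNames(d2$log2fc, d2$gene)[colnames(pb$means)]),
               unname(diff), tolerance = 1e-8)
})

test_that("vehicle-vs-vehicle contrasts centre on zero", {
  sets <- list(up = list("CD8 T" = sprintf("LARB%03d", 1:10)),
               down = list())
  scr <- gen_perturbation(n_compounds = 4, target_sets = sets, n_genes = 60,
                          cells_per_stratum = 12, effect = 0, seed = 12)
  cd <- scr$dataset$cell_data
  # relabel half the DMSO cells as a sham compound
  sham <- cd$compound == "DMSO" & seq_len(nrow(cd)) %% 2 == 0
  cd$compound[sham] <- "SHAM"
  ds <- single_cell_dataset(scr$dataset$counts, cd, gene_ids = scr$dataset$gene_ids)
  sig <- build_drug_signatures(ds, min_cells = 2)
  sh <- sig$table[sig$table$compound == "SHAM", ]
  expect_lt(abs(mean(sh$log2fc)), 0.05)
})

test_that("score_all flags planted reversers and mimics and is order invariant", {
  sets <- list(up = list("CD8 T" = sprintf("LARB%03d", 1:15),
                         "CD4 T" = sprintf("LARB%03d", 5:20)),
               down = list("CD8 T" = sprintf("LARB%03d", 21:30)))
  scr <- gen_perturbation(n_compounds = 10, target_sets = sets, n_genes = 100,
                          cells_per_stratum = 8, effect = 1.5, seed = 21)
  sig <- build_drug_signatures(scr$dataset, min_cells = 3)
  cmap <- c("CD4 T" = "CD4 T", "CD8 T" = "CD8 T")
  res <- score_all(sig, sets$up, sets$down, celltype_map = cmap, mode = "raw",
                   report_threshold = 0.5,
                   exclude = scr$truth$positive_controls)
  expect_equal(res$summary$compound[1], scr$truth$reversers)   # most negative
  expect_true(scr$truth$reversers %in% res$reversers)
  expect_true(scr$truth$mimics %in%
                res$summary$compound[res$summary$all_positive])
  expect_false(any(scr$truth$positive_controls %in% res$reversers))
  expect_error(score_all(sig, sets$up, sets$down,
                         celltype_map = c("CD8 T" = "CD8 T")), "unmapped")

  # gene order inside the sets does not matter
  res2 <- score_all(sig, lapply(sets$up, rev), lapply(sets$down, sample),
                    celltype_map = cmap, mode = "raw", report_threshold = 0.5,
                    exclude = scr$truth$positive_controls)
  expect_equal(res2$table$cs, res$table$cs)
})
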
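toy_sc <- function(counts, ann) single_cell_dataset(Matrix::Matrix(counts,
  sparse = TRUE), ann, gene_ids = colnames(counts))

test_that("cell normalisation matches the closed form and keeps zeros sparse", {
  counts <- matrix(c(10, 0, 990, 500, 0, 500), 2, 3, byrow = TRUE,
                   dimnames = list(NULL, c("gA", "gB", "gC")))
  ann <- data.frame(cell_id = c("c1", "c2"))
  ds <- normalize_cells(toy_sc(counts, ann), scale_factor = 1e4)
  expect_equal(ds$logcounts["c1", "gA"], log2(10 / 1000 * 1e4 + 1))  # log2(101)
  expect_equal(ds$logcounts["c1", "gB"], 0)
  # doubling all counts of a cell leaves its profile unchanged
  ds2 <- normalize_cells(toy_sc(counts * 2, ann), scale_factor = 1e4)
  expect_equal(as.matrix(ds2$logcounts), as.matrix(ds$logcounts))
  zero <- rbind(c(1, 1), c(0, 0))
  colnames(zero) <- c("gA", "gB")
  expect_error(normalize_cells(toy_sc(zero, ann)), "zero library")
})

test_that("pseudobulk means equal the brute-force group-by oracle", {
  withr::with_seed(14, {
    n_cells <- 60
    counts <- matrix(rpois(n_cells * 5, 8), n_cells, 5,
                     dimnames = list(NULL, paste0("g", 1:5)))
    ann <- data.frame(cell_id = sprintf("c%02d", 1:n_cells),
                      cell_type = sample(c("T", "B"), n_cells, replace = TRUE),
                      sample_id = sample(c("s1", "s2"), n_cells, replace = TRUE))
  })
  ds <- normalize_cells(toy_sc(counts, ann), scale_factor = 1e4)
  pb <- pseudobulk_mean(ds, min_cells = 1)
  key <- paste(ann$cell_type, ann$sample_id)
  oracle <- groupby_mean_oracle(as.matrix(ds$logcounts), key)
  for (i in seq_len(nrow(pb$strata))) {
    k <- paste(pb$strata$cell_type[i], pb$strata$sample_id[i])
    expect_equal(unname(pb$means[i, ]), unname(oracle[k, ]), tolerance = 1e-12)
  }
  # single-cell stratum with min_cells = 1 equals that cell
  one <- toy_sc(matrix(c(4, 2), 1, 2, dimnames = list(NULL, c("g1", "g2"))),
                data.frame(cell_id = "c1", cell_type = "T", sample_id = "s1"))
  one <- normalize_cells(one, scale_factor = 6)
  pb1 <- pseudobulk_mean(one, min_cells = 1)
  expect_equal(unname(pb1$means[1, ]), unname(as.matrix(one$logcounts)[1, ]))
  # min_cells drops small strata
  expect_message(pb20 <- pseudobulk_mean(ds, min_cells = 20), "dropped")
  expect_true(all(pb20$strata$n_cells >= 20))
  expect_true(all(pb20$dropped$n_cells < 20))
})

test_that("moderated t interpolates between ordinary and pooled t", {
  withr::with_seed(33, {
    g <- 80; n <- 8
    y <- matrix(rnorm(g * n, 5, sqrt(rchisq(g, 4) / 4)), g, n,
                dimnames = list(sprintf("g%02d", 1:g), NULL))
    design <- cbind(1, rep(0:1, each = n / 2))
  })
  fit0 <- moderated_fit(y, design, d0_override = 0)
  # d0 = 0 equals the per-gene OLS t
  tt <- apply(y, 1, function(r) unname(summary(lm(r ~ design[, 2]))$coef[2, "t value"]))
  expect_equal(unname(fit0$t), unname(tt), tolerance = 1e-8)
  fitInf <- moderated_fit(y, design, d0_override = Inf)
  expect_equal(length(unique(round(fitInf$s2_post, 12))), 1)  # one common s0
  fitEB <- moderated_fit(y, design)
  # monotone interpolation: EB t lies between the two limits gene-wise
  lo <- pmin(fit0$t, fitInf$t); hi <- pmax(fit0$t, fitInf$t)
  expect_true(all(fitEB$t >= lo - 1e-8 & fitEB$t <= hi + 1e-8))
  expect_error(moderated_fit(y, cbind(1, 1)), "rank deficient")
})

test_that("moderated statistics agree with the limma reference", {
  withr::with_seed(35, {
    g <- 120; n <- 10
    y <- matrix(rnorm(g * n, 6, 1), g, n, dimnames = list(sprintf("g%03d", 1:g), NULL))
    y[1:10, 6:10] <- y[1:10, 6:10] + 2
    design <- cbind(Intercept = 1, cond = rep(0:1, each = 5))
  })
  ours <- moderated_fit(y, design, coef = 2, trend = FALSE)
  ref <- limma::eBayes(limma::lmFit(y, design), trend = FALSE)
  expect_equal(unname(ours$coef), unname(ref$coefficients[, 2]), tolerance = 1e-10)
  expect_equal(unname(ours$t), unname(ref$t[, 2]), tolerance = 1e-8)
  expect_equal(unname(ours$p), unname(ref$p.value[, 2]), tolerance = 1e-8)
  ours_tr <- moderated_fit(y, design, coef = 2, trend = TRUE)
  ref_tr <- limma::eBayes(limma::lmFit(y, design), trend = TRUE)
  expect_equal(unname(ours_tr$t), unname(ref_tr$t[, 2]), tolerance = 1e-6)
})

test_that("BH adjustment matches direct enumeration", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  withr::with_seed(40, {
    for (i in 1:10) {
      p <- runif(sample(3:30, 1))
      expect_equal(bh_adjust(p), bh_oracle(p))
    }
  })
})

test_that("cell-type-restricted DE recovers planted up-regulation", {
  panel <- sprintf("LARB%03d", 1:30)
  planted <- list("CD8 T" = panel[1:20])
  sc <- gen_sc_biopsy(planted_sets = planted, effect = 1.5, n_genes = 150,
                      cells_per_stratum = 20, seed = 44)
  de_aa <- de_by_celltype(sc$dataset, biomarkers = panel, group = "allergic_asthma")
  tab <- de_aa$table
  hit <- tab$cell_type == "CD8 T" & tab$gene %in% planted[["CD8 T"]]
  expect_gte(mean(tab$significant[hit] & tab$direction[hit] == "up"), 0.8)
  # log2FC sign equals the sign of the pseudobulk mean difference by construction
  expect_true(all(tab$direction == ifelse(tab$log2fc > 0, "up", "down")))
  # q never smaller than p within each cell type
  expect_true(all(tab$q >= tab$p - 1e-12))
  # the control group shows no comparable response
  de_ac <- de_by_celltype(sc$dataset, biomarkers = panel, group = "allergic_control")
  ctl <- de_ac$table[de_ac$table$cell_type == "CD8 T", ]
  expect_lte(mean(ctl$significant), 0.25)
})

test_that("unbalanced conditions are skipped with a message", {
  panel <- sprintf("LARB%03d", 1:10)
  sc <- gen_sc_biopsy(planted_sets = list("CD8 T" = panel), n_genes = 60,
                      cells_per_stratum = 12, seed = 3)
  cd <- sc$dataset$cell_data
  keep <- !(cd$cell_type == "B" & cd$condition == "allergen")
  ds <- single_cell_dataset(sc$dataset$counts[keep, ], cd[keep, ],
                            gene_ids = sc$dataset$gene_ids)
  expect_message(de <- de_by_celltype(ds, panel, group = "allergic_asthma",
                                      min_cells = 5), "skipped")
  expect_false("B" %in% de$table$cell_type)
})
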
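toy_matrix <- function() {
  m <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 3,
              dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  expression_matrix(m, value_kind = "counts")
}

test_that("delimited matrix round-trips and rejects malformed input", {
  x <- toy_matrix()
  expect_equal(dim(x), c(3L, 2L))
  f <- tempfile(fileext = ".tsv")
  write_matrix_delim(x, f, seed = 42)
  y <- read_matrix_written(f)
  expect_equal(y$values, x$values)
  expect_equal(y$value_kind, "counts")

  # samples-in-rows orientation is normalised to genes x samples
  f2 <- tempfile(fileext = ".tsv")
  writeLines(c("g1\tg2\tg3", "s1\t1\t2\t3", "s2\t4\t5\t6"), f2)
  z <- read_matrix_delim(f2, orientation = "samples_in_rows")
  expect_equal(z$gene_ids, c("g1", "g2", "g3"))
  expect_equal(z$values["g2", "s2"], 5)

  bad <- tempfile(fileext = ".tsv")
  writeLines(c("s1\ts2", "g1\t1\t2", "g2\t1"), bad)
  expect_error(read_matrix_delim(bad), "ragged")

  dup <- matrix(1:4, 2, dimnames = list(c("g1", "g2"), c("s1", "s1")))
  expect_error(expression_matrix(dup), "duplicated sample ids")
  neg <- matrix(c(-1, 1), 1, 2, dimnames = list("g1", c("s1", "s2")))
  expect_error(expression_matrix(neg, value_kind = "counts"), "negative")
})

test_that("MTX triplet reader aligns annotations and handles missing barcodes", {
  dir <- tempfile(); dir.create(dir)
  m <- Matrix::sparseMatrix(i = c(1, 2, 3, 1), j = c(1, 2, 3, 4),
                            x = c(5, 2, 7, 1), dims = c(3, 4))
  Matrix::writeMM(m, file.path(dir, "m.mtx"))
  writeLines(c("gA", "gB", "gC"), file.path(dir, "features.tsv"))
  writeLines(c("c1", "c2", "c3", "c4"), file.path(dir, "barcodes.tsv"))
  ann <- data.frame(cell_id = c("c1", "c2", "c3", "c4"),
                    cell_type = c("T", "T", "B", "B"))
  write.table(ann, file.path(dir, "ann.tsv"), sep = "\t", row.names = FALSE,
              quote = FALSE)
  ds <- read_mtx_triplet(file.path(dir, "m.mtx"), file.path(dir, "features.tsv"),
                         file.path(dir, "barcodes.tsv"), file.path(dir, "ann.tsv"))
  expect_s3_class(ds, "single_cell_dataset")
  expect_equal(nrow(ds$counts), 4)     # cells x genes after transposition
  expect_equal(as.numeric(ds$counts["c1", "gA"]), 5)
  expect_equal(ds$cell_data$cell_type, c("T", "T", "B", "B"))

  # feature list shorter than mtx rows -> dimension error
  writeLines(c("gA", "gB"), file.path(dir, "short.tsv"))
  expect_error(read_mtx_triplet(file.path(dir, "m.mtx"), file.path(dir, "short.tsv"),
                                file.path(dir, "barcodes.tsv"),
                                file.path(dir, "ann.tsv")), "features")

  # unannotated barcode: error by default, dropped with warning when allowed
  write.table(ann[1:3, ], file.path(dir, "ann3.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  expect_error(read_mtx_triplet(file.path(dir, "m.mtx"), file.path(dir, "features.tsv"),
                                file.path(dir, "barcodes.tsv"),
                                file.path(dir, "ann3.tsv")), "missing")
  expect_warning(
    ds3 <- read_mtx_triplet(file.path(dir, "m.mtx"), file.path(dir, "features.tsv"),
                            file.path(dir, "barcodes.tsv"),
                            file.path(dir, "ann3.tsv"), drop_unannotated = TRUE),
    "unannotated")
  expect_equal(nrow(ds3$counts), 3)
})

test_that("GMT libraries round-trip and reject empty sets", {
  lib <- gene_set_library("demo", list(a = c("X", "Y"), b = c("Y", "Z", "W")))
  f <- tempfile(fileext = ".gmt")
  write_gmt(lib, f)
  back <- read_gmt(f, name = "demo")
  expect_equal(back$sets, lib$sets)
  writeLines("empty\tdesc", f)
  expect_error(read_gmt(f), "empty")
})

test_that("probe collapsing averages and transcript aggregation sums", {
  m <- matrix(c(2, 4, 10, 1, 2, 6), nrow = 3,
              dimnames = list(c("p1", "p2", "p3"), c("s1", "s2")))
  x <- expression_matrix(m, value_kind = "log_intensity")
  gt <- gene_table(symbol = c("G", "G", "H"), probe_id = c("p1", "p2", "p3"))
  col <- collapse_probes_mean(x, gt)
  expect_equal(col$values["G", "s1"], 3)    # mean(2, 4)
  expect_equal(col$values["H", ], c(s1 = 10, s2 = 6))
  expect_equal(ncol(col$values), ncol(x$values))

  # three probes to one symbol: plain mean
  m3 <- matrix(c(1, 2, 6), 3, 1, dimnames = list(c("a", "b", "c"), "s1"))
  x3 <- expression_matrix(m3, value_kind = "log_intensity")
  gt3 <- gene_table(symbol = rep("G", 3), probe_id = c("a", "b", "c"))
  expect_equal(unname(collapse_probes_mean(x3, gt3)$values["G", "s1"]), 3)

  # distinct symbols: identity up to renaming
  gtd <- gene_table(symbol = c("A", "B", "C"), probe_id = c("p1", "p2", "p3"))
  expect_equal(unname(collapse_probes_mean(x, gtd)$values), unname(m))

  expect_error(collapse_probes_mean(x, gt3), "absent")

  cx <- expression_matrix(m, value_kind = "counts")
  sm <- sum_transcripts(cx, gt)
  expect_equal(sm$values["G", "s1"], 6)     # 2 + 4
  expect_equal(colSums(sm$values), colSums(cx$values))  # totals preserved
  expect_error(sum_transcripts(x, gt), "invalid")
})

test_that("log2_clip transforms then zeroes negatives and NAs", {
  m <- matrix(c(8, 0.5, NA, 1), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  x <- expression_matrix(m, value_kind = "counts")
  out <- log2_clip(x)
  expect_equal(out$values["g1", "s1"], 3)          # log2(8)
  expect_equal(out$values["g2", "s1"], 0)          # log2(0.5) = -1 -> 0
  expect_equal(out$values["g1", "s2"], 0)          # NA -> 0
  expect_equal(out$values["g2", "s2"], 0)          # log2(1) = 0
  expect_equal(out$value_kind, "log_intensity")
})

test_that("log_cpm matches the closed-form value and is scale invariant", {
  m <- matrix(c(100, 1e6 - 100, 50, 1e6 - 50), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  x <- expression_matrix(m, value_kind = "counts")
  out <- log_cpm(x, prior_count = 0.5)
  expect_equal(out$values["g1", "s1"], log2((100 + 0.5) / (1e6 + 1) * 1e6))

  # zero-count gene is constant across equal-size libraries
  m2 <- rbind(m, g3 = c(0, 0))
  x2 <- expression_matrix(m2, value_kind = "counts")
  out2 <- log_cpm(x2)
  expect_equal(out2$values["g3", "s1"], out2$values["g3", "s2"])

  # prior 0: exact invariance to per-sample count scaling
  x3 <- expression_matrix(m, value_kind = "counts")
  doubled <- expression_matrix(m * 2, value_kind = "counts")
  expect_equal(log_cpm(doubled, prior_count = 0)$values,
               log_cpm(x3, prior_count = 0)$values, tolerance = 1e-12)

  zl <- expression_matrix(cbind(m, s3 = c(0, 0)), value_kind = "counts")
  expect_error(log_cpm(zl), "zero total counts")
})

test_that("low-abundance filtering applies the negative-control threshold", {
  # negative controls with known mean/SD; planted genes straddle the cutoff
  ctl <- matrix(c(4, 6, 4, 6), 2, 2)   # mean 5, sd ~1.155 -> cutoff ~7.31
  m <- rbind(hi = c(50, 60), lo = c(6, 7), hk = c(100, 100), ctl)
  rownames(m) <- c("hi", "lo", "hk", "n1", "n2")
  colnames(m) <- c("s1", "s2")
  x <- expression_matrix(m, value_kind = "counts")
  gt <- gene_table(symbol = rownames(m),
                   is_housekeeping = rownames(m) == "hk",
                   is_negative_control = rownames(m) %in% c("n1", "n2"))
  kept <- filter_low_abundance(x, gt, k_sd = 2)
  expect_equal(kept, "hi")
  # threshold disabled: all non-housekeeping, non-control genes kept
  expect_equal(filter_low_abundance(x, gt, k_sd = -Inf), c("hi", "lo"))
  gt_none <- gene_table(symbol = rownames(m),
                        is_housekeeping = rownames(m) == "hk")
  expect_error(filter_low_abundance(x, gt_none, k_sd = 2), "negative-control")
})
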
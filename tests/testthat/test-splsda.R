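make_classes <- function(n_per = 20, p = 60, n_inf = 8, effect = 2, seed = 2) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(2 * n_per * p), 2 * n_per, p,
                dimnames = list(NULL, sprintf("g%03d", 1:p)))
    inf <- if (n_inf > 0) sprintf("g%03d", 1:n_inf) else character(0)
    X[(n_per + 1):(2 * n_per), inf] <- X[(n_per + 1):(2 * n_per), inf] + effect
    list(X = X, y = factor(rep(c("ER", "DR"), each = n_per),
                           levels = c("ER", "DR")), informative = inf)
  })
}

test_that("sparsity, normalisation and permutation invariance hold", {
  d <- make_classes()
  fit <- fit_splsda(d$X, d$y, ncomp = 2, keepX = c(5, 7))
  expect_equal(colSums(fit$W != 0), c(5, 7))
  expect_equal(colSums(fit$W^2), c(1, 1), tolerance = 1e-12)

  perm <- withr::with_seed(3, sample(nrow(d$X)))
  fit_p <- fit_splsda(d$X[perm, ], d$y[perm], ncomp = 2, keepX = c(5, 7))
  expect_equal(fit_p$W, fit$W, tolerance = 1e-9)

  expect_error(fit_splsda(d$X, d$y, keepX = 1000), "keepX")
  Xc <- d$X; Xc[, 1] <- 1
  expect_error(fit_splsda(Xc, d$y), "constant")
})

test_that("planted informative genes are recovered at 2-SD effects", {
  d <- make_classes(effect = 2)
  fit <- fit_splsda(d$X, d$y, ncomp = 2, keepX = c(8, 8))
  expect_gte(mean(d$informative %in% panel_genes(fit)), 0.8)
})

test_that("the dense limit matches the reference sPLSDA implementation", {
  d <- make_classes(n_per = 15, p = 20)
  fit <- fit_splsda(d$X, d$y, ncomp = 1, keepX = 20)
  ref <- mixOmics::splsda(d$X, d$y, ncomp = 1, keepX = 20)
  w_ref <- ref$loadings$X[colnames(d$X), 1]
  cmp <- abs(cor(fit$W[, 1], w_ref))
  expect_gt(cmp, 0.999)
  # sparse weights select the same genes as mixOmics at matching keepX
  fit_s <- fit_splsda(d$X, d$y, ncomp = 1, keepX = 5)
  ref_s <- mixOmics::splsda(d$X, d$y, ncomp = 1, keepX = 5)
  expect_setequal(panel_genes(fit_s),
                  rownames(ref_s$loadings$X)[ref_s$loadings$X[, 1] != 0])
})

test_that("prediction scores centre at zero and orient to the positive class", {
  d <- make_classes()
  fit <- fit_splsda(d$X, d$y, ncomp = 2, keepX = c(8, 8))
  # the training-mean sample scores exactly zero
  mean_sample <- matrix(fit$center, 1, dimnames = list(NULL, rownames(fit$W)))
  expect_equal(predict_scores(fit, mean_sample), 0, tolerance = 1e-10)
  # class centroids land on their own side
  cen_dr <- matrix(colMeans(d$X[d$y == "DR", ]), 1,
                   dimnames = list(NULL, colnames(d$X)))
  cen_er <- matrix(colMeans(d$X[d$y == "ER", ]), 1,
                   dimnames = list(NULL, colnames(d$X)))
  expect_gt(predict_scores(fit, cen_dr), 0)
  expect_lt(predict_scores(fit, cen_er), 0)
  # training scores are monotone with T %*% q for the positive class
  tr <- predict_scores(fit, d$X)
  expect_gt(cor(tr, as.vector(fit$T %*% fit$Q["DR", ]), method = "spearman"), 0.99)
  expect_error(predict_scores(fit, d$X[, -1]), "missing genes")
})

test_that("VIP matches its closed form and normalisation identity", {
  d <- make_classes()
  fit1 <- fit_splsda(d$X, d$y, ncomp = 1, keepX = 1)
  v1 <- vip(fit1)
  p <- ncol(d$X)
  # single selected gene: VIP = sqrt(p) there, 0 elsewhere
  expect_equal(unname(sort(v1, decreasing = TRUE)[1]), sqrt(p))
  expect_equal(unname(sum(v1 > 0)), 1)
  fit2 <- fit_splsda(d$X, d$y, ncomp = 2, keepX = c(6, 6))
  expect_equal(mean(vip(fit2)^2), 1, tolerance = 1e-10)
})

test_that("AUC equals the all-pairs Mann-Whitney oracle, ties included", {
  withr::with_seed(6, {
    for (i in 1:25) {
      n <- sample(6:20, 1)
      y <- factor(sample(c("a", "b"), n, replace = TRUE))
      if (length(unique(y)) < 2) next
      s <- sample(seq(-3, 3, 0.5), n, replace = TRUE)  # forces ties
      expect_equal(auc_score(s, y), auc_oracle(s, y))
    }
  })
})

test_that("repeated CV is deterministic, separable signals score high, null near 0.5", {
  d <- make_classes(n_per = 20, p = 40, n_inf = 6, effect = 3)
  t1 <- repeated_cv_auc(d$X, d$y, keepX_grid = list(c(6, 6)), repeats = 5, seed = 9)
  t2 <- repeated_cv_auc(d$X, d$y, keepX_grid = list(c(6, 6)), repeats = 5, seed = 9)
  expect_identical(t1$mean_auc, t2$mean_auc)
  expect_gte(t1$mean_auc, 0.95)

  null <- make_classes(n_per = 20, p = 40, n_inf = 0, effect = 0, seed = 31)
  tn <- repeated_cv_auc(null$X, null$y, keepX_grid = list(c(10, 10)),
                        repeats = 10, seed = 17)
  expect_gt(tn$mean_auc, 0.3)
  expect_lt(tn$mean_auc, 0.7)
  expect_error(repeated_cv_auc(d$X[1:6, ], d$y[1:6], keepX_grid = list(5)),
               "stratify")
})

test_that("panel selection prefers the smallest qualifying configuration", {
  tun <- data.frame(config = c("20", "25", "30"),
                    n_transcripts = c(20, 25, 30),
                    mean_auc = c(0.65, 0.72, 0.73), sd_auc = c(0.05, 0.04, 0.03))
  tun$keepX <- list(20, 25, 30)
  expect_equal(select_panel(tun, 0.70)$n_transcripts, 25)
  expect_null(select_panel(tun, 0.80))
  tie <- data.frame(config = c("a", "b"), n_transcripts = c(20, 20),
                    mean_auc = c(0.72, 0.75), sd_auc = c(0.02, 0.02))
  tie$keepX <- list(20, 20)
  expect_equal(select_panel(tie, 0.70)$mean_auc, 0.75)
})

test_that("panel merging preserves order, counts slots and overlaps", {
  m <- merge_panels(list(p1 = c("A", "B"), p2 = c("B", "C")))
  expect_equal(m$panel, c("A", "B", "C"))
  expect_equal(m$slots, 4)
  expect_equal(m$n_unique, 3)
  expect_equal(m$overlap["p1", "p2"], 1L)
  single <- merge_panels(list(only = c("X", "Y")))
  expect_equal(single$panel, c("X", "Y"))
  expect_error(merge_panels(list(p = c("A", "A"))), "duplicate")
})
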
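#' Average probes mapping to the same gene symbol
#'
#' Microarray platforms carry several probesets per gene; per-sample values of
#' probes sharing a symbol are collapsed by their arithmetic mean. Symbols
#' appear in order of first appearance among the probes.
#'
#' @param x An [expression_matrix()] whose gene ids are probe ids.
#' @param genes A [gene_table()] mapping `probe_id` to `symbol`; must cover
#'   every probe in `x`.
#' @return An [expression_matrix()] with one row per symbol.
#' @export
collapse_probes_mean <- function(x, genes) {
  stopifnot(inherits(x, "expression_matrix"))
  map <- stats::setNames(genes$symbol, trimws(genes$probe_id))
  missing <- setdiff(x$gene_ids, names(map))
  if (length(missing))
    stop("probes absent from gene table: ",
         paste(utils::head(missing, 10), collapse = ", "))
  sym <- map[x$gene_ids]
  f <- factor(sym, levels = unique(sym))
  collapsed <- rowsum(x$values, f, reorder = FALSE) / as.vector(table(f)[levels(f)])
  expression_matrix(collapsed, gene_ids = levels(f), sample_ids = x$sample_ids,
                    value_kind = x$value_kind)
}

#' Sum transcript counts mapping to the same gene symbol
#'
#' RNA-seq quantifications at transcript level are aggregated by within-sample
#' summation. Only valid on the counts scale: summing log-intensities is
#' rejected.
#'
#' @param x A counts [expression_matrix()] whose gene ids are transcript ids.
#' @param genes A [gene_table()] mapping `probe_id` (transcript id) to `symbol`.
#' @return A counts [expression_matrix()] with one row per symbol.
#' @export
sum_transcripts <- function(x, genes) {
  stopifnot(inherits(x, "expression_matrix"))
  if (x$value_kind != "counts")
    stop("sum_transcripts requires a counts matrix; summing log-intensities is invalid")
  map <- stats::setNames(genes$symbol, trimws(genes$probe_id))
  missing <- setdiff(x$gene_ids, names(map))
  if (length(missing))
    stop("transcripts absent from gene table: ",
         paste(utils::head(missing, 10), collapse = ", "))
  sym <- map[x$gene_ids]
  f <- factor(sym, levels = unique(sym))
  summed <- rowsum(x$values, f, reorder = FALSE)
  expression_matrix(summed, gene_ids = levels(f), sample_ids = x$sample_ids,
                    value_kind = "counts")
}

#' Log2-transform with zero replacement
#'
#' The preprocessing rule used for MAS5/RMA-scale downloads: log2-transform,
#' then replace negative results and missing values with zero.
#'
#' @param x An [expression_matrix()] on the natural scale.
#' @return A log-intensity [expression_matrix()].
#' @export
log2_clip <- function(x) {
  stopifnot(inherits(x, "expression_matrix"))
  v <- suppressWarnings(log2(x$values))
  v[!is.finite(v) | v < 0] <- 0
  expression_matrix(v, gene_ids = x$gene_ids, sample_ids = x$sample_ids,
                    value_kind = "log_intensity")
}

#' Log counts-per-million
#'
#' Per-sample library-size normalisation:
#' `log2((count + prior) / (libsize + 2 * prior) * 1e6)`. With
#' `prior_count = 0` the transform is exactly invariant to per-sample scaling
#' of counts.
#'
#' @param x A counts [expression_matrix()].
#' @param prior_count Additive prior, default 0.5.
#' @return A log-intensity [expression_matrix()].
#' @export
log_cpm <- function(x, prior_count = 0.5) {
  stopifnot(inherits(x, "expression_matrix"))
  if (x$value_kind != "counts") stop("log_cpm requires a counts matrix")
  lib <- colSums(x$values)
  zero <- lib == 0
  if (any(zero))
    stop("sample(s) with zero total counts: ",
         paste(x$sample_ids[zero], collapse = ", "))
  v <- log2(sweep(x$values + prior_count, 2, lib + 2 * prior_count, "/") * 1e6)
  expression_matrix(v, gene_ids = x$gene_ids, sample_ids = x$sample_ids,
                    value_kind = "log_intensity")
}

#' Filter low-abundance and housekeeping genes
#'
#' NanoString-style background thresholding: a gene is retained if it is not a
#' housekeeping gene, not a negative control, and its mean count exceeds
#' `mean + k_sd * SD` of the negative-control counts. `k_sd = -Inf` disables
#' the abundance threshold (all non-housekeeping, non-control genes retained).
#'
#' @param x A counts [expression_matrix()] containing the negative-control rows.
#' @param genes A [gene_table()] aligned to `x` by symbol, with
#'   `is_housekeeping` and `is_negative_control` flags.
#' @param k_sd Number of negative-control SDs above the control mean required,
#'   default 2.
#' @return Character vector of retained gene ids in input order.
#' @export
filter_low_abundance <- function(x, genes, k_sd = 2) {
  stopifnot(inherits(x, "expression_matrix"))
  g <- genes[match(x$gene_ids, genes$symbol), ]
  if (any(is.na(g$symbol)))
    stop("gene table does not cover all matrix genes")
  neg <- which(g$is_negative_control)
  if (is.finite(k_sd) && !length(neg))
    stop("no negative-control genes present; abundance threshold needs them")
  gm <- rowMeans(x$values)
  thr <- if (is.finite(k_sd)) {
    ctl <- as.vector(x$values[neg, , drop = FALSE])
    mean(ctl) + k_sd * stats::sd(ctl)
  } else -Inf
  keep <- !g$is_housekeeping & !g$is_negative_control & gm > thr
  x$gene_ids[keep]
}

#' Empirical-Bayes batch correction
#'
#' Merges batches by the parametric location/scale model: per-gene
#' standardisation with the biological group (if given) protected in the
#' design; per-batch location effects shrunk toward a normal prior and scale
#' effects toward an inverse-gamma prior, both fit across genes by the method
#' of moments and solved iteratively; then back-transformation. All variances
#' use the maximum-likelihood (1/n) convention, so two identical batches are
#' returned unchanged to floating-point precision (the degenerate priors
#' collapse onto the observed effects and no shrinkage is applied).
#'
#' Genes constant across all samples cannot be standardised; their pooled
#' variance is floored with a warning and they pass through the adjustment
#' essentially unchanged.
#'
#' @param x A log-intensity [expression_matrix()].
#' @param batches Batch label per sample (length = n samples).
#' @param groups Optional biological group label per sample, protected during
#'   standardisation. Must not be confounded with batch.
#' @return A batch-adjusted [expression_matrix()].
#' @export
combat_adjust <- function(x, batches, groups = NULL) {
  stopifnot(inherits(x, "expression_matrix"))
  batches <- droplevels(as.factor(batches))
  if (length(batches) != length(x$sample_ids))
    stop("batches length does not match samples")
  if (nlevels(batches) < 2) stop("need at least 2 batches")
  sizes <- table(batches)
  if (any(sizes < 2))
    stop("batch(es) with a single sample: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  v <- x$values
  n <- ncol(v)
  nb <- nlevels(batches)
  batch_design <- stats::model.matrix(~ 0 + batches)
  design <- batch_design
  if (!is.null(groups)) {
    mod <- stats::model.matrix(~ as.factor(groups))[, -1, drop = FALSE]
    design <- cbind(batch_design, mod)
    if (qr(design)$rank < ncol(design))
      stop("group covariate is confounded with batch")
  }
  B <- t(solve(crossprod(design), crossprod(design, t(v))))  # genes x coefs
  n_i <- as.vector(sizes)
  grand <- as.vector(B[, seq_len(nb), drop = FALSE] %*% (n_i / n))
  stand_mean <- matrix(grand, nrow(v), n)
  if (!is.null(groups))
    stand_mean <- stand_mean +
      B[, -seq_len(nb), drop = FALSE] %*% t(design[, -seq_len(nb), drop = FALSE])
  resid <- v - t(design %*% t(B))
  var_pooled <- rowMeans(resid^2)                 # MLE convention throughout
  zero_var <- var_pooled == 0
  if (any(zero_var)) {
    warning(sum(zero_var), " gene(s) constant across samples: variance floored")
    var_pooled[zero_var] <- 1e-8
  }
  Z <- (v - stand_mean) / sqrt(var_pooled)

  adj <- Z
  for (b in levels(batches)) {
    cols <- which(batches == b)
    m <- length(cols)
    Zb <- Z[, cols, drop = FALSE]
    g_hat <- rowMeans(Zb)
    d_hat <- rowMeans((Zb - g_hat)^2)             # 1/n within-batch variance
    # method-of-moments priors across genes
    g_bar <- mean(g_hat); t2 <- stats::var(g_hat)
    D <- mean(d_hat); V <- stats::var(d_hat)
    degenerate_loc <- !is.finite(t2) || t2 < 1e-12
    degenerate_scale <- !is.finite(V) || V < 1e-12 || D < 1e-12
    if (degenerate_loc && degenerate_scale) {
      g_star <- g_hat
      d_star <- d_hat
    } else {
      a_prior <- (2 * V + D^2) / V
      b_prior <- (D * V + D^3) / V
      g_old <- g_hat
      d_old <- d_hat
      for (it in seq_len(200)) {
        g_new <- if (degenerate_loc) g_hat
                 else (t2 * m * g_hat + d_old * g_bar) / (t2 * m + d_old)
        sum2 <- rowSums((Zb - g_new)^2)
        d_new <- if (degenerate_scale) d_hat
                 else (0.5 * sum2 + b_prior) / (m / 2 + a_prior - 1)
        if (max(abs(g_new - g_old), abs(d_new - d_old)) < 1e-6) {
          g_old <- g_new; d_old <- d_new; break
        }
        g_old <- g_new; d_old <- d_new
      }
      g_star <- g_old
      d_star <- pmax(d_old, 1e-12)
    }
    adj[, cols] <- (Zb - g_star) / sqrt(d_star)
  }
  out <- adj * sqrt(var_pooled) + stand_mean
  expression_matrix(out, gene_ids = x$gene_ids, sample_ids = x$sample_ids,
                    value_kind = "log_intensity")
}

#' Impute sex from Y-chromosome expression
#'
#' Subsets the matrix to Y-chromosome genes, performs PCA on the centred
#' sample profiles and k-means (k = 2, seeded multiple restarts) on the first
#' two principal components. The cluster with higher mean Y expression is
#' labelled male.
#'
#' @param x An [expression_matrix()] (log scale recommended).
#' @param genes A [gene_table()] with a `chromosome` column; rows with
#'   `chromosome == "Y"` define the Y gene set.
#' @param seed Integer seed for the k-means restarts.
#' @param nstart Number of k-means restarts, default 10.
#' @return A list with `sex` (named character vector, per sample),
#'   `separation` (between-cluster sum of squares over total, a diagnostic in
#'   `[0, 1]`), and `y_genes` used.
#' @export
impute_sex <- function(x, genes, seed = 1, nstart = 10) {
  stopifnot(inherits(x, "expression_matrix"))
  y_genes <- intersect(x$gene_ids, genes$symbol[genes$chromosome %in% "Y"])
  if (length(y_genes) < 2) stop("need at least 2 Y-chromosome genes")
  if (length(x$sample_ids) < 4) stop("need at least 4 samples")
  ym <- t(x$values[y_genes, , drop = FALSE])       # samples x Y genes
  ym_c <- scale(ym, center = TRUE, scale = FALSE)
  if (all(abs(ym_c) < 1e-12)) stop("degenerate clustering: all samples identical")
  pc <- stats::prcomp(ym_c, center = FALSE)
  k <- min(2, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  km <- withr::with_seed(as.integer(seed),
                         stats::kmeans(scores, centers = 2, nstart = nstart))
  if (any(km$size == 0)) stop("degenerate clustering: empty cluster")
  mean_y <- tapply(rowMeans(ym), km$cluster, mean)
  male_cluster <- as.integer(names(which.max(mean_y)))
  sex <- ifelse(km$cluster == male_cluster, "male", "female")
  names(sex) <- x$sample_ids
  list(sex = sex, separation = km$betweenss / km$totss, y_genes = y_genes)
}
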
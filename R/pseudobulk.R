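#' Library-size normalise and log-transform single-cell counts
#'
#' Per cell: `log2(count / libsize * scale_factor + 1)`. Sparse zeros stay
#' zero, so the result remains sparse. The default scale factor is the median
#' library size across cells; set `scale_factor = 1e4` for the fixed-factor
#' convention.
#'
#' @param dataset A [single_cell_dataset()].
#' @param scale_factor Positive scalar, or `NULL` (default) for the median
#'   library size.
#' @return The dataset with an added sparse `logcounts` element (cells x
#'   genes) and the `scale_factor` used.
#' @export
normalize_cells <- function(dataset, scale_factor = NULL) {
  stopifnot(inherits(dataset, "single_cell_dataset"))
  lib <- Matrix::rowSums(dataset$counts)
  zero <- lib == 0
  if (any(zero))
    stop("cell(s) with zero library size: ",
         paste(utils::head(dataset$cell_data$cell_id[zero], 5), collapse = ", "))
  if (is.null(scale_factor)) scale_factor <- stats::median(lib)
  scaled <- Matrix::Diagonal(x = scale_factor / lib) %*% dataset$counts
  scaled@x <- log2(scaled@x + 1)
  dataset$logcounts <- methods::as(scaled, "CsparseMatrix")
  dimnames(dataset$logcounts) <- dimnames(dataset$counts)
  dataset$scale_factor <- scale_factor
  dataset
}

#' Pseudobulk mean expression per cell type and sample
#'
#' Averages normalised logcounts over all cells in each (cell type, sample)
#' stratum. Strata with fewer than `min_cells` cells are dropped and reported.
#'
#' @param dataset A normalised [single_cell_dataset()] (see
#'   [normalize_cells()]).
#' @param cell_type_col,sample_col Names of the annotation columns defining
#'   the strata.
#' @param min_cells Minimum cells per retained stratum, default 10.
#' @return A list: `means` (strata x genes dense matrix), `strata` (data.frame
#'   `cell_type`, `sample_id`, `n_cells` per retained row), `dropped`
#'   (data.frame of dropped strata with their cell counts).
#' @export
pseudobulk_mean <- function(dataset, cell_type_col = "cell_type",
                            sample_col = "sample_id", min_cells = 10) {
  stopifnot(inherits(dataset, "single_cell_dataset"))
  if (is.null(dataset$logcounts)) stop("run normalize_cells() first")
  ct <- dataset$cell_data[[cell_type_col]]
  sm <- dataset$cell_data[[sample_col]]
  if (is.null(ct) || is.null(sm))
    stop("annotation columns not found: ", cell_type_col, ", ", sample_col)
  key <- paste(ct, sm, sep = "\r")
  f <- factor(key, levels = unique(key))
  ind <- Matrix::fac2sparse(f)                     # strata x cells
  n_cells <- Matrix::rowSums(ind)
  means <- as.matrix(ind %*% dataset$logcounts) / n_cells
  parts <- do.call(rbind, strsplit(levels(f), "\r", fixed = TRUE))
  strata <- data.frame(cell_type = parts[, 1], sample_id = parts[, 2],
                       n_cells = as.integer(n_cells), stringsAsFactors = FALSE)
  keep <- strata$n_cells >= min_cells
  if (any(!keep))
    message(sum(!keep), " stratum/strata dropped below min_cells = ", min_cells)
  list(means = means[keep, , drop = FALSE],
       strata = strata[keep, , drop = FALSE],
       dropped = strata[!keep, , drop = FALSE])
}

#' Moderated linear-model fit with empirical-Bayes variance shrinkage
#'
#' Per gene: ordinary least squares on the given design; residual variances
#' are shrunk toward a prior fitted by moment-matching the scaled-F
#' distribution of the sample variances (with `trend = TRUE` the prior
#' variance follows average expression via a locally weighted fit). The
#' moderated t uses the posterior variance
#' `s2_post = (d0 s0^2 + d s^2) / (d0 + d)` on `d0 + d` degrees of freedom.
#' `d0_override` forces the prior df: 0 recovers the ordinary t, `Inf` the
#' complete-pooling t with the common (or trended) prior variance.
#'
#' @param y Genes x samples matrix of (pseudobulk) log-expression.
#' @param design Design matrix, samples x coefficients, full rank.
#' @param coef Name or index of the coefficient to test (default the last).
#' @param trend Logical; intensity-dependent prior variance, default `FALSE`.
#' @param d0_override Optional forced prior df (0, finite, or `Inf`).
#' @return A data.frame per gene: `gene`, `coef` (log2 fold change), `t`, `p`,
#'   `df_total`, `s2_post`, `avg_expr`. Genes constant across all samples get
#'   `NA` statistics and are flagged in the `degenerate` column.
#' @export
moderated_fit <- function(y, design, coef = ncol(design), trend = FALSE,
                          d0_override = NULL) {
  y <- as.matrix(y)
  design <- as.matrix(design)
  if (qr(design)$rank < ncol(design)) stop("design matrix is rank deficient")
  n <- ncol(y)
  df_resid <- n - ncol(design)
  if (df_resid < 1) stop("no residual degrees of freedom")
  qrd <- qr(design)
  coefs <- t(qr.coef(qrd, t(y)))
  fitted <- t(qr.fitted(qrd, t(y)))
  res <- y - fitted
  s2 <- rowSums(res^2) / df_resid
  xtxi <- chol2inv(chol(crossprod(design)))
  cidx <- if (is.character(coef)) match(coef, colnames(design)) else coef
  v_coef <- xtxi[cidx, cidx]
  avg <- rowMeans(y)
  degenerate <- apply(y, 1, function(r) all(r == r[1]))

  ok <- !degenerate
  s2ok <- s2[ok]
  if (is.null(d0_override)) {
    sq <- limma::squeezeVar(s2ok, df = df_resid,
                            covariate = if (trend) avg[ok] else NULL)
    s2_post <- sq$var.post
    d0 <- sq$df.prior
  } else if (identical(d0_override, 0) || identical(d0_override, 0L)) {
    s2_post <- s2ok
    d0 <- 0
  } else if (is.infinite(d0_override)) {
    s0 <- limma::squeezeVar(s2ok, df = df_resid,
                            covariate = if (trend) avg[ok] else NULL)$var.prior
    s2_post <- rep_len(s0, length(s2ok))
    d0 <- Inf
  } else {
    s0 <- limma::squeezeVar(s2ok, df = df_resid,
                            covariate = if (trend) avg[ok] else NULL)$var.prior
    s2_post <- (d0_override * s0 + df_resid * s2ok) / (d0_override + df_resid)
    d0 <- d0_override
  }
  tstat <- rep(NA_real_, nrow(y))
  pval <- rep(NA_real_, nrow(y))
  s2p_all <- rep(NA_real_, nrow(y))
  tstat[ok] <- coefs[ok, cidx] / sqrt(s2_post * v_coef)
  # cap the total df at the pooled residual df across genes
  df_total <- min(df_resid + d0, df_resid * sum(ok))
  pval[ok] <- 2 * stats::pt(-abs(tstat[ok]), df = df_total)
  s2p_all[ok] <- s2_post
  data.frame(
    gene = if (is.null(rownames(y))) as.character(seq_len(nrow(y))) else rownames(y),
    coef = coefs[, cidx], t = tstat, p = pval,
    df_total = ifelse(ok, df_total, NA_real_),
    s2_post = s2p_all, avg_expr = avg, degenerate = degenerate,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Benjamini-Hochberg adjusted p-values
#'
#' @param p Numeric vector of p-values.
#' @return BH q-values (monotone step-up adjustment).
#' @export
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")

#' Cell-type-specific differential expression of biomarkers
#'
#' For each cell type within the chosen disease group: normalise, pseudobulk
#' by (cell type, sample), fit the condition contrast (allergen vs baseline)
#' with [moderated_fit()] (trend on), restrict to the biomarker genes, apply
#' BH within the cell type's biomarker list, and flag significance at
#' `q < fdr`.
#'
#' @param dataset A [single_cell_dataset()] with annotations `cell_type`,
#'   `sample_id`, `condition` (`"baseline"` / `"allergen"`) and `group`.
#' @param biomarkers Character vector of biomarker gene symbols.
#' @param group Disease group to analyse (e.g. `"allergic_asthma"`); `NULL`
#'   uses all cells.
#' @param fdr BH-FDR threshold, default 0.20.
#' @param min_cells Minimum cells per pseudobulk stratum, default 10.
#' @param cell_type_col Annotation column defining the cell-type tier
#'   (`"cell_type"` or a subtype column).
#' @param scale_factor Passed to [normalize_cells()].
#' @return A list (`de_result`): `table` (per cell type x biomarker: `log2fc`,
#'   `t`, `p`, `q`, `significant`, `direction`), and `summary` (per cell type:
#'   counts of significant up/down biomarkers). Cell types present in only one
#'   condition are skipped with a message.
#' @export
de_by_celltype <- function(dataset, biomarkers, group = NULL, fdr = 0.20,
                           min_cells = 10, cell_type_col = "cell_type",
                           scale_factor = NULL) {
  stopifnot(inherits(dataset, "single_cell_dataset"))
  cd <- dataset$cell_data
  if (!is.null(group)) {
    keep <- cd$group == group
    dataset <- single_cell_dataset(dataset$counts[keep, , drop = FALSE],
                                   cd[keep, , drop = FALSE],
                                   gene_ids = dataset$gene_ids)
    cd <- dataset$cell_data
  }
  dataset <- normalize_cells(dataset, scale_factor = scale_factor)
  # condition must be carried onto the pseudobulk strata via the sample id
  cond_of_sample <- unique(cd[, c("sample_id", "condition")])
  if (anyDuplicated(cond_of_sample$sample_id))
    stop("a sample_id maps to more than one condition")
  pb <- pseudobulk_mean(dataset, cell_type_col = cell_type_col,
                        sample_col = "sample_id", min_cells = min_cells)
  bio <- intersect(biomarkers, dataset$gene_ids)
  if (!length(bio)) stop("no biomarker genes present in the dataset")
  tabs <- list()
  for (ct in unique(pb$strata$cell_type)) {
    rows <- which(pb$strata$cell_type == ct)
    cond <- cond_of_sample$condition[match(pb$strata$sample_id[rows],
                                           cond_of_sample$sample_id)]
    if (length(unique(cond)) < 2 || min(table(cond)) < 2) {
      message("cell type '", ct, "' skipped: need both conditions (>=2 samples each)")
      next
    }
    y <- t(pb$means[rows, , drop = FALSE])         # genes x samples
    design <- stats::model.matrix(~ factor(cond, levels = c("baseline", "allergen")))
    fit <- moderated_fit(y, design, coef = 2, trend = TRUE)
    fit <- fit[fit$gene %in% bio & !fit$degenerate, , drop = FALSE]
    if (!nrow(fit)) next
    fit$q <- bh_adjust(fit$p)
    tabs[[ct]] <- data.frame(
      cell_type = ct, gene = fit$gene, log2fc = fit$coef, t = fit$t,
      p = fit$p, q = fit$q, significant = fit$q < fdr,
      direction = ifelse(fit$coef > 0, "up", "down"),
      stringsAsFactors = FALSE
    )
  }
  if (!length(tabs)) stop("no cell type had both conditions")
  table <- do.call(rbind, tabs)
  rownames(table) <- NULL
  summary <- do.call(rbind, lapply(split(table, table$cell_type), function(d)
    data.frame(cell_type = d$cell_type[1],
               n_tested = nrow(d),
               n_sig_up = sum(d$significant & d$direction == "up"),
               n_sig_down = sum(d$significant & d$direction == "down"),
               stringsAsFactors = FALSE)))
  rownames(summary) <- NULL
  structure(list(table = table, summary = summary, fdr = fdr),
            class = "de_result")
}

#' Up/down signature sets from a DE result
#'
#' @param de A `de_result` from [de_by_celltype()].
#' @return A list with `up` and `down`: named lists (per cell type) of
#'   significant biomarker symbols in each direction.
#' @export
signature_sets <- function(de) {
  sig <- de$table[de$table$significant, , drop = FALSE]
  split_dir <- function(dir) {
    d <- sig[sig$direction == dir, , drop = FALSE]
    sets <- split(d$gene, d$cell_type)
    sets[lengths(sets) > 0]
  }
  list(up = split_dir("up"), down = split_dir("down"))
}
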
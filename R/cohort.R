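#' Enumerate the model grid
#'
#' Full Cartesian product of evaluation axes (dataset/sample type, comparison,
#' panel, sex stratum, classifier, ...), in deterministic order: axes vary
#' slowest-first in their declared order, levels in their declared order.
#'
#' @param axes Named list of non-empty character vectors.
#' @return A data.frame with one row per grid cell and one column per axis.
#' @export
enumerate_grid <- function(axes) {
  if (!length(axes) || is.null(names(axes))) stop("axes must be a named list")
  if (any(lengths(axes) == 0))
    stop("empty axis: ", paste(names(axes)[lengths(axes) == 0], collapse = ", "))
  grid <- rev(expand.grid(rev(axes), stringsAsFactors = FALSE,
                          KEEP.OUT.ATTRS = FALSE))
  grid[names(axes)]
}

#' Evaluate one model-grid cell
#'
#' Subsets the expression matrix to the cell's comparison groups and sex
#' stratum, restricts genes to the cell's panel, and runs repeated stratified
#' cross-validation with the cell's classifier (`plsda`: dense 2-component
#' PLS-DA; `random_forest`: 500-tree ranger ensemble with sqrt(p) features per
#' split and impurity importance). Importance scores come from a refit on the
#' full cell data (VIP for PLS-DA, node-purity for the forest).
#'
#' @param x A log-intensity [expression_matrix()].
#' @param samples A [sample_table()] aligned to `x` (matched on `sample_id`).
#' @param cell A one-row data.frame (or list) with `comparison` (two group
#'   labels separated by `" vs "`), `stratum` (`"male"`, `"female"`,
#'   `"combined"`), `classifier` (`"plsda"` or `"random_forest"`), and the
#'   panel genes in `panel_genes` (character vector, possibly in a list
#'   column).
#' @param repeats,folds CV geometry, defaults 20 x 5.
#' @param seed Master seed.
#' @param min_per_class Minimum class size (per fold count) below which the
#'   cell is skipped; skipped cells return `NULL` with a message.
#' @return A list (`eval_result`): the cell fields plus `mean_auc`, `sd_auc`,
#'   `importance` (named numeric), `n_samples`, `genes_used`,
#'   `frac_panel_present`; or `NULL` if the cell is infeasible.
#' @export
evaluate_cell <- function(x, samples, cell, repeats = 20, folds = 5, seed = 1,
                          min_per_class = NULL) {
  stopifnot(inherits(x, "expression_matrix"))
  cell <- as.list(cell)
  panel <- unlist(cell$panel_genes, use.names = FALSE)
  groups <- strsplit(cell$comparison, " vs ", fixed = TRUE)[[1]]
  if (length(groups) != 2) stop("comparison must be 'groupA vs groupB'")
  present <- intersect(panel, x$gene_ids)
  frac <- length(present) / length(panel)
  if (frac < 0.5)
    stop("fewer than 50% of panel genes present; missing: ",
         paste(utils::head(setdiff(panel, x$gene_ids), 10), collapse = ", "))
  if (frac < 1)
    message(sprintf("%.0f%% of panel genes present; %d dropped",
                    100 * frac, length(panel) - length(present)))
  meta <- samples[match(x$sample_ids, samples$sample_id), ]
  keep <- meta$group %in% groups
  if (!identical(cell$stratum, "combined")) keep <- keep & meta$sex == cell$stratum
  if (is.null(min_per_class)) min_per_class <- folds
  y <- factor(meta$group[keep], levels = groups)
  if (any(table(y) < min_per_class)) {
    message("cell skipped: class sizes ", paste(table(y), collapse = "/"),
            " below ", min_per_class)
    return(NULL)
  }
  Xc <- t(x$values[present, keep, drop = FALSE])
  ok <- apply(Xc, 2, stats::sd) > 0
  Xc <- Xc[, ok, drop = FALSE]

  fit_fun <- switch(cell$classifier,
    plsda = function(Xtr, ytr) {
      okc <- apply(Xtr, 2, stats::sd) > 0
      fit <- fit_splsda(Xtr[, okc, drop = FALSE], ytr, ncomp = 2,
                        keepX = sum(okc))
      list(fit = fit, cols = okc)
    },
    random_forest = function(Xtr, ytr) {
      fit <- ranger::ranger(x = Xtr, y = ytr, num.trees = 500,
                            mtry = max(1, floor(sqrt(ncol(Xtr)))),
                            importance = "impurity", probability = TRUE,
                            seed = as.integer(seed), num.threads = 1)
      list(fit = fit, cols = rep(TRUE, ncol(Xtr)))
    },
    stop("unknown classifier: ", cell$classifier))
  score_fun <- switch(cell$classifier,
    plsda = function(m, Xte) predict_scores(m$fit, Xte[, m$cols, drop = FALSE]),
    random_forest = function(m, Xte)
      stats::predict(m$fit, data = Xte, num.threads = 1)$predictions[, levels(y)[2]])

  aucs <- numeric(repeats)
  for (r in seq_len(repeats)) {
    fold <- withr::with_seed(as.integer(seed) + r, stratified_folds(y, folds))
    scores <- numeric(length(y))
    for (f in seq_len(folds)) {
      test <- fold == f
      m <- fit_fun(Xc[!test, , drop = FALSE], y[!test])
      scores[test] <- score_fun(m, Xc[test, , drop = FALSE])
    }
    aucs[r] <- auc_score(scores, y)
  }
  full <- fit_fun(Xc, y)
  imp <- if (cell$classifier == "plsda") vip(full$fit)
         else ranger::importance(full$fit)
  structure(
    c(cell[setdiff(names(cell), "panel_genes")],
      list(mean_auc = mean(aucs), sd_auc = stats::sd(aucs), importance = imp,
           n_samples = length(y), genes_used = colnames(Xc),
           frac_panel_present = frac)),
    class = "eval_result"
  )
}

#' Percentage rank of importance scores
#'
#' Maps importances to `[0, 1]`: the highest score gets rank 1, the lowest 0,
#' intermediate features are spaced by their ascending sort position over
#' `n - 1`; ties receive the mean of their positions' ranks.
#'
#' @param importances Named numeric vector, length >= 2.
#' @return Named numeric vector of ranks in `[0, 1]`.
#' @export
percentage_rank <- function(importances) {
  n <- length(importances)
  if (n < 2) stop("need at least 2 features")
  (rank(importances, ties.method = "average") - 1) / (n - 1)
}

#' Aggregate biomarker importance ranks across qualifying models
#'
#' Filters evaluation results to those with mean AUC above `auc_min`, converts
#' each qualifying model's importances to percentage ranks, and averages each
#' biomarker's rank over the qualifying models whose panel contains it.
#'
#' @param results List of `eval_result` objects (NULL entries are ignored).
#' @param auc_min AUC filter (exclusive), default 0.70.
#' @return A data.frame `biomarker`, `mean_rank`, `n_models`, sorted by
#'   decreasing mean rank (stable for ties); zero rows if nothing qualifies.
#' @export
aggregate_ranks <- function(results, auc_min = 0.70) {
  results <- Filter(Negate(is.null), results)
  qual <- Filter(function(r) r$mean_auc > auc_min, results)
  if (!length(qual))
    return(data.frame(biomarker = character(0), mean_rank = numeric(0),
                      n_models = integer(0), stringsAsFactors = FALSE))
  ranks <- lapply(qual, function(r) percentage_rank(r$importance))
  genes <- sort(unique(unlist(lapply(ranks, names))))
  tab <- vapply(genes, function(g) {
    v <- unlist(lapply(ranks, function(rk) rk[g]))
    v <- v[!is.na(v)]
    c(mean_rank = mean(v), n_models = length(v))
  }, numeric(2))
  out <- data.frame(biomarker = genes, mean_rank = tab["mean_rank", ],
                    n_models = as.integer(tab["n_models", ]),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-out$mean_rank), , drop = FALSE]
}
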
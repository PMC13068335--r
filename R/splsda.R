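#' Fit a sparse PLS discriminant analysis model
#'
#' Two-class sPLSDA by NIPALS with per-component variable selection. Columns
#' of `X` are centred and unit-scaled; the class factor is dummy-coded (one
#' column per class) and centred. Per component the dominant left singular
#' vector of `t(X) %*% Y` is sparsified by magnitude-ranked soft-thresholding
#' so that exactly `keepX[h]` weights remain nonzero, renormalised to unit
#' norm; scores are `t = X w`, `X` is deflated by `t p'` (Y is not deflated).
#'
#' @param X Numeric samples x genes matrix with column names.
#' @param y Two-level factor (or coercible); the second level is the positive
#'   class.
#' @param ncomp Number of components, default 2.
#' @param keepX Integer vector (recycled to `ncomp`) of variables to retain
#'   per component; `keepX = ncol(X)` gives dense PLS-DA.
#' @return An object of class `splsda_model` with weights `W`, loadings `P`,
#'   y-loadings `Q`, scores `T`, scaling parameters and class levels.
#' @export
fit_splsda <- function(X, y, ncomp = 2, keepX = ncol(X)) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  y <- factor(y)
  if (nlevels(y) != 2) stop("y must have exactly two classes")
  keepX <- rep_len(as.integer(keepX), ncomp)
  if (any(keepX > ncol(X))) stop("keepX exceeds the number of genes")
  if (any(keepX < 1)) stop("keepX must be >= 1")
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  if (any(scl == 0))
    stop("constant gene column(s): ",
         paste(utils::head(colnames(X)[scl == 0], 5), collapse = ", "))
  Xs <- scale(X, center = ctr, scale = scl)
  Y <- stats::model.matrix(~ 0 + y)
  colnames(Y) <- levels(y)
  Ys <- scale(Y, center = TRUE, scale = FALSE)

  n <- nrow(Xs); p <- ncol(Xs)
  W <- P <- matrix(0, p, ncomp, dimnames = list(colnames(X), NULL))
  Q <- matrix(0, ncol(Y), ncomp, dimnames = list(levels(y), NULL))
  Tm <- matrix(0, n, ncomp)
  Xh <- Xs
  for (h in seq_len(ncomp)) {
    M <- crossprod(Xh, Ys)
    sv <- svd(M, nu = 1, nv = 0)
    w <- sv$u[, 1]
    # deterministic sign: largest-magnitude weight is positive
    w <- w * sign(w[which.max(abs(w))])
    k <- keepX[h]
    if (k < p) {
      aw <- abs(w)
      ord <- order(aw, decreasing = TRUE)   # stable: ties keep earlier genes
      thr <- aw[ord[k + 1L]]
      w_soft <- sign(w) * pmax(aw - thr, 0)
      # exact keepX under ties: zero everything outside the top-k positions
      w_soft[-ord[seq_len(k)]] <- 0
      if (all(w_soft == 0)) { # fully tied block: fall back to hard selection
        w_soft[ord[seq_len(k)]] <- w[ord[seq_len(k)]]
      }
      w <- w_soft
    }
    w <- w / sqrt(sum(w^2))
    t_h <- as.vector(Xh %*% w)
    tt <- sum(t_h^2)
    P[, h] <- as.vector(crossprod(Xh, t_h)) / tt
    Q[, h] <- as.vector(crossprod(Ys, t_h)) / tt
    Tm[, h] <- t_h
    W[, h] <- w
    Xh <- Xh - tcrossprod(t_h, P[, h])
  }
  structure(
    list(ncomp = ncomp, keepX = keepX, W = W, P = P, Q = Q, T = Tm,
         center = ctr, scale = scl, levels = levels(y),
         positive = levels(y)[2]),
    class = "splsda_model"
  )
}

#' @export
print.splsda_model <- function(x, ...) {
  cat(sprintf("<splsda_model> %d genes, %d comps, keepX = %s, positive class '%s'\n",
              nrow(x$W), x$ncomp, paste(x$keepX, collapse = "/"), x$positive))
  invisible(x)
}

#' Genes selected by an sPLSDA model
#'
#' @param model A fitted `splsda_model`.
#' @param comp Components to include (default all).
#' @return Character vector of genes with a nonzero weight on any requested
#'   component, ordered by first appearance component-wise and by weight
#'   magnitude within a component.
#' @export
panel_genes <- function(model, comp = seq_len(model$ncomp)) {
  out <- character(0)
  for (h in comp) {
    w <- model$W[, h]
    sel <- names(sort(abs(w[w != 0]), decreasing = TRUE))
    out <- c(out, setdiff(sel, out))
  }
  out
}

#' Continuous discriminant scores for new samples
#'
#' Applies the stored centring/scaling, projects onto the model components via
#' the projection weights `W* = W (P'W)^{-1}`, and returns the regression
#' prediction for the positive-class dummy column. Positive scores favour the
#' positive class; a sample at the training mean scores 0.
#'
#' @param model A fitted `splsda_model`.
#' @param X_new Samples x genes matrix containing the model's genes.
#' @return Numeric vector of scores, one per row of `X_new`.
#' @export
predict_scores <- function(model, X_new) {
  X_new <- as.matrix(X_new)
  if (is.null(colnames(X_new))) {
    if (ncol(X_new) != nrow(model$W)) stop("X_new genes do not match the model")
    colnames(X_new) <- rownames(model$W)
  }
  missing <- setdiff(rownames(model$W), colnames(X_new))
  if (length(missing))
    stop("missing genes: ", paste(utils::head(missing, 5), collapse = ", "))
  Xs <- scale(X_new[, rownames(model$W), drop = FALSE],
              center = model$center, scale = model$scale)
  Wstar <- model$W %*% solve(crossprod(model$P, model$W))
  Tn <- Xs %*% Wstar
  Yhat <- Tn %*% t(model$Q)
  as.vector(Yhat[, model$positive])
}

#' Variable importance in projection
#'
#' `VIP_j = sqrt( p * sum_h SS_h w_jh^2 / sum_h SS_h )` with
#' `SS_h = (t_h' t_h) * sum(q_h^2)` and unit-norm `w_h`. The mean of `VIP^2`
#' over genes is exactly 1.
#'
#' @param model A fitted `splsda_model`.
#' @return Named numeric vector of VIP scores per gene.
#' @export
vip <- function(model) {
  p <- nrow(model$W)
  ss <- vapply(seq_len(model$ncomp), function(h)
    sum(model$T[, h]^2) * sum(model$Q[, h]^2), numeric(1))
  num <- as.vector((model$W^2) %*% ss)
  stats::setNames(sqrt(p * num / sum(ss)), rownames(model$W))
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC of continuous scores against two-class
#' labels; ties in scores receive mid-rank credit.
#'
#' @param scores Numeric scores, higher = more positive-class.
#' @param labels Two-level factor; second level is positive.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  labels <- factor(labels)
  if (nlevels(labels) != 2) stop("labels must have two classes")
  pos <- labels == levels(labels)[2]
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Stratified fold assignment
#'
#' @param y Factor of class labels.
#' @param folds Number of folds.
#' @return Integer fold id per sample; within each class, fold sizes differ by
#'   at most one.
#' @keywords internal
stratified_folds <- function(y, folds) {
  y <- factor(y)
  if (any(table(y) < folds)) stop("a class is too small to stratify into ", folds, " folds")
  fold <- integer(length(y))
  for (lv in levels(y)) {
    idx <- which(y == lv)
    fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  fold
}

#' Repeated stratified cross-validated AUC over a keepX grid
#'
#' For every keepX configuration, runs `repeats` independent rounds of
#' stratified `folds`-fold cross-validation: the model is fitted on the
#' training folds, test folds are scored, and the AUC of each repeat is
#' computed from that repeat's pooled test scores. Repeat `r` draws its fold
#' assignment under `seed + r`, so results are deterministic given `seed` and
#' each repeat is independently reproducible.
#'
#' @param X Samples x genes matrix.
#' @param y Two-level factor.
#' @param keepX_grid List of keepX vectors (each recycled to `ncomp`), or a
#'   numeric vector treated as one single-value configuration each.
#' @param ncomp Components per model, default 2.
#' @param repeats,folds CV geometry, defaults 20 x 5.
#' @param seed Master seed.
#' @return A data.frame (class `cv_tuning`): one row per configuration with
#'   `config`, `keepX`, `n_transcripts`, `mean_auc`, `sd_auc`.
#' @export
repeated_cv_auc <- function(X, y, keepX_grid, ncomp = 2, repeats = 20,
                            folds = 5, seed = 1) {
  X <- as.matrix(X)
  y <- droplevels(factor(y))
  if (nlevels(y) < 2) stop("need two classes to stratify cross-validation")
  if (!is.list(keepX_grid)) keepX_grid <- as.list(keepX_grid)
  keepX_grid <- lapply(keepX_grid, function(k) rep_len(as.integer(k), ncomp))
  cfg_names <- vapply(keepX_grid, paste, character(1), collapse = "+")
  aucs <- matrix(NA_real_, length(keepX_grid), repeats)
  for (r in seq_len(repeats)) {
    fold <- withr::with_seed(as.integer(seed) + r, stratified_folds(y, folds))
    scores <- matrix(NA_real_, length(keepX_grid), length(y))
    for (f in seq_len(folds)) {
      test <- fold == f
      for (i in seq_along(keepX_grid)) {
        # drop genes constant in the training split rather than failing a fold
        Xtr <- X[!test, , drop = FALSE]
        ok <- apply(Xtr, 2, stats::sd) > 0
        kx <- pmin(keepX_grid[[i]], sum(ok))
        fit <- fit_splsda(Xtr[, ok, drop = FALSE], y[!test], ncomp = ncomp, keepX = kx)
        scores[i, test] <- predict_scores(fit, X[test, ok, drop = FALSE])
      }
    }
    for (i in seq_along(keepX_grid)) aucs[i, r] <- auc_score(scores[i, ], y)
  }
  out <- data.frame(
    config = cfg_names,
    n_transcripts = vapply(keepX_grid, sum, integer(1)),
    mean_auc = rowMeans(aucs),
    sd_auc = apply(aucs, 1, stats::sd),
    stringsAsFactors = FALSE
  )
  out$keepX <- keepX_grid
  class(out) <- c("cv_tuning", class(out))
  out
}

#' Select the biomarker panel configuration
#'
#' Among configurations with mean AUC above the threshold, picks the one with
#' the fewest transcripts; ties are broken by higher mean AUC, then lower SD.
#'
#' @param tuning A `cv_tuning` table from [repeated_cv_auc()].
#' @param auc_threshold Minimum mean AUC (exclusive), default 0.70.
#' @return The chosen row of `tuning` (single-row data.frame), or `NULL` if no
#'   configuration qualifies.
#' @export
select_panel <- function(tuning, auc_threshold = 0.70) {
  ok <- tuning[tuning$mean_auc > auc_threshold, , drop = FALSE]
  if (!nrow(ok)) return(NULL)
  ord <- order(ok$n_transcripts, -ok$mean_auc, ok$sd_auc)
  ok[ord[1], , drop = FALSE]
}

#' Merge biomarker panels
#'
#' Union of panel gene symbols preserving first-appearance order, with the
#' total slot count (sum of panel sizes) and the pairwise overlap matrix.
#'
#' @param panels Named list of character vectors (each a panel, no duplicate
#'   symbols within a panel).
#' @return A list: `panel` (unique symbols), `n_unique`, `slots`, `overlap`
#'   (panels x panels intersection counts; diagonal = panel sizes).
#' @export
merge_panels <- function(panels) {
  if (!length(panels)) stop("need at least one panel")
  if (is.null(names(panels))) names(panels) <- paste0("panel", seq_along(panels))
  for (nm in names(panels))
    if (anyDuplicated(panels[[nm]]))
      stop("panel '", nm, "' contains duplicate symbols")
  combined <- unique(unlist(panels, use.names = FALSE))
  k <- length(panels)
  ov <- matrix(0L, k, k, dimnames = list(names(panels), names(panels)))
  for (i in seq_len(k)) for (j in seq_len(k))
    ov[i, j] <- length(intersect(panels[[i]], panels[[j]]))
  list(panel = combined, n_unique = length(combined),
       slots = sum(lengths(panels)), overlap = ov)
}
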
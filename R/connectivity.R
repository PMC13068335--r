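#' Ranking score for a drug signature entry
#'
#' `s = log2fc * (-log10 p)`: combines effect size and evidence so that
#' strongly induced, well-supported genes rank at the top of a drug's list
#' and strongly repressed ones at the bottom.
#'
#' @param log2fc Log2 fold change vs vehicle.
#' @param p Two-sided p-value in `(0, 1]`.
#' @return The ranking score (vectorised).
#' @export
ranking_score <- function(log2fc, p) {
  if (any(p <= 0 | p > 1)) stop("p must be in (0, 1]")
  log2fc * (-log10(p))
}

#' Build per-cell-type drug signatures from a perturbation screen
#'
#' Normalises, pseudobulks per (cell type, compound, donor), then per cell
#' type fits one moderated linear model per gene with a compound-indicator
#' design (vehicle as reference): coefficients are log2 fold changes vs
#' vehicle, with moderated two-sided p-values and the ranking score
#' `log2fc * (-log10 p)` per gene.
#'
#' @param dataset A [single_cell_dataset()] with annotations `cell_type`,
#'   `compound`, `donor`.
#' @param vehicle Label of the vehicle/negative control, default `"DMSO"`.
#' @param min_cells Minimum cells per pseudobulk stratum, default 5.
#' @param trend Use an intensity-dependent variance prior, default `TRUE`.
#' @param scale_factor Passed to [normalize_cells()].
#' @return A list (`drug_signatures`): `table` (per cell_type x compound x
#'   gene: `log2fc`, `p`, `score`), `cell_types`, `compounds`, `missing`
#'   (compound/cell-type combinations absent from the screen).
#' @export
build_drug_signatures <- function(dataset, vehicle = "DMSO", min_cells = 5,
                                  trend = TRUE, scale_factor = NULL) {
  stopifnot(inherits(dataset, "single_cell_dataset"))
  cd <- dataset$cell_data
  for (col in c("cell_type", "compound", "donor"))
    if (is.null(cd[[col]])) stop("annotation column missing: ", col)
  if (!vehicle %in% cd$compound) stop("vehicle '", vehicle, "' absent from screen")
  dataset$cell_data$pb_unit <- paste(cd$compound, cd$donor, sep = "||")
  dataset <- normalize_cells(dataset, scale_factor = scale_factor)
  pb <- pseudobulk_mean(dataset, cell_type_col = "cell_type",
                        sample_col = "pb_unit", min_cells = min_cells)
  unit <- do.call(rbind, strsplit(pb$strata$sample_id, "||", fixed = TRUE))
  pb$strata$compound <- unit[, 1]
  pb$strata$donor <- unit[, 2]

  tabs <- list()
  missing <- list()
  for (ct in unique(pb$strata$cell_type)) {
    rows <- which(pb$strata$cell_type == ct)
    comp <- pb$strata$compound[rows]
    if (sum(comp == vehicle) < 2) stop("cell type '", ct,
                                       "': need >= 2 vehicle pseudobulk replicates")
    lv <- c(vehicle, sort(setdiff(unique(comp), vehicle)))
    f <- factor(comp, levels = lv)
    design <- stats::model.matrix(~ f)
    colnames(design) <- c("(Intercept)", lv[-1])
    y <- t(pb$means[rows, , drop = FALSE])
    # one multi-coefficient fit; extract each compound's contrast column
    for (cmp in lv[-1]) {
      fit <- moderated_fit(y, design, coef = cmp, trend = trend)
      fit <- fit[!fit$degenerate, , drop = FALSE]
      p_floor <- pmax(fit$p, 1e-300)
      tabs[[length(tabs) + 1L]] <- data.frame(
        cell_type = ct, compound = cmp, gene = fit$gene,
        log2fc = fit$coef, p = fit$p,
        score = ranking_score(fit$coef, p_floor),
        stringsAsFactors = FALSE
      )
    }
    absent <- setdiff(unique(pb$strata$compound), c(lv, vehicle))
    if (length(absent)) missing[[ct]] <- absent
  }
  table <- do.call(rbind, tabs)
  rownames(table) <- NULL
  structure(
    list(table = table, cell_types = unique(table$cell_type),
         compounds = unique(table$compound), vehicle = vehicle,
         missing = missing),
    class = "drug_signatures"
  )
}

#' GSEA-style weighted running-sum enrichment score
#'
#' Genes are sorted by ranking score descending (ties broken by stable gene-id
#' order). Walking down the list, set members increment the running sum by
#' `|s|^alpha / sum_set |s|^alpha` and non-members decrement it by
#' `1 / (N - m)`; the ES is the running-sum value of maximum absolute
#' deviation from zero (signed).
#'
#' @param scores Named numeric vector of ranking scores (names = gene ids,
#'   no duplicates).
#' @param gene_set Character vector of set members.
#' @param alpha Weight exponent, default 1.
#' @return The enrichment score in `[-1, 1]`, or `NA` (with attribute
#'   `empty_intersection = TRUE`) if the set does not intersect the list.
#' @export
enrichment_score <- function(scores, gene_set, alpha = 1) {
  genes <- names(scores)
  if (is.null(genes)) stop("scores must be named by gene id")
  if (anyDuplicated(genes)) stop("duplicate genes in the ranked list")
  ord <- order(-scores, genes, method = "radix")
  s <- scores[ord]
  hit <- names(s) %in% gene_set
  m <- sum(hit)
  N <- length(s)
  if (m == 0) return(structure(NA_real_, empty_intersection = TRUE))
  if (m == N) return(1)
  w <- abs(s)^alpha
  denom <- sum(w[hit])
  steps <- rep(-1 / (N - m), N)
  steps[hit] <- if (denom > 0) w[hit] / denom else 1 / m  # all-zero scores: flat hits
  running <- cumsum(steps)
  unname(running[which.max(abs(running))])
}

#' Permutation-normalised enrichment score
#'
#' NES = ES divided by the mean |ES| of random same-size gene sets whose ES
#' shares the sign of the observed ES. Makes enrichment magnitudes comparable
#' across set sizes and score scales.
#'
#' @param scores Named numeric ranking scores.
#' @param gene_set Character vector of set members.
#' @param n_perm Number of random sets, default 1000 (minimum 100).
#' @param seed Seed for the permutations.
#' @param alpha Weight exponent, default 1.
#' @return A list: `es`, `nes` (`NA` with a flag if undefined), `n_same_sign`.
#' @export
normalized_es <- function(scores, gene_set, n_perm = 1000, seed = 1, alpha = 1) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  es <- enrichment_score(scores, gene_set, alpha = alpha)
  if (is.na(es)) return(list(es = es, nes = NA_real_, n_same_sign = 0L))
  m <- length(intersect(gene_set, names(scores)))
  genes <- names(scores)
  perm <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_perm), function(i)
      enrichment_score(scores, sample(genes, m), alpha = alpha), numeric(1))
  })
  same <- perm[sign(perm) == sign(es) & perm != 0]
  if (!length(same))
    return(list(es = es, nes = structure(NA_real_, undefined = TRUE),
                n_same_sign = 0L))
  list(es = es, nes = es / mean(abs(same)), n_same_sign = length(same))
}

#' Connectivity score
#'
#' `CS = ES_up - ES_down`. A drug whose signature moves the disease up-set
#' down and the down-set up gets a negative score (a "reverser"); a drug
#' mimicking the disease response gets a positive score.
#'
#' @param es_up,es_down Enrichment scores (raw or normalised) of the disease
#'   up- and down-regulated sets in the drug's ranked list.
#' @return The connectivity score, `NA` (flagged) if either input is `NA`.
#' @export
connectivity_score <- function(es_up, es_down) {
  if (is.na(es_up) || is.na(es_down))
    return(structure(NA_real_, undefined = TRUE))
  es_up - es_down
}

#' Score all compounds against disease signatures
#'
#' For every (compound, cell type) pair, computes the enrichment of the
#' disease up- and down-regulated biomarker sets (from the biopsy DE stage)
#' in the compound's ranked signature, and the connectivity score
#' `CS = ES_up - ES_down`. Disease cell types are mapped onto the screen's
#' cell types via `celltype_map`. With `mode = "nes"` (default) permutation-
#' normalised scores are used and the report is filtered at `|CS| >
#' report_threshold`; `mode = "raw"` uses raw ES (bounded by 2 in absolute
#' value).
#'
#' @param signatures A `drug_signatures` object.
#' @param up_sets,down_sets Named lists (per disease cell type) of gene
#'   symbols, e.g. from [signature_sets()].
#' @param celltype_map Named character vector mapping disease cell types to
#'   screen cell types; `NULL` for identity.
#' @param report_threshold `|CS|` filter for the report table, default 3
#'   (NES mode).
#' @param mode `"nes"` or `"raw"`.
#' @param n_perm,seed Permutation settings for NES mode.
#' @param exclude Compounds scored but excluded from reverser/mimic ranking
#'   (e.g. positive controls).
#' @return A list (`connectivity_result`): `table` (compound x cell type:
#'   `es_up`, `es_down`, `cs`), `report` (filtered at the threshold),
#'   `summary` (per compound: mean CS, n cell types, `all_negative`,
#'   `all_positive`), `reversers`, `mimics`.
#' @export
score_all <- function(signatures, up_sets, down_sets, celltype_map = NULL,
                      report_threshold = 3, mode = c("nes", "raw"),
                      n_perm = 1000, seed = 1, exclude = character(0)) {
  mode <- match.arg(mode)
  stopifnot(inherits(signatures, "drug_signatures"))
  disease_cts <- union(names(up_sets), names(down_sets))
  if (is.null(celltype_map))
    celltype_map <- stats::setNames(disease_cts, disease_cts)
  unmapped <- setdiff(disease_cts, names(celltype_map))
  if (length(unmapped))
    stop("unmapped disease cell type(s): ", paste(unmapped, collapse = ", "))
  tab <- signatures$table
  rows <- list()
  for (dct in disease_cts) {
    sct <- celltype_map[[dct]]
    if (!sct %in% tab$cell_type) {
      message("screen has no cell type '", sct, "' (mapped from '", dct, "')")
      next
    }
    up <- up_sets[[dct]]; down <- down_sets[[dct]]
    sub <- tab[tab$cell_type == sct, , drop = FALSE]
    for (cmp in sort(unique(sub$compound))) {
      d <- sub[sub$compound == cmp, , drop = FALSE]
      s <- stats::setNames(d$score, d$gene)
      if (mode == "nes") {
        eu <- if (length(up)) normalized_es(s, up, n_perm, seed, 1)$nes else NA_real_
        ed <- if (length(down)) normalized_es(s, down, n_perm, seed + 1, 1)$nes else NA_real_
      } else {
        eu <- if (length(up)) enrichment_score(s, up) else NA_real_
        ed <- if (length(down)) enrichment_score(s, down) else NA_real_
      }
      # a direction with no significant genes contributes 0, not undefined
      if (is.null(up) || (length(up) == 0)) eu <- 0
      if (is.null(down) || (length(down) == 0)) ed <- 0
      rows[[length(rows) + 1L]] <- data.frame(
        compound = cmp, disease_cell_type = dct, screen_cell_type = sct,
        es_up = as.numeric(eu), es_down = as.numeric(ed),
        cs = as.numeric(connectivity_score(eu, ed)),
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) stop("no scoreable compound/cell-type combinations")
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  ok <- !is.na(table$cs)
  summary <- do.call(rbind, lapply(split(table[ok, ], table$compound[ok]), function(d)
    data.frame(compound = d$compound[1], mean_cs = mean(d$cs),
               n_cell_types = nrow(d),
               all_negative = all(d$cs < 0), all_positive = all(d$cs > 0),
               stringsAsFactors = FALSE)))
  rownames(summary) <- NULL
  summary <- summary[order(summary$mean_cs), , drop = FALSE]
  rankable <- summary[!summary$compound %in% exclude, , drop = FALSE]
  structure(
    list(table = table,
         report = table[ok & abs(table$cs) > report_threshold, , drop = FALSE],
         summary = summary,
         reversers = rankable$compound[rankable$all_negative],
         mimics = rankable$compound[rankable$all_positive],
         mode = mode, threshold = report_threshold),
    class = "connectivity_result"
  )
}
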
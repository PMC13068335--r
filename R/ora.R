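#' Over-representation analysis against a gene-set library
#'
#' One-sided Fisher exact (hypergeometric tail) test of a gene list against
#' each set of a library, within a stated gene universe. Sets are intersected
#' with the universe first; sets with no universe overlap are skipped. BH
#' adjustment is applied across the tested sets.
#'
#' @param gene_list Character vector of genes of interest (must lie in the
#'   universe).
#' @param universe Character vector: the background gene universe.
#' @param library A `gene_set_library` (see [gene_set_library()] /
#'   [read_gmt()]).
#' @param q_threshold Significance threshold on BH q, default 0.01.
#' @return A data.frame (`ora_result`): per set `set`, `overlap`, `set_size`,
#'   `odds_ratio`, `p`, `q`, `significant`, `genes` (comma-joined overlap),
#'   ordered by p.
#' @export
ora <- function(gene_list, universe, library, q_threshold = 0.01) {
  gene_list <- unique(gene_list)
  universe <- unique(universe)
  outside <- setdiff(gene_list, universe)
  if (length(outside))
    stop("gene list not contained in universe: ",
         paste(utils::head(outside, 5), collapse = ", "))
  N <- length(universe)
  n <- length(gene_list)
  rows <- list()
  for (nm in names(library$sets)) {
    set <- intersect(library$sets[[nm]], universe)
    K <- length(set)
    if (K == 0) { message("set '", nm, "' has no universe overlap; skipped"); next }
    hits <- intersect(gene_list, set)
    k <- length(hits)
    # one-sided hypergeometric tail P(X >= k)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    or <- (k * (N - K - n + k)) / ((K - k) * (n - k))
    rows[[nm]] <- data.frame(
      set = nm, overlap = k, set_size = K,
      odds_ratio = ifelse(is.nan(or), Inf, or), p = p,
      genes = paste(sort(hits), collapse = ","),
      stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) stop("no testable sets")
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out$significant <- out$q < q_threshold
  out <- out[order(out$p, out$set), c("set", "overlap", "set_size",
                                      "odds_ratio", "p", "q", "significant",
                                      "genes")]
  rownames(out) <- NULL
  class(out) <- c("ora_result", class(out))
  out
}

#' Frequently occurring genes across significant sets
#'
#' Counts, for each gene of the analysed list, how many significant sets of an
#' ORA result contain it.
#'
#' @param result An `ora_result` from [ora()].
#' @param top_k Number of genes to return (default all with count > 0).
#' @return A data.frame `gene`, `n_sets`, descending by count with stable
#'   alphabetical tie order; zero rows if no set is significant.
#' @export
frequent_genes <- function(result, top_k = Inf) {
  sig <- result[result$significant, , drop = FALSE]
  if (!nrow(sig))
    return(data.frame(gene = character(0), n_sets = integer(0),
                      stringsAsFactors = FALSE))
  genes <- unlist(strsplit(sig$genes, ",", fixed = TRUE))
  genes <- genes[nzchar(genes)]
  tab <- table(genes)
  out <- data.frame(gene = names(tab), n_sets = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_sets, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, top_k)
}
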
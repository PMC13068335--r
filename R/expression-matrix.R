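#' Construct an expression matrix
#'
#' The common currency of the bulk stages: a numeric genes x samples matrix
#' tagged with the kind of values it holds. Counts matrices must be
#' non-negative; log-intensity matrices are unrestricted.
#'
#' @param values Numeric matrix, genes in rows, samples in columns.
#' @param gene_ids Character vector of row identifiers (defaults to rownames).
#' @param sample_ids Character vector of column identifiers (defaults to
#'   colnames). Must be unique.
#' @param value_kind Either `"counts"` or `"log_intensity"`.
#'
#' @return An object of class `expression_matrix`: a list with elements
#'   `values`, `gene_ids`, `sample_ids`, `value_kind`.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values),
                              value_kind = c("counts", "log_intensity")) {
  value_kind <- match.arg(value_kind)
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("'values' must be a numeric matrix")
  if (is.null(gene_ids)) stop("gene identifiers are required (rownames or gene_ids)")
  if (is.null(sample_ids)) stop("sample identifiers are required (colnames or sample_ids)")
  gene_ids <- trimws(as.character(gene_ids))
  sample_ids <- trimws(as.character(sample_ids))
  if (length(gene_ids) != nrow(values))
    stop("length(gene_ids) does not match nrow(values)")
  if (length(sample_ids) != ncol(values))
    stop("length(sample_ids) does not match ncol(values)")
  if (anyDuplicated(sample_ids))
    stop("duplicated sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (value_kind == "counts" && any(values < 0, na.rm = TRUE))
    stop("counts matrix contains negative values")
  dimnames(values) <- list(gene_ids, sample_ids)
  structure(
    list(values = values, gene_ids = gene_ids, sample_ids = sample_ids,
         value_kind = value_kind),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d samples [%s]\n",
              length(x$gene_ids), length(x$sample_ids), x$value_kind))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Construct a gene annotation table
#'
#' @param symbol Character vector of gene symbols (non-empty).
#' @param chromosome Optional chromosome labels (e.g. `"Y"`).
#' @param is_housekeeping,is_negative_control Logical flags. A gene cannot be
#'   both a housekeeping gene and a negative control.
#' @param probe_id Optional probe/transcript identifiers used for
#'   probe-to-symbol collapsing.
#'
#' @return A `data.frame` with class `gene_table` prepended.
#' @export
gene_table <- function(symbol, chromosome = NA_character_,
                       is_housekeeping = FALSE, is_negative_control = FALSE,
                       probe_id = NA_character_) {
  symbol <- trimws(as.character(symbol))
  if (any(!nzchar(symbol))) stop("gene symbols must be non-empty")
  tab <- data.frame(
    symbol = symbol,
    chromosome = as.character(chromosome),
    is_housekeeping = as.logical(is_housekeeping),
    is_negative_control = as.logical(is_negative_control),
    probe_id = as.character(probe_id),
    stringsAsFactors = FALSE
  )
  if (any(tab$is_housekeeping & tab$is_negative_control, na.rm = TRUE))
    stop("a gene cannot be both housekeeping and negative control")
  class(tab) <- c("gene_table", class(tab))
  tab
}

#' Construct a sample annotation table
#'
#' @param sample_id Unique sample identifiers.
#' @param group Group label per sample (e.g. ER/DR, healthy/moderate/severe,
#'   quiet/exacerbation/follow_up).
#' @param sex One of `"male"`, `"female"`, `"unknown"` per sample.
#' @param batch Batch / dataset label.
#' @param timepoint Optional timepoint label.
#'
#' @return A `data.frame` with class `sample_table` prepended.
#' @export
sample_table <- function(sample_id, group, sex = "unknown", batch = "batch1",
                         timepoint = NA_character_) {
  sample_id <- trimws(as.character(sample_id))
  if (anyDuplicated(sample_id))
    stop("duplicated sample ids in sample table")
  sex <- as.character(sex)
  bad <- setdiff(unique(sex), c("male", "female", "unknown"))
  if (length(bad)) stop("invalid sex labels: ", paste(bad, collapse = ", "))
  tab <- data.frame(
    sample_id = sample_id,
    group = as.character(group),
    sex = sex,
    batch = as.character(batch),
    timepoint = as.character(timepoint),
    stringsAsFactors = FALSE
  )
  class(tab) <- c("sample_table", class(tab))
  tab
}

#' Construct a single-cell dataset
#'
#' Sparse cells x genes counts with mandatory per-cell annotations. Used by
#' both the biopsy (pre/post allergen challenge) and the PBMC perturbation
#' stages; annotation columns beyond `cell_id` are free-form, but the
#' pseudobulk and signature stages expect `cell_type` and `sample_id`.
#'
#' @param counts A sparse (or dense) cells x genes non-negative count matrix.
#' @param cell_data A `data.frame` with one row per cell; must contain
#'   `cell_id` matching the rownames of `counts`.
#' @param gene_ids Character vector of gene identifiers (defaults to colnames).
#'
#' @return An object of class `single_cell_dataset` with elements `counts`
#'   (a `dgCMatrix`), `cell_data`, `gene_ids`.
#' @export
single_cell_dataset <- function(counts, cell_data, gene_ids = colnames(counts)) {
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "generalMatrix")
  if (is.null(gene_ids)) stop("gene identifiers are required")
  if (!"cell_id" %in% names(cell_data)) stop("cell_data must contain a 'cell_id' column")
  cell_data$cell_id <- as.character(cell_data$cell_id)
  if (nrow(cell_data) != nrow(counts))
    stop("cell_data rows (", nrow(cell_data), ") do not match cells (", nrow(counts), ")")
  if (length(gene_ids) != ncol(counts))
    stop("gene_ids length does not match gene columns")
  if (any(counts@x < 0)) stop("counts must be non-negative")
  rownames(counts) <- cell_data$cell_id
  colnames(counts) <- gene_ids
  structure(
    list(counts = counts, cell_data = cell_data, gene_ids = as.character(gene_ids)),
    class = "single_cell_dataset"
  )
}

#' @export
print.single_cell_dataset <- function(x, ...) {
  cat(sprintf("<single_cell_dataset> %d cells x %d genes (%.2f%% nonzero)\n",
              nrow(x$counts), ncol(x$counts),
              100 * length(x$counts@x) / prod(dim(x$counts))))
  ann <- setdiff(names(x$cell_data), "cell_id")
  if (length(ann)) cat("  annotations:", paste(ann, collapse = ", "), "\n")
  invisible(x)
}
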
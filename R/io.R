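#' Read a delimited expression matrix
#'
#' Reads a TSV (or other delimited) file with one header row of sample ids and
#' a leading column of gene/probe ids. The declared orientation is normalised
#' to genes x samples; input order is preserved.
#'
#' @param path File path.
#' @param orientation `"genes_in_rows"` (default) or `"samples_in_rows"`.
#' @param value_kind Value kind tag for the result.
#' @param sep Field separator, tab by default.
#'
#' @return An [expression_matrix()].
#' @export
read_matrix_delim <- function(path, orientation = c("genes_in_rows", "samples_in_rows"),
                              value_kind = c("counts", "log_intensity"), sep = "\t") {
  orientation <- match.arg(orientation)
  value_kind <- match.arg(value_kind)
  lines <- readLines(path)
  if (length(lines) < 2) stop("matrix file has no data rows: ", path)
  fields <- strsplit(lines, sep, fixed = TRUE)
  nf <- lengths(fields)
  # the header may or may not label the leading id column: data rows carry
  # one id field plus one field per data column
  has_id_label <- nf[2] == nf[1]
  expected <- if (has_id_label) nf[1] else nf[1] + 1L
  bad <- which(nf[-1] != expected) + 1L
  if (length(bad))
    stop("ragged row(s) at line ", paste(utils::head(bad, 5), collapse = ", "),
         ": expected ", expected, " fields")
  header <- trimws(fields[[1]])
  if (has_id_label) header <- header[-1]
  row_ids <- vapply(fields[-1], function(f) trimws(f[1]), character(1))
  vals <- t(vapply(fields[-1], function(f) as.numeric(f[-1]), numeric(length(header))))
  if (length(header) == 1L) vals <- matrix(vals, ncol = 1L)
  dimnames(vals) <- list(row_ids, header)
  if (orientation == "samples_in_rows") vals <- t(vals)
  expression_matrix(vals, value_kind = value_kind)
}

#' Write a delimited expression matrix
#'
#' Emits a TSV with deterministic column order (the matrix's sample order) and
#' a `#` header comment recording the tool version and, optionally, the seed
#' used to produce the data.
#'
#' @param x An [expression_matrix()].
#' @param path Output path.
#' @param seed Optional integer recorded in the header comment.
#' @param sep Field separator.
#' @export
write_matrix_delim <- function(x, path, seed = NULL, sep = "\t") {
  stopifnot(inherits(x, "expression_matrix"))
  ver <- as.character(utils::packageVersion("larconnect"))
  hdr <- sprintf("# larconnect %s value_kind=%s%s", ver, x$value_kind,
                 if (is.null(seed)) "" else sprintf(" seed=%d", as.integer(seed)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste(c("gene_id", x$sample_ids), collapse = sep), con)
  body <- apply(cbind(x$gene_ids, format(x$values, trim = TRUE, scientific = FALSE)),
                1, paste, collapse = sep)
  writeLines(body, con)
  invisible(path)
}

#' Re-read a matrix written by write_matrix_delim
#'
#' @param path File written by [write_matrix_delim()].
#' @return An [expression_matrix()] with the value kind recorded in the header.
#' @export
read_matrix_written <- function(path) {
  first <- readLines(path, n = 1)
  kind <- if (grepl("value_kind=log_intensity", first)) "log_intensity" else "counts"
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  tmp <- tempfile(fileext = ".tsv")
  writeLines(lines, tmp)
  on.exit(unlink(tmp))
  read_matrix_delim(tmp, value_kind = kind)
}

#' Read a MatrixMarket triplet single-cell dataset
#'
#' Loads a coordinate-format `.mtx` (genes x cells, the usual CellRanger-style
#' layout) together with feature and barcode lists and a delimited per-cell
#' annotation table keyed by barcode. The result is transposed to the package's
#' cells x genes convention.
#'
#' @param matrix_path Path to the `.mtx` file.
#' @param features_path One feature id per line (first tab-separated field used).
#' @param barcodes_path One cell barcode per line.
#' @param annotations_path TSV with a header containing a `cell_id` (or
#'   `barcode`) column plus annotation columns.
#' @param drop_unannotated If `TRUE`, cells missing from the annotation table
#'   are dropped with a warning; if `FALSE` (default) they are an error.
#'
#' @return A [single_cell_dataset()].
#' @export
read_mtx_triplet <- function(matrix_path, features_path, barcodes_path,
                             annotations_path, drop_unannotated = FALSE) {
  m <- Matrix::readMM(matrix_path)
  features <- vapply(strsplit(readLines(features_path), "\t"), `[`, character(1), 1)
  barcodes <- trimws(readLines(barcodes_path))
  if (nrow(m) != length(features))
    stop("mtx rows (", nrow(m), ") do not match features (", length(features), ")")
  if (ncol(m) != length(barcodes))
    stop("mtx columns (", ncol(m), ") do not match barcodes (", length(barcodes), ")")
  ann <- utils::read.delim(annotations_path, stringsAsFactors = FALSE)
  key <- intersect(c("cell_id", "barcode"), names(ann))[1]
  if (is.na(key)) stop("annotation table needs a 'cell_id' or 'barcode' column")
  names(ann)[names(ann) == key] <- "cell_id"
  missing <- setdiff(barcodes, ann$cell_id)
  if (length(missing)) {
    if (!drop_unannotated)
      stop("barcodes missing from annotations: ",
           paste(utils::head(missing, 5), collapse = ", "))
    warning(length(missing), " unannotated barcode(s) dropped")
    keep <- barcodes %in% ann$cell_id
    m <- m[, keep, drop = FALSE]
    barcodes <- barcodes[keep]
  }
  ann <- ann[match(barcodes, ann$cell_id), , drop = FALSE]
  single_cell_dataset(Matrix::t(m), ann, gene_ids = features)
}

#' Read a GMT gene-set library
#'
#' @param path GMT file: per line a set name, a description field, then
#'   tab-separated gene symbols.
#' @param name Library name (defaults to the file name).
#' @return A `gene_set_library`: list with `name` and `sets` (named list of
#'   character vectors). Empty sets are rejected.
#' @export
read_gmt <- function(path, name = basename(path)) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(fields, function(f) unique(trimws(f[-c(1, 2)])))
  names(sets) <- vapply(fields, `[`, character(1), 1)
  sets <- lapply(sets, function(s) s[nzchar(s)])
  if (any(lengths(sets) == 0)) stop("GMT contains empty set(s)")
  gene_set_library(name, sets)
}

#' Construct a gene-set library
#'
#' @param name Library name.
#' @param sets Named list of character vectors of gene symbols.
#' @return A `gene_set_library` object.
#' @export
gene_set_library <- function(name, sets) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("all sets must be named")
  if (any(lengths(sets) == 0)) stop("empty gene sets are not allowed")
  sets <- lapply(sets, function(s) unique(as.character(s)))
  structure(list(name = name, sets = sets), class = "gene_set_library")
}

#' Write a GMT gene-set library
#'
#' @param library A `gene_set_library`.
#' @param path Output path.
#' @export
write_gmt <- function(library, path) {
  lines <- vapply(names(library$sets), function(nm) {
    paste(c(nm, library$name, library$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
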
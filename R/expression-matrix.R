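#' Gene-by-cell expression matrix with per-cell metadata
#'
#' The universal currency of the pipeline: a dense gene x cell matrix tagged
#' with a layer (`"raw"` UMI counts, `"lognorm"` log-normalised values, or
#' `"cosine"` unit-norm cells) and a per-cell metadata table. Gene and cell
#' identifiers live in the dimnames and must be unique.
#'
#' @param values numeric matrix, genes in rows, cells in columns; both
#'   dimnames required. Raw-layer values must be non-negative integers.
#' @param layer one of `"raw"`, `"lognorm"`, `"cosine"`.
#' @param cell_meta optional `data.frame` of per-cell annotations (e.g.
#'   `dataset`, `stage`, `individual`), either with rownames equal to the
#'   cell ids or with a `cell_id` column; rows are matched to cells by id.
#' @return an object of class `ExpressionMatrix`: a list with elements
#'   `values`, `layer`, `cell_meta`.
#' @export
expression_matrix <- function(values, layer = c("raw", "lognorm", "cosine"),
                              cell_meta = NULL) {
  layer <- match.arg(layer)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry gene ids as rownames and cell ids as colnames")
  gene_ids <- rownames(values)
  cell_ids <- colnames(values)
  if (anyDuplicated(gene_ids))
    stop("duplicate gene id: ", paste(unique(gene_ids[duplicated(gene_ids)]),
                                      collapse = ", "))
  if (anyDuplicated(cell_ids))
    stop("duplicate cell id: ", paste(unique(cell_ids[duplicated(cell_ids)]),
                                      collapse = ", "))
  if (any(!is.finite(values)))
    stop("expression values must be finite")
  # raw counts are non-negative integers; derived layers (e.g. batch-
  # corrected values) may drift below zero and are not constrained
  if (layer == "raw" && (any(values < 0) || any(values != floor(values))))
    stop("raw-layer values must be non-negative integer counts")
  if (is.null(cell_meta)) {
    cell_meta <- data.frame(row.names = cell_ids)
  } else {
    cell_meta <- as.data.frame(cell_meta)
    if ("cell_id" %in% names(cell_meta)) {
      rownames(cell_meta) <- cell_meta$cell_id
      cell_meta$cell_id <- NULL
    }
    missing <- setdiff(cell_ids, rownames(cell_meta))
    if (length(missing))
      stop("cell_meta lacks rows for cells: ",
           paste(utils::head(missing, 5), collapse = ", "))
    cell_meta <- cell_meta[cell_ids, , drop = FALSE]
  }
  structure(list(values = values, layer = layer, cell_meta = cell_meta),
            class = "ExpressionMatrix")
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d cells [layer: %s]\n",
              nrow(x$values), ncol(x$values), x$layer))
  if (ncol(x$cell_meta))
    cat("cell_meta:", paste(names(x$cell_meta), collapse = ", "), "\n")
  invisible(x)
}

#' Gene and cell identifiers of an ExpressionMatrix
#' @param m an `ExpressionMatrix`.
#' @return character vector of ids.
#' @export
gene_ids <- function(m) rownames(m$values)

#' @rdname gene_ids
#' @export
cell_ids <- function(m) colnames(m$values)

#' Subset an ExpressionMatrix by cells or genes
#'
#' Cell metadata follows cell subsets; the layer tag is preserved.
#'
#' @param m an `ExpressionMatrix`.
#' @param cells cell ids, indices or a logical mask.
#' @param genes gene ids, indices or a logical mask.
#' @return a new `ExpressionMatrix`.
#' @export
subset_cells <- function(m, cells) {
  v <- m$values[, cells, drop = FALSE]
  out <- m
  out$values <- v
  out$cell_meta <- m$cell_meta[colnames(v), , drop = FALSE]
  out
}

#' @rdname subset_cells
#' @export
subset_genes <- function(m, genes) {
  if (is.character(genes)) {
    missing <- setdiff(genes, rownames(m$values))
    if (length(missing))
      stop("genes absent from matrix: ", paste(missing, collapse = ", "))
  }
  out <- m
  out$values <- m$values[genes, , drop = FALSE]
  out
}

stopifnot_layer <- function(m, layer, op) {
  if (!inherits(m, "ExpressionMatrix"))
    stop(op, " expects an ExpressionMatrix")
  if (m$layer != layer)
    stop(op, " requires the ", layer, " layer, got '", m$layer, "'")
  invisible(m)
}

#' Read a count matrix from MatrixMarket or TSV
#'
#' MatrixMarket input is a coordinate-format `.mtx` triplet file accompanied
#' by plain-text gene and cell id files (one id per line); by default these
#' are found by replacing the `.mtx` suffix with `.genes.txt` and
#' `.cells.txt`. TSV input is a dense table, first column gene ids, header
#' row of cell ids.
#'
#' @param path path to the `.mtx` or `.tsv` file.
#' @param format `"mtx"` or `"tsv"`.
#' @param meta_path optional TSV of per-cell metadata with a `cell_id`
#'   column; joined onto the cells by id.
#' @param genes_path,cells_path id files for `"mtx"` input; defaults derived
#'   from `path`.
#' @return a raw-layer `ExpressionMatrix`.
#' @export
read_counts <- function(path, format = c("mtx", "tsv"), meta_path = NULL,
                        genes_path = NULL, cells_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "mtx") {
    if (is.null(genes_path)) genes_path <- sub("\\.mtx$", ".genes.txt", path)
    if (is.null(cells_path)) cells_path <- sub("\\.mtx$", ".cells.txt", path)
    for (p in c(genes_path, cells_path))
      if (!file.exists(p)) stop("id file not found: ", p)
    mat <- tryCatch(Matrix::readMM(path),
                    error = function(e) stop("malformed MatrixMarket file '",
                                             path, "': ", conditionMessage(e)))
    genes <- readLines(genes_path)
    cells <- readLines(cells_path)
    if (nrow(mat) != length(genes))
      stop("dimension mismatch: matrix has ", nrow(mat), " rows but '",
           genes_path, "' lists ", length(genes), " genes")
    if (ncol(mat) != length(cells))
      stop("dimension mismatch: matrix has ", ncol(mat), " columns but '",
           cells_path, "' lists ", length(cells), " cells")
    values <- as.matrix(mat)
    dimnames(values) <- list(genes, cells)
  } else {
    tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                             stringsAsFactors = FALSE)
    genes <- as.character(tab[[1]])
    if (anyDuplicated(genes))
      stop("duplicate gene id: ",
           paste(unique(genes[duplicated(genes)]), collapse = ", "))
    values <- as.matrix(tab[, -1, drop = FALSE])
    rownames(values) <- genes
  }
  meta <- NULL
  if (!is.null(meta_path)) {
    meta <- utils::read.delim(meta_path, header = TRUE, check.names = FALSE,
                              stringsAsFactors = FALSE)
    if (!"cell_id" %in% names(meta))
      stop("metadata file '", meta_path, "' lacks a cell_id column")
  }
  expression_matrix(values, layer = "raw", cell_meta = meta)
}

#' Write a count matrix to MatrixMarket or TSV
#'
#' Inverse of [read_counts()]: MTX output writes the triplet file plus
#' `.genes.txt` / `.cells.txt` sibling id files.
#'
#' @param m an `ExpressionMatrix`.
#' @param path output path (`.mtx` or `.tsv`).
#' @inheritParams read_counts
#' @return `path`, invisibly.
#' @export
write_counts <- function(m, path, format = c("mtx", "tsv")) {
  format <- match.arg(format)
  if (format == "mtx") {
    Matrix::writeMM(Matrix::Matrix(m$values, sparse = TRUE), path)
    writeLines(rownames(m$values), sub("\\.mtx$", ".genes.txt", path))
    writeLines(colnames(m$values), sub("\\.mtx$", ".cells.txt", path))
  } else {
    tab <- data.frame(gene = rownames(m$values), m$values,
                      check.names = FALSE)
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Named gene set
#'
#' @param name set name.
#' @param genes character vector of gene symbols; must be non-empty and
#'   duplicate-free.
#' @return an object of class `GeneSet`.
#' @export
gene_set <- function(name, genes) {
  genes <- as.character(genes)
  if (!length(genes)) stop("gene set '", name, "' is empty")
  if (anyDuplicated(genes))
    stop("gene set '", name, "' has duplicate symbols: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  structure(list(name = name, genes = genes), class = "GeneSet")
}

#' @export
print.GeneSet <- function(x, ...) {
  cat(sprintf("GeneSet '%s': %d genes\n", x$name, length(x$genes)))
  invisible(x)
}

#' Read or write a gene set (one symbol per line)
#' @param path text file, one gene symbol per line; blank lines ignored.
#' @param name set name; defaults to the file stem.
#' @return a `GeneSet`.
#' @export
read_gene_set <- function(path, name = NULL) {
  if (is.null(name))
    name <- tools::file_path_sans_ext(basename(path))
  genes <- readLines(path)
  gene_set(name, genes[nzchar(genes)])
}

#' @rdname read_gene_set
#' @param gs a `GeneSet`.
#' @export
write_gene_set <- function(gs, path) {
  writeLines(gs$genes, path)
  invisible(path)
}
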
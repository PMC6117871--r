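#' Construct a UMI count matrix container
#'
#' Builds a [SingleCellExperiment][SingleCellExperiment::SingleCellExperiment]
#' holding a genes-in-rows integer UMI matrix with gene ids as rownames,
#' cell ids as colnames and per-cell metadata (plate/batch, dataset, age
#' group, free-form extras) as `colData`. All pipeline entry points validate
#' their input with [validateCountMatrix()].
#'
#' @param counts non-negative integer matrix (base or `Matrix` sparse),
#'   genes in rows.
#' @param gene_ids character vector of unique gene symbols (defaults to
#'   existing rownames).
#' @param cell_ids character vector of unique cell identifiers (defaults to
#'   existing colnames).
#' @param cell_meta data.frame of per-cell metadata, `nrow == ncol(counts)`.
#' @return A `SingleCellExperiment` with a `counts` assay.
#' @examples
#' m <- CountMatrix(matrix(0:5, 3, 2), paste0("g", 1:3), c("a", "b"))
#' SummarizedExperiment::assay(m)
#' @export
CountMatrix <- function(counts, gene_ids = rownames(counts),
                        cell_ids = colnames(counts), cell_meta = NULL) {
  if (is.null(gene_ids) || is.null(cell_ids))
    stop("gene_ids and cell_ids are required")
  if (!methods::is(counts, "sparseMatrix"))
    counts <- Matrix::Matrix(as.matrix(counts), sparse = TRUE)
  counts <- as(counts, "CsparseMatrix")
  rownames(counts) <- as.character(gene_ids)
  colnames(counts) <- as.character(cell_ids)
  if (is.null(cell_meta))
    cell_meta <- S4Vectors::DataFrame(row.names = colnames(counts))
  else {
    cell_meta <- S4Vectors::DataFrame(cell_meta)
    rownames(cell_meta) <- colnames(counts)
  }
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts), colData = cell_meta)
  validateCountMatrix(sce)
  sce
}

#' Validate a count matrix container
#'
#' Checks the invariants every stage relies on: unique non-empty gene and
#' cell ids, matching dimensions, and counts that are finite, non-negative
#' and integral (a small tolerance admits normalized real matrices when
#' `allow_real = TRUE`).
#'
#' @param m a `SingleCellExperiment` (or any `SummarizedExperiment` with a
#'   `counts` assay).
#' @param allow_real permit non-integer entries (normalized matrices).
#' @return `m`, invisibly; stops with a validation error otherwise.
#' @export
validateCountMatrix <- function(m, allow_real = FALSE) {
  if (!methods::is(m, "SummarizedExperiment"))
    stop("validation error: expected a SummarizedExperiment count container")
  if (!"counts" %in% SummarizedExperiment::assayNames(m))
    stop("validation error: no 'counts' assay")
  x <- SummarizedExperiment::assay(m, "counts")
  if ((nrow(m) > 0 && is.null(rownames(m))) ||
      (ncol(m) > 0 && is.null(colnames(m))))
    stop("validation error: gene and cell ids required")
  if (anyDuplicated(rownames(m)))
    stop("validation error: duplicate gene ids")
  if (anyDuplicated(colnames(m)))
    stop("validation error: duplicate cell ids")
  v <- if (methods::is(x, "sparseMatrix")) x@x else as.numeric(x)
  if (length(v)) {
    if (any(!is.finite(v)))
      stop("validation error: non-finite counts")
    if (any(v < 0))
      stop("validation error: negative counts")
    if (!allow_real && any(abs(v - round(v)) > 1e-8))
      stop("validation error: non-integer counts")
  }
  invisible(m)
}

#' Counts accessor
#' @param m count container from [CountMatrix()]
#' @param dense return a base dense matrix
#' @return the counts matrix (genes x cells).
#' @export
counts <- function(m, dense = FALSE) {
  x <- SummarizedExperiment::assay(m, "counts")
  if (dense) as.matrix(x) else x
}

#' Read a count matrix from disk
#'
#' Reads either a Matrix Market sparse triplet (`matrix.mtx` with companion
#' `genes.tsv` and `barcodes.tsv`, one id per line) or a dense tab-separated
#' table (gene ids in the first column, cell ids in the header). Both
#' representations of the same data yield identical containers.
#'
#' @param path for `format = "mtx"` a directory containing the three files
#'   (or the path of the `.mtx` file itself); for `format = "tsv"` the table
#'   path.
#' @param format "mtx" or "tsv" ("auto" picks by extension/contents).
#' @param genes_in_rows is the stored matrix genes x cells? Set `FALSE` to
#'   transpose on read.
#' @param cell_meta optional per-cell metadata data.frame.
#' @return A validated count container ([CountMatrix()]).
#' @export
readCountMatrix <- function(path, format = c("auto", "mtx", "tsv"),
                            genes_in_rows = TRUE, cell_meta = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (dir.exists(path) || grepl("\\.mtx$", path)) "mtx" else "tsv"
  }
  if (format == "mtx") {
    dirp <- if (dir.exists(path)) path else dirname(path)
    mtx <- if (dir.exists(path)) file.path(path, "matrix.mtx") else path
    gf <- file.path(dirp, "genes.tsv")
    bf <- file.path(dirp, "barcodes.tsv")
    for (f in c(mtx, gf, bf))
      if (!file.exists(f)) stop("format error: missing file ", f)
    x <- tryCatch(Matrix::readMM(mtx),
                  error = function(e) stop("format error: ", conditionMessage(e)))
    genes <- readLines(gf)
    cells <- readLines(bf)
    if (!genes_in_rows) {
      x <- Matrix::t(x)
    }
    if (nrow(x) != length(genes) || ncol(x) != length(cells))
      stop("format error: matrix dimensions (", nrow(x), " x ", ncol(x),
           ") do not match id table lengths (", length(genes), ", ",
           length(cells), ")")
    CountMatrix(x, genes, cells, cell_meta)
  } else {
    tab <- tryCatch(
      read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                 row.names = 1),
      error = function(e) stop("format error: ", conditionMessage(e)))
    x <- as.matrix(tab)
    if (!is.numeric(x)) stop("format error: non-numeric entries in table")
    if (!genes_in_rows) x <- t(x)
    CountMatrix(x, rownames(x), colnames(x), cell_meta)
  }
}

#' Write a count matrix to disk
#'
#' @param m count container.
#' @param path output directory (`mtx`) or file path (`tsv`).
#' @param format "mtx" writes `matrix.mtx` + `genes.tsv` + `barcodes.tsv`;
#'   "tsv" a dense tab-separated table, genes in rows.
#' @return `path`, invisibly.
#' @export
writeCountMatrix <- function(m, path, format = c("mtx", "tsv")) {
  format <- match.arg(format)
  validateCountMatrix(m, allow_real = TRUE)
  if (format == "mtx") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    Matrix::writeMM(as(counts(m), "generalMatrix"),
                    file.path(path, "matrix.mtx"))
    writeLines(rownames(m), file.path(path, "genes.tsv"))
    writeLines(colnames(m), file.path(path, "barcodes.tsv"))
  } else {
    tab <- data.frame(gene = rownames(m), counts(m, dense = TRUE),
                      check.names = FALSE)
    colnames(tab) <- c("gene", colnames(m))
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Subset a count matrix by id or mask
#'
#' Retains the requested cells/genes in their original matrix order and
#' subsets metadata accordingly. Unknown ids raise a key error; logical
#' masks must match the corresponding dimension.
#'
#' @param m count container.
#' @param cells,genes character id vectors, logical masks, or `NULL` (keep
#'   all).
#' @param keep_order keep the matrix's own ordering (default) rather than
#'   the order ids were requested in.
#' @return the subset container.
#' @export
subsetCounts <- function(m, cells = NULL, genes = NULL, keep_order = TRUE) {
  validateCountMatrix(m, allow_real = TRUE)
  pick <- function(ids, universe, what) {
    if (is.null(ids)) return(seq_along(universe))
    if (is.logical(ids)) {
      if (length(ids) != length(universe))
        stop("key error: ", what, " mask length mismatch")
      return(which(ids))
    }
    ids <- as.character(ids)
    miss <- setdiff(ids, universe)
    if (length(miss))
      stop("key error: unknown ", what, ": ", paste(miss, collapse = ", "))
    idx <- match(ids, universe)
    if (keep_order) sort(idx) else idx
  }
  gi <- pick(genes, rownames(m), "gene id(s)")
  ci <- pick(cells, colnames(m), "cell id(s)")
  m[gi, ci]
}

#' Read / write cluster assignment tables
#'
#' Two-column tab-separated tables with a header (`cell`, `cluster`).
#'
#' @param path file path.
#' @return [readClusterTable()] returns a [ClusterAssignment-class].
#' @export
readClusterTable <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t",
                    colClasses = "character")
  if (ncol(tab) < 2)
    stop("format error: expected columns (cell, cluster)")
  ClusterAssignment(setNames(tab[[2]], tab[[1]]))
}

#' @rdname readClusterTable
#' @param a a [ClusterAssignment-class]
#' @export
writeClusterTable <- function(a, path) {
  lab <- clusterLabels(a)
  write.table(data.frame(cell = names(lab), cluster = unname(lab)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write 2-D embedding coordinates
#'
#' Three-column tab-separated tables with header (`cell`, `x`, `y`), e.g.
#' tSNE coordinates produced by an external embedding tool. Coordinates are
#' written with 12 significant digits so round trips are stable.
#'
#' @param path file path.
#' @return [readCoords()] returns a numeric matrix (cells x 2, columns
#'   `x`,`y`, rownames = cell ids).
#' @export
readCoords <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t",
                    colClasses = c("character", "character", "character"))
  if (ncol(tab) < 3) stop("format error: expected columns (cell, x, y)")
  x <- suppressWarnings(as.numeric(tab[[2]]))
  y <- suppressWarnings(as.numeric(tab[[3]]))
  if (anyNA(x) || anyNA(y))
    stop("format error: non-numeric coordinate entries")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("format error: non-finite coordinates")
  if (anyDuplicated(tab[[1]])) stop("validation error: duplicate cell ids")
  out <- cbind(x = x, y = y)
  rownames(out) <- tab[[1]]
  out
}

#' @rdname readCoords
#' @param coords numeric matrix as returned by [readCoords()]
#' @export
writeCoords <- function(coords, path) {
  write.table(data.frame(cell = rownames(coords),
                         x = formatC(coords[, "x"], digits = 12,
                                     format = "g"),
                         y = formatC(coords[, "y"], digits = 12,
                                     format = "g")),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a result table as TSV
#'
#' Tab separated, header row, 12-significant-digit reals, no quoting.
#'
#' @param tab a data.frame.
#' @param path file path.
#' @export
writeResultTable <- function(tab, path) {
  num <- vapply(tab, is.double, logical(1))
  tab[num] <- lapply(tab[num], function(v) formatC(v, digits = 12,
                                                   format = "g"))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Check an assignment against its paired matrix
#'
#' Warns (listing the orphans) when the assignment names cells absent from
#' the matrix, and errors when `require_all = TRUE`.
#'
#' @param a a [ClusterAssignment-class].
#' @param m count container.
#' @param require_all error instead of warn on orphans.
#' @return character vector of cell ids present in both, invisibly.
#' @export
checkAssignment <- function(a, m, require_all = FALSE) {
  lab <- clusterLabels(a)
  orphans <- setdiff(names(lab), colnames(m))
  if (length(orphans)) {
    msg <- paste0("assignment names ", length(orphans),
                  " cell(s) absent from the matrix: ",
                  paste(head(orphans, 10), collapse = ", "))
    if (require_all) stop("validation error: ", msg) else warning(msg)
  }
  invisible(intersect(names(lab), colnames(m)))
}
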
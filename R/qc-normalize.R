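#' Gene list configuration for QC and filtering
#'
#' Holds the gene symbol lists used by the QC schemes: markers whose
#' expression flags a cell as non-neuronal (default: the oligodendrocyte /
#' astrocyte / microglia / vascular panel Mog, Mbp, Aqp4, Gja1, C1qc, Aif1,
#' Fn1, Cldn5), activity-dependent genes excluded before clustering, and
#' mitochondrial / rRNA genes excluded from the PatchSeq molecule and gene
#' tallies. Lists may be empty and symbols need not exist in a given matrix.
#'
#' @param non_neuronal_markers,activity_genes,mito_genes,rrna_genes
#'   character vectors of gene symbols.
#' @return a `GeneListConfig` (plain list with class attribute).
#' @export
geneListConfig <- function(non_neuronal_markers = c("Mog", "Mbp", "Aqp4",
                                                    "Gja1", "C1qc", "Aif1",
                                                    "Fn1", "Cldn5"),
                           activity_genes = character(0),
                           mito_genes = character(0),
                           rrna_genes = character(0)) {
  structure(list(non_neuronal_markers = as.character(non_neuronal_markers),
                 activity_genes = as.character(activity_genes),
                 mito_genes = as.character(mito_genes),
                 rrna_genes = as.character(rrna_genes)),
            class = "GeneListConfig")
}

#' Read a one-symbol-per-line gene list file
#' @param path text file, one gene symbol per line; blank lines and lines
#'   starting with `#` are ignored.
#' @return character vector of symbols.
#' @export
readGeneList <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}

.cellStats <- function(m) {
  x <- counts(m)
  list(total = Matrix::colSums(x),
       genes = Matrix::colSums(x > 0))
}

.qcReport <- function(cell, gene, scheme, params) {
  new("QCReport", cell = cell,
      gene = if (is.null(gene))
        data.frame(gene_id = character(0), total = numeric(0),
                   pass = logical(0))
      else gene,
      scheme = scheme, params = params)
}

.reasonString <- function(flags) {
  # flags: named list of logical vectors, TRUE = that reason fails the cell
  apply(do.call(cbind, flags), 1, function(r)
    paste(names(flags)[r], collapse = ","))
}

#' Dataset A quality control
#'
#' Cells are retained when they carry strictly more than `min_molecules`
#' UMIs; genes are removed when they carry strictly fewer than
#' `min_gene_total` molecules over the whole dataset.
#'
#' @param m count container.
#' @param min_molecules cell threshold (default 1500, strict ">").
#' @param min_gene_total gene threshold (default 25; totals below it fail).
#' @return a [QCReport-class] with both cell and gene tables.
#' @export
qcDatasetA <- function(m, min_molecules = 1500, min_gene_total = 25) {
  validateCountMatrix(m)
  st <- .cellStats(m)
  fail <- list(low_molecules = !(st$total > min_molecules))
  cell <- data.frame(cell_id = colnames(m), total = as.numeric(st$total),
                     genes_detected = as.numeric(st$genes),
                     ratio = ifelse(st$genes > 0, st$total / st$genes, NA),
                     pass = !fail$low_molecules,
                     reason = .reasonString(fail),
                     stringsAsFactors = FALSE)
  gtot <- Matrix::rowSums(counts(m))
  gene <- data.frame(gene_id = rownames(m), total = as.numeric(gtot),
                     pass = gtot >= min_gene_total,
                     stringsAsFactors = FALSE)
  .qcReport(cell, gene, "dataset_a",
            list(min_molecules = min_molecules,
                 min_gene_total = min_gene_total))
}

#' Dataset B quality control
#'
#' A cell fails when its UMI total is below `min_umi`, when the ratio of
#' total UMIs to genes detected is strictly below `min_ratio` (a ratio of
#' exactly 1.2 passes), or when it expresses more than zero molecules of
#' any configured non-neuronal marker. Cells with zero genes detected fail
#' with a dedicated reason (the ratio is undefined).
#'
#' @param m count container.
#' @param cfg a [geneListConfig()].
#' @param min_umi UMI threshold (default 800; totals below it fail).
#' @param min_ratio total/genes threshold (default 1.2, strict "<" fails).
#' @return a [QCReport-class] (cell table only).
#' @export
qcDatasetB <- function(m, cfg = geneListConfig(), min_umi = 800,
                       min_ratio = 1.2) {
  validateCountMatrix(m)
  st <- .cellStats(m)
  ratio <- ifelse(st$genes > 0, st$total / st$genes, NA)
  markers <- intersect(cfg$non_neuronal_markers, rownames(m))
  nn <- if (length(markers))
    Matrix::colSums(counts(m)[markers, , drop = FALSE] > 0) > 0
  else rep(FALSE, ncol(m))
  nogenes <- st$genes == 0
  fail <- list(low_molecules = st$total < min_umi,
               no_genes_detected = nogenes,
               low_ratio = !nogenes & ratio < min_ratio,
               non_neuronal = as.logical(nn))
  pass <- !Reduce(`|`, fail)
  cell <- data.frame(cell_id = colnames(m), total = as.numeric(st$total),
                     genes_detected = as.numeric(st$genes), ratio = ratio,
                     pass = pass, reason = .reasonString(fail),
                     stringsAsFactors = FALSE)
  .qcReport(cell, NULL, "dataset_b",
            list(min_umi = min_umi, min_ratio = min_ratio,
                 non_neuronal_markers = markers))
}

#' PatchSeq quality control
#'
#' Mitochondrial and rRNA genes (from the config) are removed before
#' counting; a cell then passes when it has strictly more than
#' `min_molecules` mRNA molecules OR strictly more than `min_genes`
#' distinct genes detected (inclusive OR).
#'
#' @param m count container.
#' @param cfg a [geneListConfig()] supplying `mito_genes` / `rrna_genes`.
#' @param min_molecules molecule threshold (default 2000, strict ">").
#' @param min_genes gene threshold (default 1000, strict ">").
#' @return a [QCReport-class] (cell table only).
#' @export
qcPatchseq <- function(m, cfg = geneListConfig(), min_molecules = 2000,
                       min_genes = 1000) {
  validateCountMatrix(m)
  drop <- intersect(c(cfg$mito_genes, cfg$rrna_genes), rownames(m))
  keep <- setdiff(rownames(m), drop)
  x <- counts(m)[keep, , drop = FALSE]
  total <- Matrix::colSums(x)
  genes <- Matrix::colSums(x > 0)
  fail <- list(low_molecules_and_genes =
                 !(total > min_molecules | genes > min_genes))
  cell <- data.frame(cell_id = colnames(m), total = as.numeric(total),
                     genes_detected = as.numeric(genes),
                     ratio = ifelse(genes > 0, total / genes, NA),
                     pass = !fail[[1]], reason = .reasonString(fail),
                     stringsAsFactors = FALSE)
  .qcReport(cell, NULL, "patchseq",
            list(min_molecules = min_molecules, min_genes = min_genes,
                 excluded_genes = drop))
}

#' Total-count normalization
#'
#' Scales every cell to `target` total molecules (each column multiplied by
#' `target/total`); with `round_to_integer` the scaled entries are then
#' rounded half-away-from-zero to the closest integer. Cells with zero
#' total cannot be scaled — QC-filter first.
#'
#' @param m count container (all cell totals > 0).
#' @param target total per cell after scaling (default 2000).
#' @param round_to_integer round the scaled entries (default TRUE).
#' @return a count container; integral when rounded, real otherwise
#'   (`validateCountMatrix(..., allow_real = TRUE)`).
#' @export
normalizeTotal <- function(m, target = 2000, round_to_integer = TRUE) {
  validateCountMatrix(m)
  tot <- Matrix::colSums(counts(m))
  if (any(tot == 0))
    stop("zero-total cell(s): run quality control before normalizing (",
         paste(head(colnames(m)[tot == 0], 5), collapse = ", "), ")")
  x <- counts(m) %*% Matrix::Diagonal(x = target / tot)
  x <- as(x, "CsparseMatrix")
  if (round_to_integer) x@x <- floor(x@x + 0.5)  # entries are >= 0
  x <- Matrix::drop0(x)
  dimnames(x) <- dimnames(m)
  out <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = x),
    colData = SummarizedExperiment::colData(m))
  out
}

#' Drop configured gene lists from a matrix
#'
#' Removes the genes named by the selected config lists (e.g. activity-
#' dependent genes before clustering). Symbols absent from the matrix are
#' ignored with a warning naming them.
#'
#' @param m count container.
#' @param cfg a [geneListConfig()].
#' @param lists which config lists to apply (default `activity_genes`).
#' @return the container without the listed genes.
#' @export
dropGeneLists <- function(m, cfg, lists = "activity_genes") {
  validateCountMatrix(m, allow_real = TRUE)
  bad <- setdiff(lists, names(cfg))
  if (length(bad)) stop("unknown gene list(s): ", paste(bad, collapse = ", "))
  symbols <- unique(unlist(cfg[lists], use.names = FALSE))
  absent <- setdiff(symbols, rownames(m))
  if (length(absent))
    warning("symbol(s) not in matrix, ignored: ",
            paste(head(absent, 10), collapse = ", "))
  keep <- setdiff(rownames(m), symbols)
  m[keep, ]
}
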
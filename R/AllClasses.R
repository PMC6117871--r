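#' @import methods
#' @importFrom stats aggregate approx coef complete.cases cor cor.test cov
#'   dnbinom hclust lm median optimize p.adjust pnorm prcomp predict pt
#'   quantile rbinom rlnorm rnbinom rnorm rpois runif sd setNames t.test var
#'   as.dist cutree dist
#' @importFrom utils combn head read.delim write.table tail
NULL

#' Cluster assignment for a set of cells
#'
#' Maps each cell identifier to a cluster label and records any merge
#' operations (fine label set to coarser label set) applied to it.
#'
#' @slot labels named character vector; names are cell ids, values cluster
#'   labels.
#' @slot hierarchy list of named character vectors, one per merge operation,
#'   each mapping the previous (finer) label set to the merged label set.
#'
#' @export
setClass("ClusterAssignment",
  representation(labels = "character", hierarchy = "list"),
  prototype(labels = character(0), hierarchy = list()))

setValidity("ClusterAssignment", function(object) {
  msgs <- character(0)
  if (length(object@labels) > 0L) {
    if (is.null(names(object@labels)) || any(!nzchar(names(object@labels))))
      msgs <- c(msgs, "labels must be named by cell id")
    if (anyDuplicated(names(object@labels)))
      msgs <- c(msgs, "duplicate cell ids in labels")
    if (anyNA(object@labels))
      msgs <- c(msgs, "NA cluster labels are not allowed")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a ClusterAssignment
#'
#' @param labels named character vector (cell id -> cluster label), or an
#'   unnamed vector together with `cell_ids`.
#' @param cell_ids optional character vector of cell ids when `labels` is
#'   unnamed.
#' @return A [ClusterAssignment-class] object.
#' @examples
#' ClusterAssignment(c(c1 = "A", c2 = "B"))
#' @export
ClusterAssignment <- function(labels, cell_ids = NULL) {
  nm <- names(labels)
  labels <- as.character(labels)
  names(labels) <- nm
  if (!is.null(cell_ids)) names(labels) <- cell_ids
  new("ClusterAssignment", labels = labels, hierarchy = list())
}

#' @describeIn ClusterAssignment-class number of labelled cells
#' @param x,object a `ClusterAssignment`
#' @export
setMethod("length", "ClusterAssignment", function(x) length(x@labels))

#' Accessors for ClusterAssignment
#'
#' `clusterLabels()` returns the named label vector, `clusterNames()` the
#' sorted unique labels, `clusterSizes()` a named table of cells per cluster.
#'
#' @param x a [ClusterAssignment-class]
#' @return character vector / table as described.
#' @export
clusterLabels <- function(x) {
  stopifnot(is(x, "ClusterAssignment"))
  x@labels
}

#' @rdname clusterLabels
#' @export
clusterNames <- function(x) sort(unique(clusterLabels(x)))

#' @rdname clusterLabels
#' @export
clusterSizes <- function(x) {
  lab <- clusterLabels(x)
  vapply(clusterNames(x), function(j) sum(lab == j), integer(1))
}

setMethod("show", "ClusterAssignment", function(object) {
  cat("ClusterAssignment:", length(object@labels), "cells,",
      length(unique(object@labels)), "clusters\n")
  sz <- clusterSizes(object)
  cat(paste0("  ", names(sz), " (", sz, ")", collapse = "\n"), "\n")
  if (length(object@hierarchy))
    cat("  merge history:", length(object@hierarchy), "operation(s)\n")
})

#' Quality-control report
#'
#' Per-cell (and, for schemes that filter genes, per-gene) pass/fail table
#' produced by the QC functions. Reason codes are drawn from a fixed
#' enumeration: `low_molecules`, `low_ratio`, `no_genes_detected`,
#' `non_neuronal`, `low_gene_total`, `low_molecules_and_genes`.
#'
#' @slot cell data.frame with columns `cell_id`, `total`, `genes_detected`,
#'   `ratio`, `pass`, `reason` (comma-separated failing reasons, "" if pass).
#' @slot gene data.frame with columns `gene_id`, `total`, `pass` (may have
#'   zero rows for schemes without gene filters).
#' @slot scheme character, one of "dataset_a", "dataset_b", "patchseq".
#' @slot params list of the thresholds used.
#' @export
setClass("QCReport",
  representation(cell = "data.frame", gene = "data.frame",
                 scheme = "character", params = "list"))

setValidity("QCReport", function(object) {
  ok <- c("low_molecules", "low_ratio", "no_genes_detected", "non_neuronal",
          "low_gene_total", "low_molecules_and_genes")
  reasons <- unlist(strsplit(object@cell$reason[object@cell$reason != ""], ","))
  if (length(reasons) && !all(reasons %in% ok))
    return("unknown reason code in cell report")
  if (any(object@cell$pass & object@cell$reason != ""))
    return("passing cell carries a failing reason")
  if (any(!object@cell$pass & object@cell$reason == ""))
    return("failing cell without reason code")
  TRUE
})

setMethod("show", "QCReport", function(object) {
  cat("QCReport [", object@scheme, "]: ",
      sum(object@cell$pass), "/", nrow(object@cell), " cells pass",
      sep = "")
  if (nrow(object@gene))
    cat("; ", sum(object@gene$pass), "/", nrow(object@gene), " genes pass",
        sep = "")
  cat("\n")
})

#' Cells passing a QC report
#' @param report a [QCReport-class]
#' @return character vector of passing cell ids.
#' @export
qcPassingCells <- function(report) {
  stopifnot(is(report, "QCReport"))
  report@cell$cell_id[report@cell$pass]
}

#' Genes passing a QC report
#' @param report a [QCReport-class]
#' @return character vector of passing gene ids (all genes if the scheme has
#'   no gene filter).
#' @export
qcPassingGenes <- function(report) {
  stopifnot(is(report, "QCReport"))
  if (!nrow(report@gene)) return(character(0))
  report@gene$gene_id[report@gene$pass]
}

#' Marker enrichment score table
#'
#' For every gene i and cluster j holds the molecule enrichment
#' `enrich[i,j]` (cluster mean over global mean), the fraction of positive
#' cells `posfrac[i,j]`, and the combined score
#' `S[i,j] = enrich[i,j] * posfrac[i,j]^power` for each requested power.
#'
#' @slot enrich genes x clusters numeric matrix.
#' @slot posfrac genes x clusters numeric matrix in \[0,1\].
#' @slot scores named list of genes x clusters matrices, one per power.
#' @slot powers numeric vector of powers.
#' @export
setClass("MarkerScores",
  representation(enrich = "matrix", posfrac = "matrix",
                 scores = "list", powers = "numeric"))

setValidity("MarkerScores", function(object) {
  if (any(object@posfrac < 0 | object@posfrac > 1))
    return("posfrac outside [0,1]")
  if (any(object@enrich < 0)) return("negative enrichment")
  if (length(object@scores) != length(object@powers))
    return("one score matrix per power required")
  TRUE
})

setMethod("show", "MarkerScores", function(object) {
  cat("MarkerScores:", nrow(object@enrich), "genes x",
      ncol(object@enrich), "clusters; powers:",
      paste(object@powers, collapse = ", "), "\n")
})

#' Gene-by-cluster specificity matrix
#'
#' `specificity[g, j]` is the mean expression of gene g in cluster j divided
#' by the sum of g's cluster means over all clusters, so each in-universe
#' gene's row sums to one. Genes with all-zero cluster means carry zeros and
#' are excluded from the background universe.
#'
#' @slot specificity genes x clusters numeric matrix.
#' @slot universe character vector of genes with a defined (nonzero) profile.
#' @export
setClass("SpecificityMatrix",
  representation(specificity = "matrix", universe = "character"))

setValidity("SpecificityMatrix", function(object) {
  sp <- object@specificity
  if (any(sp < -1e-12 | sp > 1 + 1e-12)) return("specificity outside [0,1]")
  rs <- rowSums(sp[object@universe, , drop = FALSE])
  if (length(rs) && max(abs(rs - 1)) > 1e-9)
    return("in-universe rows must sum to 1")
  TRUE
})

setMethod("show", "SpecificityMatrix", function(object) {
  cat("SpecificityMatrix:", nrow(object@specificity), "genes x",
      ncol(object@specificity), "clusters;",
      length(object@universe), "in universe\n")
})

#' Rank-1 negative-binomial latent factor model
#'
#' Model: log mu_ig = log s_i + a_g + f_i' c_g + w_g z_i with a negative
#' binomial observation model (variance mu + mu^2/theta). `z` is standardized
#' to mean 0 / variance 1; the sign is fixed so the gene with the largest
#' absolute weight has positive weight.
#'
#' @slot cellScores named numeric, standardized factor score z_i per cell.
#' @slot geneWeights named numeric, loading w_g per gene.
#' @slot intercepts named numeric a_g.
#' @slot covarCoefs genes x covariates matrix c_g (0 columns when no design).
#' @slot theta numeric shared NB dispersion.
#' @slot offsets named numeric log library-size offsets log s_i.
#' @slot logLikTrace numeric, penalized log-likelihood after each outer
#'   iteration (non-decreasing).
#' @slot converged logical.
#' @slot degenerate logical, TRUE when the input had no variance to explain.
#' @export
setClass("LatentFactorModel",
  representation(cellScores = "numeric", geneWeights = "numeric",
                 intercepts = "numeric", covarCoefs = "matrix",
                 theta = "numeric", offsets = "numeric",
                 logLikTrace = "numeric", converged = "logical",
                 degenerate = "logical"))

setMethod("show", "LatentFactorModel", function(object) {
  cat("LatentFactorModel:", length(object@cellScores), "cells,",
      length(object@geneWeights), "genes; theta =",
      signif(object@theta, 4), "\n")
  cat("  ", length(object@logLikTrace), " outer iterations; ",
      if (object@converged) "converged" else "NOT converged",
      if (object@degenerate) "; degenerate" else "", "\n", sep = "")
})

#' Latent factor cell scores
#' @param model a [LatentFactorModel-class]
#' @return named numeric vector of standardized per-cell scores.
#' @export
factorScores <- function(model) {
  stopifnot(is(model, "LatentFactorModel"))
  model@cellScores
}

#' Latent factor gene weights
#' @param model a [LatentFactorModel-class]
#' @return named numeric vector of per-gene loadings.
#' @export
factorWeights <- function(model) {
  stopifnot(is(model, "LatentFactorModel"))
  model@geneWeights
}

#' PatchSeq cluster mapping result
#'
#' @slot results data.frame with one row per query cell: `cell_id`,
#'   `assigned` (cluster label or "undefined"), `min_p`, `tie` flag.
#' @slot scores cells x clusters observed specificity-weighted scores.
#' @slot pvals cells x clusters bootstrap p-values, each in \[1/(B+1), 1\].
#' @slot genesUsed character, the variance-filtered marker genes G.
#' @slot B integer bootstrap count; @slot alpha numeric threshold;
#' @slot seed integer seed.
#' @export
setClass("PatchSeqMapping",
  representation(results = "data.frame", scores = "matrix", pvals = "matrix",
                 genesUsed = "character", B = "integer", alpha = "numeric",
                 seed = "integer"))

setValidity("PatchSeqMapping", function(object) {
  if (nrow(object@pvals)) {
    lo <- 1 / (object@B + 1)
    if (any(object@pvals < lo - 1e-12 | object@pvals > 1 + 1e-12))
      return("p-values outside [1/(B+1), 1]")
  }
  TRUE
})

setMethod("show", "PatchSeqMapping", function(object) {
  n <- nrow(object@results)
  nu <- sum(object@results$assigned == "undefined")
  cat("PatchSeqMapping:", n, "cells;", n - nu, "assigned,", nu,
      "undefined (alpha =", object@alpha, ", B =", object@B, ")\n")
})

#' Mapping summary counts
#' @param x a [PatchSeqMapping-class]
#' @return list with `n_assigned`, `n_undefined`, `assigned_table`.
#' @export
mappingSummary <- function(x) {
  stopifnot(is(x, "PatchSeqMapping"))
  undef <- x@results$assigned == "undefined"
  list(n_assigned = sum(!undef), n_undefined = sum(undef),
       assigned_table = table(x@results$assigned[!undef]))
}

#' Current-clamp sweep set for one cell
#'
#' Each sweep is a uniformly sampled voltage trace (mV) recorded while a
#' square current step (pA) is injected between `onset` and `offset`
#' seconds. All sweeps share the sampling rate and stimulus window.
#'
#' @slot voltages list of numeric vectors, one per sweep (mV).
#' @slot currents numeric, injected current per sweep (pA).
#' @slot fs numeric sampling rate (Hz).
#' @slot onset,offset numeric stimulus window (s).
#' @slot cellId character.
#' @export
setClass("SweepSet",
  representation(voltages = "list", currents = "numeric", fs = "numeric",
                 onset = "numeric", offset = "numeric", cellId = "character"))

setValidity("SweepSet", function(object) {
  if (length(object@voltages) != length(object@currents))
    return("one current per sweep required")
  n <- lengths(object@voltages)
  if (length(n) && any(n != n[1])) return("sweeps must share trace length")
  if (length(n) && object@offset * object@fs > n[1])
    return("stimulus window must lie inside the trace")
  if (object@onset >= object@offset) return("onset must precede offset")
  TRUE
})

setMethod("show", "SweepSet", function(object) {
  cat("SweepSet [", object@cellId, "]: ", length(object@voltages),
      " sweeps, ", object@fs / 1000, " kHz, step ",
      round(1000 * (object@offset - object@onset)), " ms, I in [",
      min(object@currents), ", ", max(object@currents), "] pA\n", sep = "")
})

#' Construct a SweepSet
#'
#' @param voltages list of numeric voltage traces (mV), equal lengths.
#' @param currents numeric vector of injected currents (pA), one per sweep.
#' @param fs sampling rate in Hz.
#' @param onset,offset stimulus window in seconds.
#' @param cell_id identifier for the recorded cell.
#' @return A [SweepSet-class].
#' @export
SweepSet <- function(voltages, currents, fs, onset, offset,
                     cell_id = "cell") {
  new("SweepSet", voltages = lapply(voltages, as.numeric),
      currents = as.numeric(currents), fs = as.numeric(fs),
      onset = as.numeric(onset), offset = as.numeric(offset),
      cellId = as.character(cell_id))
}
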
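#' Plate indicator design matrix
#'
#' Builds the batch-covariate design used by the latent factor model: one
#' indicator column per plate except a reference plate, holding a one if
#' the cell came from that plate and a zero otherwise.
#'
#' @param plates character/factor vector of plate labels, one per cell
#'   (names taken as cell ids when present).
#' @param reference reference plate receiving no column (default: first
#'   sorted level).
#' @return numeric matrix, cells x (plates - 1); 0 columns if one plate.
#' @export
plateDesign <- function(plates, reference = NULL) {
  plates <- as.character(plates)
  levs <- sort(unique(plates))
  if (is.null(reference)) reference <- levs[1]
  if (!reference %in% levs) stop("reference plate not present")
  keep <- setdiff(levs, reference)
  d <- vapply(keep, function(p) as.numeric(plates == p),
              numeric(length(plates)))
  d <- matrix(d, nrow = length(plates),
              dimnames = list(names(plates), paste0("plate_", keep)))
  d
}

#' Gene inclusion filter for the latent factor model
#'
#' A gene enters the within-cluster factor analysis only if it has over
#' `min_reads` reads in over `min_cells` cells of the cluster (both
#' inequalities strict: count 4 in 9 cells qualifies, count 4 in 8 cells
#' or count 3 anywhere does not).
#'
#' @param m count container restricted to the cluster's cells.
#' @param min_reads read threshold (default 3, strict ">").
#' @param min_cells cell threshold (default 8, strict ">").
#' @return character vector of retained gene ids.
#' @export
filterGenesLatent <- function(m, min_reads = 3, min_cells = 8) {
  validateCountMatrix(m)
  ncell <- Matrix::rowSums(counts(m) > min_reads)
  rownames(m)[ncell > min_cells]
}

.nbLogLik <- function(y, eta, theta) {
  mu <- exp(pmin(eta, 30))
  sum(dnbinom(y, size = theta, mu = mu, log = TRUE))
}

.fitGeneNB <- function(y, X, offset, theta, start = NULL) {
  fam <- MASS::negative.binomial(theta = theta)
  fit <- tryCatch(
    suppressWarnings(stats::glm.fit(X, y, family = fam, offset = offset,
                                    start = start,
                                    control = list(maxit = 50))),
    error = function(e) NULL)
  if (is.null(fit) || anyNA(fit$coefficients)) return(NULL)
  fit$coefficients
}

#' Fit a rank-1 negative-binomial latent factor model
#'
#' Model: `log mu_ig = log s_i + a_g + f_i' c_g + w_g z_i`, NB observation
#' model with shared dispersion theta (variance mu + mu^2/theta). The
#' offsets log s_i equalize per-cell totals (s_i = total_i / mean total),
#' the optional design `f_i` carries plate indicator columns
#' ([plateDesign()]). Fitting is block coordinate ascent: per-gene NB
#' regressions given z (IRLS), a 1-D likelihood maximization of the shared
#' theta, and per-cell 1-D concave maximizations of z_i, iterated until the
#' relative log-likelihood change drops below `tol`. z is standardized to
#' mean 0 / variance 1 after every sweep (the scale is re-absorbed into the
#' weights and intercepts, leaving the likelihood unchanged), and the
#' global sign is fixed so the gene with the largest |w| has positive
#' weight. The log-likelihood trace is non-decreasing across outer
#' iterations. Initialization is the first principal component of the
#' log2-normalized matrix, so the fit is deterministic.
#'
#' @param m count container: one cluster's cells, genes pre-filtered with
#'   [filterGenesLatent()]. Needs >= 2 genes and >= 3 cells.
#' @param design optional cells x covariates numeric matrix.
#' @param tol relative log-likelihood tolerance (default 1e-6).
#' @param max_iter outer iteration cap (default 200); non-convergence
#'   returns the model with a warning.
#' @param theta_init initial dispersion (default 2).
#' @return a [LatentFactorModel-class].
#' @export
fitLatentFactor <- function(m, design = NULL, tol = 1e-6, max_iter = 200,
                            theta_init = 2) {
  validateCountMatrix(m)
  y <- counts(m, dense = TRUE)
  G <- nrow(y); n <- ncol(y)
  if (G < 2) stop("need >= 2 genes")
  if (n < 3) stop("need >= 3 cells")
  if (is.null(design)) design <- matrix(0, n, 0)
  design <- as.matrix(design)
  if (nrow(design) != n) stop("design rows must match cells")
  p <- ncol(design)

  tot <- colSums(y)
  s <- tot / mean(tot)
  if (any(tot == 0)) stop("zero-total cell(s); QC first")
  off <- log(s)

  lx <- log2(sweep(y, 2, mean(tot) / tot, `*`) + 1)
  cellVar <- apply(lx, 2, var)
  if (all(apply(lx, 1, var) < 1e-12)) {
    zero <- setNames(rep(0, n), colnames(y))
    return(new("LatentFactorModel", cellScores = zero,
               geneWeights = setNames(rep(0, G), rownames(y)),
               intercepts = setNames(log(pmax(rowMeans(y), 1e-8)),
                                     rownames(y)),
               covarCoefs = matrix(0, G, p,
                                   dimnames = list(rownames(y),
                                                   colnames(design))),
               theta = theta_init, offsets = setNames(off, colnames(y)),
               logLikTrace = numeric(0), converged = TRUE,
               degenerate = TRUE))
  }
  # initialize from PC1 of the log-normalized matrix, residualized on the
  # covariate design so a batch direction cannot seed the factor
  lxr <- lx
  if (p > 0) {
    Xd <- cbind(1, design)
    lxr <- t(stats::lm.fit(Xd, t(lx))$residuals)
  }
  pc <- prcomp(t(lxr), center = TRUE, scale. = FALSE)
  z <- pc$x[, 1]
  if (sd(z) < 1e-12) z <- rnorm(n)  # unreachable for non-constant input
  z <- as.numeric(scale(z))

  A <- rep(0, G); W <- rep(0, G)
  Cf <- matrix(0, G, p)
  theta <- theta_init
  X <- cbind(1, design, z)
  trace <- numeric(0)
  prev_ll <- -Inf
  converged <- FALSE

  etaOf <- function(A, Cf, W, z) {
    e <- matrix(A, G, n) + W %o% z +
      (if (p > 0) Cf %*% t(design) else 0)
    sweep(e, 2, off, `+`)
  }
  llOf <- function(A, Cf, W, z, theta)
    .nbLogLik(y, etaOf(A, Cf, W, z), theta)

  for (it in seq_len(max_iter)) {
    X[, p + 2] <- z
    for (g in seq_len(G)) {
      st <- c(A[g], if (p > 0) Cf[g, ], W[g])
      cf <- .fitGeneNB(y[g, ], X, off, theta, start = st)
      if (!is.null(cf)) {
        # keep the update only if it does not hurt this gene's likelihood
        eta_new <- off + drop(X %*% cf)
        eta_old <- off + drop(X %*% st)
        if (.nbLogLik(y[g, ], eta_new, theta) >=
            .nbLogLik(y[g, ], eta_old, theta)) {
          A[g] <- cf[1]
          if (p > 0) Cf[g, ] <- cf[2:(p + 1)]
          W[g] <- cf[p + 2]
        }
      }
    }
    opt <- optimize(function(lt) llOf(A, Cf, W, z, exp(lt)),
                    interval = c(log(1e-2), log(1e4)), maximum = TRUE)
    if (llOf(A, Cf, W, z, exp(opt$maximum)) >= llOf(A, Cf, W, z, theta))
      theta <- exp(opt$maximum)
    base <- sweep(matrix(A, G, n) +
                    (if (p > 0) Cf %*% t(design) else 0), 2, off, `+`)
    for (i in seq_len(n)) {
      f <- function(zi) {
        eta <- base[, i] + W * zi
        .nbLogLik(y[, i], eta, theta)
      }
      o <- optimize(f, interval = c(-10, 10), maximum = TRUE)
      if (o$objective >= f(z[i])) z[i] <- o$maximum
    }
    mz <- mean(z); sz <- sd(z)
    if (sz < 1e-10) {
      z <- rep(0, n); W <- rep(0, G)
      trace <- c(trace, llOf(A, Cf, W, z, theta))
      degenerate <- TRUE
      converged <- TRUE
      break
    }
    A <- A + W * mz
    W <- W * sz
    z <- (z - mz) / sz
    ll <- llOf(A, Cf, W, z, theta)
    trace <- c(trace, ll)
    if (is.finite(prev_ll) &&
        abs(ll - prev_ll) / (abs(prev_ll) + 1) < tol) {
      converged <- TRUE
      break
    }
    prev_ll <- ll
  }
  if (!exists("degenerate", inherits = FALSE)) degenerate <- FALSE
  if (!converged)
    warning("latent factor fit did not converge in ", max_iter,
            " iterations")
  g_top <- which.max(abs(W))
  if (length(g_top) && W[g_top] < 0) {
    W <- -W; z <- -z
  }
  new("LatentFactorModel",
      cellScores = setNames(z, colnames(y)),
      geneWeights = setNames(W, rownames(y)),
      intercepts = setNames(A, rownames(y)),
      covarCoefs = matrix(Cf, G, p,
                          dimnames = list(rownames(y), colnames(design))),
      theta = theta, offsets = setNames(off, colnames(y)),
      logLikTrace = trace, converged = converged, degenerate = degenerate)
}

#' Association between the latent factor and one gene's expression
#'
#' Negative-binomial generalized linear model of a gene's counts on the
#' per-cell factor score z (with the model's library-size offsets and,
#' optionally, the batch design). Returns the slope on the z scale, its
#' standard error and the Wald p-value.
#'
#' @param model a [LatentFactorModel-class].
#' @param gene_counts numeric counts for the model's cells (named vectors
#'   are aligned by cell id).
#' @param design optional covariate matrix matching the cells.
#' @return list with `coefficient`, `se`, `p`, `undefined` flag.
#' @export
factorGeneAssociation <- function(model, gene_counts, design = NULL) {
  z <- factorScores(model)
  if (!is.null(names(gene_counts)))
    gene_counts <- gene_counts[names(z)]
  if (anyNA(gene_counts) || length(gene_counts) != length(z))
    stop("gene counts must cover the model's cells")
  if (all(gene_counts == 0) || var(gene_counts) == 0)
    return(list(coefficient = NA_real_, se = NA_real_, p = NA_real_,
                undefined = TRUE))
  off <- model@offsets
  dat <- data.frame(y = as.numeric(gene_counts), z = as.numeric(z))
  form <- y ~ z
  if (!is.null(design) && ncol(design) > 0) {
    dat <- cbind(dat, as.data.frame(design))
    form <- stats::reformulate(c("z", colnames(design)), response = "y")
  }
  fit <- tryCatch(
    suppressWarnings(MASS::glm.nb(form, data = dat,
                                  offset = off,
                                  control = stats::glm.control(maxit = 100))),
    error = function(e) NULL)
  if (is.null(fit)) {  # fall back to fixed-dispersion GLM at the model theta
    fit <- suppressWarnings(
      stats::glm(form, data = dat, offset = off,
                 family = MASS::negative.binomial(theta = model@theta)))
  }
  sm <- summary(fit)$coefficients
  list(coefficient = sm["z", 1], se = sm["z", 2],
       p = 2 * pnorm(-abs(sm["z", 1] / sm["z", 2])), undefined = FALSE)
}

#' Association between the factor and an electrophysiological parameter
#'
#' Projects query (PatchSeq) expression onto the factor by taking logs and
#' multiplying with the latent factor gene weights
#' (`projection_i = sum_g w_g log(x_gi + 1)`), then fits an ordinary
#' linear model of the ephys parameter on the projection.
#'
#' @param model a [LatentFactorModel-class] (or a named weight vector).
#' @param expr genes x cells expression matrix for the query cells.
#' @param ephys_param numeric, one value per query cell.
#' @param min_overlap minimum gene overlap (default 10; fewer is an error).
#' @return list with `projection` (named per cell), `slope`, `p`,
#'   `undefined` flag.
#' @export
factorEphysAssociation <- function(model, expr, ephys_param,
                                   min_overlap = 10) {
  w <- if (is(model, "LatentFactorModel")) factorWeights(model) else model
  expr <- as.matrix(expr)
  common <- intersect(names(w), rownames(expr))
  if (length(common) < min_overlap)
    stop("gene overlap (", length(common), ") below required ",
         min_overlap)
  proj <- colSums(w[common] * log(expr[common, , drop = FALSE] + 1))
  if (length(ephys_param) != length(proj))
    stop("one ephys value per query cell required")
  if (sd(proj) < 1e-12)
    return(list(projection = proj, slope = NA_real_, p = NA_real_,
                undefined = TRUE))
  fit <- lm(ephys_param ~ proj)
  sm <- summary(fit)$coefficients
  list(projection = proj, slope = sm["proj", 1], p = sm["proj", 4],
       undefined = FALSE)
}

#' Within-cluster gradient screen against embedding coordinates
#'
#' For one cluster, keeps genes expressed (> 0) in strictly more than 10%
#' of the cluster's cells and detected in strictly less than 70% of all
#' cells of the dataset, then computes the Pearson correlation between
#' each kept gene's (log-transformed) expression and the embedding x and y
#' coordinates of the cluster's cells.
#'
#' @param m count container (full dataset; detection fractions use all
#'   cells).
#' @param a a [ClusterAssignment-class].
#' @param cluster label of the cluster to screen.
#' @param coords coordinate matrix from [readCoords()] covering all
#'   cluster cells.
#' @param min_cluster_frac in-cluster detection threshold (default 0.1,
#'   strict ">").
#' @param max_dataset_frac whole-dataset detection ceiling (default 0.7,
#'   strict "<").
#' @param log_transform correlate log2(x+1) expression (default TRUE).
#' @return data.frame per gene: `gene`, `included`, `cluster_frac`,
#'   `dataset_frac`, `r_x`, `r_y` (NA for excluded genes).
#' @export
gradientScreen <- function(m, a, cluster, coords, min_cluster_frac = 0.1,
                           max_dataset_frac = 0.7, log_transform = TRUE) {
  validateCountMatrix(m, allow_real = TRUE)
  lab <- clusterLabels(a)
  cells <- names(lab)[lab == cluster]
  if (length(cells) < 3) stop("cluster has fewer than 3 cells")
  miss <- setdiff(cells, rownames(coords))
  if (length(miss))
    stop("coordinates missing for: ", paste(head(miss, 5), collapse = ", "))
  x <- counts(m)
  cl_frac <- as.numeric(Matrix::rowMeans(x[, cells, drop = FALSE] > 0))
  ds_frac <- as.numeric(Matrix::rowMeans(x > 0))
  keep <- cl_frac > min_cluster_frac & ds_frac < max_dataset_frac
  e <- as.matrix(x[, cells, drop = FALSE])
  if (log_transform) e <- log2(e + 1)
  cx <- coords[cells, "x"]; cy <- coords[cells, "y"]
  r_x <- r_y <- rep(NA_real_, nrow(m))
  if (any(keep)) {
    ek <- t(e[keep, , drop = FALSE])
    r_x[keep] <- suppressWarnings(as.numeric(cor(ek, cx)))
    r_y[keep] <- suppressWarnings(as.numeric(cor(ek, cy)))
  }
  data.frame(gene = rownames(m), included = keep, cluster_frac = cl_frac,
             dataset_frac = ds_frac, r_x = r_x, r_y = r_y,
             stringsAsFactors = FALSE)
}
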
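rank1Fixture <- function(n = 200, G = 100, seed = 1, theta = 3,
                         w_sd = 0.4) {
  set.seed(seed)
  z <- rnorm(n)
  w <- rnorm(G, 0, w_sd)
  a <- log(rlnorm(G, 1, 0.7))
  mu <- exp(matrix(a, G, n) + w %o% z)
  y <- matrix(rnbinom(G * n, mu = mu, size = theta), G, n)
  list(m = CountMatrix(y, sprintf("g%03d", 1:G), sprintf("c%03d", 1:n)),
       z = z, w = w, y = y)
}

test_that("latent gene filter applies both strict inequalities", {
  # count 4 in 9 cells: kept; 4 in 8 cells: dropped; 3 in many: dropped
  x <- matrix(0L, 3, 100,
              dimnames = list(c("kept", "few", "shallow"),
                              sprintf("c%03d", 1:100)))
  x["kept", 1:9] <- 4
  x["few", 1:8] <- 4
  x["shallow", ] <- 3
  m <- CountMatrix(x, rownames(x), colnames(x))
  expect_identical(filterGenesLatent(m), "kept")
})

test_that("plate design builds reference-omitted indicator columns", {
  d <- plateDesign(c("P2", "P1", "P3", "P1"))
  expect_identical(colnames(d), c("plate_P2", "plate_P3"))
  expect_equal(unname(rowSums(d)), c(1, 0, 1, 0))
  expect_true(all(d %in% c(0, 1)))
  expect_error(plateDesign(c("a", "b"), reference = "zz"), "not present")
})

test_that("rank-1 NB factor recovers planted scores and weights", {
  fx <- rank1Fixture(seed = 101)
  fit <- fitLatentFactor(fx$m)
  expect_true(fit@converged)
  expect_true(all(diff(fit@logLikTrace) >= -1e-6))
  expect_gt(abs(cor(factorScores(fit), fx$z)), 0.9)
  # z is standardized; sign convention: largest |w| positive
  expect_equal(mean(factorScores(fit)), 0, tolerance = 1e-8)
  expect_equal(sd(factorScores(fit)), 1, tolerance = 1e-8)
  w <- factorWeights(fit)
  expect_gt(w[which.max(abs(w))], 0)
  # sign-consistent loadings for genes well above the noise floor
  s <- sign(cor(factorScores(fit), fx$z))
  strong <- abs(fx$w) > 0.2
  expect_gt(mean(sign(w[strong]) == sign(s * fx$w[strong])), 0.9)
})

test_that("a constant matrix yields the degenerate flag and zero weights", {
  x <- matrix(5L, 10, 8)
  m <- toyMatrix(x, sprintf("g%02d", 1:10))
  fit <- fitLatentFactor(m)
  expect_true(fit@degenerate)
  expect_true(all(abs(factorWeights(fit)) < 1e-6))
})

test_that("plate covariates absorb a planted batch effect", {
  set.seed(55)
  n <- 150; G <- 80
  plate <- rep(c("P1", "P2"), length.out = n)
  pe <- rnorm(G, 0, 0.6)
  a <- log(rlnorm(G, 1, 0.6))
  mu <- exp(matrix(a, G, n) + pe %o% as.numeric(plate == "P2"))
  y <- matrix(rnbinom(G * n, mu = mu, size = 3), G, n)
  m <- CountMatrix(y, sprintf("g%03d", 1:G), sprintf("c%03d", 1:n))
  ind <- as.numeric(plate == "P2")
  f_omit <- fitLatentFactor(m)
  f_incl <- fitLatentFactor(m, design = plateDesign(plate))
  expect_gt(abs(cor(factorScores(f_omit), ind)), 0.5)
  expect_lt(abs(cor(factorScores(f_incl), ind)), 0.2)
})

test_that("factor-gene association flags degenerate genes and finds signal", {
  fx <- rank1Fixture(seed = 7)
  fit <- fitLatentFactor(fx$m)
  # strong signal: counts generated from exp(z) on the fitted score scale
  set.seed(8)
  y_sig <- rpois(length(fx$z), exp(1 + factorScores(fit)))
  res <- factorGeneAssociation(fit, y_sig)
  expect_gt(res$coefficient, 0)
  expect_lt(res$p, 1e-6)
  expect_true(factorGeneAssociation(fit, rep(3, length(fx$z)))$undefined)
})

test_that("factor-gene association p-values are calibrated under the null", {
  set.seed(12)
  n <- 500
  z <- rnorm(n)
  y0 <- matrix(rnbinom(40 * n, mu = 5, size = 3), 40, n)
  m <- CountMatrix(y0, sprintf("g%02d", 1:40), sprintf("c%03d", 1:n))
  fit <- suppressWarnings(fitLatentFactor(m, max_iter = 5))
  ps <- vapply(seq_len(200), function(i) {
    yi <- rnbinom(n, mu = 6, size = 3)
    factorGeneAssociation(fit, yi)$p
  }, numeric(1))
  expect_gt(mean(ps < 0.05), 0.02)
  expect_lt(mean(ps < 0.05), 0.09)
})

test_that("ephys association projects on log expression and needs overlap", {
  fx <- rank1Fixture(n = 50, G = 40, seed = 13)
  fit <- fitLatentFactor(fx$m)
  w <- factorWeights(fit)
  expr <- counts(fx$m, dense = TRUE)
  proj <- colSums(w * log(expr + 1))
  set.seed(14)
  ep <- 2 * proj + rnorm(50, 0, sd(proj) / 4)
  res <- factorEphysAssociation(fit, expr, ep)
  expect_equal(unname(res$projection), unname(proj))
  expect_gt(res$slope, 0)
  expect_lt(res$p, 0.01)
  expect_error(factorEphysAssociation(fit, expr[1, , drop = FALSE], ep),
               "overlap")
})

test_that("gradient screen enforces the 10% / 70% detection filters", {
  set.seed(15)
  n_in <- 40; n_out <- 160
  cells <- sprintf("c%03d", seq_len(n_in + n_out))
  lab <- setNames(c(rep("Pthlh", n_in), rep("other", n_out)), cells)
  # gene at exactly 10% in-cluster detection: excluded (strict >)
  x <- matrix(0L, 4, n_in + n_out,
              dimnames = list(c("at10", "ok", "ubiq", "xgene"), cells))
  x["at10", 1:4] <- 1                       # 4/40 = 10%
  x["ok", 1:20] <- 3                        # 50% in-cluster
  x["ubiq", ] <- 2                          # 100% dataset-wide
  coords <- cbind(x = rnorm(n_in), y = rnorm(n_in))
  rownames(coords) <- cells[1:n_in]
  x["xgene", 1:n_in] <- as.integer(round(10 + 3 * coords[, "x"]))
  m <- CountMatrix(x, rownames(x), cells)
  res <- gradientScreen(m, ClusterAssignment(lab), "Pthlh", coords,
                        log_transform = FALSE)
  inc <- setNames(res$included, res$gene)
  expect_identical(inc, c(at10 = FALSE, ok = TRUE, ubiq = FALSE,
                          xgene = TRUE))
  # a gene equal to the x coordinate correlates perfectly with x
  expect_equal(res$r_x[res$gene == "xgene"],
               cor(as.numeric(x["xgene", 1:n_in]), coords[, "x"]))
  expect_gt(res$r_x[res$gene == "xgene"], 0.95)
  expect_true(all(is.na(res$r_x[!res$included])))
})

test_that("gradient screen filter agrees with brute-force filtering", {
  set.seed(16)
  sim <- simulateCounts(countSimConfig(n_clusters = 3,
                                       cells_per_cluster = 50,
                                       n_genes = 120,
                                       markers_per_cluster = 10),
                        seed = 17)
  m <- sim$matrix
  lab <- clusterLabels(sim$assignment)
  cl1 <- names(lab)[lab == "C1"]
  coords <- cbind(x = rnorm(length(cl1)), y = rnorm(length(cl1)))
  rownames(coords) <- cl1
  res <- gradientScreen(m, sim$assignment, "C1", coords)
  x <- counts(m, dense = TRUE)
  brute <- rowMeans(x[, cl1] > 0) > 0.1 & rowMeans(x > 0) < 0.7
  expect_identical(res$included, unname(brute))
})

test_that("noise genes rarely correlate with the embedding", {
  set.seed(18)
  n <- 500
  cells <- sprintf("c%03d", 1:n)
  coords <- cbind(x = rnorm(n), y = rnorm(n))
  rownames(coords) <- cells
  hits <- vapply(seq_len(100), function(i) {
    g <- rnbinom(n, mu = 2, size = 2)
    abs(cor(g, coords[, "x"])) < 0.15
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
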
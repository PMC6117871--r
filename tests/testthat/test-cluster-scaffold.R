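test_that("variable-gene selection ranks by residual dispersion", {
  # two genes with the same mean but different CV: the dispersed one wins
  set.seed(3)
  n <- 60
  flat <- rep(4, n)
  lowcv <- rep(c(3, 5), n / 2)                      # CV ~ 0.25
  hicv <- rep(c(0, 8), n / 2)                       # CV ~ 1
  filler <- matrix(rpois(20 * n, 4), 20, n)
  x <- rbind(flat = flat, lowcv = lowcv, hicv = hicv, filler)
  rownames(x) <- c("flat", "lowcv", "hicv", sprintf("f%02d", 1:20))
  m <- toyMatrix(x, rownames(x))
  fit <- selectVariableGenes(m, n = 2)
  sel <- selectedGenes(fit)
  expect_true("hicv" %in% sel)
  expect_false("flat" %in% sel)                      # zero CV never ahead
  tab <- fit@table
  expect_gt(tab$residual[tab$gene == "hicv"],
            tab$residual[tab$gene == "lowcv"])
})

test_that("planted high-dispersion genes dominate the selection", {
  set.seed(11)
  n <- 80
  pois <- matrix(rpois(500 * n, rlnorm(500, 1, 0.5)), 500, n)
  disp <- matrix(rnbinom(50 * n, mu = rlnorm(50, 1, 0.5), size = 0.3),
                 50, n)
  x <- rbind(pois, disp)
  rownames(x) <- c(sprintf("p%03d", 1:500), sprintf("d%03d", 1:50))
  m <- CountMatrix(x, rownames(x), sprintf("c%03d", seq_len(n)))
  fit <- selectVariableGenes(m, n = 50)
  expect_gte(sum(startsWith(selectedGenes(fit), "d")), 45)
})

test_that("selection is invariant to global count rescaling", {
  set.seed(5)
  x <- matrix(rnbinom(600, mu = 6, size = 1), 30, 20)
  rownames(x) <- sprintf("g%02d", 1:30)
  m1 <- toyMatrix(x, rownames(x))
  m2 <- toyMatrix(7 * x, rownames(x))
  f1 <- selectVariableGenes(m1, n = 10)
  f2 <- selectVariableGenes(m2, n = 10)
  expect_identical(selectedGenes(f1), selectedGenes(f2))
})

test_that("stand-in clustering recovers well-separated synthetic clusters", {
  sim <- simulateCounts(countSimConfig(n_clusters = 2,
                                       cells_per_cluster = 50,
                                       n_genes = 200,
                                       markers_per_cluster = 20,
                                       marker_fold = 8), seed = 21)
  nm <- normalizeTotal(sim$matrix)
  fit <- selectVariableGenes(nm, n = 100)
  cl <- clusterCells(nm, fit, k = 2)
  expect_equal(adjustedRand(clusterLabels(cl),
                            clusterLabels(sim$assignment)), 1)
  # k = 1 puts everyone together; duplication does not change the split
  expect_equal(length(unique(clusterLabels(clusterCells(nm, fit, 1)))), 1L)
  dup <- toyMatrix(cbind(counts(nm, dense = TRUE),
                         counts(nm, dense = TRUE)),
                   rownames(nm), c(colnames(nm), paste0(colnames(nm), "_d")))
  cld <- clusterCells(dup, fit, k = 2)
  lab <- clusterLabels(cld)
  expect_identical(unname(lab[colnames(nm)]),
                   unname(lab[paste0(colnames(nm), "_d")]))
})

test_that("cluster merging relabels through the fine-to-coarse map", {
  a <- ClusterAssignment(setNames(paste0("f", rep(1:4, each = 2)),
                                  paste0("c", 1:8)))
  map <- c(f1 = "A", f2 = "A", f3 = "B", f4 = "B")
  mg <- mergeClusters(a, map)
  expect_identical(sort(unique(clusterLabels(mg))), c("A", "B"))
  expect_equal(unname(clusterSizes(mg)), c(4L, 4L))
  expect_length(mg@hierarchy, 1L)
  ident <- mergeClusters(a, setNames(paste0("f", 1:4), paste0("f", 1:4)))
  expect_identical(clusterLabels(ident), clusterLabels(a))
  expect_error(mergeClusters(a, map[1:3]), "unmapped")
})

test_that("robustness assessment is perfect on disjoint marker blocks", {
  sim <- simulateCounts(countSimConfig(n_clusters = 3,
                                       cells_per_cluster = 40,
                                       n_genes = 150,
                                       markers_per_cluster = 25,
                                       marker_fold = 12), seed = 31)
  rep <- assessRobustness(sim$matrix, sim$assignment, seed = 1)
  expect_true(all(rep@recall > 0.95))
  expect_true(all(rep@precision > 0.95, na.rm = TRUE))
  expect_equal(unname(rowSums(rep@confusion)), rep(1, 3))
})

test_that("robustness on shuffled labels collapses to chance recall", {
  sim <- simulateCounts(countSimConfig(n_clusters = 2,
                                       cells_per_cluster = 60,
                                       n_genes = 100,
                                       markers_per_cluster = 10,
                                       marker_fold = 6), seed = 41)
  set.seed(42)
  lab <- clusterLabels(sim$assignment)
  shuf <- ClusterAssignment(setNames(sample(unname(lab)), names(lab)))
  rep <- assessRobustness(sim$matrix, shuf, seed = 2, repeats = 5)
  # chance recall ~ cluster frequency 0.5; allow 3 binomial SDs at n ~ 12
  expect_true(all(abs(rep@recall - 0.5) < 3 * sqrt(0.25 / 12)))
})

test_that("robustness refuses singleton clusters by name", {
  m <- toyMatrix(matrix(rpois(40, 5), 4))
  a <- ClusterAssignment(setNames(c("A", rep("B", 9)), colnames(m)))
  expect_error(assessRobustness(m, a), "A")
})

test_that("cluster-mean dendrogram follows correlation structure", {
  # A and B share a profile up to scale (perfect correlation), C is
  # anti-structured: A and B must merge first, at height ~0
  prof <- c(10, 1, 5, 2, 8, 1, 4, 9, 2, 6)
  mk <- function(p, n) vapply(seq_len(n), function(i)
    rpois(length(p), 50 * p), numeric(length(p)))
  x <- cbind(mk(prof, 5), mk(prof, 5), mk(rev(prof), 5))
  rownames(x) <- sprintf("g%02d", seq_along(prof))
  colnames(x) <- sprintf("c%02d", 1:15)
  m <- CountMatrix(x, rownames(x), colnames(x))
  a <- ClusterAssignment(setNames(rep(c("A", "B", "C"), each = 5),
                                  colnames(x)))
  h <- clusterMeanDendrogram(m, a)
  first <- h$labels[-h$merge[1, ]]
  expect_setequal(first, c("A", "B"))
  expect_lt(h$height[1], h$height[2])
  # identical profiles merge at height 0
  x2 <- cbind(mk(prof, 3), mk(prof, 3))
  colnames(x2) <- sprintf("d%02d", 1:6)
  m2 <- CountMatrix(round(cbind(x2[, 1:3], x2[, 1:3])), rownames(x),
                    colnames(x2))
  a2 <- ClusterAssignment(setNames(rep(c("A", "B"), each = 3),
                                   colnames(x2)))
  h2 <- clusterMeanDendrogram(m2, a2)
  expect_equal(h2$height[1], 0, tolerance = 1e-12)
  expect_equal(nrow(h2$merge), 1L)
  nw <- dendrogramNewick(h)
  expect_match(nw, "^\\(")
  expect_true(all(vapply(c("A", "B", "C"), grepl, logical(1), x = nw)))
})
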
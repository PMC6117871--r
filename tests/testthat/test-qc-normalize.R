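# One gene per "row role": builds a matrix whose cells sit exactly on the
# QC decision boundaries of the three schemes.

test_that("dataset A thresholds are strict as printed", {
  # two cells at totals 1500 / 1501; two genes at totals 24 / 25
  x <- rbind(gA = c(1476, 1501), gB = c(24, 0), gC = c(0, 0))
  x["gC", ] <- 0
  m <- toyMatrix(x, c("gA", "gB", "gC"), c("lo", "hi"))
  rep <- qcDatasetA(m)
  cell <- rep@cell
  expect_equal(cell$total, c(1500, 1501))
  expect_identical(cell$pass, c(FALSE, TRUE))
  gene <- rep@gene
  expect_identical(setNames(gene$pass, gene$gene_id),
                   c(gA = TRUE, gB = FALSE, gC = FALSE))
  # all-zero matrix: everything fails
  z <- qcDatasetA(toyMatrix(matrix(0, 2, 2)))
  expect_false(any(z@cell$pass))
  expect_false(any(z@gene$pass))
})

test_that("dataset B applies UMI floor, ratio and non-neuronal rules", {
  cfg <- geneListConfig()
  # cells: 799 UMIs (fail), 800 with ratio >= 1.2 (pass), ratio exactly
  # 1.2 (pass), ratio below 1.2 (fail), Mog-positive (fail), empty (fail)
  G <- 1000
  x <- matrix(0L, G + 1, 6,
              dimnames = list(c(sprintf("g%04d", seq_len(G)), "Mog"),
                              c("low", "ok", "ratio12", "ratiolow",
                                "mog", "empty")))
  x[1:100, "low"] <- 7; x[1, "low"] <- 99          # total 799
  x[1:100, "ok"] <- 8                               # 800 / 100 = 8
  x[1:1000, "ratio12"] <- 1; x[1:200, "ratio12"] <- 2   # 1200/1000 = 1.2
  x[1:1000, "ratiolow"] <- 1; x[1:199, "ratiolow"] <- 2 # 1199/1000 < 1.2
  x[1:100, "mog"] <- 8; x["Mog", "mog"] <- 1
  m <- toyMatrix(x, rownames(x), colnames(x))
  rep <- qcDatasetB(m, cfg)
  pass <- setNames(rep@cell$pass, rep@cell$cell_id)
  expect_identical(pass, c(low = FALSE, ok = TRUE, ratio12 = TRUE,
                           ratiolow = FALSE, mog = FALSE, empty = FALSE))
  reason <- setNames(rep@cell$reason, rep@cell$cell_id)
  expect_match(reason[["mog"]], "non_neuronal")
  expect_match(reason[["empty"]], "no_genes_detected")
})

test_that("patchseq QC is a disjunction with strict thresholds", {
  cfg <- geneListConfig(mito_genes = "mt-Nd1", rrna_genes = "Rn45s")
  x <- matrix(0L, 1203, 5,
              dimnames = list(c(sprintf("g%04d", 1:1201), "mt-Nd1",
                                "Rn45s"),
                              c("mol", "gen", "both_boundary", "mito",
                                "genes1001")))
  x[1:300, "mol"] <- 6; x[1, "mol"] <- 207             # 2001 molecules
  x[1:1000, "gen"] <- 1; x[1:500, "gen"] <- 3          # 1000 genes, 2000
  x[1:1000, "both_boundary"] <- 2                      # 2000 mol, 1000 g
  x["mt-Nd1", "mito"] <- 5000                          # only mito counts
  x[1:1001, "genes1001"] <- 1                          # 1001 genes
  m <- toyMatrix(x, rownames(x), colnames(x))
  rep <- qcPatchseq(m, cfg)
  pass <- setNames(rep@cell$pass, rep@cell$cell_id)
  expect_identical(pass, c(mol = TRUE, gen = FALSE, both_boundary = FALSE,
                           mito = FALSE, genes1001 = TRUE))
  expect_equal(rep@cell$total[rep@cell$cell_id == "mito"], 0)
})

test_that("total-count normalization scales exactly and rounds to closest integer", {
  m <- toyMatrix(matrix(c(4, 0, 4), 3, 1))
  n1 <- normalizeTotal(m, target = 2000, round_to_integer = FALSE)
  expect_equal(unname(counts(n1, dense = TRUE)[, 1]), c(1000, 0, 1000))
  m2 <- toyMatrix(matrix(c(1, 1, 1), 3, 1))
  n2 <- normalizeTotal(m2, target = 2000, round_to_integer = FALSE)
  expect_equal(unname(counts(n2, dense = TRUE)[, 1]), rep(2000 / 3, 3))
  expect_equal(sum(counts(n2)), 2000)
  n3 <- normalizeTotal(m2, target = 2000)
  expect_equal(unname(counts(n3, dense = TRUE)[, 1]), rep(667, 3))
  # already at target: rounding leaves it untouched
  m4 <- toyMatrix(matrix(c(1500, 500), 2, 1))
  expect_equal(counts(normalizeTotal(m4), dense = TRUE),
               counts(m4, dense = TRUE))
  expect_error(normalizeTotal(toyMatrix(matrix(0, 2, 1))), "zero-total")
})

test_that("rounding error per cell is bounded by half a count per nonzero entry", {
  set.seed(41)
  x <- matrix(rnbinom(400, mu = 4, size = 1), 40, 10)
  x[, 1] <- pmax(x[, 1], 1)
  keep <- colSums(x) > 0
  m <- toyMatrix(x[, keep, drop = FALSE])
  rn <- counts(normalizeTotal(m, 2000), dense = TRUE)
  nz <- colSums(counts(m, dense = TRUE) > 0)
  expect_true(all(abs(colSums(rn) - 2000) <= 0.5 * nz))
})

test_that("QC commutes with cell subsetting (filters are local)", {
  set.seed(7)
  x <- matrix(rnbinom(300, mu = 300, size = 2), 10, 30)
  m <- toyMatrix(x)
  keep <- colnames(m)[seq(1, 30, by = 3)]
  full <- qcDatasetB(m)
  sub <- qcDatasetB(subsetCounts(m, cells = keep))
  ff <- full@cell[full@cell$cell_id %in% keep, ]
  expect_equal(sub@cell$pass, ff$pass)
  expect_equal(sub@cell$total, ff$total)
  expect_equal(sub@cell$reason, ff$reason)
})

test_that("gene-list removal ignores absent symbols and can empty a matrix", {
  m <- toyMatrix(matrix(1:6, 3), c("a", "b", "c"), c("x", "y"))
  cfg <- geneListConfig(activity_genes = character(0))
  expect_equal(dim(dropGeneLists(m, cfg)), dim(m))
  cfg2 <- geneListConfig(activity_genes = c("a", "b", "c"))
  expect_equal(nrow(dropGeneLists(m, cfg2)), 0L)
  cfg3 <- geneListConfig(activity_genes = c("a", "zz"))
  expect_warning(m3 <- dropGeneLists(m, cfg3), "zz")
  expect_identical(rownames(m3), c("b", "c"))
})
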
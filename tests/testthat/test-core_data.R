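test_that("ExpressionMatrix validates its invariants", {
  m <- matrix(1:6, 3, 2, dimnames = list(NULL, c("gA", "gB")))
  em <- ExpressionMatrix(m, modality = "scrna")
  expect_s4_class(em, "ExpressionMatrix")
  expect_identical(dim(em), c(3L, 2L))
  expect_error(ExpressionMatrix(matrix(c(-1, 1), 1, 2),
                                geneNames = c("a", "b")),
               "negative")
  expect_error(ExpressionMatrix(matrix(1, 1, 2),
                                geneNames = c("dup", "dup")),
               "dup")
})

test_that("buildGeneMask takes the exact name intersection", {
  ref <- randomEM(4, 3, genes = c("a", "b", "c"))
  st <- randomEM(2, 3, genes = c("b", "c", "d"), modality = "st")
  mask <- buildGeneMask(ref, st)
  expect_identical(sharedGenes(mask), c("b", "c"))
  expect_identical(unname(maskMatrix(mask)[1, ]), c(0, 1, 1))
  # every column constant
  expect_true(all(apply(maskMatrix(mask), 2, function(x) length(unique(x))) == 1))
  # symmetric outcome: the shared set is the intersection either way round
  mask2 <- buildGeneMask(st, ref)
  expect_setequal(sharedGenes(mask), sharedGenes(mask2))
})

test_that("degenerate gene sets are handled", {
  ref <- randomEM(3, 3, genes = c("a", "b", "c"))
  disjoint <- randomEM(2, 2, genes = c("x", "y"), modality = "st")
  expect_error(buildGeneMask(ref, disjoint), "no shared genes")
  # identical gene sets build an all-ones mask, which training then rejects
  same <- randomEM(2, 3, genes = c("a", "b", "c"), modality = "st")
  mask <- buildGeneMask(ref, same)
  expect_true(all(maskMatrix(mask) == 1))
  expect_error(trainModel(ref, mask, microModelConfig(nGenes = 3L)),
               "shared and unique")
})

test_that("case folding is off by default and opt-in", {
  ref <- randomEM(3, 2, genes = c("Actb", "Gapdh"))
  st <- randomEM(2, 2, genes = c("ACTB", "GAPDH"), modality = "st")
  expect_error(buildGeneMask(ref, st), "no shared genes")
  expect_identical(sharedGenes(buildGeneMask(ref, st, caseFold = TRUE)),
                   c("Actb", "Gapdh"))
})

test_that("makeCVSplits partitions the shared genes deterministically", {
  ref <- randomEM(4, 12)
  st <- randomEM(3, 10, modality = "st",
                 genes = sprintf("g%02d", 1:10))  # 10 shared
  mask <- buildGeneMask(ref, st)
  plan <- makeCVSplits(mask, k = 5, seed = 0)
  sizes <- tabulate(plan@foldAssignments + 1L, 5L)
  expect_identical(sizes, rep(2L, 5L))
  expect_setequal(names(plan@foldAssignments), sharedGenes(mask))
  # determinism
  plan2 <- makeCVSplits(mask, k = 5, seed = 0)
  expect_identical(plan@foldAssignments, plan2@foldAssignments)
  # fold sizes differ by at most one for non-divisible splits
  plan3 <- makeCVSplits(mask, k = 3, seed = 1)
  expect_lte(diff(range(tabulate(plan3@foldAssignments + 1L, 3L))), 1L)
  expect_error(makeCVSplits(mask, k = 11), "exceeds")
})

test_that("normalizeExpression lognorm scales cells to a common total", {
  em <- randomEM(5, 6)
  ln <- normalizeExpression(em, "lognorm", targetSum = 100)
  tot <- unname(rowSums(expm1(exprValues(ln))))
  expect_equal(tot, rep(100, 5), tolerance = 1e-8)
  expect_identical(exprValues(normalizeExpression(em, "raw")), exprValues(em))
})

test_that("TSV and MatrixMarket round-trips are exact", {
  em <- randomEM(3, 2, genes = c("gA", "gB"))
  tmp <- withr::local_tempdir()
  tsv <- file.path(tmp, "x.tsv")
  writeExpression(em, tsv, "tsv")
  back <- readExpression(tsv, "tsv")
  expect_identical(geneNames(back), geneNames(em))
  expect_identical(cellNames(back), cellNames(em))
  expect_equal(exprValues(back), exprValues(em), tolerance = 1e-12)

  mtx <- file.path(tmp, "x.mtx")
  writeExpression(em, mtx, "mtx_triplet")
  back2 <- readExpression(mtx, "mtx_triplet")
  expect_equal(exprValues(back2), exprValues(em), tolerance = 1e-12)
  expect_identical(geneNames(back2), geneNames(em))

  # an empty sparse matrix keeps its declared shape
  zero <- ExpressionMatrix(matrix(0, 4, 3),
                           geneNames = c("a", "b", "c"))
  mtx0 <- file.path(tmp, "zero.mtx")
  writeExpression(zero, mtx0, "mtx_triplet")
  back3 <- readExpression(mtx0, "mtx_triplet")
  expect_identical(dim(back3), c(4L, 3L))
  expect_true(all(exprValues(back3) == 0))

  expect_error(writeExpression(ExpressionMatrix(matrix(0, 2, 0),
                                                geneNames = character()),
                               file.path(tmp, "e.tsv"), "tsv"),
               "no genes")
})

test_that("HDF5 container round-trips and has the declared datasets", {
  em <- randomEM(4, 3, seed = 9)
  tmp <- withr::local_tempdir()
  h5 <- file.path(tmp, "x.h5")
  writeExpression(em, h5, "h5_container")
  back <- readExpression(h5, "h5_container")
  expect_equal(exprValues(back), exprValues(em), tolerance = 1e-12)
  expect_identical(geneNames(back), geneNames(em))
  # independent reader sees the same dataset shapes
  info <- rhdf5::h5ls(h5)
  expect_setequal(info$name, c("X", "obs_names", "var_names"))
  expect_identical(info$dim[info$name == "X"], "4 x 3")
})
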
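test_that("expression TSV round-trips through the paired reader", {
  es <- toySeries()
  tsv <- withr::local_tempfile(fileext = ".tsv")
  md <- withr::local_tempfile(fileext = ".tsv")
  writeExpressionSeries(es, tsv, md)
  back <- readExpressionSeries(tsv, md)
  expect_equal(exprValues(back), exprValues(es), tolerance = 1e-12)
  expect_identical(sampleGroups(back), sampleGroups(es))
  expect_identical(sampleSplit(back), sampleSplit(es))
})

test_that("rows with missing values are dropped and counted at load", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2\ts3\ts4",
               "g1\t0.1\t0.2\t0.3\t0.4",
               "g2\t0.5\tNA\t0.7\t0.8",
               "g3\t-1\t-2\t-3\t-4"), tsv)
  expect_message(m <- readExpressionMatrix(tsv), "1 row")
  expect_equal(dim(m), c(2L, 4L))
  expect_identical(rownames(m), c("g1", "g3"))
})

test_that("duplicate gene ids are rejected by name and empty files error", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2", "gX\t1\t2", "gX\t3\t4"), tsv)
  expect_error(readExpressionMatrix(tsv), "gX")
  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("gene_id\ts1", empty)
  expect_error(readExpressionMatrix(empty), "empty|no usable")
})

test_that("series validity enforces finiteness and two groups", {
  m <- matrix(rnorm(8), 2, 4,
              dimnames = list(c("g1", "g2"), paste0("s", 1:4)))
  md <- data.frame(sample_id = colnames(m), group = rep(c("A", "B"), 2),
                   split = "learning")
  expect_s4_class(ExpressionSeries(m, md), "ExpressionSeries")
  m2 <- m; m2[1, 1] <- NA
  expect_error(ExpressionSeries(m2, md), "finite")
  md2 <- md; md2$group <- "A"
  expect_error(ExpressionSeries(m, md2), "two group")
  expect_error(ExpressionSeries(m, md[1:3, ]), "without metadata")
})

test_that("centerNormalizeRows yields zero-mean unit-norm rows and reusable stats", {
  r <- centerNormalizeRows(matrix(c(1, 2, 3), 1))
  expect_equal(rowMeans(r$values), 0, tolerance = 1e-15)
  expect_equal(sqrt(sum(r$values^2)), 1, tolerance = 1e-15)
  expect_equal(r$stats$m, 2)
  expect_equal(r$stats$M, sqrt(2))

  # external statistics are applied verbatim: (x - m)/M, hand computed
  ext <- centerNormalizeRows(matrix(c(0, 2), 1),
                             stats = list(m = 1, M = 2))
  expect_equal(as.vector(ext$values), c(-0.5, 0.5))

  # re-normalizing an already-normalized matrix is the identity
  x <- matrix(rnorm(30), 3, 10, dimnames = list(paste0("g", 1:3), NULL))
  once <- centerNormalizeRows(x)
  twice <- centerNormalizeRows(once$values)
  expect_equal(twice$values, once$values, tolerance = 1e-12)
  expect_equal(unname(twice$stats$m), rep(0, 3), tolerance = 1e-12)
  expect_equal(unname(twice$stats$M), rep(1, 3), tolerance = 1e-12)
})

test_that("constant rows give a zero-module error naming the gene", {
  x <- matrix(c(5, 5, 5, 1, 2, 3), 2, 3, byrow = TRUE,
              dimnames = list(c("flat", "ok"), NULL))
  expect_error(centerNormalizeRows(x), "flat")
})

test_that("classification reports round-trip through JSON", {
  dec <- data.frame(sample_id = c("x1", "x2", "x3"),
                    truth = c("A", "B", "A"),
                    decision = c("attributed_A", "attributed_A",
                                 "unattributed"),
                    rms_A = c(0.1, 0.3, 0.5), rms_B = c(0.9, 0.2, 0.5),
                    stage = "top3", stringsAsFactors = FALSE)
  rep <- classificationReport(dec, c("A", "B"))
  expect_equal(rep@counts$well, c(1L, 0L))
  expect_equal(rep@counts$false, c(0L, 1L))
  expect_equal(rep@counts$unclassified, c(1L, 0L))
  f <- withr::local_tempfile(fileext = ".json")
  writeReport(rep, f)
  back <- readReport(f)
  expect_equal(decisions(back), decisions(rep), tolerance = 1e-12)
  expect_equal(back@counts, rep@counts)

  empty <- classificationReport(dec[0, ], c("A", "B"))
  expect_true(all(empty@counts[, c("well", "false", "unclassified")] == 0))
  writeReport(empty, f)
  expect_equal(nrow(decisions(readReport(f))), 0L)
})

test_that("signatures round-trip through TSV at full precision", {
  sig <- new("GeneSignature", geneIds = c("g2", "g7"),
             Fi = c(0.123456789012345, 0.2), differential = c(1.5, -0.25))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeSignature(sig, f)
  back <- readSignature(f)
  expect_identical(signatureGenes(back), signatureGenes(sig))
  expect_equal(back@Fi, sig@Fi, tolerance = 1e-12)
  expect_equal(back@differential, sig@differential, tolerance = 1e-12)
})
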
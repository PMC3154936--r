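test_that("relevance frequencies match hand-computed weighted ratios", {
  learn <- paste0("s", 1:6)
  # single matrix, c = 2: co-occurring pairs get F = 1, others 0
  one <- list(list(geneIds = c("g1", "g2"), designIds = paste0("s", 1:4),
                   c = 2L))
  r1 <- compileRelevance(one, learn)
  expect_equal(r1@F["g1", "s1"], 1)
  expect_equal(r1@F["g1", "s5"], 0)
  expect_identical(r1@H, 1L)

  # three matrices with c = 1, 2, 3 against a direct arithmetic oracle
  mats <- list(
    list(geneIds = c("g1", "g2"), designIds = c("s1", "s2", "s3"), c = 1L),
    list(geneIds = c("g2", "g3"), designIds = c("s2", "s3", "s4"), c = 2L),
    list(geneIds = c("g1", "g3"), designIds = c("s4", "s5", "s6"), c = 3L))
  rel <- compileRelevance(mats, learn)
  oracle <- matrix(0, 3, 6, dimnames = list(paste0("g", 1:3), learn))
  for (h in mats)
    oracle[h$geneIds, h$designIds] <- oracle[h$geneIds, h$designIds] + h$c
  oracle <- oracle / 6
  expect_equal(rel@F, oracle, tolerance = 1e-15)
  # marginal consistency
  expect_equal(rel@Fi, rowMeans(oracle), tolerance = 1e-15)
  expect_equal(rel@Fj, colMeans(oracle), tolerance = 1e-15)
  expect_equal(rel@mF, mean(colMeans(oracle)), tolerance = 1e-15)
  expect_equal(rel@vF, sqrt(mean((colMeans(oracle) -
                                  mean(colMeans(oracle)))^2)),
               tolerance = 1e-15)
  expect_error(compileRelevance(list(), learn), "no validated")
})

test_that("the candidate-gene universe can include genes outside validated matrices", {
  learn <- paste0("s", 1:4)
  mats <- list(list(geneIds = "g1", designIds = c("s1", "s2"), c = 1L))
  rel <- compileRelevance(mats, learn,
                          allCandidateGenes = c("g1", "g9", "g8"))
  expect_identical(rownames(rel@F), c("g1", "g8", "g9"))
  expect_true(all(rel@F["g8", ] == 0))
  expect_identical(rel@N, 3L)
  expect_error(compileRelevance(mats, learn, allCandidateGenes = "g9"),
               "must contain")
})

test_that("signature selection applies the inclusive mF + 2vF threshold", {
  mk <- function(F) {
    Fj <- colMeans(F)
    new("RelevanceTable", F = F, Fi = rowMeans(F), Fj = Fj,
        mF = mean(Fj), vF = sqrt(mean((Fj - mean(Fj))^2)),
        H = 1L, P = ncol(F), N = nrow(F), normalization = "total_weight")
  }
  # all-equal table: vF = 0, every gene sits exactly at the threshold
  flat <- mk(matrix(0.4, 3, 4, dimnames = list(paste0("g", 1:3),
                                               paste0("s", 1:4))))
  expect_setequal(selectSignature(flat), paste0("g", 1:3))

  # one dominant gene
  F <- matrix(0.01, 5, 4, dimnames = list(paste0("g", 1:5),
                                          paste0("s", 1:4)))
  F["g3", ] <- 0.9
  expect_identical(selectSignature(mk(F))[1L], "g3")

  # empty selection errors with a diagnostic
  F2 <- F; F2["g3", ] <- c(0.9, 0.01, 0.01, 0.01)  # inflates vF over Fj
  tab <- mk(F2)
  if (!any(tab@Fi >= relevanceThreshold(tab)))
    expect_error(selectSignature(tab), "threshold")
})

test_that("selection is monotone in a gene's relevance", {
  set.seed(23)
  F <- matrix(runif(20, 0, 0.1), 5, 4,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
  F["g2", ] <- 0.6          # clearly above any mean-anchored threshold
  mkFi <- function(F, Fi) {
    Fj <- colMeans(F)
    new("RelevanceTable", F = F, Fi = Fi, Fj = Fj, mF = mean(Fj),
        vF = sqrt(mean((Fj - mean(Fj))^2)), H = 1L, P = 4L, N = 5L,
        normalization = "total_weight")
  }
  base <- mkFi(F, rowMeans(F))
  sel <- selectSignature(base)
  expect_gte(length(sel), 1L)
  for (g in sel) {
    Fi2 <- rowMeans(F); Fi2[g] <- min(1, Fi2[g] + 0.1)
    expect_true(g %in% selectSignature(mkFi(F, Fi2)))
  }
})

test_that("standardization averages design-transformed rows over matrices", {
  set.seed(6)
  ids <- paste0("s", 1:8)
  full <- matrix(rnorm(24), 3, 8, dimnames = list(paste0("g", 1:3), ids))
  m1 <- list(geneIds = c("g1", "g2"), designIds = ids[1:4], c = 1L)
  m2 <- list(geneIds = c("g1", "g3"), designIds = ids[3:6], c = 2L)

  # one matrix: xi is exactly its E_h
  s1 <- standardizeMatrix(list(m1), full, c("g1", "g2"), ids[1:6])
  stats1 <- centerNormalizeRows(full[c("g1", "g2"), ids[1:4]])$stats
  E1 <- (full[c("g1", "g2"), ] - stats1$m) / stats1$M
  expect_equal(s1@xi, E1, tolerance = 1e-12)
  # restricted to the design columns it reproduces the normalized design
  expect_equal(s1@xi[, ids[1:4]],
               centerNormalizeRows(full[c("g1", "g2"), ids[1:4]])$values,
               tolerance = 1e-12)

  # two matrices: overlap gene g1 is the element-wise mean of its two E_h
  s2 <- standardizeMatrix(list(m1, m2), full, c("g1", "g2", "g3"), ids[1:6])
  stats2 <- centerNormalizeRows(full[c("g1", "g3"), ids[3:6]])$stats
  E2 <- (full[c("g1", "g3"), ] - stats2$m) / stats2$M
  expect_equal(s2@xi["g1", ], (E1["g1", ] + E2["g1", ]) / 2,
               tolerance = 1e-12)
  expect_equal(s2@xi["g2", ], E1["g2", ], tolerance = 1e-12)
  expect_equal(unname(s2@nContrib), c(2L, 1L, 1L))

  # duplicate matrices leave the mean unchanged
  sDup <- standardizeMatrix(list(m1, m1), full, c("g1", "g2"), ids[1:6])
  expect_equal(sDup@xi, s1@xi, tolerance = 1e-12)

  expect_error(standardizeMatrix(list(m1), full, c("g1", "gZ"), ids[1:6]),
               "gZ")
  expect_error(standardizeMatrix(list(m1), full, c("g1", "g3"), ids[1:6]),
               "no validated matrix")
})
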
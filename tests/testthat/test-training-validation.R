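test_that("training-space eigendecomposition matches the analytic 2x2 form", {
  set.seed(4)
  raw <- matrix(rnorm(20), 2, 10,
                dimnames = list(c("g1", "g2"), paste0("s", 1:10)))
  train <- matrix(rnorm(6), 2, 3,
                  dimnames = list(c("g1", "g2"), paste0("t", 1:3)))
  groups <- factor(rep(c("A", "B"), each = 5))
  sp <- buildTrainingSpace(raw, groups, train)

  cn <- centerNormalizeRows(raw)$values
  C <- (cn - rowMeans(cn)) %*% t(cn - rowMeans(cn)) / ncol(cn)
  a <- C[1, 1]; b <- C[1, 2]; d <- C[2, 2]
  disc <- sqrt((a - d)^2 + 4 * b^2)
  expect_equal(sp@eigenvalues[1:2],
               c((a + d + disc) / 2, (a + d - disc) / 2), tolerance = 1e-12)
  # conservation: eigenvalues sum to the total variance of the input
  expect_equal(sum(sp@eigenvalues),
               sum((cn - rowMeans(cn))^2) / ncol(cn), tolerance = 1e-12)
  # sign convention: largest-magnitude component positive
  for (j in seq_len(ncol(sp@rotation)))
    expect_gt(sp@rotation[which.max(abs(sp@rotation[, j])), j], 0)
  # held-out samples are projected with the design's own row statistics
  stats <- centerNormalizeRows(raw)$stats
  trainCn <- centerNormalizeRows(train, stats = stats)$values
  expect_equal(sp@queryCoords,
               crossprod(sp@rotation, trainCn - rowMeans(cn)),
               tolerance = 1e-12)
})

test_that("designs with fewer than two candidate genes are discarded with a message", {
  raw <- matrix(rnorm(10), 1, 10, dimnames = list("g1", paste0("s", 1:10)))
  expect_message(
    out <- buildTrainingSpace(raw, factor(rep(c("A", "B"), each = 5)),
                              raw[, 1:2, drop = FALSE]),
    "fewer than 2")
  expect_null(out)
})

test_that("RMS equals the direct root-mean-square arithmetic", {
  coords <- rbind(c(0, 1, 4, 5), c(0, -1, 2, 3), c(1, 1, 1, 1))
  colnames(coords) <- paste0("s", 1:4)
  grp <- factor(c("A", "A", "B", "B"))
  # barycenter of A on all axes: (0.5, -0.5, 1)
  q <- c(2, 0.5, -1)
  oracle <- sqrt(mean(c((2 - 0.5)^2, (0.5 + 0.5)^2, (-1 - 1)^2)))
  expect_equal(computeRms(coords, grp, q, "A", 1:3), oracle)
  # query at the barycenter gives 0
  expect_equal(computeRms(coords, grp, c(0.5, -0.5, 1), "A", 1:3), 0)
  # single axis at distance d gives d
  expect_equal(computeRms(coords, grp, c(3.5, 0, 0), "A", 1L), 3)
  expect_error(computeRms(coords, grp, q, "A", integer(0)), "empty")
})

test_that("RMS decision rules cover every branch", {
  refs <- matrix(c(-1.0, -1.1, -0.9, 0.9, 1.0, 1.1), 1,
                 dimnames = list(NULL, paste0("s", 1:6)))
  grp <- c("A", "A", "A", "B", "B", "B")
  sp <- coordSpace(refs, grp)
  decide <- function(q) classifyByRms(rmsProfile(sp, matrix(q, 1)))
  expect_identical(decide(-1.05), "attributed_A")
  expect_identical(decide(1.05), "attributed_B")
  expect_identical(decide(0), "unattributed")     # equidistant, outside both

  # interleaved reference geometry is rejected regardless of the query
  bad <- coordSpace(matrix(c(-1, 2, 0.9, 1.1), 1,
                           dimnames = list(NULL, paste0("s", 1:4))),
                    c("A", "A", "B", "B"))
  expect_identical(classifyByRms(rmsProfile(bad, matrix(-1, 1))), "rejected")
})

test_that("RMS decisions are invariant to swapping the group labels", {
  set.seed(11)
  for (i in 1:10) {
    refs <- matrix(c(rnorm(4, -2, 0.3), rnorm(4, 2, 0.3)), 1)
    colnames(refs) <- paste0("s", 1:8)
    q <- matrix(rnorm(1, 0, 2), 1)
    d1 <- classifyByRms(rmsProfile(coordSpace(refs, rep(c("A", "B"), each = 4)), q))
    d2 <- classifyByRms(rmsProfile(coordSpace(refs, rep(c("B", "A"), each = 4)), q))
    swapped <- c(attributed_A = "attributed_B", attributed_B = "attributed_A",
                 unattributed = "unattributed", rejected = "rejected")
    expect_identical(unname(swapped[d1]), d2)
  }
})

test_that("a query at the origin of mirror-image groups is unattributed", {
  refs <- matrix(c(-2, -1.5, -1, 1, 1.5, 2), 1,
                 dimnames = list(NULL, paste0("s", 1:6)))
  sp <- coordSpace(refs, rep(c("A", "B"), each = 3))
  expect_identical(classifyByRms(rmsProfile(sp, matrix(0, 1))),
                   "unattributed")
})

test_that("training-matrix validation demands one correct and zero wrong", {
  v <- validateTrainingMatrix(c("attributed_A", rep("unattributed", 15)),
                              c("A", rep(c("A", "B"), length.out = 15)))
  expect_true(v$validated); expect_identical(v$c, 1L)

  none <- validateTrainingMatrix(rep("unattributed", 4), rep("A", 4))
  expect_false(none$validated); expect_identical(none$c, 0L)

  mis <- validateTrainingMatrix(
    c(rep("attributed_A", 5), "attributed_B"), rep("A", 6))
  expect_false(mis$validated)
})

test_that("the continuation check passes at exactly 90% coverage and fails below", {
  ok <- setNames(c(rep(TRUE, 9), FALSE), paste0("s", 1:10))
  expect_true(continuationCheck(ok))
  expect_equal(attr(continuationCheck(ok), "coverage"), 0.9)
  expect_identical(attr(continuationCheck(ok), "uncovered"), "s10")
  expect_false(continuationCheck(setNames(c(rep(TRUE, 8), FALSE, FALSE),
                                          paste0("s", 1:10))))
  expect_false(continuationCheck(ok, perSampleMisclassified =
                                   c(rep(FALSE, 9), TRUE)))
})
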
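makeStd <- function(xi, learningIds, groups) {
  new("StandardizedMatrix", xi = xi,
      nContrib = rep(1L, nrow(xi)), learningIds = learningIds,
      groups = factor(groups))
}

test_that("learning coordinates are independent of which testing samples are projected", {
  set.seed(21)
  ids <- c(paste0("L", 1:8), paste0("X", 1:3))
  xi <- matrix(rnorm(5 * 11), 5, 11,
               dimnames = list(paste0("g", 1:5), ids))
  xi[1, ] <- xi[1, ] + rep(c(2, -2, 0), c(4, 4, 3))
  grp <- c(rep(c("A", "B"), each = 4), rep(NA, 3))
  learn <- ids[1:8]

  full <- buildValidationSpace(makeStd(xi, learn, grp))
  noQueries <- buildValidationSpace(makeStd(xi[, 1:8], learn, grp[1:8]))
  oneQuery <- buildValidationSpace(makeStd(xi[, 1:9], learn, grp[1:9]))

  expect_equal(full@refCoords, noQueries@refCoords, tolerance = 1e-12)
  expect_equal(full@refCoords, oneQuery@refCoords, tolerance = 1e-12)
  expect_equal(full@queryCoords[, "X1"], oneQuery@queryCoords[, "X1"],
               tolerance = 1e-12)
  expect_identical(ncol(noQueries@queryCoords), 0L)
  # eigenvalues sorted and non-negative
  expect_false(is.unsorted(rev(full@eigenvalues)))
  expect_gte(min(full@eigenvalues), -1e-9)
})

test_that("case-by-case and batch classification agree", {
  run <- fastPipeline()
  space <- buildValidationSpace(run$res$standardized)
  ids <- colnames(space@queryCoords)
  batch <- decisions(run$report)
  for (s in ids) {
    one <- classifyTesting(space, s)
    expect_identical(one$decision,
                     batch$decision[batch$sample_id == s])
  }
})

test_that("a strong planted signal separates learning groups on the first axis", {
  run <- fastPipeline()
  space <- buildValidationSpace(run$res$standardized)
  ax1 <- space@refCoords[1, ]
  g <- space@refGroups
  gap <- abs(mean(ax1[g == levels(g)[1]]) - mean(ax1[g == levels(g)[2]]))
  pooled <- sqrt((var(ax1[g == levels(g)[1]]) +
                  var(ax1[g == levels(g)[2]])) / 2)
  expect_gt(gap, 4 * pooled)
})

test_that("the variance decomposition identity holds on random coordinates", {
  set.seed(31)
  for (i in 1:20) {
    coords <- matrix(rnorm(4 * 12), 4, 12)
    groups <- factor(sample(rep(c("A", "B"), 6)))
    axes <- sort(sample(4, sample(4, 1)))
    v <- emts2pca:::.varianceDecomposition(coords, groups, axes)
    expect_equal(v$inter + v$within, v$total, tolerance = 1e-9)
  }
})

test_that("the axis-subset search finds the separating axis and honors tie-breaks", {
  set.seed(41)
  # axis 1 separates the groups, axis 2 is pure noise with larger variance
  sep <- rep(c(-1, 1), each = 5) + rnorm(10, sd = 0.05)
  noise <- rnorm(10, sd = 3)
  sp <- coordSpace(rbind(noise, sep), rep(c("A", "B"), each = 5),
                   activeAxes = 1:2)
  best <- selectAxisSubset(sp, maxAxes = 2L)
  expect_identical(best$subset, 2L)
  # optimal ratio at least matches the default (all-axes) subset
  vAll <- emts2pca:::.varianceDecomposition(sp@refCoords, sp@refGroups, 1:2)
  expect_gte(best$ratio, vAll$inter / vAll$within - 1e-12)

  # identical axes: the smallest subset wins by tie-break
  same <- coordSpace(rbind(sep, sep), rep(c("A", "B"), each = 5))
  expect_identical(selectAxisSubset(same, maxAxes = 2L)$subset, 1L)
})

test_that("subset reclassification recovers an outlier without disturbing settled calls", {
  sep <- c(rep(-1, 5), rep(1, 5)) + c(-0.02, -0.01, 0, 0.01, 0.02)
  noise <- rep(c(-0.1, 0.1), 5)
  refs <- rbind(sep, noise)
  colnames(refs) <- paste0("s", 1:10)
  # query: group-A position on the separating axis, huge noise coordinate
  q <- matrix(c(-1, 8), 2, 1, dimnames = list(NULL, "x1"))
  sp <- coordSpace(refs, rep(c("A", "B"), each = 5), queryCoords = q,
                   activeAxes = 1:2)
  expect_identical(classifyByRms(rmsProfile(sp, "x1", axes = 1:2)),
                   "unattributed")
  best <- selectAxisSubset(sp, maxAxes = 2L)
  out <- reclassifyWithSubset(sp, best$subset, "x1")
  expect_identical(unname(out), "attributed_A")
  # settled decisions re-checked without warning when they are stable
  expect_no_warning(
    reclassifyWithSubset(sp, best$subset, character(0),
                         attributedDecisions = c(s1 = "attributed_A")))
  expect_length(reclassifyWithSubset(sp, best$subset, character(0)), 0L)
})

test_that("blind classification of held-out samples is accurate under strong signal", {
  run <- fastPipeline()
  d <- decisions(run$report)
  lev <- run$res$groups
  called <- ifelse(d$decision == "attributed_A", lev[1],
                   ifelse(d$decision == "attributed_B", lev[2], NA))
  attributed <- !is.na(called)
  expect_equal(sum(attributed & called != d$truth), 0L)
  expect_gte(mean(attributed & called == d$truth), 0.75)
  # group-label swap leaves per-sample decisions consistent
  counts <- predictionCounts(run$report)
  expect_gte(rpe(counts), gpe(counts))
})
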
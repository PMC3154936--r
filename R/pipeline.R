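#' Run the signature-discovery stage
#'
#' Executes the full learning/training/compilation sequence on the learning
#' split of a series: combinatorial 10-sample designs (half-matrix
#' enumeration, confounder and overlap filters), per-design gene screening
#' (exact permutation t filter, EM over/under posteriors, candidate rules),
#' internal cross-validation of every design in its PCA training space with
#' RMS decision rules, the 90% continuation check, compilation of validated
#' matrices into relevance frequencies, signature selection at mF + 2 vF,
#' and construction of the standardized matrix xi over all samples.
#'
#' @param series an \linkS4class{ExpressionSeries} with a learning split
#'   containing both groups.
#' @param config an [emtsConfig()] list.
#' @param verbose print per-stage progress.
#' @return list with \code{signature} (\linkS4class{GeneSignature}),
#'   \code{relevance} (\linkS4class{RelevanceTable}), \code{standardized}
#'   (\linkS4class{StandardizedMatrix}), \code{groups} (labels behind A/B),
#'   and \code{log} (design/validation counts and coverage).
#' @export
runEmts <- function(series, config = emtsConfig(), verbose = FALSE) {
  stopifnot(is(series, "ExpressionSeries"))
  values <- exprValues(series)
  groups <- sampleGroups(series)
  split <- sampleSplit(series)
  confounder <- sampleConfounder(series)
  learningIds <- names(split)[split == "learning"]
  lev <- sort(unique(groups))
  learnA <- learningIds[groups[learningIds] == lev[1L]]
  learnB <- learningIds[groups[learningIds] == lev[2L]]
  if (!length(learnA) || !length(learnB))
    stop("both groups must be present in the learning split")

  say <- function(...) if (verbose) message(...)
  halvesA <- enumerateHalfMatrices(learnA, config$halfSize)
  halvesB <- enumerateHalfMatrices(learnB, config$halfSize)
  conf <- if (is.null(confounder)) NULL else confounder[learningIds]
  halvesA <- suppressMessages(filterConfounder(halvesA, conf))
  halvesB <- suppressMessages(filterConfounder(halvesB, conf))
  halvesA <- filterOverlap(halvesA, config$maxShared)
  halvesB <- filterOverlap(halvesB, config$maxShared)
  designs <- buildDesigns(halvesA, halvesB, learningIds)
  say(length(designs), " designs after filtering")

  validated <- list()
  perSampleCorrect <- setNames(rep(FALSE, length(learningIds)), learningIds)
  perSampleWrong <- setNames(rep(FALSE, length(learningIds)), learningIds)
  nCandidates <- integer(0)
  allCandidates <- character(0)
  nScreened <- 0L

  for (d in designs) {
    designIds <- c(d$A, d$B)
    X <- values[, designIds, drop = FALSE]
    keep <- suppressMessages(
      permutationTFilter(X, groupA = d$A, alpha = config$tFilterAlpha))
    if (length(keep) < 2L) next
    nScreened <- nScreened + 1L
    cn <- centerNormalizeRows(X[keep, , drop = FALSE])
    post <- tryCatch(
      fitEmPosteriors(cn$values, tol = config$emTol,
                      maxIter = config$emMaxIter),
      error = function(e) {
        say("design discarded, EM fit failed: ", conditionMessage(e))
        NULL
      })
    if (is.null(post)) next
    cand <- selectCandidates(post, groupA = d$A, groupB = d$B,
                             delta = config$emDelta)
    nCandidates <- c(nCandidates, nrow(cand))
    allCandidates <- union(allCandidates, cand$gene_id)
    if (nrow(cand) < 2L) next
    trainIds <- setdiff(learningIds, designIds)
    designGroups <- factor(rep(c("A", "B"), each = config$halfSize),
                           levels = c("A", "B"))
    space <- suppressMessages(buildTrainingSpace(
      values[cand$gene_id, designIds, drop = FALSE], designGroups,
      values[cand$gene_id, trainIds, drop = FALSE],
      nAxes = config$nAxesTraining))
    if (is.null(space)) next
    decided <- vapply(trainIds, function(s)
      classifyByRms(rmsProfile(space, s), config$rmsSdMultiplier),
      character(1))
    truth <- ifelse(groups[trainIds] == lev[1L], "A", "B")
    val <- validateTrainingMatrix(decided, truth)
    if (val$validated) {
      validated[[length(validated) + 1L]] <-
        list(geneIds = cand$gene_id, designIds = designIds, c = val$c)
      correct <- decided == paste0("attributed_", truth)
      perSampleCorrect[trainIds][correct] <- TRUE
    }
  }
  say(length(validated), " of ", length(designs), " designs validated; ",
      "mean candidate count ", round(mean(nCandidates), 1))

  ok <- continuationCheck(perSampleCorrect, perSampleWrong,
                          config$minCoverage)
  if (!ok) {
    uncov <- attr(ok, "uncovered")
    stop(errorCondition(
      paste0("continuation check failed: coverage ",
             signif(attr(ok, "coverage"), 3), " < ", config$minCoverage,
             "; uncovered sample(s): ", paste(uncov, collapse = ", ")),
      class = "emtsContinuationError"))
  }

  relevance <- compileRelevance(validated, learningIds,
                                config$relevanceNormalization,
                                allCandidateGenes = allCandidates)
  sigIds <- selectSignature(relevance)
  std <- standardizeMatrix(validated, values, sigIds, learningIds,
                           groups = groups)
  xiL <- std@xi[, learningIds, drop = FALSE]
  differential <- rowMeans(xiL[, learnA, drop = FALSE]) -
    rowMeans(xiL[, learnB, drop = FALSE])
  signature <- new("GeneSignature", geneIds = sigIds,
                   Fi = unname(relevance@Fi[sigIds]),
                   differential = unname(differential[sigIds]))
  list(signature = signature, relevance = relevance, standardized = std,
       groups = lev,
       log = list(nDesigns = length(designs), nScreened = nScreened,
                  nValidated = length(validated),
                  coverage = attr(ok, "coverage"),
                  candidateCounts = nCandidates,
                  provenance = list(
                    package = "emts2pca",
                    version = as.character(utils::packageVersion("emts2pca")),
                    config = config)))
}

#' Run the blind classification stage
#'
#' Builds the validation space from the learning columns of the standardized
#' matrix, projects every sample, and classifies each testing sample case by
#' case with the RMS rules and the axis escalation path (leading three axes,
#' then all axes, then the variance-optimal subset).
#'
#' @param std a \linkS4class{StandardizedMatrix} from [runEmts()].
#' @param config an [emtsConfig()] list.
#' @return A \linkS4class{ClassificationReport} over the testing samples.
#' @export
runPredict <- function(std, config = emtsConfig()) {
  space <- buildValidationSpace(std, nAxes = config$nAxesValidation)
  testIds <- colnames(space@queryCoords)
  lev <- levels(space@refGroups)
  truthAll <- as.character(std@groups)
  names(truthAll) <- colnames(std@xi)
  rows <- lapply(testIds, function(s) {
    r <- classifyTesting(space, s, sdMultiplier = config$rmsSdMultiplier,
                         maxAxes = config$maxAxesSubsetSearch)
    data.frame(sample_id = s, truth = truthAll[[s]], decision = r$decision,
               rms_A = unname(r$rms["A"]), rms_B = unname(r$rms["B"]),
               stage = r$stage, stringsAsFactors = FALSE)
  })
  dec <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sample_id = character(), truth = character(),
               decision = character(), rms_A = numeric(),
               rms_B = numeric(), stage = character(),
               stringsAsFactors = FALSE)
  rownames(dec) <- NULL
  classificationReport(dec, lev)
}

#' Write / read a standardized matrix as tab-delimited text
#'
#' Two files: the xi values (gene_id, nContrib, one column per sample) and a
#' sample table (sample_id, group, split).
#'
#' @param std a \linkS4class{StandardizedMatrix}.
#' @param path xi TSV path.
#' @param metadataPath sample table TSV path.
#' @export
writeStandardizedMatrix <- function(std, path, metadataPath) {
  d <- data.frame(gene_id = rownames(std@xi), nContrib = std@nContrib,
                  std@xi, check.names = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  md <- data.frame(sample_id = colnames(std@xi),
                   group = as.character(std@groups),
                   split = ifelse(colnames(std@xi) %in% std@learningIds,
                                  "learning", "testing"))
  write.table(md, metadataPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' @rdname writeStandardizedMatrix
#' @return \code{readStandardizedMatrix} returns the
#'   \linkS4class{StandardizedMatrix}.
#' @export
readStandardizedMatrix <- function(path, metadataPath) {
  d <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  md <- read.delim(metadataPath, stringsAsFactors = FALSE)
  xi <- as.matrix(d[, -(1:2), drop = FALSE])
  rownames(xi) <- d$gene_id
  new("StandardizedMatrix", xi = xi, nContrib = as.integer(d$nContrib),
      learningIds = md$sample_id[md$split == "learning"],
      groups = factor(md$group[match(colnames(xi), md$sample_id)]))
}
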
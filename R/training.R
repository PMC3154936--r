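# Internal PCA helper shared by the training and validation spaces.
# ref: genes x reference samples. Rows are centered on the reference columns
# only, the eigendecomposition of the across-sample covariance (population
# form, genes as variables) is taken via SVD, and each eigenvector's sign is
# fixed so its largest-magnitude component is positive. Queries are projected
# with the reference center, so reference coordinates never depend on which
# queries are projected.
.pcaSpace <- function(ref, refGroups, query = NULL, class = "ProjectionSpace",
                      nAxes = 3L) {
  stopifnot(is.matrix(ref), nrow(ref) >= 2L)
  ctr <- rowMeans(ref)
  X <- ref - ctr
  sv <- svd(X)
  k <- length(sv$d)
  U <- sv$u
  flip <- vapply(seq_len(k), function(j) {
    u <- U[, j]
    u[which.max(abs(u))] < 0
  }, logical(1))
  U[, flip] <- -U[, flip]
  eigenvalues <- sv$d^2 / ncol(ref)
  refCoords <- crossprod(U, X)
  colnames(refCoords) <- colnames(ref)
  queryCoords <- if (is.null(query)) {
    matrix(0, k, 0)
  } else {
    qc <- crossprod(U, query - ctr)
    colnames(qc) <- colnames(query)
    qc
  }
  rownames(U) <- rownames(ref)
  new(class, rotation = U, eigenvalues = eigenvalues, center = ctr,
      refCoords = refCoords, refGroups = as.factor(refGroups),
      queryCoords = queryCoords, geneIds = rownames(ref),
      activeAxes = seq_len(min(nAxes, k)))
}

#' Build the training space of one 10-sample design
#'
#' The design's candidate-gene sub-matrix is centered/normalized per row, its
#' across-sample covariance eigendecomposed, and a coordinate system taken
#' from the three leading eigenvectors (all, if fewer exist). The held-out
#' learning samples ("training tumors") are projected into this space using
#' the same gene set and the design's own row statistics — never refit — so
#' their placement cannot alter the space.
#'
#' @param designValues numeric matrix, candidate genes x the 10 design
#'   samples, raw log ratios.
#' @param designGroups group label per design sample.
#' @param trainValues numeric matrix, same genes x held-out learning samples,
#'   raw log ratios.
#' @param nAxes number of leading eigenvectors forming the coordinate system.
#' @return A \linkS4class{TrainingSpace}, or \code{NULL} (with a message) when
#'   fewer than two candidate genes are available.
#' @export
buildTrainingSpace <- function(designValues, designGroups, trainValues,
                               nAxes = 3L) {
  if (nrow(designValues) < 2L) {
    message("design discarded: fewer than 2 candidate genes")
    return(NULL)
  }
  cn <- centerNormalizeRows(designValues)
  train <- centerNormalizeRows(trainValues, stats = cn$stats)
  .pcaSpace(cn$values, designGroups, query = train$values,
            class = "TrainingSpace", nAxes = nAxes)
}

#' Root-mean-square distance to a group barycenter
#'
#' RMS of the per-axis differences between a sample's coordinates and the
#' barycenter (mean position) of the reference samples of group \code{g},
#' over the chosen eigenvector subset.
#'
#' @param refCoords numeric matrix, axes x reference samples.
#' @param refGroups group label per reference sample.
#' @param query numeric vector of the query's coordinates (all axes).
#' @param g the group whose barycenter is used.
#' @param axes integer indices of the eigenvectors to use.
#' @return non-negative scalar.
#' @export
computeRms <- function(refCoords, refGroups, query, g, axes) {
  if (!length(axes)) stop("empty eigenvector subset")
  members <- which(refGroups == g)
  if (!length(members)) stop("group ", g, " has no reference samples")
  bary <- rowMeans(refCoords[axes, members, drop = FALSE])
  sqrt(mean((query[axes] - bary)^2))
}

#' RMS profile of one query sample in a projection space
#'
#' Computes the matrix-side RMS of every reference sample to both group
#' barycenters and the class-side RMS of the query, over the given axes.
#'
#' @param space a \linkS4class{ProjectionSpace}.
#' @param query sample id among the projected queries, or a numeric
#'   coordinate vector over all axes.
#' @param axes eigenvector subset (default: the space's active axes).
#' @return list with \code{ref} (data.frame sample/group/rmsA/rmsB),
#'   \code{query} (named length-2 vector of class-side RMS), and
#'   \code{groups} (the two group labels, A first).
#' @export
rmsProfile <- function(space, query, axes = space@activeAxes) {
  lev <- levels(space@refGroups)
  stopifnot(length(lev) == 2L)
  qc <- if (is.character(query)) {
    if (query %in% colnames(space@queryCoords)) space@queryCoords[, query]
    else if (query %in% colnames(space@refCoords)) space@refCoords[, query]
    else stop("sample ", query, " not projected in this space")
  } else query
  rc <- space@refCoords
  refA <- vapply(seq_len(ncol(rc)), function(j)
    computeRms(rc, space@refGroups, rc[, j], lev[1L], axes), numeric(1))
  refB <- vapply(seq_len(ncol(rc)), function(j)
    computeRms(rc, space@refGroups, rc[, j], lev[2L], axes), numeric(1))
  list(ref = data.frame(sample = colnames(rc),
                        group = as.character(space@refGroups),
                        rmsA = refA, rmsB = refB,
                        stringsAsFactors = FALSE),
       query = c(A = computeRms(rc, space@refGroups, qc, lev[1L], axes),
                 B = computeRms(rc, space@refGroups, qc, lev[2L], axes)),
       groups = lev)
}

#' Attribute, leave unattributed, or reject a sample from its RMS profile
#'
#' Separability is checked first: if, for either barycenter, some reference
#' sample of that group lies farther from it than a reference sample of the
#' other group does, the two groups are not separated in this space and the
#' decision is \code{rejected}. Otherwise the query is assigned to group g
#' when its class-side RMS is below the largest matrix-side RMS of group g
#' plus \code{sdMultiplier} standard deviations of that group's matrix-side
#' RMS values ("taking the variance into account"). If exactly one group
#' qualifies the sample is attributed to it; if both or neither qualify it is
#' \code{unattributed}.
#'
#' @param profile result of [rmsProfile()].
#' @param sdMultiplier multiplier of the matrix-side RMS standard deviation
#'   added to the assignment threshold (default 1).
#' @return one of \code{"attributed_A"}, \code{"attributed_B"},
#'   \code{"unattributed"}, \code{"rejected"} (A is the first group level).
#' @export
classifyByRms <- function(profile, sdMultiplier = 1) {
  ref <- profile$ref
  inA <- ref$group == profile$groups[1L]
  # separability of the reference geometry
  if (max(ref$rmsA[inA]) > min(ref$rmsA[!inA]) ||
      max(ref$rmsB[!inA]) > min(ref$rmsB[inA]))
    return("rejected")
  thr <- function(v) max(v) + sdMultiplier * (if (length(v) > 1L) sd(v) else 0)
  okA <- profile$query["A"] < thr(ref$rmsA[inA])
  okB <- profile$query["B"] < thr(ref$rmsB[!inA])
  if (okA && !okB) "attributed_A"
  else if (okB && !okA) "attributed_B"
  else "unattributed"
}

#' Validate a training matrix from its training-tumor decisions
#'
#' A training matrix is validated iff at least one of its held-out learning
#' samples is correctly classified and none is misclassified (unattributed
#' decisions are allowed). \code{c} counts the correct classifications and
#' weights the matrix in the relevance compilation.
#'
#' @param decided character vector of decisions
#'   (\code{attributed_A}/\code{attributed_B}/\code{unattributed}/\code{rejected}).
#' @param truth character vector of the true groups (\code{"A"}/\code{"B"} in
#'   space-level coding), same length.
#' @return list with \code{validated} (logical) and \code{c} (integer count of
#'   correct classifications).
#' @export
validateTrainingMatrix <- function(decided, truth) {
  stopifnot(length(decided) == length(truth))
  attributed <- decided %in% c("attributed_A", "attributed_B")
  called <- ifelse(decided == "attributed_A", "A",
                   ifelse(decided == "attributed_B", "B", NA))
  correct <- attributed & called == truth
  wrong <- attributed & called != truth
  cCount <- sum(correct, na.rm = TRUE)
  list(validated = cCount >= 1L && !any(wrong, na.rm = TRUE),
       c = as.integer(cCount))
}

#' Decide whether the learning series supports a signature search
#'
#' The pipeline continues only if at least 90% of the learning samples are
#' correctly classified by at least one validated training matrix and none is
#' misclassified by any validated matrix. The boundary is inclusive: exactly
#' 90% coverage passes.
#'
#' @param perSampleCorrect named logical: per learning sample, was it
#'   correctly classified by at least one validated matrix.
#' @param perSampleMisclassified named logical: per learning sample, was it
#'   misclassified by any validated matrix.
#' @param minCoverage required covered fraction (default 0.9).
#' @return logical; attributes \code{coverage} and \code{uncovered} carry the
#'   diagnostic.
#' @export
continuationCheck <- function(perSampleCorrect, perSampleMisclassified = NULL,
                              minCoverage = 0.9) {
  coverage <- mean(perSampleCorrect)
  bad <- if (is.null(perSampleMisclassified)) FALSE
         else any(perSampleMisclassified)
  ok <- coverage >= minCoverage && !bad
  structure(ok, coverage = coverage,
            uncovered = names(perSampleCorrect)[!perSampleCorrect])
}
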
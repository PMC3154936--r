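#' Build the validation space from the standardized matrix
#'
#' The eigendecomposition is computed from xi' — the learning columns of xi —
#' only; every column of xi (learning and testing) is then projected onto the
#' eigenvectors, giving the coordinate matrix Psi. The default coordinate
#' system is the three leading eigenvectors. Learning coordinates are by
#' construction independent of which testing samples are projected.
#'
#' @param std a \linkS4class{StandardizedMatrix}.
#' @param nAxes number of leading eigenvectors forming the default coordinate
#'   system.
#' @return A \linkS4class{ValidationSpace}; reference samples are the
#'   learning samples, queries the remaining columns of xi.
#' @export
buildValidationSpace <- function(std, nAxes = 3L) {
  xi <- std@xi
  if (nrow(xi) < 2L) stop("fewer than 2 signature genes")
  learn <- std@learningIds
  xiL <- xi[, learn, drop = FALSE]
  grp <- std@groups[match(learn, colnames(xi))]
  if (length(unique(stats::na.omit(as.character(grp)))) != 2L)
    stop("both groups must be present among the learning samples")
  sv <- svd(xiL - rowMeans(xiL))
  if (sum(sv$d > max(sv$d) * 1e-9) < 2L)
    stop("degenerate xi': rank below 2")
  testing <- setdiff(colnames(xi), learn)
  .pcaSpace(xiL, droplevels(grp),
            query = xi[, testing, drop = FALSE],
            class = "ValidationSpace", nAxes = nAxes)
}

#' @export
setMethod("show", "ProjectionSpace", function(object) {
  cat(class(object), ":", length(object@geneIds), "genes,",
      ncol(object@refCoords), "reference +", ncol(object@queryCoords),
      "query samples,", length(object@eigenvalues), "axes (active:",
      paste(object@activeAxes, collapse = ","), ")\n")
})

#' Classify one projected sample in the validation space
#'
#' Applies the RMS decision rules over the requested eigenvector subset, with
#' the learning samples as references. With \code{escalate = TRUE} the
#' published decision path is followed: a sample left unattributed on the
#' leading three axes is retried with all eigenvectors, and then with the
#' within/between-variance-optimal subset from [selectAxisSubset()].
#'
#' @param space a \linkS4class{ValidationSpace}.
#' @param sampleId id of a projected query sample (or a learning sample).
#' @param axes eigenvector subset; default the space's active axes.
#' @param sdMultiplier passed to [classifyByRms()].
#' @param escalate logical; follow the three-stage axis escalation.
#' @param maxAxes bound of the subset search used at the last stage.
#' @return list with \code{decision}, \code{rms} (class-side RMS pair of the
#'   deciding stage), and \code{stage} (\code{"top3"}, \code{"all_axes"} or
#'   \code{"subset"}).
#' @export
classifyTesting <- function(space, sampleId, axes = space@activeAxes,
                            sdMultiplier = 1, escalate = TRUE,
                            maxAxes = 10L) {
  prof <- rmsProfile(space, sampleId, axes = axes)
  dec <- classifyByRms(prof, sdMultiplier)
  stage <- "top3"
  if (escalate && dec == "unattributed") {
    allAxes <- seq_along(space@eigenvalues)
    prof2 <- rmsProfile(space, sampleId, axes = allAxes)
    dec2 <- classifyByRms(prof2, sdMultiplier)
    if (dec2 != "unattributed") {
      prof <- prof2; dec <- dec2; stage <- "all_axes"
    } else {
      best <- selectAxisSubset(space, maxAxes = maxAxes)
      prof3 <- rmsProfile(space, sampleId, axes = best$subset)
      dec3 <- classifyByRms(prof3, sdMultiplier)
      if (dec3 != "unattributed") {
        prof <- prof3; dec <- dec3; stage <- "subset"
      }
    }
  }
  list(decision = dec, rms = prof$query, stage = stage)
}

# population variance decomposition of learning coordinates over given axes:
# total = sum of within-group variances (weighted by group size) + variance
# between the group centroids. Population denominators make the identity
# exact.
.varianceDecomposition <- function(coords, groups, axes) {
  X <- coords[axes, , drop = FALSE]
  n <- ncol(X)
  mu <- rowMeans(X)
  total <- sum((X - mu)^2) / n
  lev <- levels(as.factor(groups))
  within <- 0
  inter <- 0
  for (g in lev) {
    idx <- which(groups == g)
    mg <- rowMeans(X[, idx, drop = FALSE])
    within <- within + sum((X[, idx, drop = FALSE] - mg)^2) / n
    inter <- inter + length(idx) / n * sum((mg - mu)^2)
  }
  list(total = total, within = within, inter = inter)
}

#' Select the eigenvector subset maximizing group separation
#'
#' Exhaustive search over all non-empty subsets of the leading
#' \code{maxAxes} eigenvectors for the subset maximizing the ratio of the
#' between-centroid variance to the summed within-group variances of the
#' learning coordinates. Variances use population denominators so that
#' V_inter + sum(V_within) equals the total variance exactly. Ties are broken
#' by fewer axes, then lexicographically.
#'
#' @param space a \linkS4class{ValidationSpace}.
#' @param maxAxes number of leading eigenvectors entering the search
#'   (bounded exhaustive search over at most 2^maxAxes - 1 subsets).
#' @return list with \code{subset} (integer axis indices), \code{ratio},
#'   \code{inter} and \code{within}.
#' @export
selectAxisSubset <- function(space, maxAxes = 10L) {
  k <- min(maxAxes, length(space@eigenvalues))
  stopifnot(k >= 1L)
  groups <- space@refGroups
  best <- NULL
  for (size in seq_len(k)) {
    subsets <- combn(k, size)
    for (j in seq_len(ncol(subsets))) {
      axes <- subsets[, j]
      v <- .varianceDecomposition(space@refCoords, groups, axes)
      ratio <- if (v$within > 0) v$inter / v$within else
        (if (v$inter > 0) Inf else 0)
      if (is.null(best) || ratio > best$ratio + 1e-12)
        best <- list(subset = axes, ratio = ratio,
                     inter = v$inter, within = v$within)
      # ties: earlier (smaller, lexicographically first) subset kept
    }
  }
  best
}

#' Reclassify previously unattributed samples over an eigenvector subset
#'
#' Recomputes the RMS decisions of the given samples over \code{subset}.
#' Samples already attributed are also re-evaluated as a consistency check: a
#' changed decision is reported with a warning (the method expects the
#' refined space to classify outliers without disturbing settled calls), but
#' their original decision is kept.
#'
#' @param space a \linkS4class{ValidationSpace}.
#' @param subset integer axis indices from [selectAxisSubset()].
#' @param unattributed character, sample ids to reclassify.
#' @param attributedDecisions optional named character vector of settled
#'   decisions to verify against the subset.
#' @param sdMultiplier passed to [classifyByRms()].
#' @return named character vector of new decisions for \code{unattributed}.
#' @export
reclassifyWithSubset <- function(space, subset, unattributed,
                                 attributedDecisions = NULL,
                                 sdMultiplier = 1) {
  out <- vapply(unattributed, function(s) {
    classifyByRms(rmsProfile(space, s, axes = subset), sdMultiplier)
  }, character(1))
  if (length(attributedDecisions)) {
    redo <- vapply(names(attributedDecisions), function(s) {
      classifyByRms(rmsProfile(space, s, axes = subset), sdMultiplier)
    }, character(1))
    changed <- redo != attributedDecisions
    if (any(changed))
      warning("subset reclassification changed settled decision(s) for: ",
              paste(names(attributedDecisions)[changed], collapse = ", "))
  }
  out
}
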
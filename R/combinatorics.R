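#' Enumerate half-matrices of one group
#'
#' All \code{choose(n, k)} subsets of size \code{k} of the group's learning
#' samples, in deterministic lexicographic order of the sorted sample ids, so
#' that every downstream filter and the final design list are reproducible.
#'
#' @param sampleIds character, the learning sample ids of one group.
#' @param k half-matrix size (default 5).
#' @return list of character vectors (sorted sample ids), one per subset.
#' @examples
#' length(enumerateHalfMatrices(letters[1:13]))  # choose(13, 5) = 1287
#' @export
enumerateHalfMatrices <- function(sampleIds, k = 5L) {
  sampleIds <- sort(unique(sampleIds))
  if (length(sampleIds) < k)
    stop("group has ", length(sampleIds), " samples, fewer than k = ", k)
  cmb <- combn(sampleIds, k)
  lapply(seq_len(ncol(cmb)), function(i) cmb[, i])
}

#' Drop half-matrices homogeneous for the confounder
#'
#' Half-matrices whose samples all share one confounder level (e.g. all
#' sporadic etiology) are eliminated, so that no retained design can be driven
#' by the confounder rather than the classification focus. When no confounder
#' labels are available the filter is a no-op (a message says so).
#'
#' @param halves list of half-matrices (character vectors of sample ids).
#' @param confounder named character vector of confounder levels per sample,
#'   or \code{NULL}.
#' @return the retained half-matrices.
#' @export
filterConfounder <- function(halves, confounder = NULL) {
  if (is.null(confounder)) {
    message("no confounder labels; confounder filter skipped")
    return(halves)
  }
  keep <- vapply(halves, function(h)
    length(unique(confounder[h])) >= 2L, logical(1))
  if (any(!keep))
    message(sum(!keep), " half-matrices homogeneous for the confounder removed")
  halves[keep]
}

#' Enforce pairwise overlap below half the half-matrix size
#'
#' Implements the rule that retained half-matrices must differ by more than
#' 50% in composition: any two retained halves of size k may share at most
#' \code{maxShared} samples (default \code{floor(k/2)}). Selection is the
#' greedy maximal set scanning the lexicographic enumeration order, which
#' makes the result deterministic.
#'
#' @param halves list of half-matrices in enumeration order.
#' @param maxShared maximum pairwise intersection; default \code{floor(k/2)}.
#' @return the retained half-matrices.
#' @export
filterOverlap <- function(halves, maxShared = NULL) {
  if (!length(halves)) return(halves)
  k <- length(halves[[1L]])
  if (is.null(maxShared)) maxShared <- k %/% 2L
  kept <- list()
  for (h in halves) {
    ok <- TRUE
    for (prev in kept)
      if (length(intersect(h, prev)) > maxShared) { ok <- FALSE; break }
    if (ok) kept[[length(kept) + 1L]] <- h
  }
  kept
}

#' Cross the two groups' half-matrices into 10-sample designs
#'
#' Cartesian product of the retained group-A and group-B half-matrices. A
#' coverage check warns if any learning sample appears in no design: the
#' half-matrix size was chosen in the source method precisely so that every
#' learning sample is present in at least one selected design.
#'
#' @param halvesA,halvesB lists of half-matrices of the two groups.
#' @param learningIds optional character vector of all learning sample ids for
#'   the coverage check.
#' @return list of designs; each design is a list with elements \code{A} and
#'   \code{B} (character vectors of sample ids).
#' @export
buildDesigns <- function(halvesA, halvesB, learningIds = NULL) {
  if (!length(halvesA) || !length(halvesB))
    stop("both groups must retain at least one half-matrix")
  designs <- vector("list", length(halvesA) * length(halvesB))
  i <- 0L
  for (a in halvesA) for (b in halvesB) {
    i <- i + 1L
    designs[[i]] <- list(A = a, B = b)
  }
  if (!is.null(learningIds)) {
    used <- unique(unlist(designs))
    missing <- setdiff(learningIds, used)
    if (length(missing))
      warning("learning sample(s) in no design: ",
              paste(missing, collapse = ", "))
  }
  designs
}
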
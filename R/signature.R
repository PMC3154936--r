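#' Compile validated training matrices into relevance frequencies
#'
#' For every gene i and learning sample j, the relevance frequency F(i,j) is
#' the frequency at which gene and sample are found together in a validated
#' training matrix, weighted by each matrix's count c(h) of correctly
#' classified training tumors:
#' \deqn{F(i,j) = \sum_h g(i_h, j_h)\, c(h) / \sum_h c(h)}
#' with g = 1 iff matrix h contains both. The alternative
#' \code{"tumor_weight"} normalization divides column-wise by
#' \eqn{\sum_h g(j_h) c(h)} instead (sensitivity analysis).
#'
#' @param matrices list of validated training matrices; each element is a
#'   list with \code{geneIds} (candidate genes), \code{designIds} (the 10
#'   design sample ids) and \code{c} (correct-classification count, >= 1).
#' @param learningIds character, all learning sample ids (the columns of F).
#' @param normalization \code{"total_weight"} (default) or
#'   \code{"tumor_weight"}.
#' @param allCandidateGenes optional character vector: the candidate genes of
#'   all training matrices, validated or not (the N of the marginal
#'   definitions). Genes never present in a validated matrix keep an all-zero
#'   row of F, which places the selection threshold in the tail of the full
#'   candidate distribution. Defaults to the genes of the validated matrices.
#' @return A \linkS4class{RelevanceTable}.
#' @export
compileRelevance <- function(matrices, learningIds,
                             normalization = c("total_weight", "tumor_weight"),
                             allCandidateGenes = NULL) {
  normalization <- match.arg(normalization)
  if (!length(matrices)) stop("no validated training matrices")
  genes <- sort(unique(unlist(lapply(matrices, `[[`, "geneIds"))))
  if (!length(genes)) stop("validated matrices carry no candidate genes")
  if (!is.null(allCandidateGenes)) {
    if (!all(genes %in% allCandidateGenes))
      stop("allCandidateGenes must contain every validated-matrix gene")
    genes <- sort(unique(allCandidateGenes))
  }
  num <- matrix(0, length(genes), length(learningIds),
                dimnames = list(genes, learningIds))
  colDen <- setNames(numeric(length(learningIds)), learningIds)
  totalC <- 0
  for (h in matrices) {
    stopifnot(h$c >= 1L)
    totalC <- totalC + h$c
    j <- intersect(h$designIds, learningIds)
    num[h$geneIds, j] <- num[h$geneIds, j] + h$c
    colDen[j] <- colDen[j] + h$c
  }
  F <- switch(normalization,
    total_weight = num / totalC,
    tumor_weight = sweep(num, 2L, pmax(colDen, .Machine$double.eps), "/"))
  Fi <- rowMeans(F)
  Fj <- colMeans(F)
  mF <- mean(Fj)
  vF <- sqrt(mean((Fj - mF)^2))        # population form over the P samples
  new("RelevanceTable", F = F, Fi = Fi, Fj = Fj, mF = mF, vF = vF,
      H = length(matrices), P = length(learningIds), N = length(genes),
      normalization = normalization)
}

#' Accessors for RelevanceTable
#'
#' \code{geneRelevance} returns the per-gene mean relevance F(i),
#' \code{sampleRelevance} the per-sample marginal F(j), and
#' \code{relevanceThreshold} the signature cutoff mF + 2 vF.
#'
#' @param x a \linkS4class{RelevanceTable}.
#' @name RelevanceTable-accessors
NULL

#' @rdname RelevanceTable-accessors
#' @export
setMethod("geneRelevance", "RelevanceTable", function(x) x@Fi)

#' @rdname RelevanceTable-accessors
#' @export
setMethod("sampleRelevance", "RelevanceTable", function(x) x@Fj)

#' @rdname RelevanceTable-accessors
#' @export
setMethod("relevanceThreshold", "RelevanceTable", function(x) x@mF + 2 * x@vF)

#' @export
setMethod("show", "RelevanceTable", function(object) {
  cat("RelevanceTable:", object@N, "candidate genes x", object@P,
      "learning samples, compiled from", object@H, "validated matrices\n")
  cat(sprintf("  mF = %.4g, vF = %.4g, threshold mF + 2vF = %.4g (%s)\n",
              object@mF, object@vF, relevanceThreshold(object),
              object@normalization))
})

#' Select the final signature genes
#'
#' Exactly the genes whose mean relevance F(i) reaches the threshold
#' mF + 2 vF, ordered by decreasing F(i) (ties broken by gene id).
#'
#' @param table a \linkS4class{RelevanceTable}.
#' @return character vector of gene ids.
#' @export
selectSignature <- function(table) {
  thr <- relevanceThreshold(table)
  keep <- table@Fi >= thr
  if (!any(keep)) {
    q <- quantile(table@Fi, c(0.5, 0.9, 0.99, 1))
    stop("no gene reaches the relevance threshold ", signif(thr, 4),
         "; F(i) quantiles: ",
         paste(sprintf("%s=%.4g", names(q), q), collapse = ", "))
  }
  ids <- names(table@Fi)[keep]
  ids[order(-table@Fi[keep], ids)]
}

#' Build the standardized matrix xi
#'
#' For each validated training matrix h, the per-row mean m_h and module M_h
#' are computed on the 10 design columns only; the rows are then extended to
#' all L samples (learning + testing) and transformed as (value - m_h)/M_h,
#' giving E_h. The standardized value xi(i,j) is the mean of E_h(i,j) over the
#' validated matrices containing gene i, restricted to the signature genes.
#' Because the row statistics come from the design columns alone, the
#' geometry of the learning samples is unchanged by the arrival of testing
#' samples — the basis of case-by-case prediction.
#'
#' @param matrices list of validated training matrices (see
#'   [compileRelevance()]).
#' @param fullValues numeric matrix of raw log ratios, genes x all L samples.
#' @param signatureGenes character, the selected signature gene ids.
#' @param learningIds character, learning sample ids (defines xi').
#' @param groups optional named group labels per sample of \code{fullValues}.
#' @return A \linkS4class{StandardizedMatrix}.
#' @export
standardizeMatrix <- function(matrices, fullValues, signatureGenes,
                              learningIds, groups = NULL) {
  missing <- setdiff(signatureGenes, rownames(fullValues))
  if (length(missing))
    stop("signature gene(s) absent from the expression matrix: ",
         paste(missing, collapse = ", "))
  L <- colnames(fullValues)
  acc <- matrix(0, length(signatureGenes), length(L),
                dimnames = list(signatureGenes, L))
  nContrib <- setNames(integer(length(signatureGenes)), signatureGenes)
  for (h in matrices) {
    g <- intersect(signatureGenes, h$geneIds)
    if (!length(g)) next
    design <- fullValues[g, h$designIds, drop = FALSE]
    m <- rowMeans(design)
    M <- sqrt(rowSums((design - m)^2))
    ok <- M > 0
    g <- g[ok]
    if (!length(g)) next
    E <- (fullValues[g, , drop = FALSE] - m[ok]) / M[ok]
    acc[g, ] <- acc[g, ] + E
    nContrib[g] <- nContrib[g] + 1L
  }
  uncovered <- names(nContrib)[nContrib == 0L]
  if (length(uncovered))
    stop("signature gene(s) present in no validated matrix: ",
         paste(uncovered, collapse = ", "))
  xi <- acc / nContrib
  grp <- if (is.null(groups)) factor(rep(NA_character_, length(L)))
         else factor(unname(groups[L]))
  new("StandardizedMatrix", xi = xi, nContrib = nContrib,
      learningIds = learningIds, groups = grp)
}

#' @export
setMethod("show", "StandardizedMatrix", function(object) {
  cat("StandardizedMatrix:", nrow(object@xi), "signature genes x",
      ncol(object@xi), "samples (", length(object@learningIds),
      "learning )\n")
})
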
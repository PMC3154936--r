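#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats sd var quantile dnorm rnorm rbinom setNames
#' @importFrom utils combn read.delim write.table head tail
NULL

#' Two-group expression series
#'
#' An \code{ExpressionSeries} holds a genes x samples matrix of normalized log
#' expression ratios together with per-sample metadata. It extends
#' \linkS4class{SummarizedExperiment}: the single assay is named
#' \code{"logratio"}, and \code{colData} carries at least \code{group} (one of
#' exactly two subgroup labels, e.g. benign/malignant histology) and
#' \code{split} (\code{"learning"} or \code{"testing"}). An optional
#' \code{confounder} column (e.g. sporadic vs radiation-induced etiology) is
#' used by the half-matrix confounder filter.
#'
#' All values must be finite; rows or samples with duplicate identifiers are
#' rejected by the validity method.
#'
#' @seealso [ExpressionSeries()], [readExpressionSeries()]
#' @export
setClass("ExpressionSeries", contains = "SummarizedExperiment")

setValidity("ExpressionSeries", function(object) {
  msg <- character()
  if (!"logratio" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'logratio' is required")
  v <- SummarizedExperiment::assay(object, "logratio")
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "gene ids must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids must be present and unique")
  if (!all(is.finite(v)))
    msg <- c(msg, "all log-ratio values must be finite")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("group", "split") %in% colnames(cd))) {
    msg <- c(msg, "colData must contain 'group' and 'split'")
  } else {
    if (length(unique(cd$group)) != 2L)
      msg <- c(msg, "exactly two group labels are required")
    if (!all(cd$split %in% c("learning", "testing")))
      msg <- c(msg, "split must be 'learning' or 'testing'")
  }
  if (length(msg)) msg else TRUE
})

#' Gene signature selected from compiled relevance frequencies
#'
#' Genes retained by the relevance threshold F(i) >= mF + 2 vF, ordered by
#' decreasing mean relevance F(i). \code{differential} is the mean log-ratio
#' difference between the two groups over the learning columns of the
#' standardized matrix, recorded so the direction of deregulation is explicit.
#'
#' @slot geneIds character, unique gene identifiers.
#' @slot Fi numeric, per-gene mean relevance frequency in [0, 1].
#' @slot differential numeric, per-gene mean standardized log-ratio difference
#'   (group A minus group B).
#' @export
setClass("GeneSignature",
  representation(geneIds = "character", Fi = "numeric", differential = "numeric"))

setValidity("GeneSignature", function(object) {
  msg <- character()
  n <- length(object@geneIds)
  if (anyDuplicated(object@geneIds)) msg <- c(msg, "gene ids must be unique")
  if (length(object@Fi) != n || length(object@differential) != n)
    msg <- c(msg, "Fi and differential must match geneIds in length")
  if (n && any(object@Fi < 0 | object@Fi > 1))
    msg <- c(msg, "Fi must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Relevance frequency table compiled from validated training matrices
#'
#' \code{F} holds the c(h)-weighted co-occurrence frequency F(i,j) of gene i and
#' learning sample j across the H validated training matrices. \code{Fi} and
#' \code{Fj} are the row and column means, \code{mF} and \code{vF} the mean and
#' standard deviation of the per-sample marginals F(j) that define the
#' signature threshold mF + 2 vF.
#'
#' @slot F numeric matrix, genes x learning samples, values in [0, 1].
#' @slot Fi,Fj numeric marginal means.
#' @slot mF,vF numeric scalars.
#' @slot H,P,N integer: validated-matrix, learning-sample and candidate-gene counts.
#' @slot normalization character, \code{"total_weight"} or \code{"tumor_weight"}.
#' @export
setClass("RelevanceTable",
  representation(F = "matrix", Fi = "numeric", Fj = "numeric",
                 mF = "numeric", vF = "numeric",
                 H = "integer", P = "integer", N = "integer",
                 normalization = "character"))

setValidity("RelevanceTable", function(object) {
  msg <- character()
  if (any(object@F < -1e-12 | object@F > 1 + 1e-12))
    msg <- c(msg, "F(i,j) must lie in [0, 1]")
  if (object@mF < 0 || object@mF > 1) msg <- c(msg, "mF must lie in [0, 1]")
  if (object@vF < 0) msg <- c(msg, "vF must be non-negative")
  if (nrow(object@F) != length(object@Fi) || ncol(object@F) != length(object@Fj))
    msg <- c(msg, "marginal lengths must match F dimensions")
  if (length(msg)) msg else TRUE
})

#' Standardized expression matrix (xi)
#'
#' Per-gene average, across the validated training matrices containing the
#' gene, of the design-centered/normalized expression extended to all L
#' samples. Restricted to the signature genes. The learning-sample restriction
#' xi' drives the validation-space eigendecomposition.
#'
#' @slot xi numeric matrix, signature genes x all samples.
#' @slot nContrib integer, per gene the number of validated matrices averaged
#'   (constant along each row of \code{xi}).
#' @slot learningIds character, sample ids forming xi'.
#' @slot groups factor of length ncol(xi), the group label per sample (NA
#'   allowed for blind samples).
#' @export
setClass("StandardizedMatrix",
  representation(xi = "matrix", nContrib = "integer",
                 learningIds = "character", groups = "factor"))

setValidity("StandardizedMatrix", function(object) {
  msg <- character()
  if (length(object@nContrib) != nrow(object@xi))
    msg <- c(msg, "nContrib must have one entry per gene")
  if (any(object@nContrib < 1L))
    msg <- c(msg, "every gene must be averaged over at least one matrix")
  if (!all(object@learningIds %in% colnames(object@xi)))
    msg <- c(msg, "learning ids must be columns of xi")
  if (length(object@groups) != ncol(object@xi))
    msg <- c(msg, "groups must have one entry per sample")
  if (length(msg)) msg else TRUE
})

#' PCA coordinate space with reference samples
#'
#' Eigenvectors (in gene space) and eigenvalues of the row-centered reference
#' matrix, plus the coordinates of the reference samples and of any projected
#' query samples. Eigenvalues are sorted in decreasing order; each
#' eigenvector's sign is fixed so that its largest-magnitude component is
#' positive, making projections reproducible.
#'
#' \code{TrainingSpace} (a 10-sample design with its held-out learning samples
#' projected) and \code{ValidationSpace} (xi' with every sample projected) are
#' thin subclasses used by the internal cross-validation and the blind
#' classification stages respectively.
#'
#' @slot rotation numeric matrix, genes x axes (eigenvectors as columns).
#' @slot eigenvalues numeric, decreasing, length = number of axes.
#' @slot center numeric, per-gene centering vector applied before projection.
#' @slot refCoords numeric matrix, axes x reference samples.
#' @slot refGroups factor, group label per reference sample.
#' @slot queryCoords numeric matrix, axes x projected query samples (possibly
#'   zero columns).
#' @slot geneIds character, the genes spanning the space.
#' @slot activeAxes integer, the axis indices used by default for RMS decisions.
#' @export
setClass("ProjectionSpace",
  representation(rotation = "matrix", eigenvalues = "numeric",
                 center = "numeric", refCoords = "matrix",
                 refGroups = "factor", queryCoords = "matrix",
                 geneIds = "character", activeAxes = "integer"))

setValidity("ProjectionSpace", function(object) {
  msg <- character()
  ev <- object@eigenvalues
  if (is.unsorted(rev(ev))) msg <- c(msg, "eigenvalues must be sorted decreasing")
  if (length(ev) && min(ev) < -1e-9)
    msg <- c(msg, "eigenvalues must be non-negative within tolerance")
  if (ncol(object@refCoords) != length(object@refGroups))
    msg <- c(msg, "one group label per reference sample is required")
  if (length(object@activeAxes) &&
      (min(object@activeAxes) < 1L || max(object@activeAxes) > length(ev)))
    msg <- c(msg, "activeAxes out of range")
  if (length(msg)) msg else TRUE
})

#' @rdname ProjectionSpace-class
#' @export
setClass("TrainingSpace", contains = "ProjectionSpace")

#' @rdname ProjectionSpace-class
#' @export
setClass("ValidationSpace", contains = "ProjectionSpace")

#' Per-sample classification decisions and per-group counts
#'
#' \code{decisions} has one row per classified sample: its RMS to each group
#' barycenter, the decision (\code{attributed_A}, \code{attributed_B},
#' \code{unattributed}, \code{rejected}), the axis-selection stage that
#' produced it, and the true group where known. \code{counts} tabulates, per
#' group, the correctly classified ("well"), misclassified ("false") and
#' unclassified samples, matching the layout of published efficiency tables.
#'
#' @slot decisions data.frame.
#' @slot counts data.frame with columns group, well, false, unclassified.
#' @slot groups character of length 2, the labels behind A and B.
#' @export
setClass("ClassificationReport",
  representation(decisions = "data.frame", counts = "data.frame",
                 groups = "character"))

setValidity("ClassificationReport", function(object) {
  msg <- character()
  need <- c("group", "well", "false", "unclassified")
  if (!all(need %in% colnames(object@counts)))
    msg <- c(msg, "counts needs columns group/well/false/unclassified")
  if (length(object@groups) != 2L)
    msg <- c(msg, "exactly two group labels are required")
  d <- object@decisions
  if (nrow(d)) {
    ok <- c("attributed_A", "attributed_B", "unattributed", "rejected")
    if (!all(d$decision %in% ok))
      msg <- c(msg, "unknown decision labels")
    known <- !is.na(d$truth)
    if (sum(object@counts$well + object@counts$false +
            object@counts$unclassified) != sum(known))
      msg <- c(msg, "counts must sum to the number of samples with known truth")
  }
  if (length(msg)) msg else TRUE
})

#' Per-group prediction counts for the efficiency evaluators
#'
#' Holds, for each of the two groups, the number of correctly classified
#' ("well"), misclassified ("false") and unclassified samples — the three
#' columns of the published efficiency tables — so that printed tables can be
#' scored directly by [rpe()], [gpe()] and [sensitivitySpecificity()].
#'
#' @slot well,false,unclassified named numeric vectors, one entry per group.
#' @export
setClass("PredictionCounts",
  representation(well = "numeric", false = "numeric", unclassified = "numeric"))

setValidity("PredictionCounts", function(object) {
  msg <- character()
  if (length(object@well) != length(object@false) ||
      length(object@well) != length(object@unclassified))
    msg <- c(msg, "count vectors must have equal length")
  if (any(c(object@well, object@false, object@unclassified) < 0))
    msg <- c(msg, "counts must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Configuration of the synthetic two-group series generator
#'
#' Defaults emulate a small two-color microarray study: 2000 genes of which 50
#' carry an oppositely regulated planted signature with mean absolute
#' log-ratio 0.9 (three noise standard deviations, noise sd 0.3), 50 genes
#' driven only by a binary confounder (etiology), per-entry heterogeneity 0.2
#' (each signature value is replaced by background noise with that
#' probability), and 13 + 13 learning with 14 + 14 testing samples.
#'
#' @slot nGenes,nSignature,nConfounderGenes integer gene counts.
#' @slot nLearning,nTesting integer length-2 vectors, samples per group.
#' @slot effect numeric, mean |log-ratio| of signature genes.
#' @slot heterogeneity numeric in [0, 1), per-entry replacement probability.
#' @slot noiseSd numeric, background noise standard deviation.
#' @slot confounderEffect numeric, mean |log-ratio| of confounder genes.
#' @slot confounderFraction numeric in (0, 1), fraction of each group at the
#'   second confounder level.
#' @slot seed integer random seed.
#' @export
setClass("SimulationConfig",
  representation(nGenes = "integer", nSignature = "integer",
                 nConfounderGenes = "integer",
                 nLearning = "integer", nTesting = "integer",
                 effect = "numeric", heterogeneity = "numeric",
                 noiseSd = "numeric", confounderEffect = "numeric",
                 confounderFraction = "numeric", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@nSignature + object@nConfounderGenes > object@nGenes)
    msg <- c(msg, "signature + confounder genes must not exceed nGenes")
  if (any(c(object@nGenes, object@nLearning, object@nTesting) < 1L))
    msg <- c(msg, "all counts must be positive")
  if (length(object@nLearning) != 2L || length(object@nTesting) != 2L)
    msg <- c(msg, "nLearning and nTesting must have one entry per group")
  if (object@heterogeneity < 0 || object@heterogeneity >= 1)
    msg <- c(msg, "heterogeneity must lie in [0, 1)")
  if (object@noiseSd <= 0) msg <- c(msg, "noiseSd must be positive")
  if (object@confounderFraction <= 0 || object@confounderFraction >= 1)
    msg <- c(msg, "confounderFraction must lie in (0, 1)")
  if (length(msg)) msg else TRUE
})
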
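#' Construct an ExpressionSeries
#'
#' @param values numeric matrix of log expression ratios, genes in rows (with
#'   rownames) and samples in columns (with colnames).
#' @param metadata data.frame with one row per sample and columns
#'   \code{sample_id}, \code{group}, \code{split}, optionally
#'   \code{confounder} and further covariates. Rows are matched to the matrix
#'   columns by \code{sample_id}.
#' @return An \linkS4class{ExpressionSeries}.
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' md <- data.frame(sample_id = colnames(m),
#'                  group = rep(c("A", "B"), 2),
#'                  split = "learning")
#' es <- ExpressionSeries(m, md)
#' @export
ExpressionSeries <- function(values, metadata) {
  stopifnot(is.matrix(values))
  if (!all(c("sample_id", "group", "split") %in% colnames(metadata)))
    stop("metadata needs columns sample_id, group, split")
  missing_meta <- setdiff(colnames(values), metadata$sample_id)
  if (length(missing_meta))
    stop("samples without metadata: ", paste(missing_meta, collapse = ", "))
  metadata <- metadata[match(colnames(values), metadata$sample_id), , drop = FALSE]
  cd <- S4Vectors::DataFrame(metadata[setdiff(colnames(metadata), "sample_id")],
                             row.names = metadata$sample_id)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(logratio = values), colData = cd)
  new("ExpressionSeries", se)
}

#' Accessors for ExpressionSeries
#'
#' \code{exprValues} returns the log-ratio matrix; \code{sampleGroups},
#' \code{sampleSplit} and \code{sampleConfounder} the per-sample annotations
#' (named by sample id; \code{sampleConfounder} returns \code{NULL} when no
#' confounder column is present); \code{learningSamples} and
#' \code{testingSamples} the sample ids of each split.
#'
#' @param x an \linkS4class{ExpressionSeries}.
#' @name ExpressionSeries-accessors
NULL

#' @rdname ExpressionSeries-accessors
#' @export
setMethod("exprValues", "ExpressionSeries", function(x)
  SummarizedExperiment::assay(x, "logratio"))

#' @rdname ExpressionSeries-accessors
#' @export
setMethod("sampleGroups", "ExpressionSeries", function(x)
  setNames(as.character(SummarizedExperiment::colData(x)$group), colnames(x)))

#' @rdname ExpressionSeries-accessors
#' @export
setMethod("sampleSplit", "ExpressionSeries", function(x)
  setNames(as.character(SummarizedExperiment::colData(x)$split), colnames(x)))

#' @rdname ExpressionSeries-accessors
#' @export
setMethod("sampleConfounder", "ExpressionSeries", function(x) {
  cd <- SummarizedExperiment::colData(x)
  if (!"confounder" %in% colnames(cd)) return(NULL)
  setNames(as.character(cd$confounder), colnames(x))
})

#' @rdname ExpressionSeries-accessors
#' @export
setMethod("learningSamples", "ExpressionSeries", function(x)
  colnames(x)[sampleSplit(x) == "learning"])

#' @rdname ExpressionSeries-accessors
#' @export
setMethod("testingSamples", "ExpressionSeries", function(x)
  colnames(x)[sampleSplit(x) == "testing"])

#' @export
setMethod("show", "ExpressionSeries", function(object) {
  g <- table(sampleGroups(object), sampleSplit(object))
  cat("ExpressionSeries:", nrow(object), "genes x", ncol(object), "samples\n")
  print(g)
})

#' Read an expression matrix with sample metadata from tab-delimited text
#'
#' The expression file has a header row of sample ids, gene ids in the first
#' column, one tab-delimited row per gene. Rows containing non-numeric or
#' missing values are dropped and counted (a message reports how many). The
#' metadata file has columns \code{sample_id}, \code{group}, \code{split} and
#' optionally \code{confounder} plus covariates.
#'
#' @param path path of the expression TSV.
#' @param metadataPath path of the sample metadata TSV.
#' @return An \linkS4class{ExpressionSeries}.
#' @export
readExpressionSeries <- function(path, metadataPath) {
  m <- readExpressionMatrix(path)
  md <- read.delim(metadataPath, stringsAsFactors = FALSE)
  ExpressionSeries(m, md)
}

#' Read a genes x samples log-ratio matrix from tab-delimited text
#'
#' @inheritParams readExpressionSeries
#' @return numeric matrix with gene ids as rownames and sample ids as
#'   colnames; rows with any missing/non-numeric entry are removed (reported
#'   via a message).
#' @export
readExpressionMatrix <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(d) == 0L || ncol(d) < 2L) stop("empty or malformed expression file: ", path)
  ids <- as.character(d[[1L]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicated gene ids: ", paste(dup, collapse = ", "))
  v <- suppressWarnings(
    vapply(d[-1L], function(col) as.numeric(col), numeric(nrow(d))))
  if (nrow(d) == 1L) v <- matrix(v, nrow = 1L, dimnames = list(NULL, colnames(d)[-1L]))
  keep <- apply(is.finite(v), 1L, all)
  if (any(!keep))
    message(sum(!keep), " row(s) with missing or non-numeric values dropped")
  v <- v[keep, , drop = FALSE]
  if (nrow(v) == 0L) stop("no usable rows in ", path)
  rownames(v) <- ids[keep]
  if (anyDuplicated(colnames(v)))
    stop("duplicated sample ids: ",
         paste(unique(colnames(v)[duplicated(colnames(v))]), collapse = ", "))
  v
}

#' Write an ExpressionSeries to the tab-delimited interchange format
#'
#' @param x an \linkS4class{ExpressionSeries}.
#' @param path expression TSV output path.
#' @param metadataPath metadata TSV output path.
#' @export
writeExpressionSeries <- function(x, path, metadataPath) {
  v <- exprValues(x)
  d <- data.frame(gene_id = rownames(v), v, check.names = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  cd <- as.data.frame(SummarizedExperiment::colData(x))
  md <- data.frame(sample_id = colnames(v), cd, check.names = FALSE)
  write.table(md, metadataPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Center and normalize matrix rows
#'
#' Each row is transformed to \code{(x - m) / M}. When \code{stats} is not
#' supplied, \code{m} is the row mean and \code{M} the module (Euclidean norm
#' of the centered row), so every output row has mean 0 and norm 1; the
#' statistics used are returned so that further samples can be placed on the
#' same scale without refitting. When \code{stats} is supplied, the externally
#' fixed \code{m} and \code{M} are applied as-is.
#'
#' @param values numeric matrix (rows are genes).
#' @param stats optional list with numeric vectors \code{m} and \code{M}, one
#'   entry per row.
#' @return list with \code{values} (transformed matrix) and \code{stats}.
#' @examples
#' r <- centerNormalizeRows(matrix(c(1, 2, 3), 1))
#' rowMeans(r$values)           # 0
#' sqrt(sum(r$values^2))        # 1
#' @export
centerNormalizeRows <- function(values, stats = NULL) {
  stopifnot(is.matrix(values))
  if (is.null(stats)) {
    m <- rowMeans(values)
    centered <- values - m
    M <- sqrt(rowSums(centered^2))
    zero <- M <= .Machine$double.eps * ncol(values)
    if (any(zero)) {
      bad <- if (is.null(rownames(values))) which(zero) else rownames(values)[zero]
      stop("zero module (constant row) for gene(s): ",
           paste(bad, collapse = ", "))
    }
    list(values = centered / M, stats = list(m = m, M = M))
  } else {
    stopifnot(length(stats$m) == nrow(values), length(stats$M) == nrow(values))
    if (any(stats$M == 0)) stop("zero module in supplied stats")
    list(values = (values - stats$m) / stats$M, stats = stats)
  }
}
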
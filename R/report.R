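#' Assemble a classification report
#'
#' @param decisions data.frame with columns \code{sample_id}, \code{truth}
#'   (group label or NA), \code{decision}, \code{rms_A}, \code{rms_B},
#'   \code{stage}.
#' @param groups character of length 2: the group labels behind
#'   \code{attributed_A} and \code{attributed_B}.
#' @return A \linkS4class{ClassificationReport}; per-group well/false/
#'   unclassified counts are tabulated over the samples with known truth.
#' @export
classificationReport <- function(decisions, groups) {
  stopifnot(length(groups) == 2L)
  counts <- data.frame(group = groups, well = 0L, false = 0L,
                       unclassified = 0L, stringsAsFactors = FALSE)
  if (nrow(decisions)) {
    called <- ifelse(decisions$decision == "attributed_A", groups[1L],
                     ifelse(decisions$decision == "attributed_B", groups[2L],
                            NA_character_))
    for (g in seq_along(groups)) {
      inG <- !is.na(decisions$truth) & decisions$truth == groups[g]
      counts$well[g] <- sum(inG & !is.na(called) & called == decisions$truth)
      counts$false[g] <- sum(inG & !is.na(called) & called != decisions$truth)
      counts$unclassified[g] <- sum(inG & is.na(called))
    }
  }
  new("ClassificationReport", decisions = decisions, counts = counts,
      groups = groups)
}

#' Accessors for ClassificationReport
#'
#' \code{decisions} returns the per-sample decision table;
#' \code{predictionCounts} the per-group counts as a
#' \linkS4class{PredictionCounts} ready for [rpe()]/[gpe()].
#'
#' @param x a \linkS4class{ClassificationReport}.
#' @name ClassificationReport-accessors
NULL

#' @rdname ClassificationReport-accessors
#' @export
setMethod("decisions", "ClassificationReport", function(x) x@decisions)

#' @rdname ClassificationReport-accessors
#' @export
setMethod("predictionCounts", "ClassificationReport", function(x) {
  newPredictionCounts(
    well = setNames(as.numeric(x@counts$well), x@counts$group),
    false = setNames(as.numeric(x@counts$false), x@counts$group),
    unclassified = setNames(as.numeric(x@counts$unclassified),
                            x@counts$group))
})

#' @export
setMethod("show", "ClassificationReport", function(object) {
  cat("ClassificationReport:", nrow(object@decisions), "sample(s)\n")
  print(object@counts)
})

#' Write / read a classification report as JSON
#'
#' The JSON serialization round-trips losslessly through the paired reader.
#'
#' @param report a \linkS4class{ClassificationReport}.
#' @param path output (input) file path.
#' @export
writeReport <- function(report, path) {
  payload <- list(groups = report@groups,
                  decisions = report@decisions,
                  counts = report@counts)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(NULL)
}

#' @rdname writeReport
#' @return \code{readReport} returns the \linkS4class{ClassificationReport}.
#' @export
readReport <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  dec <- as.data.frame(payload$decisions, stringsAsFactors = FALSE)
  if (!nrow(dec))
    dec <- data.frame(sample_id = character(), truth = character(),
                      decision = character(), rms_A = numeric(),
                      rms_B = numeric(), stage = character(),
                      stringsAsFactors = FALSE)
  if (nrow(dec) && !"truth" %in% colnames(dec)) dec$truth <- NA_character_
  if (nrow(dec)) dec$truth <- as.character(dec$truth)
  classificationReport(dec, as.character(payload$groups))
}

#' Write / read a gene signature as tab-delimited text
#'
#' Columns: \code{gene_id}, \code{F_i} (mean relevance), \code{diff} (mean
#' standardized log-ratio difference, group A minus group B).
#'
#' @param signature a \linkS4class{GeneSignature}.
#' @param path output (input) file path.
#' @export
writeSignature <- function(signature, path) {
  d <- data.frame(gene_id = signature@geneIds, F_i = signature@Fi,
                  diff = signature@differential)
  write.table(format(d, digits = 17, scientific = FALSE, trim = TRUE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' @rdname writeSignature
#' @return \code{readSignature} returns the \linkS4class{GeneSignature}.
#' @export
readSignature <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  new("GeneSignature", geneIds = as.character(d$gene_id),
      Fi = as.numeric(d$F_i), differential = as.numeric(d$diff))
}

#' @rdname GeneSignature-accessors
#' @param x a \linkS4class{GeneSignature}.
#' @export
setMethod("signatureGenes", "GeneSignature", function(x) x@geneIds)

#' @export
setMethod("show", "GeneSignature", function(object) {
  cat("GeneSignature:", length(object@geneIds), "genes; top of list:\n")
  print(head(data.frame(gene_id = object@geneIds, F_i = object@Fi,
                        diff = object@differential), 5L))
})
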
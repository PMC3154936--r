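#' Build per-group prediction counts
#'
#' @param well,false,unclassified numeric vectors of equal length (one entry
#'   per group), optionally named with the group labels.
#' @return A \linkS4class{PredictionCounts}.
#' @examples
#' counts <- newPredictionCounts(well = c(FTA = 15, PTC = 13),
#'                               false = c(0, 0), unclassified = c(0, 0))
#' rpe(counts); gpe(counts)
#' @export
newPredictionCounts <- function(well, false = 0 * well,
                                unclassified = 0 * well) {
  new("PredictionCounts", well = well, false = false,
      unclassified = unclassified)
}

#' @export
setMethod("show", "PredictionCounts", function(object) {
  d <- data.frame(well = object@well, false = object@false,
                  `?` = object@unclassified, check.names = FALSE)
  print(d)
})

#' Relative predictive efficiency (RPE)
#'
#' Number of correctly classified samples (both groups pooled) divided by the
#' number of predicted samples (correctly plus incorrectly predicted);
#' unclassified samples do not enter. This evaluator is symmetric in the two
#' groups — no positive group needs to be named.
#'
#' @param counts a \linkS4class{PredictionCounts}.
#' @return scalar in [0, 1].
#' @export
rpe <- function(counts) {
  predicted <- sum(counts@well) + sum(counts@false)
  if (predicted < 1) stop("RPE undefined: no sample was predicted")
  sum(counts@well) / predicted
}

#' General predictive efficiency (GPE)
#'
#' Number of correctly classified samples divided by the total number of
#' samples (correctly classified, misclassified and unclassified), both
#' groups pooled. Unlike [rpe()], unclassified samples lower the score, so
#' GPE <= RPE whenever both are defined.
#'
#' @inheritParams rpe
#' @return scalar in [0, 1].
#' @export
gpe <- function(counts) {
  total <- sum(counts@well) + sum(counts@false) + sum(counts@unclassified)
  if (total < 1) stop("GPE undefined: no samples")
  sum(counts@well) / total
}

#' Dichotomized sensitivity and specificity
#'
#' Collapses the three-way outcome (correct / misclassified / unclassified)
#' into a 2x2 table for an explicitly named positive group. Under
#' \code{"correct_vs_rest"} (the default), a sample counts as a positive call
#' only when correctly classified, so misclassified and unclassified samples
#' of the positive group are false negatives and of the negative group true
#' negatives. Under \code{"per_group"}, misclassified samples of the negative
#' group count as false positives (they were called positive) while its
#' unclassified samples remain true negatives.
#'
#' @inheritParams rpe
#' @param positiveGroup name (or index) of the positive group within the
#'   count vectors.
#' @param dichotomization \code{"correct_vs_rest"} or \code{"per_group"}.
#' @return named numeric vector \code{c(sensitivity, specificity)}.
#' @export
sensitivitySpecificity <- function(counts, positiveGroup,
                                   dichotomization = c("correct_vs_rest",
                                                       "per_group")) {
  dichotomization <- match.arg(dichotomization)
  labels <- names(counts@well)
  pos <- if (is.character(positiveGroup)) match(positiveGroup, labels)
         else as.integer(positiveGroup)
  if (is.na(pos) || pos < 1L || pos > length(counts@well))
    stop("positive group not found")
  neg <- setdiff(seq_along(counts@well), pos)
  posTotal <- counts@well[pos] + counts@false[pos] + counts@unclassified[pos]
  if (posTotal < 1) stop("positive group is empty")
  tp <- counts@well[pos]
  fn <- posTotal - tp
  negTotal <- sum(counts@well[neg] + counts@false[neg] +
                  counts@unclassified[neg])
  fp <- switch(dichotomization,
               correct_vs_rest = 0,
               per_group = sum(counts@false[neg]))
  tn <- negTotal - fp
  c(sensitivity = unname(tp / (tp + fn)),
    specificity = unname(tn / (tn + fp)))
}
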
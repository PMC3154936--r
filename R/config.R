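#' Pipeline configuration
#'
#' Collects every tunable of the signature-discovery and classification
#' stages with the package defaults. Unknown keys are rejected, so a typo in
#' a YAML file cannot silently fall back to a default.
#'
#' @param halfSize half-matrix size k (5-vs-5 designs by default).
#' @param maxShared maximum pairwise overlap of retained half-matrices;
#'   \code{NULL} means \code{floor(halfSize / 2)}.
#' @param tFilterAlpha exact permutation t-test retention threshold.
#' @param emDelta EM candidate confidence threshold on
#'   \code{1 - |P_under - P_over|}.
#' @param emTol,emMaxIter EM convergence controls.
#' @param nAxesTraining leading eigenvectors of a training space.
#' @param nAxesValidation leading eigenvectors of the validation space.
#' @param rmsSdMultiplier standard-deviation multiplier of the RMS
#'   assignment threshold.
#' @param minCoverage continuation threshold on the fraction of learning
#'   samples correctly classified by a validated matrix.
#' @param relevanceNormalization \code{"total_weight"} or
#'   \code{"tumor_weight"}.
#' @param maxAxesSubsetSearch bound of the exhaustive eigenvector-subset
#'   search.
#' @return named list of class \code{"emtsConfig"}.
#' @export
emtsConfig <- function(halfSize = 5L, maxShared = NULL,
                       tFilterAlpha = 0.05, emDelta = 0.05,
                       emTol = 1e-8, emMaxIter = 5000L,
                       nAxesTraining = 3L, nAxesValidation = 3L,
                       rmsSdMultiplier = 1, minCoverage = 0.9,
                       relevanceNormalization = "total_weight",
                       maxAxesSubsetSearch = 10L) {
  cfg <- list(halfSize = as.integer(halfSize),
              maxShared = if (is.null(maxShared)) NULL else
                as.integer(maxShared),
              tFilterAlpha = tFilterAlpha, emDelta = emDelta,
              emTol = emTol, emMaxIter = as.integer(emMaxIter),
              nAxesTraining = as.integer(nAxesTraining),
              nAxesValidation = as.integer(nAxesValidation),
              rmsSdMultiplier = rmsSdMultiplier,
              minCoverage = minCoverage,
              relevanceNormalization = match.arg(relevanceNormalization,
                                                 c("total_weight",
                                                   "tumor_weight")),
              maxAxesSubsetSearch = as.integer(maxAxesSubsetSearch))
  class(cfg) <- "emtsConfig"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Keys must match the arguments of [emtsConfig()]; unknown keys are an
#' error.
#'
#' @param path YAML file path.
#' @return an \code{emtsConfig} list.
#' @export
readConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(emtsConfig))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  do.call(emtsConfig, raw)
}
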
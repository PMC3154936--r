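#' Build a simulation configuration
#'
#' Defaults describe the reference study conditions used throughout the
#' package's tests: a strong planted signal (effect equal to three noise
#' standard deviations) with 20% per-entry heterogeneity, learning groups of
#' 13 and testing groups of 14, 2000 genes with 50 signature and 50
#' confounder-driven genes.
#'
#' @param nGenes,nSignature,nConfounderGenes gene counts.
#' @param nLearning,nTesting samples per group (length-2, groups A and B).
#' @param effect mean |log-ratio| of signature genes (dimensionless log scale).
#' @param heterogeneity probability that a signature entry is replaced by
#'   background noise, mimicking per-tumor expression heterogeneity.
#' @param noiseSd background Gaussian noise standard deviation.
#' @param confounderEffect mean |log-ratio| of confounder genes.
#' @param confounderFraction fraction of each group assigned the second
#'   confounder level (e.g. radiation-induced etiology).
#' @param seed integer seed; the generator is fully reproducible.
#' @return A \linkS4class{SimulationConfig}.
#' @export
simulationConfig <- function(nGenes = 2000L, nSignature = 50L,
                             nConfounderGenes = 50L,
                             nLearning = c(13L, 13L), nTesting = c(14L, 14L),
                             effect = 0.9, heterogeneity = 0.2,
                             noiseSd = 0.3, confounderEffect = 0.9,
                             confounderFraction = 0.5, seed = 1L) {
  new("SimulationConfig",
      nGenes = as.integer(nGenes), nSignature = as.integer(nSignature),
      nConfounderGenes = as.integer(nConfounderGenes),
      nLearning = as.integer(nLearning), nTesting = as.integer(nTesting),
      effect = effect, heterogeneity = heterogeneity, noiseSd = noiseSd,
      confounderEffect = confounderEffect,
      confounderFraction = confounderFraction, seed = as.integer(seed))
}

#' Simulate a two-group expression series with a planted signature
#'
#' Generates a genes x samples log-ratio matrix with the structure the
#' signature-discovery pipeline assumes: signature genes have mean
#' \code{+effect} in one group and \code{-effect} in the other (direction
#' fixed per gene), each signature entry is independently replaced by
#' background noise with probability \code{heterogeneity}; confounder genes
#' depend only on the per-sample confounder label; the remaining background
#' genes are pure noise with mean 0.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return list with \code{series} (an \linkS4class{ExpressionSeries} whose
#'   colData includes the confounder label) and \code{truth} (data.frame of
#'   planted gene ids, their role and direction).
#' @examples
#' sim <- simulateSeries(simulationConfig(nGenes = 200, nSignature = 10,
#'                                        nConfounderGenes = 5,
#'                                        nLearning = c(6, 6),
#'                                        nTesting = c(4, 4)))
#' sim$series
#' head(sim$truth)
#' @export
simulateSeries <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  set.seed(config@seed)

  nA <- config@nLearning[1L] + config@nTesting[1L]
  nB <- config@nLearning[2L] + config@nTesting[2L]
  n <- nA + nB
  groups <- rep(c("A", "B"), c(nA, nB))
  splits <- c(rep("learning", config@nLearning[1L]),
              rep("testing", config@nTesting[1L]),
              rep("learning", config@nLearning[2L]),
              rep("testing", config@nTesting[2L]))
  ids <- sprintf("%s%02d", groups, c(seq_len(nA), seq_len(nB)))

  gene_ids <- sprintf("g%04d", seq_len(config@nGenes))
  sig_idx <- seq_len(config@nSignature)
  conf_idx <- config@nSignature + seq_len(config@nConfounderGenes)

  values <- matrix(rnorm(config@nGenes * n, sd = config@noiseSd),
                   config@nGenes, n, dimnames = list(gene_ids, ids))

  # planted signature: direction fixed per gene, opposite means in the groups
  direction <- rep_len(c(1, -1), config@nSignature)
  if (config@nSignature) {
    shift <- outer(direction * config@effect, ifelse(groups == "A", 1, -1))
    values[sig_idx, ] <- values[sig_idx, ] + shift
    if (config@heterogeneity > 0) {
      flip <- matrix(rbinom(config@nSignature * n, 1L,
                            config@heterogeneity) == 1L,
                     config@nSignature, n)
      noise <- matrix(rnorm(config@nSignature * n, sd = config@noiseSd),
                      config@nSignature, n)
      values[sig_idx, ][flip] <- noise[flip]
    }
  }

  md <- data.frame(sample_id = ids, group = groups, split = splits,
                   stringsAsFactors = FALSE)
  md <- assignEtiologies(md, fraction = config@confounderFraction,
                         seed = config@seed + 1L)

  # confounder genes depend only on the confounder label
  if (config@nConfounderGenes) {
    cdir <- rep_len(c(1, -1), config@nConfounderGenes)
    clev <- ifelse(md$confounder == "level2", 1, -1)
    values[conf_idx, ] <- values[conf_idx, ] +
      outer(cdir * config@confounderEffect, clev)
  }

  truth <- data.frame(
    gene_id = gene_ids[c(sig_idx, conf_idx)],
    role = rep(c("signature", "confounder"),
               c(config@nSignature, config@nConfounderGenes)),
    direction = c(ifelse(direction > 0, "up_in_A", "up_in_B"),
                  rep(NA_character_, config@nConfounderGenes)),
    stringsAsFactors = FALSE)

  list(series = ExpressionSeries(values, md), truth = truth)
}

#' Assign a binary confounder label within each group
#'
#' Labels a fraction of each group's samples with a second confounder level
#' (e.g. radiation-induced etiology vs sporadic), guaranteeing that both
#' levels are represented in every group so the half-matrix confounder filter
#' can operate.
#'
#' @param metadata data.frame with columns \code{sample_id} and \code{group}.
#' @param fraction fraction of each group at the second level, in (0, 1).
#' @param seed integer seed for the within-group label draw.
#' @return the metadata with a \code{confounder} column
#'   (\code{"level1"}/\code{"level2"}).
#' @export
assignEtiologies <- function(metadata, fraction = 0.5, seed = 1L) {
  stopifnot(fraction > 0, fraction < 1)
  set.seed(as.integer(seed))
  metadata$confounder <- "level1"
  for (g in unique(metadata$group)) {
    idx <- which(metadata$group == g)
    k <- round(length(idx) * fraction)
    if (k < 1L || k >= length(idx))
      stop("group ", g, " too small to contain both confounder levels at ",
           "fraction ", fraction)
    metadata$confounder[sample(idx, k)] <- "level2"
  }
  metadata
}
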
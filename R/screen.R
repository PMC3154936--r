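#' Exact permutation t-test filter for one design
#'
#' For every gene of a k-vs-k design, the two-sample t statistic (Welch form,
#' per-group variances) is computed for all \code{choose(2k, k)} labelings of
#' the columns — 252 assignments for a 5-vs-5 design — and the permutation p
#' value is the fraction of labelings with \code{|t|} at least the observed
#' \code{|t|}. Genes with p below \code{alpha} pass the filter. Genes whose t
#' statistic is undefined under the observed labeling (zero variance in both
#' groups) get p = 1 and are dropped.
#'
#' @param values numeric matrix, genes x design samples.
#' @param groupA character or integer, the columns of the first group.
#' @param alpha retention threshold on the exact permutation p value.
#' @return character vector of retained gene ids, with attributes
#'   \code{p} (named p values for all genes) and \code{nPermutations}.
#' @export
permutationTFilter <- function(values, groupA, alpha = 0.05) {
  stopifnot(is.matrix(values))
  if (is.character(groupA)) groupA <- match(groupA, colnames(values))
  n <- ncol(values)
  kA <- length(groupA)
  kB <- n - kA
  stopifnot(kA >= 2L, kB >= 2L)

  assign <- combn(n, kA)                       # all label assignments
  Z <- matrix(0, n, ncol(assign))
  Z[cbind(as.vector(assign), rep(seq_len(ncol(assign)), each = kA))] <- 1

  S <- values %*% Z                            # per-assignment group-A sums
  Q <- (values^2) %*% Z
  totS <- rowSums(values)
  totQ <- rowSums(values^2)
  mA <- S / kA
  mB <- (totS - S) / kB
  vA <- (Q - kA * mA^2) / (kA - 1L)
  vB <- ((totQ - Q) - kB * mB^2) / (kB - 1L)
  se2 <- vA / kA + vB / kB
  tAll <- abs(mA - mB) / sqrt(se2)
  tAll[se2 <= 0] <- NA

  obsCol <- which(colSums(Z[groupA, , drop = FALSE]) == kA)[1L]
  tObs <- tAll[, obsCol]

  p <- rowMeans(tAll >= tObs - 1e-12, na.rm = FALSE)
  p[!is.finite(tObs)] <- 1
  p[is.na(p)] <- 1                             # some permutation t undefined
  names(p) <- rownames(values)

  undef <- !is.finite(tObs)
  if (any(undef))
    message(sum(undef), " gene(s) with undefined t statistic set to p = 1")
  keep <- names(p)[p < alpha]
  structure(keep, p = p, nPermutations = ncol(assign))
}

#' Fit the over/under-expression mixture by EM
#'
#' For every gene of a row-centered and normalized design matrix, a
#' two-component one-dimensional Gaussian mixture — an under-expressed and an
#' over-expressed state sharing a within-state variance — is fitted by
#' expectation-maximization to the gene's own entries. Every entry receives
#' the posterior probabilities P_under and P_over of the two states, with
#' P_under + P_over = 1. An entry near the decision boundary of its gene's
#' two states is ambiguous (both probabilities near 0.5): this is what
#' happens to the heterogeneous per-tumor deviations of an otherwise cleanly
#' deregulated gene. The per-gene fits are computed simultaneously by
#' vectorized EM over the whole matrix.
#'
#' Initialization is fixed and deterministic: within each (centered) row the
#' negative entries seed the under-expressed state and the non-negative
#' entries the over-expressed one, each state starting from the mean and
#' proportion of its seed entries and the row's pooled within-state standard
#' deviation. Repeated fits are bit-for-bit identical.
#'
#' @param values row-centered/normalized numeric matrix (genes x samples).
#' @param tol relative convergence tolerance on the total log-likelihood.
#' @param maxIter maximum EM iterations; non-convergence is an error carrying
#'   the iteration trace.
#' @return list with matrices \code{pOver} and \code{pUnder} (same dimensions
#'   as \code{values}) and \code{model}: per-gene component means
#'   (\code{muUnder}, \code{muOver}), shared standard deviation \code{sd},
#'   over-state weight \code{wOver}, plus \code{logLik} and
#'   \code{iterations}.
#' @export
fitEmPosteriors <- function(values, tol = 1e-8, maxIter = 5000L) {
  stopifnot(is.matrix(values), ncol(values) >= 2L)
  p <- ncol(values)
  neg <- values < 0
  pos <- !neg
  n1 <- rowSums(neg)
  n2 <- p - n1
  # centered rows always carry both signs unless a row is all zero
  mu1 <- rowSums(values * neg) / pmax(n1, 1L)
  mu2 <- rowSums(values * pos) / pmax(n2, 1L)
  sig <- sqrt((rowSums(((values - mu1) * neg)^2) +
               rowSums(((values - mu2) * pos)^2)) / p)
  sigFloor <- pmax(1e-3 * apply(values, 1L, sd), 1e-8)
  sig <- pmax(sig, sigFloor)
  w2 <- n2 / p
  ll <- -Inf
  trace <- numeric(0)
  r2 <- NULL
  for (iter in seq_len(maxIter)) {
    d1 <- (1 - w2) * dnorm(values, mu1, sig)
    d2 <- w2 * dnorm(values, mu2, sig)
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    r2 <- d2 / tot
    llNew <- sum(log(tot))
    trace <- c(trace, llNew)
    if (is.finite(ll) && abs(llNew - ll) < tol * (1 + abs(llNew))) {
      ll <- llNew
      break
    }
    ll <- llNew
    k2 <- rowSums(r2)
    k1 <- p - k2
    w2 <- pmin(pmax(k2 / p, 1e-12), 1 - 1e-12)
    mu1 <- rowSums((1 - r2) * values) / pmax(k1, 1e-12)
    mu2 <- rowSums(r2 * values) / pmax(k2, 1e-12)
    sig <- pmax(sqrt((rowSums((1 - r2) * (values - mu1)^2) +
                      rowSums(r2 * (values - mu2)^2)) / p), sigFloor)
    if (iter == maxIter)
      stop("EM did not converge after ", maxIter, " iterations; ",
           "log-likelihood trace tail: ",
           paste(signif(tail(trace, 5L), 8), collapse = ", "))
  }
  swap <- mu1 > mu2                     # keep state 2 the over-expressed one
  if (any(swap)) {
    tmp <- mu1[swap]; mu1[swap] <- mu2[swap]; mu2[swap] <- tmp
    w2[swap] <- 1 - w2[swap]
    r2[swap, ] <- 1 - r2[swap, , drop = FALSE]
  }
  pOver <- r2
  dimnames(pOver) <- dimnames(values)
  list(pOver = pOver, pUnder = 1 - pOver,
       model = list(muUnder = mu1, muOver = mu2, sd = sig, wOver = w2,
                    logLik = ll, iterations = iter))
}

#' Select candidate genes of one design from the EM posteriors
#'
#' A gene is a candidate iff (rule 1) every one of its entries in the design
#' is confidently assigned — the probability difference
#' \code{1 - |P_under - P_over|} is below \code{delta} for every sample — and
#' (rule 2) it is over-expressed in every sample of one group and
#' under-expressed in every sample of the other (direction of each entry taken
#' from the majority posterior component). The per-gene direction is recorded.
#'
#' @param posteriors result of [fitEmPosteriors()].
#' @param groupA,groupB character or integer column indices of the two groups.
#' @param delta confidence threshold (default 0.05).
#' @return data.frame with columns \code{gene_id} and \code{direction}
#'   (\code{"up_in_A"}/\code{"up_in_B"}); zero rows when no gene qualifies.
#' @export
selectCandidates <- function(posteriors, groupA, groupB, delta = 0.05) {
  pOver <- posteriors$pOver
  if (is.character(groupA)) groupA <- match(groupA, colnames(pOver))
  if (is.character(groupB)) groupB <- match(groupB, colnames(pOver))
  confident <- 1 - abs(2 * pOver - 1) < delta       # |P_under-P_over| = |1-2*pOver|
  over <- pOver > 0.5                               # ties fail rule 1 anyway
  rule1 <- rowSums(confident) == ncol(pOver)
  upA <- rowSums(over[, groupA, drop = FALSE]) == length(groupA) &
         rowSums(over[, groupB, drop = FALSE]) == 0L
  upB <- rowSums(over[, groupB, drop = FALSE]) == length(groupB) &
         rowSums(over[, groupA, drop = FALSE]) == 0L
  keep <- rule1 & (upA | upB)
  data.frame(gene_id = rownames(pOver)[keep],
             direction = ifelse(upA[keep], "up_in_A", "up_in_B"),
             stringsAsFactors = FALSE)
}
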
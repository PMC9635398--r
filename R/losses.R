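## losses: geometric cross entropy, sequence NLL, motif KL, weighted total.

#' Loss weights for the composite design objective
#'
#' Nonnegative weights for the geometric, sequence and motif loss terms.
#' All default to 1; published restricted-design configurations use
#' `sequence = 25` (sequence-restricted) or `motif = 100`
#' (motif-restricted).
#'
#' @param geometric,sequence,motif Nonnegative reals.
#' @return Named numeric vector of length 3.
#' @export
lossWeights <- function(geometric = 1, sequence = 1, motif = 1) {
  w <- c(geometric = geometric, sequence = sequence, motif = motif)
  if (any(w < 0)) stop("loss weights must be nonnegative")
  w
}

#' Motif specification for motif-restricted design
#'
#' A target amino-acid distribution at a subset of the design positions,
#' e.g. 50% Y / 50% S at heavy-chain position 100A.
#'
#' @param designIndex Integer indices into the design region (1 = first
#'   design position).
#' @param probs Numeric length(designIndex) x 20 matrix of target
#'   distributions, columns in [AA20] order; rows must sum to 1.
#' @return List with class `"MotifSpec"`.
#' @export
motifSpec <- function(designIndex, probs) {
  probs <- matrix(probs, nrow = length(designIndex), ncol = 20L,
                  dimnames = list(NULL, AA20))
  if (any(probs < 0) || any(abs(rowSums(probs) - 1) > 1e-9))
    stop("motif rows must be distributions summing to 1")
  structure(list(designIndex = as.integer(designIndex), probs = probs),
            class = "MotifSpec")
}

#' Geometric loss: categorical cross entropy over contact pairs
#'
#' `L_G = -(1/(2C)) * sum over channels X and contact pairs k of
#' log p_{X = target}(k)`, with C the ordered-pair contact count.
#' Pair-channels masked invalid (missing CB) contribute no terms; the
#' normalization stays 1/(2C).
#'
#' @param pred A [GeometryPrediction-class] on the mask's pairs.
#' @param target A [TargetGeometry-class].
#' @param mask The [ContactMask-class] the prediction was made on; C must
#'   be positive.
#' @return Nonnegative scalar loss (natural log).
#' @export
geometricLoss <- function(pred, target, mask) {
  C <- nContacts(mask)
  if (C == 0L) stop("geometric loss undefined for an empty contact mask")
  pairs <- contactPairs(mask)
  total <- 0
  for (k in seq_len(6L)) {
    ch <- GEOM_CHANNELS[k]
    lab <- target@labels[[ch]]
    okT <- target@valid[[ch]]
    for (p in seq_len(C)) {
      i <- pairs[p, 1L]; j <- pairs[p, 2L]
      if (!okT[i, j] || !pred@valid[p, k]) next
      total <- total - flooredLog(pred@probs[[ch]][p, lab[i, j]])
    }
  }
  total / (2 * C)
}

## Gradient of geometricLoss with respect to the predicted probabilities:
## -(1/(2C)) / p at each (pair, target-bin), zero elsewhere.
geometricLossGradProbs <- function(pred, target, mask) {
  C <- nContacts(mask)
  pairs <- contactPairs(mask)
  grad <- lapply(pred@probs, function(m) matrix(0, nrow(m), ncol(m)))
  for (k in seq_len(6L)) {
    ch <- GEOM_CHANNELS[k]
    lab <- target@labels[[ch]]; okT <- target@valid[[ch]]
    for (p in seq_len(C)) {
      i <- pairs[p, 1L]; j <- pairs[p, 2L]
      if (!okT[i, j] || !pred@valid[p, k]) next
      pv <- max(pred@probs[[ch]][p, lab[i, j]], .PROB_FLOOR)
      grad[[ch]][p, lab[i, j]] <- -1 / (2 * C * pv)
    }
  }
  grad
}

#' Sequence loss: negative log-likelihood of the wildtype letters
#'
#' `L_S = -sum over design positions i of log p[i, wildtype_i]`, the
#' categorical cross entropy of the design distribution against the
#' wildtype sequence. Probabilities are floored at 1e-12 (with a warning)
#' to avoid infinities.
#'
#' @param designProbs Numeric |D| x 20 matrix of normalized design-position
#'   distributions.
#' @param wildtype An [FvSequence-class] (with `region`) or a character
#'   vector of the wildtype letters at the design positions.
#' @param region A [DesignRegion-class]; required when `wildtype` is an
#'   `FvSequence`.
#' @return Nonnegative scalar.
#' @export
sequenceLoss <- function(designProbs, wildtype, region = NULL) {
  wt <- if (is(wildtype, "FvSequence")) wildtypeLetters(wildtype, region)
        else wildtype
  idx <- cbind(seq_along(wt), aaToIndex(wt))
  -sum(flooredLog(designProbs[idx], warnOnFloor = TRUE))
}

#' Motif loss: KL divergence from the motif distribution
#'
#' `L_M = sum over motif positions i of KL(q0_i || p_i)` with the
#' convention `0 * log(0/x) = 0` and `p` floored at 1e-12.
#'
#' @inheritParams sequenceLoss
#' @param motif A [motifSpec()].
#' @return Nonnegative scalar.
#' @export
motifLoss <- function(designProbs, motif) {
  if (max(motif$designIndex) > nrow(designProbs))
    stop("motif position outside the design region")
  total <- 0
  for (r in seq_along(motif$designIndex)) {
    q0 <- motif$probs[r, ]
    p <- pmax(designProbs[motif$designIndex[r], ], .PROB_FLOOR)
    nz <- q0 > 0
    total <- total + sum(q0[nz] * (log(q0[nz]) - log(p[nz])))
  }
  total
}

#' Weighted total loss
#'
#' `L = w_G * L_G + w_S * L_S + w_M * L_M`; the components are retained for
#' trajectory logging.
#'
#' @param geometric,sequence,motif Scalar loss components (absent terms
#'   are 0).
#' @param weights A [lossWeights()] vector.
#' @return Named numeric vector `(total, geometric, sequence, motif)`.
#' @export
totalLoss <- function(geometric, sequence = 0, motif = 0,
                      weights = lossWeights()) {
  if (any(weights < 0)) stop("loss weights must be nonnegative")
  c(total = unname(weights[["geometric"]] * geometric +
                   weights[["sequence"]] * sequence +
                   weights[["motif"]] * motif),
    geometric = unname(geometric), sequence = unname(sequence),
    motif = unname(motif))
}
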
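## engine: the hallucination loop — initialize, decode, forward, loss,
## straight-through gradient, normalized SGD update, iterate; plus batch
## library generation.

.SENTINEL <- -1e9  # design-matrix value pinning disallowed letters at ~0

#' Configuration of a hallucination run
#'
#' @param learningRate Positive SGD step size applied to the normalized
#'   gradient (default 0.05; each step displaces the design matrix by
#'   exactly this L2 amount while the gradient is nonzero).
#' @param maxIterations Iteration cap (default 60; convergence is typically
#'   reached within 40-60 iterations).
#' @param lossTolerance Absolute total-loss change over
#'   `toleranceWindow` iterations below which the run stops (default 1e-3).
#' @param toleranceWindow Window length for the stopping rule (default 5).
#' @param seed Integer RNG seed of the run.
#' @param seeding `"none"` or `"wildtype"` (adds 0.5 to the wildtype
#'   letter's entry at each design position at initialization).
#' @param disallow Letters excluded at all design positions (default `"C"`).
#' @param weights A [lossWeights()] vector.
#' @param alphabetMask Optional logical |D| x 20 mask overriding
#'   `disallow` (see [alphabetMask()]).
#' @return List of class `"HallucinationConfig"`.
#' @export
hallucinationConfig <- function(learningRate = 0.05, maxIterations = 60L,
                                lossTolerance = 1e-3, toleranceWindow = 5L,
                                seed = 1L, seeding = c("none", "wildtype"),
                                disallow = "C",
                                weights = lossWeights(),
                                alphabetMask = NULL) {
  seeding <- match.arg(seeding)
  if (learningRate <= 0) stop("learningRate must be positive")
  if (maxIterations < 1L) stop("maxIterations must be >= 1")
  structure(list(learningRate = learningRate,
                 maxIterations = as.integer(maxIterations),
                 lossTolerance = lossTolerance,
                 toleranceWindow = as.integer(toleranceWindow),
                 seed = as.integer(seed), seeding = seeding,
                 disallow = disallow, weights = weights,
                 alphabetMask = alphabetMask),
            class = "HallucinationConfig")
}

#' Initialize the design matrix
#'
#' Each entry is drawn from U(0, 1); under wildtype seeding, 0.5 is added
#' to the wildtype letter's entry at each design position, so the decoded
#' initial sequence is biased toward (but not forced to) the wildtype.
#' Disallowed letters are pinned to a large negative sentinel so the
#' softmax assigns them zero probability. Draws come from the caller's
#' current RNG stream.
#'
#' @param wildtype An [FvSequence-class].
#' @param region A [DesignRegion-class].
#' @param seeding `"none"` or `"wildtype"`.
#' @param allowed Logical |D| x 20 mask from [alphabetMask()] (default:
#'   cysteine disallowed).
#' @return Numeric |D| x 20 design matrix.
#' @export
initializeDesign <- function(wildtype, region,
                             seeding = c("none", "wildtype"),
                             allowed = NULL) {
  seeding <- match.arg(seeding)
  nD <- length(designPositions(region))
  if (is.null(allowed)) allowed <- alphabetMask(nD)
  a <- matrix(stats::runif(nD * 20L), nD, 20L, dimnames = list(NULL, AA20))
  if (seeding == "wildtype") {
    wt <- aaToIndex(wildtypeLetters(wildtype, region))
    bad <- which(!allowed[cbind(seq_len(nD), wt)])
    if (length(bad))
      stop("wildtype letter disallowed at design position ", bad[1],
           " under wildtype seeding")
    a[cbind(seq_len(nD), wt)] <- a[cbind(seq_len(nD), wt)] + 0.5
  }
  a[!allowed] <- .SENTINEL
  a
}

#' Decode a design matrix to its amino-acid sequence
#'
#' Per design position, the argmax of the softmax row; exact ties break to
#' the alphabetically earlier letter. Sentinel-pinned (disallowed) letters
#' are never selected.
#'
#' @param a Numeric |D| x 20 design matrix.
#' @return Character vector of |D| one-letter codes.
#' @export
decodeDesign <- function(a) {
  p <- softmaxRows(a)
  AA20[apply(p, 1L, which.max)]
}

## Build the full-length L x 20 probability matrix fed to the oracle:
## fixed positions one-hot wildtype; design rows either the softmax of the
## design matrix ("soft") or the one-hot of its decoded argmax ("hard").
assembleSeqMatrix <- function(a, wildtype, region, decodeMode) {
  full <- oneHot(fvChars(wildtype))
  d <- designPositions(region)
  full[d, ] <- if (decodeMode == "soft") softmaxRows(a)
               else oneHot(decodeDesign(a))
  full
}

#' Total design loss and its gradient with respect to the design matrix
#'
#' Assembles the full sequence-probability matrix (fixed positions one-hot
#' wildtype), runs the oracle forward, and evaluates
#' `L = w_G L_G + w_S L_S + w_M L_M`. With `decodeMode = "hard"` the
#' oracle sees the decoded one-hot design rows and the gradient uses the
#' straight-through estimator (the one-hot is treated as the softmax row in
#' the backward pass); with `"soft"` the softmax rows themselves are fed
#' forward and the gradient is exact, which is the path checked against
#' finite differences. Sequence and motif losses always act on the softmax
#' rows (the design distribution).
#'
#' @param a Numeric |D| x 20 design matrix.
#' @param oracle,target,mask The geometry oracle, [TargetGeometry-class]
#'   and [ContactMask-class].
#' @param wildtype An [FvSequence-class].
#' @param region A [DesignRegion-class].
#' @param motif Optional [motifSpec()].
#' @param weights A [lossWeights()] vector.
#' @param decodeMode `"hard"` (design loop) or `"soft"` (differentiable).
#' @return List with `loss` (named vector from [totalLoss()]) and `grad`
#'   (|D| x 20 matrix).
#' @export
designLoss <- function(a, oracle, target, mask, wildtype, region,
                       motif = NULL, weights = lossWeights(),
                       decodeMode = c("hard", "soft")) {
  decodeMode <- match.arg(decodeMode)
  d <- designPositions(region)
  p <- softmaxRows(a)
  full <- assembleSeqMatrix(a, wildtype, region, decodeMode)
  pred <- oracleForward(oracle, full, mask)
  lG <- geometricLoss(pred, target, mask)
  wt <- wildtypeLetters(wildtype, region)
  lS <- if (weights[["sequence"]] > 0) sequenceLoss(p, wt) else 0
  lM <- if (!is.null(motif) && weights[["motif"]] > 0) motifLoss(p, motif)
        else 0
  loss <- totalLoss(lG, lS, lM, weights)

  ## gradient with respect to the design rows' probabilities
  gradProbs <- geometricLossGradProbs(pred, target, mask)
  gFull <- oracleBackward(oracle, full, mask, gradProbs)
  gP <- weights[["geometric"]] * gFull[d, , drop = FALSE]
  if (weights[["sequence"]] > 0) {
    idx <- cbind(seq_along(wt), aaToIndex(wt))
    gS <- matrix(0, length(d), 20L)
    pw <- p[idx]
    gS[idx] <- ifelse(pw >= .PROB_FLOOR, -1 / pw, 0)
    gP <- gP + weights[["sequence"]] * gS
  }
  if (!is.null(motif) && weights[["motif"]] > 0) {
    gM <- matrix(0, length(d), 20L)
    for (r in seq_along(motif$designIndex)) {
      i <- motif$designIndex[r]
      pv <- p[i, ]
      gM[i, ] <- ifelse(pv >= .PROB_FLOOR, -motif$probs[r, ] / pv, 0)
    }
    gP <- gP + weights[["motif"]] * gM
  }
  ## back through the row-wise softmax: g_a = p * (g - <g, p>)
  ga <- p * (gP - rowSums(gP * p))
  list(loss = loss, grad = ga)
}

#' One normalized-SGD design step
#'
#' Computes the straight-through gradient of the total loss, zeroes it at
#' disallowed letters, normalizes it to unit global L2 norm (unless it is
#' numerically zero) and takes a step of length `learningRate`.
#'
#' @inheritParams designLoss
#' @param allowed Logical |D| x 20 alphabet mask.
#' @param learningRate Step size.
#' @return List with the updated matrix `values` and the step's `loss`.
#' @export
designStep <- function(a, oracle, target, mask, wildtype, region,
                       motif = NULL, weights = lossWeights(),
                       allowed = NULL, learningRate = 0.05) {
  if (is.null(allowed)) allowed <- matrix(TRUE, nrow(a), 20L)
  res <- designLoss(a, oracle, target, mask, wildtype, region,
                    motif = motif, weights = weights, decodeMode = "hard")
  g <- res$grad
  g[!allowed] <- 0
  if (!all(is.finite(g))) stop("non-finite gradient in design step")
  nrm <- sqrt(sum(g * g))
  if (nrm >= 1e-12) g <- g / nrm
  list(values = a - learningRate * g, loss = res$loss)
}

#' Run one hallucination design trajectory
#'
#' The iterative loop: initialize the design matrix, then repeat decode ->
#' oracle forward -> loss -> straight-through gradient -> normalized SGD
#' update until the loss stops changing (by less than `lossTolerance` over
#' `toleranceWindow` iterations) or `maxIterations` is reached. The final
#' sequence is the wildtype Fv with the decoded subsequence substituted.
#'
#' @param config A [hallucinationConfig()].
#' @inheritParams designLoss
#' @return A [DesignRecord-class].
#' @examples
#' fx <- generateFixtures(fixtureSpec(seed = 7))
#' rec <- hallucinate(hallucinationConfig(seed = 1, maxIterations = 10),
#'                    fx$oracle, fx$target, fx$mask, fx$fv, fx$region)
#' rec
#' @export
hallucinate <- function(config, oracle, target, mask, wildtype, region,
                        motif = NULL) {
  stopifnot(inherits(config, "HallucinationConfig"))
  nD <- length(designPositions(region))
  allowed <- config$alphabetMask %||%
    alphabetMask(nD, disallow = config$disallow)
  withSeed(config$seed, {
    a <- initializeDesign(wildtype, region, config$seeding, allowed)
    traj <- matrix(NA_real_, config$maxIterations, 4L,
                   dimnames = list(NULL,
                     c("total", "geometric", "sequence", "motif")))
    converged <- FALSE
    it <- 0L
    while (it < config$maxIterations) {
      it <- it + 1L
      stepped <- designStep(a, oracle, target, mask, wildtype, region,
                            motif = motif, weights = config$weights,
                            allowed = allowed,
                            learningRate = config$learningRate)
      a <- stepped$values
      traj[it, ] <- stepped$loss[c("total", "geometric", "sequence",
                                   "motif")]
      w <- config$toleranceWindow
      if (it >= w) {
        recent <- traj[(it - w + 1L):it, "total"]
        if (max(recent) - min(recent) < config$lossTolerance) {
          converged <- TRUE
          break
        }
      }
    }
    designed <- decodeDesign(a)
    trajectory <- data.frame(iteration = seq_len(it),
                             traj[seq_len(it), , drop = FALSE])
    new("DesignRecord",
        sequence = substituteDesign(wildtype, region, designed),
        designed = paste(designed, collapse = ""),
        trajectory = trajectory, iterations = it,
        seed = config$seed, converged = converged)
  })
}

setMethod("show", "DesignRecord", function(object) {
  last <- object@trajectory[nrow(object@trajectory), ]
  cat(sprintf(
    "DesignRecord: '%s' (seed %d, %d iterations%s, final loss %.4f)\n",
    object@designed, object@seed, object@iterations,
    if (object@converged) ", converged" else "", last$total))
})

#' Generate a design library by repeated hallucination
#'
#' Runs `nDesigns` independent trajectories with seeds `seedBase + k - 1`,
#' `k = 1..nDesigns`; all other settings are shared.
#'
#' @param config A [hallucinationConfig()]; its `seed` is ignored in favor
#'   of `seedBase`.
#' @inheritParams hallucinate
#' @param nDesigns Number of designs (>= 1).
#' @param seedBase First seed of the series.
#' @param dedupe Drop records with duplicated designed subsequences.
#' @return List of [DesignRecord-class] objects.
#' @export
generateLibrary <- function(config, oracle, target, mask, wildtype, region,
                            motif = NULL, nDesigns, seedBase = config$seed,
                            dedupe = FALSE) {
  if (nDesigns < 1L) stop("nDesigns must be >= 1")
  records <- lapply(seq_len(nDesigns) - 1L, function(k) {
    cfg <- config
    cfg$seed <- as.integer(seedBase + k)
    hallucinate(cfg, oracle, target, mask, wildtype, region, motif = motif)
  })
  if (dedupe)
    records <- records[!duplicated(vapply(records, function(r) r@designed,
                                          character(1)))]
  records
}

#' Designed subsequences of a library
#' @param records List of [DesignRecord-class] objects.
#' @return Character vector of designed subsequences.
#' @export
designedSequences <- function(records)
  vapply(records, function(r) r@designed, character(1))

#' Write a loss trajectory to CSV
#' @param record A [DesignRecord-class].
#' @param path Output file.
#' @export
writeTrajectory <- function(record, path)
  utils::write.csv(record@trajectory, path, row.names = FALSE)
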
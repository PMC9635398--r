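## oracle: the differentiable sequence -> geometry predictor contract, the
## bundled toy oracle, ensembles, adapters, and the gradient self-check.

#' Create a toy sequence-to-geometry oracle
#'
#' Draws, once from the seed, a fixed standard-normal weight array
#' `W[a, a', channel, bin]`; the forward pass for pair (i, j) and channel X
#' is `softmax(logits / temperature)` with
#' `logits_b = sum_{a,a'} s[i,a] s[j,a'] W[a,a',X,b]`, bilinear in the two
#' residue probability rows. Deterministic, differentiable in closed form.
#'
#' @param seed Integer seed for the weight draw.
#' @param nBins Bins per channel: scalar or length-6 vector, or a
#'   [GeometryBinning-class] to match.
#' @param temperature Positive softmax temperature (default 1; lower values
#'   sharpen the landscape).
#' @return A [ToyOracle-class].
#' @examples
#' orc <- toyOracle(seed = 1, nBins = 8)
#' nBins(orc)
#' @export
toyOracle <- function(seed, nBins = 8L, temperature = 1.0) {
  if (is(nBins, "GeometryBinning")) nBins <- nBins(nBins)
  nBins <- as.integer(rep_len(nBins, 6L))
  weights <- withSeed(as.integer(seed), {
    lapply(seq_len(6L), function(k)
      array(stats::rnorm(20L * 20L * nBins[k]), dim = c(20L, 20L, nBins[k])))
  })
  names(weights) <- GEOM_CHANNELS
  new("ToyOracle", seed = as.integer(seed), weights = weights,
      temperature = as.numeric(temperature), nBins = nBins)
}

setMethod("show", "ToyOracle", function(object) {
  cat(sprintf("ToyOracle: seed %d, temperature %.3g, bins %s\n",
              object@seed, object@temperature,
              paste(object@nBins, collapse = "/")))
})

## Per-channel "half-contracted" weights for one partner row s_j:
## M[a, b] = sum_{a'} s_j[a'] W[a, a', b]. logits_b = s_i . M[, b].
.halfContract <- function(W, sj) {
  nb <- dim(W)[3L]
  m <- matrix(0, 20L, nb)
  for (b in seq_len(nb)) m[, b] <- W[, , b] %*% sj
  m
}

.checkSeqMatrix <- function(seqMatrix, mask) {
  if (ncol(seqMatrix) != 20L)
    stop("sequence matrix must have 20 columns")
  if (nrow(seqMatrix) != mask@nResidues)
    stop("sequence matrix has ", nrow(seqMatrix), " rows but mask expects ",
         mask@nResidues)
  s <- rowSums(seqMatrix)
  if (any(abs(s - 1) > 1e-6))
    stop("sequence matrix rows must sum to 1")
}

#' @rdname oracleForward
#' @export
setMethod("oracleForward", "ToyOracle", function(oracle, seqMatrix, mask) {
  .checkSeqMatrix(seqMatrix, mask)
  pairs <- contactPairs(mask)
  C <- nrow(pairs)
  probs <- lapply(seq_len(6L), function(k)
    matrix(0, C, oracle@nBins[k]))
  names(probs) <- GEOM_CHANNELS
  for (p in seq_len(C)) {
    si <- seqMatrix[pairs[p, 1L], ]
    sj <- seqMatrix[pairs[p, 2L], ]
    for (k in seq_len(6L)) {
      logits <- crossprod(.halfContract(oracle@weights[[k]], sj), si)
      probs[[k]][p, ] <- softmaxVec(as.vector(logits) / oracle@temperature)
    }
  }
  new("GeometryPrediction", probs = probs,
      valid = matrix(TRUE, C, 6L, dimnames = list(NULL, GEOM_CHANNELS)))
})

#' @rdname oracleForward
#' @export
setMethod("oracleBackward", "ToyOracle",
          function(oracle, seqMatrix, mask, gradProbs) {
  .checkSeqMatrix(seqMatrix, mask)
  pairs <- contactPairs(mask)
  grad <- matrix(0, nrow(seqMatrix), 20L)
  tau <- oracle@temperature
  for (p in seq_len(nrow(pairs))) {
    i <- pairs[p, 1L]; j <- pairs[p, 2L]
    si <- seqMatrix[i, ]; sj <- seqMatrix[j, ]
    for (k in seq_len(6L)) {
      gp <- gradProbs[[k]][p, ]
      if (!any(gp != 0)) next
      M <- .halfContract(oracle@weights[[k]], sj)
      logits <- as.vector(crossprod(M, si)) / tau
      prob <- softmaxVec(logits)
      ## softmax jacobian: dL/dlogit = p * (g - sum(g p)), then / tau
      gl <- prob * (gp - sum(gp * prob)) / tau
      ## dlogit_b/dsi = M[, b]; dlogit_b/dsj = N[, b] with
      ## N[a', b] = sum_a si[a] W[a, a', b]
      grad[i, ] <- grad[i, ] + as.vector(M %*% gl)
      W <- oracle@weights[[k]]
      Np <- matrix(0, 20L, length(gl))
      for (b in seq_along(gl)) if (gl[b] != 0)
        Np[, b] <- crossprod(W[, , b], si)
      grad[j, ] <- grad[j, ] + as.vector(Np %*% gl)
    }
  }
  grad
})

#' Target geometry with a built-in verifiable optimum
#'
#' Runs the toy oracle forward on the one-hot encoding of a reference
#' sequence and takes the per-pair, per-channel argmax bins as target
#' labels. The reference is then, by construction, a strong candidate
#' optimum of the geometric loss, which makes design-recovery experiments
#' checkable by exhaustive enumeration.
#'
#' @param oracle A [ToyOracle-class].
#' @param reference An [FvSequence-class] (or character vector of letters).
#' @param mask A [ContactMask-class].
#' @return A [TargetGeometry-class] whose labels are defined (valid) exactly
#'   on the mask's pairs.
#' @export
toyTarget <- function(oracle, reference, mask) {
  letters <- if (is(reference, "FvSequence")) fvChars(reference)
             else reference
  pred <- oracleForward(oracle, oneHot(letters), mask)
  L <- mask@nResidues
  pairs <- contactPairs(mask)
  labels <- valid <- list()
  for (k in seq_len(6L)) {
    lab <- matrix(NA_integer_, L, L)
    ok <- matrix(FALSE, L, L)
    if (nrow(pairs))
      for (p in seq_len(nrow(pairs))) {
        lab[pairs[p, 1L], pairs[p, 2L]] <- which.max(pred@probs[[k]][p, ])
        ok[pairs[p, 1L], pairs[p, 2L]] <- TRUE
      }
    labels[[k]] <- lab; valid[[k]] <- ok
  }
  names(labels) <- names(valid) <- GEOM_CHANNELS
  ## a nominal binning consistent with the oracle's bin counts
  nb <- oracle@nBins
  edges <- list(dCA = seq(0, 20, length.out = nb[1L]),
                dCB = seq(0, 20, length.out = nb[2L]),
                dNO = seq(0, 20, length.out = nb[3L]),
                theta = seq(-180, 180, length.out = nb[4L] + 1L),
                phi = seq(0, 180, length.out = nb[5L] + 1L),
                omega = seq(-180, 180, length.out = nb[6L] + 1L))
  new("TargetGeometry", labels = labels, valid = valid,
      binning = new("GeometryBinning", edges = edges))
}

#' Wrap forward/backward closures as an oracle
#'
#' Adapter entry point for external predictors: supply a forward function
#' `(seqMatrix, mask) -> GeometryPrediction` and (optionally) a backward
#' function `(seqMatrix, mask, gradProbs) -> gradient matrix`; the result
#' participates in ensembles and the design loop like the toy oracle.
#'
#' @param forward,backward Functions implementing the oracle contract.
#' @return An object usable with [oracleForward()] / [oracleBackward()].
#' @export
functionOracle <- function(forward, backward = NULL) {
  structure(list(forward = forward, backward = backward),
            class = "FunctionOracle")
}

setOldClass("FunctionOracle")

#' @rdname oracleForward
#' @export
setMethod("oracleForward", "FunctionOracle",
          function(oracle, seqMatrix, mask) oracle$forward(seqMatrix, mask))

#' @rdname oracleForward
#' @export
setMethod("oracleBackward", "FunctionOracle",
          function(oracle, seqMatrix, mask, gradProbs) {
            if (is.null(oracle$backward))
              stop("this oracle provides no backward pass")
            oracle$backward(seqMatrix, mask, gradProbs)
          })

## Named oracle registry: "toy" is built in; external adapters register
## under their own names.
.oracleRegistry <- new.env(parent = emptyenv())

#' Oracle registry
#'
#' `registerOracle` stores an oracle (or a zero-argument factory) under a
#' name; `getOracle` retrieves it. `"toy"` resolves to a default
#' [toyOracle()] and is always available.
#'
#' @param name Registry key.
#' @param oracle Oracle object or factory function.
#' @param ... Passed to a factory (e.g. `seed` for `"toy"`).
#' @export
registerOracle <- function(name, oracle) {
  assign(name, oracle, envir = .oracleRegistry)
  invisible(name)
}

#' @rdname registerOracle
#' @export
getOracle <- function(name, ...) {
  if (name == "toy" && !exists(name, envir = .oracleRegistry))
    return(toyOracle(...))
  if (!exists(name, envir = .oracleRegistry))
    stop("no oracle registered under '", name, "'")
  orc <- get(name, envir = .oracleRegistry)
  if (is.function(orc)) orc(...) else orc
}

#' Average the predictions of an oracle ensemble
#'
#' Per-pair bin probabilities are averaged across the models and
#' renormalized.
#'
#' @param oracles Non-empty list of oracles.
#' @inheritParams oracleForward
#' @return A [GeometryPrediction-class].
#' @export
ensembleForward <- function(oracles, seqMatrix, mask) {
  if (length(oracles) == 0L) stop("ensemble must contain at least one model")
  preds <- lapply(oracles, oracleForward, seqMatrix = seqMatrix, mask = mask)
  out <- preds[[1L]]
  if (length(preds) > 1L) {
    for (k in seq_len(6L)) {
      acc <- Reduce(`+`, lapply(preds, function(p) p@probs[[k]]))
      acc <- acc / length(preds)
      rs <- rowSums(acc)
      out@probs[[k]] <- acc / ifelse(rs > 0, rs, 1)
    }
    out@valid <- Reduce(`&`, lapply(preds, function(p) p@valid))
  }
  out
}

#' Finite-difference check of an oracle/loss gradient
#'
#' Verifies the analytic gradient of the soft (fully differentiable) total
#' design loss against central finite differences at randomly probed
#' design-matrix entries. Used both as a self-check for the bundled toy
#' oracle and as an acceptance gate for external adapters.
#'
#' @param oracle Oracle under test.
#' @param target,mask,wildtype,region,motif,weights As in [designLoss()].
#' @param a Design matrix at which to probe (default: random).
#' @param nProbes Number of entries probed.
#' @param h Finite-difference step.
#' @param seed RNG seed for probe selection.
#' @return `data.frame` with analytic and numeric derivative per probe and
#'   the relative error.
#' @export
checkOracleGradient <- function(oracle, target, mask, wildtype, region,
                                motif = NULL,
                                weights = lossWeights(),
                                a = NULL, nProbes = 100L, h = 1e-5,
                                seed = 1L) {
  nD <- length(designPositions(region))
  withSeed(seed, {
    if (is.null(a)) a <- matrix(stats::runif(nD * 20L), nD, 20L)
    res <- designLoss(a, oracle, target, mask, wildtype, region,
                      motif = motif, weights = weights, decodeMode = "soft")
    probes <- cbind(sample(nD, nProbes, replace = TRUE),
                    sample(20L, nProbes, replace = TRUE))
    num <- vapply(seq_len(nProbes), function(k) {
      ap <- am <- a
      ap[probes[k, 1L], probes[k, 2L]] <- a[probes[k, 1L], probes[k, 2L]] + h
      am[probes[k, 1L], probes[k, 2L]] <- a[probes[k, 1L], probes[k, 2L]] - h
      lp <- designLoss(ap, oracle, target, mask, wildtype, region,
                       motif = motif, weights = weights,
                       decodeMode = "soft")$loss[["total"]]
      lm <- designLoss(am, oracle, target, mask, wildtype, region,
                       motif = motif, weights = weights,
                       decodeMode = "soft")$loss[["total"]]
      (lp - lm) / (2 * h)
    }, numeric(1))
    ana <- res$grad[probes]
    data.frame(row = probes[, 1L], col = probes[, 2L],
               analytic = ana, numeric = num,
               relError = abs(ana - num) / pmax(abs(num), 1e-8))
  })
}
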
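## Generics. Methods live with their module files.

#' Number of bins per geometry channel
#' @param x A [GeometryBinning-class], [ToyOracle-class] or
#'   [TargetGeometry-class] object.
#' @return Named integer vector over the six channels.
#' @export
setGeneric("nBins", function(x) standardGeneric("nBins"))

#' Contact count of a mask
#' @param x A [ContactMask-class].
#' @return Integer C, the number of ordered contact pairs.
#' @export
setGeneric("nContacts", function(x) standardGeneric("nContacts"))

#' Contact pairs of a mask
#' @param x A [ContactMask-class].
#' @return Integer C x 2 matrix of ordered (i, j) linear indices.
#' @export
setGeneric("contactPairs", function(x) standardGeneric("contactPairs"))

#' Design and fixed positions of a design region
#' @param x A [DesignRegion-class].
#' @return Integer vector of linear indices.
#' @export
setGeneric("designPositions", function(x) standardGeneric("designPositions"))

#' @rdname designPositions
#' @export
setGeneric("fixedPositions", function(x) standardGeneric("fixedPositions"))

#' Chain sequences and length of an Fv
#' @param x An [FvSequence-class].
#' @return `heavyChain`/`lightChain` return a single string; `fvChars` the
#'   per-residue letters of the concatenated Fv; `fvNumbering` the numbering
#'   table.
#' @export
setGeneric("heavyChain", function(x) standardGeneric("heavyChain"))

#' @rdname heavyChain
#' @export
setGeneric("lightChain", function(x) standardGeneric("lightChain"))

#' @rdname heavyChain
#' @export
setGeneric("fvChars", function(x) standardGeneric("fvChars"))

#' @rdname heavyChain
#' @export
setGeneric("fvNumbering", function(x) standardGeneric("fvNumbering"))

#' Probability matrix of a sequence profile
#' @param x A [SequenceProfile-class].
#' @return Numeric positions x 20 matrix in [AA20] column order.
#' @export
setGeneric("profileProbs", function(x) standardGeneric("profileProbs"))

#' Oracle forward pass: sequence probabilities to geometry bin probabilities
#'
#' The oracle contract: `oracleForward` maps a full-length positions x 20
#' probability matrix (soft or one-hot rows) and a [ContactMask-class] to a
#' [GeometryPrediction-class]. `oracleBackward` propagates the gradient of a
#' scalar loss with respect to the predicted probabilities back to the input
#' matrix; together they make any conforming oracle usable in the design
#' loop and checkable by finite differences ([checkOracleGradient()]).
#'
#' @param oracle An oracle object (e.g. [ToyOracle-class]).
#' @param seqMatrix Numeric L x 20 matrix; rows sum to 1.
#' @param mask A [ContactMask-class].
#' @param gradProbs Named list of six C x bins matrices: d(loss)/d(probs).
#' @return `oracleForward`: a [GeometryPrediction-class]. `oracleBackward`:
#'   an L x 20 matrix of d(loss)/d(seqMatrix).
#' @export
setGeneric("oracleForward",
           function(oracle, seqMatrix, mask) standardGeneric("oracleForward"))

#' @rdname oracleForward
#' @export
setGeneric("oracleBackward",
           function(oracle, seqMatrix, mask, gradProbs)
             standardGeneric("oracleBackward"))
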
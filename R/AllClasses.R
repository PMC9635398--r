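## S4 class definitions for the central data objects. Constructors and
## accessors live with their modules; validity checks live here.

#' @import methods
NULL

## Geometry channel names, in fixed order. Distances in Angstrom,
## dihedrals in degrees on (-180, 180], the planar angle in [0, 180].
GEOM_CHANNELS <- c("dCA", "dCB", "dNO", "theta", "phi", "omega")
DIST_CHANNELS <- c("dCA", "dCB", "dNO")
## Channels that need a CB atom on residue i and/or j.
CB_CHANNELS <- c("dCB", "theta", "phi", "omega")
## Channels stored as symmetric matrices (theta/phi are ordered-pair).
SYM_CHANNELS <- c("dCA", "dCB", "dNO", "omega")

#' FvSequence: a paired heavy/light antibody variable fragment
#'
#' Holds the heavy- and light-chain amino-acid sequences of an Fv together
#' with a residue numbering table (chain, Chothia-style label with optional
#' insertion code, 1-based linear index over the concatenated H+L sequence,
#' heavy chain first).
#'
#' @slot heavy Heavy-chain sequence (single string).
#' @slot light Light-chain sequence (single string).
#' @slot numbering `data.frame` with columns `chain` ("H"/"L"), `label`
#'   (e.g. "95", "100A") and `linear` (1-based index).
#' @seealso [concatenateFv()]
#' @export
setClass("FvSequence", representation(
  heavy = "character", light = "character", numbering = "data.frame"))

setValidity("FvSequence", function(object) {
  n <- nchar(object@heavy) + nchar(object@light)
  num <- object@numbering
  if (!all(c("chain", "label", "linear") %in% names(num)))
    return("numbering must have columns chain, label, linear")
  if (nrow(num) != n)
    return(sprintf("numbering has %d rows but Fv has %d residues",
                   nrow(num), n))
  if (!all(num$chain %in% c("H", "L")))
    return("chain must be 'H' or 'L'")
  if (!identical(num$linear, seq_len(n)))
    return("linear indices must be 1..n in order")
  for (ch in c("H", "L")) {
    lab <- num$label[num$chain == ch]
    if (anyDuplicated(lab))
      return(sprintf("duplicate label within chain %s", ch))
  }
  TRUE
})

#' DesignRegion: the designable / fixed split of an Fv
#'
#' The ordered set D of linear indices to be designed and its complement F
#' (fixed positions), partitioning the Fv.
#'
#' @slot design Ordered integer vector of design-position linear indices.
#' @slot fixed Integer vector of fixed-position linear indices.
#' @slot nTotal Total residue count of the Fv.
#' @seealso [makeDesignRegion()]
#' @export
setClass("DesignRegion", representation(
  design = "integer", fixed = "integer", nTotal = "integer"))

setValidity("DesignRegion", function(object) {
  d <- object@design; f <- object@fixed; n <- object@nTotal
  if (length(d) == 0L) return("design region must be non-empty")
  if (length(intersect(d, f))) return("design and fixed sets overlap")
  if (!setequal(c(d, f), seq_len(n)))
    return("design and fixed sets must partition 1..nTotal")
  TRUE
})

#' StructureCoordinates: backbone coordinates of a target structure
#'
#' Per-residue coordinates (Angstrom) for atoms N, CA, C, O and CB, in the
#' order of the Fv linear indices. CB rows are NA for glycine.
#'
#' @slot n,ca,c,o,cb Numeric L x 3 coordinate matrices (lowercase slot
#'   names; use [structureCoordinates()] to construct).
#' @export
setClass("StructureCoordinates", representation(
  n = "matrix", ca = "matrix", c = "matrix", o = "matrix", cb = "matrix"))

setValidity("StructureCoordinates", function(object) {
  mats <- list(N = object@n, CA = object@ca, C = object@c,
               O = object@o, CB = object@cb)
  L <- nrow(object@ca)
  for (nm in names(mats)) {
    m <- mats[[nm]]
    if (ncol(m) != 3L) return(sprintf("%s must have 3 columns", nm))
    if (nrow(m) != L) return("all atom matrices must have equal rows")
    if (nm != "CB" && !all(is.finite(m)))
      return(sprintf("non-finite coordinates in %s", nm))
  }
  ## CB rows are either fully finite or fully NA (glycine)
  cbOk <- apply(object@cb, 1L, function(r) all(is.finite(r)) || all(is.na(r)))
  if (!all(cbOk)) return("CB rows must be fully finite or fully NA")
  TRUE
})

#' GeometryBinning: bin edges for the six geometry channels
#'
#' Monotone bin edges per channel. Distance channels get a catch-all final
#' bin for values beyond the last edge; angle channels cover their full
#' domain and have no overflow bin.
#'
#' @slot edges Named list (one numeric vector per channel in
#'   `GEOM_CHANNELS` order) of strictly increasing edges.
#' @seealso [geometryBinning()]
#' @export
setClass("GeometryBinning", representation(edges = "list"))

setValidity("GeometryBinning", function(object) {
  if (!identical(names(object@edges), GEOM_CHANNELS))
    return("edges must be named by the six geometry channels, in order")
  for (ch in GEOM_CHANNELS) {
    e <- object@edges[[ch]]
    if (length(e) < 3L) return(sprintf("channel %s needs >= 2 bins", ch))
    if (any(diff(e) <= 0)) return(sprintf("edges not increasing in %s", ch))
  }
  TRUE
})

#' TargetGeometry: binned geometry labels of the target structure
#'
#' Integer bin labels per channel for every residue pair, with a validity
#' mask (FALSE on the diagonal and wherever a required CB is missing).
#'
#' @slot labels Named list of six L x L integer matrices.
#' @slot valid Named list of six L x L logical matrices.
#' @slot binning The [GeometryBinning-class] that produced the labels.
#' @export
setClass("TargetGeometry", representation(
  labels = "list", valid = "list", binning = "GeometryBinning"))

setValidity("TargetGeometry", function(object) {
  if (!identical(names(object@labels), GEOM_CHANNELS) ||
      !identical(names(object@valid), GEOM_CHANNELS))
    return("labels and valid must be named by the six channels")
  nb <- nBins(object@binning)
  for (ch in GEOM_CHANNELS) {
    lab <- object@labels[[ch]]; ok <- object@valid[[ch]]
    if (!identical(dim(lab), dim(ok))) return("label/valid shape mismatch")
    v <- lab[ok]
    if (length(v) && (any(v < 1L) || any(v > nb[[ch]])))
      return(sprintf("labels out of bin range in %s", ch))
    if (any(diag(ok))) return("diagonal must be masked invalid")
  }
  TRUE
})

#' ContactMask: ordered residue pairs under the CA-CA contact cutoff
#'
#' Ordered pairs (i, j) with i a design position, j any other residue, and
#' CA-CA distance at or below the cutoff (default 10 Angstrom). The pair
#' count C normalizes the geometric loss; pairs with both ends in the
#' design set appear in both orders and are counted twice.
#'
#' @slot pairs Integer C x 2 matrix of (i, j) linear indices.
#' @slot cutoff Contact cutoff in Angstrom.
#' @slot nResidues Fv length the indices refer to.
#' @seealso [buildContactMask()]
#' @export
setClass("ContactMask", representation(
  pairs = "matrix", cutoff = "numeric", nResidues = "integer"))

setValidity("ContactMask", function(object) {
  p <- object@pairs
  if (ncol(p) != 2L) return("pairs must have two columns")
  if (nrow(p) && any(p[, 1L] == p[, 2L])) return("self-pairs not allowed")
  if (nrow(p) && (any(p < 1L) || any(p > object@nResidues)))
    return("pair indices out of range")
  if (object@cutoff <= 0) return("cutoff must be positive")
  TRUE
})

#' GeometryPrediction: per-pair bin probabilities from an oracle
#'
#' For every contact pair and channel, a probability distribution over that
#' channel's bins. Rows for invalid pair-channels (missing CB) are flagged
#' in `valid` and excluded from losses.
#'
#' @slot probs Named list of six (C x bins) probability matrices.
#' @slot valid Logical C x 6 matrix (columns in channel order).
#' @export
setClass("GeometryPrediction", representation(
  probs = "list", valid = "matrix"))

setValidity("GeometryPrediction", function(object) {
  if (!identical(names(object@probs), GEOM_CHANNELS))
    return("probs must be named by the six channels")
  nPair <- nrow(object@probs[[1L]])
  for (ch in GEOM_CHANNELS) {
    m <- object@probs[[ch]]
    if (nrow(m) != nPair) return("channel row counts differ")
    if (nPair == 0L) next
    ok <- object@valid[, match(ch, GEOM_CHANNELS)]
    if (any(m[ok, ] < 0)) return(sprintf("negative probability in %s", ch))
    s <- rowSums(m[ok, , drop = FALSE])
    if (length(s) && any(abs(s - 1) > 1e-6))
      return(sprintf("rows of %s must sum to 1", ch))
  }
  if (!identical(dim(object@valid), c(nPair, 6L)))
    return("valid must be C x 6")
  TRUE
})

#' ToyOracle: a deterministic differentiable toy sequence-to-geometry map
#'
#' A bilinear-softmax stand-in for a pretrained structure predictor: fixed
#' random weights drawn once from a seed define, for each residue pair and
#' channel, bin logits bilinear in the two residues' amino-acid probability
#' vectors. It is deterministic, differentiable in closed form, and has a
#' verifiable optimum, which makes the full design loop testable offline.
#'
#' @slot seed Integer seed the weights were drawn from.
#' @slot weights Named list of six 20 x 20 x bins arrays.
#' @slot temperature Positive softmax temperature (default 1).
#' @slot nBins Integer vector of bins per channel.
#' @seealso [toyOracle()], [oracleForward()], [toyTarget()]
#' @export
setClass("ToyOracle", representation(
  seed = "integer", weights = "list", temperature = "numeric",
  nBins = "integer"))

setValidity("ToyOracle", function(object) {
  if (object@temperature <= 0) return("temperature must be positive")
  if (!identical(names(object@weights), GEOM_CHANNELS))
    return("weights must be named by the six channels")
  for (k in seq_along(GEOM_CHANNELS)) {
    d <- dim(object@weights[[k]])
    if (!identical(d, c(20L, 20L, object@nBins[k])))
      return("weight array dims must be 20 x 20 x nBins")
  }
  TRUE
})

#' SequenceProfile: a positions x 20 probability matrix (PSSM)
#'
#' Per-position amino-acid frequencies of a sequence set, columns in
#' [AA20] order, rows labelled by chain + Chothia-style position label.
#'
#' @slot positions `data.frame` with columns `chain` and `label` (may be
#'   placeholder labels for anonymous alignments).
#' @slot probs Numeric positions x 20 matrix; rows sum to 1.
#' @seealso [buildPssm()]
#' @export
setClass("SequenceProfile", representation(
  positions = "data.frame", probs = "matrix"))

setValidity("SequenceProfile", function(object) {
  p <- object@probs
  if (ncol(p) != 20L) return("probs must have 20 columns")
  if (nrow(p) != nrow(object@positions))
    return("positions/probs row mismatch")
  if (any(p < 0)) return("negative probabilities")
  if (nrow(p) && any(abs(rowSums(p) - 1) > 1e-9))
    return("profile rows must sum to 1 within 1e-9")
  TRUE
})

#' DesignRecord: the outcome of one hallucination run
#'
#' @slot sequence The full [FvSequence-class] with the designed subsequence
#'   substituted at the design positions.
#' @slot designed The designed subsequence (one letter per design position).
#' @slot trajectory `data.frame` of per-iteration losses (iteration, total,
#'   geometric, sequence, motif).
#' @slot iterations Number of iterations actually run.
#' @slot seed RNG seed of the run.
#' @slot converged TRUE if the loss-change tolerance was met before the
#'   iteration cap.
#' @export
setClass("DesignRecord", representation(
  sequence = "FvSequence", designed = "character", trajectory = "data.frame",
  iterations = "integer", seed = "integer", converged = "logical"))
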
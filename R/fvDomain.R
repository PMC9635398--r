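## fv domain: FvSequence / DesignRegion constructors, accessors, alphabet
## masks.

#' Assemble an Fv from heavy and light chain sequences
#'
#' Concatenates the two chains (heavy first) and attaches the residue
#' numbering. Linear indices are assigned 1..L over the concatenated
#' sequence.
#'
#' @param heavy,light Chain sequences (single strings, canonical 20-letter
#'   alphabet).
#' @param numbering `data.frame` with columns `chain` ("H"/"L") and `label`
#'   (Chothia-style number plus optional insertion code), one row per
#'   residue in concatenated order. If omitted, sequential labels are
#'   generated per chain.
#' @return An [FvSequence-class].
#' @examples
#' fv <- concatenateFv("EVQ", "DIQ")
#' fvChars(fv)
#' @export
concatenateFv <- function(heavy, light, numbering = NULL) {
  if (!nzchar(heavy) || !nzchar(light))
    stop("heavy and light sequences must be non-empty")
  aaChars(heavy, "heavy chain")
  aaChars(light, "light chain")
  nH <- nchar(heavy); nL <- nchar(light)
  if (is.null(numbering)) {
    numbering <- data.frame(
      chain = rep(c("H", "L"), c(nH, nL)),
      label = c(as.character(seq_len(nH)), as.character(seq_len(nL))),
      stringsAsFactors = FALSE)
  }
  if (nrow(numbering) != nH + nL)
    stop("numbering has ", nrow(numbering), " rows for ", nH + nL,
         " residues")
  numbering$linear <- seq_len(nH + nL)
  new("FvSequence", heavy = heavy, light = light,
      numbering = numbering[, c("chain", "label", "linear")])
}

#' @rdname heavyChain
#' @export
setMethod("heavyChain", "FvSequence", function(x) x@heavy)

#' @rdname heavyChain
#' @export
setMethod("lightChain", "FvSequence", function(x) x@light)

#' @rdname heavyChain
#' @export
setMethod("fvChars", "FvSequence",
          function(x) c(aaChars(x@heavy), aaChars(x@light)))

#' @rdname heavyChain
#' @export
setMethod("fvNumbering", "FvSequence", function(x) x@numbering)

#' @describeIn FvSequence Total residue count (heavy + light).
#' @param x An [FvSequence-class].
#' @export
setMethod("length", "FvSequence",
          function(x) nchar(x@heavy) + nchar(x@light))

setMethod("show", "FvSequence", function(object) {
  cat(sprintf("FvSequence: H %d aa, L %d aa\n",
              nchar(object@heavy), nchar(object@light)))
  cat("  H:", object@heavy, "\n  L:", object@light, "\n")
})

## Resolve chain+label pairs ("H95", "H100A", "L27") to linear indices.
resolveLabels <- function(fv, labels) {
  num <- fvNumbering(fv)
  key <- paste0(num$chain, num$label)
  idx <- match(labels, key)
  if (anyNA(idx))
    stop("label(s) not found in Fv numbering: ",
         paste(labels[is.na(idx)], collapse = ", "))
  num$linear[idx]
}

#' Define the design region of an Fv
#'
#' Resolves chain + Chothia-style labels (e.g. `"H95"`, `"H100A"`) to
#' linear indices; the design set D keeps the given order and the fixed
#' set F is its complement.
#'
#' @param fv An [FvSequence-class].
#' @param labels Character vector of chain+label identifiers, or
#'   alternatively an integer vector of linear indices.
#' @return A [DesignRegion-class].
#' @examples
#' fv <- concatenateFv("EVQLVE", "DIQMTQ")
#' region <- makeDesignRegion(fv, c("H3", "H4"))
#' designPositions(region)
#' @export
makeDesignRegion <- function(fv, labels) {
  if (length(labels) == 0L) stop("design region must be non-empty")
  d <- if (is.numeric(labels)) as.integer(labels) else resolveLabels(fv, labels)
  if (anyDuplicated(d)) stop("duplicate design positions")
  n <- length(fv)
  if (any(d < 1L | d > n)) stop("design position out of range")
  new("DesignRegion", design = d,
      fixed = setdiff(seq_len(n), d), nTotal = as.integer(n))
}

#' @rdname designPositions
#' @export
setMethod("designPositions", "DesignRegion", function(x) x@design)

#' @rdname designPositions
#' @export
setMethod("fixedPositions", "DesignRegion", function(x) x@fixed)

setMethod("show", "DesignRegion", function(object) {
  cat(sprintf("DesignRegion: %d design / %d fixed of %d positions\n",
              length(object@design), length(object@fixed), object@nTotal))
})

#' Per-position allowed-alphabet mask for the design region
#'
#' A logical |D| x 20 matrix saying which amino acids may be sampled at
#' each design position. The default disallows cysteine everywhere, the
#' convention used for every antibody design run.
#'
#' @param nPositions Number of design positions.
#' @param disallow Letters excluded at all positions (default `"C"`).
#' @param allowed Optional character vector: restrict all positions to this
#'   set (applied before `disallow`).
#' @return Logical `nPositions` x 20 matrix with [AA20] column names.
#' @examples
#' m <- alphabetMask(3)            # everything but cysteine
#' colnames(m)[!m[1, ]]
#' @export
alphabetMask <- function(nPositions, disallow = "C", allowed = NULL) {
  m <- matrix(TRUE, nPositions, 20L, dimnames = list(NULL, AA20))
  if (!is.null(allowed)) m[, !AA20 %in% allowed] <- FALSE
  if (length(disallow)) m[, AA20 %in% disallow] <- FALSE
  if (any(rowSums(m) == 0L))
    stop("alphabet mask leaves a position with no allowed letters")
  m
}

## Substitute a designed subsequence into an Fv at the design positions.
substituteDesign <- function(fv, region, designedLetters) {
  ch <- fvChars(fv)
  ch[designPositions(region)] <- designedLetters
  nH <- nchar(heavyChain(fv))
  concatenateFv(paste(ch[seq_len(nH)], collapse = ""),
                paste(ch[-seq_len(nH)], collapse = ""),
                fvNumbering(fv)[, c("chain", "label")])
}

## Extract the wildtype letters at the design positions.
wildtypeLetters <- function(fv, region) fvChars(fv)[designPositions(region)]
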
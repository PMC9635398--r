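## library_eval: AAR, PSSMs, Bhattacharyya overlap, perplexity,
## Levenshtein profiles, FR scores.

#' Amino-acid recovery of a design library
#'
#' Mean over designs of the percentage of design positions whose letter
#' matches the wildtype.
#'
#' @param designs Character vector of designed subsequences (all of design
#'   region length).
#' @param wildtype An [FvSequence-class] or a character string / vector of
#'   the wildtype letters at the design positions.
#' @param region A [DesignRegion-class] (needed when `wildtype` is an
#'   `FvSequence`).
#' @return Percentage between 0 and 100.
#' @examples
#' aar(c("ARD", "ARA"), "ARD")   # 100 and 2/3 of 100
#' @export
aar <- function(designs, wildtype, region = NULL) {
  if (length(designs) == 0L) stop("design list must be non-empty")
  wt <- if (is(wildtype, "FvSequence")) wildtypeLetters(wildtype, region)
        else if (length(wildtype) == 1L && nchar(wildtype) > 1L)
          aaChars(wildtype) else wildtype
  nD <- length(wt)
  perDesign <- vapply(designs, function(s) {
    ch <- aaChars(s, "design")
    if (length(ch) != nD)
      stop("design length ", length(ch), " does not match region size ", nD)
    100 * sum(ch == wt) / nD
  }, numeric(1), USE.NAMES = FALSE)
  mean(perDesign)
}

#' Build an empirical PSSM from aligned sequences
#'
#' Per-position amino-acid frequencies, no pseudo-counts, columns in
#' [AA20] order.
#'
#' @param seqs Character vector of equal-length sequences.
#' @param positions Optional `data.frame` with columns `chain`, `label`
#'   naming the positions; placeholder labels are generated if omitted.
#' @return A [SequenceProfile-class].
#' @export
buildPssm <- function(seqs, positions = NULL) {
  if (length(seqs) < 1L) stop("need at least one sequence")
  n <- nchar(seqs[1L])
  if (any(nchar(seqs) != n)) stop("sequences must have equal length")
  mat <- do.call(rbind, lapply(seqs, aaChars))
  probs <- t(apply(mat, 2L, function(col) {
    tabulate(aaToIndex(col), nbins = 20L) / length(col)
  }))
  ## single-position edge case: apply() drops to a vector
  if (n == 1L) probs <- matrix(probs, 1L, 20L)
  colnames(probs) <- AA20
  if (is.null(positions))
    positions <- data.frame(chain = rep("H", n),
                            label = as.character(seq_len(n)),
                            stringsAsFactors = FALSE)
  new("SequenceProfile", positions = positions, probs = probs)
}

#' @rdname profileProbs
#' @export
setMethod("profileProbs", "SequenceProfile", function(x) x@probs)

#' @describeIn SequenceProfile Number of positions.
#' @param x A [SequenceProfile-class].
#' @export
setMethod("length", "SequenceProfile", function(x) nrow(x@probs))

setMethod("show", "SequenceProfile", function(object) {
  cat(sprintf("SequenceProfile: %d positions x 20 amino acids\n",
              nrow(object@probs)))
})

#' Bhattacharyya overlap between two sequence profiles
#'
#' Per position i, `BC_i = sum over amino acids of sqrt(p_i * q_i)` and
#' `BD_i = -ln(BC_i)`; BC values of zero are floored at 1e-6 before the
#' logarithm to keep BD finite. Also returns the position means.
#'
#' @param p,q [SequenceProfile-class] objects (or positions x 20 matrices)
#'   over the same number of positions.
#' @return List with `bc`, `bd` (per-position vectors), `bcMean`, `bdMean`.
#' @examples
#' pr <- buildPssm(c("AR", "AR"))
#' bhattacharyya(pr, pr)$bcMean   # identical profiles: 1
#' @export
bhattacharyya <- function(p, q) {
  pm <- if (is(p, "SequenceProfile")) profileProbs(p) else p
  qm <- if (is(q, "SequenceProfile")) profileProbs(q) else q
  if (nrow(pm) != nrow(qm)) stop("profiles differ in position count")
  bc <- rowSums(sqrt(pm * qm))
  bd <- -log(pmax(bc, 1e-6))
  list(bc = bc, bd = bd, bcMean = mean(bc), bdMean = mean(bd))
}

#' Per-position perplexity of a sequence profile
#'
#' `PP_i = 2^(-sum p log2 p)` with the convention `0 log 0 = 0`; ranges
#' from 1 (one-hot) to 20 (uniform).
#'
#' @param profile A [SequenceProfile-class] or positions x 20 matrix.
#' @return Numeric vector of per-position perplexities.
#' @export
perplexity <- function(profile) {
  m <- if (is(profile, "SequenceProfile")) profileProbs(profile) else profile
  if (is.null(dim(m))) m <- matrix(m, 1L)
  apply(m, 1L, function(p) {
    nz <- p > 0
    2^(-sum(p[nz] * log2(p[nz])))
  })
}

#' Levenshtein distance profile of a design library
#'
#' For each design: the edit distance to the wildtype subsequence and the
#' minimum edit distance over a reference sequence set, plus their joint
#' count table.
#'
#' @param designs Character vector of designed subsequences.
#' @param wildtype Wildtype subsequence (single string).
#' @param referenceSet Non-empty character vector of reference sequences.
#' @return List with `perDesign` (`data.frame`: design, ldWildtype,
#'   ldMinReference) and `jointHistogram` (contingency table).
#' @export
levenshteinProfile <- function(designs, wildtype, referenceSet) {
  if (length(referenceSet) == 0L) stop("reference set must be non-empty")
  ldWt <- as.integer(utils::adist(designs, wildtype))
  ldRef <- apply(utils::adist(designs, referenceSet), 1L, min)
  perDesign <- data.frame(design = designs, ldWildtype = ldWt,
                          ldMinReference = as.integer(ldRef),
                          stringsAsFactors = FALSE)
  list(perDesign = perDesign,
       jointHistogram = table(ldWildtype = ldWt, ldMinReference = ldRef))
}

#' Net FR score of a design
#'
#' Sums, over the design positions, a per-position amino-acid enrichment
#' score table (FR scores measure enrichment over the germline residue in
#' human repertoires; higher totals indicate more human-like designs).
#'
#' @param design Designed subsequence (string or letter vector).
#' @param positionLabels Character vector of chain+label identifiers for
#'   the design positions, matching the table's rows.
#' @param table Numeric matrix (positions x 20, [AA20] columns) or
#'   `data.frame` with rownames = position labels.
#' @return Scalar net FR score.
#' @export
frScore <- function(design, positionLabels, table) {
  ch <- if (length(design) == 1L) aaChars(design) else design
  if (length(ch) != length(positionLabels))
    stop("design length and positionLabels length differ")
  tab <- as.matrix(table)
  total <- 0
  for (k in seq_along(ch)) {
    pos <- positionLabels[k]
    if (!pos %in% rownames(tab))
      stop("FR table has no row for position ", pos)
    if (!ch[k] %in% colnames(tab))
      stop("FR table has no column for amino acid ", ch[k])
    v <- tab[pos, ch[k]]
    if (is.na(v))
      stop("FR table entry missing for ", pos, "/", ch[k])
    total <- total + v
  }
  total
}
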
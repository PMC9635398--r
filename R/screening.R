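## screening: Kabsch superposition, framework-aligned design-region RMSD,
## fold and bind gates, the pipeline, and offline mock adapters.

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD of
#' `mobile` onto `reference` over paired points.
#'
#' @param mobile,reference Numeric n x 3 matrices (n >= 3, non-collinear).
#' @return List with `rotation` (3 x 3), `translation` (length 3; apply as
#'   `mobile %*% rotation + translation`), `rmsd`, and `transform(x)`, a
#'   function applying the fit to new coordinates.
#' @export
kabschSuperpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (nrow(mobile) < 3L || nrow(mobile) != nrow(reference))
    stop("need >= 3 paired points")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  X <- sweep(mobile, 2L, cm); Y <- sweep(reference, 2L, cr)
  if (min(svd(X)$d) < 1e-9 * max(svd(X)$d, 1))
    stop("points are (near-)collinear; superposition is degenerate")
  s <- svd(crossprod(X, Y))
  d <- sign(det(tcrossprod(s$v, s$u)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  tvec <- cr - as.vector(cm %*% R)
  aligned <- sweep(mobile %*% R, 2L, tvec, "+")
  list(rotation = R, translation = tvec,
       rmsd = sqrt(mean(rowSums((aligned - reference)^2))),
       transform = function(x) sweep(as.matrix(x) %*% R, 2L, tvec, "+"))
}

## Stack backbone N/CA/C atoms of selected residues into a 3k x 3 matrix.
backboneAtoms <- function(coords, residues) {
  do.call(rbind, lapply(residues, function(i)
    rbind(coords@n[i, ], coords@ca[i, ], coords@c[i, ])))
}

#' Design-region backbone RMSD after framework superposition
#'
#' Superposes the folded model onto the target using the backbone N/CA/C
#' atoms of all non-design (framework) residues, then reports the RMSD
#' over the N/CA/C atoms of the design residues in that frame (O is
#' excluded). Per-residue RMSDs come from the same frame.
#'
#' @param folded,target [StructureCoordinates-class] of equal length.
#' @param region A [DesignRegion-class].
#' @return List with `rmsd` (Angstrom) and `perResidue` (one value per
#'   design position).
#' @export
designRegionRmsd <- function(folded, target, region) {
  d <- designPositions(region)
  if (length(d) == 0L) stop("design region must be non-empty")
  if (length(folded) != length(target))
    stop("folded and target structures differ in residue count")
  f <- fixedPositions(region)
  fit <- kabschSuperpose(backboneAtoms(folded, f), backboneAtoms(target, f))
  movedD <- fit$transform(backboneAtoms(folded, d))
  refD <- backboneAtoms(target, d)
  sq <- rowSums((movedD - refD)^2)
  ## snap numerical noise to zero so identical folds report exactly 0
  clean <- function(x) ifelse(x < 1e-12, 0, x)
  perResidue <- vapply(seq_along(d), function(k)
    clean(sqrt(mean(sq[(3L * (k - 1L) + 1L):(3L * k)]))), numeric(1))
  list(rmsd = clean(sqrt(mean(sq))), perResidue = perResidue)
}

#' Screening thresholds
#'
#' @param rmsdMax Fold gate: maximum design-region backbone RMSD
#'   (Angstrom, default 2.0).
#' @param dgReference Bind gate reference, normally the wildtype binding
#'   free energy computed through the same adapter (REU).
#' @param dgMargin Slack added to the reference (default 0: designs must
#'   bind comparably to or better than the wildtype).
#' @return List of class `"ScreeningThresholds"`.
#' @export
screeningThresholds <- function(rmsdMax = 2.0, dgReference = 0,
                                dgMargin = 0) {
  structure(list(rmsdMax = rmsdMax, dgReference = dgReference,
                 dgMargin = dgMargin), class = "ScreeningThresholds")
}

#' Fold gate: keep designs whose predicted structure retains the target
#'
#' Folds each design through the adapter and passes it iff its
#' design-region backbone RMSD to the target is at most `rmsdMax`.
#' Adapter failures mark the design failed and the screen continues.
#'
#' @param designs Character vector of full Fv sequences (or a list of
#'   [DesignRecord-class]).
#' @param folder Adapter: `function(sequence) -> StructureCoordinates`.
#' @param target Target [StructureCoordinates-class].
#' @param region A [DesignRegion-class].
#' @param thresholds A [screeningThresholds()].
#' @return List with `pass` (integer ids) and `results` (`data.frame`: id,
#'   rmsd, pass, failed).
#' @export
screenFolding <- function(designs, folder, target, region,
                          thresholds = screeningThresholds()) {
  seqs <- if (is.list(designs) && length(designs) &&
              is(designs[[1L]], "DesignRecord"))
    vapply(designs, function(r) paste0(heavyChain(r@sequence),
                                       lightChain(r@sequence)),
           character(1))
  else designs
  rows <- lapply(seq_along(seqs), function(k) {
    res <- tryCatch({
      coords <- folder(seqs[k])
      r <- designRegionRmsd(coords, target, region)$rmsd
      data.frame(id = k, rmsd = r, pass = r <= thresholds$rmsdMax,
                 failed = FALSE)
    }, error = function(e) {
      message("fold adapter failed for design ", k, ": ",
              conditionMessage(e))
      data.frame(id = k, rmsd = NA_real_, pass = FALSE, failed = TRUE)
    })
    res
  })
  results <- do.call(rbind, rows)
  list(pass = results$id[results$pass], results = results)
}

#' Bind gate: keep designs with decoy-minimum binding energy near wildtype
#'
#' For each design the adapter returns `nDecoys` binding free energies
#' (one per stochastic refinement replicate); the design's dG is their
#' minimum, and it passes iff `dG <= dgReference + dgMargin`.
#'
#' @inheritParams screenFolding
#' @param binder Adapter: `function(sequence) -> numeric vector` of decoy
#'   dG values (REU).
#' @param nDecoys Decoys requested per design (default 5).
#' @return List with `pass` and `results` (`data.frame`: id, dG, nDecoys,
#'   pass, failed).
#' @export
screenBinding <- function(designs, binder, nDecoys = 5L,
                          thresholds = screeningThresholds()) {
  seqs <- if (is.list(designs) && length(designs) &&
              is(designs[[1L]], "DesignRecord"))
    vapply(designs, function(r) paste0(heavyChain(r@sequence),
                                       lightChain(r@sequence)),
           character(1))
  else designs
  rows <- lapply(seq_along(seqs), function(k) {
    tryCatch({
      dgs <- binder(seqs[k])
      if (length(dgs) < 1L) stop("binder returned no decoys")
      dgs <- dgs[seq_len(min(length(dgs), nDecoys))]
      dg <- min(dgs)
      data.frame(id = k, dG = dg, nDecoys = length(dgs),
                 pass = dg <= thresholds$dgReference + thresholds$dgMargin,
                 failed = FALSE)
    }, error = function(e) {
      message("bind adapter failed for design ", k, ": ",
              conditionMessage(e))
      data.frame(id = k, dG = NA_real_, nDecoys = 0L, pass = FALSE,
                 failed = TRUE)
    })
  })
  results <- do.call(rbind, rows)
  list(pass = results$id[results$pass], results = results)
}

#' Run the full fold + bind screening pipeline
#'
#' Applies the fold gate and the bind gate and intersects the passing
#' sets; the report carries per-design metrics, the gate counts and the
#' PSSM of the screened designed subsequences.
#'
#' @inheritParams screenFolding
#' @inheritParams screenBinding
#' @param designedSubseqs Optional character vector of designed
#'   subsequences (for the screened-set PSSM) aligned with `designs`.
#' @return List with `screened` (ids), `fold`, `bind` (gate outputs),
#'   `counts` (input/foldPass/bindPass/screened) and `pssm`
#'   (screened-set [SequenceProfile-class], NULL if empty).
#' @export
runPipeline <- function(designs, folder, binder, target, region,
                        thresholds = screeningThresholds(), nDecoys = 5L,
                        designedSubseqs = NULL) {
  if (length(designs) == 0L)
    return(list(screened = integer(0), fold = NULL, bind = NULL,
                counts = c(input = 0L, foldPass = 0L, bindPass = 0L,
                           screened = 0L),
                pssm = NULL))
  fold <- screenFolding(designs, folder, target, region, thresholds)
  bind <- screenBinding(designs, binder, nDecoys, thresholds)
  screened <- intersect(fold$pass, bind$pass)
  if (is.null(designedSubseqs) && is.list(designs) &&
      is(designs[[1L]], "DesignRecord"))
    designedSubseqs <- designedSequences(designs)
  pssm <- if (!is.null(designedSubseqs) && length(screened))
    buildPssm(designedSubseqs[screened]) else NULL
  list(screened = screened, fold = fold, bind = bind,
       counts = c(input = length(fold$results$id),
                  foldPass = length(fold$pass),
                  bindPass = length(bind$pass),
                  screened = length(screened)),
       pssm = pssm)
}

#' Offline mock adapters for the screening pipeline
#'
#' `mockFolder` returns the target coordinates for every design, optionally
#' displacing the design-region atoms by a fixed amount for a
#' deterministically chosen subset (`failFraction`, by sequence hash).
#' `mockBinder` returns seeded reproducible decoy dG draws around a
#' per-sequence mean. Both mimic the adapter contracts so the pipeline is
#' fully testable without external folding or energy software.
#'
#' @param target Target [StructureCoordinates-class].
#' @param region A [DesignRegion-class].
#' @param displacement Angstrom shift applied to design-region atoms of
#'   failing designs.
#' @param failFraction Fraction of sequences displaced (deterministic in
#'   the sequence).
#' @return A folder / binder adapter closure.
#' @export
mockFolder <- function(target, region, displacement = 5, failFraction = 0) {
  d <- designPositions(region)
  function(sequence) {
    ## rolling polynomial hash: near-uniform over 0..999
    h <- Reduce(function(a, b) (a * 31 + b) %% 1000003L,
                utf8ToInt(sequence), accumulate = FALSE) %% 1000L
    coords <- target
    if (h < 1000L * failFraction) {
      shift <- c(displacement, 0, 0)
      for (i in d) {
        coords@n[i, ] <- coords@n[i, ] + shift
        coords@ca[i, ] <- coords@ca[i, ] + shift
        coords@c[i, ] <- coords@c[i, ] + shift
        coords@o[i, ] <- coords@o[i, ] + shift
        if (all(is.finite(coords@cb[i, ])))
          coords@cb[i, ] <- coords@cb[i, ] + shift
      }
    }
    coords
  }
}

#' @rdname mockFolder
#' @param seed Seed for the decoy draws.
#' @param meanDg,sdDg Decoy dG distribution parameters (REU).
#' @param nDecoys Decoys returned per call.
#' @export
mockBinder <- function(seed = 1L, meanDg = -20, sdDg = 2, nDecoys = 5L) {
  function(sequence) {
    h <- sum(utf8ToInt(sequence) * seq_len(nchar(sequence)))
    withSeed(as.integer((seed * 1000003 + h) %% .Machine$integer.max), {
      stats::rnorm(nDecoys, mean = meanDg + (h %% 7L) - 3, sd = sdDg)
    })
  }
}
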
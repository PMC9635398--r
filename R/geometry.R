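## geometry target: pairwise backbone geometries, binning, contact mask.

#' Construct backbone coordinates for an Fv-length structure
#'
#' @param N,CA,C,O Numeric L x 3 matrices of atom coordinates (Angstrom).
#' @param CB Numeric L x 3 matrix; rows of NA where the residue has no CB
#'   (glycine). Defaults to all-NA if omitted.
#' @return A [StructureCoordinates-class].
#' @export
structureCoordinates <- function(N, CA, C, O, CB = NULL) {
  toM <- function(m) {
    m <- as.matrix(m); storage.mode(m) <- "double"; dimnames(m) <- NULL; m
  }
  if (is.null(CB)) CB <- matrix(NA_real_, nrow(CA), 3L)
  new("StructureCoordinates", n = toM(N), ca = toM(CA), c = toM(C),
      o = toM(O), cb = toM(CB))
}

#' @describeIn StructureCoordinates Residue count.
#' @param x A [StructureCoordinates-class].
#' @export
setMethod("length", "StructureCoordinates", function(x) nrow(x@ca))

setMethod("show", "StructureCoordinates", function(object) {
  cat(sprintf("StructureCoordinates: %d residues (%d with CB)\n",
              nrow(object@ca), sum(is.finite(object@cb[, 1L]))))
})

## --- vector geometry -------------------------------------------------

vnorm <- function(v) sqrt(sum(v * v))

## Dihedral angle (degrees, (-180, 180]) over points p1-p2-p3-p4.
dihedralAngle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  n1xn2 <- c(n1[2] * n2[3] - n1[3] * n2[2],
             n1[3] * n2[1] - n1[1] * n2[3],
             n1[1] * n2[2] - n1[2] * n2[1])
  ang <- atan2(sum(n1xn2 * b2) / vnorm(b2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang + 360 else ang
}

## Planar angle (degrees, [0, 180]) at p2 over points p1-p2-p3.
planarAngle <- function(p1, p2, p3) {
  v1 <- p1 - p2; v2 <- p3 - p2
  cosv <- sum(v1 * v2) / (vnorm(v1) * vnorm(v2))
  acos(max(-1, min(1, cosv))) * 180 / pi
}

## --- pairwise geometry channels --------------------------------------

#' Compute the six real-valued pairwise geometry channels
#'
#' From backbone coordinates, computes per residue pair: the CA-CA, CB-CB
#' and N-O distances and the theta, phi, omega orientation channels
#' (trRosetta-style conventions: omega is the CA(i)-CB(i)-CB(j)-CA(j)
#' dihedral, theta the N(i)-CA(i)-CB(i)-CB(j) dihedral, phi the
#' CA(i)-CB(i)-CB(j) planar angle). The N-O distance is symmetrized as the
#' smaller of the two directed N(i)-O(j) distances so that all distance
#' channels are symmetric. Pair-channels needing a missing CB (glycine)
#' and the diagonal are masked invalid.
#'
#' @param coords A [StructureCoordinates-class].
#' @return List with `values` and `valid`: named lists of six L x L
#'   matrices (numeric / logical).
#' @export
computePairGeometries <- function(coords) {
  L <- length(coords)
  hasCB <- is.finite(coords@cb[, 1L])
  dmat <- function(A, B) {
    ## cross-distance matrix between row sets
    an <- rowSums(A * A); bn <- rowSums(B * B)
    d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
    sqrt(pmax(d2, 0))
  }
  values <- list(
    dCA = dmat(coords@ca, coords@ca),
    dCB = dmat(coords@cb, coords@cb),
    dNO = pmin(dmat(coords@n, coords@o), t(dmat(coords@n, coords@o))),
    theta = matrix(NA_real_, L, L),
    phi = matrix(NA_real_, L, L),
    omega = matrix(NA_real_, L, L))
  for (i in seq_len(L)) for (j in seq_len(L)) {
    if (i == j || !hasCB[i] || !hasCB[j]) next
    values$theta[i, j] <- dihedralAngle(coords@n[i, ], coords@ca[i, ],
                                        coords@cb[i, ], coords@cb[j, ])
    values$phi[i, j] <- planarAngle(coords@ca[i, ], coords@cb[i, ],
                                    coords@cb[j, ])
    if (i < j) {
      om <- dihedralAngle(coords@ca[i, ], coords@cb[i, ],
                          coords@cb[j, ], coords@ca[j, ])
      values$omega[i, j] <- om
      values$omega[j, i] <- om
    }
  }
  offDiag <- matrix(TRUE, L, L); diag(offDiag) <- FALSE
  cbPair <- outer(hasCB, hasCB, "&") & offDiag
  valid <- list(dCA = offDiag, dCB = cbPair, dNO = offDiag,
                theta = cbPair, phi = cbPair, omega = cbPair)
  for (ch in GEOM_CHANNELS) values[[ch]][!valid[[ch]]] <- NA_real_
  list(values = values, valid = valid)
}

## --- binning ----------------------------------------------------------

#' Bin-edge configuration for the geometry channels
#'
#' Defaults: distances binned 0-20 Angstrom in 0.5 Angstrom steps plus a
#' catch-all overflow bin; dihedrals in 15-degree bins over (-180, 180];
#' the planar angle in 12-degree bins over 0 to 180 degrees. All edges are
#' configurable.
#'
#' @param distanceMax,distanceStep Distance range and step (Angstrom).
#' @param dihedralStep,planarStep Angular steps (degrees).
#' @return A [GeometryBinning-class].
#' @examples
#' nBins(geometryBinning())
#' @export
geometryBinning <- function(distanceMax = 20, distanceStep = 0.5,
                            dihedralStep = 15, planarStep = 12) {
  dEdges <- seq(0, distanceMax, by = distanceStep)
  new("GeometryBinning", edges = list(
    dCA = dEdges, dCB = dEdges, dNO = dEdges,
    theta = seq(-180, 180, by = dihedralStep),
    phi = seq(0, 180, by = planarStep),
    omega = seq(-180, 180, by = dihedralStep)))
}

#' @rdname nBins
#' @export
setMethod("nBins", "GeometryBinning", function(x) {
  ## distances carry a catch-all bin beyond the final edge
  vapply(GEOM_CHANNELS, function(ch) {
    nb <- length(x@edges[[ch]]) - 1L
    if (ch %in% DIST_CHANNELS) nb + 1L else nb
  }, integer(1))
})

#' @rdname nBins
#' @export
setMethod("nBins", "TargetGeometry", function(x) nBins(x@binning))

#' @rdname nBins
#' @export
setMethod("nBins", "ToyOracle", function(x) {
  stats::setNames(x@nBins, GEOM_CHANNELS)
})

setMethod("show", "GeometryBinning", function(object) {
  nb <- nBins(object)
  cat("GeometryBinning:",
      paste(sprintf("%s=%d", names(nb), nb), collapse = " "), "bins\n")
})

## Assign one channel's values to bins: half-open [e_k, e_{k+1}); distance
## overflow goes to the catch-all bin; angle domain endpoints close on the
## right.
binChannel <- function(x, edges, distance) {
  lab <- findInterval(x, edges, rightmost.closed = !distance)
  if (distance) {
    if (any(x < edges[1L], na.rm = TRUE))
      stop("distance below first bin edge")
    lab[!is.na(x) & x >= edges[length(edges)]] <- length(edges)
  } else {
    if (any(lab == 0L | lab == length(edges), na.rm = TRUE))
      stop("angle outside binning domain")
  }
  lab
}

#' Discretize pairwise geometries into target bin labels
#'
#' @param geoms Output of [computePairGeometries()].
#' @param binning A [GeometryBinning-class].
#' @return A [TargetGeometry-class].
#' @export
discretizeGeometry <- function(geoms, binning) {
  labels <- list()
  for (ch in GEOM_CHANNELS) {
    v <- geoms$values[[ch]]
    lab <- matrix(NA_integer_, nrow(v), ncol(v))
    ok <- geoms$valid[[ch]]
    lab[ok] <- binChannel(v[ok], binning@edges[[ch]],
                          distance = ch %in% DIST_CHANNELS)
    labels[[ch]] <- lab
  }
  new("TargetGeometry", labels = labels, valid = geoms$valid,
      binning = binning)
}

#' Derive binned target geometry directly from coordinates
#'
#' Convenience composition of [computePairGeometries()] and
#' [discretizeGeometry()].
#'
#' @inheritParams computePairGeometries
#' @inheritParams discretizeGeometry
#' @return A [TargetGeometry-class].
#' @export
targetGeometryFromCoords <- function(coords, binning = geometryBinning())
  discretizeGeometry(computePairGeometries(coords), binning)

setMethod("show", "TargetGeometry", function(object) {
  L <- nrow(object@labels[[1L]])
  cat(sprintf("TargetGeometry: %d residues, bins per channel: %s\n", L,
              paste(nBins(object), collapse = "/")))
})

## --- contact mask ------------------------------------------------------

#' Build the 10-Angstrom CA contact mask over design positions
#'
#' Enumerates the ordered pairs (i, j) with i in the design set D, j any
#' other residue, and CA-CA distance at or below the cutoff. The count C of
#' these ordered pairs normalizes the geometric loss; a pair with both ends
#' in D is counted in both orders, following the double-sum contact count
#' literally.
#'
#' @param coords A [StructureCoordinates-class] aligned to the Fv.
#' @param region A [DesignRegion-class].
#' @param cutoff CA-CA cutoff in Angstrom (default 10).
#' @return A [ContactMask-class].
#' @export
buildContactMask <- function(coords, region, cutoff = 10) {
  d <- designPositions(region)
  if (length(d) == 0L) stop("design region must be non-empty")
  L <- length(coords)
  if (region@nTotal != L)
    stop("coordinates and design region disagree on residue count")
  ca <- coords@ca
  pairs <- matrix(integer(0), 0L, 2L)
  for (i in d) {
    dist <- sqrt(rowSums((ca - matrix(ca[i, ], L, 3L, byrow = TRUE))^2))
    j <- setdiff(which(dist <= cutoff), i)
    if (length(j))
      pairs <- rbind(pairs, cbind(i, j))
  }
  dimnames(pairs) <- NULL
  new("ContactMask", pairs = pairs, cutoff = as.numeric(cutoff),
      nResidues = as.integer(L))
}

#' @rdname nContacts
#' @export
setMethod("nContacts", "ContactMask", function(x) nrow(x@pairs))

#' @rdname contactPairs
#' @export
setMethod("contactPairs", "ContactMask", function(x) x@pairs)

setMethod("show", "ContactMask", function(object) {
  cat(sprintf("ContactMask: C = %d ordered pairs (cutoff %.1f A)\n",
              nrow(object@pairs), object@cutoff))
})
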
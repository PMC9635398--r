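## Small helper: backbone coordinates with arbitrary but non-degenerate
## local atom placement around given CA positions.
coordsFromCa <- function(ca, glycine = integer(0)) {
  L <- nrow(ca)
  letters <- rep("A", L); letters[glycine] <- "G"
  FvDesign:::backboneFromWalk(ca, letters)
}

test_that("pairwise distances and angles match direct computation", {
  ## CA atoms 3-4-5 apart
  ca <- rbind(c(0, 0, 0), c(3, 4, 0))
  coords <- coordsFromCa(ca)
  g <- computePairGeometries(coords)
  expect_equal(g$values$dCA[1, 2], 5.0, tolerance = 1e-12)
  expect_equal(g$values$dCA[2, 1], 5.0, tolerance = 1e-12)

  ## trans (planar) four-point arrangement gives a 180-degree dihedral
  expect_equal(abs(FvDesign:::dihedralAngle(c(0, 1, 0), c(0, 0, 0),
                                            c(1, 0, 0), c(1, -1, 0))),
               180, tolerance = 1e-9)
  ## cis arrangement gives 0
  expect_equal(FvDesign:::dihedralAngle(c(0, 1, 0), c(0, 0, 0),
                                        c(1, 0, 0), c(1, 1, 0)),
               0, tolerance = 1e-9)
})

test_that("all six channels agree with an independent per-pair oracle", {
  set.seed(11)
  ca <- FvDesign:::selfAvoidingWalk(5)
  coords <- coordsFromCa(ca)
  g <- computePairGeometries(coords)
  for (i in 1:5) for (j in 1:5) {
    if (i == j) next
    expect_equal(g$values$dCA[i, j],
                 sqrt(sum((coords@ca[i, ] - coords@ca[j, ])^2)),
                 tolerance = 1e-9)
    expect_equal(g$values$dCB[i, j],
                 sqrt(sum((coords@cb[i, ] - coords@cb[j, ])^2)),
                 tolerance = 1e-9)
    expect_equal(g$values$dNO[i, j],
                 min(sqrt(sum((coords@n[i, ] - coords@o[j, ])^2)),
                     sqrt(sum((coords@n[j, ] - coords@o[i, ])^2))),
                 tolerance = 1e-9)
    expect_equal(g$values$theta[i, j],
                 referenceDihedral(coords@n[i, ], coords@ca[i, ],
                                   coords@cb[i, ], coords@cb[j, ]),
                 tolerance = 1e-6)
    expect_equal(g$values$omega[i, j],
                 referenceDihedral(coords@ca[i, ], coords@cb[i, ],
                                   coords@cb[j, ], coords@ca[j, ]),
                 tolerance = 1e-6)
    v1 <- coords@ca[i, ] - coords@cb[i, ]
    v2 <- coords@cb[j, ] - coords@cb[i, ]
    expect_equal(g$values$phi[i, j],
                 acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi,
                 tolerance = 1e-6)
  }
  ## distance channels and omega symmetric; theta generally not
  expect_equal(g$values$dNO, t(g$values$dNO))
  expect_equal(g$values$omega, t(g$values$omega))
})

test_that("glycine masks CB-dependent channels and errors are informative", {
  set.seed(12)
  ca <- FvDesign:::selfAvoidingWalk(4)
  coords <- coordsFromCa(ca, glycine = 2L)
  g <- computePairGeometries(coords)
  expect_false(any(g$valid$dCB[2, ]))
  expect_false(any(g$valid$theta[, 2]))
  expect_true(all(g$valid$dCA[2, -2]))
  ## diagonal always invalid
  for (ch in FvDesign:::GEOM_CHANNELS)
    expect_false(any(diag(g$valid[[ch]])))
})

test_that("discretization follows half-open bins with a distance catch-all", {
  b <- geometryBinning()
  ## value exactly at an interior edge goes to the higher bin
  expect_equal(FvDesign:::binChannel(0.5, b@edges$dCA, distance = TRUE), 2L)
  ## overflow lands in the catch-all bin (index = number of bins)
  expect_equal(FvDesign:::binChannel(25, b@edges$dCA, distance = TRUE),
               nBins(b)[["dCA"]])
  expect_error(FvDesign:::binChannel(-1, b@edges$dCA, distance = TRUE),
               "below first")
  ## angle domain endpoints close on the right
  expect_equal(FvDesign:::binChannel(180, b@edges$phi, distance = FALSE),
               nBins(b)[["phi"]])

  ## random values agree with an exhaustive linear interval scan
  set.seed(13)
  edges <- b@edges$dCA
  x <- runif(100, 0, 25)
  scan <- vapply(x, function(v) {
    for (k in seq_len(length(edges) - 1L))
      if (v >= edges[k] && v < edges[k + 1L]) return(k)
    length(edges)  # catch-all
  }, integer(1))
  expect_identical(FvDesign:::binChannel(x, edges, distance = TRUE), scan)
})

test_that("contact masks enumerate ordered design pairs under the cutoff", {
  ca <- rbind(c(0, 0, 0), c(5, 0, 0), c(50, 0, 0))
  coords <- coordsFromCa(ca)
  fv <- concatenateFv("AR", "D")
  m1 <- buildContactMask(coords, makeDesignRegion(fv, 1L))
  expect_equal(nContacts(m1), 1L)
  expect_equal(contactPairs(m1), cbind(1L, 2L), ignore_attr = TRUE)

  ## both endpoints designable: both orders counted
  m2 <- buildContactMask(coords, makeDesignRegion(fv, c(1L, 2L)))
  expect_equal(nContacts(m2), 2L)
  expect_setequal(split(contactPairs(m2), seq_len(2)),
                  list(c(1L, 2L), c(2L, 1L)))

  ## everything out of range
  caFar <- rbind(c(0, 0, 0), c(20, 0, 0), c(40, 0, 0))
  m3 <- buildContactMask(coordsFromCa(caFar), makeDesignRegion(fv, 1L))
  expect_equal(nContacts(m3), 0L)
})

test_that("geometry channels are rigid-transform invariant and the contact
           count is monotone in the cutoff", {
  set.seed(14)
  ca <- FvDesign:::selfAvoidingWalk(6)
  coords <- coordsFromCa(ca)
  g0 <- computePairGeometries(coords)

  ## random proper rotation + translation
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  shift <- c(5, -3, 12)
  move <- function(m) sweep(m %*% q, 2, shift, "+")
  coordsT <- structureCoordinates(move(coords@n), move(coords@ca),
                                  move(coords@c), move(coords@o),
                                  move(coords@cb))
  gT <- computePairGeometries(coordsT)
  for (ch in FvDesign:::GEOM_CHANNELS)
    expect_equal(gT$values[[ch]], g0$values[[ch]], tolerance = 1e-6)

  fv <- concatenateFv("ARD", "YWG")
  region <- makeDesignRegion(fv, 2L)
  cuts <- c(4, 6, 8, 10, 15)
  counts <- vapply(cuts, function(ct)
    nContacts(buildContactMask(coords, region, cutoff = ct)), integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("binned labels are stable under sub-bin-width perturbations", {
  set.seed(15)
  ca <- FvDesign:::selfAvoidingWalk(5)
  coords <- coordsFromCa(ca)
  b <- geometryBinning()
  t0 <- targetGeometryFromCoords(coords, b)
  ## nudge all coordinates by well under half of the 0.5 A distance bins;
  ## only check distance channels whose values sit away from bin edges
  eps <- 1e-4
  coordsP <- structureCoordinates(coords@n + eps, coords@ca + eps,
                                  coords@c + eps, coords@o + eps,
                                  coords@cb + eps)
  t1 <- targetGeometryFromCoords(coordsP, b)
  expect_identical(t0@labels$dCA, t1@labels$dCA)
})
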
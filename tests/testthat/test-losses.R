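## Build a prediction object with given per-channel probabilities on a
## 1..C pair mask over an L-residue chain.
predFor <- function(probsList, C) {
  new("GeometryPrediction", probs = probsList,
      valid = matrix(TRUE, C, 6L))
}

## Target with label 1 at every mask pair, B bins per channel.
uniformTargetAndMask <- function(L, C, B) {
  pairs <- cbind(1L, 1L + seq_len(C))
  mask <- new("ContactMask", pairs = pairs, cutoff = 10,
              nResidues = as.integer(L))
  labels <- valid <- list()
  for (ch in FvDesign:::GEOM_CHANNELS) {
    lab <- matrix(NA_integer_, L, L); ok <- matrix(FALSE, L, L)
    lab[pairs] <- 1L; ok[pairs] <- TRUE
    labels[[ch]] <- lab; valid[[ch]] <- ok
  }
  names(labels) <- names(valid) <- FvDesign:::GEOM_CHANNELS
  edges <- lapply(seq_len(6), function(k) seq(0, B, length.out = B))
  names(edges) <- FvDesign:::GEOM_CHANNELS
  ## distance-channel edge lists give B-1 intervals + catch-all = B bins;
  ## angle channels need B+1 edges
  edges$theta <- seq(-180, 180, length.out = B + 1)
  edges$phi <- seq(0, 180, length.out = B + 1)
  edges$omega <- seq(-180, 180, length.out = B + 1)
  target <- new("TargetGeometry", labels = labels, valid = valid,
                binning = new("GeometryBinning", edges = edges))
  list(target = target, mask = mask)
}

test_that("geometric loss closed forms: perfect and uniform predictions", {
  B <- 8L; C <- 4L; L <- 6L
  tm <- uniformTargetAndMask(L, C, B)
  perfect <- lapply(1:6, function(k) {
    m <- matrix(0, C, B); m[, 1] <- 1; m
  })
  names(perfect) <- FvDesign:::GEOM_CHANNELS
  expect_equal(geometricLoss(predFor(perfect, C), tm$target, tm$mask), 0,
               tolerance = 1e-9)

  uniform <- lapply(1:6, function(k) matrix(1 / B, C, B))
  names(uniform) <- FvDesign:::GEOM_CHANNELS
  expect_equal(geometricLoss(predFor(uniform, C), tm$target, tm$mask),
               3 * log(B), tolerance = 1e-9)

  empty <- new("ContactMask", pairs = matrix(integer(0), 0, 2),
               cutoff = 10, nResidues = L)
  expect_error(geometricLoss(predFor(uniform, C), tm$target, empty),
               "empty contact mask")
})

test_that("geometric loss matches a naive double-loop summation and is
           pair-order invariant", {
  set.seed(31)
  B <- 5L; C <- 4L; L <- 6L
  tm <- uniformTargetAndMask(L, C, B)
  probs <- lapply(1:6, function(k) randomProbs(C, B))
  names(probs) <- FvDesign:::GEOM_CHANNELS
  pred <- predFor(probs, C)
  got <- geometricLoss(pred, tm$target, tm$mask)

  naive <- 0
  for (ch in FvDesign:::GEOM_CHANNELS) for (p in seq_len(C)) {
    i <- tm$mask@pairs[p, 1]; j <- tm$mask@pairs[p, 2]
    naive <- naive - log(probs[[ch]][p, tm$target@labels[[ch]][i, j]])
  }
  expect_equal(got, naive / (2 * C), tolerance = 1e-12)

  ## permuting the pair list (and prediction rows with it) changes nothing
  ord <- sample(C)
  maskP <- new("ContactMask", pairs = tm$mask@pairs[ord, ], cutoff = 10,
               nResidues = L)
  probsP <- lapply(probs, function(m) m[ord, , drop = FALSE])
  expect_equal(geometricLoss(predFor(probsP, C), tm$target, maskP), got,
               tolerance = 1e-12)
})

test_that("sequence loss closed forms and random agreement", {
  wt <- c("A", "R", "D")
  p <- FvDesign:::oneHot(wt)
  expect_equal(sequenceLoss(p, wt), 0, tolerance = 1e-9)
  suppressWarnings(
    expect_gt(sequenceLoss(FvDesign:::oneHot(c("C", "C", "C")), wt), 20))

  uni <- matrix(1 / 20, 10, 20)
  expect_equal(sequenceLoss(uni, rep("A", 10)), 10 * log(20),
               tolerance = 1e-9)

  set.seed(32)
  pr <- randomProbs(5)
  wt5 <- c("A", "C", "W", "Y", "G")
  expect_equal(sequenceLoss(pr, wt5),
               -sum(log(pr[cbind(1:5, aaToIndex(wt5))])),
               tolerance = 1e-12)
})

test_that("motif loss is a KL divergence: zero at equality, ln 20 for
           one-hot vs uniform, nonnegative", {
  set.seed(33)
  q <- randomProbs(3)
  motif <- motifSpec(1:3, q)
  expect_equal(motifLoss(q, motif), 0, tolerance = 1e-9)

  oneHotMotif <- motifSpec(1L, FvDesign:::oneHot("W"))
  uni <- matrix(1 / 20, 1, 20)
  expect_equal(motifLoss(uni, oneHotMotif), log(20), tolerance = 1e-9)

  for (k in 1:10) {
    p <- randomProbs(3)
    lm <- motifLoss(p, motif)
    direct <- sum(q * (log(q) - log(p)))
    expect_equal(lm, direct, tolerance = 1e-9)
    expect_gte(lm, -1e-12)
  }
})

test_that("total loss combines components linearly with validated weights", {
  lv <- totalLoss(2, 3, 4, lossWeights(1, 0, 0))
  expect_equal(lv[["total"]], 2)
  ## published restricted-mode weight settings
  expect_equal(totalLoss(2, 3, 0, lossWeights(1, 25, 0))[["total"]],
               2 + 25 * 3)
  expect_equal(totalLoss(2, 0, 4, lossWeights(1, 0, 100))[["total"]],
               2 + 100 * 4)
  expect_equal(totalLoss(2, 3, 4, lossWeights(2, 2, 2))[["total"]],
               2 * totalLoss(2, 3, 4, lossWeights(1, 1, 1))[["total"]])
  expect_error(lossWeights(-1, 0, 0), "nonnegative")
  expect_equal(lv[["total"]],
               sum(lossWeights(1, 0, 0) * lv[c("geometric", "sequence",
                                               "motif")]),
               tolerance = 1e-9)
})
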
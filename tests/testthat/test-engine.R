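test_that("initialization is reproducible and honors seeding and masks", {
  fx <- sharedFixture()
  a1 <- FvDesign:::withSeed(5, initializeDesign(fx$fv, fx$region))
  a2 <- FvDesign:::withSeed(5, initializeDesign(fx$fv, fx$region))
  expect_identical(a1, a2)
  expect_true(all(a1[, "C"] < -1e8))          # cysteine pinned by default
  expect_true(all(a1[a1 > -1e8] >= 0 & a1[a1 > -1e8] <= 1.5))

  ## wildtype seeding adds exactly 0.5 at the wildtype letters
  wt <- aaToIndex(fvChars(fx$fv)[designPositions(fx$region)])
  set.seed(5); plain <- initializeDesign(fx$fv, fx$region)
  set.seed(5); seeded <- initializeDesign(fx$fv, fx$region,
                                          seeding = "wildtype")
  idx <- cbind(seq_along(wt), wt)
  expect_equal(seeded[idx] - plain[idx], rep(0.5, length(wt)))
  off <- seeded; off[idx] <- plain[idx]
  expect_equal(off, plain)

  ## seeding a disallowed wildtype letter is an error
  maskNoWt <- alphabetMask(length(wt), disallow = AA20[wt[1]])
  expect_error(initializeDesign(fx$fv, fx$region, seeding = "wildtype",
                                allowed = maskNoWt),
               "disallowed")
})

test_that("decoding takes the row argmax with alphabetical tie-breaks", {
  oneHots <- FvDesign:::oneHot(c("W", "A", "M"))
  expect_identical(decodeDesign(oneHots * 10), c("W", "A", "M"))

  tie <- matrix(0, 1, 20)
  tie[1, aaToIndex("D")] <- 3; tie[1, aaToIndex("Y")] <- 3
  expect_identical(decodeDesign(tie), "D")

  set.seed(41)
  for (k in 1:5) {
    a <- matrix(rnorm(60), 3, 20)
    naive <- AA20[vapply(1:3, function(i) {
      row <- a[i, ]; which(row == max(row))[1]
    }, integer(1))]
    expect_identical(decodeDesign(a), naive)
  }
})

test_that("design steps displace the matrix by exactly the learning rate
           and never touch disallowed letters", {
  fx <- sharedFixture()
  allowed <- alphabetMask(3)
  set.seed(42); a <- initializeDesign(fx$fv, fx$region, allowed = allowed)
  stepped <- designStep(a, fx$oracle, fx$target, fx$mask, fx$fv, fx$region,
                        allowed = allowed, learningRate = 0.05)
  delta <- stepped$values - a
  expect_equal(sqrt(sum(delta^2)), 0.05, tolerance = 1e-9)
  expect_true(all(delta[, "C"] == 0))

  ## zero loss weights give a zero gradient and an unchanged matrix
  frozen <- designStep(a, fx$oracle, fx$target, fx$mask, fx$fv, fx$region,
                       weights = lossWeights(0, 0, 0), allowed = allowed)
  expect_identical(frozen$values, a)
})

test_that("hallucination is bit-reproducible and descends the loss", {
  fx <- sharedFixture()
  cfg <- hallucinationConfig(seed = 11, maxIterations = 30)
  r1 <- hallucinate(cfg, fx$oracle, fx$target, fx$mask, fx$fv, fx$region)
  r2 <- hallucinate(cfg, fx$oracle, fx$target, fx$mask, fx$fv, fx$region)
  expect_identical(r1@designed, r2@designed)
  expect_identical(r1@trajectory, r2@trajectory)

  ## median loss over the last iterations <= over the first (descent trend)
  tr <- r1@trajectory$total
  k <- min(10, floor(length(tr) / 2))
  expect_lte(median(tail(tr, k)), median(head(tr, k)))
})

test_that("a dominant sequence loss pins the design at the wildtype", {
  fx <- sharedFixture()
  cfg <- hallucinationConfig(seed = 13, maxIterations = 40,
                             weights = lossWeights(1, 50, 0))
  rec <- hallucinate(cfg, fx$oracle, fx$target, fx$mask, fx$fv, fx$region)
  wt <- paste(fvChars(fx$fv)[designPositions(fx$region)], collapse = "")
  expect_identical(rec@designed, wt)
})

test_that("a one-hot motif with the published weight forces its letter", {
  fx <- sharedFixture()
  motif <- motifSpec(2L, FvDesign:::oneHot("W"))
  cfg <- hallucinationConfig(seed = 17, maxIterations = 40,
                             weights = lossWeights(1, 0, 100))
  rec <- hallucinate(cfg, fx$oracle, fx$target, fx$mask, fx$fv, fx$region,
                     motif = motif)
  expect_identical(substr(rec@designed, 2, 2), "W")
})

test_that("libraries are reproducible, respect the alphabet and differ
           across seeds", {
  fx <- sharedFixture()
  cfg <- hallucinationConfig(maxIterations = 10)
  lib1 <- generateLibrary(cfg, fx$oracle, fx$target, fx$mask, fx$fv,
                          fx$region, nDesigns = 8, seedBase = 100)
  lib2 <- generateLibrary(cfg, fx$oracle, fx$target, fx$mask, fx$fv,
                          fx$region, nDesigns = 8, seedBase = 100)
  expect_identical(designedSequences(lib1), designedSequences(lib2))
  seqs <- designedSequences(lib1)
  expect_gte(length(unique(seqs)), 1L)
  expect_false(any(grepl("C", seqs)))
  expect_identical(vapply(lib1, function(r) r@seed, integer(1)),
                   100:107)
})

test_that("design records substitute the designed letters into the Fv", {
  fx <- sharedFixture()
  cfg <- hallucinationConfig(seed = 19, maxIterations = 5)
  rec <- hallucinate(cfg, fx$oracle, fx$target, fx$mask, fx$fv, fx$region)
  full <- fvChars(rec@sequence)
  d <- designPositions(fx$region)
  expect_identical(paste(full[d], collapse = ""), rec@designed)
  expect_identical(full[-d], fvChars(fx$fv)[-d])
})
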
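test_that("Kabsch superposition recovers rigid transforms", {
  set.seed(71)
  pts <- matrix(rnorm(30), 10, 3)
  same <- kabschSuperpose(pts, pts)
  expect_equal(same$rmsd, 0, tolerance = 1e-9)
  expect_equal(same$rotation, diag(3), tolerance = 1e-9)

  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  moved <- sweep(pts %*% q, 2, c(3, -2, 7), "+")
  fit <- kabschSuperpose(moved, pts)
  expect_lt(fit$rmsd, 1e-6)

  ## cross-check against bio3d's least-squares fit
  fitted <- suppressWarnings(
    bio3d::fit.xyz(fixed = as.vector(t(pts)),
                   mobile = as.vector(t(moved))))
  expect_equal(fit$rmsd,
               bio3d::rmsd(as.vector(t(pts)), fitted), tolerance = 1e-6)

  expect_error(kabschSuperpose(pts[1:2, ], pts[1:2, ]), ">= 3")
  line <- cbind(1:5, 0, 0)
  expect_error(kabschSuperpose(line, line), "collinear")
})

test_that("a 4-point toy with one displaced atom matches the closed form", {
  ## three anchor points identical, fourth displaced by 1 A: after
  ## aligning (the optimum leaves the anchors essentially fixed for a
  ## wide triangle), rmsd = sqrt(1/4 * d^2 * (1 - 1/4)) is bounded by the
  ## naive value; here we verify against a direct numerical optimum.
  ref <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0), c(5, 5, 0))
  mob <- ref; mob[4, 3] <- 1
  fit <- kabschSuperpose(mob, ref)
  ## centered z-offsets: best rigid fit tilts slightly; compare with a
  ## brute-force grid over small rotations about x/y plus z-shift
  grid <- expand.grid(rx = seq(-0.2, 0.2, length.out = 81),
                      dz = seq(-0.5, 0.5, length.out = 81))
  best <- min(vapply(seq_len(nrow(grid)), function(k) {
    a <- grid$rx[k]
    R <- rbind(c(1, 0, 0), c(0, cos(a), -sin(a)), c(0, sin(a), cos(a)))
    m <- sweep(mob %*% R, 2, c(0, 0, grid$dz[k]), "+")
    sqrt(mean(rowSums((m - ref)^2)))
  }, numeric(1)))
  expect_lte(fit$rmsd, best + 1e-6)
  expect_gt(fit$rmsd, 0.3)  # displacement spread over 4 points
})

test_that("design-region RMSD uses the framework frame", {
  fx <- sharedFixture()
  expect_equal(designRegionRmsd(fx$coords, fx$coords, fx$region)$rmsd, 0,
               tolerance = 1e-9)

  ## displacing only the design-region atoms by 3 A gives RMSD 3
  d <- designPositions(fx$region)
  shifted <- fx$coords
  for (i in d) {
    shifted@n[i, ] <- shifted@n[i, ] + c(3, 0, 0)
    shifted@ca[i, ] <- shifted@ca[i, ] + c(3, 0, 0)
    shifted@c[i, ] <- shifted@c[i, ] + c(3, 0, 0)
  }
  res <- designRegionRmsd(shifted, fx$coords, fx$region)
  expect_equal(res$rmsd, 3, tolerance = 1e-9)
  expect_equal(res$perResidue, rep(3, length(d)), tolerance = 1e-9)

  ## invariance under a rigid transform of the folded model
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  move <- function(m) sweep(m %*% q, 2, c(1, 2, 3), "+")
  rigid <- structureCoordinates(move(shifted@n), move(shifted@ca),
                                move(shifted@c), move(shifted@o),
                                move(shifted@cb))
  expect_equal(designRegionRmsd(rigid, fx$coords, fx$region)$rmsd,
               res$rmsd, tolerance = 1e-6)

  ## independent two-stage recomputation (bio3d fit on framework atoms)
  fw <- fixedPositions(fx$region)
  fwFold <- FvDesign:::backboneAtoms(shifted, fw)
  fwTarg <- FvDesign:::backboneAtoms(fx$coords, fw)
  dFold <- FvDesign:::backboneAtoms(shifted, d)
  dTarg <- FvDesign:::backboneAtoms(fx$coords, d)
  full <- bio3d::fit.xyz(
    fixed = as.vector(t(rbind(fwTarg, dTarg))),
    mobile = as.vector(t(rbind(fwFold, dFold))),
    fixed.inds = seq_len(3 * nrow(fwTarg)),
    mobile.inds = seq_len(3 * nrow(fwFold)))
  movedD <- matrix(full[-seq_len(3 * nrow(fwFold))], ncol = 3,
                   byrow = TRUE)
  expect_equal(res$rmsd, sqrt(mean(rowSums((movedD - dTarg)^2))),
               tolerance = 1e-6)
})

test_that("fold and bind gates and their intersection behave like the
           recounted sets", {
  fx <- sharedFixture()
  set.seed(72)
  n <- 40
  seqs <- vapply(seq_len(n), function(k)
    paste0(randomSeq(6), if (k %% 2 == 0) "W" else "A"), character(1))

  ## folder displacing designs whose sequence ends in W by 5 A
  folder <- function(sequence) {
    coords <- fx$coords
    if (endsWith(sequence, "W")) {
      for (i in designPositions(fx$region)) {
        coords@n[i, ] <- coords@n[i, ] + c(5, 0, 0)
        coords@ca[i, ] <- coords@ca[i, ] + c(5, 0, 0)
        coords@c[i, ] <- coords@c[i, ] + c(5, 0, 0)
      }
    }
    coords
  }
  th <- screeningThresholds(rmsdMax = 2, dgReference = -20, dgMargin = 0)
  fold <- screenFolding(seqs, folder, fx$coords, fx$region, th)
  expect_setequal(fold$pass, which(seq_len(n) %% 2 == 1))

  ## zero threshold passes only exact folds
  th0 <- screeningThresholds(rmsdMax = 0, dgReference = -20)
  fold0 <- screenFolding(seqs, folder, fx$coords, fx$region, th0)
  expect_setequal(fold0$pass, which(seq_len(n) %% 2 == 1))

  ## raising the gate never shrinks the pass set
  for (lim in c(1, 2, 4, 6)) {
    fl <- screenFolding(seqs, folder, fx$coords, fx$region,
                        screeningThresholds(rmsdMax = lim))
    expect_true(all(fold0$pass %in% fl$pass))
  }

  ## decoy-min rule
  binder3 <- function(sequence) c(-10, -12, -11)
  bind3 <- screenBinding(seqs[1], binder3, nDecoys = 5, th)
  expect_equal(bind3$results$dG, -12)

  binder <- mockBinder(seed = 9, meanDg = -21, sdDg = 2)
  bind <- screenBinding(seqs, binder, nDecoys = 5, th)
  recomputed <- vapply(seqs, function(s) min(binder(s)), numeric(1))
  expect_equal(bind$results$dG, recomputed, ignore_attr = TRUE)
  expect_setequal(bind$pass, which(recomputed <= -20))

  ## pipeline = intersection of the gates
  out <- runPipeline(seqs, folder, binder, fx$coords, fx$region, th)
  expect_setequal(out$screened, intersect(fold$pass, bind$pass))
  expect_true(all(out$screened %in% fold$pass))
  expect_true(all(out$screened %in% bind$pass))
  expect_equal(out$counts[["screened"]], length(out$screened))

  ## adapter failure marks the design failed but the screen continues
  flaky <- function(sequence) {
    if (startsWith(sequence, "A")) stop("boom")
    folder(sequence)
  }
  suppressMessages(
    foldFlaky <- screenFolding(seqs, flaky, fx$coords, fx$region, th))
  expect_true(all(!foldFlaky$results$pass[startsWith(seqs, "A")]))
  expect_equal(nrow(foldFlaky$results), n)

  ## empty input yields an empty report, not an error
  empty <- runPipeline(character(0), folder, binder, fx$coords,
                       fx$region, th)
  expect_equal(empty$counts[["input"]], 0L)
})
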
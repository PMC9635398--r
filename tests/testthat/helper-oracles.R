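## Independent oracles and shared fixtures for the test suite.

## One shared toy fixture set; built once per test run.
sharedFixture <- local({
  fx <- NULL
  function() {
    if (is.null(fx)) fx <<- generateFixtures(fixtureSpec(seed = 42))
    fx
  }
})

## Eight-letter design alphabet used in recovery experiments; covers the
## shared fixture's wildtype design letters (A, M, F).
RECOVERY_LETTERS <- c("A", "D", "F", "G", "M", "S", "V", "W")

## Geometric loss of a fully decoded (one-hot) candidate subsequence.
hardGeometricLoss <- function(fx, letters) {
  full <- matrix(0, length(fx$fv), 20L)
  full[cbind(seq_len(length(fx$fv)), aaToIndex(fvChars(fx$fv)))] <- 1
  d <- designPositions(fx$region)
  full[d, ] <- 0
  full[cbind(d, aaToIndex(letters))] <- 1
  geometricLoss(oracleForward(fx$oracle, full, fx$mask), fx$target, fx$mask)
}

## Exhaustive enumeration of all |letters|^3 candidates for a 3-position
## design region; returns the minimum geometric loss.
enumerateMinLoss <- function(fx, letters = RECOVERY_LETTERS) {
  stopifnot(length(designPositions(fx$region)) == 3L)
  best <- Inf
  for (a in letters) for (b in letters) for (cc in letters) {
    l <- hardGeometricLoss(fx, c(a, b, cc))
    if (l < best) best <- l
  }
  best
}

## Wagner-Fischer dynamic-programming edit distance (independent of
## utils::adist, which the package uses).
wagnerFischer <- function(s, t) {
  a <- strsplit(s, "")[[1]]
  b <- strsplit(t, "")[[1]]
  n <- length(a); m <- length(b)
  d <- matrix(0L, n + 1L, m + 1L)
  d[, 1L] <- 0:n
  d[1L, ] <- 0:m
  for (i in seq_len(n)) for (j in seq_len(m)) {
    d[i + 1L, j + 1L] <- min(d[i, j + 1L] + 1L, d[i + 1L, j] + 1L,
                             d[i, j] + (a[i] != b[j]))
  }
  d[n + 1L, m + 1L]
}

## Textbook dihedral via the two-plane normal formula with an explicit
## sign from the scalar triple product (a different derivation from the
## package's atan2 form).
referenceDihedral <- function(p1, p2, p3, p4) {
  u1 <- p2 - p1; u2 <- p3 - p2; u3 <- p4 - p3
  n1 <- pracma::cross(u1, u2)
  n2 <- pracma::cross(u2, u3)
  co <- sum(n1 * n2) / (sqrt(sum(n1^2)) * sqrt(sum(n2^2)))
  ang <- acos(max(-1, min(1, co))) * 180 / pi
  if (sum(pracma::cross(n1, n2) * u2) < 0) ang <- -ang
  if (ang <= -180) ang + 360 else ang
}

## Random amino-acid string.
randomSeq <- function(n, letters = AA20) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

## Random row-normalized probability matrix.
randomProbs <- function(nrow, ncol = 20L) {
  m <- matrix(stats::rexp(nrow * ncol), nrow, ncol)
  m / rowSums(m)
}
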
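## fixtures: deterministic synthetic inputs — toy Fv, self-avoiding-walk
## backbone coordinates, toy oracle + target, and a reference library
## drawn from a known PSSM — so every pipeline stage is testable offline.

#' Specification of a synthetic fixture set
#'
#' @param nHeavy,nLight Chain lengths of the toy Fv (default 7 + 5).
#' @param nDesignPositions Number of designed positions, centered on the
#'   heavy chain (default 3).
#' @param seed Master seed; the toy-oracle seed defaults to `seed + 1`.
#' @param oracleSeed Seed for the toy-oracle weight draw.
#' @param nBins Bins per channel for the toy oracle (default 8).
#' @param temperature Toy-oracle softmax temperature.
#' @param librarySize Number of reference sequences drawn from the
#'   reference PSSM (default 25).
#' @param contactCutoff CA-CA contact cutoff in Angstrom (default 10).
#' @return List of class `"FixtureSpec"`.
#' @export
fixtureSpec <- function(nHeavy = 7L, nLight = 5L, nDesignPositions = 3L,
                        seed = 1L, oracleSeed = seed + 1L, nBins = 8L,
                        temperature = 1.0, librarySize = 25L,
                        contactCutoff = 10) {
  stopifnot(nHeavy >= 1L, nLight >= 1L, nDesignPositions >= 1L,
            nDesignPositions <= nHeavy, librarySize >= 1L)
  structure(list(nHeavy = as.integer(nHeavy), nLight = as.integer(nLight),
                 nDesignPositions = as.integer(nDesignPositions),
                 seed = as.integer(seed),
                 oracleSeed = as.integer(oracleSeed),
                 nBins = as.integer(nBins), temperature = temperature,
                 librarySize = as.integer(librarySize),
                 contactCutoff = contactCutoff),
            class = "FixtureSpec")
}

## Self-avoiding random walk of CA positions: fixed 3.8 A steps, uniform
## random directions, rejecting any step closer than 3.5 A to a previous
## CA. Compact enough at toy sizes to put many pairs under 10 A.
selfAvoidingWalk <- function(n, step = 3.8, minSep = 3.5,
                             maxTries = 200L) {
  ca <- matrix(0, n, 3L)
  for (i in seq_len(n)[-1L]) {
    for (try in seq_len(maxTries)) {
      u <- stats::rnorm(3L)
      cand <- ca[i - 1L, ] + step * u / sqrt(sum(u * u))
      prior <- ca[seq_len(i - 2L), , drop = FALSE]
      ok <- !nrow(prior) || all(sqrt(rowSums(
        (prior - matrix(cand, nrow(prior), 3L, byrow = TRUE))^2)) >= minSep)
      if (ok) { ca[i, ] <- cand; break }
      if (try == maxTries) stop("self-avoiding walk failed to extend")
    }
  }
  ca
}

## Build N, C, O, CB around each CA from a local frame along the walk.
## Idealized bond lengths; orientations chosen only to be non-degenerate.
backboneFromWalk <- function(ca, letters) {
  L <- nrow(ca)
  N <- Cc <- O <- CB <- matrix(NA_real_, L, 3L)
  for (i in seq_len(L)) {
    e1 <- if (i < L) ca[i + 1L, ] - ca[i, ] else ca[i, ] - ca[i - 1L, ]
    e1 <- e1 / sqrt(sum(e1 * e1))
    h <- if (abs(e1[3L]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
    e2 <- h - sum(h * e1) * e1
    e2 <- e2 / sqrt(sum(e2 * e2))
    e3 <- c(e1[2L] * e2[3L] - e1[3L] * e2[2L],
            e1[3L] * e2[1L] - e1[1L] * e2[3L],
            e1[1L] * e2[2L] - e1[2L] * e2[1L])
    N[i, ] <- ca[i, ] + 1.46 * (-0.53 * e1 + 0.85 * e2)
    Cc[i, ] <- ca[i, ] + 1.52 * (0.55 * e1 + 0.84 * e2)
    O[i, ] <- Cc[i, ] + 1.23 * (0.40 * e1 + 0.92 * e3)
    if (letters[i] != "G")
      CB[i, ] <- ca[i, ] + 1.53 * (-0.40 * e2 + 0.92 * e3)
  }
  structureCoordinates(N, ca, Cc, O, CB)
}

## Draw sequences from a PSSM (positions x 20 probability matrix).
sampleFromPssm <- function(probs, n) {
  vapply(seq_len(n), function(k) {
    paste(vapply(seq_len(nrow(probs)), function(i)
      sample(AA20, 1L, prob = probs[i, ]), character(1)), collapse = "")
  }, character(1))
}

#' Generate the synthetic fixture set
#'
#' Deterministic per seed. Produces a toy Fv (random canonical letters,
#' cysteine-free so default design settings apply), backbone coordinates
#' from a self-avoiding walk with 3.8 Angstrom CA spacing, the design
#' region and its contact mask, a toy oracle, the toy target geometry
#' built from the Fv itself (so the wildtype is a verifiable optimum
#' candidate), and a reference library drawn from a random reference PSSM
#' with known expectations.
#'
#' @param spec A [fixtureSpec()].
#' @return List with elements `fv`, `coords`, `region`, `mask`, `oracle`,
#'   `target`, `referencePssm`, `referenceLibrary`, `spec`.
#' @examples
#' fx <- generateFixtures(fixtureSpec(seed = 42))
#' fx$fv
#' nContacts(fx$mask)
#' @export
generateFixtures <- function(spec = fixtureSpec()) {
  stopifnot(inherits(spec, "FixtureSpec"))
  withSeed(spec$seed, {
    letters20 <- setdiff(AA20, "C")
    heavy <- paste(sample(letters20, spec$nHeavy, replace = TRUE),
                   collapse = "")
    light <- paste(sample(letters20, spec$nLight, replace = TRUE),
                   collapse = "")
    fv <- concatenateFv(heavy, light)
    ca <- selfAvoidingWalk(length(fv))
    coords <- backboneFromWalk(ca, fvChars(fv))
    ## design positions centered on the heavy chain
    start <- max(1L, (spec$nHeavy - spec$nDesignPositions) %/% 2L + 1L)
    d <- seq.int(start, length.out = spec$nDesignPositions)
    region <- makeDesignRegion(fv, d)
    mask <- buildContactMask(coords, region, cutoff = spec$contactCutoff)
    oracle <- toyOracle(spec$oracleSeed, nBins = spec$nBins,
                        temperature = spec$temperature)
    target <- toyTarget(oracle, fv, mask)
    ## reference PSSM over the design positions: normalized Exp(1) draws
    raw <- matrix(stats::rexp(spec$nDesignPositions * 20L),
                  spec$nDesignPositions, 20L)
    probs <- raw / rowSums(raw)
    colnames(probs) <- AA20
    referencePssm <- new("SequenceProfile",
                         positions = data.frame(
                           chain = rep("H", spec$nDesignPositions),
                           label = as.character(d),
                           stringsAsFactors = FALSE),
                         probs = probs)
    referenceLibrary <- sampleFromPssm(probs, spec$librarySize)
    list(fv = fv, coords = coords, region = region, mask = mask,
         oracle = oracle, target = target, referencePssm = referencePssm,
         referenceLibrary = referenceLibrary, spec = spec)
  })
}
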
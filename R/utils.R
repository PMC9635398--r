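## Internal numerical helpers shared across modules.

## Row-wise softmax; sentinel entries (very negative) map to ~0.
softmaxRows <- function(m) {
  shifted <- m - apply(m, 1L, max)
  e <- exp(shifted)
  e / rowSums(e)
}

softmaxVec <- function(v) {
  e <- exp(v - max(v))
  e / sum(e)
}

## Evaluate `code` under a fixed RNG seed without disturbing the caller's
## RNG stream.
withSeed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

## Probability floor used inside logarithms (losses, BD).
.PROB_FLOOR <- 1e-12

flooredLog <- function(p, floor = .PROB_FLOOR, warnOnFloor = FALSE) {
  hit <- p < floor
  if (warnOnFloor && any(hit))
    warning("probability below ", floor, " floored inside log", call. = FALSE)
  log(pmax(p, floor))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
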
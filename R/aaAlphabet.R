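#' The 20-letter amino-acid alphabet used throughout FvDesign
#'
#' One-letter codes of the canonical amino acids in fixed alphabetical
#' order (A, C, D, ..., Y). Every probability matrix, PSSM and design
#' matrix in the package uses this column order.
#'
#' @format Character vector of length 20.
#' @export
AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Convert amino-acid letters to alphabet indices and back
#'
#' The mapping between one-letter codes and their 1-based position in
#' [AA20] is a bijection; both directions validate their input.
#'
#' @param letters Character vector of single-letter amino-acid codes.
#' @param idx Integer vector of indices in 1..20.
#' @return `aaToIndex` returns an integer vector; `indexToAa` a character
#'   vector of one-letter codes.
#' @examples
#' aaToIndex(c("A", "Y"))
#' indexToAa(1:3)
#' @export
aaToIndex <- function(letters) {
  idx <- match(letters, AA20)
  if (anyNA(idx)) {
    bad <- letters[is.na(idx)]
    stop("non-canonical amino acid letter(s): ",
         paste(unique(bad), collapse = ", "))
  }
  idx
}

#' @rdname aaToIndex
#' @export
indexToAa <- function(idx) {
  idx <- as.integer(idx)
  if (any(idx < 1L | idx > 20L))
    stop("amino-acid index out of range 1..20")
  AA20[idx]
}

## Split a sequence string into letters, validating the alphabet.
## `what` names the sequence in error messages.
aaChars <- function(seq, what = "sequence") {
  ch <- strsplit(seq, "")[[1]]
  bad <- which(!ch %in% AA20)
  if (length(bad))
    stop("non-canonical character '", ch[bad[1]], "' in ", what,
         " at position ", bad[1])
  ch
}

## One-hot encode a vector of letters as an n x 20 matrix.
oneHot <- function(letters) {
  idx <- aaToIndex(letters)
  m <- matrix(0, length(idx), 20L, dimnames = list(NULL, AA20))
  m[cbind(seq_along(idx), idx)] <- 1
  m
}
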
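## io: FASTA (Biostrings), PDB backbone subset (bio3d), TSV tables
## (PSSMs, FR scores, numbering maps), run-config echo.

#' Read and write FASTA files
#'
#' Thin wrappers over Biostrings that return / accept plain named
#' character vectors. Headers of the form `name|chain` are preserved
#' verbatim in the names.
#'
#' @param path FASTA file.
#' @param seqs Named character vector of amino-acid sequences.
#' @return `readFasta`: named character vector (empty if the file has no
#'   records).
#' @export
readFasta <- function(path) {
  if (file.size(path) == 0)
    return(stats::setNames(character(0), character(0)))
  x <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' @rdname readFasta
#' @export
writeFasta <- function(seqs, path) {
  x <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a residue numbering map
#'
#' TSV with columns `chain`, `label`, `sequence_index` (1-based position
#' within the chain's sequence in the file; rows in concatenated H-then-L
#' order internally).
#'
#' @param path TSV file.
#' @return `data.frame` with columns chain, label, sequence_index.
#' @export
readNumberingMap <- function(path) {
  df <- utils::read.delim(path, colClasses = c("character", "character",
                                               "integer"))
  need <- c("chain", "label", "sequence_index")
  if (!all(need %in% names(df)))
    stop("numbering map needs columns: ", paste(need, collapse = ", "))
  df
}

#' @rdname readNumberingMap
#' @param numbering `data.frame` as returned by [fvNumbering()].
#' @export
writeNumberingMap <- function(numbering, path) {
  idx <- stats::ave(seq_len(nrow(numbering)), numbering$chain,
                    FUN = seq_along)
  utils::write.table(
    data.frame(chain = numbering$chain, label = numbering$label,
               sequence_index = idx),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read backbone coordinates from a PDB file
#'
#' Restricted to ATOM records of N, CA, C, O and CB. Residues are taken in
#' file order for the requested chains (heavy chain first), insertion
#' codes are honored as part of the residue identity, and alternate
#' locations other than blank/'A' keep the highest-occupancy copy (with a
#' message). A missing N, CA, C or O is an error naming the residue; a
#' missing CB marks the residue as glycine-like.
#'
#' @param path PDB file.
#' @param chains Character vector mapping Fv chains to PDB chain ids, in
#'   heavy-then-light order (default `c(H = "H", L = "L")`).
#' @return List with `coords` ([StructureCoordinates-class]) and
#'   `numbering` (`data.frame` chain/label per residue).
#' @export
readPdbBackbone <- function(path, chains = c(H = "H", L = "L")) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM" & at$elety %in% c("N", "CA", "C", "O", "CB") &
             at$chain %in% chains, , drop = FALSE]
  at$insert[is.na(at$insert)] <- ""
  alt <- at$alt; alt[is.na(alt)] <- ""
  if (any(!alt %in% c("", "A"))) {
    message("alternate locations present; keeping highest occupancy")
    at <- at[order(-at$o), , drop = FALSE]
  }
  key <- paste(at$chain, at$resno, at$insert, at$elety)
  at <- at[!duplicated(key), , drop = FALSE]

  rows <- list(); numbering <- list()
  for (fvChain in names(chains)) {
    sub <- at[at$chain == chains[[fvChain]], , drop = FALSE]
    resKey <- paste(sub$resno, sub$insert)
    for (rk in unique(resKey)) {
      res <- sub[resKey == rk, , drop = FALSE]
      lab <- paste0(res$resno[1L], res$insert[1L])
      get1 <- function(ele, required = TRUE) {
        hit <- res[res$elety == ele, , drop = FALSE]
        if (nrow(hit) == 0L) {
          if (required)
            stop("missing atom ", ele, " in residue ", fvChain, lab)
          return(rep(NA_real_, 3L))
        }
        c(hit$x[1L], hit$y[1L], hit$z[1L])
      }
      rows[[length(rows) + 1L]] <- list(
        N = get1("N"), CA = get1("CA"), C = get1("C"), O = get1("O"),
        CB = get1("CB", required = FALSE))
      numbering[[length(numbering) + 1L]] <-
        data.frame(chain = fvChain, label = lab, stringsAsFactors = FALSE)
    }
  }
  pick <- function(a) do.call(rbind, lapply(rows, `[[`, a))
  list(coords = structureCoordinates(pick("N"), pick("CA"), pick("C"),
                                     pick("O"), pick("CB")),
       numbering = do.call(rbind, numbering))
}

#' Write backbone coordinates as a PDB file
#'
#' Emits ATOM records for N, CA, C, O and (where present) CB, 1-based
#' residue numbering with insertion codes, via bio3d.
#'
#' @param coords A [StructureCoordinates-class].
#' @param numbering `data.frame` with chain/label per residue (default
#'   sequential numbering on chain H).
#' @param path Output file.
#' @export
writePdbBackbone <- function(coords, path, numbering = NULL) {
  L <- length(coords)
  if (is.null(numbering))
    numbering <- data.frame(chain = rep("H", L),
                            label = as.character(seq_len(L)))
  xyz <- c(); elety <- c(); resno <- c(); chain <- c(); insert <- c()
  for (i in seq_len(L)) {
    atoms <- list(N = coords@n[i, ], CA = coords@ca[i, ],
                  C = coords@c[i, ], O = coords@o[i, ])
    if (all(is.finite(coords@cb[i, ]))) atoms$CB <- coords@cb[i, ]
    lab <- numbering$label[i]
    num <- as.integer(gsub("[A-Za-z]", "", lab))
    ins <- gsub("[0-9]", "", lab)
    for (a in names(atoms)) {
      xyz <- c(xyz, atoms[[a]])
      elety <- c(elety, a)
      resno <- c(resno, num)
      chain <- c(chain, numbering$chain[i])
      insert <- c(insert, if (nzchar(ins)) ins else "")
    }
  }
  bio3d::write.pdb(file = path, xyz = xyz, elety = elety, resno = resno,
                   chain = chain, insert = insert,
                   resid = rep("ALA", length(elety)))
  invisible(path)
}

#' Read and write PSSM TSV files
#'
#' Layout: a `position` column of chain+Chothia labels followed by 20
#' amino-acid columns in [AA20] order.
#'
#' @param path TSV file.
#' @param profile A [SequenceProfile-class].
#' @return `readPssmTsv`: a [SequenceProfile-class].
#' @export
readPssmTsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  if (!identical(names(df)[-1L], AA20))
    stop("PSSM columns must be 'position' then the 20 amino acids")
  probs <- as.matrix(df[, -1L])
  chain <- substr(df$position, 1L, 1L)
  new("SequenceProfile",
      positions = data.frame(chain = chain,
                             label = substring(df$position, 2L),
                             stringsAsFactors = FALSE),
      probs = probs)
}

#' @rdname readPssmTsv
#' @export
writePssmTsv <- function(profile, path) {
  pos <- paste0(profile@positions$chain, profile@positions$label)
  df <- data.frame(position = pos, profile@probs, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an FR-score table
#'
#' TSV with a `position` column (chain+label) and 20 amino-acid columns;
#' returns a numeric matrix with position rownames for [frScore()].
#'
#' @param path TSV file.
#' @return Numeric positions x 20 matrix.
#' @export
readFrTable <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1L])
  rownames(m) <- df$position
  m
}

#' Echo a run configuration to disk and read it back
#'
#' Plain-text lossless round trip of a [hallucinationConfig()] (written as
#' an R expression), so a run directory always carries the exact settings
#' that produced it.
#'
#' @param config A `"HallucinationConfig"`.
#' @param path Output file.
#' @export
writeRunConfig <- function(config, path) {
  dput(unclass(config), file = path)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  structure(dget(path), class = "HallucinationConfig")
}
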
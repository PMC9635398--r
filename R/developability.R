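## developability: instability index (full heavy chain), GRAVY over the
## padded design window, net charge of the full Fv.

## Kyte-Doolittle hydropathy values (Kyte & Doolittle 1982, J Mol Biol
## 157:105-132), alphabetical order.
KD_HYDROPATHY <- c(
  A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4, H = -3.2,
  I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5, P = -1.6, Q = -3.5,
  R = -4.5, S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3)

## EMBOSS pKa set used for the Henderson-Hasselbalch net charge.
EMBOSS_PKA <- list(
  positive = c(Nterm = 8.6, K = 10.8, R = 12.5, H = 6.5),
  negative = c(Cterm = 3.6, D = 3.9, E = 4.1, C = 8.5, Y = 10.1))

## DIWV dipeptide weights, loaded lazily from the bundled published table.
.diwvCache <- new.env(parent = emptyenv())

diwvTable <- function() {
  if (!exists("tab", envir = .diwvCache)) {
    path <- system.file("extdata", "diwv_guruprasad1990.tsv",
                        package = "FvDesign")
    raw <- utils::read.delim(path, comment.char = "#", row.names = 1L,
                             check.names = FALSE)
    assign("tab", as.matrix(raw), envir = .diwvCache)
  }
  get("tab", envir = .diwvCache)
}

#' Instability index of a protein sequence
#'
#' `II = (10/L) * sum over consecutive dipeptides of DIWV(x_i, x_{i+1})`
#' using the published dipeptide instability weight values of Guruprasad
#' et al. (1990). Values above 40 conventionally indicate an unstable
#' protein. For antibody designs the full heavy chain is the intended
#' input.
#'
#' @param seq Amino-acid sequence (length >= 2).
#' @return Scalar instability index.
#' @examples
#' instabilityIndex(strrep("A", 10))   # 9: nine A-A dipeptides
#' @export
instabilityIndex <- function(seq) {
  ch <- aaChars(seq)
  L <- length(ch)
  if (L < 2L) stop("instability index needs at least 2 residues")
  tab <- diwvTable()
  s <- sum(tab[cbind(ch[-L], ch[-1L])])
  10 * s / L
}

#' GRAVY score over the padded design window
#'
#' Mean Kyte-Doolittle hydropathy. With `designIdx` given, the window is
#' the designed stretch padded by `pad` residues on either side, clipped
#' at the chain boundaries (the convention used for design libraries);
#' without it, the whole sequence is scored.
#'
#' @param seq Amino-acid sequence (a chain, or a designed stretch alone).
#' @param designIdx Optional integer positions of the designed residues
#'   within `seq`.
#' @param pad Context residues added on each side (default 10).
#' @return Scalar GRAVY value.
#' @examples
#' gravyScore("AI")   # (1.8 + 4.5) / 2
#' @export
gravyScore <- function(seq, designIdx = NULL, pad = 10L) {
  ch <- aaChars(seq)
  if (!is.null(designIdx)) {
    lo <- max(1L, min(designIdx) - pad)
    hi <- min(length(ch), max(designIdx) + pad)
    ch <- ch[lo:hi]
  }
  if (length(ch) == 0L) stop("empty GRAVY window")
  mean(KD_HYDROPATHY[ch])
}

#' Net charge of a sequence at a given pH
#'
#' Henderson-Hasselbalch sum over the ionizable side chains (D, E, C, Y,
#' H, K, R) and the two termini, with the EMBOSS pKa set. For antibody
#' designs the full Fv sequence is the intended input.
#'
#' @param seq Amino-acid sequence.
#' @param pH Solution pH (default 7.0).
#' @param termini Include the N-/C-terminal groups (default TRUE).
#' @return Scalar net charge (elementary charges).
#' @export
netCharge <- function(seq, pH = 7.0, termini = TRUE) {
  ch <- aaChars(seq)
  counts <- table(factor(ch, levels = AA20))
  pos <- EMBOSS_PKA$positive
  neg <- EMBOSS_PKA$negative
  charge <- 0
  for (aa in c("K", "R", "H"))
    charge <- charge + counts[[aa]] / (1 + 10^(pH - pos[[aa]]))
  for (aa in c("D", "E", "C", "Y"))
    charge <- charge - counts[[aa]] / (1 + 10^(neg[[aa]] - pH))
  if (termini)
    charge <- charge + 1 / (1 + 10^(pH - pos[["Nterm"]])) -
      1 / (1 + 10^(neg[["Cterm"]] - pH))
  as.numeric(charge)
}

#' Developability report for a design library
#'
#' Sequence-level metrics per design: instability index of the full heavy
#' chain, GRAVY over the designed stretch padded by 10 residues, and net
#' charge of the full Fv at the given pH. Structure- and tool-dependent
#' metrics (solubility, aggregation propensity, MHC-II immunogenicity)
#' are external and not imitated here.
#'
#' @param records List of [DesignRecord-class] objects (or a single one).
#' @param region The [DesignRegion-class] used for the designs.
#' @param pH pH for the charge calculation.
#' @return `data.frame` with one row per design: id, designed,
#'   instability_index, gravy, net_charge.
#' @export
developabilityReport <- function(records, region, pH = 7.0) {
  if (is(records, "DesignRecord")) records <- list(records)
  rows <- lapply(seq_along(records), function(k) {
    r <- records[[k]]
    fv <- r@sequence
    heavy <- heavyChain(fv)
    nH <- nchar(heavy)
    d <- designPositions(region)
    ## GRAVY window lives on the chain carrying the design positions
    if (all(d <= nH)) {
      chainSeq <- heavy; idx <- d
    } else if (all(d > nH)) {
      chainSeq <- lightChain(fv); idx <- d - nH
    } else {
      chainSeq <- paste0(heavy, lightChain(fv)); idx <- d
    }
    data.frame(
      id = k, designed = r@designed,
      instability_index = instabilityIndex(heavy),
      gravy = gravyScore(chainSeq, designIdx = idx),
      net_charge = netCharge(paste0(heavy, lightChain(fv)), pH = pH),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
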
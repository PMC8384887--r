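#' @useDynLib mitorelax, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
NULL

# Cache for the codon state space (one genetic code per session is typical).
.mr_cache <- new.env(parent = emptyenv())

#' Vertebrate mitochondrial codon state space
#'
#' Builds the sense-codon state space of a genetic code: the ordered codon
#' set, their amino acids, the stop codons, and the pairwise accessibility
#' matrix used by the GY94 rate construction (which single-nucleotide
#' changes are synonymous/nonsynonymous transitions/transversions).
#'
#' The default code is the vertebrate mitochondrial code (NCBI table 2:
#' AGA/AGG are stops, ATA is Met, TGA is Trp), giving 60 sense codons.
#'
#' @param codeId Genetic code identifier understood by
#'   [Biostrings::getGeneticCode()]; default `"2"`.
#' @return A list with elements `codons` (character vector of sense codons),
#'   `aa` (named amino-acid vector), `stops`, `pairtype` (integer matrix:
#'   0 none/multi-nt, 1 syn transversion, 2 syn transition, 3 nonsyn
#'   transversion, 4 nonsyn transition) and `codeId`.
#' @examples
#' sp <- codonSpace()
#' length(sp$codons)  # 60 sense codons under the vertebrate mito code
#' @export
codonSpace <- function(codeId = "2") {
  key <- paste0("space_", codeId)
  if (!is.null(.mr_cache[[key]])) return(.mr_cache[[key]])
  gc <- Biostrings::getGeneticCode(codeId)
  bases <- c("T", "C", "A", "G")
  all64 <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  all64 <- sort(all64)
  aa_all <- gc[all64]
  stops <- all64[aa_all == "*"]
  codons <- all64[aa_all != "*"]
  aa <- aa_all[aa_all != "*"]
  names(aa) <- codons
  n <- length(codons)
  ts_pair <- function(x, y) {
    (x == "A" & y == "G") | (x == "G" & y == "A") |
    (x == "C" & y == "T") | (x == "T" & y == "C")
  }
  cm <- do.call(rbind, strsplit(codons, ""))
  pairtype <- matrix(0L, n, n)
  for (pos in 1:3) {
    same_other <- TRUE
    for (q in setdiff(1:3, pos)) {
      same_other <- same_other & outer(cm[, q], cm[, q], "==")
    }
    diff_pos <- outer(cm[, pos], cm[, pos], "!=")
    onechange <- same_other & diff_pos
    istrans <- outer(cm[, pos], cm[, pos], ts_pair)
    syn <- outer(aa, aa, "==")
    pairtype[onechange & syn & !istrans] <- 1L
    pairtype[onechange & syn & istrans] <- 2L
    pairtype[onechange & !syn & !istrans] <- 3L
    pairtype[onechange & !syn & istrans] <- 4L
  }
  dimnames(pairtype) <- list(codons, codons)
  out <- list(codons = codons, aa = aa, stops = stops,
              pairtype = pairtype, codeId = codeId)
  .mr_cache[[key]] <- out
  out
}

# Map codon strings to 1-based state indices (0 = unresolvable/missing).
.codonStates <- function(codons, space = codonSpace()) {
  idx <- match(codons, space$codons)
  idx[is.na(idx)] <- 0L
  idx
}
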
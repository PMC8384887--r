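#' Global pairwise alignment (Needleman-Wunsch, affine gaps)
#'
#' Optimal global alignment of two DNA strings under an affine gap scheme,
#' computed with [Biostrings::pairwiseAlignment()]. A gap of length `k`
#' costs `|gapOpen| + k * |gapExt|`. Defaults are match/mismatch/open/
#' extend = 1/-1/-5/-1; the identity percentages downstream depend on
#' these, so they are explicit and configurable.
#'
#' @param a,b DNA strings.
#' @param match,mismatch,gapOpen,gapExt scoring parameters (additive
#'   scores; gap parameters are negative).
#' @return List of class `"mrAlignment"`: gapped strings `a`, `b`, `score`
#'   and `params`.
#' @examples
#' globalAlign("ACGT", "AGT")$score
#' @export
globalAlign <- function(a, b, match = 1, mismatch = -1,
                        gapOpen = -5, gapExt = -1) {
  stopifnot(nchar(a) > 0, nchar(b) > 0)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = FALSE)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(toupper(a)), Biostrings::DNAString(toupper(b)),
    type = "global", substitutionMatrix = mat,
    gapOpening = abs(gapOpen), gapExtension = abs(gapExt))
  structure(list(
    a = as.character(Biostrings::alignedPattern(pa)),
    b = as.character(Biostrings::alignedSubject(pa)),
    score = Biostrings::score(pa),
    params = c(match = match, mismatch = mismatch,
               gapOpen = gapOpen, gapExt = gapExt)),
    class = "mrAlignment")
}

#' @export
print.mrAlignment <- function(x, ...) {
  cat(sprintf("Global alignment (score %.1f)\n  %s\n  %s\n",
              x$score, x$a, x$b))
  invisible(x)
}

#' Pairwise percent identity
#'
#' `100 * identical columns / columns where both rows are non-gap`
#' (pair-deletion: any column containing a gap is excluded from the
#' denominator).
#'
#' @param x an `"mrAlignment"` from [globalAlign()], or the first of two
#'   pre-aligned equal-length gapped strings.
#' @param y the second pre-aligned string when `x` is a string.
#' @return Percent identity (0-100).
#' @examples
#' pairwiseIdentity("ACGT", "ACGA")  # 75
#' @export
pairwiseIdentity <- function(x, y = NULL) {
  if (inherits(x, "mrAlignment")) { a <- x$a; b <- x$b } else { a <- x; b <- y }
  stopifnot(is.character(a), is.character(b), nchar(a) == nchar(b))
  ca <- strsplit(toupper(a), "")[[1]]
  cb <- strsplit(toupper(b), "")[[1]]
  ok <- ca != "-" & cb != "-"
  if (!any(ok)) stop("undefined identity: no gap-free columns")
  100 * sum(ca[ok] == cb[ok]) / sum(ok)
}

#' Per-gene identity matrix across genomes
#'
#' Extracts `gene` from every genome, globally aligns all pairs and fills
#' a symmetric percent-identity matrix (diagonal 100).
#'
#' @param gene canonical gene symbol.
#' @param genomes list of [Mitogenome-class] objects.
#' @param ... alignment parameters passed to [globalAlign()].
#' @return Symmetric numeric matrix with genome ids as dimnames.
#' @export
identityMatrix <- function(gene, genomes, ...) {
  ids <- vapply(genomes, genomeId, "")
  missing <- ids[!vapply(genomes, function(g)
    gene %in% featureTable(g)$name, TRUE)]
  if (length(missing))
    stop("gene '", gene, "' missing from: ", paste(missing, collapse = ", "))
  seqs <- lapply(genomes, extractGene, name = gene)
  n <- length(seqs)
  m <- diag(100, n)
  dimnames(m) <- list(ids, ids)
  if (n > 1) for (i in 1:(n - 1)) for (j in (i + 1):n) {
    idt <- pairwiseIdentity(globalAlign(seqs[[i]], seqs[[j]], ...))
    m[i, j] <- m[j, i] <- idt
  }
  m
}

# aligned input (DNAStringSet / named character / matrix) -> char matrix
.msaMatrix <- function(msa) {
  if (is.matrix(msa)) return(toupper(msa))
  s <- if (is.character(msa)) msa else as.character(msa)
  if (length(unique(nchar(s))) != 1L) stop("alignment rows differ in length")
  m <- do.call(rbind, strsplit(toupper(s), ""))
  rownames(m) <- names(s)
  m
}

# Shannon entropy (bits) of one alignment column over non-gap residues
.columnEntropy <- function(col) {
  col <- col[col %in% c("A", "C", "G", "T")]
  if (length(col) < 2L) return(0)
  p <- table(col) / length(col)
  -sum(p * log2(p))
}

#' Sliding-window entropy profile of an alignment
#'
#' Per-column Shannon entropy (bits; `-sum p log2 p` over non-gap
#' residues, columns with fewer than two non-gap residues contribute 0)
#' averaged within sliding windows. Window positions are reported at the
#' window center in 1-based alignment coordinates.
#'
#' @param msa aligned sequences ([Biostrings::DNAStringSet], named
#'   character vector, or character matrix).
#' @param window window size in columns (default 50).
#' @param step window step (default 1).
#' @return data.frame of class `"EntropyProfile"` with columns `position`
#'   and `entropy` (mean bits per column in the window).
#' @export
windowEntropy <- function(msa, window = 50L, step = 1L) {
  m <- .msaMatrix(msa)
  if (nrow(m) < 2L) stop("need at least two aligned sequences")
  L <- ncol(m)
  if (window > L) stop("window exceeds alignment length")
  colH <- apply(m, 2, .columnEntropy)
  starts <- seq(1L, L - window + 1L, by = step)
  cs <- c(0, cumsum(colH))
  meanH <- (cs[starts + window] - cs[starts]) / window
  out <- data.frame(position = starts + (window - 1) / 2, entropy = meanH)
  class(out) <- c("EntropyProfile", "data.frame")
  attr(out, "window") <- window
  attr(out, "step") <- step
  out
}

#' Count polymorphic sites per region
#'
#' A column is polymorphic when it carries at least two distinct non-gap
#' residues. Regions are 0-based half-open intervals on the alignment;
#' overlaps are allowed.
#'
#' @param haplotypes aligned haplotypes (any form accepted by
#'   [windowEntropy()]).
#' @param regions data.frame with columns `name`, `start`, `end`
#'   (0-based half-open); default one region covering the alignment.
#' @return data.frame with `name`, `start`, `end`, `polymorphic`.
#' @export
polymorphicSites <- function(haplotypes, regions = NULL) {
  m <- .msaMatrix(haplotypes)
  L <- ncol(m)
  if (is.null(regions))
    regions <- data.frame(name = "all", start = 0L, end = L)
  stopifnot(all(c("start", "end") %in% names(regions)))
  if (any(regions$start < 0L | regions$end > L | regions$end <= regions$start))
    stop("region out of alignment range")
  poly <- apply(m, 2, function(col) {
    r <- unique(col[col %in% c("A", "C", "G", "T")])
    length(r) >= 2L
  })
  regions$polymorphic <- vapply(seq_len(nrow(regions)), function(i)
    sum(poly[(regions$start[i] + 1L):regions$end[i]]), 0L)
  regions
}

#' Write an entropy profile as TSV
#'
#' @param profile an `"EntropyProfile"` from [windowEntropy()].
#' @param path output file with columns `position`, `entropy_bits`.
#' @return The path, invisibly.
#' @export
writeEntropyTSV <- function(profile, path) {
  utils::write.table(
    data.frame(position = profile$position, entropy_bits = profile$entropy),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an identity matrix as heatmap-ready TSV
#'
#' @param m matrix from [identityMatrix()].
#' @param path output file.
#' @return The path, invisibly.
#' @export
writeIdentityTSV <- function(m, path) {
  utils::write.table(cbind(id = rownames(m), as.data.frame(m)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
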
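#' Extract a gene's sense-strand sequence
#'
#' Returns the named feature's sequence; L-strand features are
#' reverse-complemented so the result is the coding/sense sequence. On a
#' circular record a feature may wrap the origin.
#'
#' @param genome a [Mitogenome-class].
#' @param name canonical gene symbol.
#' @return The sense-strand sequence as a character string.
#' @export
extractGene <- function(genome, name) {
  ft <- featureTable(genome)
  i <- which(ft$name == name)
  if (!length(i)) stop("lookup error: no feature named '", name, "'")
  f <- ft[i[1], ]
  seq <- as.character(genomeSeq(genome))
  len <- nchar(seq)
  s <- if (f$end <= len) substr(seq, f$start + 1L, f$end) else
    paste0(substr(seq, f$start + 1L, len), substr(seq, 1L, f$end - len))
  if (f$strand == "L")
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  s
}

.MITO_STOPS <- c("TAA", "TAG", "AGA", "AGG")

#' Translate a mitochondrial CDS
#'
#' Translation under the vertebrate mitochondrial code (AGA/AGG stop,
#' ATA = Met, TGA = Trp). With `completion = "polyA"` a terminal `T` or
#' `TA` is completed to `TAA` (the polyadenylation rescue of incomplete
#' stop codons). The terminal stop is not included in the protein.
#'
#' @param cds in-frame coding sequence (character string).
#' @param completion `"none"` or `"polyA"`.
#' @param codeId genetic code id.
#' @return The protein string. An internal stop raises a condition of
#'   class `"mrFrameshiftSuspect"` carrying the offending nucleotide
#'   `offset` (0-based).
#' @examples
#' translateMt("ATATGA")              # "MW": ATA=Met, TGA=Trp
#' translateMt("ATGAAAT", completion = "polyA")
#' @export
translateMt <- function(cds, completion = c("none", "polyA"), codeId = "2") {
  completion <- match.arg(completion)
  cds <- toupper(cds)
  if (completion == "polyA") {
    r <- nchar(cds) %% 3L
    if (r == 1L && substr(cds, nchar(cds), nchar(cds)) == "T")
      cds <- paste0(cds, "AA")
    else if (r == 2L && substr(cds, nchar(cds) - 1L, nchar(cds)) == "TA")
      cds <- paste0(cds, "A")
  }
  if (nchar(cds) < 3L) stop("CDS shorter than one codon")
  n <- nchar(cds) %/% 3L
  cod <- substring(cds, 3 * seq_len(n) - 2, 3 * seq_len(n))
  gc <- Biostrings::getGeneticCode(codeId)
  aa <- unname(gc[cod])
  aa[is.na(aa)] <- "X"
  stops <- which(aa == "*")
  if (length(stops) && any(stops < n)) {
    off <- (stops[stops < n][1] - 1L) * 3L
    stop(errorCondition(
      sprintf("internal stop codon at nucleotide offset %d (frameshift suspect)", off),
      class = c("mrFrameshiftSuspect", "error"), offset = off))
  }
  if (length(stops)) aa <- aa[-n]
  paste0(aa, collapse = "")
}

#' Classify a protein-coding gene's stop codon
#'
#' Classifies the terminal codon of a PCG as `complete` (TAA/TAG/AGA/AGG),
#' `truncated_TA` (CDS length = 2 mod 3 ending in `TA`) or `truncated_T`
#' (length = 1 mod 3 ending in `T`), the latter two being completed to TAA
#' by mRNA polyadenylation. Whether the CDS abuts the downstream feature
#' (the usual situation for truncated stops) is noted.
#'
#' @param genome a [Mitogenome-class].
#' @param gene PCG symbol.
#' @return List with `gene`, `status` (`complete`, `truncated_T`,
#'   `truncated_TA`, `unclassified`), `terminalCodon`, `abutsDownstream`.
#' @export
detectIncompleteStop <- function(genome, gene) {
  ft <- featureTable(genome)
  f <- ft[ft$name == gene, ]
  if (!nrow(f)) stop("lookup error: no feature named '", gene, "'")
  if (f$kind[1] != "PCG") stop("'", gene, "' is not a protein-coding gene")
  cds <- extractGene(genome, gene)
  r <- nchar(cds) %% 3L
  term <- substr(cds, nchar(cds) - 2L, nchar(cds))
  tail1 <- substr(cds, nchar(cds), nchar(cds))
  tail2 <- substr(cds, nchar(cds) - 1L, nchar(cds))
  status <- if (r == 0L && term %in% .MITO_STOPS) "complete"
    else if (r == 2L && tail2 == "TA") "truncated_TA"
    else if (r == 1L && tail1 == "T") "truncated_T"
    else "unclassified"
  # does the next feature start exactly where this one ends?
  dend <- if (f$strand[1] == "H") f$end[1] else f$start[1]
  abuts <- if (f$strand[1] == "H") any(ft$start == dend) else any(ft$end == dend)
  list(gene = gene, status = status,
       terminalCodon = if (r == 0L) term else substr(cds, nchar(cds) - r + 1L, nchar(cds)),
       abutsDownstream = abuts)
}

#' Detect a single-nucleotide frameshift in a CDS
#'
#' If the naive frame-0 translation hits a premature stop, searches all
#' single-nucleotide skip positions (the model of one inserted nucleotide
#' bypassed during translation) for the earliest skip that yields a
#' stop-free reading frame ending in a valid (possibly polyA-completable)
#' stop codon.
#'
#' @param cds in-frame coding sequence starting at its start codon.
#' @param codeId genetic code id.
#' @return List with `detected`, `skipPosition` (0-based offset of the
#'   skipped nucleotide, `NA` if none), `correctedProteinLength`, `note`.
#' @export
detectFrameshift <- function(cds, codeId = "2") {
  cds <- toupper(cds)
  gc <- Biostrings::getGeneticCode(codeId)
  premStop <- function(s) {
    n <- nchar(s) %/% 3L
    if (n < 1L) return(NA_integer_)
    cod <- substring(s, 3 * seq_len(n) - 2, 3 * seq_len(n))
    aa <- unname(gc[cod]); aa[is.na(aa)] <- "X"
    w <- which(aa == "*")
    if (length(w) && w[1] < n) w[1] else NA_integer_
  }
  endsValid <- function(s) {
    r <- nchar(s) %% 3L
    if (r == 0L)
      return(substr(s, nchar(s) - 2L, nchar(s)) %in% .MITO_STOPS)
    if (r == 1L) return(substr(s, nchar(s), nchar(s)) == "T")
    substr(s, nchar(s) - 1L, nchar(s)) == "TA"
  }
  first <- premStop(cds)
  if (is.na(first))
    return(list(detected = FALSE, skipPosition = NA_integer_,
                correctedProteinLength = NA_integer_,
                note = "naive reading frame is clean"))
  lim <- min(nchar(cds) - 1L, 3L * first - 1L)
  for (skip in 0:lim) {
    s2 <- paste0(substr(cds, 1L, skip), substr(cds, skip + 2L, nchar(cds)))
    if (is.na(premStop(s2)) && endsValid(s2)) {
      nprot <- nchar(s2) %/% 3L
      if (nchar(s2) %% 3L == 0L) nprot <- nprot - 1L  # drop terminal stop
      return(list(detected = TRUE, skipPosition = skip,
                  correctedProteinLength = nprot, note = ""))
    }
  }
  list(detected = FALSE, skipPosition = NA_integer_,
       correctedProteinLength = NA_integer_,
       note = "no single-nucleotide skip rescues the reading frame")
}

#' Gene-order signature of a mitogenome
#'
#' Rotation-normalized (circular) signature of the gene order: the ordered
#' `name:strand` list rotated to start at `trnF` by convention (falling
#' back to the lexicographically minimal rotation when `trnF` is absent).
#'
#' @param genome a [Mitogenome-class] with at least two features.
#' @return Character vector of `name:strand` entries.
#' @export
geneOrderSignature <- function(genome) {
  ft <- featureTable(genome)
  if (nrow(ft) < 2L) stop("need at least two features")
  sig <- paste0(ft$name, ":", ft$strand)
  k <- which(ft$name == "trnF")
  if (length(k)) {
    rot <- k[1]
  } else {
    rots <- vapply(seq_along(sig), function(i)
      paste(c(sig[i:length(sig)], sig[seq_len(i - 1)]), collapse = "|"), "")
    rot <- which.min(rank(rots, ties.method = "first"))
  }
  c(sig[rot:length(sig)], sig[seq_len(rot - 1)])
}

#' The ancestral avian gene order
#'
#' The reference gene order (chicken-like arrangement shared by most
#' birds), shipped as a data file, as `name:strand` entries starting at
#' `trnF`.
#'
#' @return Character vector of `name:strand` entries.
#' @export
ancestralAvianOrder <- function() {
  path <- system.file("extdata", "ancestral_avian_gene_order.tsv",
                      package = "mitorelax")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  paste0(tab$name, ":", tab$strand)
}

#' Compare a gene-order signature to a reference order
#'
#' @param signature output of [geneOrderSignature()].
#' @param reference reference signature; default [ancestralAvianOrder()].
#' @return List with `match` (logical), `firstMismatch` (index or `NA`) and
#'   the two signatures.
#' @export
compareGeneOrder <- function(signature, reference = ancestralAvianOrder()) {
  if (length(signature) != length(reference)) {
    return(list(match = FALSE, firstMismatch = NA_integer_,
                signature = signature, reference = reference))
  }
  neq <- which(signature != reference)
  list(match = !length(neq),
       firstMismatch = if (length(neq)) neq[1] else NA_integer_,
       signature = signature, reference = reference)
}

#' Write a gene-order signature as TSV
#'
#' @param signature output of [geneOrderSignature()].
#' @param path output file (columns `position`, `name`, `strand`;
#'   positions 1-based).
#' @return The path, invisibly.
#' @export
writeGeneOrderTSV <- function(signature, path) {
  parts <- do.call(rbind, strsplit(signature, ":"))
  utils::write.table(
    data.frame(position = seq_along(signature), name = parts[, 1],
               strand = parts[, 2]),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
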
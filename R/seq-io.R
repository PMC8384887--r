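#' Read / write FASTA
#'
#' Thin wrappers over Biostrings with the package's conventions (70-column
#' wrapping on output).
#'
#' @param path file path.
#' @return `readFasta`: a [Biostrings::DNAStringSet].
#' @export
readFasta <- function(path) Biostrings::readDNAStringSet(path)

#' @rdname readFasta
#' @param seqs a named character vector or [Biostrings::DNAStringSet].
#' @export
writeFasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path, width = 70L)
  invisible(path)
}

#' Read an in-frame codon alignment from FASTA or sequential PHYLIP
#'
#' @param path alignment file; format guessed from content (`>` = FASTA).
#' @param codeId genetic code id.
#' @return A [CodonAlignment-class].
#' @export
readCodonAlignment <- function(path, codeId = "2") {
  first <- readLines(path, n = 1L)
  if (startsWith(trimws(first), ">")) {
    seqs <- Biostrings::readDNAStringSet(path)
  } else {
    lines <- readLines(path)
    hdr <- scan(text = lines[1], what = integer(), n = 2, quiet = TRUE)
    body <- lines[-1][nzchar(trimws(lines[-1]))]
    nm <- sub("\\s.*$", "", trimws(body))
    sq <- gsub("\\s", "", sub("^\\S+\\s+", "", trimws(body)))
    if (length(nm) != hdr[1]) stop("PHYLIP taxon count mismatch")
    seqs <- Biostrings::DNAStringSet(stats::setNames(sq, nm))
  }
  CodonAlignment(seqs, codeId = codeId)
}

#' Write a codon alignment
#'
#' @param aln a [CodonAlignment-class].
#' @param path output file.
#' @param format `"fasta"` (70-column wrapped) or `"phylip"` (sequential).
#' @return The path, invisibly.
#' @export
writeCodonAlignment <- function(aln, path, format = c("fasta", "phylip")) {
  format <- match.arg(format)
  if (format == "fasta") return(writeFasta(alignedSeqs(aln), path))
  s <- as.character(alignedSeqs(aln))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("%d %d", length(s), nchar(s[1])), con)
  writeLines(sprintf("%-12s%s", names(s), s), con)
  invisible(path)
}
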
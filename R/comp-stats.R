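#' Base composition and strand skews
#'
#' Counts and frequencies of A/C/G/T (Ns excluded from the denominators)
#' plus AT skew `(A - T)/(A + T)` and GC skew `(G - C)/(G + C)`. Skews are
#' computed on the strand handed in: the deposited heavy strand for
#' genome scope, the sense strand for gene scope — which is what makes the
#' ND6 strand bias show up as a skew sign flip.
#'
#' @param seq DNA string over A,C,G,T,N.
#' @param scope free-text scope label (`"genome"` or a gene name).
#' @return List of class `"CompositionProfile"` with `counts`, `freqs`,
#'   `atSkew`, `gcSkew`, `scope`.
#' @examples
#' baseComposition("AATT")$atSkew  # 0
#' @export
baseComposition <- function(seq, scope = "genome") {
  s <- strsplit(toupper(as.character(seq)), "")[[1]]
  bad <- setdiff(unique(s), c("A", "C", "G", "T", "N"))
  if (length(bad))
    stop("ambiguity codes other than N are not supported: ",
         paste(bad, collapse = ", "))
  counts <- vapply(c(A = "A", C = "C", G = "G", T = "T"),
                   function(b) sum(s == b), 0L)
  tot <- sum(counts)
  if (tot == 0L) stop("undefined profile: sequence contains no A/C/G/T")
  freqs <- counts / tot
  atS <- if (counts["A"] + counts["T"] > 0)
    unname((counts["A"] - counts["T"]) / (counts["A"] + counts["T"])) else NA_real_
  gcS <- if (counts["G"] + counts["C"] > 0)
    unname((counts["G"] - counts["C"]) / (counts["G"] + counts["C"])) else NA_real_
  structure(list(counts = counts, freqs = freqs, atSkew = atS, gcSkew = gcS,
                 scope = scope), class = "CompositionProfile")
}

#' @export
print.CompositionProfile <- function(x, ...) {
  cat(sprintf("CompositionProfile [%s]: %s; AT skew %.3f, GC skew %.3f\n",
              x$scope,
              paste(sprintf("%s=%.1f%%", names(x$freqs), 100 * x$freqs),
                    collapse = " "),
              x$atSkew, x$gcSkew))
  invisible(x)
}

#' Relative synonymous codon usage
#'
#' Tallies codons over a set of in-frame CDSs (terminal stop codons are
#' dropped; internal stops are an error) and computes
#' `RSCU(c) = observed(c) / (family_total / family_size)` within each
#' synonymous family of the genetic code. Unused families get `NA`.
#'
#' @param cdsList list/vector of in-frame CDS strings.
#' @param codeId genetic code id (default vertebrate mitochondrial).
#' @return data.frame with columns `codon`, `aa`, `count`, `rscu`, grouped
#'   by amino acid.
#' @export
rscu <- function(cdsList, codeId = "2") {
  space <- codonSpace(codeId)
  counts <- stats::setNames(numeric(length(space$codons)), space$codons)
  for (cds in cdsList) {
    cds <- toupper(cds)
    if (nchar(cds) %% 3L != 0L)
      stop("CDS length not a multiple of 3; apply completion handling first")
    n <- nchar(cds) %/% 3L
    cod <- substring(cds, 3 * seq_len(n) - 2, 3 * seq_len(n))
    if (cod[n] %in% space$stops) cod <- cod[-n]
    if (any(cod %in% space$stops))
      stop("internal stop codon in CDS")
    cod <- cod[cod %in% space$codons]
    tab <- table(cod)
    counts[names(tab)] <- counts[names(tab)] + as.numeric(tab)
  }
  out <- data.frame(codon = space$codons, aa = unname(space$aa),
                    count = unname(counts))
  out <- out[order(out$aa, out$codon), ]
  fam_tot <- stats::ave(out$count, out$aa, FUN = sum)
  fam_size <- stats::ave(out$count, out$aa, FUN = length)
  out$rscu <- ifelse(fam_tot > 0, out$count / (fam_tot / fam_size), NA_real_)
  rownames(out) <- NULL
  attr(out, "codeId") <- codeId
  out
}

#' Amino-acid usage frequencies
#'
#' Translates each CDS with [translateMt()] and tallies amino-acid
#' frequencies (summing to one).
#'
#' @param cdsList list/vector of in-frame CDS strings.
#' @param completion stop-codon completion mode passed to [translateMt()].
#' @param codeId genetic code id.
#' @return Named numeric vector of amino-acid frequencies.
#' @export
aminoAcidUsage <- function(cdsList, completion = "none", codeId = "2") {
  aas <- unlist(lapply(cdsList, function(cds)
    strsplit(translateMt(cds, completion = completion, codeId = codeId), "")[[1]]))
  if (!length(aas)) stop("empty translation")
  tab <- table(aas)
  freqs <- stats::setNames(as.numeric(tab) / sum(tab), names(tab))
  sort(freqs, decreasing = TRUE)
}

#' Correlate two composition/skew vectors across genomes
#'
#' Pearson or Spearman correlation with a two-sided p-value between two
#' equal-length paired vectors (e.g. per-gene skews of two genomes). The
#' p-value uses the t approximation (Pearson) / large-sample approximation
#' (Spearman); for small n an exact permutation p-value is available.
#'
#' @param p1,p2 equal-length numeric vectors.
#' @param method `"pearson"` or `"spearman"`.
#' @param permute compute an exact permutation p-value (all n! orderings
#'   for n < 10) instead of the approximation.
#' @return List with `r` and `p.value`.
#' @export
compositionCorrelation <- function(p1, p2, method = c("pearson", "spearman"),
                                   permute = FALSE) {
  method <- match.arg(method)
  stopifnot(length(p1) == length(p2))
  if (stats::sd(p1) == 0 || stats::sd(p2) == 0)
    stop("undefined correlation: zero variance")
  ct <- suppressWarnings(stats::cor.test(p1, p2, method = method))
  p <- ct$p.value
  if (permute) {
    n <- length(p1)
    if (n >= 10) stop("exact permutation p-value limited to n < 10")
    perms <- .permutations(n)
    obs <- abs(stats::cor(p1, p2, method = method))
    vals <- apply(perms, 1, function(ix)
      abs(stats::cor(p1, p2[ix], method = method)))
    p <- mean(vals >= obs - 1e-12)
  }
  list(r = unname(ct$estimate), p.value = p)
}

.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Per-gene composition table of a mitogenome
#'
#' Convenience wrapper: [baseComposition()] for the whole genome (heavy
#' strand) and for every feature's sense strand.
#'
#' @param genome a [Mitogenome-class].
#' @param kinds feature kinds to include.
#' @return data.frame with one row per scope: frequencies and skews.
#' @export
compositionTable <- function(genome, kinds = c("PCG", "rRNA", "control_region")) {
  ft <- featureTable(genome)
  scopes <- c("genome", ft$name[ft$kind %in% kinds])
  rows <- lapply(scopes, function(sc) {
    prof <- if (sc == "genome") baseComposition(genomeSeq(genome), "genome")
      else baseComposition(extractGene(genome, sc), sc)
    data.frame(scope = sc, A = prof$freqs[["A"]], C = prof$freqs[["C"]],
               G = prof$freqs[["G"]], T = prof$freqs[["T"]],
               at_skew = prof$atSkew, gc_skew = prof$gcSkew)
  })
  do.call(rbind, rows)
}
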
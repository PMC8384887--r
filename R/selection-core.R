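#' Remove gapped or ambiguous codon columns
#'
#' Drops every codon column that contains a gap or a non-ACGT character in
#' any row. This is the complete-codon filter applied before model fitting;
#' block-based filtering of ambiguously aligned regions is expected to have
#' happened upstream.
#'
#' @param aln a [CodonAlignment-class].
#' @return A `CodonAlignment` with only clean columns; the number of removed
#'   columns is attached as attribute `removed`.
#' @examples
#' aln <- CodonAlignment(c(a = "ATGAAA", b = "ATG--A"))
#' nCodons(cleanCodonColumns(aln))
#' @export
cleanCodonColumns <- function(aln) {
  stopifnot(is(aln, "CodonAlignment"))
  m <- .alnMatrix(aln)
  nc <- ncol(m) %/% 3L
  keep <- logical(nc)
  for (k in seq_len(nc)) {
    block <- m[, (3 * k - 2):(3 * k), drop = FALSE]
    keep[k] <- all(block %in% c("A", "C", "G", "T"))
  }
  if (!any(keep)) stop("no codon columns left after cleaning")
  cols <- as.vector(t(outer(which(keep), 1:3, function(k, j) 3 * (k - 1) + j)))
  m2 <- m[, sort(cols), drop = FALSE]
  seqs <- apply(m2, 1, paste0, collapse = "")
  out <- CodonAlignment(stats::setNames(seqs, rownames(m)), codeId = aln@codeId)
  attr(out, "removed") <- sum(!keep)
  out
}

# alignment as a character matrix (rows = taxa)
.alnMatrix <- function(aln) {
  s <- as.character(alignedSeqs(aln))
  m <- do.call(rbind, strsplit(s, ""))
  rownames(m) <- taxa(aln)
  m
}

# codon strings per row: ntaxa x ncodons character matrix
.codonMatrix <- function(aln) {
  m <- .alnMatrix(aln)
  nc <- ncol(m) %/% 3L
  out <- matrix("", nrow(m), nc, dimnames = list(rownames(m), NULL))
  for (k in seq_len(nc))
    out[, k] <- paste0(m[, 3 * k - 2], m[, 3 * k - 1], m[, 3 * k])
  out
}

#' F3x4 codon equilibrium frequencies
#'
#' Estimates codon equilibrium frequencies from position-specific nucleotide
#' frequencies (the F3x4 convention): the frequency of a codon is the
#' product of its nucleotide frequencies at codon positions 1-3, with stop
#' codons removed and the remainder renormalized to sum to one.
#'
#' @param aln a [CodonAlignment-class]; gaps and Ns are ignored in the
#'   position counts.
#' @return Numeric vector of equilibrium frequencies named by sense codon.
#' @export
f3x4Frequencies <- function(aln) {
  stopifnot(is(aln, "CodonAlignment"))
  m <- .alnMatrix(aln)
  space <- codonSpace(aln@codeId)
  posfreq <- matrix(0, 3, 4, dimnames = list(NULL, c("T", "C", "A", "G")))
  for (p in 1:3) {
    cols <- seq(p, ncol(m), by = 3)
    v <- m[, cols]
    v <- v[v %in% c("A", "C", "G", "T")]
    if (!length(v)) stop("no unambiguous nucleotides at codon position ", p)
    tab <- table(factor(v, levels = c("T", "C", "A", "G")))
    posfreq[p, ] <- as.numeric(tab) / sum(tab)
  }
  cm <- do.call(rbind, strsplit(space$codons, ""))
  pi <- posfreq[1, cm[, 1]] * posfreq[2, cm[, 2]] * posfreq[3, cm[, 3]]
  if (sum(pi) <= 0)
    stop("all sense codons have zero F3x4 frequency; check the alignment")
  stats::setNames(pi / sum(pi), space$codons)
}

#' GY94 instantaneous rate matrix
#'
#' Builds the codon rate matrix with entries proportional to `pi_j` for a
#' synonymous transversion, `kappa*pi_j` for a synonymous transition,
#' `omega*pi_j` / `omega*kappa*pi_j` for nonsynonymous changes, and zero
#' for multi-nucleotide changes. The matrix is scaled so the expected
#' number of substitutions per codon site per unit time equals one.
#'
#' @param kappa transition/transversion rate ratio (> 0).
#' @param omega nonsynonymous/synonymous rate ratio.
#' @param pi sense-codon equilibrium frequencies (sum to 1); default
#'   uniform over the sense codons.
#' @param codeId genetic code id.
#' @param scale if `FALSE`, return the unscaled generator.
#' @return The rate matrix with the realized pre-scaling mean rate attached
#'   as attribute `rate`.
#' @export
buildQMatrix <- function(kappa, omega, pi = NULL, codeId = "2", scale = TRUE) {
  space <- codonSpace(codeId)
  n <- length(space$codons)
  if (is.null(pi)) pi <- rep(1 / n, n)
  stopifnot(length(pi) == n, abs(sum(pi) - 1) < 1e-6, kappa > 0, omega >= 0)
  res <- .codon_build_q_cpp(space$pairtype, pi, kappa, omega)
  Q <- res$Q
  if (scale && res$rate > 0) Q <- Q / res$rate
  dimnames(Q) <- list(space$codons, space$codons)
  attr(Q, "rate") <- res$rate
  Q
}

#' Codon transition probability matrix
#'
#' `expm(Q * t)` for a reversible codon generator, computed by
#' eigendecomposition of the pi-symmetrized form (with a
#' scaling-and-squaring fallback).
#'
#' @param Q rate matrix from [buildQMatrix()].
#' @param pi the equilibrium frequencies `Q` was built with.
#' @param t branch length (expected substitutions per codon site when `Q`
#'   is scaled).
#' @return The transition probability matrix.
#' @export
codonPmatrix <- function(Q, pi, t) {
  P <- .codon_pmat_cpp(unclass(Q), pi, t)
  dimnames(P) <- dimnames(Q)
  P
}

# Compress an alignment to site patterns against a codon space.
# Returns list(states = ntaxa x npat integer matrix, weights).
.sitePatterns <- function(aln, space = codonSpace(aln@codeId)) {
  cm <- .codonMatrix(aln)
  st <- matrix(.codonStates(cm, space), nrow(cm), ncol(cm),
               dimnames = dimnames(cm))
  key <- apply(st, 2, paste0, collapse = ",")
  u <- !duplicated(key)
  w <- as.numeric(table(factor(key, levels = key[u])))
  list(states = st[, u, drop = FALSE], weights = w)
}

# Internal mixture likelihood: omegas is C x G, props length C.
.mixtureLogLik <- function(patterns, tree, kappa, omegas, props, pi,
                           space, scaleFactor = -1) {
  phy <- treePhylo(tree)
  phy <- ape::reorder.phylo(phy, "postorder")
  # groups were assigned on the original edge order; remap
  ord <- match(paste(phy$edge[, 1], phy$edge[, 2]),
               paste(treePhylo(tree)$edge[, 1], treePhylo(tree)$edge[, 2]))
  groups <- edgeGroups(tree)[ord]
  tipidx <- match(phy$tip.label, rownames(patterns$states))
  if (anyNA(tipidx))
    stop("taxa missing from alignment: ",
         paste(phy$tip.label[is.na(tipidx)], collapse = ", "))
  tips <- patterns$states[tipidx, , drop = FALSE]
  .codon_loglik_cpp(tips, patterns$weights, phy$edge, phy$edge.length,
                    as.integer(groups), space$pairtype, pi, kappa,
                    rbind(omegas), props, scaleFactor)
}

#' Codon-model log-likelihood by Felsenstein pruning
#'
#' Computes the log-likelihood of a codon alignment on a labeled tree under
#' a (possibly mixture) GY94 model: per-branch transition matrices
#' `expm(Q*t)`, pruning over the 60 sense-codon states, site classes
#' marginalized per site, site log-likelihoods summed. Branch lengths are
#' interpreted as expected substitutions per codon site averaged over the
#' site classes on the background group.
#'
#' @param aln a [CodonAlignment-class] whose taxa match the tree tips.
#' @param tree a [LabeledTree-class].
#' @param kappa transition/transversion ratio.
#' @param omegas either a single omega, a vector (one per site class with
#'   `props`), or a class x group matrix for clade/branch-site structures.
#' @param props site-class proportions (default a single class).
#' @param pi sense-codon frequencies; default [f3x4Frequencies()] of `aln`.
#' @return The log-likelihood (numeric scalar) with per-site values in
#'   attribute `siteLnL`.
#' @export
codonLogLik <- function(aln, tree, kappa, omegas, props = NULL, pi = NULL) {
  stopifnot(is(aln, "CodonAlignment"), is(tree, "LabeledTree"))
  space <- codonSpace(aln@codeId)
  if (is.null(pi)) pi <- f3x4Frequencies(aln)
  if (is.null(dim(omegas))) {
    if (is.null(props)) props <- rep(1 / length(omegas), length(omegas))
    omegas <- matrix(rep(omegas, max(edgeGroups(tree))),
                     nrow = length(omegas))
  }
  if (is.null(props)) props <- rep(1 / nrow(omegas), nrow(omegas))
  stopifnot(nrow(omegas) == length(props))
  if (ncol(omegas) < max(edgeGroups(tree)))
    omegas <- omegas[, rep(1, max(edgeGroups(tree))), drop = FALSE]
  pat <- .sitePatterns(aln, space)
  res <- .mixtureLogLik(pat, tree, kappa, omegas, props, pi, space)
  if (!is.finite(res$lnL)) {
    bad <- which(!is.finite(res$site_lnL))[1]
    stop("non-finite likelihood at site pattern ", bad)
  }
  structure(res$lnL, siteLnL = res$site_lnL, scale = res$scale)
}
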
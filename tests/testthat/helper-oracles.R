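# Independent oracles used across the suite. These deliberately do not
# share code with the package implementations they check.

# Plain-R Gotoh affine-gap global alignment score. Convention matches the
# package's: a gap of length k costs |open| + k * |ext|.
gotohScore <- function(a, b, match = 1, mismatch = -1,
                       gapOpen = -5, gapExt = -1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  open <- abs(gapOpen); ext <- abs(gapExt)
  NEG <- -1e18
  M <- matrix(NEG, n + 1, m + 1)   # ends in match/mismatch
  X <- matrix(NEG, n + 1, m + 1)   # ends in gap in b (consume a)
  Y <- matrix(NEG, n + 1, m + 1)   # ends in gap in a (consume b)
  M[1, 1] <- 0
  for (i in seq_len(n) + 1) X[i, 1] <- -open - (i - 1) * ext
  for (j in seq_len(m) + 1) Y[1, j] <- -open - (j - 1) * ext
  for (i in seq_len(n) + 1) {
    for (j in seq_len(m) + 1) {
      s <- if (A[i - 1] == B[j - 1]) match else mismatch
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(X[i - 1, j] - ext,
                     max(M[i - 1, j], Y[i - 1, j]) - open - ext)
      Y[i, j] <- max(Y[i, j - 1] - ext,
                     max(M[i, j - 1], X[i, j - 1]) - open - ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Exhaustive tandem-array finder: every (start, unit, span) is checked
# directly for periodicity and maximality, then the same overlap
# resolution as the scanner (longer span, then smaller unit) is applied.
bruteStr <- function(seq, minUnit = 2, maxUnit = 10, minCopies = 3) {
  s <- strsplit(toupper(seq), "")[[1]]
  n <- length(s)
  minrot <- function(x) {
    ch <- strsplit(x, "")[[1]]
    min(vapply(seq_along(ch), function(i)
      paste0(c(ch[i:length(ch)], ch[seq_len(i - 1)]), collapse = ""), ""))
  }
  primPeriod <- function(x) {
    L <- nchar(x)
    for (d in seq_len(L %/% 2)) if (L %% d == 0 &&
        x == strrep(substr(x, 1, d), L / d)) return(d)
    L
  }
  cand <- list()
  for (u in minUnit:maxUnit) {
    for (st in 1:(n - u + 1)) {
      # longest stretch from st with period u
      len <- u
      while (st + len <= n && s[st + len] == s[st + len - u]) len <- len + 1
      if (len < u * minCopies) next
      # maximal to the left
      if (st > 1 && s[st - 1] == s[st - 1 + u]) next
      unit <- paste0(s[st:(st + u - 1)], collapse = "")
      d <- primPeriod(unit)
      if (d < u && d >= minUnit) next
      cand[[length(cand) + 1]] <- data.frame(
        unit = minrot(unit), unitAsFound = unit,
        copies = len %/% u, partial = len %% u,
        start = st - 1, end = st - 1 + len)
    }
  }
  if (!length(cand))
    return(data.frame(unit = character(), unitAsFound = character(),
                      copies = integer(), partial = integer(),
                      start = integer(), end = integer()))
  cand <- do.call(rbind, cand)
  cand <- cand[cand$copies >= minCopies, , drop = FALSE]
  cand$span <- cand$end - cand$start
  cand <- cand[order(-cand$span, nchar(cand$unit), cand$start), ]
  keep <- rep(FALSE, nrow(cand)); occ <- rep(FALSE, n)
  for (i in seq_len(nrow(cand))) {
    idx <- (cand$start[i] + 1):cand$end[i]
    if (!any(occ[idx])) { keep[i] <- TRUE; occ[idx] <- TRUE }
  }
  out <- cand[keep, c("unit", "unitAsFound", "copies", "partial",
                      "start", "end")]
  out <- out[order(out$start), ]
  rownames(out) <- NULL
  out
}

# Exhaustive inverted-repeat scan: all (arm-end, loop) pairs with maximal
# outward extension, same ranking and greedy selection as the scanner.
bruteHairpin <- function(seq, minStem = 6, maxLoop = 30) {
  s <- strsplit(toupper(seq), "")[[1]]
  n <- length(s)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  sc <- function(x, y) sum(3 * ((x == "G" & y == "C") | (x == "C" & y == "G")) +
                           2 * ((x == "A" & y == "T") | (x == "T" & y == "A")))
  cand <- list()
  for (i in 1:n) for (l in 3:maxLoop) {
    j <- i + l + 1
    if (j > n) next
    k <- 0
    while (i - k >= 1 && j + k <= n && !is.na(comp[s[i - k]]) &&
           comp[s[i - k]] == s[j + k]) k <- k + 1
    if (k < minStem) next
    cand[[length(cand) + 1]] <- data.frame(
      stemStart5p = i - k, stemLen = k, loopLen = l, stemStart3p = j - 1,
      score = sc(s[(i - k + 1):i], rev(s[j:(j + k - 1)])))
  }
  if (!length(cand))
    return(data.frame(stemStart5p = integer(), stemLen = integer(),
                      loopLen = integer(), stemStart3p = integer(),
                      score = integer()))
  cand <- unique(do.call(rbind, cand))
  cand <- cand[order(-cand$score, cand$stemStart5p, cand$loopLen), ]
  keep <- rep(FALSE, nrow(cand)); occ <- rep(FALSE, n)
  for (r in seq_len(nrow(cand))) {
    idx <- (cand$stemStart5p[r] + 1):(cand$stemStart3p[r] + cand$stemLen[r])
    if (!any(occ[idx])) { keep[r] <- TRUE; occ[idx] <- TRUE }
  }
  out <- cand[keep, ]
  out <- out[order(out$stemStart5p), ]
  rownames(out) <- NULL
  out
}

# Brute-force codon-model likelihood: explicit sum over all internal-state
# assignments with per-branch matrix exponentials from Matrix::expm.
enumLogLik <- function(aln, phy, kappa, omega, pi) {
  space <- codonSpace()
  Q <- buildQMatrix(kappa, omega, pi)
  Ps <- lapply(phy$edge.length, function(t)
    as.matrix(Matrix::expm(unclass(Q) * t)))
  cm <- vapply(as.character(alignedSeqs(aln)), function(s) {
    n <- nchar(s) %/% 3
    substring(s, 3 * seq_len(n) - 2, 3 * seq_len(n))
  }, character(nchar(as.character(alignedSeqs(aln)[[1]])) %/% 3))
  cm <- matrix(cm, ncol = length(aln@seqs),
               dimnames = list(NULL, names(alignedSeqs(aln))))
  ntip <- length(phy$tip.label)
  internals <- (ntip + 1):(ntip + phy$Nnode)
  grid <- do.call(expand.grid, rep(list(seq_along(space$codons)),
                                   length(internals)))
  names(grid) <- as.character(internals)
  root <- setdiff(phy$edge[, 1], phy$edge[, 2])
  total <- 0
  for (site in seq_len(nrow(cm))) {
    tipstate <- match(cm[site, phy$tip.label], space$codons)
    L <- pi[grid[[as.character(root)]]]
    for (e in seq_len(nrow(phy$edge))) {
      pa <- phy$edge[e, 1]; ch <- phy$edge[e, 2]
      pstate <- grid[[as.character(pa)]]
      cstate <- if (ch <= ntip) rep(tipstate[ch], nrow(grid)) else
        grid[[as.character(ch)]]
      L <- L * Ps[[e]][cbind(pstate, cstate)]
    }
    total <- total + log(sum(L))
  }
  total
}

# random rooted tree with branch lengths for the likelihood oracle
randomOracleTree <- function(ntips) {
  phy <- ape::rtree(ntips, rooted = TRUE,
                    br = function(n) stats::runif(n, 0.05, 0.6))
  phy$tip.label <- paste0("t", seq_len(ntips))
  phy
}

# random codon alignment rows (sense codons only), not evolved - the
# likelihood must be correct for arbitrary data
randomCodonRows <- function(taxa, ncodons) {
  space <- codonSpace()
  rows <- vapply(taxa, function(x)
    paste0(sample(space$codons, ncodons, replace = TRUE), collapse = ""), "")
  CodonAlignment(rows)
}

# random equilibrium frequencies (Dirichlet-ish, strictly positive)
randomPi <- function() {
  x <- stats::rgamma(60, shape = 5) + 0.05
  x / sum(x)
}
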
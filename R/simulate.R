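# Seeded generators for every stage: annotated mitogenomes with planted
# control-region elements, codon alignments evolved under branch/clade/site
# omega regimes, and intraspecific CR haplotype sets. Every generator
# returns a machine-readable truth record of what it planted.

# run expr under a fixed seed without disturbing the caller's RNG stream
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else if (exists(".Random.seed", .GlobalEnv))
            rm(".Random.seed", envir = .GlobalEnv))
  set.seed(seed)
  force(expr)
}

.sampleBases <- function(n, freqs) {
  sample(names(freqs), n, replace = TRUE, prob = freqs)
}

# instantiate an IUPAC consensus into a concrete sequence
.instantiateIUPAC <- function(pattern) {
  ch <- strsplit(toupper(pattern), "")[[1]]
  paste0(vapply(ch, function(x) {
    opts <- .IUPAC[[x]]
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, ""), collapse = "")
}

#' Specification for a synthetic avian mitogenome
#'
#' Bundles the layout a [simulateMitogenome()] run realizes: the ancestral
#' avian gene order, per-gene lengths, strand assignments, strand-specific
#' base-composition targets, the three-domain control-region layout with
#' planted conserved blocks, poly-C tract with TA island, STR array and
#' hairpin, plus the incomplete-stop and frameshift plants.
#'
#' Defaults emulate a condor-like record: heavy-strand composition target
#' A/C/G/T = 0.31/0.32/0.13/0.23, light-strand-sense genes C+G enriched,
#' truncated (polyadenylation-completed) stops in COX3/ND4/CYTB, a
#' single-nucleotide insertion in ND3, a 1214-bp CR with domains of
#' 400/500/314 nt and an AACAAAC x 20 repeat array in domain III.
#'
#' @param crStrCopies copies of the AACAAAC repeat unit (default 20).
#' @param frameshiftGene,frameshiftOffset gene carrying the planted
#'   insertion and its 0-based offset (`NULL` gene disables the plant).
#'   The offset must be mid-codon (`offset %% 3 == 1`) so the realized
#'   insertion is recoverable as the earliest rescuing skip.
#' @param seed generator seed.
#' @return List of class `"MitogenomeSpec"`.
#' @export
mitogenomeSpec <- function(crStrCopies = 20L, frameshiftGene = "ND3",
                           frameshiftOffset = 175L, seed = 1L) {
  order <- ancestralAvianOrder()
  parts <- do.call(rbind, strsplit(order, ":"))
  pcgs <- c(ND1 = 978L, ND2 = 1038L, COX1 = 1551L, COX2 = 684L,
            ATP8 = 168L, ATP6 = 684L, COX3 = 784L, ND3 = 351L,
            ND4L = 297L, ND4 = 1378L, ND5 = 1818L, CYTB = 1144L,
            ND6 = 519L)
  crLayout <- list(
    domI = 400L, domII = 500L, domIII = 314L,
    polyC = list(start = 60L, len = 14L, islandOffset = 6L, islandLen = 4L),
    motifAt = c(ETAS1 = 200L, FBOX = 400L, EBOX = 470L, DBOX = 540L,
                CBOX = 610L, CSBA = 680L, CSBB = 750L, BIRDBOX = 820L,
                CSB1 = 900L),
    str = list(unit = "AACAAAC", copies = as.integer(crStrCopies),
               start = 960L),
    hairpin = list(start5p = 1150L, stemLen = 8L, loopLen = 5L))
  structure(list(
    order = data.frame(name = parts[, 1], strand = parts[, 2]),
    pcgLengths = pcgs,
    rrnLengths = c(rrnS = 975L, rrnL = 1590L),
    trnLengthRange = c(66L, 74L),
    compositionH = c(A = 0.31, C = 0.32, G = 0.13, T = 0.23),
    compositionLsense = c(A = 0.23, C = 0.16, G = 0.35, T = 0.26),
    truncated = c(COX3 = "truncated_T", ND4 = "truncated_T",
                  CYTB = "truncated_T"),
    frameshiftGene = frameshiftGene,
    frameshiftOffset = as.integer(frameshiftOffset),
    crLayout = crLayout,
    seed = as.integer(seed)), class = "MitogenomeSpec")
}

# codon frequencies from nucleotide targets, stops excluded
.codonFreqsFromBases <- function(freqs, space = codonSpace()) {
  cm <- do.call(rbind, strsplit(space$codons, ""))
  p <- freqs[cm[, 1]] * freqs[cm[, 2]] * freqs[cm[, 3]]
  stats::setNames(p / sum(p), space$codons)
}

# ATG + nBody random sense codons + terminal
.randomCDS <- function(nBody, codonFreqs, terminal = "TAA") {
  body <- sample(names(codonFreqs), nBody, replace = TRUE,
                 prob = codonFreqs)
  paste0("ATG", paste0(body, collapse = ""), terminal)
}

#' Simulate an annotated mitogenome with planted truth
#'
#' Realizes a [mitogenomeSpec()]: 37 genes plus control region in the
#' ancestral avian order, strand-specific composition bias (light-strand
#' genes drawn from a C+G-enriched sense target), truncated stop codons
#' abutting their downstream features, a single-nucleotide insertion
#' planted in the frameshift gene (re-drawn until the earliest rescuing
#' skip equals the planted offset), and a control region carrying every
#' planted element at known coordinates.
#'
#' @param spec a `"MitogenomeSpec"` from [mitogenomeSpec()].
#' @return List with `genome` (a [Mitogenome-class]) and `truth` (planted
#'   coordinates and properties; positions 0-based).
#' @examples
#' sim <- simulateMitogenome(mitogenomeSpec(seed = 7))
#' sim$genome
#' @export
simulateMitogenome <- function(spec = mitogenomeSpec()) {
  stopifnot(inherits(spec, "MitogenomeSpec"))
  .withSeed(spec$seed, {
    space <- codonSpace()
    cfH <- .codonFreqsFromBases(spec$compositionH, space)
    cfL <- .codonFreqsFromBases(spec$compositionLsense, space)
    lay <- spec$crLayout
    crLen <- lay$domI + lay$domII + lay$domIII

    geneSeq <- function(name, strand) {
      freqs <- if (strand == "H") spec$compositionH else spec$compositionLsense
      cf <- if (strand == "H") cfH else cfL
      if (name %in% names(spec$pcgLengths)) {
        len <- spec$pcgLengths[[name]]
        if (name %in% names(spec$truncated)) {
          stopifnot(len %% 3L == 1L)
          return(.randomCDS((len - 4L) %/% 3L, cf, terminal = "T"))
        }
        stopifnot(len %% 3L == 0L)
        return(.randomCDS(len %/% 3L - 2L, cf, terminal = "TAA"))
      }
      if (name %in% names(spec$rrnLengths))
        return(paste0(.sampleBases(spec$rrnLengths[[name]], freqs),
                      collapse = ""))
      if (name == "CR") return(NA_character_)  # built separately
      len <- sample(spec$trnLengthRange[1]:spec$trnLengthRange[2], 1L)
      paste0(.sampleBases(len, freqs), collapse = "")
    }

    # control region with planted elements
    buildCR <- function() {
      s <- .sampleBases(crLen, spec$compositionH)
      put <- function(s, at, frag) {
        ch <- strsplit(frag, "")[[1]]
        s[(at + 1L):(at + length(ch))] <- ch
        s
      }
      pc <- lay$polyC
      tract <- c(rep("C", pc$islandOffset),
                 rep(c("T", "A"), pc$islandLen %/% 2L),
                 rep("C", pc$len - pc$islandOffset - pc$islandLen))
      s <- put(s, pc$start, paste0(tract, collapse = ""))
      s[pc$start] <- "A"; s[pc$start + pc$len + 1L] <- "A"  # cap the tract
      lib <- motifLibrary()
      motifSeqs <- list()
      for (nm in names(lay$motifAt)) {
        pat <- lib$pattern[lib$name == nm]
        inst <- .instantiateIUPAC(pat)
        motifSeqs[[nm]] <- inst
        s <- put(s, lay$motifAt[[nm]], inst)
      }
      u <- lay$str$unit
      arr <- strrep(u, lay$str$copies)
      s <- put(s, lay$str$start, arr)
      s[lay$str$start] <- "G"                       # block left extension
      s[lay$str$start + 1L + nchar(arr)] <- "G"     # block right extension
      hp <- lay$hairpin
      arm1 <- sample(c("G", "C"), hp$stemLen, replace = TRUE)
      arm2 <- rev(chartr("GC", "CG", arm1))
      loop <- rep("T", hp$loopLen)
      frag <- c("A", arm1, loop, arm2, "A")
      s <- put(s, hp$start5p - 1L, paste0(frag, collapse = ""))
      list(seq = paste0(s, collapse = ""), motifSeqs = motifSeqs)
    }

    # Plant the insertion so the planted offset is provably the earliest
    # rescuing skip. The insertion point p is mid-codon (p = 1 mod 3), the
    # inserted base is T and the two bases after it are set to AA: in the
    # reading produced by skipping ANY position before p, the inserted T
    # lands at a codon start and reads TAA, so no earlier skip can give a
    # stop-free frame; skipping p itself restores the clean original.
    plantFrameshift <- function(cds) {
      p <- spec$frameshiftOffset
      stopifnot(p %% 3L == 1L, p >= 3L, p + 90L < nchar(cds))
      for (attempt in 1:60) {
        ch <- strsplit(cds, "")[[1]]
        if (ch[p] == "T") ch[p] <- "C"       # keep frame 0 stop-free
        ch[p + 1L] <- "A"; ch[p + 2L] <- "A"
        mut <- paste0(c(ch[seq_len(p)], "T", ch[(p + 1L):length(ch)]),
                      collapse = "")
        det <- detectFrameshift(mut)
        if (isTRUE(det$detected) && det$skipPosition == p) return(mut)
        cds <- .randomCDS(nchar(cds) %/% 3L - 2L, cfH, terminal = "TAA")
      }
      stop("could not plant a recoverable frameshift")
    }

    cr <- buildCR()
    pieces <- character(); feats <- list(); pos <- 0L
    for (i in seq_len(nrow(spec$order))) {
      nm <- spec$order$name[i]; strand <- spec$order$strand[i]
      if (nm == "CR") {
        sseq <- cr$seq
      } else {
        sseq <- geneSeq(nm, strand)
        if (!is.null(spec$frameshiftGene) && nm == spec$frameshiftGene)
          sseq <- plantFrameshift(sseq)
      }
      genomic <- if (strand == "L")
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(sseq)))
        else sseq
      pieces <- c(pieces, genomic)
      kind <- if (nm %in% names(spec$pcgLengths)) "PCG"
        else if (nm %in% names(spec$rrnLengths)) "rRNA"
        else if (nm == "CR") "control_region" else "tRNA"
      feats[[i]] <- data.frame(name = nm, kind = kind, start = pos,
                               end = pos + nchar(genomic), strand = strand,
                               notes = "")
      pos <- pos + nchar(genomic)
    }
    features <- do.call(rbind, feats)
    genome <- Mitogenome(id = sprintf("SYN%07d", spec$seed),
                         sequence = paste0(pieces, collapse = ""),
                         features = features, circular = TRUE,
                         sourceTaxon = "synthetic condor-like mitogenome")
    crStart <- features$start[features$name == "CR"]
    truth <- list(
      seed = spec$seed,
      features = features,
      stopStatuses = spec$truncated,
      frameshift = if (is.null(spec$frameshiftGene)) NULL else
        list(gene = spec$frameshiftGene, offset = spec$frameshiftOffset),
      crStart = crStart, crLength = crLen,
      crLayout = spec$crLayout,
      motifSeqs = cr$motifSeqs,
      compositionH = spec$compositionH,
      compositionLsense = spec$compositionLsense)
    list(genome = genome, truth = truth)
  })
}

#' Default balanced two-clade simulation tree
#'
#' A rooted, balanced tree with two clades of `nPerClade` tips each;
#' clade-two edges (stem included) are labeled `target`, the rest are
#' background. Used as the default topology for codon simulations.
#'
#' @param nPerClade tips per clade (default 3).
#' @param tipLength terminal branch lengths (substitutions/codon).
#' @param internalLength internal branch lengths.
#' @return A [LabeledTree-class].
#' @export
balancedCladeTree <- function(nPerClade = 3L, tipLength = 0.3,
                              internalLength = 0.15) {
  clade <- function(tips) {
    s <- sprintf("%s:%g", tips[1], tipLength)
    for (t in tips[-1])
      s <- sprintf("(%s,%s:%g):%g", s, t, tipLength, internalLength)
    s
  }
  t1 <- paste0("sp", seq_len(nPerClade))
  t2 <- paste0("sp", nPerClade + seq_len(nPerClade))
  txt <- sprintf("(%s:%g,%s:%g);", clade(t1), internalLength,
                 clade(t2), internalLength)
  phy <- ape::read.tree(text = txt)
  labelClade(LabeledTree(phy), t2, "target", includeStem = TRUE)
}

#' Specification for a simulated codon alignment
#'
#' @param tree a [LabeledTree-class]; default [balancedCladeTree()].
#' @param kappa transition/transversion ratio (default 2).
#' @param pi sense-codon frequencies (default uniform over the 60 sense
#'   codons of the vertebrate mito code).
#' @param omegas scalar, per-class vector, or class x group matrix of
#'   omega values (columns follow the tree's groups).
#' @param props site-class proportions (default single class).
#' @param nCodons alignment length in codons.
#' @param seed generator seed.
#' @param codeId genetic code id.
#' @return List of class `"CodonSimSpec"`.
#' @export
codonSimSpec <- function(tree = balancedCladeTree(), kappa = 2,
                         pi = NULL, omegas = 0.2, props = NULL,
                         nCodons = 300L, seed = 1L, codeId = "2") {
  space <- codonSpace(codeId)
  if (is.null(pi)) pi <- stats::setNames(rep(1 / length(space$codons),
                                             length(space$codons)),
                                         space$codons)
  G <- max(edgeGroups(tree))
  if (is.null(dim(omegas))) {
    if (is.null(props)) props <- rep(1 / length(omegas), length(omegas))
    omegas <- matrix(rep(omegas, G), nrow = length(omegas))
  }
  if (is.null(props)) props <- rep(1 / nrow(omegas), nrow(omegas))
  stopifnot(nrow(omegas) == length(props), abs(sum(props) - 1) < 1e-8,
            ncol(omegas) == G || ncol(omegas) == 1L)
  if (ncol(omegas) == 1L && G > 1L)
    omegas <- omegas[, rep(1L, G), drop = FALSE]
  structure(list(tree = tree, kappa = kappa, pi = pi, omegas = omegas,
                 props = props, nCodons = as.integer(nCodons),
                 seed = as.integer(seed), codeId = codeId),
            class = "CodonSimSpec")
}

#' Simulate a codon alignment along a labeled tree
#'
#' Draws each site's class from the mixture, the root state from the
#' equilibrium frequencies, and each child state from `expm(Q t)` along
#' every branch, with the branch's group selecting the omega of the
#' site's class. The state space contains only sense codons, so no stop
#' codon is ever emitted. Branch lengths are expected substitutions per
#' codon averaged over classes on the background group (matching the
#' likelihood engine's convention).
#'
#' @param spec a `"CodonSimSpec"` from [codonSimSpec()].
#' @return List with `alignment` (a [CodonAlignment-class]), `tree`, and
#'   `truth` (site classes and all generating parameters).
#' @export
simulateCodonAlignment <- function(spec = codonSimSpec()) {
  stopifnot(inherits(spec, "CodonSimSpec"))
  .withSeed(spec$seed, {
    space <- codonSpace(spec$codeId)
    n <- length(space$codons)
    tree <- spec$tree
    phy <- ape::reorder.phylo(treePhylo(tree), "postorder")
    ord <- match(paste(phy$edge[, 1], phy$edge[, 2]),
                 paste(treePhylo(tree)$edge[, 1], treePhylo(tree)$edge[, 2]))
    groups <- edgeGroups(tree)[ord]
    C <- nrow(spec$omegas); G <- ncol(spec$omegas)
    rates <- matrix(0, C, G)
    Qs <- vector("list", C * G)
    for (c in seq_len(C)) for (g in seq_len(G)) {
      Q <- buildQMatrix(spec$kappa, spec$omegas[c, g], spec$pi,
                        codeId = spec$codeId, scale = FALSE)
      rates[c, g] <- attr(Q, "rate")
      Qs[[(c - 1) * G + g]] <- unclass(Q)
    }
    f <- sum(spec$props * rates[, 1])
    classes <- sample.int(C, spec$nCodons, replace = TRUE, prob = spec$props)
    ntip <- length(phy$tip.label)
    nnode <- max(phy$edge)
    states <- matrix(0L, nnode, spec$nCodons)
    root <- phy$edge[nrow(phy$edge), 1]
    states[root, ] <- sample.int(n, spec$nCodons, replace = TRUE,
                                 prob = spec$pi)
    # preorder: reverse postorder
    for (e in rev(seq_len(nrow(phy$edge)))) {
      par <- phy$edge[e, 1]; child <- phy$edge[e, 2]
      g <- groups[e]; t <- phy$edge.length[e]
      for (c in seq_len(C)) {
        sites <- which(classes == c)
        if (!length(sites)) next
        P <- .codon_pmat_cpp(Qs[[(c - 1) * G + g]] / f, spec$pi, t)
        ps <- states[par, sites]
        for (s in unique(ps)) {
          ix <- sites[ps == s]
          states[child, ix] <- sample.int(n, length(ix), replace = TRUE,
                                          prob = P[s, ])
        }
      }
    }
    rows <- vapply(seq_len(ntip), function(i)
      paste0(space$codons[states[i, ]], collapse = ""), "")
    names(rows) <- phy$tip.label
    aln <- CodonAlignment(rows, codeId = spec$codeId)
    truth <- list(seed = spec$seed, kappa = spec$kappa,
                  omegas = spec$omegas, props = spec$props,
                  siteClasses = classes, scale = f,
                  groupNames = groupNames(tree))
    list(alignment = aln, tree = tree, truth = truth)
  })
}

#' Simulate intraspecific control-region haplotypes
#'
#' Mutates a reference CR into `n` haplotypes with domain-specific
#' substitution processes. Two modes: per-domain per-site mutation
#' `rates` (each haplotype substitutes independently), or
#' `plantedSites` — an exact number of segregating sites per domain
#' (each planted site gets an alternate base in a random non-empty,
#' proper subset of haplotypes). Indels are not modeled, so the output
#' is an alignment.
#'
#' @param reference reference CR sequence (string).
#' @param domains data.frame with `name`, `start`, `end` (0-based
#'   half-open).
#' @param rates named per-domain mutation probabilities.
#' @param plantedSites named per-domain exact segregating-site counts.
#' @param n number of haplotypes.
#' @param seed generator seed.
#' @return List with `haplotypes` (a [Biostrings::DNAStringSet]) and
#'   `truth` (per-domain segregating-site counts and mutated positions).
#' @export
simulateCRHaplotypes <- function(reference, domains, rates = NULL,
                                 plantedSites = NULL, n = 10L, seed = 1L) {
  stopifnot(xor(is.null(rates), is.null(plantedSites)))
  .withSeed(seed, {
    ref <- strsplit(toupper(as.character(reference)), "")[[1]]
    L <- length(ref)
    stopifnot(all(domains$end <= L), all(domains$start >= 0))
    haps <- matrix(rep(ref, n), nrow = n, byrow = TRUE)
    bases <- c("A", "C", "G", "T")
    mutated <- integer()
    if (!is.null(rates)) {
      for (d in seq_len(nrow(domains))) {
        rate <- rates[[domains$name[d]]]
        if (is.null(rate) || rate <= 0) next
        cols <- (domains$start[d] + 1L):domains$end[d]
        for (j in cols) {
          hit <- which(stats::runif(n) < rate)
          if (!length(hit)) next
          for (h in hit) haps[h, j] <- sample(setdiff(bases, haps[h, j]), 1L)
          mutated <- c(mutated, j - 1L)
        }
      }
    } else {
      for (d in seq_len(nrow(domains))) {
        k <- plantedSites[[domains$name[d]]]
        if (is.null(k) || k <= 0) next
        cols <- sample((domains$start[d] + 1L):domains$end[d], k)
        for (j in cols) {
          alt <- sample(setdiff(bases, ref[j]), 1L)
          carriers <- sample.int(n, sample.int(n - 1L, 1L))
          haps[carriers, j] <- alt
          mutated <- c(mutated, j - 1L)
        }
      }
    }
    seqs <- apply(haps, 1, paste0, collapse = "")
    names(seqs) <- sprintf("hap%02d", seq_len(n))
    segPerDomain <- vapply(seq_len(nrow(domains)), function(d) {
      cols <- (domains$start[d] + 1L):domains$end[d]
      sum(vapply(cols, function(j) length(unique(haps[, j])) >= 2L, TRUE))
    }, 0L)
    names(segPerDomain) <- domains$name
    list(haplotypes = Biostrings::DNAStringSet(seqs),
         truth = list(seed = seed, segregatingSites = segPerDomain,
                      mutatedPositions = sort(unique(mutated))))
  })
}
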
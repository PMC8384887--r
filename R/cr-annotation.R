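# Control-region annotation: conserved-block motif scanning, poly-tracts,
# short tandem repeats, hairpin candidates and the three-domain partition.
# All in-memory coordinates are 0-based half-open on the CR.

.IUPAC <- list(A = "A", C = "C", G = "G", T = "T",
               R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
               W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
               B = c("C", "G", "T"), D = c("A", "G", "T"),
               H = c("A", "C", "T"), V = c("A", "C", "G"),
               N = c("A", "C", "G", "T"))

#' Find a degenerate motif with mismatches
#'
#' Reports all positions where the Hamming distance between the
#' IUPAC-expanded pattern and the sequence is at most `maxMismatch`
#' (a sequence letter matching any base in the pattern's IUPAC set is not
#' a mismatch). Hits are sorted by (mismatches, start). Matching uses
#' [Biostrings::matchPattern()] with pattern-side ambiguity.
#'
#' @param seq DNA string to scan.
#' @param pattern IUPAC consensus string.
#' @param maxMismatch maximum Hamming mismatches (must be < pattern
#'   length).
#' @param both also scan the reverse complement of the pattern.
#' @param name motif name recorded in the hits.
#' @return data.frame with `motif`, `start`, `end` (0-based half-open),
#'   `strand`, `mismatches`.
#' @examples
#' findMotif("TTAACAAACTT", "AACAAAC")
#' @export
findMotif <- function(seq, pattern, maxMismatch = 0L, both = FALSE,
                      name = pattern) {
  pattern <- toupper(pattern)
  bad <- setdiff(strsplit(pattern, "")[[1]], names(.IUPAC))
  if (length(bad)) stop("invalid IUPAC letter(s): ", paste(bad, collapse = ""))
  if (maxMismatch >= nchar(pattern))
    stop("maxMismatch must be smaller than the pattern length")
  subject <- Biostrings::DNAString(toupper(as.character(seq)))
  scan1 <- function(pat, strand) {
    hits <- Biostrings::matchPattern(pat, subject,
                                     max.mismatch = maxMismatch,
                                     fixed = c(pattern = FALSE, subject = TRUE))
    if (!length(hits)) return(NULL)
    pc <- strsplit(pat, "")[[1]]
    mm <- vapply(seq_along(hits), function(i) {
      sc <- strsplit(as.character(hits[[i]]), "")[[1]]
      sum(vapply(seq_along(pc), function(k)
        !(sc[k] %in% .IUPAC[[pc[k]]]), TRUE))
    }, 0L)
    data.frame(motif = name, start = BiocGenerics::start(hits) - 1L,
               end = BiocGenerics::end(hits), strand = strand,
               mismatches = mm)
  }
  out <- scan1(pattern, "+")
  if (both) {
    rcpat <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(pattern)))
    out <- rbind(out, scan1(rcpat, "-"))
  }
  if (is.null(out))
    return(data.frame(motif = character(), start = integer(),
                      end = integer(), strand = character(),
                      mismatches = integer()))
  out <- out[order(out$mismatches, out$start), ]
  rownames(out) <- NULL
  out
}

#' Find short tandem repeat arrays
#'
#' Maximal non-extendable tandem arrays with unit length in
#' `[minUnit, maxUnit]` and at least `minCopies` full copies. Overlapping
#' candidates are resolved greedily by longer span, then smaller unit.
#' The span includes any partial terminal copy; the unit is reported in
#' its lexicographically minimal rotation alongside the as-found phase.
#' Homopolymer runs are the business of [findPolyTract()] (units here are
#' at least 2 nt).
#'
#' @param seq DNA string.
#' @param minUnit,maxUnit unit length bounds.
#' @param minCopies minimum number of full copies (default 3).
#' @param countPartial when `TRUE`, a partial terminal copy covering at
#'   least half the unit is counted as a full copy (some published repeat
#'   counts are calibrated this way).
#' @return data.frame with `unit`, `unitAsFound`, `copies`, `partial`
#'   (residual nt), `start`, `end` (0-based half-open).
#' @examples
#' findStr("GATCTGTGTGTGTGGCTA")
#' @export
findStr <- function(seq, minUnit = 2L, maxUnit = 10L, minCopies = 3L,
                    countPartial = FALSE) {
  s <- strsplit(toupper(as.character(seq)), "")[[1]]
  n <- length(s)
  cand <- list()
  for (u in minUnit:maxUnit) {
    if (2 * u > n) break
    eq <- s[(u + 1):n] == s[1:(n - u)]  # eq[i]: s[i+u] == s[i]
    r <- rle(eq)
    pos <- cumsum(c(1L, r$lengths))
    for (k in seq_along(r$values)) {
      if (!r$values[k]) next
      run <- r$lengths[k]
      span <- run + u           # total repeated stretch length
      if (span < u * minCopies) next
      start <- pos[k]           # 1-based position in s
      copies <- span %/% u
      partial <- span %% u
      if (copies < minCopies) next
      unitFound <- paste0(s[start:(start + u - 1L)], collapse = "")
      # skip units already covered by a smaller reportable period
      # (units whose primitive period is below minUnit stay: a
      # homopolymer run is reported at the smallest allowed unit)
      d <- .primitivePeriod(unitFound)
      if (d < u && d >= minUnit) next
      cand[[length(cand) + 1L]] <- data.frame(
        unit = .minRotation(unitFound), unitAsFound = unitFound,
        copies = copies, partial = partial,
        start = start - 1L, end = start - 1L + span)
    }
  }
  if (!length(cand))
    return(data.frame(unit = character(), unitAsFound = character(),
                      copies = integer(), partial = integer(),
                      start = integer(), end = integer()))
  cand <- do.call(rbind, cand)
  cand$span <- cand$end - cand$start
  cand <- cand[order(-cand$span, nchar(cand$unit), cand$start), ]
  keep <- rep(FALSE, nrow(cand))
  occupied <- rep(FALSE, n)
  for (i in seq_len(nrow(cand))) {
    idx <- (cand$start[i] + 1L):cand$end[i]
    if (!any(occupied[idx])) {
      keep[i] <- TRUE
      occupied[idx] <- TRUE
    }
  }
  out <- cand[keep, c("unit", "unitAsFound", "copies", "partial",
                      "start", "end")]
  if (countPartial) {
    bump <- out$partial >= nchar(out$unit) / 2
    out$copies <- out$copies + as.integer(bump)
  }
  out <- out[order(out$start), ]
  rownames(out) <- NULL
  out
}

.minRotation <- function(x) {
  ch <- strsplit(x, "")[[1]]
  rots <- vapply(seq_along(ch), function(i)
    paste0(c(ch[i:length(ch)], ch[seq_len(i - 1)]), collapse = ""), "")
  sort(rots)[1]
}

.primitivePeriod <- function(x) {
  n <- nchar(x)
  for (d in seq_len(n %/% 2)) {
    if (n %% d != 0L) next
    if (identical(strsplit(x, "")[[1]],
                  rep(strsplit(substr(x, 1, d), "")[[1]], n %/% d)))
      return(d)
  }
  n
}

#' Find poly-base tracts and TA islands
#'
#' Maximal runs of a single base of length at least `minLen`; in
#' `"ta_island"` mode, reports TA-repeat islands interrupting a poly-C
#' region (a maximal `(TA)+` stretch flanked by C runs).
#'
#' @param seq DNA string.
#' @param base the tract base (default `"C"`).
#' @param minLen minimum run length (default 5).
#' @param mode `"run"` or `"ta_island"`.
#' @return data.frame with `start`, `end` (0-based half-open), `length`
#'   and, for islands, the flanking C-run lengths.
#' @examples
#' findPolyTract("AACCCCCCAA")
#' findPolyTract("CCCCTATACCCC", mode = "ta_island")
#' @export
findPolyTract <- function(seq, base = "C", minLen = 5L,
                          mode = c("run", "ta_island")) {
  mode <- match.arg(mode)
  s <- toupper(as.character(seq))
  if (mode == "run") {
    ch <- strsplit(s, "")[[1]]
    r <- rle(ch)
    pos <- cumsum(c(1L, r$lengths))
    hit <- which(r$values == base & r$lengths >= minLen)
    return(data.frame(start = pos[hit] - 1L,
                      end = pos[hit] - 1L + r$lengths[hit],
                      length = r$lengths[hit]))
  }
  # TA islands inside C context: C+(TA)+C+
  m <- gregexpr("C+((?:TA)+)C+", s, perl = TRUE)[[1]]
  if (m[1] == -1L)
    return(data.frame(start = integer(), end = integer(),
                      length = integer(), flank5 = integer(),
                      flank3 = integer()))
  out <- lapply(seq_along(m), function(i) {
    frag <- substr(s, m[i], m[i] + attr(m, "match.length")[i] - 1L)
    isl <- regexpr("(?:TA)+", frag, perl = TRUE)
    ilen <- as.integer(attr(isl, "match.length"))
    ioff <- as.integer(isl)
    data.frame(start = as.integer(m[i]) - 1L + ioff - 1L,
               end = as.integer(m[i]) - 1L + ioff - 1L + ilen,
               length = ilen,
               flank5 = ioff - 1L,
               flank3 = as.integer(attr(m, "match.length")[i]) -
                 (ioff - 1L) - ilen)
  })
  do.call(rbind, out)
}

# base-pair score: G:C = 3, A:T = 2 (DNA, no GU wobble)
.pairScore <- function(x, y) {
  gc <- (x == "G" & y == "C") | (x == "C" & y == "G")
  at <- (x == "A" & y == "T") | (x == "T" & y == "A")
  3L * gc + 2L * at
}

#' Find hairpin (inverted-repeat) candidates
#'
#' Scans for stems of reverse-complementary arms separated by a loop of
#' 3..`maxLoop` nt. Stems are maximal perfectly paired arms of length at
#' least `minStem`; candidates are ranked by pairing score (G:C = 3,
#' A:T = 2) and selected greedily without overlap. This is a structural
#' plausibility screen, not thermodynamic folding.
#'
#' @param seq DNA string (length at least `2*minStem + 3`).
#' @param minStem minimum stem length (default 6).
#' @param maxLoop maximum loop length (default 30).
#' @return data.frame with `stemStart5p`, `stemLen`, `loopLen`,
#'   `stemStart3p`, `score` (starts 0-based).
#' @examples
#' findHairpin("GGGGGGTTTCCCCCC", minStem = 4)
#' @export
findHairpin <- function(seq, minStem = 6L, maxLoop = 30L) {
  s <- strsplit(toupper(as.character(seq)), "")[[1]]
  n <- length(s)
  if (n < 2L * minStem + 3L) stop("sequence too short for a hairpin")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  cand <- list()
  # i = last index (1-based) of the 5' arm; loop of length l follows
  for (i in seq_len(n)) {
    for (l in 3:min(maxLoop, n - i - 1L)) {
      j <- i + l + 1L              # first index of 3' arm
      if (j > n) break
      # extend outward: s[i - k] pairs s[j + k]
      k <- 0L
      while (i - k >= 1L && j + k <= n &&
             !is.na(comp[s[i - k]]) && comp[s[i - k]] == s[j + k]) {
        k <- k + 1L
      }
      if (k >= minStem) {
        arm5 <- (i - k + 1L):i
        arm3 <- j:(j + k - 1L)
        # maximality: already extended as far as possible
        cand[[length(cand) + 1L]] <- data.frame(
          stemStart5p = i - k, stemLen = k, loopLen = l,
          stemStart3p = j - 1L,
          score = sum(.pairScore(s[arm5], rev(s[arm3]))))
      }
    }
  }
  if (!length(cand))
    return(data.frame(stemStart5p = integer(), stemLen = integer(),
                      loopLen = integer(), stemStart3p = integer(),
                      score = integer()))
  cand <- unique(do.call(rbind, cand))
  cand <- cand[order(-cand$score, cand$stemStart5p, cand$loopLen), ]
  keep <- rep(FALSE, nrow(cand))
  occupied <- rep(FALSE, n)
  for (r in seq_len(nrow(cand))) {
    idx <- (cand$stemStart5p[r] + 1L):(cand$stemStart3p[r] + cand$stemLen[r])
    if (!any(occupied[idx])) { keep[r] <- TRUE; occupied[idx] <- TRUE }
  }
  out <- cand[keep, ]
  out <- out[order(out$stemStart5p), ]
  rownames(out) <- NULL
  out
}

#' The shipped control-region motif library
#'
#' Literature-derived IUPAC consensus strings for the avian control-region
#' conserved elements (ETAS1/ETAS2, boxes F/E/D/C, CSBa, CSBb, the
#' avian-specific Bird Box, CSB1-3), each with a per-motif mismatch
#' allowance. The library is configuration, not code: it is a plain-text
#' TSV that can be edited or replaced without touching the package.
#'
#' @param path optional path to an alternative TSV (columns `name`,
#'   `pattern`, `max_mismatch`).
#' @return data.frame with columns `name`, `pattern`, `max_mismatch`.
#' @export
motifLibrary <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "cr_motif_library.tsv",
                        package = "mitorelax")
  lib <- utils::read.delim(path, stringsAsFactors = FALSE,
                           comment.char = "#")
  stopifnot(all(c("name", "pattern", "max_mismatch") %in% names(lib)))
  lib
}

#' Partition a control region into its three domains
#'
#' Applies the standard anchor rule: domain I runs from the CR start to
#' the F-box hit, domain II from the F-box to CSB1, domain III from CSB1
#' to the CR end. Missing anchors leave the affected boundary unresolved
#' (flagged, not invented).
#'
#' @param cr the control-region sequence (string), or its length.
#' @param hits motif hit data.frame (as from [findMotif()] runs over a
#'   [motifLibrary()]), containing at best one `FBOX` and one `CSB1` hit.
#' @param tracts,strs,hairpins optional element tables to bundle.
#' @param motifs optional full motif table (found and absent) to bundle
#'   instead of `hits`.
#' @return A [CRAnnotation-class].
#' @export
partitionDomains <- function(cr, hits, tracts = NULL, strs = NULL,
                             hairpins = NULL, motifs = NULL) {
  len <- if (is.character(cr)) nchar(cr) else as.integer(cr)
  fstart <- hits$start[hits$motif == "FBOX"][1]
  cstart <- hits$start[hits$motif == "CSB1"][1]
  mk <- function(domain, start, end, resolved)
    data.frame(domain = domain, start = start, end = end, resolved = resolved)
  domains <- rbind(
    mk("I", 0L, ifelse(is.na(fstart), NA_integer_, fstart), !is.na(fstart)),
    mk("II", fstart, ifelse(is.na(cstart), NA_integer_, cstart),
       !is.na(fstart) && !is.na(cstart)),
    mk("III", cstart, len, !is.na(cstart)))
  if (is.null(motifs)) {
    motifs <- hits
    motifs$found <- TRUE
  }
  empty <- data.frame()
  new("CRAnnotation", length = as.integer(len), domains = domains,
      motifs = motifs,
      tracts = if (is.null(tracts)) empty else tracts,
      strs = if (is.null(strs)) empty else strs,
      hairpins = if (is.null(hairpins)) empty else hairpins)
}

#' Annotate a control region end to end
#'
#' Runs the motif library scan (best hit per motif; absent motifs are
#' reported as not found rather than forced), poly-C tract and TA-island
#' detection, STR discovery and hairpin screening, then partitions the
#' domains.
#'
#' @param cr control-region sequence (string).
#' @param library motif library data.frame (default [motifLibrary()]).
#' @param minStem,maxLoop hairpin parameters.
#' @param strMinCopies minimum STR copies.
#' @param countPartial passed to [findStr()].
#' @return A [CRAnnotation-class].
#' @export
annotateCR <- function(cr, library = motifLibrary(), minStem = 6L,
                       maxLoop = 30L, strMinCopies = 3L,
                       countPartial = FALSE) {
  cr <- toupper(as.character(cr))
  rows <- lapply(seq_len(nrow(library)), function(i) {
    h <- findMotif(cr, library$pattern[i], library$max_mismatch[i],
                   name = library$name[i])
    if (nrow(h)) {
      h <- h[1, ]; h$found <- TRUE; h
    } else {
      data.frame(motif = library$name[i], start = NA_integer_,
                 end = NA_integer_, strand = "+",
                 mismatches = NA_integer_, found = FALSE)
    }
  })
  motifs <- do.call(rbind, rows)
  hits <- motifs[motifs$found, , drop = FALSE]
  polyc <- findPolyTract(cr, "C", 5L)
  if (nrow(polyc)) polyc$type <- "polyC"
  isl <- findPolyTract(cr, mode = "ta_island")
  tracts <- polyc
  if (nrow(isl)) {
    isl$type <- "TA_island"
    isl$flank5 <- NULL; isl$flank3 <- NULL
    tracts <- rbind(polyc, isl)
  }
  strs <- findStr(cr, minCopies = strMinCopies, countPartial = countPartial)
  hairpins <- tryCatch(findHairpin(cr, minStem, maxLoop),
                       error = function(e) data.frame())
  partitionDomains(cr, hits, tracts = tracts, strs = strs,
                   hairpins = hairpins, motifs = motifs)
}

#' Write a CR annotation as BED and TSV
#'
#' BED uses 0-based half-open coordinates (the in-memory convention); the
#' companion TSV is 1-based inclusive for human reading.
#'
#' @param ann a [CRAnnotation-class].
#' @param bedPath,tsvPath output paths (either may be `NULL`).
#' @param chrom name for the BED chrom column.
#' @return Invisibly, the paths written.
#' @export
writeCRAnnotation <- function(ann, bedPath = NULL, tsvPath = NULL,
                              chrom = "CR") {
  rows <- list()
  d <- crDomains(ann)
  for (i in seq_len(nrow(d))) if (d$resolved[i])
    rows[[length(rows) + 1L]] <- data.frame(
      start = d$start[i], end = d$end[i],
      name = paste0("domain_", d$domain[i]))
  mo <- crMotifs(ann); mo <- mo[mo$found, , drop = FALSE]
  for (i in seq_len(nrow(mo)))
    rows[[length(rows) + 1L]] <- data.frame(
      start = mo$start[i], end = mo$end[i], name = mo$motif[i])
  tr <- crTracts(ann)
  for (i in seq_len(nrow(tr)))
    rows[[length(rows) + 1L]] <- data.frame(
      start = tr$start[i], end = tr$end[i], name = tr$type[i])
  st <- crStrs(ann)
  for (i in seq_len(nrow(st)))
    rows[[length(rows) + 1L]] <- data.frame(
      start = st$start[i], end = st$end[i],
      name = sprintf("STR_%sx%d", st$unit[i], st$copies[i]))
  hp <- crHairpins(ann)
  for (i in seq_len(nrow(hp)))
    rows[[length(rows) + 1L]] <- data.frame(
      start = hp$stemStart5p[i],
      end = hp$stemStart3p[i] + hp$stemLen[i],
      name = sprintf("hairpin_stem%d_loop%d", hp$stemLen[i], hp$loopLen[i]))
  bed <- do.call(rbind, rows)
  bed <- bed[order(bed$start), ]
  if (!is.null(bedPath))
    utils::write.table(cbind(chrom = chrom, bed), bedPath, sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  if (!is.null(tsvPath)) {
    hr <- bed
    hr$start <- hr$start + 1L   # 1-based inclusive for the readable table
    utils::write.table(cbind(chrom = chrom, hr), tsvPath, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(c(bed = bedPath, tsv = tsvPath))
}
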
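# GenBank flatfile I/O and gene-name canonicalization.
#
# The parser targets annotated mitogenome records: LOCUS/DEFINITION/
# ORGANISM headers, a FEATURES table with plain, complement() and join()
# locations, and an ORIGIN sequence block. File coordinates are 1-based
# inclusive (GenBank convention); in memory everything is 0-based half-open.

# canonical PCG names from common flatfile spellings
.PCG_ALIASES <- c(
  ND1 = "nad1|nadh dehydrogenase subunit 1|ndh1", ND2 = "nad2|nadh dehydrogenase subunit 2",
  ND3 = "nad3|nadh dehydrogenase subunit 3", ND4 = "nad4$|nadh dehydrogenase subunit 4$",
  ND4L = "nad4l|nadh dehydrogenase subunit 4l", ND5 = "nad5|nadh dehydrogenase subunit 5",
  ND6 = "nad6|nadh dehydrogenase subunit 6",
  COX1 = "cox1|co1|coi$|cytochrome c oxidase subunit 1|cytochrome c oxidase subunit i$",
  COX2 = "cox2|co2|coii$|cytochrome c oxidase subunit 2|cytochrome c oxidase subunit ii$",
  COX3 = "cox3|co3|coiii$|cytochrome c oxidase subunit 3|cytochrome c oxidase subunit iii$",
  ATP6 = "atp6|atpase6|atp synthase f0 subunit 6",
  ATP8 = "atp8|atpase8|atp synthase f0 subunit 8",
  CYTB = "cytb|cob$|cytochrome b")

.AA3 <- c(Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C", Gln = "Q",
          Glu = "E", Gly = "G", His = "H", Ile = "I", Leu = "L", Lys = "K",
          Met = "M", Phe = "F", Pro = "P", Ser = "S", Thr = "T", Trp = "W",
          Tyr = "Y", Val = "V")

#' Canonicalize a mitochondrial gene name
#'
#' Maps flatfile `/gene` and `/product` spellings onto the package's
#' canonical symbols: 13 PCGs (`ND1`..`ND6`, `ND4L`, `COX1`..`COX3`,
#' `ATP6`, `ATP8`, `CYTB`), `rrnS`/`rrnL`, `CR`, and one-letter tRNA names
#' (`trnF`, ...) with `1`/`2` suffixes for the Leu and Ser paralogs
#' (`trnL1` = Leu(CUN), `trnL2` = Leu(UUR), `trnS1` = Ser(AGY),
#' `trnS2` = Ser(UCN)).
#'
#' @param name gene/product string from a flatfile.
#' @param kind feature kind hint (`PCG`, `tRNA`, `rRNA`, `control_region`).
#' @return Canonical symbol, or `name` unchanged when unrecognized.
#' @export
canonicalGeneName <- function(name, kind = NA_character_) {
  x <- tolower(trimws(name))
  if (x %in% c("d-loop", "control region", "cr", "d_loop")) return("CR")
  if (grepl("12s|small subunit ribosomal|rrns|s-rrna|ssu", x)) return("rrnS")
  if (grepl("16s|large subunit ribosomal|rrnl|l-rrna|lsu", x)) return("rrnL")
  for (canon in names(.PCG_ALIASES))
    if (grepl(paste0("^(", .PCG_ALIASES[[canon]], ")"), x)) return(canon)
  # tRNAs: "tRNA-Xxx (anticodon)" first, then the short trnX(-suffix) form
  m <- regmatches(x, regexec("trna-([a-z]{3})", x))[[1]]
  if (length(m)) {
    aa3 <- paste0(toupper(substr(m[2], 1, 1)), substr(m[2], 2, 3))
    aa <- .AA3[aa3]
    if (!is.na(aa)) {
      suf <- if (aa %in% c("L", "S")) .trnSuffixFromContext(x, aa) else ""
      return(paste0("trn", aa, suf))
    }
  }
  m <- regmatches(x, regexec("^trn([a-z])([12])?($|[^a-z])", x))[[1]]
  if (length(m)) {
    aa <- toupper(m[2]); suf <- m[3]
    if (aa %in% c("L", "S") && suf == "") suf <- .trnSuffixFromContext(x, aa)
    return(paste0("trn", aa, suf))
  }
  name
}

# resolve Leu/Ser paralog from an anticodon/codon-family note in the string
.trnSuffixFromContext <- function(x, aa) {
  if (aa == "L") {
    if (grepl("cun|uag|tag", x)) return("1")
    if (grepl("uur|taa|uaa", x)) return("2")
  } else {
    if (grepl("agy|agn|gcu|gct|ucu", x)) return("1")
    if (grepl("ucn|uga|tga", x)) return("2")
  }
  ""
}

.parseLocation <- function(loc) {
  strand <- "H"
  loc <- gsub("[<>]", "", loc)
  if (grepl("^complement\\(", loc)) {
    strand <- "L"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  parts <- if (grepl("^join\\(", loc)) {
    strsplit(sub("^join\\((.*)\\)$", "\\1", loc), ",")[[1]]
  } else loc
  rng <- do.call(rbind, lapply(parts, function(p) {
    nn <- as.integer(strsplit(p, "\\.\\.")[[1]])
    if (length(nn) == 1L) nn <- c(nn, nn)
    nn
  }))
  list(start = rng[1, 1], end = rng[nrow(rng), 2], strand = strand,
       wraps = nrow(rng) > 1 && rng[nrow(rng), 2] < rng[1, 1])
}

#' Read a GenBank flatfile mitogenome
#'
#' Parses a GenBank flatfile into a [Mitogenome-class]: CDS features become
#' `PCG`, tRNA/rRNA features keep their kind, `D-loop` becomes
#' `control_region`, anything else is preserved as `other`. Names are
#' canonicalized with [canonicalGeneName()]. `gene` features that duplicate
#' a CDS/tRNA/rRNA of the same name are dropped.
#'
#' @param path flatfile path.
#' @return A [Mitogenome-class].
#' @export
readGenBank <- function(path) {
  lines <- readLines(path)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (!length(locus)) stop("not a GenBank flatfile (no LOCUS line)")
  lt <- strsplit(trimws(locus[1]), "\\s+")[[1]]
  id <- lt[2]
  circular <- any(grepl("circular", locus[1], ignore.case = TRUE))
  org <- grep("^\\s*ORGANISM", lines, value = TRUE)
  taxon <- if (length(org)) trimws(sub("^\\s*ORGANISM\\s*", "", org[1])) else NA_character_

  oi <- grep("^ORIGIN", lines)
  if (!length(oi)) stop("parse error: record has no ORIGIN sequence")
  seqlines <- lines[(oi[1] + 1):length(lines)]
  seqlines <- seqlines[!grepl("^//", seqlines)]
  seq <- toupper(gsub("[^A-Za-z]", "", paste(seqlines, collapse = "")))
  if (!nchar(seq)) stop("parse error: empty ORIGIN sequence")

  fi <- grep("^FEATURES", lines)
  feats <- data.frame(name = character(), kind = character(),
                      start = integer(), end = integer(),
                      strand = character(), notes = character())
  if (length(fi)) {
    block <- lines[(fi[1] + 1):(oi[1] - 1)]
    starts <- grep("^ {5}\\S", block)
    for (i in seq_along(starts)) {
      from <- starts[i]
      to <- if (i < length(starts)) starts[i + 1] - 1 else length(block)
      chunk <- block[from:to]
      key <- sub("^ {5}(\\S+).*", "\\1", chunk[1])
      locline <- sub("^ {5}\\S+\\s+", "", chunk[1])
      # location may continue before the first qualifier
      j <- 2
      while (j <= length(chunk) && !grepl("^\\s+/", chunk[j])) {
        locline <- paste0(locline, trimws(chunk[j])); j <- j + 1
      }
      quals <- paste(trimws(chunk[seq_len(length(chunk)) >= j]), collapse = " ")
      getq <- function(q) {
        m <- regmatches(quals, regexec(sprintf('/%s="?([^"/]+)"?', q), quals))[[1]]
        if (length(m)) trimws(m[2]) else NA_character_
      }
      if (key == "source") next
      kind <- switch(key, CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA",
                     "D-loop" = "control_region", misc_feature = "other",
                     gene = "gene", "other")
      loc <- .parseLocation(locline)
      raw <- getq("gene")
      if (is.na(raw)) raw <- getq("product")
      if (is.na(raw)) raw <- getq("note")
      if (is.na(raw)) raw <- key
      nm <- canonicalGeneName(raw, kind)
      note <- getq("note")
      len <- nchar(seq)
      end0 <- if (loc$wraps) len + loc$end else loc$end
      feats <- rbind(feats, data.frame(
        name = nm, kind = kind, start = loc$start - 1L, end = end0,
        strand = loc$strand, notes = if (is.na(note)) "" else note))
    }
    # drop gene features duplicating a typed feature of the same name
    typed <- feats$name[feats$kind != "gene"]
    feats <- feats[!(feats$kind == "gene" & feats$name %in% typed), ]
    feats$kind[feats$kind == "gene"] <- "other"
  }
  len <- nchar(seq)
  if (nrow(feats) && !circular && any(feats$end > len))
    stop("validation error: feature beyond sequence end on a non-circular record")
  Mitogenome(id = id, sequence = seq, features = feats,
             circular = circular, sourceTaxon = taxon)
}

#' Write a Mitogenome as a GenBank flatfile
#'
#' Emits LOCUS/DEFINITION/FEATURES/ORIGIN with 1-based inclusive
#' coordinates and `complement()` locations for L-strand features;
#' re-reading the file with [readGenBank()] reproduces the feature table.
#'
#' @param genome a [Mitogenome-class].
#' @param path output file.
#' @return The path, invisibly.
#' @export
writeGenBank <- function(genome, path) {
  seq <- as.character(genomeSeq(genome))
  len <- nchar(seq)
  ft <- featureTable(genome)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("LOCUS       %-16s %d bp    DNA     %s   VRT",
                     genomeId(genome), len,
                     if (isCircular(genome)) "circular" else "linear"), con)
  writeLines(sprintf("DEFINITION  %s mitochondrion.",
                     ifelse(is.na(genome@sourceTaxon), genomeId(genome),
                            genome@sourceTaxon)), con)
  writeLines("SOURCE      mitochondrion", con)
  writeLines(sprintf("  ORGANISM  %s",
                     ifelse(is.na(genome@sourceTaxon), ".",
                            genome@sourceTaxon)), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", len), con)
  for (i in seq_len(nrow(ft))) {
    f <- ft[i, ]
    locstr <- if (f$end <= len) sprintf("%d..%d", f$start + 1L, f$end) else
      sprintf("join(%d..%d,1..%d)", f$start + 1L, len, f$end - len)
    if (f$strand == "L") locstr <- sprintf("complement(%s)", locstr)
    key <- switch(f$kind, PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA",
                  control_region = "D-loop", "misc_feature")
    writeLines(sprintf("     %-15s %s", key, locstr), con)
    writeLines(sprintf("                     /gene=\"%s\"", f$name), con)
    if (nzchar(f$notes))
      writeLines(sprintf("                     /note=\"%s\"", f$notes), con)
  }
  writeLines("ORIGIN", con)
  pos <- seq(1, len, by = 60)
  for (p in pos) {
    chunk <- substr(seq, p, min(p + 59, len))
    tens <- substring(chunk, seq(1, nchar(chunk), 10),
                      pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    writeLines(sprintf("%9d %s", p, tolower(paste(tens, collapse = " "))), con)
  }
  writeLines("//", con)
  invisible(path)
}
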
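#' @importFrom methods new validObject is slot show setValidity
#' @importClassesFrom Biostrings DNAString DNAStringSet
NULL

#' Mitogenome: an annotated (circular) mitochondrial genome
#'
#' Container for a mitochondrial genome sequence plus its typed gene
#' features. Coordinates are 0-based half-open on the reference (heavy, "H")
#' strand; features on the light strand carry strand `"L"`. A feature on a
#' circular record may wrap the origin, in which case `end` exceeds the
#' sequence length and is interpreted modulo the length.
#'
#' The feature table has columns `name` (canonical symbol: `ND1`..`ND6`,
#' `ND4L`, `COX1`..`COX3`, `ATP6`, `ATP8`, `CYTB`, `rrnS`, `rrnL`, `trnA`..,
#' with `trnL1/trnL2`, `trnS1/trnS2` for the Leu/Ser paralogs, and `CR`),
#' `kind` (`PCG`, `tRNA`, `rRNA`, `control_region`, `other`), `start`,
#' `end`, `strand` (`H`/`L`) and `notes`.
#'
#' @slot id accession-like identifier
#' @slot sequence a [Biostrings::DNAString] over A,C,G,T,N
#' @slot circular logical flag
#' @slot features data.frame of gene features, sorted by start
#' @slot sourceTaxon free-text taxon
#' @export
setClass("Mitogenome",
  representation(id = "character", sequence = "DNAString",
                 circular = "logical", features = "data.frame",
                 sourceTaxon = "character"))

setValidity("Mitogenome", function(object) {
  msg <- character()
  len <- length(object@sequence)
  if (len < 1L) msg <- c(msg, "sequence must be non-empty")
  ft <- object@features
  need <- c("name", "kind", "start", "end", "strand", "notes")
  if (!all(need %in% names(ft)))
    return(paste("features must have columns:", paste(need, collapse = ", ")))
  if (nrow(ft)) {
    if (any(ft$end <= ft$start)) msg <- c(msg, "feature end must exceed start")
    if (any(ft$start < 0)) msg <- c(msg, "negative feature start")
    lim <- if (isTRUE(object@circular)) 2L * len else len
    if (any(ft$end > lim))
      msg <- c(msg, "feature beyond sequence end on a non-circular record")
    if (is.unsorted(ft$start)) msg <- c(msg, "features must be sorted by start")
    if (!all(ft$strand %in% c("H", "L"))) msg <- c(msg, "strand must be H or L")
    if (!all(ft$kind %in% c("PCG", "tRNA", "rRNA", "control_region", "other")))
      msg <- c(msg, "unknown feature kind")
    dup <- ft$name[ft$kind != "other"]
    if (anyDuplicated(dup)) msg <- c(msg, "duplicate feature name")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a Mitogenome
#'
#' @param id accession-like identifier.
#' @param sequence DNA as a character string or [Biostrings::DNAString].
#' @param features data.frame with columns `name`, `kind`, `start`, `end`,
#'   `strand`, `notes` (0-based half-open coordinates).
#' @param circular is the molecule circular?
#' @param sourceTaxon free-text source organism.
#' @return A [Mitogenome-class] object.
#' @export
Mitogenome <- function(id, sequence, features, circular = TRUE,
                       sourceTaxon = NA_character_) {
  if (is.character(sequence)) sequence <- Biostrings::DNAString(sequence)
  features <- as.data.frame(features)
  if (!"notes" %in% names(features)) features$notes <- ""
  features <- features[order(features$start), , drop = FALSE]
  rownames(features) <- NULL
  new("Mitogenome", id = as.character(id), sequence = sequence,
      circular = isTRUE(circular), features = features,
      sourceTaxon = as.character(sourceTaxon))
}

#' @describeIn Mitogenome accession of the record
#' @param object,x a `Mitogenome`
#' @export
genomeId <- function(x) x@id

#' @describeIn Mitogenome genome sequence as a [Biostrings::DNAString]
#' @export
genomeSeq <- function(x) x@sequence

#' @describeIn Mitogenome the feature table (0-based half-open coordinates)
#' @export
featureTable <- function(x) x@features

#' @describeIn Mitogenome is the record circular?
#' @export
isCircular <- function(x) x@circular

setMethod("show", "Mitogenome", function(object) {
  ft <- object@features
  cat("Mitogenome", object@id,
      sprintf("(%d bp, %s)", length(object@sequence),
              if (object@circular) "circular" else "linear"), "\n")
  if (!is.na(object@sourceTaxon)) cat("  source:", object@sourceTaxon, "\n")
  cat(sprintf("  %d features: %d PCG, %d tRNA, %d rRNA, %d control region\n",
              nrow(ft), sum(ft$kind == "PCG"), sum(ft$kind == "tRNA"),
              sum(ft$kind == "rRNA"), sum(ft$kind == "control_region")))
})

#' CodonAlignment: an in-frame gapped codon alignment
#'
#' Aligned coding sequences indexed by taxon. All rows have equal length,
#' a multiple of three; gaps are `-`; no row contains an internal stop
#' codon under the alignment's genetic code once gaps are removed.
#'
#' @slot seqs a [Biostrings::DNAStringSet] of equal-width aligned rows
#' @slot codeId genetic code identifier (default vertebrate mito, "2")
#' @export
setClass("CodonAlignment",
  representation(seqs = "DNAStringSet", codeId = "character"))

setValidity("CodonAlignment", function(object) {
  w <- Biostrings::width(object@seqs)
  if (length(w) < 1L) return("alignment must contain at least one sequence")
  if (length(unique(w)) != 1L) return("rows must have equal length")
  if (w[1] %% 3L != 0L) return("alignment length must be a multiple of 3")
  if (is.null(names(object@seqs)) || anyDuplicated(names(object@seqs)))
    return("rows must carry unique taxon names")
  gc <- Biostrings::getGeneticCode(object@codeId)
  stops <- names(gc)[gc == "*"]
  for (i in seq_along(object@seqs)) {
    s <- gsub("-", "", as.character(object@seqs[[i]]))
    if (nchar(s) %% 3L != 0L)
      return(sprintf("row %s out of frame after gap removal", names(object@seqs)[i]))
    if (nchar(s) == 0L) next
    cod <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    hit <- which(cod %in% stops)
    if (length(hit) && any(hit < length(cod)))
      return(sprintf("internal stop codon in row %s", names(object@seqs)[i]))
  }
  TRUE
})

#' Construct a CodonAlignment
#'
#' @param seqs named character vector or [Biostrings::DNAStringSet] of
#'   equal-length, in-frame, gapped coding sequences.
#' @param codeId genetic code id (default vertebrate mitochondrial, `"2"`).
#' @return A [CodonAlignment-class].
#' @export
CodonAlignment <- function(seqs, codeId = "2") {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  new("CodonAlignment", seqs = seqs, codeId = codeId)
}

#' @describeIn CodonAlignment number of codon columns
#' @param x a `CodonAlignment`
#' @export
nCodons <- function(x) Biostrings::width(x@seqs)[1] %/% 3L

#' @describeIn CodonAlignment taxon names
#' @export
taxa <- function(x) names(x@seqs)

#' @describeIn CodonAlignment the aligned rows as a DNAStringSet
#' @export
alignedSeqs <- function(x) x@seqs

setMethod("show", "CodonAlignment", function(object) {
  cat(sprintf("CodonAlignment: %d taxa x %d codons (genetic code %s)\n",
              length(object@seqs), nCodons(object), object@codeId))
})

#' LabeledTree: a phylogeny with branch-to-group assignments
#'
#' Wraps an [ape::read.tree()] `phylo` object and assigns every edge to a
#' named group. Group 1 is the background by convention; clade-model and
#' branch-model fits give each group its own (class-specific) omega.
#'
#' @slot phy an ape `phylo` object
#' @slot groups integer vector, one entry per edge row of `phy$edge`
#' @slot groupNames character names, `groupNames[1]` is the background
#' @export
setClass("LabeledTree",
  representation(phy = "ANY", groups = "integer", groupNames = "character"))

setValidity("LabeledTree", function(object) {
  if (!inherits(object@phy, "phylo")) return("phy must be an ape phylo tree")
  ne <- nrow(object@phy$edge)
  if (length(object@groups) != ne) return("one group per edge required")
  if (any(is.na(object@groups)) || any(object@groups < 1L))
    return("groups must be positive integers")
  if (max(object@groups) > length(object@groupNames))
    return("group index exceeds groupNames")
  if (is.null(object@phy$edge.length)) return("tree must have branch lengths")
  TRUE
})

#' Construct a LabeledTree
#'
#' @param phy an ape `phylo` tree with branch lengths.
#' @param groups integer or character vector with one group per edge of
#'   `phy$edge`; if `NULL` all edges are background.
#' @param groupNames names of the groups; first entry is the background.
#' @return A [LabeledTree-class].
#' @export
LabeledTree <- function(phy, groups = NULL, groupNames = NULL) {
  ne <- nrow(phy$edge)
  if (is.null(groups)) groups <- rep(1L, ne)
  if (is.character(groups)) {
    if (is.null(groupNames)) {
      groupNames <- unique(c("background", setdiff(unique(groups), "background")))
    }
    groups <- match(groups, groupNames)
  }
  if (is.null(groupNames)) {
    ng <- max(groups)
    groupNames <- c("background", if (ng > 1) paste0("group", seq_len(ng - 1)))
  }
  new("LabeledTree", phy = phy, groups = as.integer(groups),
      groupNames = groupNames)
}

#' @describeIn LabeledTree per-edge group indices
#' @param x a `LabeledTree`
#' @export
edgeGroups <- function(x) x@groups

#' @describeIn LabeledTree the underlying ape phylo
#' @export
treePhylo <- function(x) x@phy

#' @describeIn LabeledTree group names (first = background)
#' @export
groupNames <- function(x) x@groupNames

setMethod("show", "LabeledTree", function(object) {
  cat(sprintf("LabeledTree: %d tips, %d edges, groups: %s\n",
              length(object@phy$tip.label), nrow(object@phy$edge),
              paste(sprintf("%s(%d)", object@groupNames,
                            tabulate(object@groups,
                                     length(object@groupNames))),
                    collapse = ", ")))
})

#' CodonModelFit: a fitted codon substitution model
#'
#' @slot model model name (`M0`, `branch`, `free_ratios`, `M2a_rel`, `CmC`,
#'   `BSM_A`, `BSM_A_null`)
#' @slot lnL maximized log-likelihood
#' @slot params list with `kappa`, `omegas` (class x group matrix), `props`,
#'   `pi`, `scale`
#' @slot npar number of free parameters
#' @slot converged logical
#' @slot iterations total objective evaluations used
#' @slot omegaSummary data.frame summary of the omega structure
#' @export
setClass("CodonModelFit",
  representation(model = "character", lnL = "numeric", params = "list",
                 npar = "integer", converged = "logical",
                 iterations = "integer", omegaSummary = "data.frame"))

setValidity("CodonModelFit", function(object) {
  p <- object@params
  if (!is.null(p$props) && abs(sum(p$props) - 1) > 1e-8)
    return("class proportions must sum to 1")
  if (!is.null(p$omegas) && any(p$omegas < 1e-4 - 1e-12 | p$omegas > 50 + 1e-9))
    return("omega outside [1e-4, 50]")
  TRUE
})

setMethod("show", "CodonModelFit", function(object) {
  cat(sprintf("CodonModelFit [%s]  lnL = %.4f  (np = %d, %s)\n",
              object@model, object@lnL, object@npar,
              if (object@converged) "converged" else "NOT converged"))
  cat(sprintf("  kappa = %.3f\n", object@params$kappa))
  print(object@omegaSummary, row.names = FALSE)
})

#' @describeIn CodonModelFit maximized log-likelihood
#' @param x a `CodonModelFit`
#' @export
fitLnL <- function(x) x@lnL

#' @describeIn CodonModelFit fitted parameter list
#' @export
fitParams <- function(x) x@params

#' @describeIn CodonModelFit number of free parameters
#' @export
fitNpar <- function(x) x@npar

#' @describeIn CodonModelFit omega structure summary
#' @export
omegaSummary <- function(x) x@omegaSummary

#' CRAnnotation: annotated control region
#'
#' Bundles the three-domain partition of a control region with the located
#' conserved elements, poly-tracts, tandem-repeat arrays and hairpin
#' candidates. All coordinates are 0-based half-open on the CR itself.
#'
#' @slot length CR length (nt)
#' @slot domains data.frame with `domain` (I/II/III), `start`, `end`,
#'   `resolved`
#' @slot motifs data.frame of motif hits (including absent motifs with
#'   `found = FALSE`)
#' @slot tracts data.frame of poly-tract runs (and TA islands)
#' @slot strs data.frame of short-tandem-repeat arrays
#' @slot hairpins data.frame of hairpin candidates
#' @export
setClass("CRAnnotation",
  representation(length = "integer", domains = "data.frame",
                 motifs = "data.frame", tracts = "data.frame",
                 strs = "data.frame", hairpins = "data.frame"))

setValidity("CRAnnotation", function(object) {
  d <- object@domains
  if (nrow(d)) {
    d <- d[d$resolved, , drop = FALSE]
    if (nrow(d) && any(d$start < 0 | d$end > object@length))
      return("domain outside CR")
    if (nrow(d) > 1) {
      d <- d[order(d$start), ]
      if (any(d$end[-nrow(d)] != d$start[-1]))
        return("resolved domains must tile the CR without overlap")
    }
  }
  TRUE
})

setMethod("show", "CRAnnotation", function(object) {
  cat(sprintf("CRAnnotation (%d bp)\n", object@length))
  cat("  domains:\n"); print(object@domains, row.names = FALSE)
  found <- object@motifs[object@motifs$found, , drop = FALSE]
  absent <- object@motifs$motif[!object@motifs$found]
  cat(sprintf("  motifs found: %d; absent: %s\n", nrow(found),
              if (length(absent)) paste(absent, collapse = ", ") else "none"))
  cat(sprintf("  %d poly-tract(s), %d STR array(s), %d hairpin(s)\n",
              nrow(object@tracts), nrow(object@strs), nrow(object@hairpins)))
})

#' @describeIn CRAnnotation domain boundary table
#' @param x a `CRAnnotation`
#' @export
crDomains <- function(x) x@domains

#' @describeIn CRAnnotation motif hit table
#' @export
crMotifs <- function(x) x@motifs

#' @describeIn CRAnnotation STR array table
#' @export
crStrs <- function(x) x@strs

#' @describeIn CRAnnotation hairpin candidate table
#' @export
crHairpins <- function(x) x@hairpins

#' @describeIn CRAnnotation poly-tract table
#' @export
crTracts <- function(x) x@tracts
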
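# GenBank parsing, gene extraction, mito translation, stop-codon and
# frameshift handling, gene-order signatures.

toyGenBank <- function(path) {
  seqline <- paste0(
    "atgaaacccg ggtttaaata agcaaatcgc tagcatgcat gcatgcatgc ",
    "aaaaccccgg ggttttaaaa ccccggggtt")
  writeLines(c(
    "LOCUS       TOY001       80 bp    DNA     circular   VRT",
    "DEFINITION  toy record.",
    "SOURCE      mitochondrion",
    "  ORGANISM  Vultur toyensis",
    "FEATURES             Location/Qualifiers",
    "     source          1..80",
    "     CDS             1..21",
    '                     /gene="nad1"',
    "     tRNA            complement(22..50)",
    '                     /product="tRNA-Leu (CUN)"',
    "     D-loop          51..80",
    '                     /note="control region"',
    "ORIGIN",
    paste0("        1 ", seqline),
    "//"), path)
  path
}

test_that("GenBank parsing canonicalizes names and survives a round trip", {
  f <- toyGenBank(withr::local_tempfile(fileext = ".gb"))
  g <- readGenBank(f)
  ft <- featureTable(g)
  expect_equal(nrow(ft), 3L)
  expect_equal(ft$name, c("ND1", "trnL1", "CR"))
  expect_equal(ft$kind, c("PCG", "tRNA", "control_region"))
  expect_equal(ft$strand, c("H", "L", "H"))
  expect_equal(ft$start, c(0L, 21L, 50L))  # 0-based half-open in memory
  expect_equal(ft$end, c(21L, 50L, 80L))
  expect_true(isCircular(g))
  expect_equal(genomeId(g), "TOY001")

  f2 <- withr::local_tempfile(fileext = ".gb")
  writeGenBank(g, f2)
  g2 <- readGenBank(f2)
  expect_identical(featureTable(g2), ft)
  expect_identical(as.character(genomeSeq(g2)), as.character(genomeSeq(g)))
})

test_that("parser rejects defective records", {
  f <- withr::local_tempfile(fileext = ".gb")
  writeLines(c("LOCUS       X  10 bp DNA linear", "FEATURES", "//"), f)
  expect_error(readGenBank(f), "ORIGIN")
  writeLines(c(
    "LOCUS       X       10 bp    DNA     linear   VRT",
    "FEATURES             Location/Qualifiers",
    "     CDS             5..40",
    '                     /gene="nad2"',
    "ORIGIN",
    "        1 acgtacgtac",
    "//"), f)
  expect_error(readGenBank(f), "beyond sequence end")
})

test_that("synthetic mitogenome has the full avian complement in order", {
  sim <- simulateMitogenome(mitogenomeSpec(seed = 11))
  ft <- featureTable(sim$genome)
  expect_equal(sum(ft$kind == "PCG"), 13L)
  expect_equal(sum(ft$kind == "tRNA"), 22L)
  expect_equal(sum(ft$kind == "rRNA"), 2L)
  expect_equal(sum(ft$kind == "control_region"), 1L)
  expect_true(compareGeneOrder(geneOrderSignature(sim$genome))$match)
})

test_that("gene-order signature is invariant under circular rotation", {
  sim <- simulateMitogenome(mitogenomeSpec(seed = 12))
  g <- sim$genome
  ft <- featureTable(g)
  seq <- as.character(genomeSeq(g))
  off <- ft$start[ft$name == "ND2"]   # rotate so ND2 leads
  len <- nchar(seq)
  rotseq <- paste0(substr(seq, off + 1, len), substr(seq, 1, off))
  ft2 <- ft
  ft2$start <- (ft$start - off) %% len
  ft2$end <- ft2$start + (ft$end - ft$start)
  rot <- Mitogenome("ROT", rotseq, ft2, circular = TRUE)
  expect_identical(geneOrderSignature(rot), geneOrderSignature(g))
  # a pseudo-CR duplication breaks the ancestral arrangement
  ft3 <- rbind(ft, data.frame(name = "pseudo_CR", kind = "other",
                              start = len, end = len + 100L,
                              strand = "H", notes = ""))
  dup <- Mitogenome("DUP", paste0(seq, strrep("A", 100)), ft3,
                    circular = TRUE)
  expect_false(compareGeneOrder(geneOrderSignature(dup))$match)
})

test_that("extractGene returns sense-strand sequence", {
  ft <- data.frame(name = c("g1", "g2"), kind = "other",
                   start = c(10L, 0L), end = c(16L, 4L),
                   strand = c("H", "L"), notes = "")
  g <- Mitogenome("X", "AACGAAAAAACGTTTT", ft, circular = FALSE)
  expect_equal(extractGene(g, "g1"), "CGTTTT")
  expect_equal(extractGene(g, "g2"), "CGTT")  # revcomp of AACG
  expect_error(extractGene(g, "nope"), "lookup")
})

test_that("ND6 sense strand carries the planted C+G enrichment", {
  sim <- simulateMitogenome(mitogenomeSpec(seed = 13))
  g <- sim$genome
  gen <- baseComposition(genomeSeq(g))
  nd6 <- baseComposition(extractGene(g, "ND6"), "ND6")
  expect_gt(sum(nd6$freqs[c("C", "G")]), sum(gen$freqs[c("C", "G")]))
  # and the skew flips sign relative to the genome strand
  expect_lt(gen$gcSkew, 0)
  expect_gt(nd6$gcSkew, 0)
})

test_that("mito translation follows the vertebrate code", {
  expect_equal(translateMt("ATATGA"), "MW")   # ATA=Met, TGA=Trp
  expect_equal(translateMt("ATAAGA"), "M")    # AGA is a stop
  expect_equal(translateMt("ATGGGGTA", completion = "polyA"), "MG")
  expect_equal(translateMt("ATGGGGT", completion = "polyA"), "MG")
  err <- tryCatch(translateMt("ATGTAAAAA"), condition = identity)
  expect_s3_class(err, "mrFrameshiftSuspect")
  expect_equal(err$offset, 3L)
  # a random stop-free frame of 300 nt gives a 100-residue protein
  space <- codonSpace()
  sense <- setdiff(space$codons, c("TAA", "TAG", "AGA", "AGG"))
  set.seed(1)
  cds <- paste0(sample(sense, 100, replace = TRUE), collapse = "")
  expect_equal(nchar(translateMt(cds)), 100L)
})

test_that("stop-codon classification distinguishes complete and truncated", {
  seqs <- paste0("ATGAAATAA",      # complete, ends TAA
                 "ATGCCCTA",       # 3k+2, ends TA
                 "ATGGGGT",        # 3k+1, ends T
                 strrep("A", 70))  # downstream tRNA
  ft <- data.frame(name = c("gA", "gB", "gC", "trnX"),
                   kind = c("PCG", "PCG", "PCG", "tRNA"),
                   start = c(0L, 9L, 17L, 24L),
                   end = c(9L, 17L, 24L, 94L),
                   strand = "H", notes = "")
  g <- Mitogenome("STOPS", seqs, ft, circular = FALSE)
  expect_equal(detectIncompleteStop(g, "gA")$status, "complete")
  st <- detectIncompleteStop(g, "gB")
  expect_equal(st$status, "truncated_TA")
  expect_true(st$abutsDownstream)
  expect_equal(detectIncompleteStop(g, "gC")$status, "truncated_T")
  expect_error(detectIncompleteStop(g, "trnX"), "protein-coding")
})

test_that("generator's truncated stops are classified as planted", {
  sim <- simulateMitogenome(mitogenomeSpec(seed = 14))
  for (gene in names(sim$truth$stopStatuses)) {
    st <- detectIncompleteStop(sim$genome, gene)
    expect_equal(st$status, unname(sim$truth$stopStatuses[gene]),
                 label = gene)
    expect_true(st$abutsDownstream)
  }
  expect_equal(detectIncompleteStop(sim$genome, "ND2")$status, "complete")
})

test_that("frameshift detection recovers the planted skip exactly", {
  # clean ORF
  expect_false(detectFrameshift("ATGAAACCCGGGTAA")$detected)
  # planted single insertions across seeds (>=30 downstream codons)
  for (seed in 1:6) {
    sim <- simulateMitogenome(mitogenomeSpec(seed = seed))
    det <- detectFrameshift(extractGene(sim$genome, "ND3"))
    expect_true(det$detected)
    expect_equal(det$skipPosition, sim$truth$frameshift$offset)
  }
  # two independent insertions cannot be rescued by a single skip
  sim <- simulateMitogenome(mitogenomeSpec(seed = 3))
  cds <- extractGene(sim$genome, "ND3")
  cds2 <- paste0(substr(cds, 1, 30), "G", substr(cds, 31, 200), "G",
                 substr(cds, 201, nchar(cds)))
  det2 <- detectFrameshift(cds2)
  expect_false(det2$detected)
  expect_match(det2$note, "no single-nucleotide skip")
})
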
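# Base composition, skews, RSCU, amino-acid usage, correlations.

test_that("base composition and skews match hand calculations", {
  p <- baseComposition("AATT")
  expect_equal(unname(p$freqs[c("A", "T")]), c(0.5, 0.5))
  expect_equal(p$atSkew, 0)
  expect_equal(baseComposition("GGGC")$gcSkew, 0.5)
  expect_error(baseComposition("NNNN"), "undefined")
  expect_error(baseComposition("ACGR"), "ambiguity")
  # N excluded from denominators
  expect_equal(unname(baseComposition("AANN")$freqs[["A"]]), 1)
})

test_that("reverse complement swaps counts and negates skews", {
  set.seed(7)
  for (i in 1:10) {
    s <- paste0(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                collapse = "")
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    p <- baseComposition(s); q <- baseComposition(rc)
    expect_equal(unname(p$counts[c("A", "C", "G", "T")]),
                 unname(q$counts[c("T", "G", "C", "A")]))
    expect_equal(p$atSkew, -q$atSkew)
    expect_equal(p$gcSkew, -q$gcSkew)
  }
})

test_that("condor-like genome composition is near its planted target", {
  sim <- simulateMitogenome(mitogenomeSpec(seed = 5))
  p <- baseComposition(genomeSeq(sim$genome))
  expect_equal(unname(p$freqs[["A"]]), 0.31, tolerance = 0.1)
  expect_lt(abs(p$freqs[["A"]] - 0.31), 0.03)
  expect_lt(abs(p$freqs[["C"]] - 0.32), 0.03)
  expect_lt(abs(p$freqs[["G"]] - 0.13), 0.03)
})

test_that("RSCU definition holds exactly", {
  # only CTA used in the six-codon Leu family
  r <- rscu(list(strrep("CTA", 6)))
  leu <- r[r$aa == "L", ]
  expect_equal(leu$rscu[leu$codon == "CTA"], 6)
  expect_equal(sum(leu$rscu), 6)  # others 0
  # uniform usage in every family: one copy of each sense codon
  space <- codonSpace()
  r2 <- rscu(list(paste0(space$codons, collapse = "")))
  expect_true(all(abs(r2$rscu - 1) < 1e-12))
  # family means are exactly 1 for used families
  set.seed(3)
  cds <- paste0(sample(space$codons, 500, replace = TRUE), collapse = "")
  r3 <- rscu(list(cds))
  means <- tapply(r3$rscu, r3$aa, mean)
  means <- means[!is.na(means)]
  expect_true(all(abs(means - 1) < 1e-12))
  expect_true(all(r3$rscu >= 0, na.rm = TRUE))
  expect_error(rscu(list("ATGC")), "multiple of 3")
})

test_that("amino-acid usage tallies translations", {
  u <- aminoAcidUsage(list(strrep("CTA", 10)))
  expect_equal(unname(u[["L"]]), 1)
  expect_error(aminoAcidUsage(list()), "empty")
  # independent recount on a random CDS
  space <- codonSpace()
  set.seed(9)
  cods <- sample(space$codons, 200, replace = TRUE)
  u2 <- aminoAcidUsage(list(paste0(cods, collapse = "")))
  recount <- table(unname(space$aa[cods])) / length(cods)
  expect_equal(unname(u2[names(recount)]), unname(as.numeric(recount)))
  expect_equal(sum(u2), 1)
})

test_that("generator codon usage: frequent codons reflect the H-strand bias", {
  sim <- simulateMitogenome(mitogenomeSpec(seed = 8))
  g <- sim$genome
  ft <- featureTable(g)
  pcgs <- ft$name[ft$kind == "PCG"]
  cds <- lapply(pcgs, function(n) {
    s <- extractGene(g, n)
    det <- detectFrameshift(s)
    if (isTRUE(det$detected)) {
      p <- det$skipPosition
      s <- paste0(substr(s, 1, p), substr(s, p + 2, nchar(s)))
    }
    if (nchar(s) %% 3 != 0) s <- paste0(s, strrep("A", 3 - nchar(s) %% 3))
    s
  })
  r <- rscu(cds)
  expect_true(all(r$count >= 0))
  # A-rich third positions favored under the planted composition
  top <- r$codon[order(-r$count)][1:10]
  expect_gt(mean(substr(top, 3, 3) %in% c("A", "C")), 0.5)
})

test_that("composition correlation behaves at the extremes", {
  x <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  expect_equal(compositionCorrelation(x, x)$r, 1)
  expect_equal(compositionCorrelation(x, -x)$r, -1)
  expect_error(compositionCorrelation(x, rep(1, 5)), "zero variance")
  # exact permutation p-value for tiny n
  set.seed(2)
  y <- x + rnorm(5, sd = 0.05)
  p <- compositionCorrelation(x, y, permute = TRUE)
  expect_gte(p$p.value, 1 / factorial(5))
})

test_that("replicate genomes off one template correlate above 0.9", {
  g1 <- simulateMitogenome(mitogenomeSpec(seed = 31))$genome
  g2 <- simulateMitogenome(mitogenomeSpec(seed = 32))$genome
  ft <- featureTable(g1)
  genes <- ft$name[ft$kind %in% c("PCG", "rRNA")]
  prof <- function(g) as.vector(vapply(genes, function(n)
    baseComposition(extractGene(g, n), n)$freqs, numeric(4)))
  res <- compositionCorrelation(prof(g1), prof(g2))
  expect_gt(res$r, 0.9)
  expect_lt(res$p.value, 0.001)
})
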
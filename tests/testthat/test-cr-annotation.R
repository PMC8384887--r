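# Motif scanning, STR discovery, poly-tracts, hairpins, domain partition.

test_that("motif scanning finds degenerate hits with mismatch counts", {
  hits <- findMotif("TTAACAAACTT", "AACAAAC")
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 2L)     # 0-based
  expect_equal(hits$end, 9L)
  expect_equal(hits$mismatches, 0L)
  hits1 <- findMotif("TTAACGAACTT", "AACAAAC", maxMismatch = 1)
  expect_equal(nrow(hits1), 1L)
  expect_equal(hits1$mismatches, 1L)
  expect_equal(nrow(findMotif("TTAACGAACTT", "AACAAAC")), 0L)
  # IUPAC degeneracy in the pattern is not a mismatch
  expect_equal(findMotif("TTAACG", "AACR")$mismatches, 0L)
  expect_equal(findMotif("TTAACA", "AACR")$mismatches, 0L)
  expect_error(findMotif("ACGT", "AXC"), "IUPAC")
  expect_error(findMotif("ACGT", "ACGT", maxMismatch = 4), "smaller")
})

test_that("STR finder handles textbook cases", {
  s <- paste0("GATTACA", strrep("TG", 5), "CCGATT")
  r <- findStr(s)
  expect_equal(nrow(r), 1L)
  expect_equal(r$unitAsFound, "TG")
  expect_equal(r$copies, 5L)
  expect_equal(r$start, 7L)
  r2 <- findStr("AAAAAA", minUnit = 2)
  expect_equal(r2$unit, "AA")
  expect_equal(r2$copies, 3L)
  # partial counted separately, optionally promoted
  s3 <- paste0("G", strrep("AACAAAC", 4), "AACA", "G")
  r3 <- findStr(s3)
  expect_equal(r3$copies, 4L)
  expect_equal(r3$partial, 4L)
  r3b <- findStr(s3, countPartial = TRUE)
  expect_equal(r3b$copies, 5L)
})

test_that("STR finder agrees with the exhaustive oracle", {
  set.seed(41)
  for (i in 1:60) {
    n <- sample(15:40, 1)
    # biased alphabet so repeats actually occur
    s <- paste0(sample(c("A", "C", "A", "T"), n, TRUE), collapse = "")
    got <- findStr(s, minUnit = 2, maxUnit = 6, minCopies = 3)
    want <- bruteStr(s, minUnit = 2, maxUnit = 6, minCopies = 3)
    expect_equal(got, want, label = s)
  }
})

test_that("poly-tracts and TA islands are located exactly", {
  r <- findPolyTract("CCCCCC", minLen = 5)
  expect_equal(r$start, 0L); expect_equal(r$length, 6L)
  expect_equal(nrow(findPolyTract("CCCC", minLen = 5)), 0L)
  isl <- findPolyTract("CCCCTATACCCC", mode = "ta_island")
  expect_equal(isl$start, 4L)
  expect_equal(isl$length, 4L)
})

test_that("hairpin finder handles the canonical stem-loop", {
  h <- findHairpin("GGGGGGTTTCCCCCC", minStem = 6)
  expect_equal(nrow(h), 1L)
  expect_equal(h$stemLen, 6L)
  expect_equal(h$loopLen, 3L)
  expect_equal(h$score, 18L)
  hr <- findHairpin(paste(rev(strsplit("GGGGGGTTTCCCCCC", "")[[1]]),
                          collapse = ""), minStem = 6)
  expect_equal(hr$stemLen, 6L)
  expect_equal(hr$loopLen, 3L)
})

test_that("hairpin finder agrees with the exhaustive oracle", {
  set.seed(51)
  for (i in 1:40) {
    n <- sample(20:40, 1)
    s <- paste0(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
    got <- findHairpin(s, minStem = 3, maxLoop = 10)
    want <- bruteHairpin(s, minStem = 3, maxLoop = 10)
    expect_equal(got, want, label = s)
  }
})

test_that("domain partition applies the F-box / CSB1 anchor rule", {
  hits <- data.frame(motif = c("FBOX", "CSB1"), start = c(400L, 900L),
                     end = c(424L, 924L), strand = "+", mismatches = 0L)
  ann <- partitionDomains(1200L, hits)
  d <- crDomains(ann)
  expect_equal(d$start, c(0L, 400L, 900L))
  expect_equal(d$end, c(400L, 900L, 1200L))
  expect_true(all(d$resolved))
  # missing CSB1 leaves the II/III boundary unresolved
  ann2 <- partitionDomains(1200L, hits[hits$motif == "FBOX", ])
  d2 <- crDomains(ann2)
  expect_false(d2$resolved[d2$domain == "II"])
  expect_false(d2$resolved[d2$domain == "III"])
})

test_that("random planted layouts are annotated at their planted anchors", {
  lib <- motifLibrary()
  set.seed(61)
  for (i in 1:100) {
    len <- sample(1000:1400, 1)
    f <- sample(300:450, 1)
    c1 <- sample(800:950, 1)
    s <- sample(c("A", "C", "G", "T"), len, TRUE,
                prob = c(0.31, 0.32, 0.13, 0.24))
    plant <- function(s, at, name) {
      pat <- lib$pattern[lib$name == name]
      inst <- strsplit(mitorelax:::.instantiateIUPAC(pat), "")[[1]]
      s[(at + 1):(at + length(inst))] <- inst
      s
    }
    s <- plant(s, f, "FBOX")
    s <- plant(s, c1, "CSB1")
    cr <- paste0(s, collapse = "")
    fhit <- findMotif(cr, lib$pattern[lib$name == "FBOX"],
                      lib$max_mismatch[lib$name == "FBOX"], name = "FBOX")
    chit <- findMotif(cr, lib$pattern[lib$name == "CSB1"],
                      lib$max_mismatch[lib$name == "CSB1"], name = "CSB1")
    ann <- partitionDomains(len, rbind(fhit[1, ], chit[1, ]))
    d <- crDomains(ann)
    expect_equal(d$start[d$domain == "II"], f)
    expect_equal(d$start[d$domain == "III"], c1)
  }
})

test_that("generator CR elements are recovered at planted coordinates", {
  sim <- simulateMitogenome(mitogenomeSpec(seed = 17))
  lay <- sim$truth$crLayout
  cr <- extractGene(sim$genome, "CR")
  ann <- annotateCR(cr)
  mo <- crMotifs(ann)
  for (nm in names(lay$motifAt)) {
    expect_equal(mo$start[mo$motif == nm], unname(lay$motifAt[nm]),
                 label = nm)
  }
  # absence reporting for elements not conserved in the layout
  expect_false(any(mo$found[mo$motif %in% c("ETAS2", "CSB2", "CSB3")]))
  # STR array
  st <- crStrs(ann)
  hit <- st[st$unitAsFound == lay$str$unit |
            st$unit == mitorelax:::.minRotation(lay$str$unit), ]
  expect_equal(hit$copies, lay$str$copies)
  expect_equal(hit$start, lay$str$start)
  # poly-C tract and TA island
  tr <- crTracts(ann)
  expect_true(any(tr$type == "polyC" & tr$start == lay$polyC$start))
  expect_true(any(tr$type == "TA_island" &
                  tr$start == lay$polyC$start + lay$polyC$islandOffset &
                  tr$length == lay$polyC$islandLen))
  # hairpin
  hp <- crHairpins(ann)
  expect_true(any(hp$stemStart5p == lay$hairpin$start5p &
                  hp$stemLen == lay$hairpin$stemLen &
                  hp$loopLen == lay$hairpin$loopLen))
  # domains tile the CR and every element sits in its domain
  d <- crDomains(ann)
  expect_equal(d$start, c(0L, lay$motifAt[["FBOX"]], lay$motifAt[["CSB1"]]))
  expect_equal(d$end[3], nchar(cr))
  expect_true(st$start[st$unitAsFound == lay$str$unit] >= d$start[3])
})

test_that("CR annotation round-trips through BED output", {
  sim <- simulateMitogenome(mitogenomeSpec(seed = 18))
  ann <- annotateCR(extractGene(sim$genome, "CR"))
  bed <- withr::local_tempfile(fileext = ".bed")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeCRAnnotation(ann, bedPath = bed, tsvPath = tsv)
  b <- utils::read.delim(bed, header = FALSE)
  expect_true(any(grepl("^STR_", b$V4)))
  expect_true(any(grepl("^domain_", b$V4)))
  expect_true(all(b$V2 >= 0 & b$V3 <= ann@length))
  h <- utils::read.delim(tsv)
  expect_equal(nrow(h), nrow(b))
})
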
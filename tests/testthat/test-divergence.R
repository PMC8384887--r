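# Alignment scoring, identity, entropy, polymorphic sites.

test_that("global alignment matches trivially predictable cases", {
  a <- globalAlign("ACGTACGT", "ACGTACGT")
  expect_equal(a$score, 8)
  expect_false(grepl("-", a$a) || grepl("-", a$b))
  b <- globalAlign("ACGT", "AGT")
  expect_equal(sum(strsplit(b$b, "")[[1]] == "-"), 1L)
})

test_that("global alignment score equals the independent Gotoh oracle", {
  set.seed(11)
  for (i in 1:60) {
    n1 <- sample(3:12, 1); n2 <- sample(3:12, 1)
    a <- paste0(sample(c("A", "C", "G", "T"), n1, TRUE), collapse = "")
    b <- paste0(sample(c("A", "C", "G", "T"), n2, TRUE), collapse = "")
    expect_equal(globalAlign(a, b)$score, gotohScore(a, b),
                 label = paste(a, b))
  }
  # and under a different parameter set
  for (i in 1:20) {
    a <- paste0(sample(c("A", "C", "G", "T"), 10, TRUE), collapse = "")
    b <- paste0(sample(c("A", "C", "G", "T"), 8, TRUE), collapse = "")
    expect_equal(globalAlign(a, b, match = 2, mismatch = -3,
                             gapOpen = -4, gapExt = -2)$score,
                 gotohScore(a, b, 2, -3, -4, -2))
  }
})

test_that("pairwise identity uses pair deletion", {
  expect_equal(pairwiseIdentity("ACGT", "ACGA"), 75)
  expect_equal(pairwiseIdentity("AC-T", "ACGT"), 100)  # gap column excluded
  expect_error(pairwiseIdentity("--", "AA"), "no gap-free columns")
})

test_that("identity matrix is symmetric with a 100 diagonal", {
  ft <- data.frame(name = "g1", kind = "PCG", start = 0L, end = 60L,
                   strand = "H", notes = "")
  set.seed(21)
  s <- paste0(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
  mutate <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    idx <- sample(length(ch), k)
    for (i in idx) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
    paste0(ch, collapse = "")
  }
  gs <- list(Mitogenome("A", s, ft),
             Mitogenome("B", s, ft),
             Mitogenome("C", mutate(s, 3), ft))
  m <- identityMatrix("g1", gs)
  expect_equal(unname(diag(m)), rep(100, 3))
  expect_lt(max(abs(m - t(m))), 1e-9)
  expect_equal(m["A", "B"], 100)
  expect_equal(m["A", "C"], 100 * 57 / 60, tolerance = 0.02)
  expect_error(identityMatrix("g2", gs), "missing")
})

test_that("identity decreases with planted divergence", {
  set.seed(4)
  base <- paste0(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  ft <- data.frame(name = "gene", kind = "PCG", start = 0L, end = 400L,
                   strand = "H", notes = "")
  mut <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    idx <- sample(length(ch), k)
    for (i in idx) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
    paste0(ch, collapse = "")
  }
  gs <- list(Mitogenome("ref", base, ft),
             Mitogenome("d1", mut(base, 4), ft),    # 1% divergence
             Mitogenome("d5", mut(base, 20), ft))   # 5% divergence
  m <- identityMatrix("gene", gs)
  expect_equal(m["ref", "d1"], 99, tolerance = 0.011)
  expect_equal(m["ref", "d5"], 95, tolerance = 0.011)
  expect_gt(m["ref", "d1"], m["ref", "d5"])
})

test_that("window entropy matches exact values", {
  inv <- c(a = strrep("ACGT", 20), b = strrep("ACGT", 20))
  prof <- windowEntropy(inv, window = 50)
  expect_true(all(prof$entropy == 0))
  # one 1:1 disagreement inside a 50-column window: mean = 1/50 bits
  x <- strrep("A", 60)
  y <- paste0(strrep("A", 29), "C", strrep("A", 30))
  prof2 <- windowEntropy(c(a = x, b = y), window = 50)
  expect_equal(max(prof2$entropy), 0.02)
  # a 2:2 split column has entropy exactly 1 bit
  m <- matrix("A", 4, 50)
  m[, 25] <- c("C", "C", "T", "T")
  prof3 <- windowEntropy(m, window = 50)
  expect_equal(prof3$entropy, 1 / 50)
  expect_error(windowEntropy(inv, window = 100), "exceeds")
})

test_that("entropy is invariant to row order and alphabet relabeling", {
  set.seed(31)
  rows <- vapply(1:5, function(i)
    paste0(sample(c("A", "C", "G", "T"), 120, TRUE), collapse = ""), "")
  names(rows) <- paste0("h", 1:5)
  p1 <- windowEntropy(rows, window = 30)
  p2 <- windowEntropy(rev(rows), window = 30)
  expect_equal(p1$entropy, p2$entropy)
  relabeled <- vapply(rows, function(s) chartr("ACGT", "GTAC", s), "")
  p3 <- windowEntropy(relabeled, window = 30)
  expect_equal(p1$entropy, p3$entropy)
})

test_that("polymorphic site counts honor regions", {
  haps <- c(h1 = "AAAAAAAAAA", h2 = "AAAAAAAAAA")
  expect_equal(polymorphicSites(haps)$polymorphic, 0L)
  expect_equal(polymorphicSites(c(h = "ACGT"))$polymorphic, 0L)
  haps2 <- c(h1 = "AAAATAAAAA", h2 = "CAAAAAAAAA", h3 = "CAAATAAAAA")
  reg <- data.frame(name = c("left", "right"), start = c(0L, 5L),
                    end = c(5L, 10L))
  expect_equal(polymorphicSites(haps2, reg)$polymorphic, c(2L, 0L))
  expect_error(polymorphicSites(haps2,
    data.frame(name = "x", start = 0L, end = 99L)), "range")
})
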
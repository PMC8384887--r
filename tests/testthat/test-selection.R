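# Codon-model machinery: column cleaning, F3x4, Q construction, pruning
# likelihood, model fits, LRTs, NG86 counting, mass~omega regression.

test_that("codon column cleaning removes exactly the dirty columns", {
  aln <- CodonAlignment(c(a = "ATGAAACTA", b = "ATGAAACTA"))
  out <- cleanCodonColumns(aln)
  expect_equal(nCodons(out), 3L)
  expect_equal(attr(out, "removed"), 0L)
  aln2 <- CodonAlignment(c(a = "ATG---CTA", b = "ATGAAACTA"))
  out2 <- cleanCodonColumns(aln2)
  expect_equal(nCodons(out2), 2L)
  expect_equal(attr(out2, "removed"), 1L)
  expect_error(cleanCodonColumns(CodonAlignment(c(a = "---", b = "AAA"))),
               "no codon columns")
  # planted gap columns in a simulated alignment
  sim <- simulateCodonAlignment(codonSimSpec(nCodons = 100, seed = 3))
  m <- as.character(alignedSeqs(sim$alignment))
  gapcols <- c(5, 17, 23, 41, 42, 77, 90)
  chs <- strsplit(m, "")
  for (k in gapcols) chs[[1]][(3 * k - 2):(3 * k)] <- "-"
  dirty <- CodonAlignment(vapply(chs, paste0, "", collapse = ""))
  names(dirty@seqs) <- names(m)
  out3 <- cleanCodonColumns(dirty)
  expect_equal(attr(out3, "removed"), 7L)
  expect_equal(nCodons(out3), 93L)
})

test_that("F3x4 frequencies follow the position products", {
  # uniform per-position nucleotide usage -> all sense codons at 1/60
  aln <- CodonAlignment(c(x = "AAACCCGGGTTT"))
  pi <- f3x4Frequencies(aln)
  expect_equal(length(pi), 60L)
  expect_true(all(abs(pi - 1 / 60) < 1e-12))
  expect_equal(sum(pi), 1)
  # skewed usage: spot-check the product for three codons
  aln2 <- CodonAlignment(c(x = "ATGATGCTACTA"))
  m <- do.call(rbind, strsplit(c("ATG", "ATG", "CTA", "CTA"), ""))
  pos <- lapply(1:3, function(p) table(factor(m[, p],
                levels = c("T", "C", "A", "G"))) / 4)
  raw <- function(cod) {
    ch <- strsplit(cod, "")[[1]]
    pos[[1]][[ch[1]]] * pos[[2]][[ch[2]]] * pos[[3]][[ch[3]]]
  }
  space <- codonSpace()
  denom <- sum(vapply(space$codons, raw, 0))
  pi2 <- f3x4Frequencies(aln2)
  for (cod in c("ATG", "CTG", "ATA"))
    expect_equal(unname(pi2[cod]), unname(raw(cod) / denom))
  # random alignments always normalize
  sim <- simulateCodonAlignment(codonSimSpec(nCodons = 50, seed = 5))
  expect_equal(sum(f3x4Frequencies(sim$alignment)), 1)
})

test_that("GY94 rate matrix has the stated structure", {
  space <- codonSpace()
  pi <- randomPi()
  names(pi) <- space$codons
  Q <- buildQMatrix(1, 1, pi, scale = FALSE)
  # kappa = omega = 1: every single-nt change proceeds at pi_j
  onestep <- space$pairtype > 0
  expect_true(all(abs(Q[onestep] -
                      matrix(pi, 60, 60, byrow = TRUE)[onestep]) < 1e-12))
  expect_true(all(Q[!onestep & diag(60) == 0] == 0))
  # AAA -> AAG is a synonymous (Lys) transition: rate kappa * pi_AAG
  Q2 <- buildQMatrix(3.7, 0.21, pi, scale = FALSE)
  expect_equal(Q2["AAA", "AAG"], 3.7 * pi[["AAG"]])
  # AAA -> AGA hits a stop codon: inaccessible
  expect_false("AGA" %in% colnames(Q2))
  # rows sum to zero; scaled matrix has unit mean rate; reversibility
  Qs <- buildQMatrix(3.7, 0.21, pi)
  expect_lt(max(abs(rowSums(Qs))), 1e-12)
  expect_equal(-sum(pi * diag(Qs)), 1)
  flux <- diag(pi) %*% Qs
  expect_lt(max(abs(flux - t(flux))), 1e-12)
})

test_that("pruning equals the enumeration oracle on small instances", {
  set.seed(71)
  for (i in 1:20) {
    ntip <- sample(2:4, 1)
    ncod <- sample(1:3, 1)
    phy <- randomOracleTree(ntip)
    aln <- randomCodonRows(phy$tip.label, ncod)
    kappa <- runif(1, 0.5, 6); omega <- runif(1, 0.05, 2)
    pi <- randomPi()
    ll <- codonLogLik(aln, LabeledTree(phy), kappa, omega, pi = pi)
    expect_equal(as.numeric(ll), enumLogLik(aln, phy, kappa, omega, pi),
                 tolerance = 1e-10)
  }
})

test_that("two-taxon likelihood approaches the independence limit", {
  pi <- rep(1 / 60, 60)
  lt <- LabeledTree(ape::read.tree(text = "(a:40,b:40);"))
  aln <- CodonAlignment(c(a = "ATG", b = "CTA"))
  ll <- codonLogLik(aln, lt, kappa = 2, omegas = 0.5, pi = pi)
  expect_equal(as.numeric(ll), log(1 / 60) + log(1 / 60), tolerance = 1e-6)
})

test_that("likelihood is invariant to re-rooting (reversibility)", {
  t1 <- ape::read.tree(text = "((a:0.1,b:0.2):0.15,(c:0.3,d:0.25):0.05);")
  t2 <- ape::read.tree(text = "(((a:0.1,b:0.2):0.2,c:0.3):0.0,d:0.25);")
  aln <- randomCodonRows(c("a", "b", "c", "d"), 5)
  pi <- randomPi()
  l1 <- codonLogLik(aln, LabeledTree(t1), 2.2, 0.4, pi = pi)
  l2 <- codonLogLik(aln, LabeledTree(t2), 2.2, 0.4, pi = pi)
  expect_equal(as.numeric(l1), as.numeric(l2), tolerance = 1e-8)
})

test_that("site-class mixtures marginalize per site", {
  # a two-class mixture equals the weighted average of per-class site
  # likelihoods, checked through the exported interface
  sim <- simulateCodonAlignment(codonSimSpec(nCodons = 10, seed = 9))
  tree <- sim$tree
  aln <- sim$alignment
  pi <- f3x4Frequencies(aln)
  llmix <- codonLogLik(aln, tree, 2, omegas = c(0.1, 1), props = c(0.4, 0.6),
                       pi = pi)
  s1 <- attr(codonLogLik(aln, tree, 2, 0.1, pi = pi), "siteLnL")
  s2 <- attr(codonLogLik(aln, tree, 2, 1, pi = pi), "siteLnL")
  # per-class Qs are rescaled by the mixture mean rate; recompute scale
  scaleTree <- function(tr, f) {
    phy <- treePhylo(tr); phy$edge.length <- phy$edge.length * f
    LabeledTree(phy, edgeGroups(tr), groupNames(tr))
  }
  f1 <- attr(buildQMatrix(2, 0.1, pi, scale = FALSE), "rate")
  f2 <- attr(buildQMatrix(2, 1, pi, scale = FALSE), "rate")
  fmix <- 0.4 * f1 + 0.6 * f2
  s1r <- attr(codonLogLik(aln, scaleTree(tree, f1 / fmix), 2, 0.1,
                          pi = pi), "siteLnL")
  s2r <- attr(codonLogLik(aln, scaleTree(tree, f2 / fmix), 2, 1,
                          pi = pi), "siteLnL")
  expect_equal(attr(llmix, "siteLnL"),
               log(0.4 * exp(s1r) + 0.6 * exp(s2r)), tolerance = 1e-8)
})

test_that("M0 recovers its generating parameters", {
  spec <- codonSimSpec(tree = balancedCladeTree(4, 0.3, 0.15), kappa = 2,
                       omegas = 0.2, nCodons = 500, seed = 101)
  sim <- simulateCodonAlignment(spec)
  fit <- fitCodonModel(sim$alignment, sim$tree, "M0", seed = 1)
  expect_true(fit@converged)
  expect_lt(abs(fitParams(fit)$omegas[1, 1] - 0.2), 0.05)
  expect_lt(abs(fitParams(fit)$kappa - 2), 0.4)
})

test_that("nested models keep the likelihood ordering", {
  tree <- balancedCladeTree(3, 0.3, 0.15)
  om <- matrix(c(0.05, 0.05, 1, 1, 0.3, 0.9), 3, 2, byrow = TRUE)
  sim <- simulateCodonAlignment(codonSimSpec(tree = tree, omegas = om,
                                             props = c(0.5, 0.2, 0.3),
                                             nCodons = 200, seed = 33))
  aln <- sim$alignment
  m0 <- fitCodonModel(aln, tree, "M0", seed = 1)
  br <- fitCodonModel(aln, tree, "branch", seed = 1, initFrom = m0)
  fr <- fitCodonModel(aln, tree, "free_ratios", seed = 1, initFrom = br)
  m2 <- fitCodonModel(aln, tree, "M2a_rel", seed = 1)
  cmc <- fitCodonModel(aln, tree, "CmC", seed = 1, initFrom = m2)
  tol <- 1e-4
  expect_gte(fitLnL(br), fitLnL(m0) - tol)
  expect_gte(fitLnL(fr), fitLnL(br) - tol)
  expect_gte(fitLnL(cmc), fitLnL(m2) - tol)
  # free-ratios exposes one omega per branch
  expect_equal(nrow(omegaSummary(fr)), nrow(treePhylo(tree)$edge))
})

test_that("branch-site model A fits its two-group structure", {
  tree <- balancedCladeTree(3, 0.25, 0.1)
  om <- matrix(c(0.1, 0.1, 1, 1, 0.1, 3, 1, 3), 4, 2, byrow = TRUE)
  sim <- simulateCodonAlignment(codonSimSpec(
    tree = tree, omegas = om, props = c(0.4, 0.3, 0.18, 0.12),
    nCodons = 200, seed = 44))
  null <- fitCodonModel(sim$alignment, tree, "BSM_A_null", seed = 1)
  alt <- fitCodonModel(sim$alignment, tree, "BSM_A", seed = 1,
                       initFrom = null)
  expect_gte(fitLnL(alt), fitLnL(null) - 1e-4)
  res <- lrt(null, alt)
  expect_equal(res$df, 1L)
  expect_gte(fitParams(alt)$omegas[3, 2], 1)  # foreground class omega >= 1
})

test_that("CmC recovers clade-specific omega2 at identifiable scale", {
  # 12 taxa / 800 codons: enough information for the divergent site
  # class; median absolute error of each clade's omega2 within 0.1
  tree <- balancedCladeTree(6, 0.3, 0.15)
  om <- matrix(c(0.05, 0.05, 1, 1, 0.3, 1.0), 3, 2, byrow = TRUE)
  errs <- vapply(1:20, function(r) {
    sim <- simulateCodonAlignment(codonSimSpec(
      tree = tree, kappa = 2, omegas = om, props = c(0.55, 0.2, 0.25),
      nCodons = 800, seed = 40000 + r))
    f <- fitCodonModel(sim$alignment, tree, "CmC", seed = 1)
    c(abs(fitParams(f)$omegas[3, 1] - 0.3),
      abs(fitParams(f)$omegas[3, 2] - 1.0))
  }, c(0, 0))
  expect_lte(median(errs[1, ]), 0.1)
  expect_lte(median(errs[2, ]), 0.1)
})

test_that("LRT mechanics are chi-square based", {
  mkfit <- function(lnl, np) new("CodonModelFit", model = "M0", lnL = lnl,
                                 params = list(kappa = 2),
                                 npar = as.integer(np), converged = TRUE,
                                 iterations = 1L,
                                 omegaSummary = data.frame())
  same <- lrt(mkfit(-100, 2), mkfit(-100, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  res <- lrt(mkfit(-100, 2), mkfit(-98.08, 3))
  expect_equal(res$statistic, 3.84)
  expect_equal(res$p.value, 0.05, tolerance = 0.002)
  expect_error(lrt(mkfit(-90, 2), mkfit(-100, 3)), "optimizer")
  expect_error(lrt(mkfit(-100, 3), mkfit(-100, 3)), "nested")
})

test_that("NG86 counting matches its definitions", {
  r0 <- ng86dnds("ATGAAACTA", "ATGAAACTA")
  expect_equal(r0$dN, 0); expect_equal(r0$dS, 0)
  expect_equal(r0$status, "undefined")
  # one synonymous change: CTA -> CTG
  r1 <- ng86dnds("ATGCTA", "ATGCTG")
  expect_equal(r1$dN, 0)
  expect_gt(r1$dS, 0)
  # one nonsynonymous change: ATG -> ATA is Met -> Met under mito code!
  r2 <- ng86dnds("AAACTA", "AACCTA")  # Lys -> Asn, nonsynonymous
  expect_gt(r2$dN, 0)
  expect_equal(r2$Sd, 0)
  expect_error(ng86dnds("ATG", "ATGAAA"), "equal length")
  expect_error(ng86dnds("AT-", "ATG"), "gaps")
})

test_that("NG86 omega tracks the generating omega and the ML estimate", {
  two <- ape::read.tree(text = "(a:0.25,b:0.25);")
  lt <- LabeledTree(two)
  omegas <- c(0.05, 0.15, 0.3, 0.5, 0.8, 1.2)
  est <- ml <- numeric(length(omegas))
  for (i in seq_along(omegas)) {
    sim <- simulateCodonAlignment(codonSimSpec(
      tree = lt, omegas = omegas[i], nCodons = 400, seed = 500 + i))
    s <- as.character(alignedSeqs(sim$alignment))
    r <- ng86dnds(s[[1]], s[[2]])
    est[i] <- r$omega
    fit <- fitCodonModel(sim$alignment, lt, "M0", seed = 1)
    ml[i] <- fitParams(fit)$omegas[1, 1]
  }
  expect_gt(cor(est, omegas, method = "spearman"), 0.8)
  expect_gt(cor(est, ml, method = "spearman"), 0.8)
  # unbiasedness at omega = 0.3 over replicate pairs
  reps <- vapply(1:30, function(r) {
    sim <- simulateCodonAlignment(codonSimSpec(
      tree = lt, omegas = 0.3, nCodons = 300, seed = 700 + r))
    s <- as.character(alignedSeqs(sim$alignment))
    ng86dnds(s[[1]], s[[2]])$omega
  }, 0)
  expect_gt(mean(reps), 0.2)
  expect_lt(mean(reps), 0.4)
})

test_that("mass~omega regression reports correlations and errors", {
  mass <- c(4, 6, 8, 10, 12, 13, 15)
  omega <- 0.01 * mass
  r <- suppressWarnings(massOmegaCorrelation(mass, omega))
  expect_equal(r$r, 1)
  expect_error(massOmegaCorrelation(mass, rep(0.2, 7)), "zero variance")
  expect_error(massOmegaCorrelation(1:2, 1:2), "at least 3")
  # independent pairs give uniform p-values
  set.seed(81)
  ps <- vapply(1:400, function(i)
    massOmegaCorrelation(rnorm(7), rnorm(7))$p.value, 0)
  ks <- stats::ks.test(ps, "punif")
  expect_gt(ks$p.value, 0.01)
})
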
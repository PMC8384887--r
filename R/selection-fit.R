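# Model fitting: bounded quasi-Newton over transformed parameters with
# seeded multi-starts. Parameter packing is model-specific; proportions go
# through an additive-logistic transform, rate parameters through log.

.OMEGA_MIN <- 1e-4
.OMEGA_MAX <- 50
.KAPPA_MIN <- 0.1
.KAPPA_MAX <- 99

# softmax over (a, b, 0)
.props3 <- function(a, b) {
  e <- c(exp(a), exp(b), 1)
  e / sum(e)
}

# model definitions: pack/unpack between optimizer vector and
# (kappa, omegas CxG, props)
.modelDef <- function(model, G) {
  lo_w <- log(.OMEGA_MIN); hi_w <- log(.OMEGA_MAX)
  lo_k <- log(.KAPPA_MIN); hi_k <- log(.KAPPA_MAX)
  switch(model,
    M0 = list(
      npar = 2L,
      lower = c(lo_k, lo_w), upper = c(hi_k, hi_w),
      init = function(r) c(log(r$kappa), log(r$omega)),
      unpack = function(th, G) list(kappa = exp(th[1]),
        omegas = matrix(exp(th[2]), 1, G), props = 1)),
    branch = list(
      npar = 1L + G,
      lower = c(lo_k, rep(lo_w, G)), upper = c(hi_k, rep(hi_w, G)),
      init = function(r) c(log(r$kappa), log(r$omega * r$jit(G))),
      unpack = function(th, G) list(kappa = exp(th[1]),
        omegas = matrix(exp(th[1 + seq_len(G)]), 1, G), props = 1)),
    M2a_rel = list(
      npar = 5L,
      lower = c(lo_k, -12, -12, lo_w, lo_w),
      upper = c(hi_k, 12, 12, log(0.999), hi_w),
      init = function(r) c(log(r$kappa), r$a, r$b, log(r$w0), log(r$w2)),
      unpack = function(th, G) {
        p <- .props3(th[2], th[3])
        list(kappa = exp(th[1]),
             omegas = matrix(rep(c(exp(th[4]), 1, exp(th[5])), G), 3, G),
             props = p)
      }),
    CmC = list(
      npar = 4L + G,
      lower = c(lo_k, -12, -12, lo_w, rep(lo_w, G)),
      upper = c(hi_k, 12, 12, log(0.999), rep(hi_w, G)),
      init = function(r) c(log(r$kappa), r$a, r$b, log(r$w0),
                           log(r$w2 * r$jit(G))),
      unpack = function(th, G) {
        p <- .props3(th[2], th[3])
        w2 <- exp(th[4 + seq_len(G)])
        list(kappa = exp(th[1]),
             omegas = rbind(rep(exp(th[4]), G), rep(1, G), w2),
             props = p)
      }),
    BSM_A = list(
      npar = 5L,
      lower = c(lo_k, -12, -12, lo_w, 0),
      upper = c(hi_k, 12, 12, log(0.999), hi_w),
      init = function(r) c(log(r$kappa), r$a, r$b, log(r$w0),
                           log(max(r$w2, 1.05))),
      unpack = function(th, G) {
        stopifnot(G == 2L)
        p3 <- .props3(th[2], th[3])
        w0 <- exp(th[4]); w2 <- exp(th[5])
        p <- c(p3[1], p3[2],
               p3[3] * p3[1] / (p3[1] + p3[2]),
               p3[3] * p3[2] / (p3[1] + p3[2]))
        list(kappa = exp(th[1]),
             omegas = rbind(c(w0, w0), c(1, 1), c(w0, w2), c(1, w2)),
             props = p)
      }),
    BSM_A_null = list(
      npar = 4L,
      lower = c(lo_k, -12, -12, lo_w),
      upper = c(hi_k, 12, 12, log(0.999)),
      init = function(r) c(log(r$kappa), r$a, r$b, log(r$w0)),
      unpack = function(th, G) {
        stopifnot(G == 2L)
        p3 <- .props3(th[2], th[3])
        w0 <- exp(th[4])
        p <- c(p3[1], p3[2],
               p3[3] * p3[1] / (p3[1] + p3[2]),
               p3[3] * p3[2] / (p3[1] + p3[2]))
        list(kappa = exp(th[1]),
             omegas = rbind(c(w0, w0), c(1, 1), c(w0, 1), c(1, 1)),
             props = p)
      }),
    stop("unknown model: ", model)
  )
}

# forward-difference gradient reusing the cached objective value
.fdGrad <- function(fn, th, f0, lower, upper, h = 1e-6) {
  g <- numeric(length(th))
  for (i in seq_along(th)) {
    hi <- max(h, h * abs(th[i]))
    step <- if (th[i] + hi <= upper[i]) hi else -hi
    thi <- th; thi[i] <- th[i] + step
    g[i] <- (fn(thi) - f0) / step
  }
  g
}

#' Fit a codon substitution model by maximum likelihood
#'
#' Maximizes the pruning log-likelihood over kappa and the model's omega
#' structure with bounded quasi-Newton (L-BFGS-B) runs from five seeded
#' starts (one informed, four random); the best exploratory start is
#' polished to convergence (|delta lnL| < 1e-6). Branch lengths are fixed
#' to the input tree. Omega is bounded to [1e-4, 50], kappa to [0.1, 99].
#'
#' Models:
#' \describe{
#'   \item{M0}{one omega for the whole tree.}
#'   \item{branch}{one omega per branch group of the tree.}
#'   \item{free_ratios}{one omega per branch (every edge its own group).}
#'   \item{M2a_rel}{three site classes: omega0 < 1, omega1 = 1, omega2
#'     free; no clade divergence. Null for CmC.}
#'   \item{CmC}{clade model C: classes 0/1 shared, class-2 omega divergent
#'     per branch group.}
#'   \item{BSM_A, BSM_A_null}{branch-site model A on a two-group
#'     (background/foreground) tree; the null fixes omega2 = 1.}
#' }
#'
#' @param aln a [CodonAlignment-class].
#' @param tree a [LabeledTree-class]; its groups define the branch/clade
#'   partition where the model needs one.
#' @param model model name, see Details.
#' @param pi codon frequencies (default F3x4 from the alignment).
#' @param nstarts number of multi-starts (default 5).
#' @param seed seed for the random starts.
#' @param initFrom optional [CodonModelFit-class] of a nested model whose
#'   estimates seed the informed start (e.g. pass the M2a_rel fit when
#'   fitting CmC); guards the nested-model lnL ordering.
#' @return A [CodonModelFit-class].
#' @examples
#' \donttest{
#' sim <- simulateCodonAlignment(codonSimSpec(nCodons = 120, seed = 1))
#' fit <- fitCodonModel(sim$alignment, sim$tree, "M0", seed = 1)
#' }
#' @export
fitCodonModel <- function(aln, tree,
                          model = c("M0", "branch", "free_ratios", "M2a_rel",
                                    "CmC", "BSM_A", "BSM_A_null"),
                          pi = NULL, nstarts = 5L, seed = 1L,
                          initFrom = NULL) {
  model <- match.arg(model)
  stopifnot(is(aln, "CodonAlignment"), is(tree, "LabeledTree"))
  space <- codonSpace(aln@codeId)
  if (is.null(pi)) pi <- f3x4Frequencies(aln)

  fitModel <- model
  if (model == "free_ratios") {
    ne <- nrow(treePhylo(tree)$edge)
    tree <- LabeledTree(treePhylo(tree), seq_len(ne),
                        groupNames = paste0("edge", seq_len(ne)))
    fitModel <- "branch"
  }
  G <- max(edgeGroups(tree))
  if (fitModel %in% c("M0", "M2a_rel")) G <- 1L
  if (model %in% c("BSM_A", "BSM_A_null") && max(edgeGroups(tree)) != 2L)
    stop("branch-site model A needs exactly one foreground group")
  if (fitModel %in% c("branch", "CmC") && max(edgeGroups(tree)) < 2L)
    stop(model, " needs at least one non-background branch group")

  def <- .modelDef(fitModel, G)
  pat <- .sitePatterns(aln, space)
  # for M0/M2a_rel all edges share one group
  treeG <- if (G == 1L && max(edgeGroups(tree)) > 1L)
    LabeledTree(treePhylo(tree)) else tree

  evals <- 0L
  negll <- function(th) {
    evals <<- evals + 1L
    u <- def$unpack(th, G)
    r <- .mixtureLogLik(pat, treeG, u$kappa, u$omegas, u$props, pi, space)
    if (!is.finite(r$lnL)) return(1e10)
    -r$lnL
  }

  # starting points: one informed (optionally from a nested fit), the
  # rest randomized; starts are scored, the two most promising get a
  # short exploratory run, and the winner is polished to convergence
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  informed <- list(kappa = 2, omega = 0.4, a = log(2), b = log(1),
                   w0 = 0.1, w2 = 1.2, jit = function(n) rep(1, n))
  if (!is.null(initFrom)) {
    p <- fitParams(initFrom)
    informed$kappa <- p$kappa
    informed$omega <- mean(p$omegas[1, ])
    if (length(p$props) >= 3) {
      pr <- pmax(p$props[1:3], 1e-6)
      informed$a <- log(pr[1] / pr[3]); informed$b <- log(pr[2] / pr[3])
      informed$w0 <- min(p$omegas[1, 1], 0.99)
      informed$w2 <- p$omegas[min(3, nrow(p$omegas)), 1]
    }
  }
  mkstart <- function(random) {
    r <- informed
    if (random) {
      r$kappa <- exp(stats::runif(1, log(0.5), log(8)))
      r$omega <- exp(stats::runif(1, log(0.02), log(3)))
      r$a <- stats::runif(1, -1, 2); r$b <- stats::runif(1, -1, 2)
      r$w0 <- stats::runif(1, 0.01, 0.6)
      r$w2 <- exp(stats::runif(1, log(0.2), log(4)))
      r$jit <- function(n) exp(stats::runif(n, -0.5, 0.5))
    }
    pmin(pmax(def$init(r), def$lower), def$upper)
  }
  starts <- lapply(seq_len(max(1L, nstarts)), function(i) mkstart(i > 1L))
  sc <- vapply(starts, negll, 0)
  top <- order(sc)[seq_len(min(2L, length(starts)))]
  explore <- lapply(starts[top], function(s) {
    stats::optim(s, negll,
                 gr = function(th) .fdGrad(negll, th, negll(th),
                                           def$lower, def$upper),
                 method = "L-BFGS-B", lower = def$lower, upper = def$upper,
                 control = list(maxit = 8, factr = 1e12))
  })
  best <- explore[[which.min(vapply(explore, `[[`, 0, "value"))]]
  final <- stats::optim(best$par, negll,
                        gr = function(th) .fdGrad(negll, th, negll(th),
                                                  def$lower, def$upper),
                        method = "L-BFGS-B",
                        lower = def$lower, upper = def$upper,
                        control = list(maxit = 500, factr = 4.5e9))
  u <- def$unpack(final$par, G)
  gn <- if (G == 1L) "all" else groupNames(tree)[seq_len(G)]
  osum <- data.frame(
    class = rep(seq_len(nrow(rbind(u$omegas))) - 1L, each = G),
    group = rep(gn, nrow(rbind(u$omegas))),
    prop = rep(round(u$props, 6), each = G),
    omega = as.vector(t(rbind(u$omegas))))
  new("CodonModelFit", model = model, lnL = -final$value,
      params = list(kappa = u$kappa, omegas = rbind(u$omegas),
                    props = u$props, pi = pi,
                    groupNames = gn),
      npar = def$npar, converged = final$convergence == 0L,
      iterations = evals, omegaSummary = osum)
}

#' Likelihood ratio test between nested codon-model fits
#'
#' Computes `2 * (lnL_alt - lnL_null)` (clipped at zero) and compares it to
#' a chi-square distribution. The degrees of freedom default to the
#' difference in free parameter counts (CmC vs M2a_rel: the number of extra
#' divergent-omega parameters; branch-site model A vs its null: 1).
#'
#' @param nullFit,altFit nested [CodonModelFit-class] objects.
#' @param df degrees of freedom; default `fitNpar(altFit) - fitNpar(nullFit)`.
#' @return A list of class `"mrLRT"` with `null`, `alt`, `statistic`, `df`,
#'   `p.value`.
#' @export
lrt <- function(nullFit, altFit, df = NULL) {
  stopifnot(is(nullFit, "CodonModelFit"), is(altFit, "CodonModelFit"))
  if (is.null(df)) df <- fitNpar(altFit) - fitNpar(nullFit)
  if (df < 1L) stop("models are not nested (df < 1)")
  stat <- 2 * (fitLnL(altFit) - fitLnL(nullFit))
  if (stat < -0.1)
    stop("alternative lnL far below null lnL (", round(stat, 4),
         "): optimizer failure")
  stat <- max(0, stat)
  structure(list(null = nullFit@model, alt = altFit@model,
                 statistic = stat, df = df,
                 p.value = stats::pchisq(stat, df, lower.tail = FALSE)),
            class = "mrLRT")
}

#' @export
print.mrLRT <- function(x, ...) {
  cat(sprintf("LRT %s vs %s: 2dlnL = %.4f, df = %d, p = %.4g\n",
              x$alt, x$null, x$statistic, x$df, x$p.value))
  invisible(x)
}

#' Nei-Gojobori (1986) pairwise dN/dS
#'
#' Counting-based estimate of synonymous and nonsynonymous distances for a
#' gap-free in-frame pair: synonymous/nonsynonymous site fractions per
#' codon position (changes to stop codons excluded from the possible-change
#' set), pathway counting with equal weighting over substitution orders
#' (pathways through stop codons skipped when any stop-free pathway
#' exists), and Jukes-Cantor multiple-hit correction. Serves as the
#' counting oracle for the ML engine.
#'
#' @param seq1,seq2 equal-length in-frame DNA strings without gaps.
#' @param codeId genetic code id.
#' @return List with `dN`, `dS`, `omega`, the raw counts (`S`, `N`, `Sd`,
#'   `Nd`) and a `status` of `"ok"`, `"undefined"` (dS = 0) or
#'   `"saturated"`.
#' @examples
#' ng86dnds("ATGAAACTA", "ATGAAGCTG")  # two synonymous changes
#' @export
ng86dnds <- function(seq1, seq2, codeId = "2") {
  space <- codonSpace(codeId)
  gc <- Biostrings::getGeneticCode(codeId)
  s1 <- toupper(seq1); s2 <- toupper(seq2)
  if (nchar(s1) != nchar(s2)) stop("sequences must have equal length")
  if (nchar(s1) %% 3L != 0L) stop("length must be a multiple of 3")
  if (grepl("-", s1) || grepl("-", s2)) stop("gaps are not allowed")
  n <- nchar(s1) %/% 3L
  cod1 <- substring(s1, 3 * seq_len(n) - 2, 3 * seq_len(n))
  cod2 <- substring(s2, 3 * seq_len(n) - 2, 3 * seq_len(n))
  keep <- cod1 %in% space$codons & cod2 %in% space$codons
  cod1 <- cod1[keep]; cod2 <- cod2[keep]
  bases <- c("A", "C", "G", "T")

  sites <- function(cod) {
    ch <- strsplit(cod, "")[[1]]
    fS <- 0
    for (p in 1:3) {
      alt <- bases[bases != ch[p]]
      muts <- vapply(alt, function(b) {
        x <- ch; x[p] <- b; paste0(x, collapse = "")
      }, "")
      ok <- !(gc[muts] == "*")
      if (!any(ok)) next
      fS <- fS + sum(gc[muts[ok]] == gc[cod]) / sum(ok)
    }
    c(S = fS, N = 3 - fS)
  }
  st <- vapply(unique(c(cod1, cod2)), sites, c(S = 0, N = 0))
  S <- sum((st["S", cod1] + st["S", cod2]) / 2)
  N <- sum((st["N", cod1] + st["N", cod2]) / 2)

  pathdiff <- function(a, b) {
    pos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    k <- length(pos)
    if (k == 0L) return(c(Sd = 0, Nd = 0))
    perms <- if (k == 1L) list(pos) else
      if (k == 2L) list(pos, rev(pos)) else
      lapply(list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1)),
             function(o) pos[o])
    walk <- function(order) {
      cur <- a; sd <- 0; nd <- 0
      for (p in order) {
        nxt <- strsplit(cur, "")[[1]]
        nxt[p] <- substr(b, p, p)
        nxt <- paste0(nxt, collapse = "")
        if (gc[nxt] == "*") return(NULL)
        if (gc[cur] == gc[nxt]) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      c(Sd = sd, Nd = nd)
    }
    res <- lapply(perms, walk)
    ok <- !vapply(res, is.null, TRUE)
    if (!any(ok)) {  # every pathway crosses a stop: count through them
      res <- lapply(perms, function(order) {
        cur <- a; sd <- 0; nd <- 0
        for (p in order) {
          nxt <- strsplit(cur, "")[[1]]
          nxt[p] <- substr(b, p, p)
          nxt <- paste0(nxt, collapse = "")
          if (gc[cur] == gc[nxt]) sd <- sd + 1 else nd <- nd + 1
          cur <- nxt
        }
        c(Sd = sd, Nd = nd)
      })
      ok <- rep(TRUE, length(res))
    }
    Reduce(`+`, res[ok]) / sum(ok)
  }
  dd <- mapply(function(a, b) pathdiff(a, b), cod1, cod2)
  Sd <- sum(dd["Sd", ]); Nd <- sum(dd["Nd", ])

  jc <- function(p) {
    if (p >= 0.75) return(NA_real_)
    -0.75 * log(1 - 4 * p / 3)
  }
  dS <- if (S > 0) jc(Sd / S) else NA_real_
  dN <- if (N > 0) jc(Nd / N) else NA_real_
  status <- "ok"
  omega <- NA_real_
  if (is.na(dS) || is.na(dN)) status <- "saturated"
  else if (dS == 0) status <- "undefined"
  else omega <- dN / dS
  list(dN = dN, dS = dS, omega = omega, S = S, N = N, Sd = Sd, Nd = Nd,
       status = status)
}

#' Body-mass ~ omega correlation/regression
#'
#' Tests for a relation between species body mass and terminal-branch omega
#' estimates: correlation coefficient (Pearson or Spearman) with its
#' two-sided p-value, plus the least-squares slope of `omega ~ mass`.
#'
#' @param mass per-species body masses (kg).
#' @param omega per-species terminal-branch omega estimates.
#' @param method `"pearson"` or `"spearman"`.
#' @return List with `r`, `p.value`, `slope`, `slope.p`, `n`.
#' @export
massOmegaCorrelation <- function(mass, omega,
                                 method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(mass) == length(omega))
  if (length(mass) < 3L) stop("need at least 3 paired observations")
  if (stats::sd(mass) == 0 || stats::sd(omega) == 0)
    stop("zero variance in mass or omega")
  ct <- suppressWarnings(stats::cor.test(mass, omega, method = method))
  fit <- stats::lm(omega ~ mass)
  cf <- summary(fit)$coefficients
  list(r = unname(ct$estimate), p.value = ct$p.value,
       slope = unname(cf[2, 1]), slope.p = unname(cf[2, 4]),
       n = length(mass))
}
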
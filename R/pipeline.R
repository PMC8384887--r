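# Pipeline stages as functions: each takes a validated RunConfig (a YAML
# file or a named list), writes a stable output bundle with manifest.json,
# and is idempotent given identical config + seed.

.CONFIG_KEYS <- list(
  characterize = c("genbank", "out", "seed", "motif_library", "kinds"),
  divergence = c("genbank", "cr_alignment", "genes", "out", "seed",
                 "window", "step", "regions",
                 "match", "mismatch", "gap_open", "gap_ext"),
  selection = c("alignments", "tree", "branch_map", "models", "out",
                "seed", "nstarts", "mass_table"),
  simulate = c("what", "out", "seed", "n_codons", "kappa", "omega",
               "str_copies", "n_haplotypes", "rates", "planted_sites"))

#' Load and validate a pipeline run configuration
#'
#' Configurations are YAML files (or equivalent named lists). Unknown keys
#' are rejected; referenced input paths must exist at validation time.
#'
#' @param config path to a YAML file or a named list.
#' @param stage pipeline stage the config is for.
#' @return The validated config as a list (with `out` defaulted to
#'   `"mitorelax_out"`).
#' @export
readRunConfig <- function(config,
                          stage = c("characterize", "divergence",
                                    "selection", "simulate")) {
  stage <- match.arg(stage)
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (!is.list(cfg)) stop("config must be a YAML file or a named list")
  unknown <- setdiff(names(cfg), .CONFIG_KEYS[[stage]])
  if (length(unknown))
    stop("unknown config key(s) for stage '", stage, "': ",
         paste(unknown, collapse = ", "))
  for (key in c("genbank", "alignments")) {
    for (p in cfg[[key]]) if (!file.exists(p))
      stop("input path does not exist: ", p)
  }
  for (key in c("tree", "branch_map", "mass_table", "motif_library",
                "cr_alignment")) {
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]]))
      stop("input path does not exist: ", cfg[[key]])
  }
  if (is.null(cfg$out)) cfg$out <- "mitorelax_out"
  if (is.null(cfg$seed)) cfg$seed <- 1L
  cfg
}

.writeManifest <- function(dir, stage, cfg, files, errors = list()) {
  manifest <- list(
    tool = "mitorelax",
    version = as.character(utils::packageVersion("mitorelax")),
    stage = stage,
    seed = cfg$seed,
    config = cfg[order(names(cfg))],
    files = sort(unname(files)),
    errors = errors)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Characterize mitogenomes
#'
#' For each input GenBank record: composition and skews (genome + per-gene
#' sense strand), RSCU and amino-acid usage over the PCGs, stop-codon
#' statuses, frameshift reports, gene-order comparison against the
#' ancestral avian order, and the CR annotation (BED + TSV). Per-record
#' failures are isolated and logged in the manifest; the call fails only
#' if every record fails.
#'
#' @param config config path or list: keys `genbank` (vector of flatfile
#'   paths), `out`, `seed`, optional `motif_library`.
#' @return The manifest, invisibly.
#' @export
runCharacterize <- function(config) {
  cfg <- readRunConfig(config, "characterize")
  if (!length(cfg$genbank)) stop("usage error: no GenBank inputs")
  dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
  lib <- if (is.null(cfg$motif_library)) motifLibrary() else
    motifLibrary(cfg$motif_library)
  files <- character(); errors <- list(); ok <- 0L
  for (path in cfg$genbank) {
    res <- tryCatch({
      g <- readGenBank(path)
      id <- genomeId(g)
      pfx <- file.path(cfg$out, id)
      comp <- compositionTable(g)
      utils::write.table(comp, paste0(pfx, "_composition.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      ft <- featureTable(g)
      pcgs <- ft$name[ft$kind == "PCG"]
      cds <- lapply(pcgs, extractGene, genome = g)
      # usage statistics want readable CDSs: apply the frameshift skip
      # where one is detected, then complete truncated stops with A's
      cds3 <- lapply(cds, function(s) {
        det <- detectFrameshift(s)
        if (isTRUE(det$detected)) {
          p <- det$skipPosition
          s <- paste0(substr(s, 1L, p), substr(s, p + 2L, nchar(s)))
        }
        if (nchar(s) %% 3L != 0L)
          s <- paste0(s, strrep("A", 3L - nchar(s) %% 3L))
        s
      })
      rs <- rscu(cds3)
      utils::write.table(rs, paste0(pfx, "_rscu.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      aa <- aminoAcidUsage(cds3)
      utils::write.table(data.frame(aa = names(aa), freq = as.numeric(aa)),
                         paste0(pfx, "_aa_usage.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      stops <- do.call(rbind, lapply(pcgs, function(nm) {
        st <- detectIncompleteStop(g, nm)
        data.frame(gene = nm, status = st$status,
                   terminal = st$terminalCodon,
                   abuts_downstream = st$abutsDownstream)
      }))
      utils::write.table(stops, paste0(pfx, "_stop_codons.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      fs <- do.call(rbind, lapply(seq_along(pcgs), function(i) {
        r <- detectFrameshift(cds[[i]])
        data.frame(gene = pcgs[i], detected = r$detected,
                   skip_position = r$skipPosition,
                   corrected_protein_length = r$correctedProteinLength,
                   note = r$note)
      }))
      utils::write.table(fs, paste0(pfx, "_frameshift.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      sig <- geneOrderSignature(g)
      cmpGO <- compareGeneOrder(sig)
      writeGeneOrderTSV(sig, paste0(pfx, "_gene_order.tsv"))
      go <- data.frame(genome = id, ancestral_avian_match = cmpGO$match,
                       first_mismatch = cmpGO$firstMismatch)
      utils::write.table(go, paste0(pfx, "_gene_order_match.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      if ("CR" %in% ft$name) {
        ann <- annotateCR(extractGene(g, "CR"), library = lib)
        writeCRAnnotation(ann, bedPath = paste0(pfx, "_cr.bed"),
                          tsvPath = paste0(pfx, "_cr.tsv"),
                          chrom = paste0(id, "_CR"))
      }
      paste0(pfx, c("_composition.tsv", "_rscu.tsv", "_aa_usage.tsv",
                    "_stop_codons.tsv", "_frameshift.tsv",
                    "_gene_order.tsv", "_gene_order_match.tsv",
                    if ("CR" %in% ft$name) c("_cr.bed", "_cr.tsv")))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[path]] <- conditionMessage(res)
    } else {
      files <- c(files, res); ok <- ok + 1L
    }
  }
  if (ok == 0L) stop("all records failed: ",
                     paste(unlist(errors), collapse = "; "))
  invisible(.writeManifest(cfg$out, "characterize", cfg, files, errors))
}

#' Per-gene identity matrices and CR entropy profiles
#'
#' @param config config path or list: `genbank` (two or more records)
#'   and/or `cr_alignment` (aligned FASTA); optional `genes` (default all
#'   shared PCG/rRNA), `window`, `step`, `regions`
#'   (list of `name`/`start`/`end`, 0-based half-open), alignment scores.
#' @return The manifest, invisibly.
#' @export
runDivergence <- function(config) {
  cfg <- readRunConfig(config, "divergence")
  dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
  files <- character(); errors <- list()
  if (length(cfg$genbank) >= 2L) {
    genomes <- lapply(cfg$genbank, readGenBank)
    genes <- cfg$genes
    if (is.null(genes)) {
      tabs <- lapply(genomes, function(g) {
        ft <- featureTable(g); ft$name[ft$kind %in% c("PCG", "rRNA")]
      })
      genes <- Reduce(intersect, tabs)
    }
    args <- list(match = cfg$match, mismatch = cfg$mismatch,
                 gapOpen = cfg$gap_open, gapExt = cfg$gap_ext)
    args <- args[!vapply(args, is.null, TRUE)]
    for (gene in genes) {
      res <- tryCatch({
        m <- do.call(identityMatrix, c(list(gene, genomes), args))
        f <- file.path(cfg$out, paste0("identity_", gene, ".tsv"))
        writeIdentityTSV(m, f)
        f
      }, error = function(e) e)
      if (inherits(res, "error")) errors[[gene]] <- conditionMessage(res)
      else files <- c(files, res)
    }
  }
  if (!is.null(cfg$cr_alignment)) {
    msa <- readFasta(cfg$cr_alignment)
    prof <- windowEntropy(msa, window = if (is.null(cfg$window)) 50L else cfg$window,
                          step = if (is.null(cfg$step)) 1L else cfg$step)
    f <- file.path(cfg$out, "entropy.tsv")
    writeEntropyTSV(prof, f); files <- c(files, f)
    regions <- if (is.null(cfg$regions)) NULL else
      do.call(rbind, lapply(cfg$regions, as.data.frame))
    ps <- polymorphicSites(msa, regions)
    f <- file.path(cfg$out, "polymorphic_sites.tsv")
    utils::write.table(ps, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f)
  }
  if (!length(files))
    stop("usage error: need >= 2 GenBank inputs or a CR alignment")
  invisible(.writeManifest(cfg$out, "divergence", cfg, files, errors))
}

#' Fit selection models and LRTs over gene alignments
#'
#' For each input codon alignment: cleans codon columns, fits the
#' requested model pairs on the labeled tree, and writes fit parameters
#' and LRT tables (TSV + JSON). Default comparison is CmC vs M2a_rel;
#' `"branch"` (vs M0) and `"BSM_A"` (vs its omega2 = 1 null) are also
#' understood. A mass table (TSV: `taxon`, `mass_kg`) adds the
#' mass ~ terminal-omega regression from a free-ratios fit.
#'
#' @param config config path or list: `alignments`, `tree`, optional
#'   `branch_map`, `models`, `nstarts`, `mass_table`, `out`, `seed`.
#' @return The manifest, invisibly.
#' @export
runSelection <- function(config) {
  cfg <- readRunConfig(config, "selection")
  if (!length(cfg$alignments)) stop("usage error: no alignments")
  if (is.null(cfg$tree)) stop("usage error: no tree")
  dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
  tree <- readLabeledTree(cfg$tree, branchMap = cfg$branch_map)
  models <- if (is.null(cfg$models)) "CmC" else cfg$models
  nstarts <- if (is.null(cfg$nstarts)) 5L else cfg$nstarts
  files <- character(); fitrows <- list(); lrtrows <- list()
  freefits <- list()
  for (path in cfg$alignments) {
    gene <- tools::file_path_sans_ext(basename(path))
    aln <- cleanCodonColumns(readCodonAlignment(path))
    miss <- setdiff(treePhylo(tree)$tip.label, taxa(aln))
    extra <- setdiff(taxa(aln), treePhylo(tree)$tip.label)
    if (length(miss) || length(extra))
      stop("taxon mismatch for ", gene,
           if (length(miss)) paste0("; missing from alignment: ",
                                    paste(miss, collapse = ", ")),
           if (length(extra)) paste0("; absent from tree: ",
                                     paste(extra, collapse = ", ")))
    for (model in models) {
      pair <- switch(model,
        CmC = c("M2a_rel", "CmC"),
        branch = c("M0", "branch"),
        BSM_A = c("BSM_A_null", "BSM_A"),
        free_ratios = c("M0", "free_ratios"),
        stop("unknown model requested: ", model))
      f0 <- fitCodonModel(aln, tree, pair[1], nstarts = nstarts,
                          seed = cfg$seed)
      f1 <- fitCodonModel(aln, tree, pair[2], nstarts = nstarts,
                          seed = cfg$seed, initFrom = f0)
      test <- lrt(f0, f1)
      for (f in list(f0, f1)) {
        os <- omegaSummary(f)
        fitrows[[length(fitrows) + 1L]] <- cbind(
          data.frame(gene = gene, model = f@model, lnL = fitLnL(f),
                     kappa = fitParams(f)$kappa,
                     converged = f@converged), os)
      }
      lrtrows[[length(lrtrows) + 1L]] <- data.frame(
        gene = gene, null = test$null, alt = test$alt,
        statistic = test$statistic, df = test$df, p_value = test$p.value)
      if (pair[2] == "free_ratios") freefits[[gene]] <- f1
    }
  }
  fits <- do.call(rbind, fitrows)
  lrts <- do.call(rbind, lrtrows)
  ffit <- file.path(cfg$out, "fits.tsv")
  flrt <- file.path(cfg$out, "lrt.tsv")
  utils::write.table(fits, ffit, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(lrts, flrt, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(fits = fits, lrt = lrts),
                       file.path(cfg$out, "selection.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(files, ffit, flrt, file.path(cfg$out, "selection.json"))
  if (!is.null(cfg$mass_table) && length(freefits)) {
    mass <- utils::read.delim(cfg$mass_table, stringsAsFactors = FALSE)
    phy <- treePhylo(tree)
    tipEdge <- match(seq_along(phy$tip.label), phy$edge[, 2])
    rows <- lapply(names(freefits), function(gene) {
      os <- omegaSummary(freefits[[gene]])
      tipOmega <- os$omega[tipEdge]
      keep <- match(mass$taxon, phy$tip.label)
      mo <- massOmegaCorrelation(mass$mass_kg, tipOmega[keep])
      data.frame(gene = gene, r = mo$r, p_value = mo$p.value,
                 slope = mo$slope, slope_p = mo$slope.p, n = mo$n)
    })
    f <- file.path(cfg$out, "mass_omega.tsv")
    utils::write.table(do.call(rbind, rows), f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, f)
  }
  invisible(.writeManifest(cfg$out, "selection", cfg, files))
}

#' Generate a synthetic dataset bundle
#'
#' Dispatches to the generators and writes the data next to its truth
#' record (JSON): `what = "mitogenome"` (GenBank + truth),
#' `"codon_alignment"` (FASTA + labeled Newick + truth) or
#' `"cr_haplotypes"` (aligned FASTA + truth).
#'
#' @param config config path or list: `what`, `out`, `seed` and the
#'   generator knobs (`n_codons`, `kappa`, `omega`, `str_copies`,
#'   `n_haplotypes`, `rates`, `planted_sites`).
#' @return The manifest, invisibly.
#' @export
runSimulate <- function(config) {
  cfg <- readRunConfig(config, "simulate")
  what <- cfg$what
  if (is.null(what) ||
      !what %in% c("mitogenome", "codon_alignment", "cr_haplotypes"))
    stop("config key 'what' must be one of mitogenome, codon_alignment, ",
         "cr_haplotypes")
  dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  if (what == "mitogenome") {
    spec <- mitogenomeSpec(
      crStrCopies = if (is.null(cfg$str_copies)) 20L else cfg$str_copies,
      seed = cfg$seed)
    sim <- simulateMitogenome(spec)
    fg <- file.path(cfg$out, "mitogenome.gb")
    writeGenBank(sim$genome, fg)
    ft <- file.path(cfg$out, "mitogenome_truth.json")
    jsonlite::write_json(sim$truth, ft, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    files <- c(fg, ft)
  } else if (what == "codon_alignment") {
    spec <- codonSimSpec(
      nCodons = if (is.null(cfg$n_codons)) 300L else cfg$n_codons,
      kappa = if (is.null(cfg$kappa)) 2 else cfg$kappa,
      omegas = if (is.null(cfg$omega)) 0.2 else cfg$omega,
      seed = cfg$seed)
    sim <- simulateCodonAlignment(spec)
    fa <- file.path(cfg$out, "alignment.fasta")
    writeCodonAlignment(sim$alignment, fa)
    ftr <- file.path(cfg$out, "tree.nwk")
    writeLabeledTree(sim$tree, ftr)
    ft <- file.path(cfg$out, "alignment_truth.json")
    jsonlite::write_json(sim$truth, ft, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    files <- c(fa, ftr, ft)
  } else {
    msim <- simulateMitogenome(mitogenomeSpec(seed = cfg$seed))
    cr <- extractGene(msim$genome, "CR")
    lay <- msim$truth$crLayout
    domains <- data.frame(
      name = c("I", "II", "III"),
      start = c(0L, lay$domI, lay$domI + lay$domII),
      end = c(lay$domI, lay$domI + lay$domII, nchar(cr)))
    n <- if (is.null(cfg$n_haplotypes)) 10L else cfg$n_haplotypes
    sim <- if (!is.null(cfg$planted_sites))
      simulateCRHaplotypes(cr, domains, plantedSites = cfg$planted_sites,
                           n = n, seed = cfg$seed)
    else
      simulateCRHaplotypes(cr, domains,
                           rates = if (is.null(cfg$rates))
                             list(I = 0.02, II = 0.002, III = 0.001)
                           else cfg$rates,
                           n = n, seed = cfg$seed)
    fa <- file.path(cfg$out, "cr_haplotypes.fasta")
    writeFasta(sim$haplotypes, fa)
    ft <- file.path(cfg$out, "cr_haplotypes_truth.json")
    jsonlite::write_json(sim$truth, ft, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    files <- c(fa, ft)
  }
  invisible(.writeManifest(cfg$out, "simulate", cfg, files))
}
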
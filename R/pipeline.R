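#' Pipeline run configuration
#'
#' Bundles stage toggles, per-stage configurations and paths for one
#' reproducible end-to-end run: simulate -> filter -> annotate -> concord ->
#' structure -> scan. When the simulate stage is disabled, input paths
#' (`vcf`, `fasta`, `gff3`, `metadata`, `chip`, `trait`) must be supplied.
#'
#' @param outDir output directory.
#' @param seed master seed for the run.
#' @param stages character vector of enabled stages, a subset of
#'   `c("simulate", "filter", "annotate", "concord", "structure", "scan")`.
#' @param sim a [simulationConfig()] (its seed is overridden by `seed`).
#' @param filter a [siteFilterConfig()].
#' @param scan a [scanConfig()].
#' @param paths named list of input paths when not simulating.
#' @param ldMaxDist maximum pair distance for the LD decay curves (bp).
#' @param duplicateThreshold identity percent for the duplicate scan.
#' @return A list of class `"RunConfig"`.
#' @export
runConfig <- function(outDir, seed = 1L,
                      stages = c("simulate", "filter", "annotate",
                                 "concord", "structure", "scan"),
                      sim = simulationConfig(seed = seed),
                      filter = siteFilterConfig(), scan = scanConfig(),
                      paths = list(), ldMaxDist = 50000,
                      duplicateThreshold = 99) {
  known <- c("simulate", "filter", "annotate", "concord", "structure", "scan")
  if (!all(stages %in% known))
    stop("unknown stage(s): ", paste(setdiff(stages, known), collapse = ", "))
  sim$seed <- as.integer(seed)
  if (!"simulate" %in% stages && length(stages) > 0L) {
    need <- c("vcf", "fasta", "gff3", "metadata")
    if (!all(need %in% names(paths)))
      stop("without the simulate stage, paths must include: ",
           paste(need, collapse = ", "))
    for (p in unlist(paths))
      if (!file.exists(p)) stop("input path does not exist: ", p)
  }
  structure(list(outDir = outDir, seed = as.integer(seed), stages = stages,
                 sim = sim, filter = filter, scan = scan, paths = paths,
                 ldMaxDist = ldMaxDist,
                 duplicateThreshold = duplicateThreshold),
            class = "RunConfig")
}

.stageLog <- function(stage, ...) {
  message("[", stage, "] ", ...)
}

#' Run the pipeline end to end
#'
#' Executes the enabled stages in fixed order with seeds derived from the
#' run seed, logs input/output counts per stage to the message stream, and
#' returns a manifest listing every produced file with its MD5 content
#' digest. Re-running with the same configuration reproduces identical
#' digests. A stage failure aborts with the failing stage named and leaves a
#' `FAILED` marker next to any partial outputs.
#'
#' @param config a [runConfig()].
#' @return `list(manifest = <data.frame file/md5>, summary = <data.frame>)`.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  summaryRows <- list()
  note <- function(stage, what, n) {
    summaryRows[[length(summaryRows) + 1L]] <<-
      data.frame(stage = stage, quantity = what, value = n,
                 stringsAsFactors = FALSE)
  }
  runStage <- function(stage, fn) {
    if (!stage %in% config$stages) return(invisible(NULL))
    tryCatch(fn(), error = function(e) {
      writeLines(paste("FAILED at stage", stage, ":", conditionMessage(e)),
                 file.path(config$outDir, "FAILED"))
      stop("pipeline failed at stage '", stage, "': ",
           conditionMessage(e), call. = FALSE)
    })
  }
  env <- new.env(parent = emptyenv())

  runStage("simulate", function() {
    .stageLog("simulate", "generating collection, seed ", config$seed)
    sim <- simulateCollection(config$sim)
    paths <- writeCollection(sim, file.path(config$outDir, "sim"))
    written <<- c(written, paths)
    env$sim <- sim
    env$genotypes <- sim$genotypes
    env$reference <- sim$reference
    env$geneModels <- sim$geneModels
    env$metadata <- sim$metadata
    env$chip <- sim$chip
    env$trait <- sim$trait
    note("simulate", "sites", nrow(sim$genotypes))
    note("simulate", "accessions", ncol(sim$genotypes))
  })
  if (!"simulate" %in% config$stages && length(config$stages) > 0L) {
    env$genotypes <- readVcfGenotypes(config$paths$vcf)
    env$reference <- readReferenceFasta(config$paths$fasta)
    env$geneModels <- readGeneModels(config$paths$gff3)
    env$metadata <- readAccessionMetadata(config$paths$metadata)
    if (!is.null(config$paths$chip))
      env$chip <- readChipMatrix(config$paths$chip)
    if (!is.null(config$paths$trait))
      env$trait <- readTraitTable(config$paths$trait)
  }

  runStage("filter", function() {
    f <- filterSites(env$genotypes, config$filter)
    env$filtered <- f$genotypes
    rp <- file.path(config$outDir, "filter_report.tsv")
    utils::write.table(f$report, rp, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    vp <- file.path(config$outDir, "filtered.vcf")
    writeVcfGenotypes(f$genotypes, vp)
    written <<- c(written, rp, vp)
    .stageLog("filter", nrow(env$genotypes), " sites in, ",
              nrow(f$genotypes), " surviving")
    note("filter", "input_sites", nrow(env$genotypes))
    note("filter", "surviving_sites", nrow(f$genotypes))
  })
  getFiltered <- function() {
    if (is.null(env$filtered)) env$genotypes else env$filtered
  }

  runStage("annotate", function() {
    ann <- annotateSnps(getFiltered(), env$geneModels, env$reference,
                        metadata = env$metadata)
    ap <- file.path(config$outDir, "annotation_report.tsv")
    writeAnnotationReport(ann, ap)
    written <<- c(written, ap)
    .stageLog("annotate", nrow(ann), " SNPs annotated")
    note("annotate", "snps", nrow(ann))
  })

  runStage("concord", function() {
    dups <- duplicateScan(getFiltered(), config$duplicateThreshold)
    dp <- file.path(config$outDir, "duplicates.tsv")
    utils::write.table(dups, dp, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written <<- c(written, dp)
    note("concord", "duplicate_pairs", nrow(dups))
    if (!is.null(env$chip)) {
      eq <- matchAccessions(env$chip, env$genotypes)
      ep <- file.path(config$outDir, "equivalents.tsv")
      utils::write.table(eq, ep, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      written <<- c(written, ep)
      note("concord", "matched_accessions", nrow(eq))
    }
    .stageLog("concord", nrow(dups), " duplicate pair(s) found")
  })

  runStage("structure", function() {
    g <- getFiltered()
    pruned <- ldPrune(g)
    ibs <- ibsMatrix(pruned)
    if (anyNA(ibs)) {
      # a pruned panel can leave accession pairs without a common called
      # site; fall back to the full filtered matrix for the distances
      ibs <- ibsMatrix(g)
    }
    nw <- njTree(ibs)$newick
    np <- file.path(config$outDir, "nj_tree.nwk")
    writeLines(nw, np)
    pca <- pcaGenotypes(pruned, k = min(10L, ncol(pruned) - 1L))
    sp <- file.path(config$outDir, "pca_scores.tsv")
    utils::write.table(data.frame(accession_id = rownames(pca$scores),
                                  pca$scores), sp, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    vp <- file.path(config$outDir, "pca_variance.tsv")
    utils::write.table(data.frame(component = seq_along(pca$variance_fraction),
                                  variance_fraction = pca$variance_fraction),
                       vp, sep = "\t", quote = FALSE, row.names = FALSE)
    written <<- c(written, np, sp, vp)
    # group-wise LD decay
    md <- env$metadata
    for (type in intersect(c("wild", "landrace", "cultivar"),
                           unique(md$germplasm_type))) {
      acc <- md$accession_id[md$germplasm_type == type]
      acc <- intersect(acc, accessionIds(g))
      if (length(acc) < 5L) next
      curve <- ldDecayCurve(g[, acc], maxDist = config$ldMaxDist)
      cp <- file.path(config$outDir, paste0("ld_decay_", type, ".tsv"))
      utils::write.table(as.data.frame(curve), cp, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      written <<- c(written, cp)
    }
    .stageLog("structure", nrow(pruned), " pruned sites; tree and PCA written")
    note("structure", "pruned_sites", nrow(pruned))
  })

  runStage("scan", function() {
    if (is.null(env$trait)) {
      .stageLog("scan", "no trait supplied; skipping")
      return(invisible(NULL))
    }
    res <- associationScan(getFiltered(), env$trait, config$scan)
    ap <- file.path(config$outDir, "association.tsv")
    utils::write.table(res$results, ap, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    regions <- peakRegions(res)
    rp <- file.path(config$outDir, "association_regions.tsv")
    utils::write.table(regions, rp, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written <<- c(written, ap, rp)
    .stageLog("scan", res$m_tests, " sites tested, ",
              sum(res$results$significant), " significant")
    note("scan", "m_tests", res$m_tests)
    note("scan", "significant_sites", sum(res$results$significant))
  })

  manifest <- if (length(written)) {
    data.frame(file = unname(written),
               md5 = unname(tools::md5sum(written)),
               stringsAsFactors = FALSE)
  } else {
    data.frame(file = character(), md5 = character())
  }
  summary <- if (length(summaryRows)) do.call(rbind, summaryRows) else
    data.frame(stage = character(), quantity = character(),
               value = numeric())
  mp <- file.path(config$outDir, "manifest.tsv")
  utils::write.table(manifest, mp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(manifest = manifest, summary = summary)
}
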
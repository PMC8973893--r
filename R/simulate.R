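#' @importFrom Biostrings DNAStringSet GENETIC_CODE
#' @importFrom stats rbeta rbinom rgeom rnorm runif
NULL

.BASES <- c("A", "C", "G", "T")
.CODON_TABLE <- local({
  gc <- Biostrings::GENETIC_CODE
  names(gc) <- names(Biostrings::GENETIC_CODE)
  gc
})
.STOP_CODONS <- names(.CODON_TABLE)[.CODON_TABLE == "*"]
.NONSTOP_CODONS <- names(.CODON_TABLE)[.CODON_TABLE != "*"]

.aa <- function(codon) unname(.CODON_TABLE[codon])

.randomDna <- function(n) paste(sample(.BASES, n, replace = TRUE), collapse = "")

.revcomp <- function(x) {
  chartr("ACGT", "TGCA",
         vapply(x, function(s)
           paste(rev(strsplit(s, "")[[1]]), collapse = ""), ""))
}

.complementBase <- function(x) chartr("ACGT", "TGCA", x)

.refAsChar <- function(reference) {
  if (is(reference, "DNAStringSet")) {
    out <- as.character(reference)
    names(out) <- names(reference)
    out
  } else {
    stopifnot(is.character(reference), !is.null(names(reference)))
    reference
  }
}

#' Configuration for the synthetic germplasm collection
#'
#' Bundles every parameter of the simulator that emulates a two-subpopulation
#' (wild / cultivated) germplasm collection: a small multi-chromosome
#' reference, stranded multi-exon gene models, Balding-Nichols diverged
#' subpopulation allele frequencies, founder-haplotype mosaic linkage
#' structure (smaller founder pool and longer copying tracts for the
#' cultivated group, emulating a domestication bottleneck and its
#' longer-range LD), planted duplicate accessions, planted coding variants of
#' every effect class, and a planted quantitative trait locus.
#'
#' @param n_chromosomes,chromosome_length genome shape (counts, bp).
#' @param n_genes number of non-overlapping protein-coding genes to place.
#' @param n_wild,n_cultivated accessions per subpopulation.
#' @param divergence Fst-like allele-frequency divergence in `[0, 1)` between
#'   the two subpopulations (Balding-Nichols).
#' @param wild_diversity,cultivated_diversity per-site probability that a
#'   segregating site remains polymorphic in the subpopulation; must satisfy
#'   `wild_diversity > cultivated_diversity` so the wild group is the more
#'   diverse, as in wild/domesticated crop collections.
#' @param n_duplicates number of planted duplicate accession pairs.
#' @param duplicate_mismatch_rate per-genotype flip probability between the
#'   members of a planted duplicate pair.
#' @param qtl_effect trait units per alt allele at the causal site.
#' @param trait_heritability fraction of trait variance explained by the
#'   causal site, in `(0, 1]`.
#' @param nocall_rate_chip no-call rate applied when subsetting the chip panel.
#' @param seed integer master seed; all stages derive from it.
#' @param n_sites total segregating sites across the genome.
#' @param chip_n_sites sites sampled onto the chip panel.
#' @param founder_pool_wild,founder_pool_cultivated founder-haplotype pool
#'   sizes for the Li-Stephens-style mosaic.
#' @param recomb_length_wild,recomb_length_cultivated mean copying-tract
#'   length (bp) of the mosaic per subpopulation.
#' @return A validated list of class `"SimulationConfig"`.
#' @export
simulationConfig <- function(n_chromosomes = 2L, chromosome_length = 50000L,
                             n_genes = 20L, n_wild = 60L, n_cultivated = 60L,
                             divergence = 0.3, wild_diversity = 1.0,
                             cultivated_diversity = 0.4, n_duplicates = 2L,
                             duplicate_mismatch_rate = 0.005,
                             qtl_effect = 1.0, trait_heritability = 0.3,
                             nocall_rate_chip = 0.1, seed = 1L,
                             n_sites = 2000L, chip_n_sites = 500L,
                             founder_pool_wild = 30L,
                             founder_pool_cultivated = 3L,
                             recomb_length_wild = 2000,
                             recomb_length_cultivated = 10000) {
  cfg <- list(n_chromosomes = as.integer(n_chromosomes),
              chromosome_length = as.integer(chromosome_length),
              n_genes = as.integer(n_genes), n_wild = as.integer(n_wild),
              n_cultivated = as.integer(n_cultivated),
              divergence = divergence, wild_diversity = wild_diversity,
              cultivated_diversity = cultivated_diversity,
              n_duplicates = as.integer(n_duplicates),
              duplicate_mismatch_rate = duplicate_mismatch_rate,
              qtl_effect = qtl_effect,
              trait_heritability = trait_heritability,
              nocall_rate_chip = nocall_rate_chip, seed = as.integer(seed),
              n_sites = as.integer(n_sites),
              chip_n_sites = as.integer(chip_n_sites),
              founder_pool_wild = as.integer(founder_pool_wild),
              founder_pool_cultivated = as.integer(founder_pool_cultivated),
              recomb_length_wild = recomb_length_wild,
              recomb_length_cultivated = recomb_length_cultivated)
  counts <- c("n_chromosomes", "chromosome_length", "n_genes", "n_wild",
              "n_cultivated", "n_sites", "chip_n_sites",
              "founder_pool_wild", "founder_pool_cultivated")
  for (f in counts)
    if (is.na(cfg[[f]]) || cfg[[f]] < 1L)
      stop("configuration error: ", f, " must be >= 1")
  if (cfg$n_duplicates < 0L)
    stop("configuration error: n_duplicates must be >= 0")
  fr <- c("divergence", "duplicate_mismatch_rate", "nocall_rate_chip")
  for (f in fr)
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop("configuration error: ", f, " must lie in [0, 1]")
  if (cfg$divergence >= 1)
    stop("configuration error: divergence must be < 1")
  if (cfg$trait_heritability <= 0 || cfg$trait_heritability > 1)
    stop("configuration error: trait_heritability must lie in (0, 1]")
  if (!(cfg$wild_diversity > cfg$cultivated_diversity))
    stop("configuration error: wild_diversity must exceed cultivated_diversity")
  if (cfg$wild_diversity > 1 || cfg$cultivated_diversity <= 0)
    stop("configuration error: diversity scalers must lie in (0, 1]")
  class(cfg) <- "SimulationConfig"
  cfg
}

.deriveSeed <- function(seed, k) as.integer((as.numeric(seed) + k) %% 2147483587)

#' Generate a uniform-random reference genome
#'
#' @param config a [simulationConfig()].
#' @return A [Biostrings::DNAStringSet] with one sequence per chromosome,
#'   named `chr1`, `chr2`, ...; deterministic under `config$seed`.
#' @export
simulateReference <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(.deriveSeed(config$seed, 0L))
  seqs <- vapply(seq_len(config$n_chromosomes),
                 function(i) .randomDna(config$chromosome_length), "")
  names(seqs) <- paste0("chr", seq_len(config$n_chromosomes))
  DNAStringSet(seqs)
}

# one gene architecture in transcript orientation; returns sequence pieces and
# local feature intervals
.geneArchitecture <- function() {
  nEx <- sample(2:3, 1L)
  cdsLens <- sample(30:90, nEx, replace = TRUE)
  rem <- sum(cdsLens) %% 3L
  cdsLens[nEx] <- cdsLens[nEx] + (3L - rem) %% 3L
  intronLens <- if (nEx > 1L) sample(60:120, nEx - 1L, replace = TRUE) else integer()
  u5 <- sample(40:70, 1L)
  u3 <- sample(40:70, 1L)
  nCodons <- sum(cdsLens) / 3L
  codons <- c("ATG",
              sample(.NONSTOP_CODONS, nCodons - 2L, replace = TRUE),
              sample(.STOP_CODONS, 1L))
  cdsSeq <- paste(codons, collapse = "")
  cdsPieces <- substring(cdsSeq, cumsum(c(1L, cdsLens[-nEx])),
                         cumsum(cdsLens))
  intronSeqs <- vapply(intronLens, function(l)
    paste0("GT", .randomDna(l - 4L), "AG"), "")
  # assemble span sequence and local intervals
  segs <- list(list(type = "UTR5", seq = .randomDna(u5)))
  for (i in seq_len(nEx)) {
    segs[[length(segs) + 1L]] <- list(type = "CDS", seq = cdsPieces[i], rank = i)
    if (i < nEx)
      segs[[length(segs) + 1L]] <- list(type = "intron", seq = intronSeqs[i],
                                        rank = i)
  }
  segs[[length(segs) + 1L]] <- list(type = "UTR3", seq = .randomDna(u3))
  cur <- 0L
  rows <- list()
  for (s in segs) {
    w <- nchar(s$seq)
    rows[[length(rows) + 1L]] <-
      data.frame(type = s$type, local_start = cur + 1L, local_end = cur + w,
                 rank = if (is.null(s$rank)) NA_integer_ else s$rank,
                 stringsAsFactors = FALSE)
    cur <- cur + w
  }
  intervals <- do.call(rbind, rows)
  firstCds <- intervals$local_start[intervals$type == "CDS"][1L]
  lastCdsEnd <- max(intervals$local_end[intervals$type == "CDS"])
  intervals <- rbind(intervals,
                     data.frame(type = "start_codon", local_start = firstCds,
                                local_end = firstCds + 2L, rank = NA_integer_),
                     data.frame(type = "stop_codon",
                                local_start = lastCdsEnd - 2L,
                                local_end = lastCdsEnd, rank = NA_integer_))
  list(seq = paste(vapply(segs, `[[`, "", "seq"), collapse = ""),
       intervals = intervals, span = cur)
}

#' Generate stranded multi-exon gene models and write them into the reference
#'
#' Places `config$n_genes` non-overlapping genes on randomly chosen strands.
#' Each gene has a 5' UTR, 2-3 CDS exons (total CDS length divisible by 3,
#' beginning with ATG and ending in a stop codon, with no internal in-frame
#' stop), GT..AG introns and a 3' UTR. The gene sequences (start/stop codons,
#' splice dinucleotides) are written into the returned copy of the reference.
#'
#' @param reference a [Biostrings::DNAStringSet] from [simulateReference()].
#' @param config a [simulationConfig()].
#' @return `list(reference = <edited DNAStringSet>, geneModels =
#'   <GeneModelSet>)`.
#' @export
simulateGeneModels <- function(reference, config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(.deriveSeed(config$seed, 1L))
  refs <- .refAsChar(reference)
  chromLens <- nchar(refs)
  archs <- replicate(config$n_genes, .geneArchitecture(), simplify = FALSE)
  # greedy sequential placement, chromosome by chromosome
  geneRows <- list()
  featRows <- list()
  gi <- 1L
  for (chr in names(refs)) {
    cursor <- 150L + sample(0:100, 1L)
    while (gi <= config$n_genes) {
      span <- archs[[gi]]$span
      gstart <- cursor + sample(100:250, 1L)
      gend <- gstart + span - 1L
      if (gend > chromLens[[chr]] - 100L) break
      strand <- sample(c("+", "-"), 1L)
      spanSeq <- archs[[gi]]$seq
      if (strand == "-") spanSeq <- .revcomp(spanSeq)
      substr(refs[[chr]], gstart, gend) <- spanSeq
      iv <- archs[[gi]]$intervals
      if (strand == "+") {
        iv$start <- gstart + iv$local_start - 1L
        iv$end <- gstart + iv$local_end - 1L
      } else {
        iv$start <- gend - iv$local_end + 1L
        iv$end <- gend - iv$local_start + 1L
      }
      gid <- sprintf("gene%03d", gi)
      tid <- sprintf("gene%03d.t1", gi)
      geneRows[[gi]] <- data.frame(gene_id = gid, transcript_id = tid,
                                   chrom = chr, strand = strand,
                                   start = gstart, end = gend,
                                   stringsAsFactors = FALSE)
      featRows[[gi]] <- data.frame(gene_id = gid, transcript_id = tid,
                                   chrom = chr, strand = strand,
                                   type = iv$type, start = iv$start,
                                   end = iv$end, rank = iv$rank,
                                   stringsAsFactors = FALSE)
      cursor <- gend
      gi <- gi + 1L
    }
  }
  if (gi <= config$n_genes)
    stop("placement error: genome too small to place ", config$n_genes,
         " genes (placed ", gi - 1L, ")")
  gm <- geneModelSet(do.call(rbind, geneRows), do.call(rbind, featRows))
  list(reference = DNAStringSet(refs), geneModels = gm)
}

# ---- transcript context helpers (shared with the annotation engine) --------

# ordered genomic positions of the spliced CDS (5'->3' in transcript
# orientation) plus the CDS nucleotide string
.txContext <- function(refs, gm, transcript_id) {
  f <- featureTable(gm)
  f <- f[f$transcript_id == transcript_id, , drop = FALSE]
  if (nrow(f) == 0L) stop("unknown transcript: ", transcript_id)
  cds <- f[f$type == "CDS", , drop = FALSE]
  cds <- cds[order(cds$rank), , drop = FALSE]
  strand <- f$strand[1L]
  chrom <- f$chrom[1L]
  posList <- lapply(seq_len(nrow(cds)), function(i) {
    p <- cds$start[i]:cds$end[i]
    if (strand == "-") rev(p) else p
  })
  posMap <- unlist(posList, use.names = FALSE)
  chromSeq <- refs[[chrom]]
  bases <- vapply(posMap, function(p) substr(chromSeq, p, p), "")
  if (strand == "-") bases <- .complementBase(bases)
  list(chrom = chrom, strand = strand, posMap = posMap,
       cdsSeq = paste(bases, collapse = ""))
}

# search a transcript for a single-base substitution forcing the wanted
# coding effect class; returns NULL if none exists in this transcript
.searchCodingSite <- function(ctx, class) {
  n <- nchar(ctx$cdsSeq) / 3L
  idxRange <- switch(class,
                     start_lost = 1L,
                     stop_lost = n,
                     seq(2L, n - 1L))
  for (i in idxRange) {
    refCodon <- substr(ctx$cdsSeq, (i - 1L) * 3L + 1L, i * 3L)
    refAa <- .aa(refCodon)
    for (off in 1:3) {
      refBase <- substr(refCodon, off, off)
      for (alt in setdiff(.BASES, refBase)) {
        altCodon <- refCodon
        substr(altCodon, off, off) <- alt
        altAa <- .aa(altCodon)
        ok <- switch(class,
          start_lost = altCodon != "ATG",
          stop_lost = refAa == "*" && altAa != "*",
          stop_gained = refAa != "*" && altAa == "*",
          synonymous = refAa == altAa && refAa != "*",
          nonsynonymous = refAa != altAa && refAa != "*" && altAa != "*")
        if (isTRUE(ok)) {
          cdsPos <- (i - 1L) * 3L + off
          gpos <- ctx$posMap[cdsPos]
          galt <- if (ctx$strand == "-") .complementBase(alt) else alt
          return(list(chrom = ctx$chrom, pos = gpos, alt = galt))
        }
      }
    }
  }
  NULL
}

# plant one site per effect class; errors naming the class when impossible
.plantEffectSites <- function(refs, gm) {
  f <- featureTable(gm)
  txIds <- unique(f$transcript_id)
  ctxs <- lapply(txIds, function(tx) .txContext(refs, gm, tx))
  names(ctxs) <- txIds
  used <- character()
  out <- list()
  take <- function(class, chrom, pos, alt) {
    key <- paste(chrom, pos)
    if (key %in% used) return(FALSE)
    used <<- c(used, key)
    ref <- substr(refs[[chrom]], pos, pos)
    out[[length(out) + 1L]] <<- data.frame(class = class, chrom = chrom,
                                           pos = pos, ref = ref, alt = alt,
                                           stringsAsFactors = FALSE)
    TRUE
  }
  for (class in c("synonymous", "nonsynonymous", "stop_gained", "stop_lost",
                  "start_lost")) {
    placed <- FALSE
    for (tx in sample(txIds)) {
      hit <- .searchCodingSite(ctxs[[tx]], class)
      if (!is.null(hit) && take(class, hit$chrom, hit$pos, hit$alt)) {
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("generation error: no plantable site for effect class ", class)
  }
  # splice site: first base of a donor (GT); transcript orientation
  introns <- f[f$type == "intron", , drop = FALSE]
  if (nrow(introns) == 0L)
    stop("generation error: no plantable site for effect class splice_site")
  ir <- introns[sample(nrow(introns), 1L), ]
  spos <- if (ir$strand == "+") ir$start else ir$end
  sref <- substr(refs[[ir$chrom]], spos, spos)
  take("splice_site", ir$chrom, spos, sample(setdiff(.BASES, sref), 1L))
  # structural classes inside features (introns: keep >= 3 bp off each end)
  for (class in c("UTR5", "UTR3", "intron")) {
    feats <- f[f$type == class, , drop = FALSE]
    if (nrow(feats) == 0L)
      stop("generation error: no plantable site for effect class ", class)
    placed <- FALSE
    for (k in sample(nrow(feats))) {
      fr <- feats[k, ]
      lo <- fr$start + if (class == "intron") 3L else 0L
      hi <- fr$end - if (class == "intron") 3L else 0L
      if (lo > hi) next
      pos <- sample(lo:hi, 1L)
      ref <- substr(refs[[fr$chrom]], pos, pos)
      if (take(class, fr$chrom, pos, sample(setdiff(.BASES, ref), 1L))) {
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("generation error: no plantable site for effect class ", class)
  }
  # intergenic: any position outside every gene span
  genes <- geneTable(gm)
  placed <- FALSE
  for (try in 1:200) {
    chrom <- sample(names(refs), 1L)
    pos <- sample(nchar(refs[[chrom]]), 1L)
    g <- genes[genes$chrom == chrom, , drop = FALSE]
    if (any(pos >= g$start & pos <= g$end)) next
    ref <- substr(refs[[chrom]], pos, pos)
    if (take("intergenic", chrom, pos, sample(setdiff(.BASES, ref), 1L))) {
      placed <- TRUE
      break
    }
  }
  if (!placed)
    stop("generation error: no plantable site for effect class intergenic")
  do.call(rbind, out)
}

# founder-haplotype mosaic: nHap haplotypes over K founders with expected
# copying-tract length L (bp); freqs is the per-site alt frequency
.mosaicHaplotypes <- function(freqs, chrom, pos, nHap, K, L) {
  S <- length(freqs)
  founders <- matrix(rbinom(K * S, 1L, rep(freqs, each = K)), nrow = K)
  d <- c(Inf, diff(pos))
  d[c(TRUE, chrom[-1L] != chrom[-S])] <- Inf
  pSwitch <- 1 - exp(-d / L)
  haps <- matrix(0L, nrow = S, ncol = nHap)
  for (h in seq_len(nHap)) {
    sw <- runif(S) < pSwitch
    sw[1L] <- TRUE
    seg <- cumsum(sw)
    fid <- sample.int(K, max(seg), replace = TRUE)[seg]
    haps[, h] <- founders[cbind(fid, seq_len(S))]
  }
  haps
}

#' Simulate the two-subpopulation genotype matrix with planted ground truth
#'
#' Draws an ancestral allele frequency per segregating site, diverges the
#' wild and cultivated subpopulation frequencies with the Balding-Nichols
#' construction at `config$divergence`, thins polymorphism by each group's
#' diversity scaler, and samples diploid accessions as mosaics of a small
#' founder-haplotype pool (smaller pool and longer tracts for the cultivated
#' group, inducing longer-range LD). One site of every effect class
#' (synonymous, nonsynonymous, stop_gained, stop_lost, start_lost,
#' splice_site, UTR5, UTR3, intron, intergenic) is planted, duplicate
#' accessions are planted by copying a genotype vector and flipping calls at
#' `duplicate_mismatch_rate`, a causal site for the trait simulator is
#' chosen, and per-call depths (geometric, mean 8) plus site qualities
#' (uniform 20-80) straddle the default filter thresholds.
#'
#' @param reference edited reference from [simulateGeneModels()].
#' @param geneModels the [GeneModelSet-class] from [simulateGeneModels()].
#' @param config a [simulationConfig()].
#' @return `list(genotypes = <GenotypeData>, truth = <list>, metadata =
#'   <data.frame>)`. `truth` holds `planted_sites` (class/chrom/pos/ref/alt),
#'   `duplicate_pairs`, `causal_site` and `subpop_labels`.
#' @export
simulatePopulation <- function(reference, geneModels, config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(.deriveSeed(config$seed, 2L))
  refs <- .refAsChar(reference)
  chromLens <- nchar(refs)
  planted <- .plantEffectSites(refs, geneModels)
  # random segregating sites, proportional to chromosome length
  nPer <- pmax(round(config$n_sites * (chromLens / sum(chromLens))), 1L)
  rows <- list()
  for (chr in names(refs)) {
    avoid <- planted$pos[planted$chrom == chr]
    pool <- setdiff(seq_len(chromLens[[chr]]), avoid)
    pos <- sort(sample(pool, min(nPer[[chr]], length(pool))))
    ref <- vapply(pos, function(p) substr(refs[[chr]], p, p), "")
    alt <- vapply(ref, function(r) sample(setdiff(.BASES, r), 1L), "")
    rows[[chr]] <- data.frame(chrom = chr, pos = pos, ref = ref, alt = alt,
                              planted = FALSE, stringsAsFactors = FALSE)
  }
  sites <- rbind(do.call(rbind, rows),
                 data.frame(chrom = planted$chrom, pos = planted$pos,
                            ref = planted$ref, alt = planted$alt,
                            planted = TRUE, stringsAsFactors = FALSE))
  sites <- sites[order(sites$chrom, sites$pos), , drop = FALSE]
  rownames(sites) <- NULL
  S <- nrow(sites)
  pAnc <- runif(S, 0.05, 0.95)
  bn <- function(p, F) {
    if (F == 0) return(p)
    rbeta(length(p), p * (1 - F) / F, (1 - p) * (1 - F) / F)
  }
  pW <- bn(pAnc, config$divergence)
  pC <- bn(pAnc, config$divergence)
  # diversity thinning: a site stays polymorphic in a group with the group's
  # diversity probability, otherwise is fixed for one allele
  fixW <- runif(S) >= config$wild_diversity
  fixC <- runif(S) >= config$cultivated_diversity
  pW[fixW] <- rbinom(sum(fixW), 1L, pW[fixW])
  pC[fixC] <- rbinom(sum(fixC), 1L, pC[fixC])
  # planted sites stay comfortably polymorphic in both groups
  pW[sites$planted] <- 0.35
  pC[sites$planted] <- 0.35
  # causal site for the trait simulator: common and shared across groups
  candidates <- which(!sites$planted & pAnc >= 0.25 & pAnc <= 0.5)
  causalIdx <- if (length(candidates)) sample(candidates, 1L) else
    which(!sites$planted)[1L]
  pW[causalIdx] <- pAnc[causalIdx]
  pC[causalIdx] <- pAnc[causalIdx]
  hapW <- .mosaicHaplotypes(pW, sites$chrom, sites$pos, 2L * config$n_wild,
                            config$founder_pool_wild,
                            config$recomb_length_wild)
  hapC <- .mosaicHaplotypes(pC, sites$chrom, sites$pos,
                            2L * config$n_cultivated,
                            config$founder_pool_cultivated,
                            config$recomb_length_cultivated)
  genoW <- hapW[, seq(1L, ncol(hapW), 2L), drop = FALSE] +
    hapW[, seq(2L, ncol(hapW), 2L), drop = FALSE]
  genoC <- hapC[, seq(1L, ncol(hapC), 2L), drop = FALSE] +
    hapC[, seq(2L, ncol(hapC), 2L), drop = FALSE]
  geno <- cbind(genoW, genoC)
  ids <- c(sprintf("W%03d", seq_len(config$n_wild)),
           sprintf("C%03d", seq_len(config$n_cultivated)))
  colnames(geno) <- ids
  subpop <- setNames(rep(c("wild", "cultivated"),
                         c(config$n_wild, config$n_cultivated)), ids)
  # planted duplicate accessions: copies of cultivated lines with flips
  dupPairs <- NULL
  if (config$n_duplicates > 0L) {
    if (config$n_duplicates > config$n_cultivated)
      stop("generation error: more duplicate pairs than cultivated accessions")
    src <- sprintf("C%03d", seq_len(config$n_duplicates))
    dupIds <- paste0(src, "dup")
    dupGeno <- geno[, src, drop = FALSE]
    flip <- matrix(runif(length(dupGeno)) < config$duplicate_mismatch_rate,
                   nrow = nrow(dupGeno))
    if (any(flip)) {
      idx <- which(flip)
      cur <- dupGeno[idx]
      dupGeno[idx] <- vapply(cur, function(g)
        sample(setdiff(0:2, g), 1L), 0L)
    }
    colnames(dupGeno) <- dupIds
    geno <- cbind(geno, dupGeno)
    subpop <- c(subpop, setNames(rep("cultivated", length(dupIds)), dupIds))
    dupPairs <- data.frame(a = src, b = dupIds, stringsAsFactors = FALSE)
  }
  nAcc <- ncol(geno)
  # overdispersed per-call depth around 14x coverage; a few percent of calls
  # fall below the depth-5 mask so both filter branches are exercised
  depth <- matrix(pmax(1L, stats::rnbinom(S * nAcc, size = 8, mu = 14)),
                  nrow = S, dimnames = list(NULL, colnames(geno)))
  qual <- runif(S, 20, 80)
  gd <- genotypeData(data.frame(chrom = sites$chrom, pos = sites$pos,
                                ref = sites$ref, alt = sites$alt,
                                qual = qual, stringsAsFactors = FALSE),
                     geno, depth = depth)
  metadata <- .syntheticMetadata(colnames(geno), subpop, dupPairs)
  truth <- list(planted_sites = planted,
                duplicate_pairs = dupPairs,
                causal_site = list(chrom = sites$chrom[causalIdx],
                                   pos = sites$pos[causalIdx]),
                subpop_labels = subpop)
  list(genotypes = gd, truth = truth, metadata = metadata)
}

.syntheticMetadata <- function(ids, subpop, dupPairs) {
  type <- character(length(ids))
  names(type) <- ids
  wild <- names(subpop)[subpop == "wild"]
  cult <- names(subpop)[subpop == "cultivated"]
  type[wild] <- "wild"
  # alternate landrace / cultivar within the cultivated group
  type[cult] <- rep(c("landrace", "cultivar"), length.out = length(cult))
  if (!is.null(dupPairs))
    type[dupPairs$b] <- type[dupPairs$a]
  origins <- c("China", "United States", "Japan", "South Korea", "Russia")
  data.frame(accession_id = ids,
             species_group = ifelse(subpop[ids] == "wild", "G. soja", "G. max"),
             germplasm_type = unname(type[ids]),
             origin = sample(origins, length(ids), replace = TRUE),
             maturity_group = sample(c("I", "II", "III", "IV", "V"),
                                     length(ids), replace = TRUE),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Subset a chip-style genotype panel from a collection
#'
#' Uniformly samples `nSites` site coordinates and masks genotypes to
#' no-call independently at `nocallRate`, emulating an array platform
#' genotyping a fixed marker panel with missing calls.
#'
#' @param genotypes a [GenotypeData-class].
#' @param nSites number of sites to sample (must not exceed `nSites(x)`).
#' @param nocallRate per-genotype no-call probability in `[0, 1]`.
#' @param seed integer seed.
#' @return A [GenotypeData-class] restricted to the sampled coordinates
#'   (depth assay dropped).
#' @export
subsetChip <- function(genotypes, nSites, nocallRate, seed = 1L) {
  if (nSites > nrow(genotypes))
    stop("nSites exceeds available sites (", nrow(genotypes), ")")
  if (nocallRate < 0 || nocallRate > 1)
    stop("nocallRate must lie in [0, 1]")
  set.seed(.deriveSeed(seed, 0L))
  keep <- sort(sample(nrow(genotypes), nSites))
  gt <- dosage(genotypes)[keep, , drop = FALSE]
  if (nocallRate > 0) {
    mask <- matrix(runif(length(gt)) < nocallRate, nrow = nrow(gt))
    gt[mask] <- NA_integer_
  }
  st <- snpTable(genotypes)[keep, , drop = FALSE]
  genotypeData(st, gt)
}

#' Simulate a quantitative trait controlled by one planted QTL
#'
#' `trait = qtl_effect * dosage + noise`, with the Gaussian noise variance
#' scaled so the causal site explains approximately `heritability` of the
#' trait variance. `heritability = 1` gives the zero-noise limit.
#'
#' @param genotypes a [GenotypeData-class].
#' @param causalSite `list(chrom=, pos=)` naming a site in `genotypes`.
#' @param qtlEffect trait units per alt allele.
#' @param heritability fraction in `(0, 1]`.
#' @param seed integer seed.
#' @return Named numeric trait vector (one value per accession).
#' @export
simulateTrait <- function(genotypes, causalSite, qtlEffect, heritability,
                          seed = 1L) {
  if (heritability <= 0 || heritability > 1)
    stop("heritability must lie in (0, 1]")
  st <- snpTable(genotypes)
  idx <- which(st$chrom == causalSite$chrom & st$pos == causalSite$pos)
  if (length(idx) != 1L)
    stop("causal site ", causalSite$chrom, ":", causalSite$pos,
         " not present in genotypes")
  set.seed(.deriveSeed(seed, 0L))
  g <- dosage(genotypes)[idx, ]
  g[is.na(g)] <- mean(g, na.rm = TRUE)
  genetic <- qtlEffect * g
  vg <- stats::var(genetic)
  noiseVar <- if (vg > 0) vg * (1 - heritability) / heritability else 1
  trait <- genetic + rnorm(length(g), 0, sqrt(noiseVar))
  names(trait) <- accessionIds(genotypes)
  trait
}

#' Simulate a complete synthetic germplasm collection
#'
#' Convenience wrapper running [simulateReference()],
#' [simulateGeneModels()], [simulatePopulation()], [subsetChip()] and
#' [simulateTrait()] under seeds derived from `config$seed`.
#'
#' @param config a [simulationConfig()].
#' @return List with `reference`, `geneModels`, `genotypes`, `truth`,
#'   `metadata`, `chip`, `trait` and the `config` itself.
#' @export
simulateCollection <- function(config) {
  reference <- simulateReference(config)
  gmref <- simulateGeneModels(reference, config)
  pop <- simulatePopulation(gmref$reference, gmref$geneModels, config)
  chip <- subsetChip(pop$genotypes,
                     min(config$chip_n_sites, nrow(pop$genotypes)),
                     config$nocall_rate_chip,
                     seed = .deriveSeed(config$seed, 3L))
  trait <- simulateTrait(pop$genotypes, pop$truth$causal_site,
                         config$qtl_effect, config$trait_heritability,
                         seed = .deriveSeed(config$seed, 4L))
  list(reference = gmref$reference, geneModels = gmref$geneModels,
       genotypes = pop$genotypes, truth = pop$truth,
       metadata = pop$metadata, chip = chip, trait = trait, config = config)
}

#' Write a simulated collection to disk in standard formats
#'
#' Emits FASTA (reference), GFF3 (gene models), VCF v4.2 with GT:DP
#' (genotypes), TSV (chip matrix in AA/AB/BB/NN coding, accession metadata,
#' trait) and a JSON sidecar of the planted truth.
#'
#' @param sim output of [simulateCollection()].
#' @param dir output directory (created if needed).
#' @return Invisibly, a named character vector of written paths.
#' @export
writeCollection <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(reference = file.path(dir, "reference.fa"),
             gff3 = file.path(dir, "genes.gff3"),
             vcf = file.path(dir, "genotypes.vcf"),
             chip = file.path(dir, "chip.tsv"),
             metadata = file.path(dir, "metadata.tsv"),
             trait = file.path(dir, "trait.tsv"),
             truth = file.path(dir, "truth.json"))
  writeReferenceFasta(sim$reference, paths[["reference"]])
  writeGeneModels(sim$geneModels, paths[["gff3"]])
  writeVcfGenotypes(sim$genotypes, paths[["vcf"]])
  writeChipMatrix(sim$chip, paths[["chip"]])
  writeAccessionMetadata(sim$metadata, paths[["metadata"]])
  utils::write.table(data.frame(accession_id = names(sim$trait),
                                trait = unname(sim$trait)),
                     paths[["trait"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth <- sim$truth
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
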
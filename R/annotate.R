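#' Classify a genomic position against gene models
#'
#' A position inside any transcript span is `genic`, with the feature
#' resolved by priority `splice_site > start_codon > stop_codon > CDS >
#' UTR5 > UTR3 > intron`; splice sites are the first/last 2 intronic bases
#' of each intron. Positions outside every transcript are `intergenic` with
#' the distance to the nearest gene boundary.
#'
#' @param chrom,pos chromosome and 1-based position (scalars).
#' @param gm a [GeneModelSet-class].
#' @param chromLens optional named vector of chromosome lengths; positions
#'   beyond the chromosome raise an error.
#' @return `list(region_class, gene_id, transcript_id, strand,
#'   feature_class, distance_to_nearest_gene)`; gene fields are `NA` for
#'   intergenic positions.
#' @export
classifyRegion <- function(chrom, pos, gm, chromLens = NULL) {
  if (!is.null(chromLens)) {
    if (!chrom %in% names(chromLens))
      stop("unknown chromosome: ", chrom)
    if (pos < 1L || pos > chromLens[[chrom]])
      stop("position ", pos, " beyond chromosome ", chrom)
  }
  genes <- geneTable(gm)
  g <- genes[genes$chrom == chrom & genes$start <= pos & genes$end >= pos, ,
             drop = FALSE]
  if (nrow(g) == 0L) {
    gc <- genes[genes$chrom == chrom, , drop = FALSE]
    dist <- if (nrow(gc) == 0L) NA_integer_ else
      min(pmax(gc$start - pos, pos - gc$end))
    return(list(region_class = "intergenic", gene_id = NA_character_,
                transcript_id = NA_character_, strand = NA_character_,
                feature_class = "intergenic",
                distance_to_nearest_gene = dist))
  }
  g <- g[1L, ]  # genes are non-overlapping; first wins if ever not
  f <- featureTable(gm)
  f <- f[f$transcript_id == g$transcript_id, , drop = FALSE]
  hit <- function(type) {
    ff <- f[f$type == type, , drop = FALSE]
    any(ff$start <= pos & ff$end >= pos)
  }
  introns <- f[f$type == "intron", , drop = FALSE]
  spliceHit <- FALSE
  if (nrow(introns) > 0L) {
    spliceHit <- any((pos >= introns$start & pos <= introns$start + 1L) |
                     (pos >= introns$end - 1L & pos <= introns$end))
  }
  feature <- if (spliceHit) "splice_site"
    else if (hit("start_codon")) "start_codon"
    else if (hit("stop_codon")) "stop_codon"
    else if (hit("CDS")) "CDS"
    else if (hit("UTR5")) "UTR5"
    else if (hit("UTR3")) "UTR3"
    else if (hit("intron")) "intron"
    else "intron"  # inside span but in no feature: treat as intronic
  list(region_class = "genic", gene_id = g$gene_id,
       transcript_id = g$transcript_id, strand = g$strand,
       feature_class = feature, distance_to_nearest_gene = NA_integer_)
}

#' Codon-level consequence of a coding SNP
#'
#' Builds the spliced, strand-oriented CDS of the transcript, substitutes
#' the alternative base (reverse-complemented for minus-strand transcripts)
#' and reports the codon change. Effect classes: `synonymous` (amino acid
#' unchanged), `stop_gained` (non-stop to stop), `stop_lost` (stop to
#' non-stop), `start_lost` (first codon no longer ATG), otherwise
#' `nonsynonymous`.
#'
#' @param chrom,pos,ref,alt the SNP (position must lie in the CDS, start or
#'   stop codon of `transcript_id`).
#' @param transcript_id transcript to annotate against.
#' @param reference [Biostrings::DNAStringSet] or named character vector.
#' @param gm a [GeneModelSet-class].
#' @return `list(cds_position, aa_position, codon_offset, ref_codon,
#'   alt_codon, ref_aa, alt_aa, effect_class)`.
#' @export
codonEffect <- function(chrom, pos, ref, alt, transcript_id, reference, gm) {
  refs <- .refAsChar(reference)
  ctx <- .txContext(refs, gm, transcript_id)
  .codonEffectCtx(ctx, chrom, pos, ref, alt)
}

.codonEffectCtx <- function(ctx, chrom, pos, ref, alt) {
  if (ctx$chrom != chrom)
    stop("SNP chromosome does not match transcript")
  cdsPos <- match(pos, ctx$posMap)
  if (is.na(cdsPos))
    stop("position ", pos, " not in the CDS of this transcript")
  txRef <- substr(ctx$cdsSeq, cdsPos, cdsPos)
  genomicRef <- if (ctx$strand == "-") .complementBase(txRef) else txRef
  if (genomicRef != ref)
    stop("consistency error: VCF ref allele ", ref,
         " disagrees with reference base ", genomicRef, " at ", chrom, ":",
         pos)
  txAlt <- if (ctx$strand == "-") .complementBase(alt) else alt
  aaPos <- (cdsPos - 1L) %/% 3L + 1L
  off <- (cdsPos - 1L) %% 3L + 1L
  refCodon <- substr(ctx$cdsSeq, (aaPos - 1L) * 3L + 1L, aaPos * 3L)
  altCodon <- refCodon
  substr(altCodon, off, off) <- txAlt
  refAa <- .aa(refCodon)
  altAa <- .aa(altCodon)
  effect <- if (aaPos == 1L && altCodon != "ATG") "start_lost"
    else if (refAa == altAa) "synonymous"
    else if (refAa != "*" && altAa == "*") "stop_gained"
    else if (refAa == "*" && altAa != "*") "stop_lost"
    else "nonsynonymous"
  list(cds_position = cdsPos, aa_position = aaPos, codon_offset = off,
       ref_codon = refCodon, alt_codon = altCodon, ref_aa = refAa,
       alt_aa = altAa, effect_class = effect)
}

#' Per-group allele frequencies at every site
#'
#' Computes reference/alternative allele frequencies over non-missing
#' alleles for the `G. max` and `G. soja` species groups, plus overall minor
#' allele frequency, missing rate, called count and het count. Accessions
#' with unknown group are excluded from the group columns but included in
#' the overall statistics; a group with zero called accessions at a site
#' gets `NA` frequencies.
#'
#' @param x a [GenotypeData-class].
#' @param metadata accession metadata (see [readAccessionMetadata()]).
#' @return data.frame with one row per site: `n_called`, `missing_rate`,
#'   `maf_all`, `ref_freq_gmax`, `alt_freq_gmax`, `ref_freq_gsoja`,
#'   `alt_freq_gsoja`, `het_count`.
#' @export
groupFrequencies <- function(x, metadata) {
  gt <- dosage(x)
  ids <- accessionIds(x)
  grp <- setNames(metadata$species_group, metadata$accession_id)[ids]
  freqFor <- function(cols) {
    if (length(cols) == 0L)
      return(list(ref = rep(NA_real_, nrow(gt)), alt = rep(NA_real_, nrow(gt))))
    sub <- gt[, cols, drop = FALSE]
    altCount <- rowSums(sub, na.rm = TRUE)
    alleles <- 2 * rowSums(!is.na(sub))
    alt <- ifelse(alleles > 0, altCount / alleles, NA_real_)
    list(ref = 1 - alt, alt = alt)
  }
  fmax <- freqFor(which(!is.na(grp) & grp == "G. max"))
  fsoja <- freqFor(which(!is.na(grp) & grp == "G. soja"))
  data.frame(n_called = rowSums(!is.na(gt)),
             missing_rate = siteMissingRate(gt),
             maf_all = siteMaf(gt),
             ref_freq_gmax = fmax$ref, alt_freq_gmax = fmax$alt,
             ref_freq_gsoja = fsoja$ref, alt_freq_gsoja = fsoja$alt,
             het_count = rowSums(gt == 1L, na.rm = TRUE))
}

.ANNOTATION_COLUMNS <- c(
  "chromosome", "position", "snp_id", "ref_allele", "alt_allele",
  "site_quality", "region_class", "gene_id", "transcript_id", "strand",
  "feature_class", "distance_to_nearest_gene", "cds_position",
  "aa_position", "codon_offset", "ref_codon", "alt_codon", "ref_aa",
  "alt_aa", "effect_class", "provean_score", "deleterious_flag",
  "n_called", "missing_rate", "maf_all", "ref_freq_gmax", "alt_freq_gmax",
  "ref_freq_gsoja", "alt_freq_gsoja", "het_count")

#' Build the 30-column per-SNP annotation report
#'
#' Produces one report row per SNP with exactly 30 categories: location and
#' alleles, site quality, region/feature classification, codon-level
#' consequence for coding SNPs, optional deleteriousness score and flag, and
#' population/per-species-group allele frequencies. SNPs in splice sites get
#' `effect_class = "splice_site"`; UTR/intron/intergenic SNPs are
#' `"noncoding"`.
#'
#' @param x a [GenotypeData-class].
#' @param gm a [GeneModelSet-class].
#' @param reference [Biostrings::DNAStringSet] or named character vector.
#' @param metadata optional accession metadata (group frequency columns are
#'   `NA` without it).
#' @param scores optional deleteriousness score table
#'   (see [readProveanScores()]); applied via [applyDeleteriousness()].
#' @param scoreThreshold deleteriousness threshold (default -4.1; scores at
#'   or below it flag the SNP).
#' @return data.frame with the 30 columns of `.ANNOTATION_COLUMNS`, one row
#'   per SNP site.
#' @export
annotateSnps <- function(x, gm, reference, metadata = NULL, scores = NULL,
                         scoreThreshold = -4.1) {
  refs <- .refAsChar(reference)
  st <- snpTable(x)
  n <- nrow(st)
  chromLens <- nchar(refs)
  # per-transcript context cache for codon effects
  ctxCache <- new.env(parent = emptyenv())
  getCtx <- function(tx) {
    if (is.null(ctxCache[[tx]])) ctxCache[[tx]] <- .txContext(refs, gm, tx)
    ctxCache[[tx]]
  }
  empty <- list(cds_position = NA_integer_, aa_position = NA_integer_,
                codon_offset = NA_integer_, ref_codon = NA_character_,
                alt_codon = NA_character_, ref_aa = NA_character_,
                alt_aa = NA_character_)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    cls <- classifyRegion(st$chrom[i], st$pos[i], gm, chromLens)
    codon <- empty
    effect <- "noncoding"
    if (cls$feature_class %in% c("CDS", "start_codon", "stop_codon")) {
      ce <- .codonEffectCtx(getCtx(cls$transcript_id), st$chrom[i],
                            st$pos[i], st$ref[i], st$alt[i])
      codon <- ce[names(empty)]
      effect <- ce$effect_class
    } else if (cls$feature_class == "splice_site") {
      effect <- "splice_site"
    }
    rows[[i]] <- data.frame(
      chromosome = st$chrom[i], position = st$pos[i],
      snp_id = paste(st$chrom[i], st$pos[i], sep = "_"),
      ref_allele = st$ref[i], alt_allele = st$alt[i],
      site_quality = st$qual[i], region_class = cls$region_class,
      gene_id = cls$gene_id, transcript_id = cls$transcript_id,
      strand = cls$strand, feature_class = cls$feature_class,
      distance_to_nearest_gene = cls$distance_to_nearest_gene,
      cds_position = codon$cds_position, aa_position = codon$aa_position,
      codon_offset = codon$codon_offset, ref_codon = codon$ref_codon,
      alt_codon = codon$alt_codon, ref_aa = codon$ref_aa,
      alt_aa = codon$alt_aa, effect_class = effect,
      provean_score = NA_real_, deleterious_flag = FALSE,
      stringsAsFactors = FALSE)
  }
  ann <- do.call(rbind, rows)
  freq <- if (!is.null(metadata)) {
    groupFrequencies(x, metadata)
  } else {
    gt <- dosage(x)
    data.frame(n_called = rowSums(!is.na(gt)),
               missing_rate = siteMissingRate(gt), maf_all = siteMaf(gt),
               ref_freq_gmax = NA_real_, alt_freq_gmax = NA_real_,
               ref_freq_gsoja = NA_real_, alt_freq_gsoja = NA_real_,
               het_count = rowSums(gt == 1L, na.rm = TRUE))
  }
  ann <- cbind(ann, freq)
  ann <- ann[, .ANNOTATION_COLUMNS]
  if (!is.null(scores))
    ann <- applyDeleteriousness(ann, scores, threshold = scoreThreshold)
  ann
}

#' Flag deleterious nonsynonymous SNPs from supplied scores
#'
#' Sets `provean_score` and `deleterious_flag` on the annotation report:
#' a SNP is flagged iff a score is present for its (chrom, pos, alt) key,
#' the SNP is nonsynonymous, and the score is `<= threshold`. Scores
#' supplied for non-nonsynonymous SNPs are ignored and counted in a message.
#'
#' @param annotations output of [annotateSnps()].
#' @param scores data.frame with columns `chrom`, `pos`, `alt`, `score`.
#' @param threshold deleteriousness cutoff (default -4.1).
#' @return The annotations with score/flag columns updated.
#' @export
applyDeleteriousness <- function(annotations, scores, threshold = -4.1) {
  key <- paste(annotations$chromosome, annotations$position,
               annotations$alt_allele)
  skey <- paste(scores$chrom, scores$pos, scores$alt)
  idx <- match(key, skey)
  hasScore <- !is.na(idx)
  nonsyn <- annotations$effect_class == "nonsynonymous"
  ignored <- sum(hasScore & !nonsyn)
  if (ignored > 0L)
    message("applyDeleteriousness: ignored ", ignored,
            " score(s) on non-nonsynonymous SNPs")
  annotations$provean_score <- NA_real_
  annotations$provean_score[hasScore & nonsyn] <-
    scores$score[idx[hasScore & nonsyn]]
  annotations$deleterious_flag <- !is.na(annotations$provean_score) &
    annotations$provean_score <= threshold
  annotations
}

#' Summarize an annotation report
#'
#' Category tallies on their stated denominators: genic/intergenic percent
#' of all SNPs; UTR/intron/CDS percent of genic SNPs; synonymous /
#' nonsynonymous counts and nonsynonymous percent of CDS SNPs (stop-gained
#' is tallied as its own positional category, separate from nonsynonymous);
#' splice-site / start-codon / stop-codon / premature-stop counts; per-gene
#' SNP and nonsynonymous averages; fraction of genes carrying at least one
#' nonsynonymous SNP; SNP density per kb. With zero CDS SNPs the
#' synonymous/nonsynonymous percentages are `NA` (undefined), not 0.
#'
#' @param annotations output of [annotateSnps()].
#' @param genomeLengthBp total genome length in bp (for density).
#' @param nGenes number of gene models (denominator for per-gene averages).
#' @return Named list of tallies.
#' @export
summarizeAnnotations <- function(annotations, genomeLengthBp, nGenes) {
  n <- nrow(annotations)
  genic <- annotations$region_class == "genic"
  nGenic <- sum(genic)
  feat <- annotations$feature_class
  nUtr <- sum(feat %in% c("UTR5", "UTR3"))
  nIntron <- sum(feat == "intron")
  cdsSnp <- !is.na(annotations$cds_position)
  nCds <- sum(cdsSnp)
  eff <- annotations$effect_class
  nSyn <- sum(cdsSnp & eff == "synonymous")
  nNonsyn <- sum(cdsSnp & eff == "nonsynonymous")
  nStopGained <- sum(eff == "stop_gained")
  perGene <- table(annotations$gene_id[genic])
  nonsynPerGene <- table(annotations$gene_id[eff %in%
                                             c("nonsynonymous")])
  list(n_snps = n,
       density_snps_per_kb = n / (genomeLengthBp / 1000),
       pct_genic = 100 * nGenic / n,
       pct_intergenic = 100 * sum(!genic) / n,
       pct_genic_utr = if (nGenic > 0) 100 * nUtr / nGenic else NA_real_,
       pct_genic_intron = if (nGenic > 0) 100 * nIntron / nGenic else NA_real_,
       pct_genic_cds = if (nGenic > 0) 100 * nCds / nGenic else NA_real_,
       n_synonymous = nSyn,
       n_nonsynonymous = nNonsyn,
       pct_nonsyn_of_cds = if (nCds > 0) 100 * nNonsyn / nCds else NA_real_,
       pct_syn_of_cds = if (nCds > 0) 100 * nSyn / nCds else NA_real_,
       n_splice_site = sum(feat == "splice_site"),
       n_start_codon = sum(feat == "start_codon"),
       n_stop_codon = sum(feat == "stop_codon"),
       n_stop_gained = nStopGained,
       snps_per_gene = nGenic / nGenes,
       nonsyn_snps_per_gene = sum(eff == "nonsynonymous") / nGenes,
       frac_genes_with_nonsyn = length(nonsynPerGene) / nGenes)
}

#' Write an annotation report as TSV
#' @param annotations output of [annotateSnps()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeAnnotationReport <- function(annotations, path) {
  utils::write.table(annotations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
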
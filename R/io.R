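#' @importFrom Biostrings readDNAStringSet writeXStringSet
#' @importFrom utils read.delim write.table
NULL

#' Read a population VCF into a GenotypeData object
#'
#' Parses a VCF v4.2 with per-sample GT (and optionally DP). Multi-allelic
#' records and non-SNP records (indels, symbolic alleles) are skipped and
#' counted; `./.` (or `.`) genotypes become missing calls. Unphased and
#' phased separators are treated identically (genotypes are unordered allele
#' pairs).
#'
#' @param path path to an uncompressed or gzipped VCF.
#' @return A [GenotypeData-class]; the number of skipped records is attached
#'   as attribute `"n_skipped"` and reported via `message()`.
#' @export
readVcfGenotypes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop("VCF parse error in ", path, ": ",
                                         conditionMessage(e)))
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  snp <- !is.na(alt) & nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% .BASES & alt %in% .BASES
  nSkipped <- sum(!snp)
  if (nSkipped > 0L)
    message("readVcfGenotypes: skipped ", nSkipped,
            " multi-allelic/non-SNP record(s)")
  if (!any(snp)) stop("no biallelic SNP records in ", path)
  gtChar <- vcfR::extract.gt(v, element = "GT")[snp, , drop = FALSE]
  geno <- matrix(NA_integer_, nrow = nrow(gtChar), ncol = ncol(gtChar),
                 dimnames = dimnames(gtChar))
  clean <- gsub("\\|", "/", gtChar)
  geno[clean %in% c("0/0", "0")] <- 0L
  geno[clean %in% c("0/1", "1/0")] <- 1L
  geno[clean %in% c("1/1", "1")] <- 2L
  depth <- NULL
  fmtIds <- tryCatch(vcfR::vcf_field_names(v, tag = "FORMAT")$ID,
                     error = function(e) character())
  if ("DP" %in% fmtIds) {
    depth <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)[
      snp, , drop = FALSE]
    mode(depth) <- "integer"
  }
  qual <- suppressWarnings(as.numeric(fix[snp, "QUAL"]))
  out <- genotypeData(data.frame(chrom = fix[snp, "CHROM"],
                                 pos = as.integer(fix[snp, "POS"]),
                                 ref = ref[snp], alt = alt[snp],
                                 qual = qual, stringsAsFactors = FALSE),
                      geno, depth = depth)
  attr(out, "n_skipped") <- nSkipped
  out
}

#' Write a GenotypeData object as VCF v4.2
#'
#' Emits GT (and DP when present) per sample, with site QUAL populated.
#'
#' @param x a [GenotypeData-class].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeVcfGenotypes <- function(x, path) {
  st <- snpTable(x)
  gt <- dosage(x)
  dp <- depthMatrix(x)
  gtChar <- matrix("./.", nrow = nrow(gt), ncol = ncol(gt))
  gtChar[which(gt == 0L)] <- "0/0"
  gtChar[which(gt == 1L)] <- "0/1"
  gtChar[which(gt == 2L)] <- "1/1"
  if (!is.null(dp)) {
    dpChar <- ifelse(is.na(dp), ".", as.character(dp))
    gtChar <- matrix(paste(gtChar, dpChar, sep = ":"), nrow = nrow(gt))
    fmt <- "GT:DP"
  } else {
    fmt <- "GT"
  }
  header <- c("##fileformat=VCFv4.2",
              "##source=GermplasmVarKit",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              if (!is.null(dp))
                '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", accessionIds(x)), collapse = "\t"))
  body <- paste(st$chrom, st$pos, paste(st$chrom, st$pos, sep = "_"),
                st$ref, st$alt, formatC(st$qual, format = "g", digits = 10),
                "PASS", ".", fmt,
                apply(gtChar, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a reference genome FASTA
#' @param path FASTA path.
#' @return A [Biostrings::DNAStringSet].
#' @export
readReferenceFasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  readDNAStringSet(path)
}

#' Write a reference genome FASTA
#' @param reference a [Biostrings::DNAStringSet] (or named character vector).
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeReferenceFasta <- function(reference, path) {
  if (!is(reference, "DNAStringSet"))
    reference <- DNAStringSet(.refAsChar(reference))
  writeXStringSet(reference, path)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Imports a GFF3 (1-based inclusive) and assembles a validated
#' [GeneModelSet-class]. Introns are derived as gaps between consecutive
#' exons of a transcript; CDS pieces, introns and UTRs are ordered 5'->3' in
#' transcript orientation; start/stop codons are taken from the CDS extremes
#' (strand-aware). A transcript whose total CDS length is not divisible by 3
#' raises a validation error naming the transcript.
#'
#' @param path GFF3 path.
#' @return A [GeneModelSet-class].
#' @export
readGeneModels <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  gr <- rtracklayer::import(path)
  df <- as.data.frame(gr)
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  mrna <- df[df$type %in% c("mRNA", "transcript"), , drop = FALSE]
  geneRows <- list()
  featRows <- list()
  for (i in seq_len(nrow(mrna))) {
    tid <- mrna$ID[i]
    gid <- if (!is.null(mrna$Parent) && length(mrna$Parent[[i]]))
      as.character(mrna$Parent[[i]][1]) else tid
    strand <- mrna$strand[i]
    chrom <- mrna$seqnames[i]
    kids <- df[vapply(df$Parent, function(p) tid %in% as.character(p), TRUE), ,
               drop = FALSE]
    pick <- function(types) {
      k <- kids[kids$type %in% types, , drop = FALSE]
      k[order(k$start), , drop = FALSE]
    }
    exons <- pick("exon")
    cds <- pick("CDS")
    utr5 <- pick(c("five_prime_UTR", "5UTR"))
    utr3 <- pick(c("three_prime_UTR", "3UTR"))
    if (nrow(cds) == 0L)
      stop("model-validation error: transcript ", tid, " has no CDS")
    if (sum(cds$end - cds$start + 1L) %% 3L != 0L)
      stop("model-validation error: transcript ", tid,
           ": total CDS length not divisible by 3")
    introns <- NULL
    if (nrow(exons) > 1L) {
      introns <- data.frame(start = exons$end[-nrow(exons)] + 1L,
                            end = exons$start[-1L] - 1L)
      introns <- introns[introns$end >= introns$start, , drop = FALSE]
    }
    # transcript-orientation ranks: genomic order for "+", reversed for "-"
    rankIt <- function(tab) {
      if (is.null(tab) || nrow(tab) == 0L) return(integer())
      r <- seq_len(nrow(tab))
      if (strand == "-") rev(r) else r
    }
    addFeat <- function(tab, type, rank = NA_integer_) {
      if (is.null(tab) || nrow(tab) == 0L) return(NULL)
      data.frame(gene_id = gid, transcript_id = tid, chrom = chrom,
                 strand = strand, type = type, start = tab$start,
                 end = tab$end, rank = rank, stringsAsFactors = FALSE)
    }
    cdsOrdered <- cds
    startRow <- if (strand == "+") {
      data.frame(start = cds$start[1L], end = cds$start[1L] + 2L)
    } else {
      data.frame(start = cds$end[nrow(cds)] - 2L, end = cds$end[nrow(cds)])
    }
    stopRow <- if (strand == "+") {
      data.frame(start = cds$end[nrow(cds)] - 2L, end = cds$end[nrow(cds)])
    } else {
      data.frame(start = cds$start[1L], end = cds$start[1L] + 2L)
    }
    featRows[[length(featRows) + 1L]] <- rbind(
      addFeat(utr5, "UTR5"),
      addFeat(cdsOrdered, "CDS", rankIt(cdsOrdered)),
      if (!is.null(introns)) addFeat(introns, "intron", rankIt(introns)),
      addFeat(utr3, "UTR3"),
      addFeat(startRow, "start_codon"),
      addFeat(stopRow, "stop_codon"))
    geneRows[[length(geneRows) + 1L]] <-
      data.frame(gene_id = gid, transcript_id = tid, chrom = chrom,
                 strand = strand, start = mrna$start[i], end = mrna$end[i],
                 stringsAsFactors = FALSE)
  }
  geneModelSet(do.call(rbind, geneRows), do.call(rbind, featRows))
}

#' Write gene models as GFF3
#'
#' Emits gene, mRNA, five_prime_UTR, exon, CDS (with phase) and
#' three_prime_UTR records, 1-based inclusive.
#'
#' @param gm a [GeneModelSet-class].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeGeneModels <- function(gm, path) {
  lines <- "##gff-version 3"
  genes <- geneTable(gm)
  feats <- featureTable(gm)
  rec <- function(chrom, src, type, start, end, strand, phase, attrs)
    paste(chrom, src, type, start, end, ".", strand, phase, attrs, sep = "\t")
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    f <- feats[feats$transcript_id == g$transcript_id, , drop = FALSE]
    lines <- c(lines,
               rec(g$chrom, "sim", "gene", g$start, g$end, g$strand, ".",
                   paste0("ID=", g$gene_id)),
               rec(g$chrom, "sim", "mRNA", g$start, g$end, g$strand, ".",
                   paste0("ID=", g$transcript_id, ";Parent=", g$gene_id)))
    par <- paste0("Parent=", g$transcript_id)
    # exons = transcript intervals minus introns (UTR5/CDS/UTR3 merged)
    core <- f[f$type %in% c("UTR5", "CDS", "UTR3"), , drop = FALSE]
    core <- core[order(core$start), , drop = FALSE]
    exS <- core$start[1L]; exE <- core$end[1L]
    exons <- NULL
    if (nrow(core) > 1L) {
      for (j in 2:nrow(core)) {
        if (core$start[j] == exE + 1L) {
          exE <- core$end[j]
        } else {
          exons <- rbind(exons, c(exS, exE))
          exS <- core$start[j]; exE <- core$end[j]
        }
      }
    }
    exons <- rbind(exons, c(exS, exE))
    for (j in seq_len(nrow(exons)))
      lines <- c(lines, rec(g$chrom, "sim", "exon", exons[j, 1], exons[j, 2],
                            g$strand, ".", par))
    u5 <- f[f$type == "UTR5", , drop = FALSE]
    for (j in seq_len(nrow(u5)))
      lines <- c(lines, rec(g$chrom, "sim", "five_prime_UTR", u5$start[j],
                            u5$end[j], g$strand, ".", par))
    cds <- f[f$type == "CDS", , drop = FALSE]
    cds <- cds[order(cds$rank), , drop = FALSE]
    phase <- 0L
    for (j in seq_len(nrow(cds))) {
      lines <- c(lines, rec(g$chrom, "sim", "CDS", cds$start[j], cds$end[j],
                            g$strand, phase, par))
      phase <- (3L - (cds$end[j] - cds$start[j] + 1L - phase) %% 3L) %% 3L
    }
    u3 <- f[f$type == "UTR3", , drop = FALSE]
    for (j in seq_len(nrow(u3)))
      lines <- c(lines, rec(g$chrom, "sim", "three_prime_UTR", u3$start[j],
                            u3$end[j], g$strand, ".", par))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read accession metadata
#'
#' TSV with columns `accession_id`, `species_group` (`G. max` / `G. soja`),
#' `germplasm_type` (`wild`, `landrace`, `cultivar`, `unknown`), `origin`,
#' `maturity_group`. A `G. soja` accession typed as anything other than
#' `wild`/`unknown` is a validation error.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
readAccessionMetadata <- function(path) {
  md <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("accession_id", "species_group", "germplasm_type")
  if (!all(need %in% colnames(md)))
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  bad <- md$species_group == "G. soja" &
    !md$germplasm_type %in% c("wild", "unknown")
  if (any(bad))
    stop("metadata error: G. soja accessions must be wild/unknown: ",
         paste(md$accession_id[bad], collapse = ", "))
  md
}

#' @rdname readAccessionMetadata
#' @param md metadata data.frame.
#' @export
writeAccessionMetadata <- function(md, path) {
  write.table(md, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write chip genotype matrices
#'
#' The chip TSV has columns `chrom`, `pos`, `ref`, `alt`, then one column per
#' accession with values in `AA`/`AB`/`BB`/`NN` coded against the companion
#' VCF reference allele (`AA` hom-ref, `AB` het, `BB` hom-alt; `N`/`NN`
#' no-call).
#'
#' @param path TSV path.
#' @return `readChipMatrix()` returns a [GenotypeData-class] (site quality
#'   set to `NA`-free 0 since arrays carry none).
#' @export
readChipMatrix <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% colnames(tab)))
    stop("chip matrix must have columns: ", paste(need, collapse = ", "))
  accCols <- setdiff(colnames(tab), need)
  codes <- as.matrix(tab[, accCols, drop = FALSE])
  geno <- matrix(NA_integer_, nrow = nrow(codes), ncol = ncol(codes),
                 dimnames = list(NULL, accCols))
  geno[codes == "AA"] <- 0L
  geno[codes == "AB"] <- 1L
  geno[codes == "BB"] <- 2L
  genotypeData(data.frame(chrom = tab$chrom, pos = tab$pos, ref = tab$ref,
                          alt = tab$alt, qual = 0,
                          stringsAsFactors = FALSE), geno)
}

#' @rdname readChipMatrix
#' @param x a [GenotypeData-class].
#' @export
writeChipMatrix <- function(x, path) {
  st <- snpTable(x)
  gt <- dosage(x)
  codes <- matrix("NN", nrow = nrow(gt), ncol = ncol(gt),
                  dimnames = dimnames(gt))
  codes[which(gt == 0L)] <- "AA"
  codes[which(gt == 1L)] <- "AB"
  codes[which(gt == 2L)] <- "BB"
  out <- cbind(data.frame(chrom = st$chrom, pos = st$pos, ref = st$ref,
                          alt = st$alt, stringsAsFactors = FALSE),
               as.data.frame(codes, stringsAsFactors = FALSE))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a trait table
#'
#' TSV with columns `accession_id`, `trait`.
#' @param path TSV path.
#' @return Named numeric vector.
#' @export
readTraitTable <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  setNames(as.numeric(tab$trait), tab$accession_id)
}

#' Read per-variant deleteriousness scores
#'
#' TSV keyed by `chrom`, `pos`, `alt` with a numeric `score` column
#' (protein-variation deleteriousness, more negative = more damaging).
#' @param path TSV path.
#' @return data.frame with columns chrom, pos, alt, score.
#' @export
readProveanScores <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "alt", "score")
  if (!all(need %in% colnames(tab)))
    stop("scores table must have columns: ", paste(need, collapse = ", "))
  tab
}
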
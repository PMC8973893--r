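#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<-
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges seqnames start
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<- assays
#'   assayNames rowRanges colData
NULL

#' GenotypeData: a population SNP genotype matrix
#'
#' `GenotypeData` extends [SummarizedExperiment::RangedSummarizedExperiment]
#' to hold biallelic SNP genotypes for a germplasm collection. Rows are SNP
#' sites (1-bp `GRanges` with metadata columns `ref`, `alt`, `qual`), columns
#' are accessions. The `"GT"` assay stores unphased diploid genotypes as
#' alt-allele dosage: `0` hom-ref, `1` het, `2` hom-alt, `NA` missing/no-call.
#' An optional `"DP"` assay stores per-call read depth.
#'
#' Validity requires single-base `ref`/`alt` alleles in `{A,C,G,T}` with
#' `ref != alt`, rows sorted by (chromosome, position) with unique positions
#' per chromosome, and dosage values confined to `{0, 1, 2, NA}`.
#'
#' @aliases GenotypeData-class
#' @export
setClass("GenotypeData", contains = "RangedSummarizedExperiment")

setValidity("GenotypeData", function(object) {
  msg <- character()
  if (!"GT" %in% assayNames(object))
    msg <- c(msg, "assay 'GT' (alt-allele dosage) is required")
  rr <- rowRanges(object)
  mc <- mcols(rr)
  if (!all(c("ref", "alt", "qual") %in% colnames(mc))) {
    msg <- c(msg, "rowRanges must carry metadata columns ref, alt, qual")
  } else if (length(rr) > 0L) {
    bases <- c("A", "C", "G", "T")
    if (!all(mc$ref %in% bases) || !all(mc$alt %in% bases))
      msg <- c(msg, "ref/alt alleles must be single bases in {A,C,G,T}")
    if (any(mc$ref == mc$alt))
      msg <- c(msg, "ref and alt alleles must differ at every site")
    chrom <- as.character(seqnames(rr))
    pos <- start(rr)
    o <- order(chrom, pos)
    if (!identical(o, seq_along(pos)))
      msg <- c(msg, "sites must be sorted by (chromosome, position)")
    if (anyDuplicated(paste(chrom, pos)))
      msg <- c(msg, "positions must be unique within each chromosome")
  }
  if ("GT" %in% assayNames(object) && nrow(object) > 0L) {
    gt <- assay(object, "GT")
    if (!all(gt %in% c(0L, 1L, 2L, NA)))
      msg <- c(msg, "GT dosage values must be 0, 1, 2 or NA")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeData object
#'
#' @param sites data.frame with columns `chrom`, `pos`, `ref`, `alt`, `qual`
#'   (one row per biallelic SNP). Rows are re-sorted by (chrom, pos).
#' @param geno integer matrix of alt-allele dosages (sites x accessions;
#'   values 0/1/2/NA) whose column names are accession identifiers.
#' @param depth optional integer matrix of per-call read depths, same
#'   dimensions as `geno`.
#' @return A [GenotypeData-class] object.
#' @examples
#' sites <- data.frame(chrom = "chr1", pos = c(10, 20), ref = c("A", "C"),
#'                     alt = c("G", "T"), qual = 60)
#' g <- matrix(c(0L, 1L, 2L, NA), 2, 2,
#'             dimnames = list(NULL, c("acc1", "acc2")))
#' gd <- genotypeData(sites, g)
#' nSites(gd)
#' @export
genotypeData <- function(sites, geno, depth = NULL) {
  stopifnot(is.data.frame(sites),
            all(c("chrom", "pos", "ref", "alt", "qual") %in% colnames(sites)),
            nrow(sites) == nrow(geno))
  o <- order(sites$chrom, sites$pos)
  sites <- sites[o, , drop = FALSE]
  geno <- geno[o, , drop = FALSE]
  mode(geno) <- "integer"
  if (is.null(colnames(geno)))
    stop("genotype matrix must have accession column names")
  rr <- GRanges(sites$chrom, IRanges(sites$pos, width = 1L),
                ref = as.character(sites$ref), alt = as.character(sites$alt),
                qual = as.numeric(sites$qual))
  names(rr) <- paste(sites$chrom, sites$pos, sep = "_")
  rownames(geno) <- names(rr)
  assays <- list(GT = geno)
  if (!is.null(depth)) {
    depth <- depth[o, , drop = FALSE]
    mode(depth) <- "integer"
    dimnames(depth) <- dimnames(geno)
    assays$DP <- depth
  }
  se <- SummarizedExperiment(assays = assays, rowRanges = rr)
  new("GenotypeData", se)
}

#' GeneModelSet: stranded multi-exon gene models
#'
#' Container for validated protein-coding gene models on a reference genome.
#' Slot `genes` has one row per gene/transcript (`gene_id`, `transcript_id`,
#' `chrom`, `strand`, `start`, `end`); slot `features` has one row per
#' feature interval (`type` in `UTR5`, `CDS`, `intron`, `UTR3`,
#' `start_codon`, `stop_codon`; 1-based inclusive `start`/`end`; `rank`
#' orders CDS pieces and introns 5'->3' in transcript orientation).
#'
#' Validity requires the total CDS length of every transcript to be a
#' multiple of 3 and feature intervals within a transcript to be
#' non-overlapping.
#'
#' @aliases GeneModelSet-class
#' @export
setClass("GeneModelSet",
         representation(genes = "data.frame", features = "data.frame"))

setValidity("GeneModelSet", function(object) {
  msg <- character()
  gneed <- c("gene_id", "transcript_id", "chrom", "strand", "start", "end")
  fneed <- c("gene_id", "transcript_id", "chrom", "strand", "type",
             "start", "end", "rank")
  if (!all(gneed %in% colnames(object@genes)))
    msg <- c(msg, paste("genes slot needs columns:", paste(gneed, collapse = ", ")))
  if (!all(fneed %in% colnames(object@features)))
    msg <- c(msg, paste("features slot needs columns:", paste(fneed, collapse = ", ")))
  if (!length(msg)) {
    ok_types <- c("UTR5", "CDS", "intron", "UTR3", "start_codon", "stop_codon")
    if (!all(object@features$type %in% ok_types))
      msg <- c(msg, "unknown feature type")
    for (tx in unique(object@features$transcript_id)) {
      f <- object@features[object@features$transcript_id == tx, , drop = FALSE]
      cds <- f[f$type == "CDS", , drop = FALSE]
      if (nrow(cds) == 0L) {
        msg <- c(msg, paste0("transcript ", tx, " has no CDS"))
        next
      }
      if (sum(cds$end - cds$start + 1L) %% 3L != 0L)
        msg <- c(msg, paste0("transcript ", tx,
                             ": total CDS length not divisible by 3"))
      core <- f[f$type %in% c("UTR5", "CDS", "intron", "UTR3"), , drop = FALSE]
      core <- core[order(core$start), , drop = FALSE]
      if (nrow(core) > 1L &&
          any(core$start[-1L] <= core$end[-nrow(core)]))
        msg <- c(msg, paste0("transcript ", tx, ": overlapping intervals"))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GeneModelSet
#'
#' @param genes data.frame of gene records (see [GeneModelSet-class]).
#' @param features data.frame of feature intervals.
#' @return A validated [GeneModelSet-class].
#' @export
geneModelSet <- function(genes, features) {
  genes$chrom <- as.character(genes$chrom)
  features$chrom <- as.character(features$chrom)
  new("GeneModelSet", genes = genes, features = features)
}

setMethod("show", "GenotypeData", function(object) {
  cat("GenotypeData with", nrow(object), "SNP sites x",
      ncol(object), "accessions\n")
  cat("  assays:", paste(assayNames(object), collapse = ", "), "\n")
  chrom <- as.character(seqnames(rowRanges(object)))
  if (length(chrom))
    cat("  chromosomes:", paste(unique(chrom), collapse = ", "), "\n")
  miss <- mean(is.na(assay(object, "GT")))
  cat(sprintf("  missing call fraction: %.4f\n", miss))
})

setMethod("show", "GeneModelSet", function(object) {
  cat("GeneModelSet with", nrow(object@genes), "genes on",
      length(unique(object@genes$chrom)), "chromosome(s)\n")
  tab <- table(object@features$type)
  cat("  features:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
})

setMethod("length", "GeneModelSet", function(x) nrow(x@genes))

# ---- accessors -------------------------------------------------------------

#' Accessors for GenotypeData and GeneModelSet
#'
#' `dosage()` returns the sites x accessions alt-allele dosage matrix;
#' `depthMatrix()` the per-call read-depth matrix (or `NULL`);
#' `snpTable()` a data.frame of site records (`chrom`, `pos`, `ref`, `alt`,
#' `qual`); `accessionIds()` the accession identifiers; `nSites()` the site
#' count; `geneTable()`/`featureTable()` the gene and feature tables of a
#' [GeneModelSet-class].
#'
#' @param x a [GenotypeData-class] or [GeneModelSet-class] object.
#' @return See description; matrices, data.frames or vectors.
#' @name accessors
NULL

#' @rdname accessors
#' @export
dosage <- function(x) assay(x, "GT")

#' @rdname accessors
#' @export
depthMatrix <- function(x) {
  if ("DP" %in% assayNames(x)) assay(x, "DP") else NULL
}

#' @rdname accessors
#' @export
snpTable <- function(x) {
  rr <- rowRanges(x)
  data.frame(chrom = as.character(seqnames(rr)), pos = start(rr),
             ref = mcols(rr)$ref, alt = mcols(rr)$alt,
             qual = mcols(rr)$qual, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' @rdname accessors
#' @export
accessionIds <- function(x) colnames(x)

#' @rdname accessors
#' @export
nSites <- function(x) nrow(x)

#' @rdname accessors
#' @export
geneTable <- function(x) x@genes

#' @rdname accessors
#' @export
featureTable <- function(x) x@features

# internal: replace the GT assay, preserving class
.setDosage <- function(x, gt) {
  assay(x, "GT") <- gt
  x
}
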
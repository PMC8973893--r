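# Independent brute-force oracles used across the suite. These deliberately
# re-derive results from first principles (exhaustive enumeration, whole-
# protein translation) and never call the code paths they check.

# exhaustive sliding-window oracle: a site is removed iff ANY window of
# `w` consecutive bp containing it holds more than `maxN` sites
oracleWindowKeep <- function(pos, w, maxN) {
  vapply(seq_along(pos), function(i) {
    for (p in (pos[i] - w + 1L):pos[i]) {
      if (sum(pos >= p & pos <= p + w - 1L) > maxN) return(FALSE)
    }
    TRUE
  }, TRUE)
}

# per-site allele statistics recomputed by explicit per-accession counting
oracleSiteStats <- function(gtRow) {
  called <- gtRow[!is.na(gtRow)]
  altAlleles <- sum(called)
  totAlleles <- 2L * length(called)
  maf <- if (totAlleles > 0) {
    p <- altAlleles / totAlleles
    min(p, 1 - p)
  } else NaN
  list(missing = mean(is.na(gtRow)), maf = maf)
}

# spliced CDS of a transcript rebuilt directly from the feature table and
# reference sequence (strand-aware), independent of the package internals
oracleSplicedCds <- function(refChar, gm, tx) {
  f <- featureTable(gm)
  cds <- f[f$transcript_id == tx & f$type == "CDS", , drop = FALSE]
  cds <- cds[order(cds$start), , drop = FALSE]
  strand <- cds$strand[1L]
  seqs <- vapply(seq_len(nrow(cds)), function(i)
    substr(refChar[[cds$chrom[i]]], cds$start[i], cds$end[i]), "")
  s <- paste(seqs, collapse = "")
  if (strand == "-") {
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }
  s
}

# whole-protein translation with Biostrings (the independent translation
# route against the per-codon engine)
oracleTranslate <- function(cdsSeq) {
  as.character(Biostrings::translate(Biostrings::DNAString(cdsSeq),
                                     no.init.codon = TRUE))
}

# brute-force merge of significant positions into regions by gap rule
oracleMergeRegions <- function(chrom, pos, gapBp) {
  o <- order(chrom, pos)
  chrom <- chrom[o]; pos <- pos[o]
  out <- list()
  cur <- NULL
  for (i in seq_along(pos)) {
    if (is.null(cur) || chrom[i] != cur$chrom || pos[i] - cur$end > gapBp) {
      if (!is.null(cur)) out[[length(out) + 1L]] <- cur
      cur <- list(chrom = chrom[i], start = pos[i], end = pos[i], n = 1L)
    } else {
      cur$end <- pos[i]
      cur$n <- cur$n + 1L
    }
  }
  out[[length(out) + 1L]] <- cur
  do.call(rbind, lapply(out, as.data.frame))
}

# genotype matrix helper for hand-built fixtures
gdFromMatrix <- function(geno, pos = NULL, chrom = "chr1", qual = 60) {
  n <- nrow(geno)
  if (is.null(pos)) pos <- seq(100L, by = 100L, length.out = n)
  sites <- data.frame(chrom = chrom, pos = pos,
                      ref = rep_len(c("A", "C", "G", "T"), n),
                      alt = rep_len(c("G", "T", "A", "C"), n),
                      qual = qual)
  genotypeData(sites, geno)
}
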
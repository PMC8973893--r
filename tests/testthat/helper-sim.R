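# Shared simulated collections, built once per test run and cached.
.simCache <- new.env(parent = emptyenv())

demoSim <- function(seed = 42L) {
  key <- paste0("demo", seed)
  if (is.null(.simCache[[key]]))
    .simCache[[key]] <- simulateCollection(simulationConfig(seed = seed))
  .simCache[[key]]
}

# smaller/faster collection for IO and filter tests
smallSim <- function(seed = 11L) {
  key <- paste0("small", seed)
  if (is.null(.simCache[[key]])) {
    cfg <- simulationConfig(seed = seed, n_chromosomes = 1L,
                            chromosome_length = 30000L, n_genes = 8L,
                            n_wild = 15L, n_cultivated = 15L,
                            n_sites = 400L, chip_n_sites = 100L)
    .simCache[[key]] <- simulateCollection(cfg)
  }
  .simCache[[key]]
}

refChar <- function(sim) {
  out <- as.character(sim$reference)
  names(out) <- names(sim$reference)
  out
}

# hand-built single-gene model with fully controlled CDS content, used by
# the codon-effect examples; returns reference, gene model set and layout
handcraftedGene <- function(strand = "+") {
  # transcript layout (transcript orientation):
  # UTR5 20bp | CDS1 = ATG CCA GGA TGG AAA (15bp) | intron 40bp (GT..AG) |
  # CDS2 = CCT TTC TAA (9bp) | UTR3 20bp
  utr5 <- strrep("C", 20)
  cds1 <- "ATGCCAGGATGGAAA"
  intron <- paste0("GT", strrep("A", 36), "AG")
  cds2 <- "CCTTTCTAA"
  utr3 <- strrep("G", 20)
  spanSeq <- paste0(utr5, cds1, intron, cds2, utr3)
  span <- nchar(spanSeq)
  lead <- strrep("T", 50)
  tail <- strrep("T", 250)
  gstart <- 51L
  gend <- gstart + span - 1L
  genomicSpan <- if (strand == "-") {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(spanSeq)))
  } else spanSeq
  ref <- c(chrH = paste0(lead, genomicSpan, tail))
  local2genomic <- function(a, b) {
    if (strand == "+") c(gstart + a - 1L, gstart + b - 1L)
    else c(gend - b + 1L, gend - a + 1L)
  }
  iv <- rbind(
    data.frame(type = "UTR5", a = 1L, b = 20L, rank = NA),
    data.frame(type = "CDS", a = 21L, b = 35L, rank = 1L),
    data.frame(type = "intron", a = 36L, b = 75L, rank = 1L),
    data.frame(type = "CDS", a = 76L, b = 84L, rank = 2L),
    data.frame(type = "UTR3", a = 85L, b = 104L, rank = NA),
    data.frame(type = "start_codon", a = 21L, b = 23L, rank = NA),
    data.frame(type = "stop_codon", a = 82L, b = 84L, rank = NA))
  g <- t(vapply(seq_len(nrow(iv)), function(i)
    local2genomic(iv$a[i], iv$b[i]), c(0L, 0L)))
  feats <- data.frame(gene_id = "gH", transcript_id = "gH.t1",
                      chrom = "chrH", strand = strand, type = iv$type,
                      start = g[, 1L], end = g[, 2L], rank = iv$rank,
                      stringsAsFactors = FALSE)
  genes <- data.frame(gene_id = "gH", transcript_id = "gH.t1",
                      chrom = "chrH", strand = strand, start = gstart,
                      end = gend, stringsAsFactors = FALSE)
  gm <- geneModelSet(genes, feats)
  # genomic coordinate of a 1-based spliced-CDS offset
  cdsCoord <- function(cdsPos) {
    local <- if (cdsPos <= 15L) 20L + cdsPos else 75L + (cdsPos - 15L)
    lg <- local2genomic(local, local)
    lg[1L]
  }
  list(reference = ref, gm = gm, strand = strand, cdsCoord = cdsCoord,
       gstart = gstart, gend = gend)
}
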
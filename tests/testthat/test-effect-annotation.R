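test_that("region classification resolves features by priority", {
  h <- handcraftedGene("+")
  gm <- h$gm
  lens <- c(chrH = nchar(h$reference[["chrH"]]))
  f <- featureTable(gm)
  intron <- f[f$type == "intron", ]
  # first and second intronic bases are splice sites, third is plain intron
  expect_equal(classifyRegion("chrH", intron$start, gm, lens)$feature_class,
               "splice_site")
  expect_equal(classifyRegion("chrH", intron$start + 1L, gm,
                              lens)$feature_class, "splice_site")
  expect_equal(classifyRegion("chrH", intron$start + 2L, gm,
                              lens)$feature_class, "intron")
  expect_equal(classifyRegion("chrH", intron$end, gm, lens)$feature_class,
               "splice_site")
  start <- f[f$type == "start_codon", ]
  expect_equal(classifyRegion("chrH", start$start, gm, lens)$feature_class,
               "start_codon")
  u5 <- f[f$type == "UTR5", ]
  expect_equal(classifyRegion("chrH", u5$start, gm, lens)$feature_class,
               "UTR5")
  # intergenic with distance to the nearest gene boundary
  out <- classifyRegion("chrH", h$gend + 150L, gm, lens)
  expect_equal(out$region_class, "intergenic")
  expect_equal(out$distance_to_nearest_gene, 150L)
  expect_true(is.na(out$gene_id))
  expect_error(classifyRegion("chrH", lens[["chrH"]] + 5L, gm, lens),
               "beyond")
})

test_that("region classification agrees with a linear-scan oracle", {
  sim <- smallSim()
  gm <- sim$geneModels
  refs <- refChar(sim)
  lens <- nchar(refs)
  f <- featureTable(gm)
  genes <- geneTable(gm)
  oracleClass <- function(chrom, pos) {
    g <- genes[genes$chrom == chrom & genes$start <= pos & genes$end >= pos, ]
    if (nrow(g) == 0L) return("intergenic")
    ff <- f[f$transcript_id == g$transcript_id[1L], ]
    within <- function(type) {
      t <- ff[ff$type == type, ]
      nrow(t) > 0L && any(t$start <= pos & t$end >= pos)
    }
    ints <- ff[ff$type == "intron", ]
    if (nrow(ints) > 0L &&
        any((pos - ints$start) %in% 0:1 | (ints$end - pos) %in% 0:1))
      return("splice_site")
    for (type in c("start_codon", "stop_codon", "CDS", "UTR5", "UTR3",
                   "intron")) {
      if (within(type)) return(type)
    }
    "intron"
  }
  set.seed(402)
  for (k in 1:400) {
    chrom <- sample(names(refs), 1L)
    pos <- sample.int(lens[[chrom]], 1L)
    expect_identical(classifyRegion(chrom, pos, gm, lens)$feature_class,
                     oracleClass(chrom, pos))
  }
})

test_that("codon effects match the worked examples on both strands", {
  for (strand in c("+", "-")) {
    h <- handcraftedGene(strand)
    flip <- function(b) if (strand == "-") chartr("ACGT", "TGCA", b) else b
    ce <- function(cdsPos, txAlt) {
      gpos <- h$cdsCoord(cdsPos)
      ref <- substr(h$reference[["chrH"]], gpos, gpos)
      codonEffect("chrH", gpos, ref, flip(txAlt), "gH.t1", h$reference, h$gm)
    }
    # CCA with C->G at codon offset 2: CGA, P->R, nonsynonymous
    e1 <- ce(5L, "G")
    expect_equal(e1[c("ref_codon", "alt_codon", "ref_aa", "alt_aa",
                      "effect_class")],
                 list(ref_codon = "CCA", alt_codon = "CGA", ref_aa = "P",
                      alt_aa = "R", effect_class = "nonsynonymous"))
    expect_equal(e1$aa_position, 2L)
    expect_equal(e1$codon_offset, 2L)
    # GGA with A->G at offset 3: GGG, synonymous
    e2 <- ce(9L, "G")
    expect_equal(e2$effect_class, "synonymous")
    expect_equal(e2$alt_codon, "GGG")
    # TGG with G->A at offset 2: TAG, W->stop, stop_gained
    e3 <- ce(11L, "A")
    expect_equal(e3$effect_class, "stop_gained")
    expect_equal(e3$alt_aa, "*")
    # ATG start disrupted: start_lost
    e4 <- ce(1L, "C")
    expect_equal(e4$effect_class, "start_lost")
    # stop codon TAA -> CAA: stop_lost
    e5 <- ce(22L, "C")
    expect_equal(e5$effect_class, "stop_lost")
    # TAA -> TAG would be synonymous at the stop (offset 3 A->G)
    e6 <- ce(24L, "G")
    expect_equal(e6$effect_class, "synonymous")
    expect_equal(e6$ref_aa, "*")
    # ref-allele disagreement is a consistency error
    gpos <- h$cdsCoord(5L)
    wrongRef <- setdiff(c("A", "C", "G", "T"),
                        substr(h$reference[["chrH"]], gpos, gpos))[1L]
    expect_error(codonEffect("chrH", gpos, wrongRef, flip("G"), "gH.t1",
                             h$reference, h$gm), "consistency")
  }
})

test_that("codon engine agrees exhaustively with whole-protein translation", {
  sim <- smallSim()
  gm <- sim$geneModels
  refs <- refChar(sim)
  f <- featureTable(gm)
  txs <- unique(f$transcript_id)
  # both strands must be exercised
  expect_setequal(unique(f$strand), c("+", "-"))
  for (tx in txs[1:4]) {
    cdsSeq <- oracleSplicedCds(refs, gm, tx)
    refProt <- oracleTranslate(cdsSeq)
    cds <- f[f$transcript_id == tx & f$type == "CDS", ]
    cds <- cds[order(cds$rank), ]
    strand <- cds$strand[1L]
    posMap <- unlist(lapply(seq_len(nrow(cds)), function(i) {
      p <- cds$start[i]:cds$end[i]
      if (strand == "-") rev(p) else p
    }))
    for (cdsPos in seq_len(nchar(cdsSeq))) {
      txRef <- substr(cdsSeq, cdsPos, cdsPos)
      gpos <- posMap[cdsPos]
      gref <- substr(refs[[cds$chrom[1L]]], gpos, gpos)
      for (txAlt in setdiff(c("A", "C", "G", "T"), txRef)) {
        galt <- if (strand == "-") chartr("ACGT", "TGCA", txAlt) else txAlt
        got <- codonEffect(cds$chrom[1L], gpos, gref, galt, tx,
                           refs, gm)
        mutSeq <- cdsSeq
        substr(mutSeq, cdsPos, cdsPos) <- txAlt
        altProt <- oracleTranslate(mutSeq)
        aaPos <- (cdsPos - 1L) %/% 3L + 1L
        oRef <- substr(refProt, aaPos, aaPos)
        oAlt <- substr(altProt, aaPos, aaPos)
        oEffect <- if (aaPos == 1L &&
                       substr(mutSeq, 1L, 3L) != "ATG") "start_lost"
          else if (oRef == oAlt) "synonymous"
          else if (oRef != "*" && oAlt == "*") "stop_gained"
          else if (oRef == "*" && oAlt != "*") "stop_lost"
          else "nonsynonymous"
        expect_identical(got$ref_aa, oRef)
        expect_identical(got$alt_aa, oAlt)
        expect_identical(got$effect_class, oEffect)
      }
    }
  }
})

test_that("group frequencies match hand counts and the allele-count oracle", {
  g <- matrix(c(0L, 1L, 2L, NA), 1, 4,
              dimnames = list(NULL, c("m1", "m2", "m3", "s1")))
  x <- gdFromMatrix(g)
  md <- data.frame(accession_id = c("m1", "m2", "m3", "s1"),
                   species_group = c("G. max", "G. max", "G. max", "G. soja"),
                   germplasm_type = c("cultivar", "landrace", "cultivar",
                                      "wild"),
                   origin = "x", maturity_group = "I")
  fr <- groupFrequencies(x, md)
  expect_equal(fr$alt_freq_gmax, 0.5)   # alleles: 0+1+2 of 6
  expect_equal(fr$ref_freq_gmax, 0.5)
  expect_equal(fr$het_count, 1L)
  expect_true(is.na(fr$alt_freq_gsoja))  # only member is missing
  expect_equal(fr$n_called, 3L)
  # all-soja hom alt
  g2 <- matrix(2L, 1, 2, dimnames = list(NULL, c("s1", "s2")))
  md2 <- data.frame(accession_id = c("s1", "s2"), species_group = "G. soja",
                    germplasm_type = "wild", origin = "x",
                    maturity_group = "I")
  fr2 <- groupFrequencies(gdFromMatrix(g2), md2)
  expect_equal(fr2$alt_freq_gsoja, 1.0)
  # random oracle
  set.seed(19)
  sim <- smallSim()
  frS <- groupFrequencies(sim$genotypes, sim$metadata)
  gt <- dosage(sim$genotypes)
  soja <- sim$metadata$accession_id[sim$metadata$species_group == "G. soja"]
  for (i in sample(nrow(gt), 50L)) {
    row <- gt[i, soja]
    called <- row[!is.na(row)]
    expect_equal(frS$alt_freq_gsoja[i], sum(called) / (2 * length(called)))
    expect_equal(frS$ref_freq_gsoja[i] + frS$alt_freq_gsoja[i], 1)
  }
})

test_that("deleteriousness flags respect the threshold and the class gate", {
  sim <- smallSim()
  ann <- annotateSnps(sim$genotypes, sim$geneModels, sim$reference,
                      sim$metadata)
  nonsyn <- ann[ann$effect_class == "nonsynonymous", ][1L, ]
  syn <- ann[ann$effect_class == "synonymous", ][1L, ]
  scores <- data.frame(
    chrom = c(nonsyn$chromosome, syn$chromosome),
    pos = c(nonsyn$position, syn$position),
    alt = c(nonsyn$alt_allele, syn$alt_allele),
    score = c(-4.1, -9))
  out <- suppressMessages(applyDeleteriousness(ann, scores))
  key <- paste(out$chromosome, out$position)
  expect_true(out$deleterious_flag[key == paste(nonsyn$chromosome,
                                                nonsyn$position)])
  expect_false(out$deleterious_flag[key == paste(syn$chromosome,
                                                 syn$position)])
  expect_message(applyDeleteriousness(ann, scores), "ignored 1")
  # boundary: -4.0 does not flag
  scores$score[1L] <- -4.0
  out2 <- suppressMessages(applyDeleteriousness(ann, scores))
  expect_false(any(out2$deleterious_flag))
})

test_that("the report has exactly 30 columns and consistent summaries", {
  sim <- smallSim()
  ann <- annotateSnps(sim$genotypes, sim$geneModels, sim$reference,
                      sim$metadata)
  expect_equal(ncol(ann), 30L)
  expect_equal(nrow(ann), nrow(sim$genotypes))
  expect_false(anyDuplicated(ann$snp_id) > 0)
  inter <- ann$region_class == "intergenic"
  expect_true(all(is.na(ann$gene_id[inter])))
  expect_true(all(!is.na(ann$distance_to_nearest_gene[inter])))
  sg <- ann$effect_class == "stop_gained"
  expect_true(all(ann$alt_aa[sg] == "*"))
  total <- sum(nchar(as.character(sim$reference)))
  s <- summarizeAnnotations(ann, total, length(sim$geneModels))
  expect_equal(s$pct_genic + s$pct_intergenic, 100)
  expect_equal(s$density_snps_per_kb, nrow(ann) / (total / 1000))
  # brute-force recount from report rows
  expect_equal(s$n_nonsynonymous,
               sum(ann$effect_class == "nonsynonymous" &
                   !is.na(ann$cds_position)))
  expect_equal(s$n_splice_site, sum(ann$feature_class == "splice_site"))
  # degenerate case: no CDS SNPs gives undefined percentages, not zero
  noCds <- ann[ann$feature_class == "intergenic", ]
  s0 <- summarizeAnnotations(noCds, total, length(sim$geneModels))
  expect_true(is.na(s0$pct_nonsyn_of_cds))
  # toy density: 10 SNPs on 1 kb
  expect_equal(summarizeAnnotations(ann[1:10, ], 1000, 1)$density_snps_per_kb,
               10)
})
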
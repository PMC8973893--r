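test_that("reference generation is deterministic with uniform composition", {
  cfg <- simulationConfig(seed = 5L)
  r1 <- simulateReference(cfg)
  r2 <- simulateReference(cfg)
  expect_identical(as.character(r1), as.character(r2))
  expect_equal(length(r1), 2L)
  expect_equal(unname(Biostrings::width(r1)), c(50000L, 50000L))
  comp <- Biostrings::alphabetFrequency(r1[[1]])[c("A", "C", "G", "T")]
  expect_true(all(abs(comp / 50000 - 0.25) < 0.02))
  expect_error(simulationConfig(chromosome_length = 0), "configuration error")
})

test_that("gene models satisfy their construction invariants", {
  sim <- demoSim()
  gm <- sim$geneModels
  genes <- geneTable(gm)
  expect_equal(nrow(genes), 20L)
  # pairwise non-overlap (interval oracle)
  for (chr in unique(genes$chrom)) {
    g <- genes[genes$chrom == chr, ]
    if (nrow(g) < 2L) next
    for (i in seq_len(nrow(g) - 1L)) {
      for (j in seq((i + 1L), nrow(g))) {
        expect_true(g$end[i] < g$start[j] || g$end[j] < g$start[i])
      }
    }
  }
  refs <- refChar(sim)
  feats <- featureTable(gm)
  for (tx in genes$transcript_id) {
    cds <- oracleSplicedCds(refs, gm, tx)
    expect_equal(nchar(cds) %% 3L, 0L)
    expect_identical(substr(cds, 1L, 3L), "ATG")
    prot <- oracleTranslate(cds)
    # terminal stop only, none internal
    expect_identical(substr(prot, nchar(prot), nchar(prot)), "*")
    expect_false(grepl("\\*", substr(prot, 1L, nchar(prot) - 1L)))
    # splice dinucleotides GT..AG in transcript orientation
    f <- feats[feats$transcript_id == tx & feats$type == "intron", ,
               drop = FALSE]
    for (k in seq_len(nrow(f))) {
      iseq <- substr(refs[[f$chrom[k]]], f$start[k], f$end[k])
      if (f$strand[k] == "-") {
        iseq <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(iseq)))
      }
      expect_identical(substr(iseq, 1L, 2L), "GT")
      expect_identical(substr(iseq, nchar(iseq) - 1L, nchar(iseq)), "AG")
    }
  }
  # a minus-strand gene's reverse-complemented genomic CDS begins with ATG
  minus <- genes$transcript_id[genes$strand == "-"]
  expect_gt(length(minus), 0L)
  expect_error(
    simulateGeneModels(simulateReference(simulationConfig(
      n_chromosomes = 1L, chromosome_length = 2000L, n_genes = 20L)),
      simulationConfig(n_chromosomes = 1L, chromosome_length = 2000L,
                       n_genes = 20L)),
    "placement error")
})

test_that("population simulation honours planted truth and duplicates", {
  sim <- demoSim()
  st <- snpTable(sim$genotypes)
  key <- paste(st$chrom, st$pos)
  pl <- sim$truth$planted_sites
  expect_equal(nrow(pl), 10L)
  expect_true(all(paste(pl$chrom, pl$pos) %in% key))
  # planted ref/alt recorded in the emitted sites
  idx <- match(paste(pl$chrom, pl$pos), key)
  expect_identical(st$ref[idx], pl$ref)
  expect_identical(st$alt[idx], pl$alt)
  # duplicates flip at approximately the configured rate
  dp <- sim$truth$duplicate_pairs
  gt <- dosage(sim$genotypes)
  rates <- vapply(seq_len(nrow(dp)), function(i)
    mean(gt[, dp$a[i]] != gt[, dp$b[i]]), 0)
  expect_true(all(rates < 0.02))  # 0.005 expected over 2010 sites
  # mismatch rate 0 gives identical copies
  cfg0 <- simulationConfig(seed = 9L, duplicate_mismatch_rate = 0,
                           n_sites = 300L, n_wild = 10L, n_cultivated = 10L,
                           n_genes = 6L, n_chromosomes = 1L,
                           chromosome_length = 25000L)
  sim0 <- simulateCollection(cfg0)
  dp0 <- sim0$truth$duplicate_pairs
  g0 <- dosage(sim0$genotypes)
  expect_identical(g0[, dp0$a[1L]], g0[, dp0$b[1L]])
  # wild diversity exceeds cultivated diversity in expected heterozygosity
  lab <- sim$truth$subpop_labels
  hetOf <- function(group) {
    cols <- names(lab)[lab == group]
    p <- rowMeans(gt[, cols, drop = FALSE]) / 2
    mean(2 * p * (1 - p))
  }
  expect_gt(hetOf("wild"), hetOf("cultivated"))
  # seed determinism
  sim2 <- simulateCollection(simulationConfig(seed = 42L))
  expect_identical(dosage(sim2$genotypes), gt)
  expect_identical(sim2$truth$planted_sites, pl)
})

test_that("zero divergence gives exchangeable subpopulation frequencies", {
  # matched founder pools, tract lengths and (near-)equal diversity so the
  # only between-group difference is the divergence parameter itself
  nRep <- 100L
  pass <- 0L
  for (r in seq_len(nRep)) {
    cfg <- simulationConfig(seed = 1000L + r, divergence = 0,
                            n_chromosomes = 1L, chromosome_length = 20000L,
                            n_genes = 4L, n_sites = 150L, n_wild = 15L,
                            n_cultivated = 15L, n_duplicates = 0L,
                            wild_diversity = 1.0,
                            cultivated_diversity = 0.9999,
                            founder_pool_wild = 20L,
                            founder_pool_cultivated = 20L,
                            recomb_length_wild = 2000,
                            recomb_length_cultivated = 2000)
    ref <- simulateReference(cfg)
    gmr <- simulateGeneModels(ref, cfg)
    pop <- simulatePopulation(gmr$reference, gmr$geneModels, cfg)
    lab <- pop$truth$subpop_labels
    gt <- dosage(pop$genotypes)
    fW <- rowMeans(gt[, names(lab)[lab == "wild"], drop = FALSE]) / 2
    fC <- rowMeans(gt[, names(lab)[lab == "cultivated"], drop = FALSE]) / 2
    p <- suppressWarnings(stats::ks.test(fW, fC)$p.value)
    if (p > 0.01) pass <- pass + 1L
  }
  expect_gte(pass / nRep, 0.95)
})

test_that("chip subsetting preserves coordinates and masks at the no-call rate", {
  sim <- smallSim()
  x <- sim$genotypes
  chip0 <- subsetChip(x, 100L, 0, seed = 3L)
  key <- paste(snpTable(x)$chrom, snpTable(x)$pos)
  idx <- match(paste(snpTable(chip0)$chrom, snpTable(chip0)$pos), key)
  expect_false(any(is.na(idx)))
  expect_identical(unname(dosage(chip0)), unname(dosage(x)[idx, ]))
  chip1 <- subsetChip(x, 100L, 1, seed = 3L)
  expect_true(all(is.na(dosage(chip1))))
  big <- gdFromMatrix(matrix(rep(0:2, length.out = 1000 * 50), 1000, 50,
                             dimnames = list(NULL, sprintf("a%02d", 1:50))),
                      pos = seq_len(1000))
  chipR <- subsetChip(big, 1000L, 0.1, seed = 4L)
  expect_lt(abs(mean(is.na(dosage(chipR))) - 0.1), 0.02)
  expect_error(subsetChip(x, nrow(x) + 1L, 0), "exceeds")
})

test_that("trait simulation scales noise to the requested heritability", {
  sim <- smallSim()
  x <- sim$genotypes
  cs <- sim$truth$causal_site
  g <- dosage(x)[paste0(cs$chrom, "_", cs$pos), ]
  t1 <- simulateTrait(x, cs, qtlEffect = 2, heritability = 1, seed = 8L)
  expect_equal(stats::cor(t1, g, method = "spearman"), 1)
  t0 <- simulateTrait(x, cs, qtlEffect = 0, heritability = 0.5, seed = 8L)
  expect_lt(abs(stats::cor(t0, g)), 0.3)
  # regression R-squared oracle at n = 600
  cfg <- simulationConfig(seed = 21L, n_chromosomes = 1L,
                          chromosome_length = 50000L, n_genes = 6L,
                          n_wild = 300L, n_cultivated = 300L,
                          n_sites = 300L, n_duplicates = 0L)
  big <- simulateCollection(cfg)
  tr <- simulateTrait(big$genotypes, big$truth$causal_site, qtlEffect = 1,
                      heritability = 0.5, seed = 77L)
  gg <- dosage(big$genotypes)[paste0(big$truth$causal_site$chrom, "_",
                                     big$truth$causal_site$pos), ]
  r2 <- summary(stats::lm(tr ~ gg))$r.squared
  expect_lt(abs(r2 - 0.5), 0.1)
  expect_error(simulateTrait(x, cs, 1, heritability = 0), "heritability")
})
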
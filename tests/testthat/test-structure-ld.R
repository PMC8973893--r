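test_that("IBS distances take their hand-computed values", {
  mk <- function(a, b) {
    g <- cbind(a = a, b = b)
    mode(g) <- "integer"
    gdFromMatrix(g, pos = seq_along(a) * 10L)
  }
  expect_equal(ibsMatrix(mk(rep(0L, 10), rep(0L, 10)))["a", "b"], 0)
  expect_equal(ibsMatrix(mk(rep(0L, 10), rep(2L, 10)))["a", "b"], 1)
  expect_equal(ibsMatrix(mk(rep(0L, 10), rep(1L, 10)))["a", "b"], 0.5)
  d <- ibsMatrix(mk(c(0L, 2L, 1L, NA), c(0L, 0L, 1L, 2L)))
  expect_equal(d["a", "b"], mean(c(0, 1, 0)))  # NA site excluded
  expect_equal(diag(d), c(a = 0, b = 0))
  expect_error(ibsMatrix(mk(0L, 0L)[, 1]), "2 accessions")
})

test_that("neighbor-joining reproduces the three-point worked example", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- ape::read.tree(text = njTree(d)$newick)
  expect_setequal(tr$tip.label, c("A", "B", "C"))
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[c("A", "B", "C")], c(A = 1, B = 1, C = 3))
  # identical accessions become zero-length sisters
  d2 <- matrix(c(0, 0, 3, 3, 0, 0, 3, 3, 3, 3, 0, 2, 3, 3, 2, 0), 4, 4,
               dimnames = list(letters[1:4], letters[1:4]))
  tr2 <- ape::read.tree(text = njTree(d2)$newick)
  bl2 <- setNames(tr2$edge.length, c(tr2$tip.label, "")[tr2$edge[, 2]])
  expect_equal(unname(bl2["a"]), 0)
  expect_equal(unname(bl2["b"]), 0)
  expect_error(njTree(matrix(c(0, NA, NA, 0), 2, 2)), "incomplete|taxa")
})

test_that("neighbor-joining recovers additive-tree topologies", {
  skip_if_not_installed("ape")
  skip_if_not_installed("phangorn")
  for (s in 1:5) {
    set.seed(700 + s)
    n <- sample(6:12, 1L)
    gen <- ape::rtree(n)
    d <- ape::cophenetic.phylo(gen)
    d <- d[sort(rownames(d)), sort(colnames(d))]
    mine <- ape::read.tree(text = njTree(d)$newick)
    expect_equal(phangorn::RF.dist(ape::unroot(mine), ape::unroot(gen)), 0)
    # cross-check against the reference NJ implementation
    ref <- ape::nj(d)
    expect_equal(phangorn::RF.dist(ape::unroot(mine), ape::unroot(ref)), 0)
  }
})

test_that("PCA separates subpopulations and co-locates duplicates", {
  sim <- demoSim()
  pca <- pcaGenotypes(sim$genotypes, k = 5L)
  vf <- pca$variance_fraction
  expect_true(all(diff(vf) <= 1e-12))
  expect_true(all(vf >= 0 & vf <= 1))
  expect_lte(sum(vf), 1 + 1e-9)
  lab <- sim$truth$subpop_labels[rownames(pca$scores)]
  s1 <- pca$scores[, 1L]
  m <- tapply(s1, lab, mean)
  sds <- tapply(s1, lab, stats::sd)
  expect_gt(abs(diff(m)) / sqrt(mean(sds^2)), 4)
  dp <- sim$truth$duplicate_pairs
  rng <- diff(range(s1))
  for (i in seq_len(nrow(dp))) {
    expect_lt(abs(s1[dp$a[i]] - s1[dp$b[i]]), 0.01 * rng)
  }
  expect_warning(pcaGenotypes(sim$genotypes[1:5, 1:4], k = 10L), "rank")
})

test_that("r-squared matches the brute-force correlation oracle", {
  g <- rbind(c(0L, 0L, 1L, 1L, 2L, 2L),
             c(0L, 0L, 1L, 1L, 2L, 2L),
             c(2L, 2L, 1L, 1L, 0L, 0L))
  colnames(g) <- sprintf("a%d", 1:6)
  x <- gdFromMatrix(g, pos = c(100L, 200L, 300L))
  expect_equal(ldR2(x, 1L, 2L), 1)
  expect_equal(ldR2(x, 1L, 3L), 1)  # perfect anticorrelation squares to 1
  set.seed(246)
  gr <- matrix(sample(c(0:2, NA), 30 * 20, replace = TRUE,
                      prob = c(0.35, 0.25, 0.3, 0.1)), 30, 20,
               dimnames = list(NULL, sprintf("b%02d", 1:20)))
  xr <- gdFromMatrix(gr, pos = seq_len(30) * 40L)
  for (k in 1:40) {
    ij <- sample.int(30, 2L)
    got <- ldR2(xr, ij[1], ij[2])
    a <- gr[ij[1], ]; b <- gr[ij[2], ]
    ok <- !is.na(a) & !is.na(b)
    exp <- if (sum(ok) < 2 || stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0)
      NA_real_ else stats::cor(a[ok], b[ok])^2
    expect_equal(got, exp, tolerance = 1e-12)
  }
  # monomorphic pair undefined
  gm <- rbind(rep(0L, 6), c(0L, 1L, 2L, 0L, 1L, 2L))
  colnames(gm) <- sprintf("c%d", 1:6)
  expect_true(is.na(ldR2(gdFromMatrix(gm, pos = c(10L, 20L)), 1L, 2L)))
})

test_that("LD decay bin means equal the all-pairs brute force", {
  sim <- smallSim()
  x <- sim$genotypes[1:120, ]
  maxDist <- 10000
  bw <- 1000
  curve <- ldDecayCurve(x, maxDist = maxDist, minMaf = 0.05, binWidth = bw)
  # brute force on the MAF-filtered set
  maf <- siteMaf(x)
  xs <- x[!is.nan(maf) & maf >= 0.05, ]
  st <- snpTable(xs)
  gt <- dosage(xs)
  sums <- numeric(nrow(curve)); cnt <- integer(nrow(curve))
  for (i in seq_len(nrow(st) - 1L)) {
    for (j in seq((i + 1L), nrow(st))) {
      if (st$chrom[i] != st$chrom[j]) next
      d <- abs(st$pos[j] - st$pos[i])
      if (d == 0 || d > maxDist) next
      r2 <- .r2 <- suppressWarnings(stats::cor(gt[i, ], gt[j, ],
                                               use = "pairwise.complete.obs"))^2
      if (is.na(r2)) next
      b <- min(max(ceiling(d / bw), 1L), nrow(curve))
      sums[b] <- sums[b] + r2
      cnt[b] <- cnt[b] + 1L
    }
  }
  expect_equal(curve$n_pairs, cnt)
  expect_equal(curve$mean_r2, ifelse(cnt > 0, sums / cnt, NA_real_),
               tolerance = 1e-9)
  # monomorphic population flags a degenerate curve
  gmono <- matrix(0L, 20, 6, dimnames = list(NULL, sprintf("m%d", 1:6)))
  mono <- gdFromMatrix(gmono, pos = seq_len(20) * 100L)
  cmono <- ldDecayCurve(mono, maxDist = 2000)
  expect_true(attr(cmono, "degenerate"))
  expect_true(is.na(decayDistance(cmono)))
})

test_that("decay distance interpolates the threshold crossing", {
  mkCurve <- function(mid, r2) {
    c <- data.frame(bin_mid = mid, mean_r2 = r2, n_pairs = 100L)
    attr(c, "degenerate") <- FALSE
    class(c) <- c("LdDecayCurve", "data.frame")
    c
  }
  # constant-slope curve: smoothed values cross 0.2 between 300 and 500
  cv <- mkCurve(c(100, 300, 500, 700), c(0.5, 0.32, 0.14, 0.05))
  dd <- decayDistance(cv, 0.2)
  expect_gt(dd, 300)
  expect_lt(dd, 500)
  # never dropping below the threshold
  expect_equal(decayDistance(mkCurve(c(100, 300), c(0.9, 0.8)), 0.2), Inf)
})

test_that("LD pruning keeps one of each correlated cluster", {
  g <- rbind(c(0L, 0L, 1L, 1L, 2L, 2L),
             c(0L, 0L, 1L, 1L, 2L, 2L),
             c(0L, 2L, 1L, 0L, 2L, 1L))
  colnames(g) <- sprintf("a%d", 1:6)
  x <- gdFromMatrix(g, pos = c(100L, 150L, 5000L))
  pruned <- ldPrune(x, r2Threshold = 0.5, windowBp = 10000)
  expect_equal(nrow(pruned), 2L)
  expect_equal(snpTable(pruned)$pos, c(100L, 5000L))
  # independent sites all retained; retained set passes brute-force check
  sim <- smallSim()
  xs <- sim$genotypes[seq(1, nrow(sim$genotypes), by = 4L), ]
  pr <- ldPrune(xs, r2Threshold = 0.5, windowBp = 5000)
  st <- snpTable(pr)
  gt <- dosage(pr)
  for (i in seq_len(nrow(st) - 1L)) {
    for (j in seq((i + 1L), nrow(st))) {
      if (st$chrom[i] != st$chrom[j]) next
      if (st$pos[j] - st$pos[i] > 5000) next
      r2 <- .r2Check <- suppressWarnings(
        stats::cor(gt[i, ], gt[j, ], use = "pairwise.complete.obs"))^2
      if (!is.na(r2)) expect_lte(r2, 0.5)
    }
  }
  expect_true(all(siteMissingRate(pr) <= 0.2))
})
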
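#' Identity-by-state distance matrix
#'
#' For every accession pair, over sites called in both: the per-site shared
#' allele fraction of the unordered diploid genotypes is `1 - |d_i - d_j|/2`
#' (1 for identical genotypes, 0.5 for hom vs het, 0 for opposite
#' homozygotes); the IBS distance is one minus its average.
#'
#' @param x a [GenotypeData-class] with at least 2 accessions.
#' @return Symmetric numeric matrix with zero diagonal; a pair with no
#'   comparable site gets `NA`.
#' @export
ibsMatrix <- function(x) {
  gt <- dosage(x)
  n <- ncol(gt)
  if (n < 2L) stop("need at least 2 accessions")
  d <- matrix(0, n, n, dimnames = list(colnames(gt), colnames(gt)))
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      diff <- abs(gt[, i] - gt[, j]) / 2
      d[i, j] <- d[j, i] <- mean(diff, na.rm = TRUE)
      if (all(is.na(diff))) d[i, j] <- d[j, i] <- NA_real_
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration: at each step the pair minimizing
#' `Q(i,j) = (n-2) d(i,j) - r_i - r_j` is joined, branch lengths are
#' computed from the three-point formulas and negative branch lengths are
#' clamped to zero. The final three nodes are joined in a trifurcation.
#'
#' @param d complete symmetric distance matrix with labelled rows (n >= 3).
#' @return `list(newick = <string>)`; parse with `ape::read.tree(text=)` for
#'   downstream tree work.
#' @export
njTree <- function(d) {
  if (!is.matrix(d)) d <- as.matrix(d)
  if (any(is.na(d))) stop("incomplete distance matrix")
  n <- nrow(d)
  if (n < 3L) stop("need at least 3 taxa")
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  nodes <- labels  # newick fragment per active node
  active <- d
  fmt <- function(x) formatC(max(x, 0), format = "g", digits = 10)
  while (nrow(active) > 3L) {
    m <- nrow(active)
    r <- rowSums(active)
    q <- (m - 2) * active - outer(r, r, "+")
    diag(q) <- Inf
    ij <- which(q == min(q), arr.ind = TRUE)[1L, ]
    i <- min(ij); j <- max(ij)
    dij <- active[i, j]
    li <- dij / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- dij - li
    newNode <- sprintf("(%s:%s,%s:%s)", nodes[i], fmt(li), nodes[j], fmt(lj))
    dNew <- (active[i, ] + active[j, ] - dij) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    active <- rbind(cbind(active[keep, keep, drop = FALSE], dNew[keep]),
                    c(dNew[keep], 0))
    nodes <- c(nodes[keep], newNode)
  }
  # final trifurcation via three-point formulas
  dab <- active[1, 2]; dac <- active[1, 3]; dbc <- active[2, 3]
  la <- (dab + dac - dbc) / 2
  lb <- (dab + dbc - dac) / 2
  lc <- (dac + dbc - dab) / 2
  newick <- sprintf("(%s:%s,%s:%s,%s:%s);", nodes[1], fmt(la),
                    nodes[2], fmt(lb), nodes[3], fmt(lc))
  list(newick = newick)
}

#' Principal component analysis of genotype dosages
#'
#' Missing dosages are mean-imputed per site, zero-variance sites excluded,
#' each site centered and scaled by `sqrt(2 p (1 - p))` with `p` the alt
#' allele frequency, and the accession covariance eigen-decomposed.
#'
#' @param x a [GenotypeData-class].
#' @param k number of components to return (truncated to the rank with a
#'   warning when larger).
#' @return `list(scores = <accessions x k matrix>, variance_fraction =
#'   <length-k vector>)`; fractions are eigenvalue shares of the total
#'   variance, non-increasing.
#' @export
pcaGenotypes <- function(x, k = 10L) {
  gt <- dosage(x)
  rm <- rowMeans(gt, na.rm = TRUE)
  idx <- which(is.na(gt))
  if (length(idx))
    gt[idx] <- rm[(idx - 1L) %% nrow(gt) + 1L]
  v <- apply(gt, 1L, stats::var)
  keep <- !is.na(v) & v > 0
  gt <- gt[keep, , drop = FALSE]
  p <- rowMeans(gt) / 2
  z <- (gt - 2 * p) / sqrt(2 * p * (1 - p))
  cov <- crossprod(z) / nrow(z)
  eig <- eigen(cov, symmetric = TRUE)
  pos <- pmax(eig$values, 0)
  rank <- sum(pos > 1e-12)
  if (k > rank) {
    warning("k truncated to rank ", rank)
    k <- rank
  }
  scores <- sweep(eig$vectors[, seq_len(k), drop = FALSE], 2L,
                  sqrt(pos[seq_len(k)]), "*")
  rownames(scores) <- accessionIds(x)
  colnames(scores) <- paste0("PC", seq_len(k))
  list(scores = scores, variance_fraction = pos[seq_len(k)] / sum(pos))
}

#' Pairwise linkage disequilibrium r-squared
#'
#' Squared Pearson correlation of alt-allele dosages over accessions called
#' at both sites (genotype-correlation r-squared, unphased).
#'
#' @param x a [GenotypeData-class].
#' @param i,j site indices (rows of `x`).
#' @return r-squared in `[0, 1]`, or `NA` when fewer than 2 common calls or
#'   either site is monomorphic among them.
#' @export
ldR2 <- function(x, i, j) {
  gt <- dosage(x)
  .r2Vec(gt[i, ], gt[j, ])
}

.r2Vec <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 2L) return(NA_real_)
  a <- a[ok]; b <- b[ok]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)^2
}

#' Binned LD decay curve and decay distance
#'
#' `ldDecayCurve()` MAF-filters the sites, computes pairwise r-squared for
#' all same-chromosome site pairs within `maxDist`, and bins mean r-squared
#' by pair distance. `decayDistance()` smooths the curve with a 3-bin moving
#' average and returns the distance at which it first drops below the
#' threshold (monotone linear interpolation between adjacent bin midpoints);
#' `Inf` when the curve never drops below the threshold within `maxDist`.
#'
#' @param x a [GenotypeData-class].
#' @param maxDist maximum pair distance in bp (default 1 Mb).
#' @param minMaf minor-allele-frequency filter (default 0.05).
#' @param binWidth bin width in bp (default `maxDist / 100`).
#' @return data.frame of class `"LdDecayCurve"` with columns `bin_mid`
#'   (bp), `mean_r2`, `n_pairs`; attribute `"degenerate"` is `TRUE` when no
#'   pair yields a defined r-squared.
#' @export
ldDecayCurve <- function(x, maxDist = 1e6, minMaf = 0.05,
                         binWidth = maxDist / 100) {
  maf <- siteMaf(x)
  x <- x[!is.nan(maf) & maf >= minMaf, ]
  st <- snpTable(x)
  gt <- dosage(x)
  breaks <- seq(0, maxDist, by = binWidth)
  if (breaks[length(breaks)] < maxDist) breaks <- c(breaks, maxDist)
  nb <- length(breaks) - 1L
  sums <- numeric(nb)
  counts <- integer(nb)
  for (chr in unique(st$chrom)) {
    idx <- which(st$chrom == chr)
    if (length(idx) < 2L) next
    sub <- gt[idx, , drop = FALSE]
    pos <- st$pos[idx]
    cc <- suppressWarnings(stats::cor(t(sub),
                                      use = "pairwise.complete.obs"))^2
    dd <- abs(outer(pos, pos, "-"))
    up <- upper.tri(dd)
    sel <- up & dd <= maxDist & dd > 0 & !is.na(cc)
    if (!any(sel)) next
    bin <- pmin(pmax(ceiling(dd[sel] / binWidth), 1L), nb)
    sums <- sums + as.numeric(tapply(cc[sel], factor(bin, levels = seq_len(nb)),
                                     sum, default = 0))
    counts <- counts + as.integer(tapply(rep(1L, sum(sel)),
                                         factor(bin, levels = seq_len(nb)),
                                         sum, default = 0L))
  }
  curve <- data.frame(bin_mid = (breaks[-length(breaks)] + breaks[-1L]) / 2,
                      mean_r2 = ifelse(counts > 0, sums / counts, NA_real_),
                      n_pairs = counts)
  attr(curve, "degenerate") <- all(counts == 0L)
  class(curve) <- c("LdDecayCurve", "data.frame")
  curve
}

#' @rdname ldDecayCurve
#' @param curve an `"LdDecayCurve"`.
#' @param threshold r-squared threshold (default 0.2).
#' @export
decayDistance <- function(curve, threshold = 0.2) {
  if (isTRUE(attr(curve, "degenerate"))) return(NA_real_)
  ok <- !is.na(curve$mean_r2)
  mid <- curve$bin_mid[ok]
  r2 <- curve$mean_r2[ok]
  if (length(r2) == 0L) return(NA_real_)
  # centered 3-bin moving average (partial at the edges)
  sm <- vapply(seq_along(r2), function(i)
    mean(r2[max(1L, i - 1L):min(length(r2), i + 1L)]), 0)
  below <- which(sm < threshold)
  if (length(below) == 0L) return(Inf)
  i <- below[1L]
  if (i == 1L) return(mid[1L])
  # linear interpolation between the last bin at/above and the first below
  x0 <- mid[i - 1L]; y0 <- sm[i - 1L]
  x1 <- mid[i]; y1 <- sm[i]
  x0 + (y0 - threshold) / (y0 - y1) * (x1 - x0)
}

#' Greedy LD pruning
#'
#' Sites with missing rate above `maxMissing` are dropped first; then a
#' greedy left-to-right scan per chromosome drops any site whose r-squared
#' with an already-retained site within `windowBp` exceeds `r2Threshold`.
#'
#' @param x a [GenotypeData-class].
#' @param r2Threshold r-squared cutoff (default 0.5).
#' @param maxMissing missing-rate cutoff (default 0.2).
#' @param windowBp comparison window in bp (default 100000).
#' @return A pruned [GenotypeData-class].
#' @export
ldPrune <- function(x, r2Threshold = 0.5, maxMissing = 0.2,
                    windowBp = 1e5) {
  x <- x[siteMissingRate(x) <= maxMissing, ]
  st <- snpTable(x)
  gt <- dosage(x)
  keepAll <- logical(nrow(st))
  for (chr in unique(st$chrom)) {
    idx <- which(st$chrom == chr)
    pos <- st$pos[idx]
    retained <- integer()
    for (k in seq_along(idx)) {
      inWin <- retained[pos[retained] >= pos[k] - windowBp]
      drop <- FALSE
      for (r in inWin) {
        r2 <- .r2Vec(gt[idx[k], ], gt[idx[r], ])
        if (!is.na(r2) && r2 > r2Threshold) {
          drop <- TRUE
          break
        }
      }
      if (!drop) {
        retained <- c(retained, k)
        keepAll[idx[k]] <- TRUE
      }
    }
  }
  x[keepAll, ]
}
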
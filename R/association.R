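#' @importFrom stats pt complete.cases setNames var
NULL

#' Association scan configuration
#'
#' @param minMaf minor-allele-frequency filter for tested sites
#'   (default 0.01, sites with MAF >= `minMaf` are tested).
#' @param nPcs number of genotype principal components included as fixed
#'   covariates (default 3).
#' @return A validated list of class `"ScanConfig"`.
#' @export
scanConfig <- function(minMaf = 0.01, nPcs = 3L) {
  if (minMaf < 0 || minMaf >= 0.5) stop("minMaf must lie in [0, 0.5)")
  if (nPcs < 0) stop("nPcs must be >= 0")
  structure(list(minMaf = minMaf, nPcs = as.integer(nPcs)),
            class = "ScanConfig")
}

#' Bonferroni genome-wide significance threshold
#'
#' @param alpha family-wise error rate (default 0.05).
#' @param mTests number of tests (SNPs), must be >= 1.
#' @return Exactly `alpha / mTests`.
#' @export
bonferroniThreshold <- function(alpha = 0.05, mTests) {
  if (mTests < 1) stop("mTests must be >= 1")
  alpha / mTests
}

#' PC-adjusted single-marker association scan
#'
#' For every site passing the MAF filter, fits the fixed-effect linear model
#' `trait ~ intercept + PCs + dosage` on accessions with a called genotype
#' and a defined trait value, and reports the Wald p-value for the dosage
#' term. Population structure is absorbed by the leading genotype principal
#' components (a deliberate simplification of a kinship mixed model,
#' sufficient for planted-truth recovery at this scale). Binary traits are
#' handled by the same linear model on 0/1 coding.
#'
#' @param x a [GenotypeData-class].
#' @param trait named numeric vector (names = accession ids); needs >= 30
#'   defined values.
#' @param config a [scanConfig()].
#' @param pcs optional precomputed accession score matrix; computed from `x`
#'   via [pcaGenotypes()] when `NULL` and `nPcs > 0`.
#' @return List of class `"AssociationResult"`: `results` (data.frame
#'   chrom, pos, maf, n, effect, se, p, significant), `threshold`
#'   (`0.05 / m`), `m_tests`, `n_skipped`.
#' @export
associationScan <- function(x, trait, config = scanConfig(), pcs = NULL) {
  ids <- accessionIds(x)
  y <- trait[ids]
  if (sum(!is.na(y)) < 30L)
    stop("trait defined for fewer than 30 accessions")
  if (config$nPcs > 0L && is.null(pcs))
    pcs <- pcaGenotypes(x, k = config$nPcs)$scores
  covar <- if (config$nPcs > 0L)
    pcs[ids, seq_len(config$nPcs), drop = FALSE] else NULL
  gt <- dosage(x)
  st <- snpTable(x)
  maf <- siteMaf(x)
  test <- which(!is.nan(maf) & maf >= config$minMaf)
  nCov <- 1L + config$nPcs
  eff <- se <- p <- rep(NA_real_, length(test))
  nUsed <- integer(length(test))
  nSkipped <- 0L
  for (k in seq_along(test)) {
    g <- gt[test[k], ]
    Xfull <- cbind(`(Intercept)` = 1, covar, dosage = g)
    ok <- !is.na(y) & complete.cases(Xfull)
    n <- sum(ok)
    nUsed[k] <- n
    if (n < nCov + 2L) {
      nSkipped <- nSkipped + 1L
      next
    }
    X <- Xfull[ok, , drop = FALSE]
    yy <- y[ok]
    if (var(X[, ncol(X)]) == 0) {
      nSkipped <- nSkipped + 1L
      next
    }
    qr. <- qr(X)
    if (qr.$rank < ncol(X)) {
      nSkipped <- nSkipped + 1L
      next
    }
    beta <- qr.coef(qr., yy)
    res <- yy - X %*% beta
    df <- n - ncol(X)
    sigma2 <- sum(res^2) / df
    XtXinv <- chol2inv(qr.R(qr.))
    se[k] <- sqrt(sigma2 * XtXinv[ncol(X), ncol(X)])
    eff[k] <- beta[ncol(X)]
    tval <- eff[k] / se[k]
    p[k] <- 2 * pt(-abs(tval), df)
  }
  if (nSkipped > 0L)
    message("associationScan: skipped ", nSkipped, " site(s)")
  tested <- !is.na(p)
  m <- sum(tested)
  thr <- bonferroniThreshold(0.05, max(m, 1L))
  results <- data.frame(chrom = st$chrom[test], pos = st$pos[test],
                        maf = maf[test], n = nUsed, effect = eff, se = se,
                        p = p, significant = !is.na(p) & p < thr,
                        stringsAsFactors = FALSE)
  structure(list(results = results, threshold = thr, m_tests = m,
                 n_skipped = nSkipped),
            class = "AssociationResult")
}

#' Merge significant sites into peak regions
#'
#' Significant sites on the same chromosome separated by at most `gapBp`
#' are merged into one region; the lead SNP is the minimum p-value.
#'
#' @param result an `"AssociationResult"` from [associationScan()].
#' @param gapBp maximum within-region gap in bp (default 200 kb, the scale
#'   of an LD block around a strong QTL in a diverse crop collection).
#' @return data.frame: `chrom`, `start`, `end`, `n_snps`, `lead_pos`,
#'   `lead_p`.
#' @export
peakRegions <- function(result, gapBp = 2e5) {
  sig <- result$results[result$results$significant, , drop = FALSE]
  if (nrow(sig) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), n_snps = integer(),
                      lead_pos = integer(), lead_p = numeric()))
  sig <- sig[order(sig$chrom, sig$pos), , drop = FALSE]
  rows <- list()
  for (chr in unique(sig$chrom)) {
    s <- sig[sig$chrom == chr, , drop = FALSE]
    grp <- cumsum(c(TRUE, diff(s$pos) > gapBp))
    for (g in unique(grp)) {
      sg <- s[grp == g, , drop = FALSE]
      lead <- which.min(sg$p)
      rows[[length(rows) + 1L]] <-
        data.frame(chrom = chr, start = min(sg$pos), end = max(sg$pos),
                   n_snps = nrow(sg), lead_pos = sg$pos[lead],
                   lead_p = sg$p[lead], stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
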
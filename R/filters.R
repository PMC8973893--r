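#' Site-filter configuration
#'
#' Thresholds for the fixed filter cascade applied to a population callset:
#' per-genotype depth masking, site-quality dropping, SNP-cluster window
#' removal, then population-level minor-allele-frequency / missing-rate /
#' call-fraction filtering.
#'
#' @param minDepth calls with read depth below this are set to missing
#'   (default 5, i.e. depth >= 5 is retained).
#' @param minQuality sites with phred-scaled quality below this are dropped
#'   (default 50).
#' @param maxSnpsPerWindow,windowSize any site lying in at least one
#'   `windowSize`-bp window containing more than `maxSnpsPerWindow` sites is
#'   removed, with the whole cluster (defaults: 2 SNPs per 10 bp).
#' @param minSiteCallFraction minimum fraction of accessions with a called
#'   genotype at a site (default 0.20).
#' @param minMaf sites with minor allele frequency `<= minMaf` are dropped
#'   (default 0.001, i.e. MAF > 0.001 is retained).
#' @param maxMissing sites with missing rate `>= maxMissing` are dropped
#'   (default 0.5, i.e. missing rate < 0.5 is retained).
#' @return A validated list of class `"SiteFilterConfig"`.
#' @export
siteFilterConfig <- function(minDepth = 5L, minQuality = 50,
                             maxSnpsPerWindow = 2L, windowSize = 10L,
                             minSiteCallFraction = 0.20, minMaf = 0.001,
                             maxMissing = 0.5) {
  cfg <- list(minDepth = minDepth, minQuality = minQuality,
              maxSnpsPerWindow = as.integer(maxSnpsPerWindow),
              windowSize = as.integer(windowSize),
              minSiteCallFraction = minSiteCallFraction,
              minMaf = minMaf, maxMissing = maxMissing)
  if (any(vapply(cfg, function(v) is.na(v) || v < 0, TRUE)))
    stop("all thresholds must be >= 0")
  if (cfg$windowSize < 1L) stop("windowSize must be >= 1")
  for (f in c("minSiteCallFraction", "minMaf", "maxMissing"))
    if (cfg[[f]] > 1) stop(f, " must lie in [0, 1]")
  class(cfg) <- "SiteFilterConfig"
  cfg
}

#' Per-site allele statistics
#'
#' `siteMaf()` computes the minor allele frequency over non-missing alleles
#' (each diploid call contributes 2 alleles, a het one of each);
#' `siteMissingRate()` the fraction of accessions with a missing call;
#' `siteCallFraction()` its complement.
#'
#' @param x a [GenotypeData-class] or a dosage matrix.
#' @return Numeric vector, one value per site (`NaN` MAF where no calls).
#' @export
siteMaf <- function(x) {
  gt <- if (is.matrix(x)) x else dosage(x)
  altCount <- rowSums(gt, na.rm = TRUE)
  alleles <- 2L * rowSums(!is.na(gt))
  p <- altCount / alleles
  unname(pmin(p, 1 - p))
}

#' @rdname siteMaf
#' @export
siteMissingRate <- function(x) {
  gt <- if (is.matrix(x)) x else dosage(x)
  unname(rowMeans(is.na(gt)))
}

#' @rdname siteMaf
#' @export
siteCallFraction <- function(x) 1 - siteMissingRate(x)

#' Mask low-confidence genotypes and drop low-quality sites
#'
#' Calls with depth `< minDepth` are set to missing; sites with quality
#' `< minQuality` are dropped entirely. If the object carries no depth
#' assay, calls are retained and this is logged once.
#'
#' @param x a [GenotypeData-class].
#' @param config a [siteFilterConfig()].
#' @return `list(genotypes = <GenotypeData>, n_masked_genotypes,
#'   n_dropped_sites)`.
#' @export
maskLowConfidenceGenotypes <- function(x, config = siteFilterConfig()) {
  gt <- dosage(x)
  dp <- depthMatrix(x)
  nMasked <- 0L
  if (is.null(dp)) {
    message("maskLowConfidenceGenotypes: no depth assay; calls retained")
  } else {
    mask <- !is.na(gt) & (is.na(dp) | dp < config$minDepth)
    # absent depth at an individual call retains the call
    mask[is.na(dp)] <- FALSE
    nMasked <- sum(mask)
    gt[mask] <- NA_integer_
    x <- .setDosage(x, gt)
  }
  qual <- snpTable(x)$qual
  keep <- is.na(qual) | qual >= config$minQuality
  nDropped <- sum(!keep)
  x <- x[keep, ]
  list(genotypes = x, n_masked_genotypes = nMasked,
       n_dropped_sites = nDropped)
}

# logical keep vector for the SNP-cluster window rule on one sorted position
# vector: a site is removed iff some length-w window containing it holds more
# than maxN sites; every window can be shifted so its left edge is a site,
# so windows anchored at each site suffice
.windowKeep <- function(pos, windowSize, maxN) {
  n <- length(pos)
  if (n == 0L) return(logical(0))
  if (is.unsorted(pos)) stop("positions must be sorted within chromosome")
  keep <- rep(TRUE, n)
  j <- 1L
  for (i in seq_len(n)) {
    if (j < i) j <- i
    while (j < n && pos[j + 1L] <= pos[i] + windowSize - 1L) j <- j + 1L
    if (j - i + 1L > maxN) keep[i:j] <- FALSE
  }
  keep
}

#' SNP-cluster window filter
#'
#' Removes every site lying in at least one `windowSize`-bp window containing
#' more than `maxSnpsPerWindow` sites (whole-cluster removal, GATK-style:
#' dense clusters indicate alignment artifacts).
#'
#' @param x a [GenotypeData-class], or a data.frame with columns
#'   `chrom`, `pos` (sorted by position within chromosome).
#' @param config a [siteFilterConfig()].
#' @return For a `GenotypeData`: `list(genotypes, n_removed, keep)`. For a
#'   data.frame: `list(sites, n_removed, keep)` where `keep` is the logical
#'   retention vector in input order.
#' @export
windowFilter <- function(x, config = siteFilterConfig()) {
  st <- if (is.data.frame(x)) x else snpTable(x)
  keep <- rep(TRUE, nrow(st))
  for (chr in unique(st$chrom)) {
    idx <- which(st$chrom == chr)
    keep[idx] <- .windowKeep(st$pos[idx], config$windowSize,
                             config$maxSnpsPerWindow)
  }
  if (is.data.frame(x)) {
    list(sites = x[keep, , drop = FALSE], n_removed = sum(!keep), keep = keep)
  } else {
    list(genotypes = x[keep, ], n_removed = sum(!keep), keep = keep)
  }
}

#' Population-level site filter
#'
#' Drops sites with missing rate `>= maxMissing`, minor allele frequency
#' `<= minMaf` (computed over non-missing alleles; a het contributes one
#' allele of each kind), or called fraction `< minSiteCallFraction`.
#'
#' @param x a [GenotypeData-class] (genotype masking already applied).
#' @param config a [siteFilterConfig()].
#' @return `list(genotypes, n_removed, removed_by_rule)` where
#'   `removed_by_rule` attributes each removed site to the first rule (in
#'   order missing-rate, call-fraction, MAF) that fails it.
#' @export
populationFilter <- function(x, config = siteFilterConfig()) {
  if (ncol(x) == 0L || nrow(x) == 0L) stop("empty genotype matrix")
  miss <- siteMissingRate(x)
  maf <- siteMaf(x)
  failMiss <- miss >= config$maxMissing
  failCall <- (1 - miss) < config$minSiteCallFraction
  failMaf <- is.nan(maf) | maf <= config$minMaf
  keep <- !(failMiss | failCall | failMaf)
  removed_by_rule <- c(missing_rate = sum(failMiss),
                       call_fraction = sum(!failMiss & failCall),
                       maf = sum(!failMiss & !failCall & failMaf))
  list(genotypes = x[keep, ], n_removed = sum(!keep),
       removed_by_rule = removed_by_rule)
}

#' Run the full filter cascade
#'
#' Fixed order: per-genotype depth masking, site-quality drop, SNP-cluster
#' window removal, population-level MAF/missing/call-fraction filter. The
#' report reconciles exactly: input = removed + surviving at every stage.
#'
#' @param x a [GenotypeData-class].
#' @param config a [siteFilterConfig()].
#' @return `list(genotypes = <filtered GenotypeData>, report =
#'   <data.frame stage/input_sites/removed_sites/surviving_sites>)`.
#' @export
filterSites <- function(x, config = siteFilterConfig()) {
  n0 <- nrow(x)
  m <- maskLowConfidenceGenotypes(x, config)
  n1 <- nrow(m$genotypes)
  w <- windowFilter(m$genotypes, config)
  n2 <- nrow(w$genotypes)
  p <- populationFilter(w$genotypes, config)
  n3 <- nrow(p$genotypes)
  report <- data.frame(
    stage = c("genotype_mask_site_quality", "window_cluster", "population"),
    input_sites = c(n0, n1, n2),
    removed_sites = c(n0 - n1, n1 - n2, n2 - n3),
    surviving_sites = c(n1, n2, n3))
  list(genotypes = p$genotypes, report = report,
       n_masked_genotypes = m$n_masked_genotypes)
}

#' Count sites exceeding MAF thresholds
#'
#' Returns the number of sites with minor allele frequency strictly above
#' each threshold; counts are monotonically non-increasing in the threshold.
#'
#' @param x a [GenotypeData-class] or dosage matrix.
#' @param thresholds numeric vector of MAF thresholds.
#' @return Named integer vector of site counts.
#' @export
mafPartition <- function(x, thresholds = c(0.01, 0.05)) {
  maf <- siteMaf(x)
  out <- vapply(thresholds, function(t) sum(maf > t, na.rm = TRUE), 0L)
  names(out) <- paste0("maf_gt_", thresholds)
  out
}
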
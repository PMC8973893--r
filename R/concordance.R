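#' Coordinate-matched genotype identity between two accessions
#'
#' Aligns two genotype sources on shared (chromosome, position) coordinates,
#' drops coordinates where either source is missing/no-call, and reports the
#' percent of the remaining coordinates with an exactly identical genotype
#' (hom-ref = hom-ref, het = het, hom-alt = hom-alt): the ratio of identical
#' genotypes to all coordinates compared.
#'
#' @param xA,xB [GenotypeData-class] objects (may be the same object).
#' @param accA,accB accession identifiers, one in each source.
#' @return `list(n_compared, n_identical, identity)` with `identity` in
#'   percent (rounded display at 0.01% is left to callers); `identity` is
#'   `NA` (undefined) when no coordinate is comparable. Comparisons with
#'   `n_compared < 30` carry `low_confidence = TRUE`.
#' @export
pairwiseIdentity <- function(xA, accA, xB, accB) {
  kA <- paste(snpTable(xA)$chrom, snpTable(xA)$pos)
  kB <- paste(snpTable(xB)$chrom, snpTable(xB)$pos)
  idx <- match(kA, kB)
  shared <- !is.na(idx)
  da <- dosage(xA)[shared, accA]
  db <- dosage(xB)[idx[shared], accB]
  .identityFromVectors(da, db)
}

.identityFromVectors <- function(da, db) {
  ok <- !is.na(da) & !is.na(db)
  nCompared <- sum(ok)
  nIdentical <- sum(da[ok] == db[ok])
  list(n_compared = nCompared, n_identical = nIdentical,
       identity = if (nCompared > 0) 100 * nIdentical / nCompared else
         NA_real_,
       low_confidence = nCompared < 30L)
}

#' Best-match ("genomic equivalent") accession assignment
#'
#' `bestMatch()` returns, for one query accession, the panel accession with
#' the highest coordinate-matched identity (ties reported in full; the
#' primary pick is the lexicographically smallest identifier).
#' `matchAccessions()` applies it to every query accession.
#'
#' @param query a [GenotypeData-class] holding the query accession(s).
#' @param queryAcc query accession id (for `bestMatch()`).
#' @param panel a [GenotypeData-class] holding the candidate panel.
#' @return `bestMatch()`: `list(best_match, identity, n_compared, ties)`.
#'   `matchAccessions()`: data.frame with one row per query accession.
#' @export
bestMatch <- function(query, queryAcc, panel) {
  ids <- accessionIds(panel)
  if (length(ids) == 0L) stop("empty panel")
  res <- lapply(ids, function(p) pairwiseIdentity(query, queryAcc, panel, p))
  idents <- vapply(res, function(r)
    if (is.na(r$identity)) -Inf else r$identity, 0)
  if (all(!is.finite(idents)))
    stop("all identities undefined for query ", queryAcc)
  top <- max(idents)
  ties <- sort(ids[idents == top])
  best <- ties[1L]
  bi <- which(ids == best)
  list(best_match = best, identity = res[[bi]]$identity,
       n_compared = res[[bi]]$n_compared, ties = ties)
}

#' @rdname bestMatch
#' @export
matchAccessions <- function(query, panel) {
  rows <- lapply(accessionIds(query), function(q) {
    b <- bestMatch(query, q, panel)
    data.frame(query = q, best_match = b$best_match,
               identity = b$identity, n_compared = b$n_compared,
               n_ties = length(b$ties), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Scan a collection for duplicate accessions
#'
#' Computes pairwise identity for every unordered accession pair and returns
#' those at or above the identity threshold.
#'
#' @param x a [GenotypeData-class].
#' @param thresholdPercent identity threshold in `[0, 100]`.
#' @return data.frame with columns `a`, `b`, `identity`, `n_compared`,
#'   `n_identical` for every qualifying pair.
#' @export
duplicateScan <- function(x, thresholdPercent) {
  if (thresholdPercent < 0 || thresholdPercent > 100)
    stop("thresholdPercent must lie in [0, 100]")
  gt <- dosage(x)
  ids <- accessionIds(x)
  rows <- list()
  for (i in seq_len(length(ids) - 1L)) {
    for (j in seq((i + 1L), length(ids))) {
      r <- .identityFromVectors(gt[, i], gt[, j])
      if (!is.na(r$identity) && r$identity >= thresholdPercent)
        rows[[length(rows) + 1L]] <-
          data.frame(a = ids[i], b = ids[j], identity = r$identity,
                     n_compared = r$n_compared,
                     n_identical = r$n_identical, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(a = character(), b = character(),
                      identity = numeric(), n_compared = integer(),
                      n_identical = integer()))
  do.call(rbind, rows)
}

#' Coordinate-set novelty comparison
#'
#' Exact intersection/difference counts of two SNP coordinate sets keyed by
#' (chromosome, position), as used to compare a callset against a reference
#' SNP database: coordinates absent from `b` are novel to `a`.
#'
#' @param a,b data.frames with columns `chrom`, `pos` (or
#'   [GenotypeData-class] objects).
#' @return `list(shared, novel_to_a)`.
#' @export
coordinateNovelty <- function(a, b) {
  keyOf <- function(z) {
    st <- if (is.data.frame(z)) z else snpTable(z)
    unique(paste(st$chrom, st$pos))
  }
  ka <- keyOf(a)
  kb <- keyOf(b)
  list(shared = sum(ka %in% kb), novel_to_a = sum(!ka %in% kb))
}
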
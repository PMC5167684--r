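# Collinearity pruning: pairwise Pearson correlations, then iterative
# removal until no kept pair exceeds the cutoff.

#' Pearson correlation matrix of a FeatureTable
#'
#' Symmetric with unit diagonal. Zero-variance columns get correlation 0
#' against everything and are flagged in the `"zeroVariance"` attribute
#' (they carry no information and can be dropped separately).
#'
#' @param x a [FeatureTable-class] (or numeric matrix) with at least 3
#'   rows.
#' @return correlation matrix with attribute `zeroVariance` (character
#'   vector of flagged features).
#' @export
correlationMatrix <- function(x) {
  m <- if (is(x, "FeatureTable")) featureMatrix(x) else x
  if (nrow(m) < 3) stop("need at least 3 rows to estimate correlations",
                        call. = FALSE)
  sds <- apply(m, 2, stats::sd)
  zv <- colnames(m)[sds == 0]
  r <- suppressWarnings(stats::cor(m))
  r[is.na(r)] <- 0
  diag(r) <- 1
  attr(r, "zeroVariance") <- zv
  r
}

#' Remove collinear features by pairwise correlation
#'
#' Iteratively finds the feature pair with the largest absolute Pearson
#' correlation above `cutoff` and removes the member with the larger mean
#' absolute correlation against all remaining features, until no kept
#' pair exceeds the cutoff. Deterministic for a given column order (ties
#' remove the later column).
#'
#' @param x a [FeatureTable-class], numeric matrix, or precomputed
#'   correlation matrix (square, symmetric).
#' @param cutoff absolute correlation cutoff in (0, 1]; default 0.7.
#' @return A [PruneResult-class]; `keptFeatures(result)` satisfies
#'   max off-diagonal |r| <= cutoff.
#' @export
pruneCorrelated <- function(x, cutoff = 0.7) {
  if (length(cutoff) != 1 || cutoff <= 0 || cutoff > 1)
    stop("cutoff must be in (0, 1]", call. = FALSE)
  r <- if (is.matrix(x) && nrow(x) == ncol(x) &&
           !is.null(rownames(x)) && identical(rownames(x), colnames(x)))
    x else correlationMatrix(x)
  feats <- colnames(r)
  a <- abs(r); diag(a) <- 0
  meanAbs0 <- stats::setNames(rowMeans(a), feats)
  removed <- character(0)
  while (ncol(a) >= 2) {
    top <- which.max(a)
    if (a[top] <= cutoff) break
    ij <- arrayInd(top, dim(a))
    i <- ij[1]; j <- ij[2]
    mi <- mean(a[i, -i]); mj <- mean(a[j, -j])
    drop <- if (mi > mj) i else if (mj > mi) j else max(i, j)
    removed <- c(removed, colnames(a)[drop])
    a <- a[-drop, -drop, drop = FALSE]
  }
  kept <- setdiff(feats, removed)
  new("PruneResult", kept = kept, removed = removed, cutoff = cutoff,
      meanAbsCor = meanAbs0)
}
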
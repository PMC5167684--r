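# Greedy identity-threshold clustering (CD-HIT-style, without the k-mer
# prefilter): records are processed longest-first; each joins the first
# cluster whose representative identity >= threshold, else founds a new
# cluster. Identity is the number of identical aligned positions of a
# global alignment divided by the shorter sequence length.

.identityMatrixAA <- function() {
  if (!is.null(.oligoFPcache$submat)) return(.oligoFPcache$submat)
  letters <- c(AA20, "X", "*", "-", "+", ".", "B", "J", "Z", "U", "O")
  m <- matrix(0, length(letters), length(letters),
              dimnames = list(letters, letters))
  diag(m)[seq_along(AA20)] <- 1
  .oligoFPcache$submat <- m
  m
}

#' Pairwise sequence identity (global alignment)
#'
#' Global alignment with match +1, mismatch 0 and a linear gap penalty;
#' identity is identical aligned positions divided by the length of the
#' shorter sequence (CD-HIT convention). Symmetric.
#'
#' @param a,b protein sequences (character or `AAString`).
#' @return identity in `[0, 1]`.
#' @export
pairwiseIdentity <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  stopifnot(nchar(a) > 0, nchar(b) > 0)
  if (a == b) return(1)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = .identityMatrixAA(),
    gapOpening = 0, gapExtension = 1, type = "global")
  Biostrings::nmatch(al) / min(nchar(a), nchar(b))
}

# identities of one query against a set of references, vectorized in C;
# minLen is min(width) pairwise
.identityToSet <- function(query, refs) {
  eq <- refs == query
  out <- numeric(length(refs))
  if (any(eq)) out[eq] <- 1
  todo <- which(!eq)
  if (length(todo)) {
    al <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(refs[todo]), Biostrings::AAString(query),
      substitutionMatrix = .identityMatrixAA(),
      gapOpening = 0, gapExtension = 1, type = "global")
    out[todo] <- Biostrings::nmatch(al) /
      pmin(nchar(refs[todo]), nchar(query))
  }
  out
}

#' Greedy identity-threshold clustering
#'
#' Sorts records by length (descending, ties in input order), then
#' assigns each record to the first existing cluster whose representative
#' has identity `>=` threshold with it, founding a new cluster otherwise.
#' Representatives are therefore the longest members of their clusters.
#' A composition-based upper bound on alignment identity (sum of
#' per-residue minimum counts over the shorter length) is used to skip
#' alignments that cannot reach the threshold; candidates that pass the
#' bound are aligned in cluster order, so the first-match rule is exact.
#'
#' @param x named `AAStringSet` (or named character vector).
#' @param threshold identity threshold in (0, 1]. At 1.00 the result is
#'   equivalent to exact-duplicate removal for sequence sets without
#'   subsequence containment.
#' @return A [ClusterResult-class].
#' @export
greedyCluster <- function(x, threshold) {
  stopifnot(threshold > 0, threshold <= 1)
  if (is.character(x)) x <- Biostrings::AAStringSet(x)
  if (length(x) == 0)
    return(new("ClusterResult", threshold = threshold, clusters = list(),
               retained = Biostrings::AAStringSet()))
  ids <- names(x)
  if (is.null(ids) || anyDuplicated(ids))
    stop("sequences must carry unique names", call. = FALSE)
  seqs <- as.character(x)
  ord <- order(-nchar(seqs))  # stable: ties keep input order
  seqs <- seqs[ord]; ids <- ids[ord]

  repSeq <- character(0)
  repComp <- NULL                      # 20 x nrep residue count matrix
  clusters <- list()
  for (k in seq_along(seqs)) {
    s <- seqs[[k]]
    n <- nchar(s)
    qc <- as.integer(table(factor(strsplit(s, "")[[1]], levels = AA20)))
    assigned <- 0L
    if (length(repSeq)) {
      bound <- colSums(pmin(repComp, qc)) / n   # n = shorter length
      cand <- which(bound >= threshold - 1e-12)
      for (j in cand) {
        idv <- .identityToSet(s, repSeq[j])
        if (idv >= threshold - 1e-12) { assigned <- j; break }
      }
    }
    if (assigned > 0L) {
      clusters[[assigned]] <- c(clusters[[assigned]], ids[[k]])
    } else {
      repSeq <- c(repSeq, s)
      repComp <- cbind(repComp, qc)
      clusters[[length(repSeq)]] <- ids[[k]]
    }
  }
  names(clusters) <- vapply(clusters, `[[`, "", 1L)
  retained <- x[names(clusters)]
  new("ClusterResult", threshold = threshold, clusters = clusters,
      retained = retained)
}

#' Write cluster membership as CSV
#' @param x a [ClusterResult-class]
#' @param file output path (columns `member_id`, `representative_id`).
#' @export
writeClusterCSV <- function(x, file) {
  write.csv(clusterMembers(x), file, row.names = FALSE)
}
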
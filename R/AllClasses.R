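#' @import methods
#' @importFrom stats cor sd qbeta setNames
#' @importFrom utils read.delim write.csv head
NULL

#' FeatureTable: descriptor values per sequence
#'
#' A numeric matrix of sequence descriptors with one row per sequence id and
#' one column per named feature, in a deterministic canonical order for a
#' given descriptor configuration.
#'
#' @slot values numeric matrix; rownames are sequence ids, colnames are
#'   feature names (unique, non-empty).
#' @exportClass FeatureTable
setClass("FeatureTable", representation(values = "matrix"))

setValidity("FeatureTable", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("values must be a numeric matrix")
  if (is.null(colnames(v)) || anyDuplicated(colnames(v)) ||
      any(!nzchar(colnames(v))))
    return("feature names must be unique and non-empty")
  if (is.null(rownames(v)) || anyDuplicated(rownames(v)) ||
      any(!nzchar(rownames(v))))
    return("sequence ids must be unique and non-empty")
  TRUE
})

#' Construct a FeatureTable
#'
#' @param values numeric matrix with sequence ids as rownames and feature
#'   names as colnames.
#' @return A [FeatureTable-class] object.
#' @export
FeatureTable <- function(values) {
  new("FeatureTable", values = values)
}

#' @describeIn FeatureTable-class number of sequences (rows)
#' @param x,object a FeatureTable
#' @export
setMethod("nrow", "FeatureTable", function(x) nrow(x@values))

#' @describeIn FeatureTable-class number of features (columns)
#' @export
setMethod("ncol", "FeatureTable", function(x) ncol(x@values))

#' Feature names of a FeatureTable
#' @param x a FeatureTable
#' @return character vector of feature names in canonical order.
#' @export
featureNames <- function(x) {
  stopifnot(is(x, "FeatureTable"))
  colnames(x@values)
}

#' Sequence ids of a FeatureTable
#' @param x a FeatureTable
#' @return character vector of sequence ids (row order).
#' @export
sequenceIds <- function(x) {
  stopifnot(is(x, "FeatureTable"))
  rownames(x@values)
}

#' Extract the descriptor matrix from a FeatureTable
#' @param x a FeatureTable
#' @return the underlying numeric matrix.
#' @export
featureMatrix <- function(x) {
  stopifnot(is(x, "FeatureTable"))
  x@values
}

#' @describeIn FeatureTable-class subset rows/columns, keeping the class
#' @param i,j,...,drop row/column indices (drop is ignored)
#' @export
setMethod("[", "FeatureTable", function(x, i, j, ..., drop = FALSE) {
  v <- x@values
  if (!missing(i)) v <- v[i, , drop = FALSE]
  if (!missing(j)) v <- v[, j, drop = FALSE]
  FeatureTable(v)
})

setMethod("show", "FeatureTable", function(object) {
  cat("FeatureTable:", nrow(object@values), "sequences x",
      ncol(object@values), "features\n")
  fn <- colnames(object@values)
  cat("  features:", paste(head(fn, 4), collapse = ", "),
      if (length(fn) > 4) "..." else "", "\n")
})

#' Write a FeatureTable to CSV
#'
#' First column `id`, then the feature columns in canonical order.
#'
#' @param x a FeatureTable
#' @param file path of the CSV to write
#' @export
writeFeatureCSV <- function(x, file) {
  stopifnot(is(x, "FeatureTable"))
  df <- data.frame(id = rownames(x@values), x@values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(df, file, row.names = FALSE)
}

#' ClusterResult: greedy identity clustering outcome
#'
#' @slot threshold identity threshold in (0, 1].
#' @slot clusters named list; names are representative ids, elements are
#'   character vectors of member ids (representative included).
#' @slot retained `AAStringSet` of cluster representatives.
#' @exportClass ClusterResult
setClass("ClusterResult", representation(
  threshold = "numeric", clusters = "list", retained = "ANY"))

setValidity("ClusterResult", function(object) {
  if (length(object@threshold) != 1 || object@threshold <= 0 ||
      object@threshold > 1)
    return("threshold must be a single value in (0, 1]")
  members <- unlist(object@clusters, use.names = FALSE)
  if (anyDuplicated(members))
    return("each id must appear in exactly one cluster")
  TRUE
})

setMethod("show", "ClusterResult", function(object) {
  cat("ClusterResult: threshold", object@threshold, "-",
      length(unlist(object@clusters)), "sequences in",
      length(object@clusters), "clusters\n")
})

#' Representatives retained after clustering
#' @param x a ClusterResult
#' @return `AAStringSet` of representatives (one per cluster).
#' @export
retainedSequences <- function(x) {
  stopifnot(is(x, "ClusterResult"))
  x@retained
}

#' Cluster membership table
#' @param x a ClusterResult
#' @return data.frame with columns `member_id`, `representative_id`.
#' @export
clusterMembers <- function(x) {
  stopifnot(is(x, "ClusterResult"))
  data.frame(
    member_id = unlist(x@clusters, use.names = FALSE),
    representative_id = rep(names(x@clusters),
                            lengths(x@clusters)),
    stringsAsFactors = FALSE)
}

#' PruneResult: correlation-based feature pruning outcome
#'
#' @slot kept character, features retained (input order).
#' @slot removed character, features removed (removal order).
#' @slot cutoff the absolute Pearson correlation cutoff used.
#' @slot meanAbsCor named numeric, mean absolute correlation of every input
#'   feature against all other input features.
#' @exportClass PruneResult
setClass("PruneResult", representation(
  kept = "character", removed = "character", cutoff = "numeric",
  meanAbsCor = "numeric"))

setValidity("PruneResult", function(object) {
  if (length(intersect(object@kept, object@removed)) > 0)
    return("kept and removed must be disjoint")
  TRUE
})

setMethod("show", "PruneResult", function(object) {
  cat("PruneResult: cutoff", object@cutoff, "-", length(object@kept),
      "kept,", length(object@removed), "removed\n")
})

#' Features kept after pruning
#' @param x a PruneResult
#' @export
keptFeatures <- function(x) {
  stopifnot(is(x, "PruneResult")); x@kept
}

#' Features removed by pruning
#' @param x a PruneResult
#' @export
removedFeatures <- function(x) {
  stopifnot(is(x, "PruneResult")); x@removed
}

#' Write a PruneResult to CSV
#' @param x a PruneResult
#' @param file path of the CSV to write
#' @export
writePruneCSV <- function(x, file) {
  stopifnot(is(x, "PruneResult"))
  feats <- c(x@kept, x@removed)
  df <- data.frame(
    feature = feats,
    status = rep(c("kept", "removed"),
                 c(length(x@kept), length(x@removed))),
    mean_abs_cor = unname(x@meanAbsCor[feats]),
    stringsAsFactors = FALSE)
  write.csv(df, file, row.names = FALSE)
}

#' TreeModel: induced gain-ratio decision tree
#'
#' Internal nodes carry a feature name and a numeric threshold (values
#' `<=` threshold are routed to the left child); leaves carry per-class
#' counts and the majority class.
#'
#' @slot root recursive list of nodes.
#' @slot params list with `minLeaf`, `cf` (pruning confidence), `criterion`.
#' @slot features character, feature names seen at fit time.
#' @slot classes character, the two class labels (level order).
#' @exportClass TreeModel
setClass("TreeModel", representation(
  root = "list", params = "list", features = "character",
  classes = "character"))

setMethod("show", "TreeModel", function(object) {
  cat("TreeModel (gain-ratio decision tree)\n")
  cat("  classes:", paste(object@classes, collapse = " / "), "\n")
  cat("  leaves:", countLeaves(object), " features used:",
      length(usedFeatures(object)), "\n")
  cat(formatTree(object), sep = "\n")
})

#' PerformanceReport: benchmark metrics over iterations
#'
#' @slot surfaces data.frame of aggregated metrics: columns `surface`
#'   (train / cv / external), `metric` (Ac, Sn, Sp, MCC), `mean`, `sd`.
#' @slot perIteration data.frame of per-iteration metrics (columns
#'   `iteration`, `surface`, `Ac`, `Sn`, `Sp`, `MCC`).
#' @slot nIterations number of split iterations aggregated.
#' @exportClass PerformanceReport
setClass("PerformanceReport", representation(
  surfaces = "data.frame", perIteration = "data.frame",
  nIterations = "integer"))

setMethod("show", "PerformanceReport", function(object) {
  cat("PerformanceReport over", object@nIterations, "iterations\n")
  print(reportTable(object), row.names = FALSE)
})

#' Aggregated metrics of a PerformanceReport
#' @param x a PerformanceReport
#' @return data.frame with columns surface, metric, mean, sd.
#' @export
reportMetrics <- function(x) {
  stopifnot(is(x, "PerformanceReport")); x@surfaces
}

#' Format a PerformanceReport as a mean +/- SD table
#'
#' One row per evaluation surface (train, tenfold CV, external), one
#' column per statistic, each cell "mean +/- SD".
#'
#' @param x a PerformanceReport
#' @return data.frame of formatted strings.
#' @export
reportTable <- function(x) {
  stopifnot(is(x, "PerformanceReport"))
  s <- x@surfaces
  surf <- unique(s$surface)
  out <- data.frame(surface = surf, stringsAsFactors = FALSE)
  for (m in unique(s$metric)) {
    sub <- s[s$metric == m, ]
    digits <- if (m == "MCC") 2 else 2
    out[[m]] <- vapply(surf, function(sf) {
      r <- sub[sub$surface == sf, ]
      sprintf("%.2f ± %.2f", r$mean, r$sd)
    }, character(1))
  }
  out
}
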
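# C4.5-style decision tree: binary numeric splits chosen by gain ratio
# (plain information gain behind a flag), recursive growth, then
# pessimistic-error pruning at a configurable confidence. All features
# are numeric; values <= threshold are routed left.

.entropy2 <- function(c1, n) {
  # binary entropy from class-1 count and total, vectorized, 0 log 0 = 0
  p <- c1 / n
  q <- 1 - p
  t1 <- ifelse(p > 0, -p * log2(p), 0)
  t2 <- ifelse(q > 0, -q * log2(q), 0)
  t1 + t2
}

#' Decision-tree parameters
#'
#' Defaults mirror the documented J48/C4.5 defaults: minimum 2 instances
#' per leaf, pruning confidence 0.25, gain-ratio splitting.
#'
#' @param minLeaf minimum instances per leaf.
#' @param cf pruning confidence in (0, 0.5]; `NA` disables pruning.
#' @param criterion `"gain_ratio"` (C4.5) or `"info_gain"`.
#' @return list of validated parameters.
#' @export
treeParams <- function(minLeaf = 2L, cf = 0.25,
                       criterion = c("gain_ratio", "info_gain")) {
  criterion <- match.arg(criterion)
  stopifnot(minLeaf >= 1, is.na(cf) || (cf > 0 && cf <= 0.5))
  list(minLeaf = as.integer(minLeaf), cf = cf, criterion = criterion)
}

# best (feature, threshold) over all features; candidate thresholds are
# midpoints between sorted distinct values; children must have >= minLeaf
# rows. Splits with positive information gain are preferred; when none
# exists at an impure node, a zero-gain split is still taken (first
# feature, lowest threshold) so that layouts like XOR, where every single
# split is individually uninformative, remain learnable -- recursion
# terminates because both children shrink, and pessimistic pruning later
# collapses subtrees that never pay off.
.bestSplit <- function(X, y, minLeaf, criterion) {
  n <- length(y)
  c1 <- sum(y == 1L)
  H0 <- .entropy2(c1, n)
  best <- NULL
  fallback <- NULL
  for (f in seq_len(ncol(X))) {
    x <- X[, f]
    ord <- order(x)
    xs <- x[ord]
    is1 <- as.numeric(y[ord] == 1L)
    cum1 <- cumsum(is1)
    t <- which(xs[-n] < xs[-1])          # split after position t
    t <- t[t >= minLeaf & (n - t) >= minLeaf]
    if (!length(t)) next
    if (is.null(fallback))
      fallback <- list(feature = colnames(X)[f],
                       threshold = (xs[t[1]] + xs[t[1] + 1]) / 2,
                       score = 0, gain = 0)
    nl <- t; nr <- n - t
    gain <- H0 - (nl * .entropy2(cum1[t], nl) +
                    nr * .entropy2(c1 - cum1[t], nr)) / n
    ok <- gain > 1e-12
    if (!any(ok)) next
    score <- if (criterion == "gain_ratio") {
      si <- .entropy2(nl, n)             # split information
      ifelse(ok, gain / si, -Inf)
    } else ifelse(ok, gain, -Inf)
    k <- which.max(score)                # lowest threshold on ties
    if (is.null(best) || score[k] > best$score + 1e-12) {
      best <- list(feature = colnames(X)[f],
                   threshold = (xs[t[k]] + xs[t[k] + 1]) / 2,
                   score = score[k], gain = gain[k])
    }
  }
  if (is.null(best)) fallback else best
}

.growTree <- function(X, y, idx, minLeaf, criterion) {
  counts <- tabulate(y[idx], 2L)
  leaf <- list(leaf = TRUE, counts = counts,
               pred = which.max(counts))   # ties -> first class level
  if (min(counts) == 0L || length(idx) < 2L * minLeaf) return(leaf)
  best <- .bestSplit(X[idx, , drop = FALSE], y[idx], minLeaf, criterion)
  if (is.null(best)) return(leaf)
  goLeft <- X[idx, best$feature] <= best$threshold
  list(leaf = FALSE, feature = best$feature, threshold = best$threshold,
       counts = counts,
       left = .growTree(X, y, idx[goLeft], minLeaf, criterion),
       right = .growTree(X, y, idx[!goLeft], minLeaf, criterion))
}

# C4.5 pessimistic (upper-confidence-bound) error estimate: exact
# binomial upper bound on the error rate of e errors in n instances
.ucfError <- function(e, n, cf) {
  if (n == 0) return(0)
  if (e >= n) return(n)
  n * stats::qbeta(1 - cf, e + 1, n - e)
}

.subtreeError <- function(node, cf) {
  if (node$leaf)
    return(.ucfError(sum(node$counts) - max(node$counts),
                     sum(node$counts), cf))
  .subtreeError(node$left, cf) + .subtreeError(node$right, cf)
}

.pruneNode <- function(node, cf) {
  if (node$leaf) return(node)
  node$left <- .pruneNode(node$left, cf)
  node$right <- .pruneNode(node$right, cf)
  n <- sum(node$counts)
  leafErr <- .ucfError(n - max(node$counts), n, cf)
  if (leafErr <= .subtreeError(node, cf) + 1e-9)
    return(list(leaf = TRUE, counts = node$counts,
                pred = which.max(node$counts)))
  node
}

#' Fit a gain-ratio decision tree
#'
#' Recursive growth choosing, at each node, the binary numeric split
#' maximizing the gain ratio (or information gain) over candidate
#' thresholds at midpoints between sorted distinct values; growth stops
#' on pure nodes, nodes smaller than `2 * minLeaf`, or when no split has
#' positive gain. The grown tree is then pruned by pessimistic-error
#' estimation at confidence `cf`.
#'
#' @param x a [FeatureTable-class] (or numeric matrix with dimnames).
#' @param labels factor of class labels aligned with the rows of `x`
#'   (two levels; single-class input yields a single leaf).
#' @param params a [treeParams()] list.
#' @return A [TreeModel-class].
#' @export
fitTree <- function(x, labels, params = treeParams()) {
  X <- if (is(x, "FeatureTable")) featureMatrix(x) else x
  if (!is.numeric(X)) stop("feature values must be numeric", call. = FALSE)
  if (nrow(X) == 0) stop("empty feature table", call. = FALSE)
  labels <- as.factor(labels)
  if (nlevels(labels) > 2) stop("binary classification only", call. = FALSE)
  if (length(labels) != nrow(X))
    stop("labels must align with feature rows", call. = FALSE)
  y <- as.integer(labels)
  root <- .growTree(X, y, seq_len(nrow(X)), params$minLeaf,
                    params$criterion)
  if (!is.na(params$cf)) root <- .pruneNode(root, params$cf)
  new("TreeModel", root = root, params = params,
      features = colnames(X), classes = levels(labels))
}

#' @describeIn fitTree predict class labels for new rows; values exactly
#'   at a node threshold are routed left (`<=` convention). Errors if a
#'   model feature is absent from the table.
#' @param object a [TreeModel-class]
#' @param newdata a [FeatureTable-class] or numeric matrix containing
#'   every feature the model uses
#' @param ... unused
#' @export
setMethod("predict", "TreeModel", function(object, newdata, ...) {
  X <- if (is(newdata, "FeatureTable")) featureMatrix(newdata) else newdata
  need <- usedFeatures(object)
  missing <- setdiff(need, colnames(X))
  if (length(missing))
    stop("feature(s) missing from table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  out <- integer(nrow(X))
  for (r in seq_len(nrow(X))) {
    node <- object@root
    while (!node$leaf) {
      node <- if (X[r, node$feature] <= node$threshold) node$left
      else node$right
    }
    out[r] <- node$pred
  }
  factor(object@classes[out], levels = object@classes) |>
    stats::setNames(rownames(X))
})

#' Features used by a fitted tree
#' @param model a [TreeModel-class]
#' @return character vector of feature names appearing at internal nodes.
#' @export
usedFeatures <- function(model) {
  walk <- function(node) {
    if (node$leaf) return(character(0))
    c(node$feature, walk(node$left), walk(node$right))
  }
  unique(walk(model@root))
}

#' Number of leaves of a fitted tree
#' @param model a [TreeModel-class]
#' @export
countLeaves <- function(model) {
  walk <- function(node) {
    if (node$leaf) return(1L)
    walk(node$left) + walk(node$right)
  }
  walk(model@root)
}

#' Render a fitted tree as indented rules
#' @param model a [TreeModel-class]
#' @return character vector, one line per rule/leaf.
#' @export
formatTree <- function(model) {
  cl <- model@classes
  walk <- function(node, indent) {
    pad <- strrep("  ", indent)
    if (node$leaf)
      return(sprintf("%s-> %s (%s)", pad, cl[node$pred],
                     paste(node$counts, collapse = "/")))
    c(sprintf("%s%s <= %.6g", pad, node$feature, node$threshold),
      walk(node$left, indent + 1),
      sprintf("%s%s > %.6g", pad, node$feature, node$threshold),
      walk(node$right, indent + 1))
  }
  walk(model@root, 0)
}

#' Convert a fitted tree to a plain list (JSON-ready)
#' @param model a [TreeModel-class]
#' @return nested list mirroring the tree structure.
#' @export
treeToList <- function(model) {
  cl <- model@classes
  walk <- function(node) {
    if (node$leaf)
      return(list(leaf = TRUE, class = cl[node$pred],
                  counts = as.list(stats::setNames(node$counts, cl))))
    list(leaf = FALSE, feature = node$feature,
         threshold = node$threshold,
         left = walk(node$left), right = walk(node$right))
  }
  walk(model@root)
}

#' Feature usage across benchmark iterations
#'
#' For every feature appearing in any model: the percentage of models
#' (iterations) whose induced tree uses it. The mean and SD are computed
#' over up to `nBlocks` contiguous blocks of iterations.
#'
#' @param models list of [TreeModel-class] objects (one per iteration).
#' @param nBlocks number of iteration blocks for the mean/SD.
#' @return data.frame with columns `feature`, `usage`, `mean`, `sd`,
#'   sorted by decreasing usage (ties alphabetically).
#' @export
featureUsage <- function(models, nBlocks = 10L) {
  stopifnot(length(models) >= 1)
  used <- lapply(models, usedFeatures)
  feats <- sort(unique(unlist(used)))
  pres <- vapply(used, function(u) feats %in% u,
                 logical(length(feats)))
  pres <- matrix(pres, nrow = length(feats))
  usage <- 100 * rowMeans(pres)
  nb <- min(nBlocks, length(models))
  blk <- split(seq_along(models),
               ceiling(seq_along(models) * nb / length(models)))
  perBlock <- vapply(blk, function(ix)
    100 * rowMeans(pres[, ix, drop = FALSE]), numeric(length(feats)))
  perBlock <- matrix(perBlock, nrow = length(feats))
  mu <- rowMeans(perBlock)
  sdv <- if (nb > 1) apply(perBlock, 1, stats::sd) else rep(0, length(feats))
  df <- data.frame(feature = feats, usage = usage, mean = mu, sd = sdv,
                   stringsAsFactors = FALSE)
  df[order(-df$usage, df$feature), , drop = FALSE] |>
    `rownames<-`(NULL)
}

#' Top-k features by usage
#'
#' @param usage data.frame from [featureUsage()].
#' @param k number of features to return; ties at the k-th rank are
#'   broken alphabetically. If `k` exceeds the number of available
#'   features, all are returned with a warning.
#' @return character vector of feature names.
#' @export
topFeatures <- function(usage, k = 20L) {
  stopifnot(k >= 1)
  if (k > nrow(usage)) {
    warning("k exceeds available features; returning all", call. = FALSE)
    k <- nrow(usage)
  }
  usage <- usage[order(-usage$usage, usage$feature), , drop = FALSE]
  usage$feature[seq_len(k)]
}

#' Write a feature-usage table to CSV
#' @param usage data.frame from [featureUsage()]
#' @param file output path
#' @export
writeUsageCSV <- function(usage, file) {
  write.csv(usage, file, row.names = FALSE)
}
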
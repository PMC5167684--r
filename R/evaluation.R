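# Statistical assessment: accuracy, sensitivity, specificity and the
# Matthews correlation coefficient from pooled confusion counts, under a
# repeated stratified 80/20 split protocol with tenfold cross-validation
# on the internal (80%) set.

#' Confusion counts from truth and prediction
#'
#' @param truth,pred factors with identical levels.
#' @param positive the positive class (default `"monomer"`).
#' @return named numeric vector `c(TP, TN, FP, FN)`.
#' @export
confusionCounts <- function(truth, pred, positive = "monomer") {
  truth <- as.character(truth); pred <- as.character(pred)
  stopifnot(length(truth) == length(pred))
  c(TP = sum(truth == positive & pred == positive),
    TN = sum(truth != positive & pred != positive),
    FP = sum(truth != positive & pred == positive),
    FN = sum(truth == positive & pred != positive))
}

#' Classification metrics from confusion counts
#'
#' Accuracy, sensitivity and specificity as percentages and the Matthews
#' correlation coefficient. An MCC denominator of zero (all predictions
#' in one class, or a single-class truth) yields MCC = 0, the
#' random-prediction convention.
#'
#' @param counts named vector with elements `TP`, `TN`, `FP`, `FN`
#'   (as from [confusionCounts()]), or the four counts as separate
#'   arguments via `...`.
#' @param ... alternatively `TP`, `TN`, `FP`, `FN` given individually.
#' @return named numeric vector `c(Ac, Sn, Sp, MCC)`.
#' @examples
#' classMetrics(c(TP = 3, TN = 2, FP = 1, FN = 1))
#' @export
classMetrics <- function(counts = NULL, ...) {
  if (is.null(counts)) counts <- c(...)
  tp <- counts[["TP"]]; tn <- counts[["TN"]]
  fp <- counts[["FP"]]; fn <- counts[["FN"]]
  n <- tp + tn + fp + fn
  if (n == 0) stop("no evaluated instances", call. = FALSE)
  ac <- (tp + tn) / n * 100
  sn <- if (tp + fn > 0) tp / (tp + fn) * 100 else NA_real_
  sp <- if (tn + fp > 0) tn / (tn + fp) * 100 else NA_real_
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (den == 0) 0 else (tp * tn - fp * fn) / den
  c(Ac = ac, Sn = sn, Sp = sp, MCC = mcc)
}

#' Stratified 80/20 split
#'
#' Randomly partitions labelled records into an internal (80%) and an
#' external (20%) set, stratified by class with largest-remainder
#' rounding of the per-class external counts. Reproducible by seed.
#'
#' @param labels named factor of class labels.
#' @param seed integer seed.
#' @param externalFraction fraction assigned to the external set.
#' @return list with character vectors `internal` and `external` of ids.
#' @export
splitTrainExternal <- function(labels, seed, externalFraction = 0.2) {
  stopifnot(!is.null(names(labels)))
  if (length(labels) < 5) stop("need at least 5 records", call. = FALSE)
  tab <- table(labels)
  if (any(tab < 2))
    stop("every class needs at least 2 members", call. = FALSE)
  target <- length(labels) * externalFraction
  exact <- as.numeric(tab) * externalFraction
  nExt <- floor(exact)
  rem <- round(target) - sum(nExt)
  if (rem > 0) {
    ord <- order(-(exact - floor(exact)), names(tab))
    nExt[ord[seq_len(rem)]] <- nExt[ord[seq_len(rem)]] + 1
  }
  names(nExt) <- names(tab)
  set.seed(seed)
  external <- character(0)
  for (cl in names(tab)) {
    ids <- names(labels)[labels == cl]
    external <- c(external, sample(ids, nExt[[cl]]))
  }
  list(internal = setdiff(names(labels), external), external = external)
}

# stratified fold assignment: per-class shuffled ids are concatenated and
# folds assigned cyclically, so per-class and total fold sizes differ by
# at most one
.stratifiedFolds <- function(labels, k, seed) {
  set.seed(seed)
  ids <- character(0)
  for (cl in levels(labels))
    ids <- c(ids, sample(names(labels)[labels == cl]))
  stats::setNames(rep(seq_len(k), length.out = length(ids)), ids)
}

#' Stratified tenfold cross-validation
#'
#' Splits the internal set into `k` stratified folds (sizes differing by
#' at most one); fits a tree on each k-1 folds and predicts the held-out
#' fold; confusion counts are pooled over folds before metrics are
#' computed.
#'
#' @param x a [FeatureTable-class] covering the internal set.
#' @param labels named factor aligned with the rows of `x`.
#' @param k number of folds (default 10; requires at least `k` records).
#' @param params a [treeParams()] list.
#' @param seed integer seed for fold assignment.
#' @param positive positive class for the confusion counts.
#' @return list with `counts` (pooled confusion counts) and `metrics`.
#' @export
crossValidate <- function(x, labels, k = 10L, params = treeParams(),
                          seed = 1L, positive = "monomer") {
  ids <- sequenceIds(x)
  stopifnot(identical(sort(ids), sort(names(labels))))
  if (length(ids) < k)
    stop(sprintf("need at least %d records for %d-fold CV", k, k),
         call. = FALSE)
  labels <- labels[ids]
  folds <- .stratifiedFolds(labels, k, seed)[ids]
  counts <- c(TP = 0, TN = 0, FP = 0, FN = 0)
  for (fold in seq_len(k)) {
    hold <- ids[folds == fold]
    train <- ids[folds != fold]
    if (!length(hold)) next
    model <- fitTree(x[train, ], droplevels(labels[train]), params)
    pred <- predict(model, x[hold, ])
    counts <- counts + confusionCounts(labels[hold], pred, positive)
  }
  list(counts = counts, metrics = classMetrics(counts))
}

#' Benchmark a descriptor class over repeated splits
#'
#' The repeated-split protocol: for each iteration, a stratified 80/20
#' internal/external split; optional correlation pruning (computed on the
#' internal set only, or on all records with `pruneScope = "all"`); a
#' tree fitted on the full internal set (train surface), stratified
#' tenfold CV on the internal set (cv surface), and prediction of the
#' held-out external set (external surface). Metrics are aggregated as
#' mean and SD over iterations; the per-iteration models feed the
#' feature-usage score.
#'
#' @param x named `AAStringSet` of sequences (already homology-reduced if
#'   desired), or a precomputed [FeatureTable-class].
#' @param labels named factor of class labels covering the sequences.
#' @param class descriptor class (see [computeDescriptors()]); ignored
#'   when `x` is already a FeatureTable or `features` is given.
#' @param features optional selected feature names (production mode);
#'   computed via [computeSelectedFeatures()].
#' @param nIterations number of split iterations (reference protocol: 100).
#' @param seed master seed; iteration i uses seed + i.
#' @param prune logical, apply correlation pruning per iteration.
#' @param cutoff correlation cutoff for pruning.
#' @param pruneScope `"internal"` (leakage-safe default) or `"all"`.
#' @param params a [treeParams()] list.
#' @param config a [descriptorConfig()].
#' @param cvFolds folds for the CV surface.
#' @param positive positive class (default `"monomer"`).
#' @return list with `report` (a [PerformanceReport-class]), `usage`
#'   (a [featureUsage()] data.frame) and `models`.
#' @export
benchmarkDescriptors <- function(x, labels, class = "aac_dpc_tpc",
                                 features = NULL, nIterations = 100L,
                                 seed = 1L, prune = TRUE, cutoff = 0.7,
                                 pruneScope = c("internal", "all"),
                                 params = treeParams(),
                                 config = descriptorConfig(),
                                 cvFolds = 10L, positive = "monomer") {
  pruneScope <- match.arg(pruneScope)
  ft <- if (is(x, "FeatureTable")) x
  else if (!is.null(features)) computeSelectedFeatures(x, features, config)
  else computeDescriptors(x, class, config)
  ids <- sequenceIds(ft)
  stopifnot(all(ids %in% names(labels)))
  labels <- labels[ids]

  if (prune && pruneScope == "all")
    ft <- ft[, keptFeatures(pruneCorrelated(ft, cutoff))]

  surfaces <- c("train", "cv", "external")
  rows <- vector("list", nIterations * 3)
  models <- vector("list", nIterations)
  for (i in seq_len(nIterations)) {
    iterSeed <- seed + i
    res <- tryCatch({
      sp <- splitTrainExternal(labels, iterSeed)
      fti <- ft[sp$internal, ]
      if (prune && pruneScope == "internal")
        fti <- fti[, keptFeatures(pruneCorrelated(fti, cutoff))]
      model <- fitTree(fti, labels[sp$internal], params)
      trainM <- classMetrics(confusionCounts(
        labels[sp$internal], predict(model, fti), positive))
      cvM <- crossValidate(fti, labels[sp$internal], k = cvFolds,
                           params = params, seed = iterSeed,
                           positive = positive)$metrics
      fte <- ft[sp$external, featureNames(fti)]
      extM <- classMetrics(confusionCounts(
        labels[sp$external], predict(model, fte), positive))
      list(model = model, m = list(train = trainM, cv = cvM,
                                   external = extM))
    }, error = function(e)
      stop(sprintf("iteration %d failed: %s", i, conditionMessage(e)),
           call. = FALSE))
    models[[i]] <- res$model
    for (sfi in seq_along(surfaces))
      rows[[(i - 1) * 3 + sfi]] <- data.frame(
        iteration = i, surface = surfaces[[sfi]],
        t(res$m[[surfaces[[sfi]]]]))
  }
  perIter <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(surfaces, function(sf) {
    sub <- perIter[perIter$surface == sf, c("Ac", "Sn", "Sp", "MCC")]
    data.frame(surface = sf, metric = c("Ac", "Sn", "Sp", "MCC"),
               mean = colMeans(sub),
               sd = if (nIterations > 1) apply(sub, 2, stats::sd)
               else rep(0, 4))
  }))
  rownames(agg) <- NULL
  report <- new("PerformanceReport", surfaces = agg,
                perIteration = perIter,
                nIterations = as.integer(nIterations))
  list(report = report, usage = featureUsage(models), models = models)
}

#' Write a PerformanceReport to CSV
#'
#' Layout mirrors the benchmark tables: one row per evaluation surface,
#' columns Ac/Sn/Sp/MCC formatted "mean +/- SD".
#'
#' @param x a [PerformanceReport-class]
#' @param file output path
#' @export
writeReportCSV <- function(x, file) {
  write.csv(reportTable(x), file, row.names = FALSE)
}
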
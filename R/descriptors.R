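# Six descriptor classes computed from a protein sequence:
#   aac_dpc_tpc  20 + 400 + 8000 = 8420 overlapping k-mer frequencies
#   ac           3 kinds x 8 scales x 30 lags = 720 autocorrelations
#   ctd          7 properties x (3 C + 3 T + 15 D) = 147
#   ctriad       7^3 = 343 conjoint triads
#   qso          60 sequence-order-coupling numbers + 100 QSO = 160
#   pseaac       50 PseAAC + 80 amphiphilic PseAAC = 130

.seqChars <- function(x) {
  s <- as.character(x)
  if (length(s) != 1) stop("expected a single sequence")
  strsplit(s, "")[[1]]
}

.kmerLevels <- function(k) {
  key <- paste0("kmer", k)
  if (!is.null(.oligoFPcache[[key]])) return(.oligoFPcache[[key]])
  lev <- AA20
  if (k >= 2) for (i in 2:k) lev <- paste0(rep(lev, each = 20), AA20)
  .oligoFPcache[[key]] <- lev
  lev
}

.checkLen <- function(n, need, what) {
  if (n < need)
    stop(sprintf("sequence too short for %s (length %d, need >= %d)",
                 what, n, need), call. = FALSE)
}

#' Amino acid composition (20 features)
#'
#' Frequency of each residue, `N_r / N`; components sum to 1.
#'
#' @param x a single protein sequence (character or `AAString`).
#' @return named numeric 20-vector (`AAC.A` .. `AAC.Y`).
#' @export
computeAAC <- function(x) {
  s <- .seqChars(x)
  .checkLen(length(s), 1, "amino acid composition")
  v <- table(factor(s, levels = AA20)) / length(s)
  stats::setNames(as.numeric(v), paste0("AAC.", AA20))
}

#' Dipeptide composition (400 features)
#'
#' Overlapping dipeptide frequencies, `N_rs / (N - 1)`; components sum
#' to 1.
#'
#' @inheritParams computeAAC
#' @return named numeric 400-vector (`DPC.AA` ..).
#' @export
computeDPC <- function(x) {
  s <- .seqChars(x)
  .checkLen(length(s), 2, "dipeptides")
  n <- length(s)
  di <- paste0(s[-n], s[-1])
  v <- table(factor(di, levels = .kmerLevels(2))) / (n - 1)
  stats::setNames(as.numeric(v), paste0("DPC.", .kmerLevels(2)))
}

#' Tripeptide composition (8000 features)
#'
#' Overlapping tripeptide frequencies, `N_rst / (N - 2)`; components sum
#' to 1.
#'
#' @inheritParams computeAAC
#' @return named numeric 8000-vector (`TPC.AAA` ..).
#' @export
computeTPC <- function(x) {
  s <- .seqChars(x)
  .checkLen(length(s), 3, "tripeptides")
  n <- length(s)
  tri <- paste0(s[1:(n - 2)], s[2:(n - 1)], s[3:n])
  v <- table(factor(tri, levels = .kmerLevels(3))) / (n - 2)
  stats::setNames(as.numeric(v), paste0("TPC.", .kmerLevels(3)))
}

# One autocorrelation value from a numeric property profile.
# moreau_broto: sum(P_i P_{i+d}) / (N - d)      (normalized form)
# moran:  [sum (P_i - Pbar)(P_{i+d} - Pbar)/(N-d)] / [sum (P_i - Pbar)^2 / N]
# geary:  [sum (P_i - P_{i+d})^2 / (2(N-d))] / [sum (P_i - Pbar)^2 / (N-1)]
# moran/geary with a zero-variance profile return 0 by convention.
.autocorr <- function(p, d, kind) {
  n <- length(p)
  i <- seq_len(n - d)
  if (kind == "moreau_broto")
    return(sum(p[i] * p[i + d]) / (n - d))
  dev <- p - mean(p)
  ss <- sum(dev^2)
  if (ss == 0) return(0)
  if (kind == "moran")
    sum(dev[i] * dev[i + d]) / (n - d) / (ss / n)
  else
    sum((p[i] - p[i + d])^2) / (2 * (n - d)) / (ss / (n - 1))
}

#' Autocorrelation descriptors for one kind (240 features)
#'
#' Lagged autocorrelation of standardized physicochemical property
#' profiles along the sequence, for each of 8 AAindex scales and lags
#' `1..lag`. Moran and Geary values for a zero-variance profile (e.g. a
#' homopolymer) are 0 by convention, with a warning.
#'
#' @inheritParams computeAAC
#' @param kind one of `"moreau_broto"`, `"moran"`, `"geary"`.
#' @param scales list of property scales as from [propertyScales()].
#' @param lag maximum lag (must be < sequence length).
#' @return named numeric vector of `8 * lag` values
#'   (`AC.<kind>.<accession>.<d>`).
#' @export
computeAutocorrelation <- function(x, kind = c("moreau_broto", "moran",
                                               "geary"),
                                   scales = propertyScales(), lag = 30L) {
  kind <- match.arg(kind)
  s <- .seqChars(x)
  n <- length(s)
  if (lag >= n)
    stop(sprintf("lag (%d) exceeds sequence length (%d)", lag, n),
         call. = FALSE)
  tag <- c(moreau_broto = "MB", moran = "Moran", geary = "Geary")[[kind]]
  out <- numeric(0)
  warned <- FALSE
  for (sc in scales) {
    p <- unname(sc$z[s])
    if (kind != "moreau_broto" && sum((p - mean(p))^2) == 0 && !warned) {
      warning("zero property variance along sequence; ",
              "Moran/Geary values set to 0", call. = FALSE)
      warned <- TRUE
    }
    v <- vapply(seq_len(lag), function(d) .autocorr(p, d, kind), numeric(1))
    names(v) <- paste0("AC.", tag, ".", sc$id, ".", seq_len(lag))
    out <- c(out, v)
  }
  out
}

#' Composition/transition/distribution descriptors (147 features)
#'
#' For each of seven physicochemical properties the residues are encoded
#' into three groups; the descriptor reports per property the three group
#' compositions `n_r / N`, the three unordered transition frequencies
#' `(n_rs + n_sr) / (N - 1)`, and fifteen distribution values: the
#' positions (percent of N) of the first, 25, 50, 75 and 100 percent
#' occurrence of each group, using the ceiling(q * n_r) occurrence index.
#' A group absent from the sequence contributes five zeros.
#'
#' @inheritParams computeAAC
#' @return named numeric 147-vector.
#' @export
computeCTD <- function(x) {
  s <- .seqChars(x)
  n <- length(s)
  .checkLen(n, 2, "CTD")
  groups <- ctdGroups()
  qs <- c(first = 0, `25` = 0.25, `50` = 0.5, `75` = 0.75, `100` = 1)
  out <- numeric(0)
  for (p in names(groups)) {
    g <- unname(groups[[p]][s])
    comp <- tabulate(g, 3) / n
    names(comp) <- paste0("CTD.C.", p, ".", 1:3)
    pair <- paste0(pmin(g[-n], g[-1]), pmax(g[-n], g[-1]))
    tr <- vapply(c("12", "13", "23"),
                 function(rs) sum(pair == rs), numeric(1)) / (n - 1)
    names(tr) <- paste0("CTD.T.", p, ".", c("12", "13", "23"))
    dist <- numeric(0)
    for (grp in 1:3) {
      pos <- which(g == grp)
      v <- if (length(pos) == 0) rep(0, 5) else {
        idx <- pmax(1L, ceiling(qs * length(pos)))
        pos[idx] / n * 100
      }
      names(v) <- paste0("CTD.D.", p, ".", grp, ".", names(qs))
      dist <- c(dist, v)
    }
    out <- c(out, comp, tr, dist)
  }
  out
}

#' Conjoint triad descriptors (343 features)
#'
#' Residues are mapped to seven side-chain dipole/volume classes; the
#' counts of all 7^3 class triads over sliding windows of length 3 are
#' max-normalized within the sequence (count / max count).
#'
#' @inheritParams computeAAC
#' @return named numeric 343-vector (`CTriad.111` .. `CTriad.777`).
#' @export
computeCTriad <- function(x) {
  s <- .seqChars(x)
  n <- length(s)
  .checkLen(n, 3, "conjoint triads")
  cl <- unname(triadClasses()[s])
  tri <- paste0(cl[1:(n - 2)], cl[2:(n - 1)], cl[3:n])
  lev <- paste0(rep(1:7, each = 49), rep(rep(1:7, each = 7), 7),
                rep(1:7, 49))
  cnt <- table(factor(tri, levels = lev))
  v <- as.numeric(cnt) / max(cnt)
  stats::setNames(v, paste0("CTriad.", lev))
}

#' Quasi-sequence-order descriptors (160 features)
#'
#' For each of two residue distance matrices (see
#' [qsoDistanceMatrices()]): sequence-order-coupling numbers
#' `tau_d = sum_i d(R_i, R_{i+d})^2` for `d = 1..lag` (60 values), then
#' quasi-sequence-order values: 20 composition components
#' `f_r / (sum f + w sum tau)` and `lag` coupling components
#' `w tau_d / (sum f + w sum tau)` per matrix (100 values).
#'
#' @inheritParams computeAAC
#' @param lag maximum lag (must be < sequence length).
#' @param w weighting factor for the coupling terms.
#' @param matrices named list of 20 x 20 residue distance matrices.
#' @return named numeric vector of `2*lag + 2*(20 + lag)` values
#'   (160 at the default `lag = 30`).
#' @export
computeQSO <- function(x, lag = 30L, w = 0.5,
                       matrices = qsoDistanceMatrices()) {
  s <- .seqChars(x)
  n <- length(s)
  if (lag >= n)
    stop(sprintf("lag (%d) exceeds sequence length (%d)", lag, n),
         call. = FALSE)
  f <- as.numeric(table(factor(s, levels = AA20)))
  taus <- lapply(matrices, function(m) {
    vapply(seq_len(lag), function(d) {
      i <- seq_len(n - d)
      sum(m[cbind(s[i], s[i + d])]^2)
    }, numeric(1))
  })
  socn <- unlist(lapply(names(taus), function(nm)
    stats::setNames(taus[[nm]], paste0("SOCN.", nm, ".", seq_len(lag)))))
  qso <- unlist(lapply(names(taus), function(nm) {
    denom <- sum(f) + w * sum(taus[[nm]])
    c(stats::setNames(f / denom, paste0("QSO.", nm, ".", AA20)),
      stats::setNames(w * taus[[nm]] / denom,
                      paste0("QSO.", nm, ".tau.", seq_len(lag))))
  }))
  c(socn, qso)
}

# sequence-order correlation factors for PseAAC (type 1):
# theta_k = mean over i of the average squared difference of the three
# standardized scales between residues i and i+k.
.paacTheta <- function(s, lambda, sc) {
  n <- length(s)
  h1 <- unname(sc$hydrophobicity$z[s])
  h2 <- unname(sc$hydrophilicity$z[s])
  m <- unname(sc$mass$z[s])
  vapply(seq_len(lambda), function(k) {
    i <- seq_len(n - k)
    mean(((h1[i] - h1[i + k])^2 + (h2[i] - h2[i + k])^2 +
            (m[i] - m[i + k])^2) / 3)
  }, numeric(1))
}

#' Pseudo amino acid composition (50 features at lambda = 30)
#'
#' 20 composition components plus `lambda` sequence-order components
#' built from three standardized scales (hydrophobicity, hydrophilicity,
#' side-chain mass); the shared denominator forces the whole vector to
#' sum to 1.
#'
#' @inheritParams computeAAC
#' @param lambda number of sequence-order factors (< sequence length).
#' @param w weighting factor of the sequence-order terms.
#' @return named numeric vector of `20 + lambda` values.
#' @export
computePseAAC <- function(x, lambda = 30L, w = 0.5) {
  s <- .seqChars(x)
  n <- length(s)
  if (lambda >= n)
    stop(sprintf("lambda (%d) exceeds sequence length (%d)", lambda, n),
         call. = FALSE)
  f <- as.numeric(table(factor(s, levels = AA20))) / n
  theta <- .paacTheta(s, lambda, paacScales())
  denom <- sum(f) + w * sum(theta)
  if (abs(denom) < 1e-12) stop("degenerate PseAAC denominator")
  c(stats::setNames(f / denom, paste0("PAAC.", AA20)),
    stats::setNames(w * theta / denom,
                    paste0("PAAC.lambda.", seq_len(lambda))))
}

#' Amphiphilic pseudo amino acid composition (80 features at lambda = 30)
#'
#' 20 composition components plus `2*lambda` amphiphilic correlation
#' components: `tau_{2k-1}` and `tau_{2k}` are the mean lag-k products of
#' standardized hydrophobicity and hydrophilicity respectively; the
#' shared denominator forces the whole vector to sum to 1.
#'
#' @inheritParams computePseAAC
#' @return named numeric vector of `20 + 2*lambda` values.
#' @export
computeAPseAAC <- function(x, lambda = 30L, w = 0.5) {
  s <- .seqChars(x)
  n <- length(s)
  if (lambda >= n)
    stop(sprintf("lambda (%d) exceeds sequence length (%d)", lambda, n),
         call. = FALSE)
  sc <- paacScales()
  h1 <- unname(sc$hydrophobicity$z[s])
  h2 <- unname(sc$hydrophilicity$z[s])
  f <- as.numeric(table(factor(s, levels = AA20))) / n
  tau <- numeric(2 * lambda)
  for (k in seq_len(lambda)) {
    i <- seq_len(n - k)
    tau[2 * k - 1] <- sum(h1[i] * h1[i + k]) / (n - k)
    tau[2 * k] <- sum(h2[i] * h2[i + k]) / (n - k)
  }
  denom <- sum(f) + w * sum(tau)
  if (abs(denom) < 1e-12) stop("degenerate APseAAC denominator")
  c(stats::setNames(f / denom, paste0("APAAC.", AA20)),
    stats::setNames(w * tau / denom, paste0("APAAC.tau.", seq_len(2 * lambda))))
}

#' Descriptor configuration
#'
#' @param lag autocorrelation / sequence-order lag (default 30).
#' @param lambda PseAAC lambda (default 30).
#' @param w weighting factor for QSO and PseAAC order terms (default 0.5).
#' @param selected optional character vector of feature names for
#'   selected-feature (production) mode.
#' @return list with class `"DescriptorConfig"`.
#' @export
descriptorConfig <- function(lag = 30L, lambda = 30L, w = 0.5,
                             selected = NULL) {
  stopifnot(lag >= 1, lambda >= 1, w > 0)
  structure(list(lag = as.integer(lag), lambda = as.integer(lambda),
                 w = w, selected = selected),
            class = "DescriptorConfig")
}

DESCRIPTOR_CLASSES <- c("aac_dpc_tpc", "ac", "ctd", "ctriad", "qso",
                        "pseaac")

.classMinLength <- function(class, config) {
  switch(class,
         aac_dpc_tpc = 3L,
         ac = config$lag + 1L,
         ctd = 2L,
         ctriad = 3L,
         qso = config$lag + 1L,
         pseaac = config$lambda + 1L)
}

.computeOne <- function(s, class, config) {
  switch(class,
         aac_dpc_tpc = c(computeAAC(s), computeDPC(s), computeTPC(s)),
         ac = c(computeAutocorrelation(s, "moreau_broto", lag = config$lag),
                computeAutocorrelation(s, "moran", lag = config$lag),
                computeAutocorrelation(s, "geary", lag = config$lag)),
         ctd = computeCTD(s),
         ctriad = computeCTriad(s),
         qso = computeQSO(s, lag = config$lag, w = config$w),
         pseaac = c(computePseAAC(s, lambda = config$lambda, w = config$w),
                    computeAPseAAC(s, lambda = config$lambda, w = config$w)))
}

#' Compute one descriptor class for a set of sequences
#'
#' @param x named `AAStringSet` (or named character vector) of protein
#'   sequences.
#' @param class one of `"aac_dpc_tpc"` (8420 features), `"ac"` (720),
#'   `"ctd"` (147), `"ctriad"` (343), `"qso"` (160), `"pseaac"` (130).
#' @param config a [descriptorConfig()].
#' @return A [FeatureTable-class] with one row per sequence.
#' @export
computeDescriptors <- function(x, class = DESCRIPTOR_CLASSES,
                               config = descriptorConfig()) {
  class <- match.arg(class)
  if (is.character(x)) x <- Biostrings::AAStringSet(x)
  ids <- names(x)
  if (is.null(ids) || any(!nzchar(ids)) || anyDuplicated(ids))
    stop("sequences must carry unique non-empty names", call. = FALSE)
  seqs <- as.character(x)
  need <- .classMinLength(class, config)
  short <- nchar(seqs) < need
  if (any(short))
    stop(sprintf(
      "sequence(s) too short for descriptor class '%s' (need >= %d): %s",
      class, need, paste(ids[short], collapse = ", ")), call. = FALSE)
  rows <- lapply(seqs, function(s)
    tryCatch(.computeOne(s, class, config),
             error = function(e) stop("descriptor error for sequence '",
                                      ids[[match(s, seqs)]], "': ",
                                      conditionMessage(e), call. = FALSE)))
  FeatureTable(do.call(rbind, c(rows, list(deparse.level = 0))) |>
                 `rownames<-`(ids))
}

# resolve a selected feature name to (class, detail); bare 1/2/3-mers map
# to AAC/DPC/TPC as in the feature-usage figures
.resolveFeature <- function(name) {
  if (grepl(sprintf("^[%s]{1,3}$", paste(AA20, collapse = "")), name)) {
    cls <- c("AAC", "DPC", "TPC")[nchar(name)]
    return(list(prefix = cls, kmer = name,
                full = paste0(cls, ".", name)))
  }
  if (grepl("^(AAC|DPC|TPC)\\.", name)) {
    kmer <- sub("^(AAC|DPC|TPC)\\.", "", name)
    pre <- sub("\\..*$", "", name)
    if (nchar(kmer) == match(pre, c("AAC", "DPC", "TPC")) &&
        grepl(sprintf("^[%s]+$", paste(AA20, collapse = "")), kmer))
      return(list(prefix = pre, kmer = kmer, full = name))
    stop("unknown feature name: ", name, call. = FALSE)
  }
  pre <- sub("\\..*$", "", name)
  cls <- switch(pre, AC = "ac", CTD = "ctd", CTriad = "ctriad",
                SOCN = "qso", QSO = "qso", PAAC = "pseaac",
                APAAC = "pseaac", NULL)
  if (is.null(cls)) stop("unknown feature name: ", name, call. = FALSE)
  list(class = cls, full = name)
}

# overlapping occurrence count of a k-mer
.countKmer <- function(s, kmer) {
  length(gregexpr(sprintf("(?=%s)", kmer), s, perl = TRUE)[[1]] |>
           (\(p) p[p > 0])())
}

#' Compute only a selected set of named features
#'
#' Production mode: named composition k-mers (e.g. `"RMY"`, `"LI"`,
#' `"TPC.RMY"`) are counted directly without materializing the 8420-wide
#' composition block; features of other classes are computed from their
#' (small) class block and projected. Values are identical to the
#' corresponding columns of [computeDescriptors()].
#'
#' @inheritParams computeDescriptors
#' @param features character vector of feature names; bare 1/2/3-mer
#'   names resolve to AAC/DPC/TPC.
#' @return A [FeatureTable-class] with `length(features)` columns, in the
#'   requested order.
#' @export
computeSelectedFeatures <- function(x, features,
                                    config = descriptorConfig()) {
  if (is.character(x)) x <- Biostrings::AAStringSet(x)
  ids <- names(x)
  seqs <- as.character(x)
  res <- lapply(features, .resolveFeature)
  out <- matrix(0, length(seqs), length(features),
                dimnames = list(ids, vapply(res, `[[`, "", "full")))
  blockCache <- list()
  for (k in seq_along(res)) {
    r <- res[[k]]
    if (!is.null(r$kmer)) {
      km <- nchar(r$kmer)
      short <- nchar(seqs) < km
      if (any(short))
        stop("sequence(s) too short for feature ", r$full, ": ",
             paste(ids[short], collapse = ", "), call. = FALSE)
      out[, k] <- vapply(seqs, function(s)
        .countKmer(s, r$kmer) / (nchar(s) - km + 1), numeric(1))
    } else {
      if (is.null(blockCache[[r$class]]))
        blockCache[[r$class]] <- computeDescriptors(x, r$class, config)
      fm <- featureMatrix(blockCache[[r$class]])
      if (!r$full %in% colnames(fm))
        stop("unknown feature name: ", r$full, call. = FALSE)
      out[, k] <- fm[, r$full]
    }
  }
  FeatureTable(out)
}
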
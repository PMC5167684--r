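# Independent naive-loop oracles for every descriptor family. These are
# deliberately written as plain position-by-position loops over the
# published formulas, sharing only the reference scale data (which is an
# input, not a computation) with the package implementation.

AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

oracleAAC <- function(s) {
  ch <- strsplit(s, "")[[1]]
  v <- numeric(20); names(v) <- AA
  for (r in ch) v[r] <- v[r] + 1
  v / length(ch)
}

oracleKmer <- function(s, k) {
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  counts <- new.env()
  for (i in seq_len(n - k + 1)) {
    key <- paste(ch[i:(i + k - 1)], collapse = "")
    counts[[key]] <- (if (is.null(counts[[key]])) 0 else counts[[key]]) + 1
  }
  lev <- AA
  if (k >= 2) for (j in 2:k) lev <- as.vector(vapply(
    lev, function(p) paste0(p, AA), character(20)))
  lev <- sort(lev)
  v <- numeric(length(lev)); names(v) <- lev
  for (key in ls(counts)) v[key] <- counts[[key]]
  v / (n - k + 1)
}

# autocorrelation on a standardized property profile, by explicit loops
oracleAuto <- function(p, d, kind) {
  n <- length(p)
  if (kind == "moreau_broto") {
    acc <- 0
    for (i in 1:(n - d)) acc <- acc + p[i] * p[i + d]
    return(acc / (n - d))
  }
  pbar <- sum(p) / n
  ss <- 0; for (i in 1:n) ss <- ss + (p[i] - pbar)^2
  if (ss == 0) return(0)
  if (kind == "moran") {
    num <- 0
    for (i in 1:(n - d)) num <- num + (p[i] - pbar) * (p[i + d] - pbar)
    (num / (n - d)) / (ss / n)
  } else {
    num <- 0
    for (i in 1:(n - d)) num <- num + (p[i] - p[i + d])^2
    (num / (2 * (n - d))) / (ss / (n - 1))
  }
}

oracleACBlock <- function(s, kind, scales, lag = 30) {
  ch <- strsplit(s, "")[[1]]
  out <- numeric(0)
  for (sc in scales) {
    p <- as.numeric(sc$z[ch])
    for (d in 1:lag) out <- c(out, oracleAuto(p, d, kind))
  }
  out
}

oracleCTD <- function(s, groups) {
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  out <- numeric(0)
  for (pn in names(groups)) {
    g <- as.integer(groups[[pn]][ch])
    comp <- c(sum(g == 1), sum(g == 2), sum(g == 3)) / n
    tr <- numeric(3); names(tr) <- c("12", "13", "23")
    for (i in 1:(n - 1)) {
      a <- min(g[i], g[i + 1]); b <- max(g[i], g[i + 1])
      if (a != b) {
        key <- paste0(a, b)
        tr[key] <- tr[key] + 1
      }
    }
    tr <- tr / (n - 1)
    dist <- numeric(0)
    for (grp in 1:3) {
      pos <- which(g == grp)
      if (length(pos) == 0) dist <- c(dist, rep(0, 5))
      else {
        nr <- length(pos)
        for (q in c(0, 0.25, 0.5, 0.75, 1)) {
          idx <- max(1, ceiling(q * nr))
          dist <- c(dist, pos[idx] / n * 100)
        }
      }
    }
    out <- c(out, comp, tr, dist)
  }
  out
}

oracleCTriad <- function(s, classes) {
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  cnt <- array(0, c(7, 7, 7))
  for (i in 1:(n - 2))
    cnt[classes[ch[i]], classes[ch[i + 1]], classes[ch[i + 2]]] <-
      cnt[classes[ch[i]], classes[ch[i + 1]], classes[ch[i + 2]]] + 1
  out <- numeric(0)
  for (a in 1:7) for (b in 1:7) for (cc in 1:7)
    out <- c(out, cnt[a, b, cc])
  out / max(out)
}

oracleQSO <- function(s, mats, lag = 30, w = 0.5) {
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  taus <- lapply(mats, function(m) {
    tau <- numeric(lag)
    for (d in 1:lag) {
      acc <- 0
      for (i in 1:(n - d)) acc <- acc + m[ch[i], ch[i + d]]^2
      tau[d] <- acc
    }
    tau
  })
  f <- numeric(20); names(f) <- AA
  for (r in ch) f[r] <- f[r] + 1
  socn <- unlist(taus, use.names = FALSE)
  qso <- numeric(0)
  for (tau in taus) {
    denom <- sum(f) + w * sum(tau)
    qso <- c(qso, f / denom, w * tau / denom)
  }
  c(socn, qso)
}

oraclePAAC <- function(s, sc, lambda = 30, w = 0.5) {
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  h1 <- sc$hydrophobicity$z; h2 <- sc$hydrophilicity$z; ms <- sc$mass$z
  theta <- numeric(lambda)
  for (k in 1:lambda) {
    acc <- 0
    for (i in 1:(n - k)) {
      a <- ch[i]; b <- ch[i + k]
      acc <- acc + ((h1[a] - h1[b])^2 + (h2[a] - h2[b])^2 +
                      (ms[a] - ms[b])^2) / 3
    }
    theta[k] <- acc / (n - k)
  }
  f <- numeric(20); names(f) <- AA
  for (r in ch) f[r] <- f[r] + 1
  f <- f / n
  denom <- sum(f) + w * sum(theta)
  c(f / denom, w * theta / denom)
}

oracleAPAAC <- function(s, sc, lambda = 30, w = 0.5) {
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  h1 <- sc$hydrophobicity$z; h2 <- sc$hydrophilicity$z
  tau <- numeric(2 * lambda)
  for (k in 1:lambda) {
    a1 <- 0; a2 <- 0
    for (i in 1:(n - k)) {
      a1 <- a1 + h1[ch[i]] * h1[ch[i + k]]
      a2 <- a2 + h2[ch[i]] * h2[ch[i + k]]
    }
    tau[2 * k - 1] <- a1 / (n - k)
    tau[2 * k] <- a2 / (n - k)
  }
  f <- numeric(20); names(f) <- AA
  for (r in ch) f[r] <- f[r] + 1
  f <- f / n
  denom <- sum(f) + w * sum(tau)
  c(f / denom, w * tau / denom)
}

# exhaustive split enumeration for the tree: best gain ratio over all
# features and midpoint thresholds, by direct entropy counting
oracleBestSplit <- function(X, y, minLeaf = 2) {
  ent <- function(lab) {
    n <- length(lab)
    if (n == 0) return(0)
    h <- 0
    for (cl in unique(lab)) {
      p <- sum(lab == cl) / n
      h <- h - p * log2(p)
    }
    h
  }
  n <- length(y)
  H0 <- ent(y)
  best <- list(score = -Inf)
  for (f in colnames(X)) {
    vals <- sort(unique(X[, f]))
    if (length(vals) < 2) next
    for (v in seq_len(length(vals) - 1)) {
      thr <- (vals[v] + vals[v + 1]) / 2
      left <- X[, f] <= thr
      nl <- sum(left); nr <- n - nl
      if (nl < minLeaf || nr < minLeaf) next
      gain <- H0 - (nl * ent(y[left]) + nr * ent(y[!left])) / n
      if (gain <= 1e-12) next
      si <- -(nl / n) * log2(nl / n) - (nr / n) * log2(nr / n)
      score <- gain / si
      if (score > best$score + 1e-12)
        best <- list(feature = f, threshold = thr, score = score,
                     gain = gain)
    }
  }
  best
}

# independent recursive path walk over the exported list form of a tree
oraclePredict <- function(model, X) {
  tl <- treeToList(model)
  walk <- function(node, row) {
    if (isTRUE(node$leaf)) return(node$class)
    if (row[[node$feature]] <= node$threshold) walk(node$left, row)
    else walk(node$right, row)
  }
  out <- character(nrow(X))
  for (r in seq_len(nrow(X)))
    out[r] <- walk(tl, as.list(setNames(as.numeric(X[r, ]), colnames(X))))
  out
}

randomSeqs <- function(n, minLen = 35, maxLen = 60, seed = 1) {
  set.seed(seed)
  lens <- minLen + sample.int(maxLen - minLen + 1, n, replace = TRUE) - 1L
  s <- vapply(lens, function(l)
    paste(sample(AA, l, replace = TRUE), collapse = ""), character(1))
  names(s) <- sprintf("s%03d", seq_len(n))
  s
}
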
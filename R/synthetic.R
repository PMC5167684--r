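# Synthetic labelled protein sets with controllable class signal, so the
# whole pipeline is testable without an external curated data set. The
# defaults emulate fluorescent-protein-like chains (length 220-240).

HYDROPHOBIC_SET <- strsplit("CLVIMFW", "")[[1]]

#' Generate a labelled synthetic protein set
#'
#' Monomer-class sequences are drawn i.i.d. from a background residue
#' composition. Oligomer-class sequences carry a class signal of the
#' requested type and strength: `"composition_bias"` interpolates the
#' background towards a hydrophobic-residue-enriched composition
#' (hydrophobic residues upweighted threefold at strength 1, echoing the
#' hydrophobic character of oligomerization interfaces);
#' `"motif_insertion"` plants `round(3 * strength)` copies of tripeptide
#' motifs (default `RMY`) into each oligomer and scrubs chance
#' occurrences from monomers; `"none"` (or strength 0) yields identically
#' distributed classes.
#'
#' @param nPerClass sequences per class.
#' @param lengthRange integer range of sequence lengths; minimum 35 so
#'   all descriptor preconditions (lag/lambda 30) hold.
#' @param signal `"composition_bias"`, `"motif_insertion"` or `"none"`.
#' @param strength signal strength in `[0, 1]`.
#' @param motifs tripeptide motifs planted under `motif_insertion`.
#' @param background `"uniform"` or `"uniprot"` residue frequencies.
#' @param seed integer seed; a fixed seed yields identical sequences.
#' @return list with `sequences` (named `AAStringSet`) and `labels`
#'   (named factor, levels monomer/oligomer).
#' @export
simulateProteins <- function(nPerClass = 100L,
                             lengthRange = c(220L, 240L),
                             signal = c("composition_bias",
                                        "motif_insertion", "none"),
                             strength = 1, motifs = "RMY",
                             background = "uniform", seed = 1L) {
  signal <- match.arg(signal)
  stopifnot(nPerClass >= 1, strength >= 0, strength <= 1)
  if (min(lengthRange) < 35)
    stop("minimum length must be >= 35 (descriptor preconditions)",
         call. = FALSE)
  bg <- backgroundFrequencies(background)
  set.seed(seed)

  drawSeq <- function(len, freqs)
    paste(sample(AA20, len, replace = TRUE, prob = freqs), collapse = "")
  scrubMotifs <- function(s) {
    # replace the middle residue of any motif occurrence; repeat until none
    repeat {
      hit <- FALSE
      for (m in motifs) {
        p <- regexpr(m, s, fixed = TRUE)
        if (p > 0) {
          hit <- TRUE
          repl <- sample(setdiff(AA20, substr(m, 2, 2)), 1)
          substr(s, p + 1, p + 1) <- repl
        }
      }
      if (!hit) return(s)
    }
  }
  plantMotifs <- function(s, nCopies) {
    len <- nchar(s)
    starts <- integer(0)
    taken <- logical(len)
    for (k in seq_len(nCopies)) {
      m <- motifs[[(k - 1) %% length(motifs) + 1]]
      free <- which(!taken[seq_len(len - 2)] &
                      !taken[seq_len(len - 2) + 1] &
                      !taken[seq_len(len - 2) + 2])
      pos <- if (length(free)) sample(free, 1) else break
      substr(s, pos, pos + 2) <- m
      taken[pos:(pos + 2)] <- TRUE
    }
    s
  }

  oligFreqs <- bg
  if (signal == "composition_bias") {
    enriched <- bg
    enriched[HYDROPHOBIC_SET] <- enriched[HYDROPHOBIC_SET] * 3
    enriched <- enriched / sum(enriched)
    oligFreqs <- (1 - strength) * bg + strength * enriched
  }
  nCopies <- if (signal == "motif_insertion") round(3 * strength) else 0L

  lens <- lengthRange[1] - 1L +
    sample.int(lengthRange[2] - lengthRange[1] + 1L, 2 * nPerClass,
               replace = TRUE)
  seqs <- character(2 * nPerClass)
  for (k in seq_len(nPerClass)) {               # monomers
    s <- drawSeq(lens[k], bg)
    if (signal == "motif_insertion") s <- scrubMotifs(s)
    seqs[k] <- s
  }
  for (k in seq_len(nPerClass)) {               # oligomers
    s <- drawSeq(lens[nPerClass + k], oligFreqs)
    if (signal == "motif_insertion") {
      s <- scrubMotifs(s)
      if (nCopies > 0) s <- plantMotifs(s, nCopies)
    }
    seqs[nPerClass + k] <- s
  }
  ids <- c(sprintf("mono_%03d", seq_len(nPerClass)),
           sprintf("olig_%03d", seq_len(nPerClass)))
  sequences <- Biostrings::AAStringSet(stats::setNames(seqs, ids))
  labels <- factor(rep(c("monomer", "oligomer"), each = nPerClass),
                   levels = c("monomer", "oligomer"))
  names(labels) <- ids
  list(sequences = sequences, labels = labels)
}

#' Append near-duplicate copies of each sequence
#'
#' Each record gains `k` mutated copies carrying exactly `mutations`
#' random substitutions (distinct positions, changed to a different
#' residue), i.e. identity `(N - mutations) / N` to its source. Useful
#' for exact expected cluster counts in homology-reduction tests.
#'
#' @param x named `AAStringSet`.
#' @param k copies per record.
#' @param mutations substitutions per copy (< sequence length).
#' @param seed integer seed.
#' @return named `AAStringSet`: the originals followed by the copies
#'   (ids suffixed `_dupNN`).
#' @export
makeDuplicates <- function(x, k, mutations, seed = 1L) {
  if (is.character(x)) x <- Biostrings::AAStringSet(x)
  stopifnot(k >= 1, mutations >= 0,
            all(mutations < nchar(as.character(x))))
  set.seed(seed)
  seqs <- as.character(x)
  out <- seqs
  for (id in names(seqs)) {
    for (j in seq_len(k)) {
      s <- seqs[[id]]
      if (mutations > 0) {
        pos <- sample(nchar(s), mutations)
        for (p in pos) {
          old <- substr(s, p, p)
          substr(s, p, p) <- sample(setdiff(AA20, old), 1)
        }
      }
      out[[sprintf("%s_dup%02d", id, j)]] <- s
    }
  }
  Biostrings::AAStringSet(out)
}
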
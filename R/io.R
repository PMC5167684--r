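# Sequence and label input/output. Sequences are held as a named
# Biostrings::AAStringSet restricted to the 20 canonical residues.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Read and validate a protein FASTA file
#'
#' Reads a multi-record FASTA (wrapped or unwrapped lines), uppercases
#' sequences, strips `*` stop characters and surrounding whitespace, and
#' validates against the 20-letter amino acid alphabet. Ids are the header
#' up to the first whitespace and must be unique.
#'
#' @param file path to a FASTA file, or a character vector of FASTA text
#'   (anything containing a newline or starting with `>` is treated as
#'   literal text rather than a path).
#' @param nonCanonical policy for residues outside `ACDEFGHIKLMNPQRSTVWY`:
#'   `"reject"` (default) raises an error naming the id, position and
#'   character; `"drop"` removes the offending sequence with a warning.
#' @return A named `AAStringSet`, one element per record, input order
#'   preserved.
#' @examples
#' fa <- readProteinFasta(">a\nMKV\n")
#' @export
readProteinFasta <- function(file, nonCanonical = c("reject", "drop")) {
  nonCanonical <- match.arg(nonCanonical)
  if (length(file) > 1 || any(grepl("\n", file)) ||
      any(startsWith(file, ">")) || !file.exists(file[[1]])) {
    tmp <- tempfile(fileext = ".fasta")
    on.exit(unlink(tmp))
    writeLines(sub("\n$", "", paste(file, collapse = "\n")), tmp)
    file <- tmp
  }
  raw <- tryCatch(
    Biostrings::readBStringSet(file),
    error = function(e) stop("failed to parse FASTA: ", conditionMessage(e),
                             call. = FALSE))
  if (length(raw) == 0) stop("no sequences in FASTA input", call. = FALSE)
  ids <- sub("\\s.*$", "", names(raw))
  if (any(!nzchar(ids))) stop("empty FASTA header id", call. = FALSE)
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate sequence id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  seqs <- toupper(gsub("[*[:space:]]", "", as.character(raw)))
  keep <- rep(TRUE, length(seqs))
  for (k in seq_along(seqs)) {
    bad <- regexpr(sprintf("[^%s]", paste(AA20, collapse = "")), seqs[[k]])
    if (bad > 0) {
      msg <- sprintf(
        "non-canonical residue '%s' at position %d in sequence '%s'",
        substr(seqs[[k]], bad, bad), bad, ids[[k]])
      if (nonCanonical == "reject") stop(msg, call. = FALSE)
      warning(msg, "; sequence dropped", call. = FALSE)
      keep[[k]] <- FALSE
    }
  }
  seqs <- seqs[keep]; ids <- ids[keep]
  if (any(!nchar(seqs)))
    stop("empty sequence for id(s): ",
         paste(ids[!nchar(seqs)], collapse = ", "), call. = FALSE)
  out <- Biostrings::AAStringSet(seqs)
  names(out) <- ids
  out
}

#' Write protein sequences to FASTA
#'
#' Round-trips with [readProteinFasta()]: parsing the written file yields
#' identical ids and sequences.
#'
#' @param x named `AAStringSet` (or named character vector).
#' @param file output path.
#' @param width line-wrap width (residues per line).
#' @export
writeProteinFasta <- function(x, file, width = 60L) {
  if (is.character(x)) x <- Biostrings::AAStringSet(x)
  Biostrings::writeXStringSet(x, file, width = width)
  invisible(file)
}

#' Read oligomeric-state labels and match them to sequences
#'
#' Reads a two-column CSV (`id,label`, header optional) and matches every
#' sequence to exactly one label. Labels map case-insensitively to
#' `monomer` / `oligomer`.
#'
#' @param file path to the CSV, or literal CSV text.
#' @param sequences named `AAStringSet` the labels must cover.
#' @return factor of labels (levels `monomer`, `oligomer`) named by
#'   sequence id, in the order of `sequences`.
#' @export
readLabels <- function(file, sequences) {
  if (length(file) > 1 || any(grepl("\n", file))) {
    tmp <- tempfile(fileext = ".csv")
    on.exit(unlink(tmp))
    writeLines(sub("\n$", "", paste(file, collapse = "\n")), tmp)
    file <- tmp
  }
  df <- utils::read.csv(file, header = FALSE, stringsAsFactors = FALSE,
                        strip.white = TRUE)
  if (ncol(df) < 2) stop("label CSV must have columns id,label", call. = FALSE)
  df <- df[, 1:2]
  names(df) <- c("id", "label")
  if (nrow(df) && tolower(df$id[[1]]) == "id") df <- df[-1, , drop = FALSE]
  lab <- tolower(trimws(df$label))
  unknown <- setdiff(unique(lab), c("monomer", "oligomer"))
  if (length(unknown))
    stop("unknown label(s): ", paste(unknown, collapse = ", "),
         " (expected monomer/oligomer)", call. = FALSE)
  if (anyDuplicated(df$id))
    stop("duplicate id(s) in label table: ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "),
         call. = FALSE)
  ids <- names(sequences)
  hit <- match(ids, df$id)
  if (anyNA(hit))
    stop("missing label for sequence id(s): ",
         paste(ids[is.na(hit)], collapse = ", "), call. = FALSE)
  factor(lab[hit], levels = c("monomer", "oligomer"),
         labels = c("monomer", "oligomer")) |>
    stats::setNames(ids)
}
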
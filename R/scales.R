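# Reference physicochemical data: AAindex scales for the autocorrelation
# descriptors, three-group encodings for CTD, the seven conjoint-triad
# classes, residue distance matrices for QSO and the three PseAAC scales.
# Small tables ship as plain-text TSV under inst/extdata; AAindex scales
# are looked up from seqinr's bundled AAindex catalogue.

.oligoFPcache <- new.env(parent = emptyenv())

.extdata <- function(name) {
  f <- system.file("extdata", name, package = "oligoFP", mustWork = TRUE)
  read.delim(f, stringsAsFactors = FALSE)
}

# seqinr's aaindex names residues by three-letter code
.AA3TO1 <- c(Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C",
             Gln = "Q", Glu = "E", Gly = "G", His = "H", Ile = "I",
             Leu = "L", Lys = "K", Met = "M", Phe = "F", Pro = "P",
             Ser = "S", Thr = "T", Trp = "W", Tyr = "Y", Val = "V")

# default AAindex accessions for the autocorrelation descriptors:
# hydrophobicity, flexibility, polarizability, free energy of solution,
# accessible surface area, residue volume, steric parameter, mutability
AC_SCALE_IDS <- c("CIDH920105", "BHAR880101", "CHAM820101", "CHAM820102",
                  "CHOC760101", "BIGC670101", "CHAM810101", "DAYM780201")

#' Standardize a 20-residue property scale
#'
#' Centers to zero mean and scales to unit population standard deviation
#' over the 20 residues.
#'
#' @param x named numeric vector of 20 residue property values.
#' @return standardized named vector in the same residue order.
#' @export
standardizeScale <- function(x) {
  stopifnot(length(x) == 20)
  mu <- mean(x)
  sdev <- sqrt(mean((x - mu)^2))
  if (sdev == 0) stop("constant property scale cannot be standardized")
  (x - mu) / sdev
}

#' Physicochemical property scales for autocorrelation descriptors
#'
#' Looks up property scales by AAindex accession from the AAindex
#' catalogue bundled with seqinr and returns both raw and standardized
#' (zero mean, unit population SD over the 20 residues) values.
#'
#' @param ids character vector of AAindex accessions; the default is the
#'   eight scales used by the autocorrelation descriptor block.
#' @return named list (by accession); each element is a list with
#'   elements `id`, `raw` and `z`, the latter two being named 20-vectors
#'   in `ACDEFGHIKLMNPQRSTVWY` order.
#' @export
propertyScales <- function(ids = AC_SCALE_IDS) {
  key <- paste(ids, collapse = ",")
  if (!is.null(.oligoFPcache[[key]])) return(.oligoFPcache[[key]])
  aaindex <- NULL
  utils::data("aaindex", package = "seqinr", envir = environment())
  acc <- vapply(aaindex, function(e) e$H, character(1))
  out <- lapply(ids, function(id) {
    hit <- which(acc == id)
    if (!length(hit)) stop("AAindex accession not found: ", id)
    v <- aaindex[[hit[[1]]]]$I
    names(v) <- unname(.AA3TO1[names(v)])
    v <- v[AA20]
    if (anyNA(v)) stop("incomplete AAindex scale: ", id)
    list(id = id, raw = v, z = standardizeScale(v))
  })
  names(out) <- ids
  .oligoFPcache[[key]] <- out
  out
}

#' CTD three-group residue encodings
#'
#' The seven physicochemical properties (hydrophobicity, normalized van
#' der Waals volume, polarity, polarizability, charge, secondary
#' structure, solvent accessibility), each partitioning the 20 residues
#' into three groups. Shipped as an auditable TSV.
#'
#' @return named list (by property); each element is a length-20 integer
#'   vector of group indices 1..3 named by residue.
#' @export
ctdGroups <- function() {
  if (!is.null(.oligoFPcache$ctd)) return(.oligoFPcache$ctd)
  df <- .extdata("ctd_groups.tsv")
  props <- unique(df$property)
  out <- lapply(props, function(p) {
    sub <- df[df$property == p, ]
    g <- integer(20); names(g) <- AA20
    for (k in seq_len(nrow(sub))) {
      res <- strsplit(sub$residues[[k]], "")[[1]]
      g[res] <- sub$group[[k]]
    }
    if (any(g == 0)) stop("incomplete CTD grouping for property ", p)
    g
  })
  names(out) <- props
  .oligoFPcache$ctd <- out
  out
}

#' Conjoint-triad residue classes
#'
#' The seven side-chain dipole/volume classes used by the conjoint triad
#' descriptor.
#'
#' @return integer vector of class indices 1..7 named by residue.
#' @export
triadClasses <- function() {
  if (!is.null(.oligoFPcache$triad)) return(.oligoFPcache$triad)
  df <- .extdata("triad_classes.tsv")
  cl <- integer(20); names(cl) <- AA20
  for (k in seq_len(nrow(df)))
    cl[strsplit(df$residues[[k]], "")[[1]]] <- df$class[[k]]
  if (any(cl == 0)) stop("incomplete triad class table")
  .oligoFPcache$triad <- cl
  cl
}

#' PseAAC property scales
#'
#' Hydrophobicity, hydrophilicity and side-chain mass for the 20 residues
#' (raw and standardized), used by the pseudo and amphiphilic pseudo
#' amino acid composition descriptors.
#'
#' @return list with elements `hydrophobicity`, `hydrophilicity`, `mass`;
#'   each a list of `raw` and `z` named 20-vectors.
#' @export
paacScales <- function() {
  if (!is.null(.oligoFPcache$paac)) return(.oligoFPcache$paac)
  df <- .extdata("paac_scales.tsv")
  get <- function(col) {
    v <- stats::setNames(df[[col]], df$residue)[AA20]
    list(raw = v, z = standardizeScale(v))
  }
  out <- list(hydrophobicity = get("hydrophobicity"),
              hydrophilicity = get("hydrophilicity"),
              mass = get("sidechain_mass"))
  .oligoFPcache$paac <- out
  out
}

#' Residue distance matrices for quasi-sequence-order descriptors
#'
#' Two 20 x 20 symmetric distance matrices. `grantham` is the Grantham
#' (1974) chemical distance computed from the published
#' composition/polarity/volume formula
#' (rho * sqrt(1.833 dc^2 + 0.1018 dp^2 + 0.000399 dv^2), rho = 50.723).
#' `physchemSynthetic` is a SYNTHETIC physicochemical distance built in
#' this package: the Euclidean distance over the three standardized
#' PseAAC scales (hydrophobicity, hydrophilicity, side-chain mass),
#' divided by sqrt(3). It stands in the same role as published
#' sequence-order distance matrices but is not a reproduction of any of
#' them.
#'
#' @return named list of two 20 x 20 matrices with residue dimnames.
#' @export
qsoDistanceMatrices <- function() {
  if (!is.null(.oligoFPcache$qso)) return(.oligoFPcache$qso)
  gp <- .extdata("grantham_properties.tsv")
  rn <- gp$residue
  prop <- as.matrix(gp[, c("composition", "polarity", "volume")])
  rownames(prop) <- rn
  prop <- prop[AA20, ]
  w <- c(1.833, 0.1018, 0.000399)
  grantham <- matrix(0, 20, 20, dimnames = list(AA20, AA20))
  for (i in 1:20) for (j in 1:20)
    grantham[i, j] <- 50.723 * sqrt(sum(w * (prop[i, ] - prop[j, ])^2))

  sc <- paacScales()
  z <- cbind(sc$hydrophobicity$z, sc$hydrophilicity$z, sc$mass$z)
  synth <- matrix(0, 20, 20, dimnames = list(AA20, AA20))
  for (i in 1:20) for (j in 1:20)
    synth[i, j] <- sqrt(sum((z[i, ] - z[j, ])^2) / 3)

  out <- list(physchemSynthetic = synth, grantham = grantham)
  .oligoFPcache$qso <- out
  out
}

#' Background residue frequencies
#'
#' @param source `"uniform"` (1/20 each) or `"uniprot"` (Swiss-Prot-like
#'   average composition shipped as a TSV).
#' @return named numeric 20-vector summing to 1.
#' @export
backgroundFrequencies <- function(source = c("uniform", "uniprot")) {
  source <- match.arg(source)
  if (source == "uniform")
    return(stats::setNames(rep(1 / 20, 20), AA20))
  df <- .extdata("uniprot_frequencies.tsv")
  v <- stats::setNames(df$frequency, df$residue)[AA20]
  v / sum(v)
}
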
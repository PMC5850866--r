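NUCLEOTIDES <- c("A", "C", "G", "T")

#' The standard genetic code over the 61 sense codons
#'
#' Builds the bookkeeping tables used throughout the package: the 64 codons
#' in lexicographic (A, C, G, T) order, their amino-acid translation, the 61
#' sense codons with a fixed integer indexing, and the pairwise
#' classification of single-nucleotide codon changes as synonymous or
#' nonsynonymous.
#'
#' @param code_table Named character vector mapping all 64 codons to
#'   one-letter amino-acid symbols, with `"*"` for stop codons. Defaults to
#'   the standard nuclear code. Alternative codes may be supplied but are
#'   untested.
#' @return An object of class `genetic_code`: a list with elements
#'   `codons` (61 sense codons, lexicographic order), `aa` (their amino
#'   acids), `stop_codons`, `index` (named integer vector codon -> 1..61),
#'   `class` (61 x 61 integer matrix: 0 identical, 1 synonymous,
#'   2 nonsynonymous, 3 multiple-hit), `is_transition` (61 x 61 logical,
#'   TRUE where the pair differs by exactly one transition), and
#'   `codon_nuc` (61 x 3 integer matrix of nucleotide indices per position).
#' @export
genetic_code <- function(code_table = standard_code_table()) {
  codons64 <- sort(apply(expand.grid(NUCLEOTIDES, NUCLEOTIDES, NUCLEOTIDES,
                                     stringsAsFactors = FALSE), 1, paste0,
                         collapse = ""))
  aa64 <- unname(code_table[codons64])
  if (anyNA(aa64)) stop("code_table must cover all 64 codons")
  stops <- codons64[aa64 == "*"]
  sense <- codons64[aa64 != "*"]
  aa <- aa64[aa64 != "*"]
  n <- length(sense)
  index <- stats::setNames(seq_len(n), sense)

  codon_nuc <- t(vapply(strsplit(sense, ""),
                        function(x) match(x, NUCLEOTIDES), integer(3)))

  ndiff <- matrix(0L, n, n)
  for (p in 1:3) ndiff <- ndiff + outer(codon_nuc[, p], codon_nuc[, p], "!=")
  same_aa <- outer(aa, aa, "==")
  cls <- matrix(3L, n, n)
  cls[ndiff == 1L & same_aa] <- 1L
  cls[ndiff == 1L & !same_aa] <- 2L
  cls[ndiff == 0L] <- 0L

  # transitions: A<->G, C<->T; purine = A/G (indices 1,3)
  is_purine <- c(TRUE, FALSE, TRUE, FALSE)
  trans <- matrix(FALSE, n, n)
  for (p in 1:3) {
    differs <- outer(codon_nuc[, p], codon_nuc[, p], "!=")
    same_type <- outer(is_purine[codon_nuc[, p]], is_purine[codon_nuc[, p]], "==")
    trans <- trans | (differs & same_type & ndiff == 1L)
  }

  structure(
    list(codons = sense, aa = aa, stop_codons = stops, index = index,
         class = cls, is_transition = trans, codon_nuc = codon_nuc),
    class = "genetic_code"
  )
}

#' Standard nuclear genetic code as a 64-entry lookup table
#' @return Named character vector: codon -> amino acid, `"*"` for stops.
#' @keywords internal
standard_code_table <- function() {
  # standard code, written out by amino-acid family
  tab <- c(
    TTT = "F", TTC = "F", TTA = "L", TTG = "L",
    CTT = "L", CTC = "L", CTA = "L", CTG = "L",
    ATT = "I", ATC = "I", ATA = "I", ATG = "M",
    GTT = "V", GTC = "V", GTA = "V", GTG = "V",
    TCT = "S", TCC = "S", TCA = "S", TCG = "S",
    CCT = "P", CCC = "P", CCA = "P", CCG = "P",
    ACT = "T", ACC = "T", ACA = "T", ACG = "T",
    GCT = "A", GCC = "A", GCA = "A", GCG = "A",
    TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
    CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
    AAT = "N", AAC = "N", AAA = "K", AAG = "K",
    GAT = "D", GAC = "D", GAA = "E", GAG = "E",
    TGT = "C", TGC = "C", TGA = "*", TGG = "W",
    CGT = "R", CGC = "R", CGA = "R", CGG = "R",
    AGT = "S", AGC = "S", AGA = "R", AGG = "R",
    GGT = "G", GGC = "G", GGA = "G", GGG = "G"
  )
  tab
}

.cache <- new.env(parent = emptyenv())

#' Shared instance of the standard genetic code
#' @return The cached [genetic_code()] for the standard nuclear code.
#' @export
std_genetic_code <- function() {
  if (is.null(.cache$code)) .cache$code <- genetic_code()
  .cache$code
}

#' Classify a pair of sense codons
#'
#' A single-nucleotide change between sense codons is synonymous when both
#' codons encode the same amino acid, nonsynonymous otherwise. Pairs that
#' differ at more than one position are multiple-hit changes (instantaneous
#' rate zero under the YN98 model); identical codons are classified as such.
#'
#' @param x,y Codon strings (e.g. `"AAA"`), sense codons of the code.
#' @param code A [genetic_code()] object.
#' @return One of `"identical"`, `"synonymous"`, `"nonsynonymous"`,
#'   `"multiple_hit"`.
#' @examples
#' classify_pair("AAA", "AAG")  # synonymous (Lys -> Lys)
#' classify_pair("AAA", "ACA")  # nonsynonymous (Lys -> Thr)
#' @export
classify_pair <- function(x, y, code = std_genetic_code()) {
  ix <- code$index[x]
  iy <- code$index[y]
  if (is.na(ix)) stop("not a sense codon: ", x)
  if (is.na(iy)) stop("not a sense codon: ", y)
  c("identical", "synonymous", "nonsynonymous",
    "multiple_hit")[code$class[ix, iy] + 1L]
}

#' Nucleotide composition from a single G+C proportion
#'
#' The symmetric parameterization used on the simulation grid: the G+C mass
#' theta is split evenly between G and C, and the A+T mass between A and T,
#' so theta is the single compositional degree of freedom.
#'
#' @param theta G+C proportion, in `[0, 1]`.
#' @return Named numeric vector of frequencies over A, C, G, T.
#' @examples
#' gc_parameterization(0.5)  # uniform
#' gc_parameterization(0.9)  # A = T = 0.05, G = C = 0.45
#' @export
gc_parameterization <- function(theta) {
  if (!is.numeric(theta) || length(theta) != 1L || is.na(theta) ||
      theta < 0 || theta > 1) {
    stop("theta must be a single number in [0, 1]")
  }
  c(A = (1 - theta) / 2, C = theta / 2, G = theta / 2, T = (1 - theta) / 2)
}

#' Frequency parameterization for codon equilibrium or root composition
#'
#' F1X4 uses one nucleotide distribution shared by the three codon
#' positions (3 free parameters); F3X4 uses one distribution per position
#' (9 free parameters).
#'
#' @param freqs For `"F1X4"`, a length-4 distribution over A, C, G, T (in
#'   that order); for `"F3X4"`, a 3 x 4 matrix with one distribution per
#'   row (positions 1..3).
#' @param scheme `"F1X4"` or `"F3X4"`.
#' @return Object of class `freq_param`.
#' @export
freq_param <- function(freqs, scheme = c("F1X4", "F3X4")) {
  scheme <- match.arg(scheme)
  if (scheme == "F1X4") {
    freqs <- as.numeric(freqs)
    if (length(freqs) != 4L) stop("F1X4 needs 4 nucleotide frequencies")
    freqs <- matrix(freqs, 1, 4, dimnames = list(NULL, NUCLEOTIDES))
  } else {
    freqs <- as.matrix(freqs)
    if (!all(dim(freqs) == c(3L, 4L))) stop("F3X4 needs a 3 x 4 matrix")
    colnames(freqs) <- NUCLEOTIDES
  }
  if (any(freqs < 0) || any(freqs > 1)) stop("frequencies must lie in [0, 1]")
  sums <- rowSums(freqs)
  if (any(abs(sums - 1) > 1e-8)) stop("each nucleotide distribution must sum to 1")
  structure(list(scheme = scheme, freqs = freqs), class = "freq_param")
}

#' Codon frequencies from a nucleotide frequency parameterization
#'
#' Builds the distribution over the 61 sense codons as the product of the
#' position-wise nucleotide frequencies, zeroes the stop codons, and
#' renormalizes. A degenerate nucleotide distribution with zeros is allowed
#' and propagates zero codon frequencies.
#'
#' @param fp A [freq_param()] object, or a length-4 nucleotide distribution
#'   (interpreted as F1X4).
#' @param code A [genetic_code()] object.
#' @return Numeric vector of length 61 summing to 1, named by codon.
#' @export
codon_frequencies <- function(fp, code = std_genetic_code()) {
  if (!inherits(fp, "freq_param")) fp <- freq_param(fp, "F1X4")
  f <- fp$freqs
  if (fp$scheme == "F1X4") f <- f[c(1, 1, 1), , drop = FALSE]
  w <- f[cbind(1L, code$codon_nuc[, 1])] *
       f[cbind(2L, code$codon_nuc[, 2])] *
       f[cbind(3L, code$codon_nuc[, 3])]
  s <- sum(w)
  if (s <= 0) stop("all sense codons have zero frequency under this parameterization")
  stats::setNames(w / s, code$codons)
}
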
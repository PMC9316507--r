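DNA_BASES <- c("A", "C", "G", "T")

# IUPAC nucleotide codes -> the set of DNA bases each one covers
IUPAC_DNA <- list(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Normalise a nucleotide string to uppercase DNA
#'
#' RNA input (containing U) is converted to its DNA equivalent (U -> T);
#' case is folded to upper. Characters outside the DNA alphabet are
#' rejected with the 1-based position of the first offender.
#'
#' @param x character scalar, nucleotide sequence (DNA or RNA).
#' @param allow_iupac logical; accept IUPAC ambiguity codes as well.
#' @return uppercase DNA character scalar.
#' @export
as_dna <- function(x, allow_iupac = FALSE) {
  stopifnot(is.character(x), length(x) == 1L)
  x <- chartr("u", "U", toupper(x))
  x <- chartr("U", "T", x)
  alphabet <- if (allow_iupac) names(IUPAC_DNA) else DNA_BASES
  chars <- strsplit(x, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% alphabet)
  if (length(bad) > 0L) {
    stop("non-nucleotide character '", chars[bad[1L]], "' at position ",
         bad[1L], call. = FALSE)
  }
  x
}

#' Render a DNA string as RNA
#'
#' @param x DNA character scalar.
#' @return RNA string (T -> U), uppercase.
#' @export
as_rna <- function(x) chartr("T", "U", toupper(x))

#' Reverse complement of a DNA string
#'
#' @param x DNA character scalar.
#' @return reverse complement, uppercase DNA.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# substring of a circular sequence; `start` 0-based, may be negative or
# exceed the length, `len` >= 0
circ_substr <- function(seq, start, len) {
  n <- nchar(seq)
  if (len == 0L) return("")
  idx <- ((start + seq_len(len) - 1L) %% n) + 1L
  paste(strsplit(seq, "", fixed = TRUE)[[1L]][idx], collapse = "")
}

# rotate a string left by r characters (r in [0, nchar))
rotate_str <- function(x, r) {
  n <- nchar(x)
  r <- ((r %% n) + n) %% n
  if (r == 0L) return(x)
  paste0(substr(x, r + 1L, n), substr(x, 1L, r))
}

# lexicographically minimal rotation (rotation-invariant string key)
min_rotation <- function(x) {
  n <- nchar(x)
  rots <- vapply(seq_len(n) - 1L, function(r) rotate_str(x, r), character(1))
  sort(rots)[1L]
}

# GC fraction of a DNA string
gc_fraction <- function(x) {
  chars <- strsplit(toupper(x), "", fixed = TRUE)[[1L]]
  if (length(chars) == 0L) return(NA_real_)
  mean(chars %in% c("G", "C"))
}

# random DNA string of length n with a target GC fraction, drawn from the
# supplied RNG stream (caller controls the seed)
random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

# Hamming distance between equal-length strings
hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  if (nchar(a) == 0L) return(0L)
  sum(strsplit(a, "", fixed = TRUE)[[1L]] != strsplit(b, "", fixed = TRUE)[[1L]])
}

# validate an IUPAC pattern (RNA or DNA spelling); returns DNA spelling
check_iupac <- function(pattern) {
  as_dna(pattern, allow_iupac = TRUE)
}
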
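# IUPAC degenerate nucleotide codes, RNA alphabet. Base sets are kept in
# A < C < G < U order so that library enumeration is lexicographic.
IUPAC_RNA <- list(
  A = "A", C = "C", G = "G", U = "U",
  R = c("A", "G"), Y = c("C", "U"), S = c("C", "G"), W = c("A", "U"),
  K = c("G", "U"), M = c("A", "C"),
  B = c("C", "G", "U"), D = c("A", "G", "U"), H = c("A", "C", "U"),
  V = c("A", "C", "G"),
  N = c("A", "C", "G", "U")
)

#' Expand an IUPAC degenerate nucleotide code
#'
#' Maps a single-letter IUPAC code to the set of RNA bases it denotes, e.g.
#' `N` to A/C/G/U and `H` to A/C/U. `T` is accepted as a synonym for `U`
#' (DNA input is canonicalized to the RNA alphabet throughout the package).
#'
#' @param code A single IUPAC nucleotide code (case-insensitive).
#' @return A character vector of concrete RNA bases, sorted A < C < G < U;
#'   length 1 to 4.
#' @examples
#' iupac_bases("N")
#' iupac_bases("H")
#' iupac_bases("A")
#' @export
iupac_bases <- function(code) {
  if (!is.character(code) || length(code) != 1L || is.na(code)) {
    abort("`code` must be a single IUPAC nucleotide code.")
  }
  code <- toupper(code)
  if (code == "T") code <- "U"
  bases <- IUPAC_RNA[[code]]
  if (is.null(bases)) {
    abort(sprintf("Unknown IUPAC nucleotide code: '%s'.", code))
  }
  bases
}

# Canonicalize a nucleotide string to the uppercase RNA alphabet.
canonicalize_rna <- function(x) {
  chartr("acgutT", "ACGUUU", x)
}

# Reverse complement of DNA strings (vectorized).
revcomp_dna <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Split equal-length strings into a character matrix (one row per string).
seq_char_matrix <- function(x, width = NULL) {
  width <- width %||% nchar(x[1])
  matrix(unlist(strsplit(x, "", fixed = TRUE), use.names = FALSE),
         nrow = length(x), ncol = width, byrow = TRUE)
}

# Per-string mismatch counts between equal-length strings and one pattern.
mismatch_counts <- function(x, pattern) {
  n <- length(x)
  if (n == 0L) return(integer(0))
  mat <- seq_char_matrix(x, nchar(pattern))
  pat <- strsplit(pattern, "", fixed = TRUE)[[1]]
  rowSums(mat != matrix(pat, nrow = n, ncol = length(pat), byrow = TRUE))
}
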
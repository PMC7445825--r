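#' Define a degenerate library template
#'
#' A library template ties together the reference (positive-control) ribozyme
#' sequence, the degenerate loci that were randomized during library
#' synthesis, and the constant flanking sequences that surround the variable
#' cassette in sequencing reads.
#'
#' @param reference Reference RNA sequence of the positive-control ribozyme
#'   (a single string; `T` is read as `U`). Positions are 1-based.
#' @param loci A data frame with one row per degenerate locus and columns
#'   `position` (1-based index into `reference`), `code` (IUPAC code of the
#'   degenerate base synthesized at that locus) and, optionally, `ca_code`
#'   (IUPAC code describing the constitutively active genotype at that locus;
#'   all `NA` disables the CA class). The reference base at each position is
#'   taken as the positive-control genotype.
#' @param flank5,flank3 Constant DNA sequences flanking the variable cassette
#'   in reads (used for anchored trimming; may be empty strings).
#' @param catalytic_position Position whose reference base is required for
#'   catalysis; variants carrying any other base there are classified
#'   inactive. Must be one of the loci positions (or `NA` to disable the
#'   inactive rule).
#' @return An object of class `library_template`: a list with elements
#'   `reference`, `loci` (tibble with `position`, `code`, `pc_base`,
#'   `ca_code`), `flank5`, `flank3`, `catalytic_position`.
#' @seealso [control_template()] for the built-in theophylline-ribozyme
#'   control-library template.
#' @export
library_template <- function(reference, loci, flank5 = "", flank3 = "",
                             catalytic_position = NA_integer_) {
  if (!is.character(reference) || length(reference) != 1L) {
    abort("`reference` must be a single nucleotide string.")
  }
  reference <- canonicalize_rna(toupper(reference))
  if (grepl("[^ACGU]", reference)) {
    abort("`reference` may only contain A, C, G, U (or T).")
  }
  loci <- as_tibble(loci)
  if (!all(c("position", "code") %in% names(loci))) {
    abort("`loci` must have columns `position` and `code`.")
  }
  if (!"ca_code" %in% names(loci)) loci$ca_code <- NA_character_
  loci$position <- as.integer(loci$position)
  if (any(loci$position < 1L) || any(loci$position > nchar(reference))) {
    abort("All loci positions must fall within the reference sequence.")
  }
  if (is.unsorted(loci$position, strictly = TRUE)) {
    abort("Loci positions must be strictly increasing.")
  }
  loci$code <- toupper(loci$code)
  for (code in loci$code) iupac_bases(code)  # validates
  loci$pc_base <- vapply(loci$position, function(p) substr(reference, p, p),
                         character(1))
  ok <- purrr::map2_lgl(loci$pc_base, loci$code,
                        ~ .x %in% iupac_bases(.y))
  if (!all(ok)) {
    abort("Each reference base must be contained in its locus's IUPAC code.")
  }
  if (!is.na(catalytic_position) &&
      !catalytic_position %in% loci$position) {
    abort("`catalytic_position` must be one of the loci positions.")
  }
  structure(
    list(
      reference = reference,
      loci = loci[, c("position", "code", "pc_base", "ca_code")],
      flank5 = toupper(flank5),
      flank3 = toupper(flank3),
      catalytic_position = as.integer(catalytic_position)
    ),
    class = "library_template"
  )
}

#' @export
print.library_template <- function(x, ...) {
  cat("<library_template>\n")
  cat("  reference: ", nchar(x$reference), " nt\n", sep = "")
  cat("  loci:      ", paste(x$loci$position, collapse = ", "), "\n", sep = "")
  cat("  PC bases:  ", paste(x$loci$pc_base, collapse = ""), "\n", sep = "")
  cat("  flanks:    ", nchar(x$flank5), " nt / ", nchar(x$flank3), " nt\n",
      sep = "")
  invisible(x)
}

# Synthetic stand-in reference for the control library. The published
# full-length sequence is not reproduced here; this 110-nt surrogate carries
# the design's constraints -- PC genotype C/C/U/C/G at the degenerate loci
# 52/63/73/74/81, the fixed C at position 76 required by the inactive rule,
# and A at position 68 so that A68U-style off-template labels arise. All
# combinatorial logic depends only on the loci, not on the surrounding bases.
CONTROL_REFERENCE <- paste0(
  "CAACCUAAUGCCGCGACAAAACGGCCCGUCGACAGCCGAGACGACUGAUU",
  "ACCACAAACGGUCAUGAAUGUAUCACCACCGAAAGGCGCGAUCUACUGGG",
  "CUACCGUCGC"
)

#' The built-in control-library template
#'
#' A 1024-member degenerate library built around a theophylline-activated
#' hammerhead ribozyme. Five loci (positions 52, 63, 73, 74, 81) were fully
#' randomized (`N`); the positive control (PC) genotype is C, C, U, C, G.
#' Variants lacking G at position 81 are catalytically inactive (3/4 of the
#' library), while a D/U/C/A/G genotype pattern yields three constitutively
#' active (CA) sequences that cleave regardless of ligand.
#'
#' The reference sequence shipped here is a synthetic stand-in that satisfies
#' the design's positional constraints (see source); classification and all
#' enumeration results depend only on the loci, so they are unaffected by the
#' surrounding bases. The flanks are synthetic constant adapters (the 5'
#' flank ends in a T7 promoter-like motif).
#'
#' @param flank5,flank3 Override the constant flanking DNA sequences.
#' @return A [library_template()] object.
#' @examples
#' tpl <- control_template()
#' tpl$loci
#' @export
control_template <- function(flank5 = "ACTAATACGACTCACTATAGGG",
                             flank3 = "CTGCAGGCATGCAAGCTTGG") {
  library_template(
    reference = CONTROL_REFERENCE,
    loci = tibble(
      position = c(52L, 63L, 73L, 74L, 81L),
      code = c("N", "N", "N", "N", "N"),
      ca_code = c("D", "U", "C", "A", "G")
    ),
    flank5 = flank5,
    flank3 = flank3,
    catalytic_position = 81L
  )
}

# Full variable-cassette sequence (RNA) for a variant id under a template.
variant_sequence <- function(variant_id, template) {
  parsed <- parse_variant_id(variant_id)
  ref <- strsplit(template$reference, "", fixed = TRUE)[[1]]
  vapply(parsed, function(p) {
    s <- ref
    s[template$loci$position] <- strsplit(p$locus_bases, "", fixed = TRUE)[[1]]
    for (m in p$off_template) {
      pos <- as.integer(gsub("[ACGU]", "", m))
      alt <- substr(m, nchar(m), nchar(m))
      s[pos] <- alt
    }
    paste(s, collapse = "")
  }, character(1))
}

# Parse "CCUCG" / "CCGAG+A68U+..." variant ids into genotype components.
parse_variant_id <- function(variant_id) {
  lapply(strsplit(variant_id, "+", fixed = TRUE), function(parts) {
    list(locus_bases = parts[1],
         off_template = if (length(parts) > 1L) parts[-1] else character(0))
  })
}

make_variant_id <- function(locus_bases, off_template) {
  ifelse(off_template == "" | is.na(off_template),
         locus_bases,
         paste(locus_bases, gsub(",", "+", off_template), sep = "+"))
}
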
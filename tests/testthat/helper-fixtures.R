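# Small fixtures built in code; all synthetic.

# Two-locus, 16-member toy library: positions 3 and 8 are N, the reference
# carries G at both, position 8 is catalytic (non-G there -> INACTIVE) and
# the CA pattern is D at 3 / G at 8. Partition: 1 PC, 12 INACTIVE, 2 CA,
# 1 OTHER.
mini_template <- function() {
  library_template(
    reference = "ACGUCAUGGA",
    loci = tibble::tibble(position = c(3L, 8L), code = c("N", "N"),
                          ca_code = c("D", "G")),
    flank5 = "ACGT",
    flank3 = "TTGCA",
    catalytic_position = 8L
  )
}

# One-locus, two-member template (Y at position 3: C or U) for tiny
# generator experiments; no inactive/CA structure.
two_variant_template <- function() {
  library_template(
    reference = "ACCUCAUGGA",
    loci = tibble::tibble(position = 3L, code = "Y"),
    flank5 = "ACGT",
    flank3 = "TTGCA",
    catalytic_position = NA_integer_
  )
}

# DNA read (flank5 + cassette + flank3) for a variant id under a template.
read_for_variant <- function(variant_id, template) {
  cassette <- chartr("U", "T",
                     riboselect:::variant_sequence(variant_id, template))
  paste0(template$flank5, cassette, template$flank3)
}

# Write a FASTQ of the given DNA reads with uniform Q30 qualities.
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads)
  names(x) <- sprintf("read%05d", seq_along(reads))
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(rep(strrep("?", nchar(reads[1])),
                                           length(reads))))
  path
}

# Random valid pool over n variants.
random_pool <- function(n, ids = sprintf("v%02d", seq_len(n))) {
  f <- stats::runif(n)
  tibble::tibble(variant_id = ids, frequency = f / sum(f))
}

random_profiles <- function(ids) {
  tibble::tibble(variant_id = ids,
                 r_plus = stats::runif(length(ids)),
                 r_minus = stats::runif(length(ids)))
}
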
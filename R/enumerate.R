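#' Enumerate a degenerate library
#'
#' Expands the Cartesian product of the IUPAC base sets at each degenerate
#' locus of a template into the full set of library members, in
#' deterministic lexicographic order (A < C < G < U, first locus slowest).
#'
#' @param template A [library_template()].
#' @return A tibble with one row per library member and columns `variant_id`
#'   (the concatenated locus bases, e.g. `"CCUCG"`), `locus_bases` and
#'   `off_template` (empty string: enumerated members have no off-template
#'   substitutions).
#' @examples
#' nrow(enumerate_variants(control_template()))  # 1024
#' @export
enumerate_variants <- function(template) {
  stopifnot(inherits(template, "library_template"))
  base_sets <- lapply(template$loci$code, iupac_bases)
  names(base_sets) <- paste0("locus_", template$loci$position)
  grid <- tidyr::expand_grid(!!!base_sets)
  locus_bases <- purrr::reduce(grid, paste0)
  tibble(
    variant_id = locus_bases,
    locus_bases = locus_bases,
    off_template = ""
  )
}

#' Classify library variants by phenotype
#'
#' Assigns each variant one of five mutually exclusive phenotype classes,
#' applying the control-library design rules in order:
#'
#' 1. `OFF_TEMPLATE` -- any substitution outside the degenerate loci
#'    (synthesis or PCR error relative to the designed library);
#' 2. `INACTIVE` -- the base at the catalytic locus (position 81 in the
#'    built-in template) differs from the reference G, abolishing catalysis;
#' 3. `PC` -- the positive-control genotype (all loci equal the reference);
#' 4. `CA` -- constitutively active: matches the template's CA genotype
#'    pattern (D/U/C/A/G in the built-in template), i.e. the ligand-sensing
#'    C at position 52 is lost while a catalytically active conformation is
#'    hard-wired;
#' 5. `OTHER` -- everything else.
#'
#' @param variants A data frame with columns `locus_bases` and (optionally)
#'   `off_template`, as returned by [enumerate_variants()] or
#'   [genotype_from_sequence()].
#' @param template A [library_template()].
#' @return The input tibble with a `class` factor column added (levels
#'   `PC`, `INACTIVE`, `CA`, `OTHER`, `OFF_TEMPLATE`).
#' @examples
#' library(dplyr)
#' enumerate_variants(control_template()) |>
#'   classify_variants(control_template()) |>
#'   count(class)
#' @export
classify_variants <- function(variants, template) {
  stopifnot(inherits(template, "library_template"))
  variants <- as_tibble(variants)
  if (is.null(variants$off_template)) variants$off_template <- ""
  n_loci <- nrow(template$loci)
  if (any(nchar(variants$locus_bases) != n_loci)) {
    abort("`locus_bases` must have one base per template locus.")
  }
  mat <- seq_char_matrix(variants$locus_bases, n_loci)

  off <- !(variants$off_template %in% c("", NA))
  cls <- rep("OTHER", nrow(variants))

  if (!is.na(template$catalytic_position)) {
    i_cat <- match(template$catalytic_position, template$loci$position)
    inactive <- mat[, i_cat] != template$loci$pc_base[i_cat]
  } else {
    inactive <- rep(FALSE, nrow(variants))
  }
  pc <- rowSums(mat != matrix(template$loci$pc_base, nrow(variants),
                              n_loci, byrow = TRUE)) == 0L
  if (all(is.na(template$loci$ca_code))) {
    ca <- rep(FALSE, nrow(variants))
  } else {
    ca_ok <- vapply(seq_len(n_loci), function(j) {
      mat[, j] %in% iupac_bases(template$loci$ca_code[j])
    }, logical(nrow(variants)))
    ca_ok <- matrix(ca_ok, nrow = nrow(variants))
    ca <- rowSums(!ca_ok) == 0L
  }

  cls[ca] <- "CA"
  cls[pc] <- "PC"
  cls[inactive] <- "INACTIVE"
  cls[off] <- "OFF_TEMPLATE"
  variants$class <- factor(cls, levels = phenotype_classes())
  variants
}

#' @rdname classify_variants
#' @export
phenotype_classes <- function() {
  c("PC", "INACTIVE", "CA", "OTHER", "OFF_TEMPLATE")
}

#' Extract variant genotypes from cassette sequences
#'
#' Aligns each variable-cassette sequence end-to-end against the template
#' reference (equal length; `T` is read as `U`), reads off the bases at the
#' degenerate loci, and records every other mismatch as an off-template
#' substitution named by the field convention reference-base + position +
#' alternate base (e.g. `"A68U"`).
#'
#' @param seqs Character vector of cassette sequences (DNA or RNA).
#' @param template A [library_template()].
#' @param max_off_template Reads with more than this many off-template
#'   mismatches are rejected (status `"too_many_mismatches"`).
#' @return A tibble with columns `sequence`, `status` (`"ok"`,
#'   `"length_mismatch"` or `"too_many_mismatches"`), `locus_bases`,
#'   `off_template` (comma-separated labels, `""` if none), `n_off_template`
#'   and `variant_id` (`locus_bases`, plus `+label` suffixes for
#'   off-template substitutions). Non-`"ok"` rows carry `NA` genotypes.
#' @examples
#' tpl <- control_template()
#' genotype_from_sequence(tpl$reference, tpl)$variant_id  # "CCUCG"
#' @export
genotype_from_sequence <- function(seqs, template, max_off_template = 2L) {
  stopifnot(inherits(template, "library_template"))
  seqs_canon <- canonicalize_rna(toupper(seqs))
  ref_len <- nchar(template$reference)
  n <- length(seqs_canon)

  out <- tibble(
    sequence = seqs,
    status = rep("ok", n),
    locus_bases = NA_character_,
    off_template = NA_character_,
    n_off_template = NA_integer_,
    variant_id = NA_character_
  )
  bad_len <- nchar(seqs_canon) != ref_len |
    grepl("[^ACGU]", seqs_canon)
  out$status[bad_len] <- "length_mismatch"
  idx <- which(!bad_len)
  if (length(idx) == 0L) return(out)

  mat <- seq_char_matrix(seqs_canon[idx], ref_len)
  ref <- strsplit(template$reference, "", fixed = TRUE)[[1]]
  mm <- mat != matrix(ref, length(idx), ref_len, byrow = TRUE)

  loci_pos <- template$loci$position
  locus_bases <- apply(mat[, loci_pos, drop = FALSE], 1, paste, collapse = "")

  mm[, loci_pos] <- FALSE  # locus substitutions are not off-template
  n_off <- rowSums(mm)
  too_many <- n_off > max_off_template
  out$status[idx[too_many]] <- "too_many_mismatches"

  labels <- rep("", length(idx))
  has_off <- which(n_off > 0L & !too_many)
  if (length(has_off) > 0L) {
    hits <- which(mm[has_off, , drop = FALSE], arr.ind = TRUE)
    lab <- paste0(ref[hits[, "col"]], hits[, "col"],
                  mat[cbind(has_off[hits[, "row"]], hits[, "col"])])
    ord <- order(hits[, "row"], hits[, "col"])
    grp <- factor(hits[ord, "row"], levels = seq_along(has_off))
    labels[has_off] <- vapply(
      split(lab[ord], grp),
      paste, character(1), collapse = ","
    )
  }

  keep <- idx[!too_many]
  out$locus_bases[keep] <- locus_bases[!too_many]
  out$off_template[keep] <- labels[!too_many]
  out$n_off_template[keep] <- as.integer(n_off[!too_many])
  out$variant_id[keep] <- make_variant_id(out$locus_bases[keep],
                                          out$off_template[keep])
  out
}

#' Mutation distance between two variants
#'
#' Hamming distance over the degenerate loci plus the size of the symmetric
#' difference of the off-template substitution sets. The positive control
#' and an A68U/U73G/C74A triple mutant, for instance, are at distance 3
#' (two locus substitutions plus one off-template substitution).
#'
#' @param a,b Variant ids (as produced by [enumerate_variants()] or
#'   [genotype_from_sequence()]); vectorized and recycled.
#' @return Integer vector of distances.
#' @examples
#' mutation_distance("CCUCG", "CAUCG")        # 1 (C63A)
#' mutation_distance("CCUCG", "CCGAG+A68U")   # 3
#' @export
mutation_distance <- function(a, b) {
  pa <- parse_variant_id(a)
  pb <- parse_variant_id(b)
  n <- max(length(pa), length(pb))
  pa <- rep_len(pa, n)
  pb <- rep_len(pb, n)
  purrr::map2_int(pa, pb, function(x, y) {
    if (nchar(x$locus_bases) != nchar(y$locus_bases)) {
      abort("Variants must come from the same template (equal loci count).")
    }
    ham <- sum(strsplit(x$locus_bases, "", fixed = TRUE)[[1]] !=
                 strsplit(y$locus_bases, "", fixed = TRUE)[[1]])
    sym <- length(union(x$off_template, y$off_template)) -
      length(intersect(x$off_template, y$off_template))
    as.integer(ham + sym)
  })
}

#' Sequencing coverage of a library
#'
#' Fold coverage of a library at a given read depth, the read count divided
#' by the number of library members (16,600 reads over a 1024-member
#' library is 16-fold coverage).
#'
#' @param depth Number of retained reads.
#' @param library_size Number of library members.
#' @return `depth / library_size`.
#' @export
coverage_fold <- function(depth, library_size) {
  stopifnot(library_size > 0)
  depth / library_size
}
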
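# Round labels: "initial", then "1+", "1-", "2+", ... ordered
# initial < 1+ < 1- < 2+ < ...
round_label <- function(cycle, polarity) {
  ifelse(polarity == "initial", "initial", paste0(cycle, polarity))
}

#' Total order of selection rounds
#'
#' Maps round labels to sortable integers: `initial` = 0, then each cycle's
#' positive step before its negative step (`1+` = 1, `1-` = 2, `2+` = 3, ...).
#'
#' @param cycle Integer cycle index (0 for the initial pool).
#' @param polarity `"initial"`, `"+"` or `"-"`.
#' @return Integer round index.
#' @export
round_index <- function(cycle, polarity) {
  ifelse(polarity == "initial", 0L,
         2L * as.integer(cycle) - (polarity == "+"))
}

#' Merge one overlapping read pair
#'
#' Minimal ungapped merger for overlapping paired-end amplicon reads: the
#' reverse read is reverse-complemented and the overlap maximizing
#' matches − mismatches (among overlaps of at least `min_overlap` bases
#' whose mismatch fraction is at most `max_mismatch_frac`) is chosen.
#' Disagreements within the overlap are resolved toward the base with the
#' higher Phred quality; ties (or absent qualities) become `N`.
#'
#' @param fwd,rev Forward read and reverse read (as sequenced, i.e. the
#'   reverse read is complementary to the template's other strand).
#' @param fwd_qual,rev_qual Optional Phred+33 quality strings.
#' @param min_overlap Minimum acceptable overlap length.
#' @param max_mismatch_frac Maximum mismatch fraction within the overlap.
#' @return The merged sequence, or `NA_character_` when no acceptable
#'   overlap exists.
#' @examples
#' merge_pairs("ACGTACGTACGTACGTACGTAAAA", "GGGGACGTACGTACGTACGTACGT",
#'             min_overlap = 10)
#' @export
merge_pairs <- function(fwd, rev, fwd_qual = NULL, rev_qual = NULL,
                        min_overlap = 10L, max_mismatch_frac = 0.1) {
  stopifnot(nchar(fwd) > 0, nchar(rev) > 0)
  rc <- revcomp_dna(rev)
  rc_qual <- if (!is.null(rev_qual)) {
    paste(rev(strsplit(rev_qual, "", fixed = TRUE)[[1]]), collapse = "")
  }
  nf <- nchar(fwd)
  nr <- nchar(rc)
  fchr <- strsplit(fwd, "", fixed = TRUE)[[1]]
  rchr <- strsplit(rc, "", fixed = TRUE)[[1]]
  fq <- if (!is.null(fwd_qual)) utf8ToInt(fwd_qual) else rep(0L, nf)
  rq <- if (!is.null(rc_qual)) utf8ToInt(rc_qual) else rep(0L, nr)

  best <- NULL
  best_score <- -Inf
  for (L in seq(min(nf, nr), min_overlap)) {
    f_idx <- (nf - L + 1):nf
    r_idx <- 1:L
    mm <- fchr[f_idx] != rchr[r_idx]
    n_mm <- sum(mm)
    if (n_mm / L > max_mismatch_frac) next
    score <- (L - n_mm) - n_mm
    if (score > best_score) {
      best_score <- score
      best <- list(L = L, mm = mm)
    }
  }
  if (is.null(best)) return(NA_character_)

  L <- best$L
  overlap <- rchr[1:L]
  f_part <- fchr[(nf - L + 1):nf]
  qf <- fq[(nf - L + 1):nf]
  qr <- rq[1:L]
  take_f <- best$mm & qf > qr
  tie <- best$mm & qf == qr
  overlap[take_f] <- f_part[take_f]
  overlap[tie] <- "N"
  paste0(
    if (nf > L) substr(fwd, 1, nf - L) else "",
    paste(overlap, collapse = ""),
    if (nr > L) substr(rc, L + 1, nr) else ""
  )
}

#' Extract variable cassettes by anchored flank trimming
#'
#' Locates the constant 5' and 3' flanks of the template at the ends of each
#' read (allowing up to `max_flank_mismatches` mismatches per flank), trying
#' the reverse-complement orientation when the forward orientation fails,
#' and returns the enclosed variable cassette.
#'
#' @param reads Character vector of merged reads (DNA).
#' @param template A [library_template()] with non-empty flanks.
#' @param max_flank_mismatches Per-flank mismatch tolerance.
#' @return A tibble with columns `read`, `status` (`"ok"`, `"length"`,
#'   `"flank"`, or `"ambiguous"` for cassettes containing `N`) and
#'   `cassette` (`NA` unless `"ok"`).
#' @export
trim_flanks <- function(reads, template, max_flank_mismatches = 1L) {
  stopifnot(inherits(template, "library_template"))
  f5 <- template$flank5
  f3 <- template$flank3
  n5 <- nchar(f5)
  n3 <- nchar(f3)
  ncas <- nchar(template$reference)
  expected <- n5 + ncas + n3

  status <- rep("ok", length(reads))
  cassette <- rep(NA_character_, length(reads))

  reads_u <- toupper(reads)
  len_ok <- nchar(reads_u) == expected
  status[!len_ok] <- "length"

  try_orient <- function(x) {
    mm5 <- if (n5 > 0) mismatch_counts(substr(x, 1, n5), f5) else 0L
    mm3 <- if (n3 > 0) {
      mismatch_counts(substr(x, expected - n3 + 1, expected), f3)
    } else 0L
    mm5 <= max_flank_mismatches & mm3 <= max_flank_mismatches
  }

  idx <- which(len_ok)
  if (length(idx) > 0) {
    fwd_ok <- try_orient(reads_u[idx])
    cassette[idx[fwd_ok]] <- substr(reads_u[idx[fwd_ok]], n5 + 1, n5 + ncas)
    rest <- idx[!fwd_ok]
    if (length(rest) > 0) {
      rc <- revcomp_dna(reads_u[rest])
      rc_ok <- try_orient(rc)
      cassette[rest[rc_ok]] <- substr(rc[rc_ok], n5 + 1, n5 + ncas)
      status[rest[!rc_ok]] <- "flank"
    }
  }

  amb <- !is.na(cassette) & grepl("N", cassette, fixed = TRUE)
  status[amb] <- "ambiguous"
  cassette[amb] <- NA_character_
  tibble(read = reads, status = status, cassette = cassette)
}

#' Count library variants across selection rounds
#'
#' Runs each round's FASTQ through flank trimming and genotype extraction
#' and tallies reads per variant. Reads failing trimming or carrying more
#' than `max_off_template` substitutions outside the degenerate loci are
#' rejected; per-round rejection reasons are kept in the `"rejects"`
#' attribute. Counting is invariant to read order and strand orientation.
#'
#' @param manifest A data frame with columns `file` (FASTQ path,
#'   optionally gzipped), `cycle`, `polarity` (`"initial"`, `"+"`, `"-"`),
#'   one row per round.
#' @param template A [library_template()].
#' @param max_off_template Passed to [genotype_from_sequence()].
#' @param max_flank_mismatches Passed to [trim_flanks()].
#' @return A `count_table` tibble with columns `round`, `round_idx`,
#'   `cycle`, `polarity`, `variant_id`, `count`. Per-round counts sum to
#'   the retained depth; see [count_rejects()] and [round_depths()].
#' @export
count_variants <- function(manifest, template, max_off_template = 2L,
                           max_flank_mismatches = 1L) {
  manifest <- as_tibble(manifest)
  if (!all(c("file", "cycle", "polarity") %in% names(manifest))) {
    abort("`manifest` needs columns `file`, `cycle`, `polarity`.")
  }
  rounds <- purrr::pmap(manifest, function(file, cycle, polarity, ...) {
    label <- round_label(cycle, polarity)
    reads <- as.character(Biostrings::readDNAStringSet(file, format = "fastq"))
    if (length(reads) == 0) {
      warn(sprintf("Round %s has zero reads.", label))
    }
    trimmed <- trim_flanks(reads, template, max_flank_mismatches)
    rejects <- dplyr::count(trimmed[trimmed$status != "ok", ],
                            .data$status, name = "n")
    cass <- trimmed$cassette[trimmed$status == "ok"]
    tab <- table(cass)
    geno <- genotype_from_sequence(names(tab), template, max_off_template)
    bad <- geno$status != "ok"
    if (any(bad)) {
      rejects <- dplyr::bind_rows(
        rejects,
        dplyr::count(tibble(status = rep(geno$status[bad],
                                         as.integer(tab[bad]))),
                     .data$status, name = "n"))
    }
    counts <- tibble(variant_id = geno$variant_id[!bad],
                     count = as.integer(tab[!bad])) |>
      dplyr::summarise(count = sum(.data$count), .by = "variant_id") |>
      dplyr::arrange(dplyr::desc(.data$count), .data$variant_id)
    list(
      counts = dplyr::mutate(counts, round = label,
                             round_idx = round_index(cycle, polarity),
                             cycle = as.integer(cycle), polarity = polarity),
      rejects = dplyr::mutate(rejects, round = label)
    )
  })
  out <- dplyr::bind_rows(purrr::map(rounds, "counts"))
  out <- out[, c("round", "round_idx", "cycle", "polarity",
                 "variant_id", "count")]
  out <- dplyr::arrange(out, .data$round_idx, dplyr::desc(.data$count),
                        .data$variant_id)
  attr(out, "rejects") <- dplyr::bind_rows(purrr::map(rounds, "rejects"))
  class(out) <- c("count_table", class(out))
  out
}

#' @rdname count_variants
#' @param counts A `count_table`.
#' @export
count_rejects <- function(counts) {
  attr(counts, "rejects") %||% tibble(round = character(),
                                      status = character(), n = integer())
}

#' @rdname count_variants
#' @export
round_depths <- function(counts) {
  dplyr::summarise(as_tibble(counts), depth = sum(.data$count),
                   .by = dplyr::all_of(c("round", "round_idx", "cycle",
                                         "polarity")))
}

#' Per-round variant frequencies
#'
#' Converts a count table to frequencies; within each round, frequencies
#' sum to 1.
#'
#' @param counts A `count_table` (or any data frame with `round` and
#'   `count` columns).
#' @return The input with a `frequency` column added.
#' @export
variant_frequencies <- function(counts) {
  counts <- as_tibble(counts)
  dplyr::mutate(counts, frequency = .data$count / sum(.data$count),
                .by = "round")
}
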
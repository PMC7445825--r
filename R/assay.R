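#' Relative molar amount from a gel band
#'
#' Band fluorescence is proportional to mass; dividing the intensity by the
#' species length (in nucleotides, the molecular-weight proxy: per-base
#' masses differ by < 2% and the shared per-nucleotide constant cancels in
#' ratios) gives a relative molar amount.
#'
#' @param intensity Band intensity in arbitrary fluorescence units (>= 0).
#' @param length_nt Species length in nucleotides (> 0).
#' @return `intensity / length_nt`, vectorized.
#' @examples
#' molar_amount(1000, 100)  # 10
#' @export
molar_amount <- function(intensity, length_nt) {
  if (any(length_nt <= 0)) abort("`length_nt` must be > 0.")
  if (any(intensity < 0)) abort("`intensity` must be >= 0.")
  intensity / length_nt
}

#' Cleaved molar fraction from a pair of bands
#'
#' \eqn{r = C / (C + F)} where `C` and `F` are the molar amounts of the
#' cleaved and full-length species in one lane. Invariant under any common
#' rescaling of both intensities (imager gain cancels).
#'
#' @param cleaved_intensity,full_intensity Band intensities.
#' @param cleaved_length,full_length Species lengths in nucleotides.
#' @return Cleaved fraction in `[0, 1]`, vectorized.
#' @examples
#' cleaved_fraction(600, 60, 1000, 100)   # 0.5: equal molarity
#' cleaved_fraction(600, 60, 3000, 100)   # 0.25
#' @export
cleaved_fraction <- function(cleaved_intensity, cleaved_length,
                             full_intensity, full_length) {
  mc <- molar_amount(cleaved_intensity, cleaved_length)
  mf <- molar_amount(full_intensity, full_length)
  if (any(mc + mf == 0)) {
    abort("Both bands have zero molar amount: cleaved fraction undefined.")
  }
  mc / (mc + mf)
}

#' Cleaved fractions from a band-intensity table
#'
#' Reduces a tidy gel table (one row per band) to one cleaved fraction per
#' reaction, pairing the `cleaved` and `full_length` species within each
#' `condition_label` x `theophylline_mM` combination. Fractions that land
#' outside `[0, 1]` after noise are clipped with a warning.
#'
#' @param bands A data frame with columns `condition_label`,
#'   `theophylline_mM`, `species` (`"cleaved"` / `"full_length"`),
#'   `intensity`, `length_nt`; extra columns (e.g. `time_min`) are carried
#'   through.
#' @return A tibble with one row per reaction and columns `condition_label`,
#'   `theophylline_mM`, `r`, plus any carried columns.
#' @export
band_fractions <- function(bands) {
  bands <- as_tibble(bands)
  need <- c("condition_label", "theophylline_mM", "species", "intensity",
            "length_nt")
  if (!all(need %in% names(bands))) {
    abort(paste("`bands` needs columns:", paste(need, collapse = ", ")))
  }
  if (!all(bands$species %in% c("cleaved", "full_length"))) {
    abort("`species` must be 'cleaved' or 'full_length'.")
  }
  carry <- setdiff(names(bands), c("species", "intensity", "length_nt",
                                   "lane_id"))
  if (any(bands$length_nt <= 0)) abort("`length_nt` must be > 0.")
  out <- bands |>
    # negative intensities (noise below baseline) are tolerated here and
    # handled by clipping the resulting fraction
    dplyr::mutate(molar = .data$intensity / .data$length_nt) |>
    dplyr::summarise(
      r = sum(.data$molar[.data$species == "cleaved"]) /
        sum(.data$molar),
      .by = dplyr::all_of(carry)
    )
  clip <- out$r < 0 | out$r > 1
  if (any(clip, na.rm = TRUE)) {
    warn(sprintf("%d cleaved fraction(s) outside [0, 1] clipped.", sum(clip)))
    out$r <- pmin(pmax(out$r, 0), 1)
  }
  out
}

#' Fitness scan over matched selection conditions
#'
#' Pairs positive-condition (`theophylline_mM > 0`) and negative-condition
#' (`theophylline_mM == 0`) cleaved fractions by `condition_label` and
#' applies the fitness metric \eqn{r^{(+)}(1 - r^{(-)})} to each pair.
#'
#' @param fractions Output of [band_fractions()] (columns
#'   `condition_label`, `theophylline_mM`, `r`; `time_min` carried through
#'   if present).
#' @return A `fitness_scan` tibble with columns `condition_label`
#'   (plus `time_min` if present), `r_plus`, `r_minus`, `fitness`.
#' @export
fitness_scan <- function(fractions) {
  fractions <- as_tibble(fractions)
  pos <- fractions[fractions$theophylline_mM > 0, ]
  neg <- fractions[fractions$theophylline_mM == 0, ]
  if (any(duplicated(pos$condition_label)) ||
      any(duplicated(neg$condition_label))) {
    abort("Multiple measurements per condition_label and polarity.")
  }
  unmatched <- union(setdiff(pos$condition_label, neg$condition_label),
                     setdiff(neg$condition_label, pos$condition_label))
  if (length(unmatched) > 0) {
    abort(sprintf("Unpaired condition(s): %s.",
                  paste(unmatched, collapse = ", ")))
  }
  keys <- intersect(c("condition_label", "time_min", "mode"),
                    names(fractions))
  out <- dplyr::inner_join(
    dplyr::rename(pos[, c(keys, "r")], r_plus = "r"),
    dplyr::rename(neg[, c(keys, "r")], r_minus = "r"),
    by = keys
  )
  out$fitness <- fitness(out$r_plus, out$r_minus)
  class(out) <- c("fitness_scan", class(out))
  out
}

#' Pick the optimal selection condition
#'
#' Returns the condition with maximal fitness; ties are broken by shortest
#' incubation time (`time_min`, if present) to minimize background-cleavage
#' exposure. Permutation-invariant over the scan rows.
#'
#' @param scan A [fitness_scan()] result (columns `condition_label`,
#'   `fitness`, optionally `time_min`).
#' @return The winning `condition_label` (length-1 character).
#' @export
select_optimal_condition <- function(scan) {
  scan <- as_tibble(scan)
  if (nrow(scan) == 0) abort("Empty condition scan.")
  if ("time_min" %in% names(scan)) {
    scan <- dplyr::arrange(scan, dplyr::desc(.data$fitness), .data$time_min,
                           .data$condition_label)
  } else {
    scan <- dplyr::arrange(scan, dplyr::desc(.data$fitness),
                           .data$condition_label)
  }
  scan$condition_label[1]
}

#' Percent change between two values
#'
#' `100 * (to - from) / from`; a drop from fitness 0.73 to 0.15 is -79.5%.
#'
#' @param from,to Numeric vectors (recycled).
#' @return Percent change.
#' @export
percent_change <- function(from, to) {
  100 * (to - from) / from
}
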
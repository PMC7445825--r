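#' Cleaved fraction accumulated during transcription
#'
#' Co-transcriptional cleavage model behind the gel-scan generator: RNA is
#' synthesized at a constant rate over the reaction time `T`, and each
#' molecule then self-cleaves as a first-order process with rate constant
#' `k` (per minute). The population cleaved fraction at harvest is
#' \deqn{r(T) = 1 - \frac{1 - e^{-kT}}{kT},}
#' which is 0 at `k = 0`, strictly increasing in both `k` and `T`, and
#' approaches 1 as `kT` grows. In a combined transcription/reverse
#' transcription (TRT) reaction, partial reverse transcription attenuates
#' ribozyme activity after `tau` minutes, so the effective exposure is
#' `min(T, tau)` and the response becomes independent of incubation time
#' once `T >= tau`.
#'
#' @param k First-order cleavage rate constant (per minute, >= 0);
#'   vectorized.
#' @param time Reaction time in minutes (> 0); vectorized.
#' @param tau Attenuation time in minutes (`Inf` for plain in vitro
#'   transcription).
#' @return Cleaved fraction in `[0, 1)`.
#' @examples
#' transcription_cleavage_fraction(0.1, 10)  # 1 - (1 - exp(-1)) = 0.3679
#' @export
transcription_cleavage_fraction <- function(k, time, tau = Inf) {
  stopifnot(all(k >= 0), all(time > 0), all(tau > 0))
  t_eff <- pmin(time, tau)
  x <- k * t_eff
  r <- ifelse(x < 1e-8, x / 2, 1 + expm1(-x) / x)
  pmin(pmax(r, 0), 1)
}

#' Phenotype-conditional cleavage-profile distributions
#'
#' Defaults encode the control-library design: inactive variants barely
#' cleave under either condition (Beta(2, 150); ~1.3% residual cleavage),
#' constitutively active variants cleave nearly completely regardless of
#' ligand (Beta(150, 2); ~98.7%), so both classes have fitness ~0; the
#' positive control is fixed at its measured operating point (saturating
#' cleavage 0.8595 with ligand, background 0.1274 without, fitness ~0.75);
#' the remaining genotypes get broad Beta(2, 3) draws (partial, variably
#' leaky switches - some of which can rival the positive control, as
#' observed in real selections).
#'
#' @param pc_r_plus,pc_r_minus Fixed positive-control profile.
#' @param inactive_r_plus,inactive_r_minus,ca_r_plus,ca_r_minus,other_r_plus,other_r_minus
#'   Length-2 `c(shape1, shape2)` Beta parameters per class; off-template
#'   variants use the `other` distributions.
#' @return A `profile_spec` list.
#' @export
profile_spec <- function(pc_r_plus = 0.8595, pc_r_minus = 0.1274,
                         inactive_r_plus = c(2, 150),
                         inactive_r_minus = c(2, 150),
                         ca_r_plus = c(150, 2), ca_r_minus = c(150, 2),
                         other_r_plus = c(2, 3), other_r_minus = c(2, 3)) {
  spec <- list(
    pc = c(r_plus = pc_r_plus, r_minus = pc_r_minus),
    INACTIVE = list(r_plus = inactive_r_plus, r_minus = inactive_r_minus),
    CA = list(r_plus = ca_r_plus, r_minus = ca_r_minus),
    OTHER = list(r_plus = other_r_plus, r_minus = other_r_minus)
  )
  structure(spec, class = "profile_spec")
}

#' Draw cleavage profiles for classified variants
#'
#' Samples one `(r_plus, r_minus)` pair per variant from its phenotype
#' class's distribution ([profile_spec()]); the positive control is fixed
#' at the spec's operating point. Reproducible under a fixed seed.
#'
#' @param variants A classified variant table ([classify_variants()]):
#'   columns `variant_id`, `class`.
#' @param spec A [profile_spec()].
#' @param seed Optional RNG seed (global RNG state is restored on exit).
#' @return A tibble `variant_id`, `class`, `r_plus`, `r_minus`.
#' @export
sample_profiles <- function(variants, spec = profile_spec(), seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  variants <- as_tibble(variants)
  stopifnot(all(c("variant_id", "class") %in% names(variants)))
  n <- nrow(variants)
  cls <- as.character(variants$class)
  cls[cls == "OFF_TEMPLATE"] <- "OTHER"
  r_plus <- numeric(n)
  r_minus <- numeric(n)
  for (cl in c("INACTIVE", "CA", "OTHER")) {
    i <- which(cls == cl)
    if (length(i) == 0) next
    r_plus[i] <- rbeta(length(i), spec[[cl]]$r_plus[1], spec[[cl]]$r_plus[2])
    r_minus[i] <- rbeta(length(i), spec[[cl]]$r_minus[1],
                        spec[[cl]]$r_minus[2])
  }
  i <- which(cls == "PC")
  r_plus[i] <- spec$pc["r_plus"]
  r_minus[i] <- spec$pc["r_minus"]
  tibble(variant_id = variants$variant_id, class = variants$class,
         r_plus = r_plus, r_minus = r_minus)
}

# Spawn distinct single-substitution off-template variants: each picks a
# uniform parent genotype and a random substitution at a non-degenerate
# position.
spawn_off_template <- function(template, parents, n_variants) {
  ref <- strsplit(template$reference, "", fixed = TRUE)[[1]]
  free_pos <- setdiff(seq_along(ref), template$loci$position)
  out <- character(0)
  guard <- 0L
  while (length(out) < n_variants && guard < 50L) {
    need <- n_variants - length(out)
    par <- sample(parents, need, replace = TRUE)
    pos <- sample(free_pos, need, replace = TRUE)
    alt <- vapply(pos, function(p) {
      sample(setdiff(c("A", "C", "G", "U"), ref[p]), 1)
    }, character(1))
    ids <- paste0(par, "+", ref[pos], pos, alt)
    out <- unique(c(out, ids))
    guard <- guard + 1L
  }
  head(out, n_variants)
}

#' Generate a synthetic selection experiment with per-round FASTQ files
#'
#' Simulates the default control experiment end to end with known ground
#' truth: a 1024-member degenerate library (plus rare off-template
#' synthesis-error variants), five cycles of positive-then-negative
#' selection through a finite-material bottleneck, and 16,600 reads
#' sequenced per pool (the initial pool and every post-step pool) with
#' per-base substitution errors. Reads carry the template's constant flanks
#' and a uniform Q30 quality string (no downstream stage uses qualities
#' except pair merging).
#'
#' The written ground truth records, per round and variant, the true pool
#' frequency and the expected read-level frequency after the sequencing
#' error channel (`true_freq * (1 - seq_error_rate)^cassette_length`: an
#' error anywhere in the cassette moves the read to another variant id,
#' while flank errors cause variant-independent rejections that cancel in
#' frequencies).
#'
#' @param outdir Output directory (created if needed).
#' @param template A [library_template()].
#' @param profiles Optional cleavage profiles (`variant_id`, `r_plus`,
#'   `r_minus`); drawn from `spec` when `NULL`. Off-template variants
#'   missing from user profiles are drawn from the broad class.
#' @param spec A [profile_spec()] used when drawing profiles.
#' @param n_cycles Selection cycles (each one positive + one negative step).
#' @param depth Reads sequenced per round.
#' @param epsilon_pos,epsilon_neg Background survival probabilities.
#' @param n_molecules Finite pool size carried between steps.
#' @param synthesis_sub_rate Per-base substitution probability at
#'   non-degenerate positions during library synthesis; sets the total
#'   initial frequency of off-template variants.
#' @param n_synthesis_variants Number of distinct off-template variants
#'   carrying that frequency.
#' @param seq_error_rate Per-base substitution probability in reads.
#' @param seed RNG seed (required: the experiment is fully reproducible).
#' @return (Invisibly) a list with `manifest` (tibble: `file`, `cycle`,
#'   `polarity`), `truth` (per-round per-variant tibble with `true_freq`,
#'   `expected_read_freq`), `profiles`, and the file paths `manifest_file`,
#'   `truth_file`, `profiles_file` (all TSV, written under `outdir`).
#' @export
generate_round_fastqs <- function(outdir,
                                  template = control_template(),
                                  profiles = NULL,
                                  spec = profile_spec(),
                                  n_cycles = 5, depth = 16600,
                                  epsilon_pos = 1e-3, epsilon_neg = 1e-3,
                                  n_molecules = 1e6,
                                  synthesis_sub_rate = 1e-4,
                                  n_synthesis_variants = 50,
                                  seq_error_rate = 1e-3,
                                  seed = 1) {
  stopifnot(depth >= 1)
  withr::local_seed(seed)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  variants <- classify_variants(enumerate_variants(template), template)
  n_free <- nchar(template$reference) - nrow(template$loci)
  p_off <- 1 - (1 - synthesis_sub_rate)^n_free
  if (p_off > 0 && n_synthesis_variants > 0) {
    off_ids <- spawn_off_template(template, variants$variant_id,
                                  n_synthesis_variants)
    off <- genotype_from_sequence(
      chartr("U", "T", variant_sequence(off_ids, template)),
      template)
    off_tbl <- classify_variants(
      tibble(variant_id = off$variant_id, locus_bases = off$locus_bases,
             off_template = off$off_template), template)
  } else {
    off_tbl <- variants[0, ]
  }
  all_variants <- dplyr::bind_rows(variants, off_tbl)

  if (is.null(profiles)) {
    profiles <- sample_profiles(all_variants, spec)
  } else {
    profiles <- as_tibble(profiles)
    missing <- dplyr::anti_join(all_variants, profiles, by = "variant_id")
    if (nrow(missing) > 0) {
      profiles <- dplyr::bind_rows(
        profiles[, intersect(names(profiles),
                             c("variant_id", "class", "r_plus", "r_minus"))],
        sample_profiles(missing, spec))
    }
  }

  n_on <- nrow(variants)
  pool <- tibble(
    variant_id = all_variants$variant_id,
    frequency = c(rep((1 - p_off) / n_on, n_on),
                  rep(p_off / max(1, nrow(off_tbl)),
                      nrow(off_tbl)))
  )
  pool$frequency <- pool$frequency / sum(pool$frequency)

  traj <- simulate_selection(pool, profiles, n_cycles,
                             epsilon_pos = epsilon_pos,
                             epsilon_neg = epsilon_neg,
                             n_molecules = n_molecules)

  seqs_dna <- chartr("U", "T", variant_sequence(pool$variant_id, template))
  names(seqs_dna) <- pool$variant_id
  cassette_len <- nchar(template$reference)
  read_template <- paste0(template$flank5, seqs_dna, template$flank3)
  names(read_template) <- pool$variant_id
  read_len <- nchar(read_template[[1]])
  qual <- strrep("?", read_len)  # Phred+33 Q30

  pools <- split(traj, traj$step_index)
  manifest <- purrr::map_dfr(pools, function(p) {
    label <- p$step[1]
    fname <- if (label == "initial") "initial" else {
      paste0(p$cycle[1], ifelse(p$polarity[1] == "+", "pos", "neg"))
    }
    file <- file.path(outdir, sprintf("round_%02d_%s.fastq",
                                      p$step_index[1], fname))
    present <- p[p$frequency > 0, ]
    n_per <- as.vector(rmultinom(1, depth, present$frequency))
    reads <- rep(read_template[present$variant_id], n_per)
    reads <- apply_read_errors(reads, seq_error_rate)
    reads <- sample(reads)  # shuffle read order
    ids <- sprintf("%s_read%06d", gsub("[+]", "p", gsub("-", "m", label)),
                   seq_along(reads))
    stringset <- Biostrings::DNAStringSet(reads)
    names(stringset) <- ids
    Biostrings::writeXStringSet(stringset, file, format = "fastq",
                                qualities = Biostrings::BStringSet(
                                  rep(qual, length(reads))))
    tibble(file = file, cycle = p$cycle[1], polarity = p$polarity[1])
  })

  truth <- traj |>
    dplyr::left_join(all_variants[, c("variant_id", "class")],
                     by = "variant_id") |>
    dplyr::mutate(
      round = round_label(.data$cycle, .data$polarity),
      true_freq = .data$frequency,
      expected_read_freq = .data$frequency *
        (1 - seq_error_rate)^cassette_len
    ) |>
    dplyr::select(dplyr::all_of(c("round", "step_index", "cycle", "polarity",
                                  "variant_id", "class", "true_freq",
                                  "expected_read_freq")))

  manifest_file <- file.path(outdir, "manifest.tsv")
  truth_file <- file.path(outdir, "ground_truth.tsv")
  profiles_file <- file.path(outdir, "profiles.tsv")
  readr::write_tsv(manifest, manifest_file)
  readr::write_tsv(truth, truth_file)
  readr::write_tsv(profiles, profiles_file)

  invisible(list(manifest = manifest, truth = truth, profiles = profiles,
                 manifest_file = manifest_file, truth_file = truth_file,
                 profiles_file = profiles_file))
}

# Apply independent per-base substitution errors to reads.
apply_read_errors <- function(reads, rate) {
  if (rate <= 0 || length(reads) == 0) return(reads)
  read_len <- nchar(reads[1])
  n_err <- rbinom(length(reads), read_len, rate)
  hit <- which(n_err > 0)
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    pos <- sample.int(read_len, n_err[i])
    for (p in pos) {
      cur <- substr(reads[i], p, p)
      substr(reads[i], p, p) <- sample(setdiff(bases, cur), 1)
    }
  }
  reads
}

#' Generate a synthetic gel scan of cleavage time courses
#'
#' Emulates the condition-optimization experiment: the positive control is
#' transcribed for each time in `times` under positive (ligand present,
#' cleavage rate `k_plus`) and negative (no ligand, rate `k_minus`)
#' conditions, the cleaved fraction follows
#' [transcription_cleavage_fraction()], and the two species are read out as
#' gel bands (intensity = molar amount x length, with multiplicative
#' lognormal noise of coefficient of variation `gel_cv`). In `"trt"` mode,
#' partial reverse transcription attenuates cleavage after `tau` minutes.
#'
#' The default rate constants (`k_plus` = 2/min, `k_minus` = 0.055/min)
#' were calibrated so the 10-min fitness (~0.73) exceeds the 20-min fitness
#' (~0.59), the qualitative ordering that makes short transcription
#' optimal.
#'
#' @param k_plus,k_minus Cleavage rate constants (per minute) with and
#'   without ligand.
#' @param times Reaction times in minutes.
#' @param mode `"ivt"` (plain transcription, no attenuation) or `"trt"`.
#' @param tau Attenuation time (minutes), used in `"trt"` mode.
#' @param theophylline_mM Ligand concentrations for the positive and
#'   negative conditions (first element must be > 0, second 0).
#' @param cleaved_length,full_length Species lengths in nucleotides.
#' @param gel_cv Coefficient of variation of multiplicative lognormal band
#'   noise (0 = noiseless).
#' @param total_molar Total molar amount loaded per lane.
#' @param seed Optional RNG seed.
#' @return A band tibble (columns `lane_id`, `condition_label`, `mode`,
#'   `time_min`, `theophylline_mM`, `species`, `intensity`, `length_nt`)
#'   ready for [band_fractions()].
#' @export
generate_gel_scan <- function(k_plus = 2, k_minus = 0.055,
                              times = c(2.5, 5, 10, 20, 40),
                              mode = c("ivt", "trt"), tau = 8,
                              theophylline_mM = c(3.16, 0),
                              cleaved_length = 78, full_length = 110,
                              gel_cv = 0.1, total_molar = 1, seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) withr::local_seed(seed)
  stopifnot(length(times) >= 1, length(theophylline_mM) == 2,
            theophylline_mM[1] > 0, theophylline_mM[2] == 0, gel_cv >= 0)
  tau_eff <- if (mode == "trt") tau else Inf

  grid <- tidyr::expand_grid(time_min = times, theo = theophylline_mM)
  grid$r <- transcription_cleavage_fraction(
    ifelse(grid$theo > 0, k_plus, k_minus), grid$time_min, tau_eff)

  sdlog <- sqrt(log(1 + gel_cv^2))
  noise <- function(n) {
    if (gel_cv == 0) rep(1, n) else rlnorm(n, -sdlog^2 / 2, sdlog)
  }
  bands <- grid |>
    dplyr::mutate(
      condition_label = sprintf("%s %g min", toupper(mode), .data$time_min)
    ) |>
    tidyr::expand_grid(species = c("cleaved", "full_length")) |>
    dplyr::mutate(
      molar = ifelse(.data$species == "cleaved",
                     total_molar * .data$r, total_molar * (1 - .data$r)),
      length_nt = ifelse(.data$species == "cleaved",
                         cleaved_length, full_length),
      intensity = .data$molar * .data$length_nt * noise(dplyr::n()),
      mode = mode
    )
  tibble(
    lane_id = sprintf("lane%02d", seq_len(nrow(bands))),
    condition_label = bands$condition_label,
    mode = bands$mode,
    time_min = bands$time_min,
    theophylline_mM = bands$theo,
    species = bands$species,
    intensity = bands$intensity,
    length_nt = bands$length_nt
  )
}
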
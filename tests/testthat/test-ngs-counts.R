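test_that("read pairs merge across exact and mismatched overlaps", {
  core <- "ACGTACGTACGTACGTACGT"  # 20-nt overlap
  fwd <- paste0("AAAACCCC", core)
  rc_rev <- paste0(core, "GGGGTTTT")
  rev <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(rc_rev)))
  merged <- merge_pairs(fwd, rev, min_overlap = 10)
  expect_equal(merged, paste0("AAAACCCC", core, "GGGGTTTT"))
  expect_equal(nchar(merged), nchar(fwd) + nchar(rev) - 20)

  # overlap below the minimum is rejected
  expect_true(is.na(merge_pairs(fwd, rev, min_overlap = 25)))

  # one mismatch in the overlap resolved toward the higher-quality read
  core_mm <- sub("^ACGT", "TCGT", core)
  rc_rev_mm <- paste0(core_mm, "GGGGTTTT")
  rev_mm <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(rc_rev_mm)))
  hi <- strrep("I", nchar(fwd))
  lo <- strrep("#", nchar(rev_mm))
  m_fwd_wins <- merge_pairs(fwd, rev_mm, fwd_qual = hi, rev_qual = lo,
                            min_overlap = 10)
  expect_equal(substr(m_fwd_wins, 9, 9), "A")
  m_rev_wins <- merge_pairs(fwd, rev_mm, fwd_qual = lo, rev_qual = hi,
                            min_overlap = 10)
  expect_equal(substr(m_rev_wins, 9, 9), "T")
  # quality tie becomes N
  m_tie <- merge_pairs(fwd, rev_mm, fwd_qual = hi,
                       rev_qual = strrep("I", nchar(rev_mm)),
                       min_overlap = 10)
  expect_equal(substr(m_tie, 9, 9), "N")
  # mismatch fraction cap rejects
  expect_true(is.na(merge_pairs(fwd, rev_mm, min_overlap = 10,
                                max_mismatch_frac = 0.01)))
})

test_that("anchored flank trimming recovers cassettes in both orientations", {
  tpl <- mini_template()
  cassette <- chartr("U", "T", tpl$reference)
  read <- paste0(tpl$flank5, cassette, tpl$flank3)

  out <- trim_flanks(read, tpl)
  expect_equal(out$status, "ok")
  expect_equal(out$cassette, cassette)

  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(read)))
  out_rc <- trim_flanks(rc, tpl)
  expect_equal(out_rc$cassette, cassette)  # orientation invariance

  # one flank mismatch tolerated at the default threshold, two rejected
  read1 <- read
  substr(read1, 1, 1) <- "G"
  expect_equal(trim_flanks(read1, tpl)$status, "ok")
  read2 <- read1
  substr(read2, 2, 2) <- "G"
  expect_equal(trim_flanks(read2, tpl, max_flank_mismatches = 1)$status,
               "flank")

  expect_equal(trim_flanks(substr(read, 1, 10), tpl)$status, "length")

  readN <- read
  substr(readN, nchar(tpl$flank5) + 2, nchar(tpl$flank5) + 2) <- "N"
  expect_equal(trim_flanks(readN, tpl)$status, "ambiguous")
})

test_that("variant counting matches known read composition", {
  tpl <- mini_template()
  lib <- classify_variants(enumerate_variants(tpl), tpl)
  ids <- lib$variant_id[1:4]
  n_per <- c(400, 300, 200, 100)
  reads <- rep(read_for_variant(ids, tpl), n_per)

  dir <- withr::local_tempdir()
  f <- write_fastq(reads, file.path(dir, "r0.fastq"))
  manifest <- tibble::tibble(file = f, cycle = 0, polarity = "initial")
  ct <- count_variants(manifest, tpl)
  expect_equal(sum(ct$count), 1000L)
  expect_equal(ct$count[match(ids, ct$variant_id)], n_per)
  expect_equal(nrow(count_rejects(ct)), 0)

  # order and strand-orientation invariance
  set.seed(2)
  flipped <- reads
  flip <- sample(length(reads), 500)
  flipped[flip] <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(flipped[flip])))
  f2 <- write_fastq(sample(flipped), file.path(dir, "r0b.fastq"))
  ct2 <- count_variants(tibble::tibble(file = f2, cycle = 0,
                                       polarity = "initial"), tpl)
  expect_equal(dplyr::arrange(as.data.frame(ct2), variant_id)$count,
               dplyr::arrange(as.data.frame(ct), variant_id)$count)

  # a round of one variant only
  f3 <- write_fastq(rep(read_for_variant("AA", tpl), 50),
                    file.path(dir, "mono.fastq"))
  ct3 <- count_variants(tibble::tibble(file = f3, cycle = 1, polarity = "+"),
                        tpl)
  fr3 <- variant_frequencies(ct3)
  expect_equal(fr3$frequency, 1)
  expect_equal(fr3$variant_id, "AA")
})

test_that("per-round frequencies sum to one and depths are retained reads", {
  tpl <- mini_template()
  dir <- withr::local_tempdir()
  lib <- enumerate_variants(tpl)
  f1 <- write_fastq(rep(read_for_variant(lib$variant_id[1:3], tpl),
                        c(5, 3, 2)), file.path(dir, "a.fastq"))
  f2 <- write_fastq(rep(read_for_variant(lib$variant_id[2:4], tpl),
                        c(4, 4, 2)), file.path(dir, "b.fastq"))
  manifest <- tibble::tibble(file = c(f1, f2), cycle = c(0, 1),
                             polarity = c("initial", "+"))
  fr <- variant_frequencies(count_variants(manifest, tpl))
  sums <- tapply(fr$frequency, fr$round, sum)
  expect_equal(as.vector(sums), c(1, 1))
  expect_equal(round_depths(count_variants(manifest, tpl))$depth, c(10, 10))
})

test_that("rounds are totally ordered initial < 1+ < 1- < 2+ < ...", {
  expect_equal(round_index(0, "initial"), 0L)
  expect_equal(round_index(1, "+"), 1L)
  expect_equal(round_index(1, "-"), 2L)
  expect_equal(round_index(2, "+"), 3L)
  expect_equal(round_index(5, "-"), 10L)
})

make_lumped_counts <- function(freqs, depth, counts = NULL) {
  n <- length(freqs)
  if (is.null(counts)) counts <- freqs * depth
  dplyr::bind_rows(
    tibble::tibble(cycle = 0:(n - 1),
                   polarity = c("initial", rep("-", n - 1)),
                   variant_id = "target", count = counts),
    tibble::tibble(cycle = 0:(n - 1),
                   polarity = c("initial", rep("-", n - 1)),
                   variant_id = "background", count = depth - counts)
  )
}

test_that("enrichment-ratio fit is exact on noise-free log-linear data", {
  lt <- lumped_trajectory(1 / 1024, 4, 1, 5)
  fit <- estimate_fitness_ratio(make_lumped_counts(lt$frequency, 16600),
                                "target")
  expect_equal(fit$rho_hat, 4, tolerance = 1e-10)
  expect_true(fit$conf_low <= 4 && 4 <= fit$conf_high)
  expect_equal(glance(fit)$rho_hat, fit$rho_hat)
  expect_equal(tidy(fit)$estimate, log(4), tolerance = 1e-10)

  # constant-frequency target
  flat <- estimate_fitness_ratio(make_lumped_counts(rep(0.1, 6), 1000),
                                 "target")
  expect_equal(flat$rho_hat, 1, tolerance = 1e-10)

  # failure modes
  expect_error(estimate_fitness_ratio(make_lumped_counts(rep(0, 3), 100,
                                                         counts = rep(0, 3)),
                                      "target"), "never observed")
  expect_error(estimate_fitness_ratio(
    make_lumped_counts(0.5, 100), "target"), "at least two")
})

test_that("boundary counts get the Haldane-Anscombe pseudocount", {
  counts <- make_lumped_counts(c(0.001, 0.01, 0.1), 1000,
                               counts = c(0, 10, 100))
  fit <- estimate_fitness_ratio(counts, "target")
  expect_equal(fit$data$count[1], 0)
  expect_gt(fit$rho_hat, 1)  # finite despite the zero count
  expect_true(is.finite(fit$slope))
})

test_that("weighted fit agrees with lm() point estimate", {
  set.seed(8)
  freqs <- lumped_trajectory(0.01, 2.5, 1, 5)$frequency
  depth <- 5000
  counts <- rbinom(6, depth, freqs)
  fit <- estimate_fitness_ratio(
    make_lumped_counts(freqs, depth, counts = counts), "target")
  p <- counts / depth
  y <- log(p / (1 - p))
  w <- depth * p * (1 - p)
  lm_fit <- stats::lm(y ~ x, data.frame(y = y, x = 0:5), weights = w)
  expect_equal(fit$slope, unname(stats::coef(lm_fit)[2]), tolerance = 1e-10)
})

test_that("rho recovery from sampled counts is calibrated", {
  # multinomial counts at study depth; the estimator should recover rho
  # closely and its CI should cover at roughly the nominal rate
  lt <- lumped_trajectory(1 / 1024, 4, 1, 5)
  depth <- 16600
  set.seed(123)
  res <- vapply(1:100, function(i) {
    counts <- rbinom(6, depth, lt$frequency)
    fit <- estimate_fitness_ratio(
      make_lumped_counts(lt$frequency, depth, counts = counts), "target")
    c(err = abs(fit$rho_hat - 4) / 4,
      covered = fit$conf_low <= 4 && 4 <= fit$conf_high)
  }, numeric(2))
  expect_lt(median(res["err", ]), 0.1)
  expect_gte(mean(res["covered", ]), 0.85)
})

test_that("trajectory comparison computes R2 with its edge cases", {
  obs <- tibble::tibble(round = c("initial", "1-", "2-", "3-"),
                        frequency = c(0.01, 0.05, 0.2, 0.5))
  expect_equal(compare_trajectories(obs, obs), 1)

  # observed constant while reference varies: no better than the mean model
  flat <- obs
  flat$frequency <- rep(0.2, 4)
  expect_lte(compare_trajectories(flat, obs), 0)

  expect_error(compare_trajectories(obs[1:2, ], obs[1:2, ]), "Fewer than 3")

  # noisy counts of a strongly enriching target track the truth closely
  set.seed(5)
  truth <- lumped_trajectory(1 / 1024, 4, 1, 5)$frequency
  noisy <- rbinom(6, 16600, truth) / 16600
  expect_gt(compare_trajectories(noisy, truth), 0.95)

  # log scale requires positive frequencies
  expect_error(compare_trajectories(c(0, 0.1, 0.2), c(0.1, 0.1, 0.2),
                                    scale = "log"), "positive")
  expect_equal(compare_trajectories(truth, truth, scale = "log"), 1)
})

test_that("generated reads flow through counting with zero rejects", {
  # pipeline composition at desk scale: truth -> FASTQ -> counts -> estimate
  dir <- withr::local_tempdir()
  tpl <- mini_template()
  lib <- classify_variants(enumerate_variants(tpl), tpl)
  prof <- sample_profiles(lib, seed = 4)
  sim <- generate_round_fastqs(dir, template = tpl, profiles = prof,
                               n_cycles = 3, depth = 3000,
                               epsilon_pos = 0, epsilon_neg = 0,
                               synthesis_sub_rate = 0, seq_error_rate = 0,
                               n_molecules = 1e6, seed = 21)
  ct <- count_variants(sim$manifest, tpl)
  expect_equal(nrow(count_rejects(ct)), 0)
  expect_equal(round_depths(ct)$depth, rep(3000L, 7))

  # observed counts are calibrated against multinomial 99% envelopes of
  # truth: at most a few percent of points may fall outside
  fr <- variant_frequencies(ct)
  joined <- dplyr::inner_join(
    fr, sim$truth[, c("round", "variant_id", "expected_read_freq")],
    by = c("round", "variant_id"))
  with_env <- joined[joined$expected_read_freq > 0.005, ]
  lo <- qbinom(0.005, 3000, with_env$expected_read_freq)
  hi <- qbinom(0.995, 3000, with_env$expected_read_freq)
  expect_lte(mean(with_env$count < lo | with_env$count > hi), 0.03)
})
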
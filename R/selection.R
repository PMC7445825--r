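#' Selection fitness of a cleavage profile
#'
#' The per-cycle survival propensity of a variant under one cycle of
#' alternating positive and negative selection,
#' \deqn{fitness = r^{(+)} (1 - r^{(-)}),}
#' where \eqn{r^{(+)}} and \eqn{r^{(-)}} are the molar fractions of the
#' variant's transcripts cleaved under positive-selection (ligand present)
#' and negative-selection (ligand absent) conditions. Fitness is directly
#' proportional to a variant's rate of enrichment during selection: cleaved
#' material survives the positive step, full-length material survives the
#' negative step.
#'
#' @param r_plus,r_minus Cleaved molar fractions in `[0, 1]` under positive
#'   and negative selection conditions; vectorized and recycled.
#' @return Numeric vector of fitness values in `[0, 1]`.
#' @examples
#' fitness(0.9, 0.2)          # 0.72
#' fitness(1, 1)              # constitutively active: 0
#' fitness(0.8595, 0.1274)    # ~0.75, a well-optimized switch
#' @export
fitness <- function(r_plus, r_minus) {
  if (any(r_plus < 0 | r_plus > 1, na.rm = TRUE) ||
      any(r_minus < 0 | r_minus > 1, na.rm = TRUE)) {
    abort("`r_plus` and `r_minus` must lie in [0, 1].")
  }
  r_plus * (1 - r_minus)
}

check_pool <- function(pool) {
  pool <- as_tibble(pool)
  if (!all(c("variant_id", "frequency") %in% names(pool))) {
    abort("A pool needs columns `variant_id` and `frequency`.")
  }
  if (any(pool$frequency < 0)) abort("Pool frequencies must be >= 0.")
  tot <- sum(pool$frequency)
  if (abs(tot - 1) > 1e-8) {
    abort("Pool frequencies must sum to 1.")
  }
  pool$frequency <- pool$frequency / tot
  pool
}

join_profiles <- function(pool, profiles) {
  profiles <- as_tibble(profiles)
  if (!all(c("variant_id", "r_plus", "r_minus") %in% names(profiles))) {
    abort("Profiles need columns `variant_id`, `r_plus`, `r_minus`.")
  }
  i <- match(pool$variant_id, profiles$variant_id)
  if (anyNA(i)) {
    abort(sprintf("No cleavage profile for %d pool variant(s), e.g. '%s'.",
                  sum(is.na(i)), pool$variant_id[which(is.na(i))[1]]))
  }
  profiles[i, c("r_plus", "r_minus")]
}

#' Apply one selection step to a pool
#'
#' A positive step retains cleaved material, a negative step retains
#' full-length material; either is followed by PCR amplification back to a
#' constant pool size, modeled as exact renormalization. A small background
#' survival probability `epsilon` lets the "wrong" species leak through
#' (ligation infidelity, bead carryover), so zero-fitness classes persist at
#' low frequency instead of going extinct in one step:
#' positive-step weight \eqn{r^{(+)} + \epsilon (1 - r^{(+)})},
#' negative-step weight \eqn{(1 - r^{(-)}) + \epsilon r^{(-)}}.
#'
#' @param pool A data frame with columns `variant_id`, `frequency`
#'   (frequencies sum to 1).
#' @param profiles A data frame with columns `variant_id`, `r_plus`,
#'   `r_minus` covering every pool variant.
#' @param polarity `"positive"` (or `"+"`) / `"negative"` (or `"-"`).
#' @param epsilon Background survival probability in `[0, 1)`.
#' @return The post-step pool: a tibble `variant_id`, `frequency`,
#'   renormalized to sum to 1.
#' @export
selection_step <- function(pool, profiles, polarity = c("positive", "negative"),
                           epsilon = 1e-3) {
  if (length(polarity) == 1 && polarity %in% c("+", "-")) {
    polarity <- if (polarity == "+") "positive" else "negative"
  }
  polarity <- match.arg(polarity)
  if (epsilon < 0 || epsilon >= 1) abort("`epsilon` must lie in [0, 1).")
  pool <- check_pool(pool)
  prof <- join_profiles(pool, profiles)
  w <- if (polarity == "positive") {
    prof$r_plus + epsilon * (1 - prof$r_plus)
  } else {
    (1 - prof$r_minus) + epsilon * prof$r_minus
  }
  z <- sum(pool$frequency * w)
  if (z <= 0) {
    abort("Degenerate pool: no material survives this selection step.")
  }
  tibble(variant_id = pool$variant_id,
         frequency = pool$frequency * w / z)
}

#' Simulate multi-cycle selection dynamics
#'
#' Runs `n_cycles` selection cycles, each a positive step followed by a
#' negative step, recording the pool after every step. With
#' `n_molecules = NULL` the dynamics are deterministic (infinite pool);
#' with a finite `n_molecules`, the pool is resampled after each step by a
#' multinomial draw of that many molecules, modeling the finite-material
#' bottleneck between steps (rare variants can then go extinct).
#'
#' @inheritParams selection_step
#' @param n_cycles Number of selection cycles (>= 0).
#' @param epsilon_pos,epsilon_neg Background survival probabilities for
#'   positive and negative steps.
#' @param n_molecules Finite pool size for stochastic simulation, or `NULL`
#'   for deterministic dynamics.
#' @param seed Optional seed for the stochastic bottleneck (the global RNG
#'   state is restored on exit).
#' @return A `selection_trajectory` tibble with columns `step_index`
#'   (0 = initial), `step` (`"initial"`, `"1+"`, `"1-"`, ...), `cycle`,
#'   `polarity` and one `frequency` per `variant_id`, one block per
#'   recorded pool.
#' @examples
#' pool <- tibble::tibble(variant_id = c("a", "b"), frequency = c(0.5, 0.5))
#' prof <- tibble::tibble(variant_id = c("a", "b"),
#'                        r_plus = c(0.9, 0.1), r_minus = c(0.1, 0.1))
#' simulate_selection(pool, prof, n_cycles = 2, epsilon_pos = 0,
#'                    epsilon_neg = 0)
#' @export
simulate_selection <- function(pool, profiles, n_cycles,
                               epsilon_pos = 1e-3, epsilon_neg = 1e-3,
                               n_molecules = NULL, seed = NULL) {
  stopifnot(n_cycles >= 0)
  if (!is.null(seed)) withr::local_seed(seed)
  if (!is.null(n_molecules)) {
    stopifnot(is.finite(n_molecules), n_molecules >= 1)
  }
  pool <- check_pool(pool)

  resample <- function(p) {
    if (is.null(n_molecules)) return(p)
    counts <- as.vector(rmultinom(1, size = n_molecules, prob = p$frequency))
    p$frequency <- counts / n_molecules
    p
  }

  records <- vector("list", 1 + 2 * n_cycles)
  records[[1]] <- dplyr::mutate(pool, step_index = 0L, step = "initial",
                                cycle = 0L, polarity = "initial")
  current <- pool
  k <- 1L
  for (cyc in seq_len(n_cycles)) {
    for (pol in c("positive", "negative")) {
      eps <- if (pol == "positive") epsilon_pos else epsilon_neg
      current <- resample(selection_step(current, profiles, pol, eps))
      sign <- if (pol == "positive") "+" else "-"
      k <- k + 1L
      records[[k]] <- dplyr::mutate(
        current, step_index = k - 1L, step = paste0(cyc, sign),
        cycle = cyc, polarity = sign)
    }
  }
  traj <- dplyr::bind_rows(records)
  traj <- traj[, c("step_index", "step", "cycle", "polarity",
                   "variant_id", "frequency")]
  class(traj) <- c("selection_trajectory", class(traj))
  traj
}

#' Closed-form enrichment trajectory of a lumped two-type model
#'
#' When every sequence except the tracked target is diluted at a common
#' rate, the pool collapses to a two-type system and the target's odds are
#' multiplied by the fitness ratio \eqn{\rho = f_{target}/f_{background}}
#' each cycle:
#' \deqn{odds_n = \frac{x_0}{1 - x_0}\, \rho^n, \qquad
#'       x_n = \frac{odds_n}{1 + odds_n}.}
#'
#' @param x0 Initial target frequency, in (0, 1).
#' @param f_target Target fitness (>= 0).
#' @param f_background Common effective fitness of the background (>= 0).
#' @param n_cycles Number of cycles to project.
#' @return A tibble with columns `cycle` (0..`n_cycles`) and `frequency`.
#'   If `f_background = 0` with `f_target > 0`, the target fixes
#'   immediately (frequency 1 from cycle 1 on).
#' @examples
#' lumped_trajectory(1 / 1024, f_target = 4, f_background = 1, n_cycles = 8)
#' @export
lumped_trajectory <- function(x0, f_target, f_background = 1, n_cycles) {
  stopifnot(x0 > 0, x0 < 1, f_target >= 0, f_background >= 0, n_cycles >= 0)
  cycles <- 0:n_cycles
  if (f_background == 0) {
    if (f_target == 0) abort("Both fitnesses are zero: dynamics undefined.")
    return(tibble(cycle = cycles,
                  frequency = c(x0, rep(1, n_cycles))))
  }
  rho <- f_target / f_background
  odds <- x0 / (1 - x0) * rho^cycles
  tibble(cycle = cycles, frequency = odds / (1 + odds))
}

#' Cycles of selection needed to reach a target frequency
#'
#' Smallest integer number of cycles `n` at which the lumped two-type model
#' reaches `threshold`:
#' \deqn{n = \left\lceil \frac{\ln\frac{thr}{1-thr} -
#'   \ln\frac{x_0}{1-x_0}}{\ln \rho} \right\rceil .}
#'
#' @inheritParams lumped_trajectory
#' @param threshold Target frequency in (0, 1).
#' @return Integer cycle count; 0 if `threshold <= x0`; `Inf` (with a
#'   warning) if the fitness ratio is <= 1 so the threshold is unreachable.
#' @examples
#' cycles_to_threshold(1 / 1024, f_target = 4, f_background = 1,
#'                     threshold = 0.5)  # 5
#' @export
cycles_to_threshold <- function(x0, f_target, f_background = 1, threshold) {
  stopifnot(x0 > 0, x0 < 1, threshold > 0, threshold < 1)
  if (threshold <= x0) return(0L)
  if (f_background == 0 && f_target > 0) return(1L)
  rho <- f_target / f_background
  if (rho <= 1) {
    warn("Fitness ratio <= 1: threshold unreachable.")
    return(Inf)
  }
  lodds <- function(p) log(p / (1 - p))
  n <- ceiling((lodds(threshold) - lodds(x0)) / log(rho))
  # guard the ceiling against floating-point boundary error
  odds_at <- function(k) x0 / (1 - x0) * rho^k
  while (n > 0 && odds_at(n - 1) / (1 + odds_at(n - 1)) >= threshold) {
    n <- n - 1
  }
  while (odds_at(n) / (1 + odds_at(n)) < threshold) n <- n + 1
  as.integer(n)
}

#' Effective background fitness of a pool
#'
#' Frequency-weighted mean fitness of every pool variant except the tracked
#' target; collapses a full pool onto the two-type lumped model.
#'
#' @inheritParams selection_step
#' @param exclude `variant_id` of the tracked target.
#' @return A single fitness value.
#' @export
effective_background_fitness <- function(pool, profiles, exclude) {
  pool <- check_pool(pool)
  if (!exclude %in% pool$variant_id) {
    abort(sprintf("Variant '%s' is not in the pool.", exclude))
  }
  rest <- pool[pool$variant_id != exclude, ]
  if (sum(rest$frequency) <= 0) {
    abort("Excluded variant has frequency 1: background fitness undefined.")
  }
  prof <- join_profiles(rest, profiles)
  f <- fitness(prof$r_plus, prof$r_minus)
  sum(rest$frequency * f) / sum(rest$frequency)
}
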
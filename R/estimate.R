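#' Estimate a variant's per-cycle enrichment ratio
#'
#' Fits the log-odds of the target variant's frequency against cycle index
#' by weighted least squares and exponentiates the slope: under the lumped
#' two-type model the odds are multiplied by the fitness ratio
#' \eqn{\rho} each cycle, so \eqn{\ln odds_n = \ln odds_0 + n \ln\rho}.
#' Weights are the inverse binomial variances of the observed log-odds,
#' \eqn{w_t = n_t \hat p_t (1 - \hat p_t)}; since these variances are
#' known (not estimated from residuals), the confidence interval uses the
#' normal quantile. Boundary counts (0 or the full depth) receive a 0.5
#' Haldane–Anscombe pseudocount.
#'
#' @param counts A `count_table` from [count_variants()], or any data frame
#'   with columns `cycle`, `polarity`, `variant_id`, `count`.
#' @param target `variant_id` of the tracked variant.
#' @param rounds Which rounds to use: `"cycle_end"` (default: the initial
#'   pool plus each cycle's post-negative-step round, i.e. one point per
#'   completed cycle) or `"all"` (every round, at half-cycle spacing).
#' @param conf Confidence level for the interval on \eqn{\rho}.
#' @return An object of class `enrichment_fit` with components `rho_hat`,
#'   `conf_low`, `conf_high`, `slope`, `se`, `conf`, `n_rounds` and `data`
#'   (the per-round tibble used in the fit). [tidy()] and [glance()]
#'   methods are provided.
#' @examples
#' traj <- lumped_trajectory(1 / 1024, 4, 1, n_cycles = 5)
#' counts <- tibble::tibble(
#'   cycle = traj$cycle, polarity = ifelse(traj$cycle == 0, "initial", "-"),
#'   variant_id = "PC", count = traj$frequency * 16600)
#' bg <- dplyr::mutate(counts, variant_id = "BG",
#'                     count = 16600 - count)
#' fit <- estimate_fitness_ratio(rbind(counts, bg), "PC")
#' glance(fit)$rho_hat  # 4
#' @export
estimate_fitness_ratio <- function(counts, target,
                                   rounds = c("cycle_end", "all"),
                                   conf = 0.95) {
  rounds <- match.arg(rounds)
  counts <- as_tibble(counts)
  need <- c("cycle", "polarity", "variant_id", "count")
  if (!all(need %in% names(counts))) {
    abort(paste("`counts` needs columns:", paste(need, collapse = ", ")))
  }
  if (rounds == "cycle_end") {
    counts <- counts[counts$polarity %in% c("initial", "-"), ]
    x_of <- function(cycle, polarity) as.numeric(cycle)
  } else {
    x_of <- function(cycle, polarity) round_index(cycle, polarity) / 2
  }
  per_round <- counts |>
    dplyr::summarise(
      depth = sum(.data$count),
      count = sum(.data$count[.data$variant_id == target]),
      .by = dplyr::all_of(c("cycle", "polarity"))
    ) |>
    dplyr::mutate(x = x_of(.data$cycle, .data$polarity)) |>
    dplyr::arrange(.data$x)
  if (nrow(per_round) < 2) {
    abort("Need at least two usable rounds to estimate an enrichment ratio.")
  }
  if (all(per_round$count == 0)) {
    abort(sprintf("Target '%s' was never observed.", target))
  }
  c_adj <- per_round$count
  c_adj[c_adj == 0] <- 0.5
  full <- c_adj == per_round$depth
  c_adj[full] <- per_round$depth[full] - 0.5
  p <- c_adj / per_round$depth
  y <- log(p / (1 - p))
  w <- per_round$depth * p * (1 - p)

  xbar <- sum(w * per_round$x) / sum(w)
  ybar <- sum(w * y) / sum(w)
  sxx <- sum(w * (per_round$x - xbar)^2)
  if (sxx <= 0) abort("Rounds are not spread over distinct cycles.")
  slope <- sum(w * (per_round$x - xbar) * (y - ybar)) / sxx
  se <- sqrt(1 / sxx)
  z <- qnorm(1 - (1 - conf) / 2)

  structure(
    list(
      target = target,
      rho_hat = exp(slope),
      conf_low = exp(slope - z * se),
      conf_high = exp(slope + z * se),
      slope = slope, se = se, conf = conf,
      n_rounds = nrow(per_round),
      data = dplyr::mutate(per_round, log_odds = y, weight = w)
    ),
    class = "enrichment_fit"
  )
}

#' @export
print.enrichment_fit <- function(x, ...) {
  cat(sprintf(
    "<enrichment_fit> target '%s': rho = %.4g (%d%% CI %.4g-%.4g), %d rounds\n",
    x$target, x$rho_hat, round(100 * x$conf), x$conf_low, x$conf_high,
    x$n_rounds))
  invisible(x)
}

#' Tidiers for enrichment-ratio fits
#'
#' @param x An `enrichment_fit`.
#' @param ... Unused.
#' @return `tidy()` gives one row per model term on the log-odds scale;
#'   `glance()` gives a one-row summary on the ratio scale.
#' @export
tidy.enrichment_fit <- function(x, ...) {
  tibble(
    term = "log_rho",
    estimate = x$slope,
    std.error = x$se,
    conf.low = x$slope - qnorm(1 - (1 - x$conf) / 2) * x$se,
    conf.high = x$slope + qnorm(1 - (1 - x$conf) / 2) * x$se
  )
}

#' @rdname tidy.enrichment_fit
#' @export
glance.enrichment_fit <- function(x, ...) {
  tibble(
    target = x$target,
    rho_hat = x$rho_hat,
    conf.low = x$conf_low,
    conf.high = x$conf_high,
    n_rounds = x$n_rounds
  )
}

#' Goodness of fit between observed and simulated trajectories
#'
#' Coefficient of determination \eqn{R^2 = 1 - SS_{res}/SS_{tot}} between an
#' observed frequency trajectory and a reference (e.g. simulated) one,
#' computed over their shared rounds. On raw frequencies by default; the
#' `"log"` scale compares log10 frequencies (both trajectories must then be
#' strictly positive). Can be negative when the reference fits worse than
#' the observed mean.
#'
#' @param observed,simulated Data frames with columns `round` and
#'   `frequency`, or plain numeric vectors of equal length (matched by
#'   position).
#' @param scale `"frequency"` (default) or `"log"`.
#' @return A single \eqn{R^2} value.
#' @export
compare_trajectories <- function(observed, simulated,
                                 scale = c("frequency", "log")) {
  scale <- match.arg(scale)
  if (is.data.frame(observed) || is.data.frame(simulated)) {
    observed <- as_tibble(observed)
    simulated <- as_tibble(simulated)
    joined <- dplyr::inner_join(
      dplyr::rename(observed[, c("round", "frequency")], obs = "frequency"),
      dplyr::rename(simulated[, c("round", "frequency")], sim = "frequency"),
      by = "round")
    obs <- joined$obs
    sim <- joined$sim
  } else {
    stopifnot(length(observed) == length(simulated))
    obs <- observed
    sim <- simulated
  }
  if (length(obs) < 3) {
    abort("Fewer than 3 shared rounds: R^2 not meaningful.")
  }
  if (scale == "log") {
    if (any(obs <= 0 | sim <= 0)) {
      abort("Log-scale comparison requires strictly positive frequencies.")
    }
    obs <- log10(obs)
    sim <- log10(sim)
  }
  1 - sum((obs - sim)^2) / sum((obs - mean(obs))^2)
}
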
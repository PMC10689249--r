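#' Attenuate an odds ratio by a minPPV
#'
#' Contamination of a case set shrinks the log odds ratio approximately in
#' proportion to the true-case fraction, so the effect detectable with a
#' candidate definition is `exp(minppv * ln(or_true))`.
#'
#' @param or_true True odds ratio (> 0).
#' @param minppv Attenuation factor in \[0, 1\] (the definition's minPPV).
#' @return The attenuated odds ratio.
#' @export
#' @examples
#' attenuated_or(1.1, 0.669)
attenuated_or <- function(or_true, minppv) {
  stopifnot(all(or_true > 0), all(minppv >= 0 & minppv <= 1))
  exp(minppv * log(or_true))
}

#' Power scenario
#'
#' Bundles the inputs of the attenuation-aware power calculation. Defaults
#' follow the common-weak-effect benchmark: a risk allele at population
#' frequency 0.30 with true odds ratio 1.1, tested against 141,279 selected
#' controls at a two-sided alpha of 0.05.
#'
#' @param n_case,n_control Case and control participant counts.
#' @param maf Control (population) effect-allele frequency.
#' @param or_true True odds ratio of the risk factor.
#' @param minppv Attenuation factor (the candidate definition's minPPV).
#' @param alpha Two-sided significance threshold.
#' @return A one-row tibble of class `power_scenario`.
#' @export
power_scenario <- function(n_case, n_control = 141279, maf = 0.30,
                           or_true = 1.1, minppv = 1, alpha = 0.05) {
  stopifnot(n_case >= 1, n_control >= 1,
            maf > 0, maf < 1, or_true > 0,
            minppv >= 0, minppv <= 1, alpha > 0, alpha < 1)
  out <- tibble::tibble(n_case = n_case, n_control = n_control, maf = maf,
                        or_true = or_true, minppv = minppv, alpha = alpha)
  class(out) <- c("power_scenario", class(out))
  out
}

#' Analytic power for an attenuated allelic association test
#'
#' Power of the two-proportion (allelic) chi-square test to detect a risk
#' allele, after attenuating the true log odds ratio by the candidate
#' definition's minPPV. The case allele frequency is `p1 =
#' case_freq(maf, attenuated_or(or_true, minppv))`; with per-allele counts
#' `m1 = 2 n_case`, `m2 = 2 n_control` and pooled frequency `pbar`, the
#' noncentrality is `(p1 - p2)^2 / (pbar (1 - pbar) (1/n_case +
#' 1/n_control))` and power is the upper tail of a noncentral chi-square
#' with 1 df at the central `1 - alpha` quantile. At `minppv = 0` the
#' noncentrality is zero and power equals `alpha` exactly.
#'
#' @param s A [power_scenario()] (or any one-row data frame with its
#'   columns).
#' @return Power, a number in (0, 1).
#' @export
#' @examples
#' analytic_power(power_scenario(n_case = 4244, minppv = 0.669))
analytic_power <- function(s) {
  p2 <- s$maf
  p1 <- case_freq(p2, attenuated_or(s$or_true, s$minppv))
  pbar <- (s$n_case * p1 + s$n_control * p2) / (s$n_case + s$n_control)
  lambda <- (p1 - p2)^2 /
    (pbar * (1 - pbar) * (1 / s$n_case + 1 / s$n_control))
  crit <- stats::qchisq(1 - s$alpha, df = 1)
  stats::pchisq(crit, df = 1, ncp = lambda, lower.tail = FALSE)
}

#' Monte-Carlo power estimate
#'
#' Independent simulation-based check of [analytic_power()]: simulates the
#' per-participant two-proportion experiment at a single risk factor
#' carrying the attenuated odds ratio (no further misclassification; the
#' attenuation already encodes it), computes the Woolf chi-square per
#' cohort, and reports the rejection fraction with its binomial standard
#' error. The power model counts risk-factor carriage per participant, so
#' the simulated 2x2 table has one draw per participant: case exposures
#' `Binomial(n_case, p1)` against control exposures
#' `Binomial(n_control, p2)`.
#'
#' @param s A [power_scenario()].
#' @param reps Number of simulated cohorts (>= 100).
#' @param seed Integer seed.
#' @return A one-row tibble with `power`, `se`, `reps`.
#' @export
mc_power <- function(s, reps = 2000, seed = 1) {
  stopifnot(reps >= 100)
  p2 <- s$maf
  p1 <- case_freq(p2, attenuated_or(s$or_true, s$minppv))
  crit <- stats::qchisq(1 - s$alpha, df = 1)
  withr::with_seed(as.integer(seed), {
    a <- stats::rbinom(reps, s$n_case, p1)
    c_ <- stats::rbinom(reps, s$n_control, p2)
  })
  est <- estimate_log_or(tibble::tibble(
    a = a, b = s$n_case - a, c = c_, d = s$n_control - c_))
  p_hat <- mean((est$beta / est$se)^2 > crit)
  tibble::tibble(power = p_hat,
                 se = sqrt(p_hat * (1 - p_hat) / reps),
                 reps = reps)
}

#' Power for a table of candidate definitions
#'
#' Evaluates [analytic_power()] for each row of a table of candidate
#' phenotype definitions under shared defaults, mirroring a published-style
#' report of name, case count, minPPV and power.
#'
#' @param rows A data frame with columns `name`, `n_case`, `minppv`.
#' @param defaults A [power_scenario()] supplying `n_control`, `maf`,
#'   `or_true` and `alpha` (its `n_case`/`minppv` are ignored).
#' @return `rows` with a `power` column appended.
#' @export
#' @examples
#' power_table(tibble::tibble(name = "SRP", n_case = 4244, minppv = 0.669))
power_table <- function(rows, defaults = power_scenario(n_case = 1)) {
  stopifnot(nrow(rows) >= 1,
            all(c("name", "n_case", "minppv") %in% names(rows)))
  rows$power <- purrr::map2_dbl(rows$n_case, rows$minppv, function(n, m) {
    analytic_power(power_scenario(
      n_case = n, n_control = defaults$n_control, maf = defaults$maf,
      or_true = defaults$or_true, minppv = m, alpha = defaults$alpha))
  })
  rows
}

#' Highest-powered definition in a power table
#'
#' @param tbl Output of [power_table()].
#' @return The one-row tibble attaining maximum power.
#' @export
max_power <- function(tbl) {
  stopifnot("power" %in% names(tbl))
  tbl[which.max(tbl$power), , drop = FALSE]
}

#' Power against minPPV for a grid of case counts
#'
#' @param n_case Vector of case counts (one curve each).
#' @param minppv Grid of attenuation values.
#' @param defaults A [power_scenario()] for the remaining parameters.
#' @return A ggplot object: power vs minPPV, one line per case count.
#' @export
plot_power_curve <- function(n_case, minppv = seq(0.05, 1, by = 0.05),
                             defaults = power_scenario(n_case = 1)) {
  grid <- tidyr::expand_grid(n_case = n_case, minppv = minppv)
  grid$power <- purrr::map2_dbl(grid$n_case, grid$minppv, function(n, m) {
    analytic_power(power_scenario(
      n_case = n, n_control = defaults$n_control, maf = defaults$maf,
      or_true = defaults$or_true, minppv = m, alpha = defaults$alpha))
  })
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$minppv, y = .data$power,
                                     colour = factor(.data$n_case))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "minPPV (attenuation factor)", y = "Power",
                  colour = "Cases")
}
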
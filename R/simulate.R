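#' Effect-allele frequency in true cases
#'
#' Under a single-locus odds-ratio model, the effect-allele frequency among
#' cases implied by a control frequency and a per-allele odds ratio:
#' `p_control * OR / (1 - p_control + p_control * OR)`.
#'
#' @param p_control Control effect-allele frequency, in (0, 1).
#' @param or_true Per-allele odds ratio in true cases, > 0.
#' @return Case effect-allele frequency.
#' @export
#' @examples
#' case_freq(0.3, 1.1)  # 0.33 / 1.03
case_freq <- function(p_control, or_true) {
  stopifnot(all(p_control > 0 & p_control < 1), all(or_true > 0))
  p_control * or_true / (1 - p_control + p_control * or_true)
}

#' Effect-allele frequency in a contaminated case set
#'
#' Labelled cases are modelled as a mixture of true cases (fraction `pi`,
#' the true-case fraction or PPV) and misclassified non-cases carrying
#' control allele frequencies.
#'
#' @param p_case Effect-allele frequency in true cases.
#' @param p_control Effect-allele frequency in controls.
#' @param pi True-case fraction, in \[0, 1\].
#' @return Mixture frequency `pi * p_case + (1 - pi) * p_control`.
#' @export
mixture_freq <- function(p_case, p_control, pi) {
  stopifnot(all(pi >= 0 & pi <= 1))
  pi * p_case + (1 - pi) * p_control
}

#' Default panel of independent risk loci
#'
#' Builds a locus specification table emulating a curated panel of
#' independent risk variants: control effect-allele frequencies evenly
#' spaced across a range and true odds ratios log-spaced across a range.
#' Alleles are assigned deterministically from non-palindromic pairs so the
#' panel survives harmonization untouched.
#'
#' @param n_loci Number of loci (default 35).
#' @param maf_range Range of control effect-allele frequencies (default
#'   0.1–0.5).
#' @param or_range Range of true odds ratios, filled log-spaced (default
#'   1.1–2.0).
#' @return A tibble with columns `variant_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `p_control`, `or_true`.
#' @export
locus_panel <- function(n_loci = 35, maf_range = c(0.1, 0.5),
                        or_range = c(1.1, 2.0)) {
  stopifnot(n_loci >= 1)
  allele_pairs <- list(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"))
  pair <- allele_pairs[((seq_len(n_loci) - 1) %% 4) + 1]
  tibble::tibble(
    variant_id = sprintf("rs%d", seq_len(n_loci)),
    chrom = as.character(((seq_len(n_loci) - 1) %% 22) + 1),
    pos = seq_len(n_loci) * 100000L,
    effect_allele = vapply(pair, `[`, character(1), 1),
    other_allele = vapply(pair, `[`, character(1), 2),
    p_control = seq(maf_range[1], maf_range[2], length.out = n_loci),
    or_true = exp(seq(log(or_range[1]), log(or_range[2]),
                      length.out = n_loci))
  )
}

#' Reference summary statistics implied by a locus panel
#'
#' The reference cohort is taken as (effectively) error-free: betas are the
#' true log odds ratios, with a small nominal SE representing a very large
#' specialist-diagnosed cohort.
#'
#' @param loci Locus panel from [locus_panel()].
#' @param se Nominal reference SE (default 0.01).
#' @return A sumstats tibble usable as the `reference` of [harmonize()].
#' @export
reference_sumstats <- function(loci, se = 0.01) {
  tibble::tibble(
    variant_id = loci$variant_id,
    chrom = loci$chrom,
    pos = loci$pos,
    effect_allele = loci$effect_allele,
    other_allele = loci$other_allele,
    beta = log(loci$or_true),
    se = se,
    eaf = loci$p_control
  )
}

#' Simulate allele counts for a contaminated case-control cohort
#'
#' For each locus, draws the control effect-allele count from
#' `Binomial(2 n_control, p_control)` and the labelled-case count from
#' `Binomial(2 n_case, p_mix)` where `p_mix` is the mixture frequency of
#' true cases (fraction `pi`, at the case frequency implied by the locus
#' odds ratio) and misclassified non-cases (at control frequency). Loci are
#' independent and alleles are sampled under Hardy-Weinberg equilibrium,
#' so allele counts are a sufficient substrate for the per-locus Woolf log
#' odds ratio.
#'
#' @param loci Locus panel (columns `variant_id`, `p_control`, `or_true`).
#' @param n_case,n_control Participant counts (>= 1).
#' @param pi True-case fraction among labelled cases, in \[0, 1\].
#' @param seed Integer seed; a fixed seed yields identical output.
#' @return A tibble with one row per locus: `variant_id`, `a` (effect-allele
#'   count in labelled cases), `b` (other-allele count in cases), `c`
#'   (effect-allele count in controls), `d` (other-allele count in
#'   controls), plus `n_case`, `n_control` attributes carried as columns.
#' @export
simulate_cohort <- function(loci, n_case, n_control, pi, seed) {
  stopifnot(n_case >= 1, n_control >= 1, pi >= 0, pi <= 1)
  p_case <- case_freq(loci$p_control, loci$or_true)
  p_mix <- mixture_freq(p_case, loci$p_control, pi)
  withr::with_seed(as.integer(seed), {
    a <- stats::rbinom(nrow(loci), 2L * n_case, p_mix)
    c_ <- stats::rbinom(nrow(loci), 2L * n_control, loci$p_control)
  })
  tibble::tibble(
    variant_id = loci$variant_id,
    a = a,
    b = 2L * n_case - a,
    c = c_,
    d = 2L * n_control - c_,
    n_case = n_case,
    n_control = n_control
  )
}

#' Woolf log odds ratio from allele counts
#'
#' Per-locus log odds ratio `ln(ad / bc)` with standard error
#' `sqrt(1/a + 1/b + 1/c + 1/d)`. When any cell of a locus is zero, the
#' Haldane-Anscombe correction adds 0.5 to all four cells of that locus
#' before computing.
#'
#' @param counts Cohort counts tibble from [simulate_cohort()] (columns `a`,
#'   `b`, `c`, `d`), or any tibble with those columns.
#' @return The input with columns `beta` and `se` appended.
#' @export
#' @examples
#' estimate_log_or(tibble::tibble(a = 30, b = 70, c = 20, d = 80))
estimate_log_or <- function(counts) {
  stopifnot(all(c("a", "b", "c", "d") %in% names(counts)))
  m <- as.matrix(counts[, c("a", "b", "c", "d")])
  if (any(m < 0)) {
    rlang::abort("Allele counts must be non-negative.",
                 class = "minppv_invalid_counts")
  }
  zero_row <- rowSums(m == 0) > 0
  m[zero_row, ] <- m[zero_row, , drop = FALSE] + 0.5
  if (any(m == 0)) {
    rlang::abort("Degenerate count table: zero margin after correction.",
                 class = "minppv_undefined_estimate")
  }
  counts$beta <- unname(log(m[, "a"] * m[, "d"] / (m[, "b"] * m[, "c"])))
  counts$se <- unname(sqrt(rowSums(1 / m)))
  counts
}

#' Candidate summary statistics from a simulated cohort
#'
#' Convenience wrapper: per-locus Woolf log odds ratios from simulated
#' allele counts, packaged as a sumstats tibble oriented to the panel's
#' effect alleles.
#'
#' @param counts Output of [simulate_cohort()].
#' @param loci The locus panel the counts were simulated from.
#' @return A sumstats tibble usable as the `candidate` of [harmonize()].
#' @export
cohort_sumstats <- function(counts, loci) {
  est <- estimate_log_or(counts)
  tibble::tibble(
    variant_id = loci$variant_id,
    chrom = loci$chrom,
    pos = loci$pos,
    effect_allele = loci$effect_allele,
    other_allele = loci$other_allele,
    beta = est$beta,
    se = est$se,
    eaf = (counts$a / (counts$a + counts$b) * counts$n_case +
             counts$c / (counts$c + counts$d) * counts$n_control) /
      (counts$n_case + counts$n_control)
  )
}

#' Validation experiment: slope recovery of a known true-case fraction
#'
#' Repeatedly simulates case-control cohorts in which a known fraction `pi`
#' of labelled cases are true cases, estimates per-locus log odds ratios,
#' harmonizes against the reference panel, and fits the IVW slope. Because
#' contamination attenuates log odds ratios approximately by `pi` (nearly
#' exactly for weak effects), the mean fitted slope should recover `pi` and
#' its 95 percent CI should cover `pi` at close to nominal rate.
#'
#' Each replicate uses a deterministic substream `seed + rep`, so any
#' individual replicate can be reproduced in isolation.
#'
#' @param loci Locus panel from [locus_panel()].
#' @param n_case,n_control Participant counts per cohort.
#' @param pi True-case fraction.
#' @param reference Reference sumstats (betas equal to the true per-locus
#'   log odds ratios); default derived from `loci`.
#' @param reps Number of simulated cohorts.
#' @param seed Base seed.
#' @param level CI level checked for coverage (default 0.95).
#' @return A list with `samples` (tibble of per-rep `rep`, `slope`, `se`,
#'   `ci_lo`, `ci_hi`, `covered`) and `summary` (one-row tibble of `pi`,
#'   `reps`, `mean_slope`, `sd_slope`, `coverage`).
#' @export
run_validation_sim <- function(loci, n_case, n_control, pi,
                               reference = reference_sumstats(loci),
                               reps = 200, seed = 1, level = 0.95) {
  stopifnot(reps >= 1)
  one_rep <- function(r) {
    counts <- simulate_cohort(loci, n_case, n_control, pi, seed = seed + r)
    cand <- cohort_sumstats(counts, loci)
    pairs <- suppressMessages(harmonize(cand, reference,
                                        drop_palindromic = FALSE))
    fit <- ivw_slope(pairs, level = level)
    tibble::tibble(rep = r, slope = fit$slope, se = fit$se,
                   ci_lo = fit$ci_lo, ci_hi = fit$ci_hi,
                   covered = fit$ci_lo <= pi & pi <= fit$ci_hi)
  }
  samples <- purrr::map_dfr(seq_len(reps), one_rep)
  summary <- tibble::tibble(
    pi = pi, reps = reps,
    mean_slope = mean(samples$slope),
    sd_slope = stats::sd(samples$slope),
    coverage = mean(samples$covered)
  )
  list(samples = samples, summary = summary)
}
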
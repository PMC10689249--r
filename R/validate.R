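#' Validate one candidate phenotype definition end to end
#'
#' Harmonizes candidate summary statistics to the reference panel, fits the
#' IVW slope (minPPV), and computes the attenuated power to detect a common
#' weak risk factor for that definition's case count — one published-style
#' report row per call.
#'
#' @param candidate,reference Sumstats tibbles (see [read_sumstats()]).
#' @param n_case Genotyped case count for the candidate definition.
#' @param name Definition name for the report row.
#' @param drop_palindromic Passed to [harmonize()].
#' @param defaults A [power_scenario()] supplying `n_control`, `maf`,
#'   `or_true` and `alpha` for the power column.
#' @return A one-row tibble: `name`, `n_case`, `n_variants`, `slope`, `se`,
#'   `ci_lo`, `ci_hi`, `power`.
#' @export
#' @examples
#' ref <- reference_sumstats(locus_panel())
#' validate_phenotype(ref, ref, n_case = 4244, name = "identity")
validate_phenotype <- function(candidate, reference, n_case,
                               name = "candidate",
                               drop_palindromic = TRUE,
                               defaults = power_scenario(n_case = 1)) {
  pairs <- harmonize(candidate, reference,
                     drop_palindromic = drop_palindromic)
  rlang::inform(sprintf("%s: %d variant(s) harmonized.", name, nrow(pairs)))
  fit <- ivw_slope(pairs)
  pow <- analytic_power(power_scenario(
    n_case = n_case, n_control = defaults$n_control, maf = defaults$maf,
    or_true = defaults$or_true,
    minppv = min(max(fit$slope, 0), 1),
    alpha = defaults$alpha))
  tibble::tibble(
    name = name, n_case = n_case, n_variants = fit$n_variants,
    slope = fit$slope, se = fit$se,
    ci_lo = fit$ci_lo, ci_hi = fit$ci_hi,
    power = pow
  )
}

#' Write a validation report
#'
#' @param rows Tibble of [validate_phenotype()] rows.
#' @param path Output path for a tab-delimited report.
#' @return `rows`, invisibly.
#' @export
write_report <- function(rows, path) {
  readr::write_tsv(rows, path, progress = FALSE)
  invisible(rows)
}
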
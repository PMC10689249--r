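#' Built-in phenotype component predicates
#'
#' Each component is a named predicate over one row of a per-participant
#' indicator table (columns `srp`, `srm`, `hes_main`, `hes_sec`, `gp_count`,
#' `psa_sr`, `psa_hes`, `psa_gp`):
#'
#' * `SRP` — self-reported psoriasis
#' * `SRM` — self-reported psoriasis-relevant medication
#' * `SRPM` — SRP and SRM
#' * `HESmain` / `HESsec` / `HESany` — hospital main / secondary / either
#'   diagnosis
#' * `GP` / `GP2` / `GP3` — at least 1 / 2 / 3 GP psoriasis diagnoses
#' * `SRP+PsA`, `SRPM+PsA`, `HESany+PsA`, `GP+PsA` — the corresponding
#'   predicate with psoriatic-arthritis codes merged in
#'
#' @return Named list of functions, each mapping an indicator tibble to a
#'   logical vector.
#' @export
phenotype_components <- function() {
  list(
    SRP = function(d) d$srp,
    SRM = function(d) d$srm,
    SRPM = function(d) d$srp & d$srm,
    HESmain = function(d) d$hes_main,
    HESsec = function(d) d$hes_sec,
    HESany = function(d) d$hes_main | d$hes_sec,
    GP = function(d) d$gp_count >= 1,
    GP2 = function(d) d$gp_count >= 2,
    GP3 = function(d) d$gp_count >= 3,
    `SRP+PsA` = function(d) d$srp | d$psa_sr,
    `SRM+PsA` = function(d) d$srm | d$psa_sr,
    `SRPM+PsA` = function(d) (d$srp | d$psa_sr) & d$srm,
    `HESany+PsA` = function(d) d$hes_main | d$hes_sec | d$psa_hes,
    `GP+PsA` = function(d) d$gp_count >= 1 | d$psa_gp
  )
}

#' Define a k-of-n composite phenotype rule
#'
#' A participant is a case under the rule iff at least `k` of the named
#' component predicates are true for them.
#'
#' @param name Rule name (used in reports).
#' @param components Character vector of component names from
#'   [phenotype_components()].
#' @param k Minimum number of components that must hold (1 <= k <=
#'   length(components)).
#' @return An object of class `composite_rule`.
#' @export
#' @examples
#' composite_rule("2-SRP-HESany-GP", c("SRP", "HESany", "GP"), k = 2)
composite_rule <- function(name, components, k = 1) {
  known <- names(phenotype_components())
  unknown <- setdiff(components, known)
  if (length(unknown) > 0) {
    rlang::abort(
      sprintf("Unknown component(s): %s. Known: %s",
              paste(unknown, collapse = ", "),
              paste(known, collapse = ", ")),
      class = "minppv_unknown_component"
    )
  }
  if (k < 1 || k > length(components)) {
    rlang::abort("`k` must satisfy 1 <= k <= number of components.",
                 class = "minppv_invalid_rule")
  }
  structure(list(name = name, components = components, k = as.integer(k)),
            class = "composite_rule")
}

#' @export
print.composite_rule <- function(x, ...) {
  cat(sprintf("<composite_rule> %s: >= %d of {%s}\n",
              x$name, x$k, paste(x$components, collapse = ", ")))
  invisible(x)
}

#' Apply a composite rule to an indicator table
#'
#' @param table Per-participant indicator tibble (see
#'   [phenotype_components()] for the expected columns; `participant_id`
#'   must be unique).
#' @param rule A [composite_rule()].
#' @return The subset of `table` whose participants satisfy the rule (cases).
#' @export
#' @examples
#' tab <- simulate_indicators(20, seed = 1)
#' apply_rule(tab, composite_rule("SRP", "SRP"))
apply_rule <- function(table, rule) {
  stopifnot(inherits(rule, "composite_rule"))
  if (anyDuplicated(table$participant_id)) {
    rlang::abort("participant_id must be unique.",
                 class = "minppv_duplicate_participant")
  }
  preds <- phenotype_components()[rule$components]
  hits <- vapply(preds, function(f) f(table), logical(nrow(table)))
  if (nrow(table) == 1) hits <- matrix(hits, nrow = 1)
  n_true <- rowSums(hits)
  table[n_true >= rule$k, , drop = FALSE]
}

#' Select controls free of any exclusion indicator
#'
#' Controls are participants matching none of the exclusion rules. The
#' default exclusion is any psoriasis or psoriatic-arthritis indicator
#' (self-report, medication, hospital, GP, or PsA codes), which guarantees
#' the control set is disjoint from every case set built from the built-in
#' components.
#'
#' @param table Per-participant indicator tibble.
#' @param exclusion List of [composite_rule()]s; a participant matching any
#'   is excluded.
#' @return The subset of `table` eligible as controls.
#' @export
select_controls <- function(table, exclusion = default_exclusion()) {
  if (inherits(exclusion, "composite_rule")) exclusion <- list(exclusion)
  excluded <- rep(FALSE, nrow(table))
  for (rule in exclusion) {
    excluded <- excluded |
      table$participant_id %in% apply_rule(table, rule)$participant_id
  }
  table[!excluded, , drop = FALSE]
}

#' Default control-exclusion rule set
#'
#' Any single psoriasis or PsA indicator excludes a participant from the
#' control set.
#'
#' @return A list with one 1-of-n [composite_rule()] over all base
#'   indicators (including PsA codes).
#' @export
default_exclusion <- function() {
  list(composite_rule(
    "any-psoriasis-or-psa-indicator",
    c("SRP", "SRM", "HESany", "GP", "SRP+PsA", "HESany+PsA", "GP+PsA"),
    k = 1
  ))
}

#' Simulate a per-participant indicator table
#'
#' Generates a synthetic indicator table for exercising composite rules.
#' Marginal indicator rates default to the rough per-source prevalences
#' seen in large population biobanks (about 1–2% per psoriasis source,
#' lower for PsA); sources are drawn independently given case status so
#' that multi-source corroboration is informative but not deterministic.
#'
#' @param n Number of participants.
#' @param seed Integer seed.
#' @param prev_psoriasis Fraction of participants with any psoriasis signal.
#' @param p_source Probability each source fires for a participant with
#'   psoriasis signal (self-report, medication, HES main/sec).
#' @param gp_lambda Poisson mean of GP diagnosis count for participants
#'   with psoriasis signal.
#' @param p_psa Probability of each PsA code given psoriasis signal.
#' @return An indicator tibble with columns `participant_id`, `srp`, `srm`,
#'   `hes_main`, `hes_sec`, `gp_count`, `psa_sr`, `psa_hes`, `psa_gp`.
#' @export
simulate_indicators <- function(n, seed = 1, prev_psoriasis = 0.03,
                                p_source = 0.5, gp_lambda = 1.0,
                                p_psa = 0.05) {
  withr::with_seed(as.integer(seed), {
    has_pso <- stats::runif(n) < prev_psoriasis
    draw <- function(p) has_pso & stats::runif(n) < p
    tibble::tibble(
      participant_id = sprintf("P%06d", seq_len(n)),
      srp = draw(p_source),
      srm = draw(p_source),
      hes_main = draw(p_source / 2),
      hes_sec = draw(p_source),
      gp_count = ifelse(has_pso, stats::rpois(n, gp_lambda), 0L),
      psa_sr = draw(p_psa),
      psa_hes = draw(p_psa),
      psa_gp = draw(p_psa)
    )
  })
}
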
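#' Published UK Biobank psoriasis phenotype definitions
#'
#' The 27 candidate psoriasis phenotype definitions evaluated in UK Biobank,
#' with their published case counts (before and after genotyping QC), IVW
#' regression slopes (minPPV) with 95% CIs against 141,279 selected
#' controls, and the published power to detect a common (MAF 0.30) weak
#' (OR 1.1) risk factor. These printed values are inputs: `power_table()`
#' on `n_cases` and `slope` recomputes the power column from scratch.
#'
#' @return A tibble with columns `name`, `description`, `group`,
#'   `n_cases_all`, `n_cases` (genotyped, unrelated), `slope`, `ci_lo`,
#'   `ci_hi`, `power_printed`.
#' @export
#' @examples
#' defs <- ukb_psoriasis_definitions()
#' power_table(dplyr::transmute(defs, name, n_case = n_cases, minppv = slope))
ukb_psoriasis_definitions <- function() {
  tibble::tribble(
    ~name, ~description, ~group,
    ~n_cases_all, ~n_cases, ~slope, ~ci_lo, ~ci_hi, ~power_printed,
    "SRP", "Self-reported psoriasis", "single",
    6110L, 4244L, 0.669, 0.612, 0.726, 0.478,
    "SRPM", "Self-reported psoriasis and medication relevant to psoriasis", "single",
    2750L, 1927L, 0.739, 0.652, 0.826, 0.296,
    "HESmain", "Psoriasis as main diagnosis in linked HES", "single",
    449L, 289L, 0.605, 0.422, 0.788, 0.077,
    "HESsec", "Psoriasis as secondary diagnosis in linked HES", "single",
    2300L, 1532L, 0.587, 0.491, 0.683, 0.175,
    "HESany", "Psoriasis as main or secondary diagnosis in linked HES", "single",
    2593L, 1726L, 0.579, 0.489, 0.668, 0.178,
    "GPraw", "Psoriasis diagnosis in linked GP data, ICD-10-mapped read codes", "single",
    11560L, 7956L, 0.324, 0.279, 0.370, 0.243,
    "GP", "Psoriasis diagnosis in linked GP data, curated read codes", "single",
    8444L, 5768L, 0.464, 0.405, 0.523, 0.340,
    "GP2", "Two or more psoriasis diagnoses in GP data, curated read codes", "single",
    3472L, 2422L, 0.586, 0.503, 0.669, 0.242,
    "GP3", "Three or more psoriasis diagnoses in GP data, curated read codes", "single",
    1984L, 1389L, 0.614, 0.515, 0.714, 0.172,
    "1-SRP-HESany", "Any one of SRP or HESany", "combined",
    7568L, 5194L, 0.624, 0.570, 0.677, 0.499,
    "1-SRP-GP", "Any one of SRP or GP", "combined",
    12616L, 8647L, 0.517, 0.471, 0.563, 0.543,
    "1-SRP-GP2", "Any one of SRP or GP2", "combined",
    8320L, 5786L, 0.615, 0.559, 0.670, 0.538,
    "1-SRP-HESany-GP", "Any one of SRP, HESany or GP", "combined",
    13666L, 9316L, 0.508, 0.463, 0.553, 0.561,
    "1-SRP-HESany-GP2", "Any one of SRP, HESany or GP2", "combined",
    9546L, 6574L, 0.585, 0.535, 0.636, 0.542,
    "2-SRP-HESany-GP", "Any two of SRP, HESany or GP", "combined",
    3056L, 2122L, 0.721, 0.638, 0.805, 0.303,
    "All-SRP-HESany-GP", "All three of SRP, HESany or GP", "combined",
    425L, 300L, 0.818, 0.616, 1.020, 0.105,
    "2-SRP-SRM-HESany-GP", "Any two of SRP, SRM, HESany or GP", "combined",
    5080L, 3499L, 0.696, 0.628, 0.763, 0.443,
    "2-SRP-SRM-HESany-GP2", "Any two of SRP, SRM, HESany or GP2", "combined",
    4291L, 2965L, 0.726, 0.660, 0.792, 0.416,
    "3-SRP-SRM-HESany-GP", "Any three of SRP, SRM, HESany or GP", "combined",
    1599L, 1122L, 0.771, 0.675, 0.866, 0.216,
    "All-SRP-SRM-HESany-GP", "All four of SRP, SRM, HESany or GP", "combined",
    262L, 185L, 0.870, 0.637, 1.104, 0.084,
    "SRP+PsA", "Self-reported psoriasis or psoriatic arthritis", "psa",
    6636L, 4603L, 0.664, 0.606, 0.721, 0.503,
    "SRPM+PsA", "Self-reported psoriasis or PsA, and psoriasis-relevant medication", "psa",
    3013L, 2107L, 0.747, 0.661, 0.832, 0.330,
    "HESany+PsA", "Psoriasis or PsA as main or secondary diagnosis in linked HES", "psa",
    3388L, 2272L, 0.616, 0.530, 0.703, 0.252,
    "GP+PsA", "Psoriasis or PsA diagnosis in linked GP data, curated read codes", "psa",
    8808L, 6024L, 0.457, 0.398, 0.517, 0.348,
    "1-SRP-HESany-GP+PsA", "Any one of SRP+PsA, HESany+PsA or GP+PsA", "psa",
    14475L, 9864L, 0.510, 0.464, 0.555, 0.582,
    "2-SRP-HESany-GP+PsA", "Any two of SRP+PsA, HESany+PsA or GP+PsA", "psa",
    3719L, 2579L, 0.713, 0.629, 0.797, 0.348,
    "2-SRP-SRM-HESany-GP+PsA", "Any two of SRP+PsA, SRM+PsA, HESany+PsA or GP+PsA", "psa",
    5692L, 3917L, 0.688, 0.620, 0.756, 0.468
  )
}
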
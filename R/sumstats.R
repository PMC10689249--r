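#' Read GWAS summary statistics
#'
#' Reads a tab-delimited summary-statistics file (optionally gzipped) into a
#' tibble with the standardised columns `variant_id`, `chrom`, `pos`,
#' `effect_allele`, `other_allele`, `beta`, `se` and (if present) `eaf`.
#' `beta` is the log odds ratio for the effect allele; `se` its standard
#' error. Rows with a non-finite `beta` or with `se <= 0` are dropped and the
#' number of dropped rows is reported via a message and attached as the
#' `n_rejected` attribute.
#'
#' @param source Path to a tab-delimited file (plain or `.gz`), or a
#'   connection. A literal block of text can be passed with [I()].
#' @param dialect Named character vector mapping standardised field names to
#'   column names in the file. Defaults to the common
#'   SNP/CHR/BP/A1/A2/BETA/SE/EAF convention; see [sumstats_dialect()].
#' @param provenance Optional label recorded as the `provenance` attribute
#'   (e.g. `"candidate:SRP"` or `"reference"`).
#'
#' @return A tibble of variant effect records, one row per retained variant,
#'   with attributes `provenance` and `n_rejected`.
#' @export
#' @examples
#' tsv <- "SNP\tA1\tA2\tBETA\tSE\nrs1\tA\tG\t0.10\t0.05\nrs2\tC\tT\t-0.20\t0.04\n"
#' read_sumstats(I(tsv), provenance = "candidate:demo")
read_sumstats <- function(source,
                          dialect = sumstats_dialect(),
                          provenance = NULL) {
  dialect <- utils::modifyList(as.list(sumstats_dialect()), as.list(dialect))
  raw <- readr::read_tsv(source,
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)

  required <- c("variant_id", "effect_allele", "other_allele", "beta", "se")
  for (field in required) {
    col <- dialect[[field]]
    if (is.null(col) || !col %in% names(raw)) {
      rlang::abort(
        sprintf("Required column '%s' (field '%s') not found in input.",
                col %||% "<unmapped>", field),
        class = "minppv_missing_column"
      )
    }
  }

  pick <- function(field) {
    col <- dialect[[field]]
    if (!is.null(col) && col %in% names(raw)) raw[[col]] else NA_character_
  }

  num <- function(field) {
    x <- pick(field)
    out <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(out))
    if (length(bad) > 0) {
      rlang::abort(
        sprintf("Unparsable numeric value '%s' for field '%s' at data row %d.",
                x[bad[1]], field, bad[1]),
        class = "minppv_parse_error"
      )
    }
    out
  }

  tbl <- tibble::tibble(
    variant_id    = pick("variant_id"),
    chrom         = pick("chrom"),
    pos           = suppressWarnings(as.integer(num("pos"))),
    effect_allele = toupper(pick("effect_allele")),
    other_allele  = toupper(pick("other_allele")),
    beta          = num("beta"),
    se            = num("se"),
    eaf           = num("eaf")
  )

  keep <- is.finite(tbl$beta) & is.finite(tbl$se) & tbl$se > 0
  n_rejected <- sum(!keep)
  if (n_rejected > 0) {
    rlang::inform(sprintf("Rejected %d row(s) with non-finite beta or se <= 0.",
                          n_rejected))
  }
  tbl <- tbl[keep, , drop = FALSE]

  if (anyDuplicated(tbl$variant_id)) {
    rlang::abort("Duplicate variant_id values in summary statistics table.",
                 class = "minppv_duplicate_variant")
  }

  attr(tbl, "provenance") <- provenance
  attr(tbl, "n_rejected") <- n_rejected
  tbl
}

#' Default summary-statistics column dialect
#'
#' @return Named character vector mapping standardised field names to the
#'   default column names `SNP`, `CHR`, `BP`, `A1`, `A2`, `BETA`, `SE`, `EAF`.
#' @export
sumstats_dialect <- function() {
  c(variant_id = "SNP", chrom = "CHR", pos = "BP",
    effect_allele = "A1", other_allele = "A2",
    beta = "BETA", se = "SE", eaf = "EAF")
}

#' Write summary statistics to a tab-delimited file
#'
#' @param x A sumstats tibble (as returned by [read_sumstats()] or built in
#'   code with the same columns).
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_sumstats <- function(x, path) {
  out <- tibble::tibble(
    SNP = x$variant_id, CHR = x$chrom, BP = x$pos,
    A1 = x$effect_allele, A2 = x$other_allele,
    BETA = x$beta, SE = x$se, EAF = if ("eaf" %in% names(x)) x$eaf else NA_real_
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(x)
}

complement_allele <- function(a) {
  unname(c(A = "T", C = "G", G = "C", T = "A")[a])
}

is_palindromic <- function(ea, oa) {
  (ea == "A" & oa == "T") | (ea == "T" & oa == "A") |
    (ea == "C" & oa == "G") | (ea == "G" & oa == "C")
}

#' Harmonize candidate effects to a reference panel
#'
#' Pairs candidate and reference summary statistics at shared variants
#' (matched by `variant_id`) and orients the candidate effect to the
#' reference effect allele. If the candidate's alleles are swapped relative
#' to the reference, the candidate beta sign is flipped; if they match only
#' after complementary-strand relabelling, the strand is flipped (with a
#' sign flip when the strand-flipped alleles are also swapped). Variants
#' whose allele sets cannot be reconciled are dropped with a message, as are
#' strand-ambiguous palindromic (A/T, C/G) variants when
#' `drop_palindromic = TRUE` (the default: with a small curated locus panel,
#' conservative exclusion is preferred over frequency-based strand
#' inference).
#'
#' @param candidate,reference Sumstats tibbles with at least `variant_id`,
#'   `effect_allele`, `other_allele`, `beta`, `se`.
#' @param drop_palindromic Drop A/T and C/G variants before pairing.
#' @return A tibble of paired effects with columns `variant_id`, `x`
#'   (reference beta), `y` (candidate beta, reference-oriented), `se_y`
#'   (candidate SE) and `se_x` (reference SE). The number of variants
#'   dropped for irreconcilable alleles is attached as attribute
#'   `n_dropped_alleles`; palindromic drops as `n_dropped_palindromic`.
#' @export
#' @examples
#' ref <- tibble::tibble(variant_id = "rs1", effect_allele = "A",
#'                       other_allele = "G", beta = 0.3, se = 0.02)
#' cand <- tibble::tibble(variant_id = "rs1", effect_allele = "G",
#'                        other_allele = "A", beta = -0.2, se = 0.05)
#' harmonize(cand, ref)  # candidate beta flipped to +0.2
harmonize <- function(candidate, reference, drop_palindromic = TRUE) {
  if (nrow(candidate) == 0 || nrow(reference) == 0) {
    rlang::abort("Both candidate and reference tables must be non-empty.",
                 class = "minppv_empty_table")
  }

  merged <- dplyr::inner_join(
    dplyr::select(reference, "variant_id",
                  ref_ea = "effect_allele", ref_oa = "other_allele",
                  x = "beta", se_x = "se"),
    dplyr::select(candidate, "variant_id",
                  cand_ea = "effect_allele", cand_oa = "other_allele",
                  y = "beta", se_y = "se"),
    by = "variant_id"
  )

  n_palindromic <- 0L
  if (drop_palindromic) {
    pal <- is_palindromic(merged$ref_ea, merged$ref_oa) |
      is_palindromic(merged$cand_ea, merged$cand_oa)
    n_palindromic <- sum(pal)
    if (n_palindromic > 0) {
      rlang::inform(sprintf("Dropped %d palindromic variant(s).", n_palindromic))
    }
    merged <- merged[!pal, , drop = FALSE]
  }

  same  <- merged$cand_ea == merged$ref_ea & merged$cand_oa == merged$ref_oa
  swap  <- merged$cand_ea == merged$ref_oa & merged$cand_oa == merged$ref_ea
  cand_ea_c <- complement_allele(merged$cand_ea)
  cand_oa_c <- complement_allele(merged$cand_oa)
  flip  <- !same & !swap & cand_ea_c == merged$ref_ea & cand_oa_c == merged$ref_oa
  flipswap <- !same & !swap & !flip &
    cand_ea_c == merged$ref_oa & cand_oa_c == merged$ref_ea

  reconcilable <- same | swap | flip | flipswap
  n_dropped <- sum(!reconcilable)
  if (n_dropped > 0) {
    rlang::inform(sprintf(
      "Dropped %d variant(s) with irreconcilable alleles: %s",
      n_dropped, paste(merged$variant_id[!reconcilable], collapse = ", ")))
  }
  merged <- merged[reconcilable, , drop = FALSE]
  sign_flip <- (swap | flipswap)[reconcilable]
  merged$y <- ifelse(sign_flip, -merged$y, merged$y)

  if (nrow(merged) == 0) {
    rlang::abort("No overlapping variants between candidate and reference.",
                 class = "minppv_empty_overlap")
  }

  out <- dplyr::select(merged, "variant_id", "x", "y", "se_y", "se_x")
  attr(out, "n_dropped_alleles") <- n_dropped
  attr(out, "n_dropped_palindromic") <- n_palindromic
  out
}
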
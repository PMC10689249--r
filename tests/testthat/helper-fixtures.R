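# Small fixtures built in code.

sumstats_text <- function(rows,
                          header = "SNP\tCHR\tBP\tA1\tA2\tBETA\tSE") {
  I(paste(c(header, rows, ""), collapse = "\n"))
}

make_sumstats <- function(id, ea, oa, beta, se, chrom = "1",
                          pos = seq_along(id) * 1000L) {
  tibble::tibble(variant_id = id, chrom = chrom, pos = pos,
                 effect_allele = ea, other_allele = oa,
                 beta = beta, se = se)
}

random_pairs <- function(n, rng_seed) {
  withr::with_seed(rng_seed, {
    tibble::tibble(
      variant_id = sprintf("rs%d", seq_len(n)),
      x = stats::rnorm(n, 0, 0.3),
      y = stats::rnorm(n, 0, 0.3),
      se_y = stats::runif(n, 0.02, 0.2)
    )
  })
}

# WLS through the origin via stats::lm — the independent oracle for the
# closed-form IVW slope.
lm_origin_slope <- function(pairs) {
  unname(stats::coef(stats::lm(y ~ 0 + x, data = pairs,
                               weights = 1 / pairs$se_y^2))["x"])
}

# All 8 participants enumerating subsets of {SRP, HESany (via hes_main),
# GP (gp_count = 3, so GP, GP2 and GP3 all fire)}.
truth_table_indicators <- function() {
  grid <- expand.grid(srp = c(FALSE, TRUE), hes = c(FALSE, TRUE),
                      gp = c(FALSE, TRUE))
  tibble::tibble(
    participant_id = sprintf("T%d", seq_len(8)),
    srp = grid$srp,
    srm = FALSE,
    hes_main = grid$hes,
    hes_sec = FALSE,
    gp_count = ifelse(grid$gp, 3L, 0L),
    psa_sr = FALSE, psa_hes = FALSE, psa_gp = FALSE
  )
}
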
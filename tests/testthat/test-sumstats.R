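test_that("read_sumstats parses the default dialect and filters bad rows", {
  tbl <- read_sumstats(sumstats_text(c(
    "rs1\t1\t100\tA\tG\t0.10\t0.05",
    "rs2\t2\t200\tC\tT\t-0.20\t0.04",
    "rs3\t3\t300\tG\tA\t0.05\t0.10"
  )))
  expect_s3_class(tbl, "tbl_df")
  expect_equal(nrow(tbl), 3)
  expect_equal(tbl$variant_id, c("rs1", "rs2", "rs3"))
  expect_equal(tbl$beta, c(0.10, -0.20, 0.05))
  expect_equal(attr(tbl, "n_rejected"), 0)

  # rows with se <= 0 or non-finite beta are rejected, with a count
  expect_message(
    tbl2 <- read_sumstats(sumstats_text(c(
      "rs1\t1\t100\tA\tG\t0.10\t0.05",
      "rs2\t2\t200\tC\tT\t-0.20\t0",
      "rs3\t3\t300\tG\tA\tNA\t0.10",
      "rs4\t4\t400\tT\tC\t0.02\t0.03",
      "rs5\t5\t500\tA\tC\t0.01\t-0.1"
    ))),
    "Rejected 3"
  )
  expect_equal(nrow(tbl2), 2)
  expect_equal(attr(tbl2, "n_rejected"), 3)
})

test_that("read_sumstats reports configuration and parse errors precisely", {
  expect_error(
    read_sumstats(sumstats_text("rs1\tA\tG\t0.1", header = "SNP\tA1\tA2\tBETA")),
    class = "minppv_missing_column"
  )
  expect_error(
    read_sumstats(sumstats_text("rs1\t1\t100\tA\tG\tnot_a_number\t0.05")),
    class = "minppv_parse_error"
  )
  expect_error(
    read_sumstats(sumstats_text(c("rs1\t1\t1\tA\tG\t0.1\t0.05",
                                  "rs1\t1\t1\tA\tG\t0.1\t0.05"))),
    class = "minppv_duplicate_variant"
  )
})

test_that("read_sumstats honours a custom column dialect", {
  txt <- sumstats_text("rs9\tA\tG\t0.3\t0.07",
                       header = "rsid\tea\toa\tlogOR\tstderr")
  tbl <- read_sumstats(txt, dialect = c(
    variant_id = "rsid", effect_allele = "ea", other_allele = "oa",
    beta = "logOR", se = "stderr"))
  expect_equal(tbl$variant_id, "rs9")
  expect_equal(tbl$se, 0.07)
})

test_that("write_sumstats round-trips through read_sumstats", {
  tbl <- make_sumstats(c("rs1", "rs2"), c("A", "C"), c("G", "T"),
                       c(0.12, -0.30), c(0.05, 0.04))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats(tbl, path)
  back <- read_sumstats(path)
  expect_equal(back$variant_id, tbl$variant_id)
  expect_equal(back$beta, tbl$beta)
  expect_equal(back$effect_allele, tbl$effect_allele)
})

test_that("harmonize orients candidate effects to the reference allele", {
  ref <- make_sumstats("rs1", "A", "G", 0.30, 0.02)
  # identical orientation: beta unchanged
  cand_same <- make_sumstats("rs1", "A", "G", 0.20, 0.05)
  expect_equal(harmonize(cand_same, ref)$y, 0.20)
  # swapped alleles: sign flips
  cand_swap <- make_sumstats("rs1", "G", "A", 0.20, 0.05)
  expect_equal(harmonize(cand_swap, ref)$y, -0.20)
  # complementary strand, same orientation: beta unchanged
  cand_flip <- make_sumstats("rs1", "T", "C", 0.20, 0.05)
  expect_equal(harmonize(cand_flip, ref)$y, 0.20)
  # complementary strand and swapped: sign flips
  cand_flipswap <- make_sumstats("rs1", "C", "T", 0.20, 0.05)
  expect_equal(harmonize(cand_flipswap, ref)$y, -0.20)
})

test_that("harmonize drops palindromic and irreconcilable variants", {
  ref <- make_sumstats(c("rs1", "rs2", "rs3"),
                       c("A", "A", "C"), c("G", "T", "G"),
                       c(0.3, 0.2, 0.1), c(0.02, 0.02, 0.02))
  cand <- make_sumstats(c("rs1", "rs2", "rs3"),
                        c("A", "A", "C"), c("G", "T", "G"),
                        c(0.2, 0.2, 0.2), c(0.05, 0.05, 0.05))
  dropped <- suppressMessages(harmonize(cand, ref, drop_palindromic = TRUE))
  expect_equal(dropped$variant_id, "rs1")
  kept <- harmonize(cand, ref, drop_palindromic = FALSE)
  expect_equal(nrow(kept), 3)

  # allele mismatch that no strand relabelling can fix is dropped
  ref2 <- make_sumstats(c("rs1", "rs2"), c("A", "A"), c("G", "G"),
                        c(0.3, 0.3), c(0.02, 0.02))
  cand2 <- make_sumstats(c("rs1", "rs2"), c("A", "A"), c("G", "C"),
                         c(0.2, 0.2), c(0.05, 0.05))
  expect_message(out <- harmonize(cand2, ref2), "irreconcilable")
  expect_equal(out$variant_id, "rs1")

  # zero overlap is an error
  expect_error(
    harmonize(make_sumstats("rsX", "A", "G", 0.1, 0.05), ref),
    class = "minppv_empty_overlap"
  )
})

test_that("harmonize is idempotent and sign-flip is an involution", {
  lp <- locus_panel(n_loci = 12)
  ref <- reference_sumstats(lp)
  cand <- ref
  cand$beta <- cand$beta * 0.7
  cand$se <- 0.05
  pairs1 <- harmonize(cand, ref)
  # feed the harmonized candidate back through: nothing changes
  cand_aligned <- cand
  pairs2 <- harmonize(cand_aligned, ref)
  expect_equal(pairs1, pairs2)

  # flipping candidate alleles twice returns the original pairing
  flipped <- cand
  flipped$effect_allele <- cand$other_allele
  flipped$other_allele <- cand$effect_allele
  flipped$beta <- -cand$beta
  twice <- flipped
  twice$effect_allele <- flipped$other_allele
  twice$other_allele <- flipped$effect_allele
  twice$beta <- -flipped$beta
  expect_equal(harmonize(twice, ref), pairs1)
  # and a single flip harmonizes to the same oriented pairs
  expect_equal(harmonize(flipped, ref), pairs1)
})

test_that("overlap never exceeds the smaller input table", {
  lp <- locus_panel(n_loci = 10)
  ref <- reference_sumstats(lp)
  cand <- ref[3:10, ]
  cand$se <- 0.05
  pairs <- harmonize(cand, ref)
  expect_lte(nrow(pairs), min(nrow(cand), nrow(ref)))
  expect_equal(nrow(pairs), 8)
})
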
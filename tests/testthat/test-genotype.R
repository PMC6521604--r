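# Library with the mir-A variant (offset 19, G->C) and helper to fabricate
# score-filtered alignment rows on its entries.
poly_lib <- function() tiny_library(mirA_variant())

mirA_rows <- function(n_ref = 0, n_alt = 0, sample_id = "s1",
                      cover_variant = TRUE, lib = poly_lib()) {
  entries <- as.data.frame(lib)
  mk <- function(entry_name, count) {
    if (count == 0) return(NULL)
    seq <- entries$sequence[entries$entry_name == entry_name]
    if (!cover_variant) seq <- substr(seq, 1, 17)
    data.frame(entry_name = entry_name, read_start = 1L,
               read_end = nchar(seq), ref_start = 1L, ref_end = nchar(seq),
               clip5 = "", clip3 = "", core_len = nchar(seq), sequence = seq,
               count = count, sample_id = sample_id, mature_name = "mir-A",
               is_canonical = entry_name == "mir-A", weight = 1,
               ambiguous = FALSE, stringsAsFactors = FALSE)
  }
  rbind(mk("mir-A", n_ref), mk("mir-A|rsAC", n_alt))
}

calls_for <- function(gt, lib = poly_lib(), sample_id = "s1") {
  v <- mirA_variant()
  gts <- matrix(gt, 1, 1, dimnames = list("rsA", sample_id))
  load_genotypes(gts, v, sample_id)
}

test_that("GT strings parse to the standard call classes", {
  expect_equal(polymiR:::parse_gt_call("0/0", "G", "C")$type, "hom_ref")
  expect_equal(polymiR:::parse_gt_call("0/1", "G", "C")$type, "het")
  expect_setequal(polymiR:::parse_gt_call("0/1", "G", "C")$alleles, c("G", "C"))
  expect_equal(polymiR:::parse_gt_call("1|1", "G", "C")$type, "hom_alt")
  expect_equal(polymiR:::parse_gt_call("./.", "G", "C")$type, "missing")
  expect_warning(bad <- polymiR:::parse_gt_call("0/9", "G", "C"), "malformed")
  expect_equal(bad$type, "missing")
  # absent sample: missing for all variants
  calls <- load_genotypes(matrix("0/0", 1, 1, dimnames = list("rsA", "other")),
                          mirA_variant(), "s1")
  expect_equal(calls[["s1"]][["rsA"]]$type, "missing")
})

test_that("allele evidence requires the core to cover the variant position", {
  lib <- poly_lib()
  pm <- attr(lib, "polymirs")[["mir-A"]]
  alt_row <- mirA_rows(n_alt = 1)[1, ]
  hap <- c(rsA = "C")
  expect_equal(infer_supported_allele(alt_row, pm, hap), c(rsA = "C"))
  short <- mirA_rows(n_alt = 1, cover_variant = FALSE)[1, ]
  expect_length(infer_supported_allele(short, pm, hap), 0L)
  ref_row <- mirA_rows(n_ref = 1)[1, ]
  expect_equal(infer_supported_allele(ref_row, pm, c(rsA = "G")), c(rsA = "G"))
})

test_that("the 980/20 worked example flags a 2% alternative as plausible", {
  lib <- poly_lib()
  res <- check_consistency(mirA_rows(n_ref = 980, n_alt = 20), lib,
                           calls_for("0/0"))
  dec <- res$decisions
  alt <- dec[dec$allele_mature == "C", ]
  expect_equal(alt$supporting, 20)
  expect_equal(alt$total, 1000)
  expect_equal(alt$rate, 0.02)
  expect_false(alt$expected)
  expect_true(alt$plausible)
  expect_equal(alt$action, "discard+report")
  # the alternative alignments are discarded either way
  expect_equal(sum(res$discarded$count), 20)
  expect_equal(sum(res$kept$count), 980)
})

test_that("rare unexpected alleles are discarded silently below both thresholds", {
  lib <- poly_lib()
  # high-depth regime: 3 / 800 < 1% -> silent
  res <- check_consistency(mirA_rows(n_ref = 797, n_alt = 3), lib,
                           calls_for("0/0"))
  alt <- res$decisions[res$decisions$allele_mature == "C", ]
  expect_false(alt$plausible)
  expect_equal(alt$action, "discard+silent")
  expect_equal(sum(res$discarded$count), 3)
})

test_that("plausibility flips exactly at the stated boundaries in both regimes", {
  lib <- poly_lib()
  plaus <- function(n_ref, n_alt) {
    res <- check_consistency(mirA_rows(n_ref = n_ref, n_alt = n_alt), lib,
                             calls_for("0/0"))
    res$decisions$plausible[res$decisions$allele_mature == "C"]
  }
  # low-depth regime (< 500 total): >= 5 supporting reads
  expect_false(plaus(100, 4))
  expect_true(plaus(100, 5))
  # high-depth regime (>= 500 total): > 1% of total
  expect_false(plaus(990, 10))   # 10/1000 = 1%, not greater
  expect_true(plaus(989, 11))    # 11/1000 > 1%
  # regime switch at exactly 500 informative reads
  expect_true(plaus(494, 5))     # total 499: absolute floor applies
  expect_false(plaus(495, 5))    # total 500: 1% rule, 5/500 = 1% fails
})

test_that("heterozygous samples keep both alleles; missing genotypes never discard", {
  lib <- poly_lib()
  res <- check_consistency(mirA_rows(n_ref = 10, n_alt = 10), lib,
                           calls_for("0/1"))
  expect_equal(nrow(res$discarded), 0L)
  expect_true(all(res$decisions$action == "keep"))
  res2 <- check_consistency(mirA_rows(n_ref = 10, n_alt = 10), lib,
                            calls_for("./."))
  expect_equal(nrow(res2$discarded), 0L)
})

test_that("hom-alt samples discard reference reads unless a variant-free paralog exists", {
  # mir-B has two loci; plant the variant on the chr2 copy only
  ref <- load_tiny_reference()
  vB <- data.frame(id = "rsB", chrom = "chr2", pos = 1030L,
                   ref = substr(MAT_B, 10, 10), alt = "A",
                   stringsAsFactors = FALSE)
  libB <- build_library(ref, map_variants(vB, ref$matures))
  rows <- data.frame(entry_name = "mir-B", read_start = 1L, read_end = 22L,
                     ref_start = 1L, ref_end = 22L, clip5 = "", clip3 = "",
                     core_len = 22L, sequence = MAT_B, count = 50L,
                     sample_id = "s1", mature_name = "mir-B",
                     is_canonical = TRUE, weight = 1, ambiguous = FALSE,
                     stringsAsFactors = FALSE)
  gts <- matrix("1/1", 1, 1, dimnames = list("rsB", "s1"))
  calls <- load_genotypes(gts, vB, "s1")
  res <- check_consistency(rows, libB, calls)
  expect_equal(nrow(res$discarded), 0L)  # reference reads protected
  # same situation without the paralog (variant on single-locus mir-A)
  libA <- poly_lib()
  resA <- check_consistency(mirA_rows(n_ref = 50), libA, calls_for("1/1"))
  expect_equal(sum(resA$discarded$count), 50)
})

test_that("kept and discarded partition the input exactly", {
  lib <- poly_lib()
  al <- mirA_rows(n_ref = 7, n_alt = 3)
  res <- check_consistency(al, lib, calls_for("0/0"))
  expect_equal(nrow(res$kept) + nrow(res$discarded), nrow(al))
  expect_setequal(c(res$kept$entry_name, res$discarded$entry_name),
                  al$entry_name)
})

test_that("without genotypes the consistency step is skipped entirely", {
  lib <- poly_lib()
  al <- mirA_rows(n_ref = 7, n_alt = 3)
  res <- check_consistency(al, lib, NULL)
  expect_true(res$skipped)
  expect_equal(res$kept, al)
  expect_equal(nrow(res$decisions), 0L)
})
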
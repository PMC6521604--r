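# Align one read against the tiny-reference library and annotate it.
annotate_one <- function(read, lib, config = scoring_config(),
                         sample_id = "s1") {
  idx <- build_seed_index(lib)
  cand <- align_reads(data.frame(sequence = read, count = 1L,
                                 sample_id = sample_id,
                                 stringsAsFactors = FALSE), idx)
  annotate_alignments(cand, lib, config)
}

test_that("editing events and labels follow the trimming/tailing taxonomy", {
  lib <- tiny_library()
  # identity: canonical, all counts zero
  ann <- annotate_one(MAT_A, lib)
  a <- ann[ann$entry_name == "mir-A", ]
  expect_equal(a$label, "canonical")
  expect_equal(a$trim5 + a$trim3 + a$tail5_nontemplated + a$tail3_nontemplated +
                 a$tail5_templated + a$tail3_templated, 0L)
  expect_equal(a$score, 0L)
  # one missing 3' base
  ann <- annotate_one(substr(MAT_A, 1, 21), lib)
  a <- ann[ann$entry_name == "mir-A", ]
  expect_equal(a$trim3, 1L)
  expect_equal(a$label, "iso_3p:-1")
  expect_equal(a$score, 1L)
  # two templated 3' bases (hp-A downstream flank starts "CT"): free
  ann <- annotate_one(paste0(MAT_A, "CT"), lib)
  a <- ann[ann$entry_name == "mir-A", ]
  expect_equal(a$tail3_templated, 2L)
  expect_equal(a$N3, 0L)
  expect_equal(a$label, "iso_3p:+2")
  expect_equal(a$score, 0L)
  # non-templated tail ("AA" vs flank "CT")
  ann <- annotate_one(paste0(MAT_A, "AA"), lib)
  a <- ann[ann$entry_name == "mir-A", ]
  expect_equal(a$tail3_nontemplated, 2L)
  expect_equal(a$label, "iso_add3p")
  expect_equal(a$score, 2L)
  # trimming followed by non-templated tailing ("G" != trimmed "T")
  ann <- annotate_one(paste0(substr(MAT_A, 1, 21), "G"), lib)
  a <- ann[ann$entry_name == "mir-A", ]
  expect_equal(c(a$trim3, a$tail3_nontemplated), c(1L, 1L))
  expect_equal(a$label, "iso_3p:-1,iso_add3p")
  # partial run: first tail base templated ("C"), second not ("A")
  ann <- annotate_one(paste0(MAT_A, "CA"), lib)
  a <- ann[ann$entry_name == "mir-A", ]
  expect_equal(c(a$tail3_templated, a$tail3_nontemplated), c(1L, 1L))
  expect_equal(a$label, "iso_3p:+1,iso_add3p")
})

test_that("5' labels follow the configured sign convention", {
  lib <- tiny_library()
  read <- substr(MAT_A, 2, 22)  # 5' trimmed by 1
  a <- annotate_one(read, lib)
  expect_equal(a$trim5[a$entry_name == "mir-A"], 1L)
  expect_equal(a$label[a$entry_name == "mir-A"], "iso_5p:+1")
  a2 <- annotate_one(read, lib, scoring_config(iso5p_sign = "mirgff3"))
  expect_equal(a2$label[a2$entry_name == "mir-A"], "iso_5p:-1")
  # templated 5' tail: hp-A upstream flank ends "T"
  up1 <- substr(HP_A, 20, 20)
  a3 <- annotate_one(paste0(up1, MAT_A), lib)
  expect_equal(a3$tail5_templated[a3$entry_name == "mir-A"], 1L)
  expect_equal(a3$label[a3$entry_name == "mir-A"], "iso_5p:-1")
  expect_equal(a3$score[a3$entry_name == "mir-A"], 0L)
})

test_that("the score is N5*W5 + N3 on the printed examples", {
  expect_equal(alignment_score(0L, 0L, 4L), 0L)   # perfect match
  expect_equal(alignment_score(0L, 1L, 4L), 1L)   # one 3' trim
  expect_equal(alignment_score(1L, 0L, 4L), 4L)   # one 5' trim, W5 = 4
  # trim3=2 + one non-templated 3' tail + trim5=1 -> 1*4 + 3
  expect_equal(alignment_score(1L, 3L, 4L), 7L)
})

test_that("the score law holds for random event counts and any W5", {
  set.seed(303)
  for (rep in seq_len(500)) {
    trim5 <- sample(0:3, 1); t5n <- sample(0:2, 1); t5t <- sample(0:2, 1)
    trim3 <- sample(0:5, 1); t3n <- sample(0:3, 1); t3t <- sample(0:3, 1)
    N5 <- trim5 + t5n; N3 <- trim3 + t3n
    for (W5 in 1:6) {
      s <- alignment_score(N5, N3, W5)
      expect_identical(s, as.integer(N5 * W5 + N3))
      # templated tails never contribute
      expect_identical(alignment_score(trim5 + t5n, trim3 + t3n, W5), s)
    }
  }
})

test_that("appending hairpin-flank bases to a canonical read never changes its score", {
  lib <- tiny_library()
  flank <- substr(HP_A, 43, 60)  # downstream of mir-A
  for (L in 1:4) {
    a <- annotate_one(paste0(MAT_A, substr(flank, 1, L)), lib)
    expect_equal(a$score[a$entry_name == "mir-A"], 0L, info = L)
  }
})

test_that("score differences count extra 3' events one-for-one", {
  lib <- tiny_library()
  base <- annotate_one(MAT_A, lib)
  s0 <- base$score[base$entry_name == "mir-A"]
  for (k in 1:3) {
    a <- annotate_one(substr(MAT_A, 1, 22 - k), lib)
    expect_equal(a$score[a$entry_name == "mir-A"] - s0, k)
  }
})

test_that("disambiguation keeps minimum-score alignments with 1/n weights", {
  # two-entry library where the read matches e1 perfectly and e2 minus a base
  lib0 <- tiny_library()
  ref <- attr(lib0, "reference")
  read <- MAT_A
  libA <- data.frame(entry_name = c("m1", "m2"), mature_name = c("m1", "m2"),
                     sequence = c(read, paste0(substr(read, 1, 21), "G")),
                     is_canonical = TRUE, haplotype = "",
                     stringsAsFactors = FALSE)
  attr(libA, "reference") <- list(
    matures = list(m1 = list(name = "m1", sequence = read,
                             parents = character(0),
                             offsets = data.frame(parent = character(0),
                                                  start = integer(0),
                                                  end = integer(0))),
                   m2 = list(name = "m2",
                             sequence = paste0(substr(read, 1, 21), "G"),
                             parents = character(0),
                             offsets = data.frame(parent = character(0),
                                                  start = integer(0),
                                                  end = integer(0)))),
    hairpins = list())
  attr(libA, "polymirs") <- list()
  # m1/m2 have no hairpins, so the flankless-tail warning is expected here
  ann <- suppressWarnings(annotate_one(read, libA))
  expect_setequal(ann$score, c(0L, 2L))  # perfect vs trim3=1 + 1 nontemplated
  kept <- disambiguate(ann, libA)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$entry_name, "m1")
  expect_equal(kept$weight, 1)
  # exact tie across two distinct matures: weight 0.5 each, flagged ambiguous
  libB <- libA; libB$sequence <- c(read, read)
  attr(libB, "reference")$matures$m2$sequence <- read
  ann2 <- annotate_one(read, libB)
  kept2 <- disambiguate(ann2, libB)
  expect_equal(nrow(kept2), 2L)
  expect_equal(kept2$weight, c(0.5, 0.5))
  expect_true(all(kept2$ambiguous))
})

test_that("variant-blind ties between haplotype entries collapse to the canonical entry", {
  lib <- tiny_library(mirA_variant())  # variant at mir-A offset 19
  read <- substr(MAT_A, 1, 17)         # core covers offsets 0..16 only
  ann <- annotate_one(read, lib)
  both <- ann[ann$mature_name == "mir-A", ]
  expect_equal(nrow(both), 2L)         # canonical + alt entry, tied
  expect_equal(length(unique(both$score)), 1L)
  # brute-force check: both entry sequences identical over the read span
  entries <- as.data.frame(lib)
  seqs <- entries$sequence[entries$mature_name == "mir-A"]
  expect_equal(substr(seqs[1], 1, 17), substr(seqs[2], 1, 17))
  kept <- disambiguate(ann, lib)
  kept <- kept[kept$mature_name == "mir-A", ]
  expect_equal(nrow(kept), 1L)
  expect_true(kept$is_canonical)
  expect_equal(kept$weight, 1)
  # a read covering the variant stays on its own entry
  alt_seq <- entries$sequence[!entries$is_canonical]
  annv <- annotate_one(alt_seq, lib)
  keptv <- disambiguate(annv, lib)
  expect_equal(keptv$entry_name[keptv$mature_name == "mir-A"], "mir-A|rsAC")
  expect_equal(keptv$weight, 1)
})

test_that("weights of each read's retained alignments always sum to one", {
  spec <- simulation_spec(seed = 5)
  fb <- make_fixture_bundle(spec, tempfile("wc"))
  res <- run_pipeline(fb$refset$mature_fasta, fb$refset$hairpin_fasta,
                      fb$refset$coords_gff3, fb$reads$fastq,
                      vcf = fb$refset$vcf, out_dir = tempfile("wco"))
  ret <- res$retained
  sums <- tapply(ret$weight, paste(ret$sample_id, ret$sequence), sum)
  expect_true(all(abs(sums - 1) < 1e-12))
})

test_that("score filtering is inclusive at the threshold", {
  cfg <- scoring_config(score_threshold = 9L)
  tab <- data.frame(score = c(0L, 9L, 10L, 76L))
  fs <- filter_by_score(tab, cfg)
  expect_equal(fs$passed$score, c(0L, 9L))
  expect_equal(fs$discarded$score, c(10L, 76L))
  # effectively infinite threshold keeps everything
  fs2 <- filter_by_score(tab, scoring_config(score_threshold = .Machine$integer.max))
  expect_equal(nrow(fs2$discarded), 0L)
})

test_that("templated tails attribute reads to the hairpin that explains them", {
  lib <- tiny_library()
  # mir-B has two parents; a "G" tail matches only hp-B1's downstream flank
  a <- annotate_one(paste0(MAT_B, "G"), lib)
  a <- a[a$entry_name == "mir-B", ]
  expect_equal(a$tail3_templated, 1L)
  expect_equal(a$hairpin_origin, "hp-B1")
  # canonical read on a two-parent mature: undetermined
  a2 <- annotate_one(MAT_B, lib)
  expect_equal(a2$hairpin_origin[a2$entry_name == "mir-B"], "undetermined")
  # single-parent mature: that parent
  a3 <- annotate_one(MAT_A, lib)
  expect_equal(a3$hairpin_origin[a3$entry_name == "mir-A"], "hp-A")
})
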
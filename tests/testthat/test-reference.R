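test_that("reference loading embeds matures in hairpins and merges multi-locus matures", {
  ref <- load_tiny_reference()
  expect_named(ref$matures, c("mir-A", "mir-B", "mir-C"))

  a <- ref$matures[["mir-A"]]
  expect_equal(a$sequence, MAT_A)
  expect_equal(nrow(a$loci), 1L)
  expect_equal(a$parents, "hp-A")
  expect_equal(a$offsets$start, 21L)
  expect_equal(substr(HP_A, a$offsets$start, a$offsets$end), MAT_A)

  # same mature name at two loci -> one record, two parents
  b <- ref$matures[["mir-B"]]
  expect_equal(nrow(b$loci), 2L)
  expect_setequal(b$parents, c("hp-B1", "hp-B2"))

  # minus-strand locus: length and containment still validated
  cc <- ref$matures[["mir-C"]]
  expect_equal(cc$loci$strand, "-")
  expect_equal(nchar(cc$sequence), cc$loci$end - cc$loci$start + 1L)
})

test_that("RNA-alphabet FASTA input is normalized to DNA", {
  p <- write_tiny_reference()
  lines <- readLines(p$mature)
  lines[2] <- chartr("T", "U", lines[2])  # mir-A as RNA
  writeLines(lines, p$mature)
  ref <- load_reference(p$mature, p$hairpin, p$gff3)
  expect_equal(ref$matures[["mir-A"]]$sequence, MAT_A)
})

test_that("coordinate span mismatching the sequence length is a hard error", {
  p <- write_tiny_reference()
  gff <- readLines(p$gff3)
  gff <- sub("miRNA\t1021\t1042\t.\t\\+\t.\tID=mir-A",
             "miRNA\t1021\t1041\t.\t+\t.\tID=mir-A", gff)
  writeLines(gff, p$gff3)
  expect_error(load_reference(p$mature, p$hairpin, p$gff3), "mir-A")
})

test_that("mature absent from its parent hairpin is a hard error", {
  p <- write_tiny_reference()
  lines <- readLines(p$hairpin)
  lines[2] <- paste0(substr(lines[2], 1, 25), "AAAAAAAAAA",
                     substr(lines[2], 36, nchar(lines[2])))  # corrupt hp-A
  writeLines(lines, p$hairpin)
  expect_error(load_reference(p$mature, p$hairpin, p$gff3), "substring|mir-A")
})

test_that("plus-strand variant mapping gives 5'-anchored offsets and alleles", {
  ref <- load_tiny_reference()
  v <- data.frame(id = "rs1", chrom = "chr1", pos = 1025L,
                  ref = "G", alt = "A", stringsAsFactors = FALSE)
  pm <- map_variants(v, ref$matures)
  expect_named(pm, "mir-A")
  expect_equal(pm[["mir-A"]]$variants$offset, 4L)
  expect_equal(pm[["mir-A"]]$variants$ref_mature, "G")
  expect_equal(pm[["mir-A"]]$variants$alts_mature, "A")
  expect_equal(substr(MAT_A, 5, 5), "G")
})

test_that("minus-strand variant mapping mirrors the offset and complements alleles", {
  ref <- load_tiny_reference()
  # mir-C genomic 2019-2040 (-): genomic 2023 -> offset end - pos = 17
  v <- data.frame(id = "rs2", chrom = "chr4", pos = 2023L,
                  ref = "C", alt = "A", stringsAsFactors = FALSE)
  pm <- map_variants(v, ref$matures)
  expect_equal(pm[["mir-C"]]$variants$offset, 17L)
  expect_equal(pm[["mir-C"]]$variants$ref_mature, "G")
  expect_equal(pm[["mir-C"]]$variants$alts_mature, "T")
  expect_equal(substr(MAT_C, 18, 18), "G")
})

test_that("a variant shared by overlapping opposite-strand matures joins both polymiRs", {
  spec <- simulation_spec(seed = 11)
  dir <- tempfile("opp")
  fb <- make_fixture_bundle(spec, dir)
  ref <- load_reference(fb$refset$mature_fasta, fb$refset$hairpin_fasta,
                        fb$refset$coords_gff3)
  pm <- map_variants(fb$refset$variants, ref$matures)
  expect_true(all(c("toy-miR-oppA", "toy-miR-oppB") %in% names(pm)))
  expect_equal(pm[["toy-miR-oppA"]]$variants$variant_id, "rs105")
  expect_equal(pm[["toy-miR-oppB"]]$variants$variant_id, "rs105")
  # mature-strand alleles on opposite strands are complementary
  expect_equal(pm[["toy-miR-oppB"]]$variants$ref_mature,
               chartr("ACGT", "TGCA", pm[["toy-miR-oppA"]]$variants$ref_mature))
})

test_that("variants outside all mature loci are excluded with a warning", {
  ref <- load_tiny_reference()
  v <- data.frame(id = c("rs1", "rsX"), chrom = c("chr1", "chr1"),
                  pos = c(1025L, 1005L), ref = c("G", "A"), alt = c("A", "C"),
                  stringsAsFactors = FALSE)
  expect_warning(pm <- map_variants(v, ref$matures), "rsX")
  expect_named(pm, "mir-A")
})

test_that("multi-nucleotide variants are rejected", {
  ref <- load_tiny_reference()
  v <- data.frame(id = "rsIndel", chrom = "chr1", pos = 1025L,
                  ref = "GA", alt = "G", stringsAsFactors = FALSE)
  expect_error(map_variants(v, ref$matures), "single-nucleotide")
})

test_that("haplotype enumeration yields the full Cartesian product of alleles", {
  ref <- load_tiny_reference()
  m <- ref$matures[["mir-A"]]
  # k = 0: identity
  ent0 <- enumerate_haplotypes(NULL, m)
  expect_equal(nrow(ent0), 1L)
  expect_true(ent0$is_canonical)
  expect_equal(ent0$sequence, MAT_A)

  make_pm <- function(offsets, n_alts) {
    bases <- substring(MAT_A, offsets + 1L, offsets + 1L)
    list(mature_name = "mir-A",
         variants = data.frame(
           variant_id = paste0("rs", seq_along(offsets)),
           offset = offsets, ref_mature = bases,
           alts_mature = vapply(seq_along(offsets), function(i)
             paste(setdiff(c("A", "C", "G", "T"), bases[i])[seq_len(n_alts[i])],
                   collapse = ","), character(1)),
           alts_vcf = "x", ref_vcf = "x", strand = "+",
           stringsAsFactors = FALSE),
         has_nonpolymorphic_paralog = FALSE)
  }
  # k = 1..3 biallelic plus one multi-allelic case: entries == prod(alleles)
  cases <- list(list(off = 4L, alts = 1L, n = 2L),
                list(off = c(4L, 10L), alts = c(1L, 1L), n = 4L),
                list(off = c(2L, 9L, 16L), alts = c(1L, 1L, 1L), n = 8L),
                list(off = c(4L, 10L), alts = c(3L, 2L), n = 12L))
  for (cs in cases) {
    ent <- enumerate_haplotypes(make_pm(cs$off, cs$alts), m)
    expect_equal(nrow(ent), cs$n)
    expect_equal(sum(ent$is_canonical), 1L)
    expect_equal(anyDuplicated(ent$entry_name), 0L)
    # alternative entries differ from canonical exactly at variant offsets
    can <- ent$sequence[ent$is_canonical]
    for (s in ent$sequence[!ent$is_canonical]) {
      diffs <- which(strsplit(can, "")[[1]] != strsplit(s, "")[[1]]) - 1L
      expect_true(all(diffs %in% cs$off))
      expect_gt(length(diffs), 0L)
    }
  }
})

test_that("minus-strand substitution round-trips to the genome-forward alt allele", {
  ref <- load_tiny_reference()
  v <- data.frame(id = "rs2", chrom = "chr4", pos = 2023L,
                  ref = "C", alt = "A", stringsAsFactors = FALSE)
  pm <- map_variants(v, ref$matures)
  ent <- enumerate_haplotypes(pm[["mir-C"]], ref$matures[["mir-C"]])
  alt_seq <- ent$sequence[!ent$is_canonical]
  # reverse-complement the mature-strand alt sequence back onto the forward
  # strand: the base at the VCF position must be the VCF alt allele
  fwd <- vapply(strsplit(chartr("ACGT", "TGCA", alt_seq), "")[[1]],
                identity, character(1))
  fwd <- paste(rev(fwd), collapse = "")
  locus <- ref$matures[["mir-C"]]$loci
  pos_in_fwd <- 2023L - locus$start + 1L
  expect_equal(substr(fwd, pos_in_fwd, pos_in_fwd), "A")
})

test_that("library building is deterministic and serializes entry metadata", {
  v <- mirA_variant()
  ref <- load_tiny_reference()
  pm <- map_variants(v, ref$matures)
  f1 <- tempfile(fileext = ".fa"); m1 <- tempfile(fileext = ".tsv")
  f2 <- tempfile(fileext = ".fa"); m2 <- tempfile(fileext = ".tsv")
  lib <- build_library(ref, pm, fasta_out = f1, metadata_out = m1)
  build_library(ref, pm, fasta_out = f2, metadata_out = m2)
  # 3 canonical + 1 alternative
  expect_equal(nrow(lib), 4L)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(readLines(m1), readLines(m2))
  meta <- read.delim(m1)
  alt <- meta[!meta$is_canonical, ]
  expect_equal(alt$entry_name, "mir-A|rsAC")
  expect_match(alt$haplotype, "rsA=C")
})

test_that("paralog flag marks matures with a variant-free locus", {
  ref <- load_tiny_reference()
  # variant on the chr2 copy of mir-B only
  v <- data.frame(id = "rsB", chrom = "chr2", pos = 1030L,
                  ref = substr(MAT_B, 10, 10), alt = "A",
                  stringsAsFactors = FALSE)
  pm <- map_variants(v, ref$matures)
  expect_true(pm[["mir-B"]]$has_nonpolymorphic_paralog)
  # single-locus mature: flag off
  pm2 <- map_variants(mirA_variant(), ref$matures)
  expect_false(pm2[["mir-A"]]$has_nonpolymorphic_paralog)
})
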
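# Hand-built tiny reference used across tests.
#
# mir-A : 22 nt mature on the plus strand of chr1, one parent hairpin whose
#         downstream flank starts "CT" (templated-tail probe).
# mir-B : one mature produced by two hairpins (chr2/chr3) with different
#         flanks: hpB1 downstream starts "G", hpB2 starts "T".
# mir-C : minus-strand mature on chr4.
MAT_A <- "TGAGGTAGTAGGTTGTATAGTT"
HP_A <- paste0("ACGTACGTACGTACGTACGT", MAT_A, "CTCTCTCTCTCTCTCTCT")
MAT_B <- "ACCGTTCAAGTCCGAGGACGGC"
HP_B1 <- paste0("TTGACCTTGAGGACCTTGAG", MAT_B, "GAAGGAAGGAAGGAAGGA")
HP_B2 <- paste0("CCAACCAACCAACCAACCAA", MAT_B, "TCCTTCCTTCCTTCCTTC")
MAT_C <- "CAGTGCAATGTTAAAAGGGCAT"
HP_C <- paste0("GGAAGGAAGGAAGGAAGGAA", MAT_C, "ATTATTATTATTATTATT")

write_tiny_reference <- function(dir = tempfile("ref")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mat <- file.path(dir, "mature.fa")
  hp <- file.path(dir, "hairpin.fa")
  writeLines(c(">mir-A", MAT_A, ">mir-B", MAT_B, ">mir-C", MAT_C), mat)
  writeLines(c(">hp-A", HP_A, ">hp-B1", HP_B1, ">hp-B2", HP_B2,
               ">hp-C", HP_C), hp)
  gff <- file.path(dir, "coords.gff3")
  # hp-A chr1:1001-1060 (+), mir-A at 1021-1042
  # hp-B1 chr2:1001-1060 (+), hp-B2 chr3:1001-1060 (+), mir-B at x021-x042
  # hp-C chr4:2001-2060 (-): sense offset 21..42 -> genomic 2019-2040
  writeLines(c(
    "##gff-version 3",
    "chr1\t.\tmiRNA_primary_transcript\t1001\t1060\t.\t+\t.\tID=hp-A;Name=hp-A",
    "chr1\t.\tmiRNA\t1021\t1042\t.\t+\t.\tID=mir-A;Name=mir-A;Derives_from=hp-A",
    "chr2\t.\tmiRNA_primary_transcript\t1001\t1060\t.\t+\t.\tID=hp-B1;Name=hp-B1",
    "chr2\t.\tmiRNA\t1021\t1042\t.\t+\t.\tID=mir-B-1;Name=mir-B;Derives_from=hp-B1",
    "chr3\t.\tmiRNA_primary_transcript\t1001\t1060\t.\t+\t.\tID=hp-B2;Name=hp-B2",
    "chr3\t.\tmiRNA\t1021\t1042\t.\t+\t.\tID=mir-B-2;Name=mir-B;Derives_from=hp-B2",
    "chr4\t.\tmiRNA_primary_transcript\t2001\t2060\t.\t-\t.\tID=hp-C;Name=hp-C",
    "chr4\t.\tmiRNA\t2019\t2040\t.\t-\t.\tID=mir-C;Name=mir-C;Derives_from=hp-C"),
    gff)
  list(mature = mat, hairpin = hp, gff3 = gff, dir = dir)
}

load_tiny_reference <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      p <- write_tiny_reference()
      cache <<- load_reference(p$mature, p$hairpin, p$gff3)
    }
    cache
  }
})

# minimal VCF writer; rows: data.frame(chrom, pos, id, ref, alt);
# gts: optional matrix rows x samples of GT strings
write_test_vcf <- function(path, rows, samples = NULL, gts = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  if (!is.null(samples)) cols <- c(cols, "FORMAT", samples)
  lines <- c(hdr, paste(cols, collapse = "\t"))
  for (i in seq_len(nrow(rows))) {
    f <- c(rows$chrom[i], rows$pos[i], rows$id[i], rows$ref[i], rows$alt[i],
           ".", "PASS", ".")
    if (!is.null(samples)) f <- c(f, "GT", gts[i, ])
    lines <- c(lines, paste(f, collapse = "\t"))
  }
  writeLines(lines, path)
  path
}

# library over the tiny reference, optionally with planted variants
tiny_library <- function(variants = NULL) {
  ref <- load_tiny_reference()
  pm <- if (is.null(variants)) list() else map_variants(variants, ref$matures)
  build_library(ref, pm)
}

# a variant on mir-A at mature offset 19 (genomic chr1:1040, base G -> C)
mirA_variant <- function() {
  data.frame(id = "rsA", chrom = "chr1", pos = 1040L, ref = "G", alt = "C",
             stringsAsFactors = FALSE)
}
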
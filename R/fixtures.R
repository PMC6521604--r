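# Seeded synthetic fixture generator: toy hairpins with embedded matures,
# planted SNPs (plus strand, minus strand, two-SNP, opposite-strand shared,
# and a paralogous mature with a single polymorphic locus), per-sample
# genotypes, and simulated reads with known editing events.

#' Simulation specification for synthetic fixtures
#'
#' The defaults describe a small but complete study: three unedited
#' ("plain") matures plus one polymiR of every structural kind the workflow
#' distinguishes, three samples covering the three genotype classes at every
#' variant, and an editing-event mix that mirrors the field's typical isomiR
#' profile (most reads canonical or 3'-edited, 5' events rare). One forced
#' exemplar read per isomiR label class is always emitted so every branch of
#' the annotation taxonomy is exercised regardless of the random draw.
#'
#' @param seed Integer seed; a single seeded generator drives all sampling.
#' @param n_plain_matures Number of variant-free matures.
#' @param mature_len_range Inclusive range of mature lengths (nt).
#' @param reads_per_mature Reads simulated per mature per sample.
#' @param het_alt_fraction Probability that a read from a heterozygous sample
#'   carries the alternative allele (0.5 = balanced expression).
#' @param event_probs Named probabilities of the per-read editing classes
#'   `canonical`, `trim3`, `add3`, `tmpl3`, `trim3_add3`, `trim5`, `tmpl5`,
#'   `add5`, `both_ends`.
#' @param samples Sample ids.
#' @param default_gt Genotype (GT string) per sample applied to every
#'   planted variant.
#' @param inject_inconsistent Optional data frame (`sample_id`, `mature`,
#'   `n_reads`) planting alternative-allele reads that contradict the
#'   sample's genotype (used to probe the consistency thresholds).
#' @param adapter3 Adapter appended to simulated reads.
#' @param low_quality_tail_prob Fraction of reads receiving a few extra
#'   low-quality 3' junk bases (exercises quality trimming).
#' @return A `simulation_spec` list.
#' @export
simulation_spec <- function(seed = 42L, n_plain_matures = 3L,
                            mature_len_range = c(20L, 23L),
                            reads_per_mature = 30L,
                            het_alt_fraction = 0.5,
                            event_probs = c(canonical = 0.40, trim3 = 0.25,
                                            add3 = 0.12, tmpl3 = 0.06,
                                            trim3_add3 = 0.05, trim5 = 0.04,
                                            tmpl5 = 0.03, add5 = 0.02,
                                            both_ends = 0.03),
                            samples = c("S1", "S2", "S3"),
                            default_gt = c(S1 = "0/0", S2 = "0/1", S3 = "1/1"),
                            inject_inconsistent = NULL,
                            adapter3 = "GATCGGAAGAGCACACGTCTGAACTCCAGTCAC",
                            low_quality_tail_prob = 0.1) {
  assert_that(abs(sum(event_probs) - 1) < 1e-8, "event_probs must sum to 1")
  structure(list(seed = as.integer(seed), n_plain_matures = n_plain_matures,
                 mature_len_range = mature_len_range,
                 reads_per_mature = reads_per_mature,
                 het_alt_fraction = het_alt_fraction,
                 event_probs = event_probs, samples = samples,
                 default_gt = default_gt,
                 inject_inconsistent = inject_inconsistent,
                 adapter3 = normalize_dna(adapter3),
                 low_quality_tail_prob = low_quality_tail_prob),
            class = "simulation_spec")
}

#' @keywords internal
#' @noRd
rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# TRUE when the adapter-removal rule would bite into this insert; used to
# resample fixture sequences so simulated inserts survive trimming intact.
#' @keywords internal
#' @noRd
insert_trim_safe <- function(insert, pre_cfg) {
  identical(trim_adapter(paste0(insert, pre_cfg$adapter3), NULL, pre_cfg), insert)
}

# mature whose trimmed (0-2 nt) and templated-tailed (1-2 nt) 3' variants all
# survive adapter removal
#' @keywords internal
#' @noRd
mature_is_safe <- function(mature, down_flank, pre_cfg) {
  n <- nchar(mature)
  for (t in 0:2) {
    if (!insert_trim_safe(substr(mature, 1L, n - t), pre_cfg)) return(FALSE)
  }
  for (t in 1:2) {
    if (nchar(down_flank) >= t &&
        !insert_trim_safe(paste0(mature, substr(down_flank, 1L, t)), pre_cfg))
      return(FALSE)
  }
  TRUE
}

#' Generate the synthetic reference bundle (FASTA/GFF3/VCF)
#'
#' Writes `mature.fa` and `hairpin.fa` (RNA alphabet, miRBase style),
#' `coords.gff3` and `variants.vcf` into `dir`. The constructs are: plain
#' matures; `toy-miR-plus` (one SNP, plus strand); `toy-miR-minus` (one SNP
#' on a minus-strand locus, so VCF alleles are complemented on the mature);
#' `toy-miR-duo` (two SNPs, four haplotypes); `toy-miR-oppA`/`toy-miR-oppB`
#' (two opposite-strand matures sharing one genomic SNP); and `toy-miR-par`,
#' one mature produced by two hairpins where only one locus carries the
#' variant (the non-polymorphic-paralog case).
#'
#' Call via [make_fixture_bundle()] for seeding; calling directly uses the
#' current RNG state.
#'
#' @param spec A [simulation_spec()].
#' @param dir Output directory (created if needed).
#' @return List with file paths and the planted-variant table.
#' @export
make_reference_set <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pre_cfg <- preprocess_config(adapter3 = spec$adapter3)
  matures <- list(); hairpins <- list(); gff <- list(); variants <- list()
  chrom_i <- 0L
  new_chrom <- function() {
    chrom_i <<- chrom_i + 1L
    paste0("chr", chrom_i)
  }
  draw_mature_len <- function()
    sample(seq(spec$mature_len_range[1], spec$mature_len_range[2]), 1L)

  # build one plus-strand hairpin + mature; returns record, resampling until
  # adapter-safe and (if snp_offset given) until ref != possible alts exist
  build_simple <- function(name, hp_name, snp_offset = NULL) {
    repeat {
      mlen <- draw_mature_len()
      pad5 <- sample(12:18, 1L); pad3 <- sample(12:18, 1L)
      mat <- rand_dna(mlen)
      hp <- paste0(rand_dna(pad5), mat, rand_dna(pad3))
      down <- substr(hp, pad5 + mlen + 1L, nchar(hp))
      if (mature_is_safe(mat, down, pre_cfg)) {
        return(list(name = name, hp_name = hp_name, mature = mat, hairpin = hp,
                    pad5 = pad5, mlen = mlen))
      }
    }
  }

  add_plus_construct <- function(rec, strand = "+") {
    chrom <- new_chrom()
    hstart <- 1000L; hend <- hstart + nchar(rec$hairpin) - 1L
    if (strand == "+") {
      mstart <- hstart + rec$pad5; mend <- mstart + rec$mlen - 1L
    } else {
      mend <- hend - rec$pad5; mstart <- mend - rec$mlen + 1L
    }
    hairpins[[rec$hp_name]] <<- rec$hairpin
    matures[[rec$name]] <<- rec$mature
    gff[[length(gff) + 1L]] <<- sprintf(
      "%s\t.\tmiRNA_primary_transcript\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
      chrom, hstart, hend, strand, rec$hp_name, rec$hp_name)
    gff[[length(gff) + 1L]] <<- sprintf(
      "%s\t.\tmiRNA\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s;Derives_from=%s",
      chrom, mstart, mend, strand, rec$name, rec$name, rec$hp_name)
    list(chrom = chrom, mstart = mstart, mend = mend, strand = strand)
  }

  plant_snp <- function(rsid, rec, loc, offset) {
    base_m <- substr(rec$mature, offset + 1L, offset + 1L)
    alt_m <- sample(setdiff(c("A", "C", "G", "T"), base_m), 1L)
    if (loc$strand == "+") {
      pos <- loc$mstart + offset
      ref_v <- base_m; alt_v <- alt_m
    } else {
      pos <- loc$mend - offset
      ref_v <- dna_complement(base_m); alt_v <- dna_complement(alt_m)
    }
    variants[[rsid]] <<- data.frame(id = rsid, chrom = loc$chrom, pos = pos,
                                    ref = ref_v, alt = alt_v,
                                    stringsAsFactors = FALSE)
  }

  for (i in seq_len(spec$n_plain_matures)) {
    rec <- build_simple(paste0("toy-miR-", i), paste0("toy-mir-", i))
    add_plus_construct(rec)
  }

  rec <- build_simple("toy-miR-plus", "toy-mir-plus")
  loc <- add_plus_construct(rec)
  plant_snp("rs101", rec, loc, sample(3:(rec$mlen - 4L), 1L))

  rec <- build_simple("toy-miR-minus", "toy-mir-minus")
  loc <- add_plus_construct(rec, strand = "-")
  plant_snp("rs102", rec, loc, sample(3:(rec$mlen - 4L), 1L))

  rec <- build_simple("toy-miR-duo", "toy-mir-duo")
  loc <- add_plus_construct(rec)
  offs <- sort(sample(3:(rec$mlen - 4L), 2L))
  while (diff(offs) < 3L) offs <- sort(sample(3:(rec$mlen - 4L), 2L))
  plant_snp("rs103", rec, loc, offs[1])
  plant_snp("rs104", rec, loc, offs[2])

  # opposite-strand pair sharing one genomic SNP: both hairpins derive from
  # one genomic fragment so their sequences are mutually reverse-complement
  repeat {
    frag <- rand_dna(80L)
    hpA <- substr(frag, 1L, 60L)
    hpB <- dna_revcomp(substr(frag, 21L, 80L))
    matA <- substr(frag, 26L, 47L)
    matB <- dna_revcomp(substr(frag, 31L, 52L))
    downA <- substr(hpA, 48L, 60L)
    downB <- substr(hpB, 51L, 60L)
    if (mature_is_safe(matA, downA, pre_cfg) &&
        mature_is_safe(matB, downB, pre_cfg)) break
  }
  chrom <- new_chrom()
  hairpins[["toy-mir-oppA"]] <- hpA; matures[["toy-miR-oppA"]] <- matA
  hairpins[["toy-mir-oppB"]] <- hpB; matures[["toy-miR-oppB"]] <- matB
  gff[[length(gff) + 1L]] <- sprintf(
    "%s\t.\tmiRNA_primary_transcript\t%d\t%d\t.\t+\t.\tID=toy-mir-oppA;Name=toy-mir-oppA",
    chrom, 1001L, 1060L)
  gff[[length(gff) + 1L]] <- sprintf(
    "%s\t.\tmiRNA\t%d\t%d\t.\t+\t.\tID=toy-miR-oppA;Name=toy-miR-oppA;Derives_from=toy-mir-oppA",
    chrom, 1026L, 1047L)
  gff[[length(gff) + 1L]] <- sprintf(
    "%s\t.\tmiRNA_primary_transcript\t%d\t%d\t.\t-\t.\tID=toy-mir-oppB;Name=toy-mir-oppB",
    chrom, 1021L, 1080L)
  gff[[length(gff) + 1L]] <- sprintf(
    "%s\t.\tmiRNA\t%d\t%d\t.\t-\t.\tID=toy-miR-oppB;Name=toy-miR-oppB;Derives_from=toy-mir-oppB",
    chrom, 1031L, 1052L)
  ref_v <- substr(frag, 40L, 40L)
  variants[["rs105"]] <- data.frame(
    id = "rs105", chrom = chrom, pos = 1040L, ref = ref_v,
    alt = sample(setdiff(c("A", "C", "G", "T"), ref_v), 1L),
    stringsAsFactors = FALSE)

  # paralogous mature: two hairpins on different chromosomes produce the same
  # mature; only the first locus carries the variant
  repeat {
    rec <- build_simple("toy-miR-par", "toy-mir-par-1")
    pad5b <- sample(12:18, 1L); pad3b <- sample(12:18, 1L)
    hp2 <- paste0(rand_dna(pad5b), rec$mature, rand_dna(pad3b))
    down2 <- substr(hp2, pad5b + rec$mlen + 1L, nchar(hp2))
    if (mature_is_safe(rec$mature, down2, pre_cfg)) break
  }
  loc1 <- add_plus_construct(rec)
  chrom2 <- new_chrom()
  h2start <- 5000L; h2end <- h2start + nchar(hp2) - 1L
  m2start <- h2start + pad5b; m2end <- m2start + rec$mlen - 1L
  hairpins[["toy-mir-par-2"]] <- hp2
  gff[[length(gff) + 1L]] <- sprintf(
    "%s\t.\tmiRNA_primary_transcript\t%d\t%d\t.\t+\t.\tID=toy-mir-par-2;Name=toy-mir-par-2",
    chrom2, h2start, h2end)
  gff[[length(gff) + 1L]] <- sprintf(
    "%s\t.\tmiRNA\t%d\t%d\t.\t+\t.\tID=toy-miR-par-b;Name=toy-miR-par;Derives_from=toy-mir-par-2",
    chrom2, m2start, m2end)
  plant_snp("rs106", rec, loc1, sample(3:(rec$mlen - 4L), 1L))

  variants <- do.call(rbind, variants)
  rownames(variants) <- NULL

  to_rna <- function(x) chartr("T", "U", x)
  mature_fa <- file.path(dir, "mature.fa")
  hairpin_fa <- file.path(dir, "hairpin.fa")
  writeLines(unlist(lapply(names(matures), function(n)
    c(paste0(">", n), to_rna(matures[[n]])))), mature_fa)
  writeLines(unlist(lapply(names(hairpins), function(n)
    c(paste0(">", n), to_rna(hairpins[[n]])))), hairpin_fa)

  gff3 <- file.path(dir, "coords.gff3")
  writeLines(c("##gff-version 3", unlist(gff)), gff3)

  vcf <- file.path(dir, "variants.vcf")
  gt_of <- function(s, vid) {
    gt <- spec$default_gt[[s]]
    if (is.null(gt)) "./." else gt
  }
  vcf_lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", spec$samples), collapse = "\t"))
  for (vi in seq_len(nrow(variants))) {
    v <- variants[vi, ]
    vcf_lines <- c(vcf_lines, paste(
      c(v$chrom, v$pos, v$id, v$ref, v$alt, ".", "PASS", ".", "GT",
        vapply(spec$samples, gt_of, character(1), vid = v$id)),
      collapse = "\t"))
  }
  writeLines(vcf_lines, vcf)

  list(mature_fasta = mature_fa, hairpin_fasta = hairpin_fa,
       coords_gff3 = gff3, vcf = vcf, variants = variants, dir = dir)
}

#' Simulate small-RNA reads with known truth
#'
#' Draws reads for every mature and sample: the haplotype follows the
#' sample's genotype (heterozygotes draw the alternative allele with
#' probability `het_alt_fraction`; for the paralogous mature the producing
#' hairpin is drawn first and reads from the variant-free copy always carry
#' the reference allele), the editing class follows `event_probs`, and the
#' adapter (plus, occasionally, a low-quality junk tail) is appended. Every
#' isomiR label class additionally gets one forced exemplar read on the
#' first plain mature. A truth table records the planted events, the
#' editing-event counts, and the expected post-collapse alignment entry
#' (reads whose core cannot cover a variant are expected on the canonical
#' entry).
#'
#' Call via [make_fixture_bundle()] for seeding.
#'
#' @param spec A [simulation_spec()].
#' @param refset Output of [make_reference_set()].
#' @param dir Output directory for FASTQ files and `truth.tsv`.
#' @return List with `fastq` (named paths), `truth` (data frame) and
#'   `truth_path`.
#' @export
simulate_reads <- function(spec, refset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pre_cfg <- preprocess_config(adapter3 = spec$adapter3)
  reference <- load_reference(refset$mature_fasta, refset$hairpin_fasta,
                              refset$coords_gff3)
  polymirs <- map_variants(refset$variants, reference$matures)
  flanks <- mature_flanks(reference)
  entries_by_mature <- lapply(reference$matures, function(m)
    enumerate_haplotypes(polymirs[[m$name]], m))

  truth <- list(); fastq_recs <- stats::setNames(
    replicate(length(spec$samples), list(character(0))), spec$samples)
  serial <- 0L

  emit_read <- function(sample_id, mature_name, entry, hap, parent, edit) {
    serial <<- serial + 1L
    rid <- sprintf("r%05d", serial)
    insert <- edit$insert
    read <- paste0(insert, spec$adapter3)
    qual <- strrep("I", nchar(read))
    if (stats::runif(1) < spec$low_quality_tail_prob) {
      junk <- rand_dna(3L)
      read <- paste0(read, junk)
      qual <- paste0(qual, strrep("#", 3L))
    }
    fastq_recs[[sample_id]] <<- c(fastq_recs[[sample_id]],
                                  paste0("@", rid), read, "+", qual)
    pm <- polymirs[[mature_name]]
    expected_entry <- entry$entry_name
    if (!is.null(pm) && !entry$is_canonical) {
      mlen <- nchar(reference$matures[[mature_name]]$sequence)
      lo <- edit$trim5; hi <- mlen - edit$trim3 - 1L  # covered offsets, 0-based
      hap_alleles <- parse_haplotype(entry$haplotype)
      covered_alt <- FALSE
      for (vi in seq_len(nrow(pm$variants))) {
        o <- pm$variants$offset[vi]
        if (o >= lo && o <= hi &&
            hap_alleles[[pm$variants$variant_id[vi]]] != pm$variants$ref_mature[vi])
          covered_alt <- TRUE
      }
      if (!covered_alt) expected_entry <- mature_name
    }
    truth[[length(truth) + 1L]] <<- data.frame(
      read_id = rid, sample_id = sample_id, mature_name = mature_name,
      entry_name = entry$entry_name, expected_entry = expected_entry,
      haplotype = entry$haplotype, parent = parent, insert = insert,
      trim5 = edit$trim5, tail5_templated = edit$t5t,
      tail5_nontemplated = edit$t5n, trim3 = edit$trim3,
      tail3_templated = edit$t3t, tail3_nontemplated = edit$t3n,
      N5 = edit$trim5 + edit$t5n, N3 = edit$trim3 + edit$t3n,
      label = isomir_label(edit$trim5, edit$t5t, edit$t5n,
                           edit$trim3, edit$t3t, edit$t3n),
      injected = edit$injected, stringsAsFactors = FALSE)
  }

  pick_entry <- function(mature_name, sample_id, forced_copy = NULL) {
    ent <- entries_by_mature[[mature_name]]
    pm <- polymirs[[mature_name]]
    m <- reference$matures[[mature_name]]
    parent <- if (length(m$parents)) sample(m$parents, 1L) else NA_character_
    if (is.null(pm)) {
      return(list(entry = ent[ent$is_canonical, ], parent = parent))
    }
    if (!is.null(forced_copy)) parent <- forced_copy
    if (pm$has_nonpolymorphic_paralog && identical(parent, "toy-mir-par-2")) {
      # variant-free copy: always the reference haplotype
      return(list(entry = ent[ent$is_canonical, ], parent = parent))
    }
    alleles <- character(nrow(pm$variants))
    for (vi in seq_len(nrow(pm$variants))) {
      v <- pm$variants[vi, ]
      gt <- spec$default_gt[[sample_id]]
      alt1 <- strsplit(v$alts_mature, ",", fixed = TRUE)[[1]][1]
      alleles[vi] <- switch(gt,
        "0/0" = v$ref_mature,
        "1/1" = alt1,
        "0/1" = if (stats::runif(1) < spec$het_alt_fraction) alt1 else v$ref_mature,
        v$ref_mature)
    }
    hap <- paste0(pm$variants$variant_id, "=", alleles, collapse = ";")
    hit <- ent[ent$haplotype == hap, ]
    list(entry = hit[1, ], parent = parent)
  }

  # editing classes; all constraints keep the planted interpretation the
  # maximal-core one (junction bases mismatch reference/flank as needed)
  apply_edit <- function(entry_seq, mature_name, parent) {
    cls <- sample(names(spec$event_probs), 1L, prob = spec$event_probs)
    edit_of_class(cls, entry_seq, mature_name, parent)
  }

  edit_of_class <- function(cls, entry_seq, mature_name, parent) {
    n <- nchar(entry_seq)
    fl <- flanks[[mature_name]]
    all_first_down <- vapply(fl, function(f)
      substr(f$down, 1L, 1L), character(1))
    all_last_up <- vapply(fl, function(f) {
      u <- f$up; if (nchar(u)) substr(u, nchar(u), nchar(u)) else ""
    }, character(1))
    canonical <- list(insert = entry_seq, trim5 = 0L, t5t = 0L, t5n = 0L,
                      trim3 = 0L, t3t = 0L, t3n = 0L, injected = FALSE)
    pick_not <- function(excl) {
      choices <- setdiff(c("A", "C", "G", "T"), excl)
      if (length(choices) == 0) return(NA_character_)
      sample(choices, 1L)
    }
    res <- switch(cls,
      canonical = canonical,
      trim3 = {
        t <- sample(1:2, 1L)
        if (n - t < 17L) canonical
        else list(insert = substr(entry_seq, 1L, n - t), trim5 = 0L, t5t = 0L,
                  t5n = 0L, trim3 = t, t3t = 0L, t3n = 0L, injected = FALSE)
      },
      add3 = {
        L <- sample(1:2, 1L)
        b1 <- pick_not(all_first_down)
        tail <- paste0(b1, if (L > 1L) rand_dna(L - 1L) else "")
        list(insert = paste0(entry_seq, tail), trim5 = 0L, t5t = 0L, t5n = 0L,
             trim3 = 0L, t3t = 0L, t3n = L, injected = FALSE)
      },
      tmpl3 = {
        f <- fl[[parent]]
        L <- sample(1:2, 1L)
        if (is.null(f) || nchar(f$down) < L) canonical
        else list(insert = paste0(entry_seq, substr(f$down, 1L, L)),
                  trim5 = 0L, t5t = 0L, t5n = 0L, trim3 = 0L,
                  t3t = L, t3n = 0L, injected = FALSE)
      },
      trim3_add3 = {
        t <- sample(1:2, 1L)
        if (n - t < 17L) canonical
        else {
          trimmed_base <- substr(entry_seq, n - t + 1L, n - t + 1L)
          b1 <- pick_not(trimmed_base)
          list(insert = paste0(substr(entry_seq, 1L, n - t), b1),
               trim5 = 0L, t5t = 0L, t5n = 0L, trim3 = t, t3t = 0L, t3n = 1L,
               injected = FALSE)
        }
      },
      trim5 = {
        t <- 1L
        if (n - t < 17L) canonical
        else list(insert = substr(entry_seq, t + 1L, n), trim5 = t, t5t = 0L,
                  t5n = 0L, trim3 = 0L, t3t = 0L, t3n = 0L, injected = FALSE)
      },
      tmpl5 = {
        f <- fl[[parent]]
        if (is.null(f) || nchar(f$up) < 1L) canonical
        else list(insert = paste0(substr(f$up, nchar(f$up), nchar(f$up)),
                                  entry_seq),
                  trim5 = 0L, t5t = 1L, t5n = 0L, trim3 = 0L, t3t = 0L,
                  t3n = 0L, injected = FALSE)
      },
      add5 = {
        b1 <- pick_not(all_last_up)
        list(insert = paste0(b1, entry_seq), trim5 = 0L, t5t = 0L, t5n = 1L,
             trim3 = 0L, t3t = 0L, t3n = 0L, injected = FALSE)
      },
      both_ends = {
        if (n - 2L < 17L) canonical
        else list(insert = substr(entry_seq, 2L, n - 1L), trim5 = 1L,
                  t5t = 0L, t5n = 0L, trim3 = 1L, t3t = 0L, t3n = 0L,
                  injected = FALSE)
      })
    # length window + adapter-survival check; fall back to canonical
    if (is.null(res) || anyNA(res$insert) ||
        nchar(res$insert) < 15L || nchar(res$insert) > 27L ||
        !insert_trim_safe(res$insert, pre_cfg)) {
      tries <- 0L
      while (tries < 20L) {
        tries <- tries + 1L
        res2 <- edit_of_class(cls, entry_seq, mature_name, parent)
        if (!anyNA(res2$insert) && nchar(res2$insert) >= 15L &&
            nchar(res2$insert) <= 27L && insert_trim_safe(res2$insert, pre_cfg))
          return(res2)
      }
      return(canonical)
    }
    res
  }

  # forced exemplars: one read per label class on the first plain mature
  exemplar_mature <- "toy-miR-1"
  ex_entry <- entries_by_mature[[exemplar_mature]][1, ]
  ex_parent <- reference$matures[[exemplar_mature]]$parents[1]
  for (cls in names(spec$event_probs)) {
    edit <- edit_of_class(cls, ex_entry$sequence, exemplar_mature, ex_parent)
    for (s in spec$samples) {
      emit_read(s, exemplar_mature, ex_entry, "", ex_parent, edit)
    }
  }

  for (s in spec$samples) {
    for (mname in names(reference$matures)) {
      m <- reference$matures[[mname]]
      is_paralog <- !is.null(polymirs[[mname]]) &&
        polymirs[[mname]]$has_nonpolymorphic_paralog
      for (r in seq_len(spec$reads_per_mature)) {
        forced <- if (is_paralog) sample(m$parents, 1L) else NULL
        pe <- pick_entry(mname, s, forced)
        edit <- apply_edit(pe$entry$sequence, mname, pe$parent)
        emit_read(s, mname, pe$entry, pe$entry$haplotype, pe$parent, edit)
      }
    }
  }

  # planted genotype-inconsistent reads: canonical-shape reads carrying the
  # first alternative allele regardless of the sample's genotype
  if (!is.null(spec$inject_inconsistent)) {
    for (ii in seq_len(nrow(spec$inject_inconsistent))) {
      row <- spec$inject_inconsistent[ii, ]
      pm <- polymirs[[row$mature]]
      assert_that(!is.null(pm), paste0(row$mature, " is not a polymiR"))
      ent <- entries_by_mature[[row$mature]]
      alt1 <- strsplit(pm$variants$alts_mature[1], ",", fixed = TRUE)[[1]][1]
      want <- paste0(pm$variants$variant_id, "=",
                     c(alt1, pm$variants$ref_mature[-1]), collapse = ";")
      entry <- ent[ent$haplotype == want, ][1, ]
      parent <- reference$matures[[row$mature]]$parents[1]
      for (k in seq_len(row$n_reads)) {
        edit <- list(insert = entry$sequence, trim5 = 0L, t5t = 0L, t5n = 0L,
                     trim3 = 0L, t3t = 0L, t3n = 0L, injected = TRUE)
        emit_read(row$sample_id, row$mature, entry, entry$haplotype, parent, edit)
      }
    }
  }

  fastq <- character(0)
  for (s in spec$samples) {
    p <- file.path(dir, paste0(s, ".fastq"))
    writeLines(fastq_recs[[s]], p)
    fastq[s] <- p
  }
  truth <- do.call(rbind, truth)
  truth_path <- file.path(dir, "truth.tsv")
  writeLines(paste0("# seed: ", spec$seed), truth_path)
  suppressWarnings(utils::write.table(truth, truth_path, sep = "\t",
                                      quote = FALSE, row.names = FALSE,
                                      col.names = TRUE, append = TRUE))
  list(fastq = fastq, truth = truth, truth_path = truth_path)
}

#' Generate a complete fixture bundle
#'
#' Seeds the RNG once with `spec$seed` and generates the reference set and
#' the simulated reads; identical specs therefore produce byte-identical
#' bundles.
#'
#' @param spec A [simulation_spec()].
#' @param dir Output directory.
#' @return List with `refset` and `reads` components.
#' @export
make_fixture_bundle <- function(spec, dir) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(spec$seed)
  refset <- make_reference_set(spec, dir)
  reads <- simulate_reads(spec, refset, dir)
  list(refset = refset, reads = reads)
}

#' Compare pipeline output against the planted truth
#'
#' @param result A [run_pipeline()] result on a fixture bundle.
#' @param truth Truth table from [simulate_reads()].
#' @param W5 5' weight used by the pipeline (to price expected scores).
#' @return List: `score_agreement` (fraction of distinct sample x insert keys
#'   whose pipeline score equals the planted `N5*W5 + N3`), `n_keys`,
#'   `allele_counts` (per sample x expected entry: truth vs observed weighted
#'   counts), `n_inconsistent_discarded`, and
#'   `n_uninjected_discarded` (discards among clean reads; zero on a
#'   noiseless run).
#' @export
recover_truth <- function(result, truth, W5 = 4L) {
  kept <- result$kept
  key <- function(s, q) paste(s, q, sep = "\r")
  truth$expected_score <- truth$N5 * W5 + truth$N3
  clean0 <- truth[!truth$injected, ]
  tk <- key(clean0$sample_id, clean0$insert)
  exp_score <- tapply(clean0$expected_score, tk, min)
  obs <- kept[!duplicated(key(kept$sample_id, kept$sequence)), ]
  obs_score <- stats::setNames(obs$score, key(obs$sample_id, obs$sequence))
  agree <- vapply(names(exp_score), function(k)
    !is.na(obs_score[k]) && obs_score[k] == exp_score[k], logical(1))
  # planted allele counts per sample x expected entry (clean reads only)
  clean <- truth[!truth$injected, ]
  truth_counts <- stats::aggregate(list(n_truth = rep(1, nrow(clean))),
                                   by = list(sample_id = clean$sample_id,
                                             entry = clean$expected_entry),
                                   FUN = sum)
  w <- kept$count * kept$weight
  obs_counts <- stats::aggregate(list(n_obs = w),
                                 by = list(sample_id = kept$sample_id,
                                           entry = kept$entry_name), FUN = sum)
  allele_counts <- merge(truth_counts, obs_counts, all = TRUE)
  inc <- result$inconsistent
  injected_keys <- unique(key(truth$sample_id[truth$injected],
                              truth$insert[truth$injected]))
  n_inc <- if (nrow(inc)) sum(inc$count * inc$weight) else 0
  n_uninjected <- if (nrow(inc))
    sum((inc$count * inc$weight)[!key(inc$sample_id, inc$sequence) %in%
                                   injected_keys]) else 0
  list(score_agreement = mean(agree), n_keys = length(exp_score),
       allele_counts = allele_counts,
       n_inconsistent_discarded = n_inc,
       n_uninjected_discarded = n_uninjected)
}
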
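#' Load a miRBase-style miRNA reference
#'
#' Reads mature and hairpin FASTA files together with a miRBase-dialect GFF3
#' of genomic coordinates (`miRNA` and `miRNA_primary_transcript` features,
#' `Name=` attributes) and assembles validated mature-miRNA records.
#'
#' A mature miRNA annotated at several genomic loci under the same name (a
#' paralogous family producing one identical mature sequence) is merged into a
#' single record carrying all loci and all parent hairpins. Every record is
#' checked against its annotation: the sequence length must equal the genomic
#' span at every locus, and the mature sequence must occur verbatim inside each
#' parent hairpin. Sequences are normalized internally to the DNA alphabet
#' (U -> T, uppercase).
#'
#' Parent hairpins are resolved by locus containment: a hairpin whose genomic
#' span contains a mature locus on the same strand is that locus's parent.
#'
#' @param mature_fasta Path to the mature miRNA FASTA.
#' @param hairpin_fasta Path to the hairpin (pri-miRNA) FASTA.
#' @param coords_gff3 Path to the GFF3 with genomic coordinates.
#' @return A list with components `matures` (named list of mature records;
#'   each has `name`, `sequence`, `loci` data frame, `parents` character
#'   vector and `offsets` data frame giving the 1-based position of the mature
#'   within each parent hairpin) and `hairpins` (named list with `name`,
#'   `sequence` and locus fields).
#' @export
load_reference <- function(mature_fasta, hairpin_fasta, coords_gff3) {
  mat_seqs <- Biostrings::readDNAStringSet(normalize_fasta_alphabet(mature_fasta))
  hp_seqs <- Biostrings::readDNAStringSet(normalize_fasta_alphabet(hairpin_fasta))
  names(mat_seqs) <- sub("\\s.*$", "", names(mat_seqs))
  names(hp_seqs) <- sub("\\s.*$", "", names(hp_seqs))

  gff <- rtracklayer::import(coords_gff3)
  is_mat <- as.character(gff$type) == "miRNA"
  is_hp <- as.character(gff$type) == "miRNA_primary_transcript"
  assert_that(any(is_mat), "GFF3 contains no miRNA features")

  hp_gr <- gff[is_hp]
  hairpins <- list()
  for (i in seq_along(hp_gr)) {
    nm <- hp_gr$Name[i]
    assert_that(nm %in% names(hp_seqs),
                paste0("hairpin '", nm, "' has coordinates but no FASTA sequence"))
    seq <- normalize_dna(as.character(hp_seqs[[nm]]))
    width <- GenomicRanges::width(hp_gr[i])
    assert_that(nchar(seq) == width,
                paste0("hairpin '", nm, "': sequence length ", nchar(seq),
                       " != genomic span ", width))
    hairpins[[nm]] <- list(
      name = nm, sequence = seq,
      chrom = as.character(GenomicRanges::seqnames(hp_gr[i])),
      start = GenomicRanges::start(hp_gr[i]),
      end = GenomicRanges::end(hp_gr[i]),
      strand = as.character(GenomicRanges::strand(hp_gr[i])))
  }

  mat_gr <- gff[is_mat]
  matures <- list()
  for (i in seq_along(mat_gr)) {
    nm <- mat_gr$Name[i]
    assert_that(nm %in% names(mat_seqs),
                paste0("mature '", nm, "' has coordinates but no FASTA sequence"))
    seq <- normalize_dna(as.character(mat_seqs[[nm]]))
    chrom <- as.character(GenomicRanges::seqnames(mat_gr[i]))
    start <- GenomicRanges::start(mat_gr[i])
    end <- GenomicRanges::end(mat_gr[i])
    strand <- as.character(GenomicRanges::strand(mat_gr[i]))
    assert_that(nchar(seq) == end - start + 1L,
                paste0("mature '", nm, "': sequence length ", nchar(seq),
                       " != genomic span ", end - start + 1L, " at ",
                       chrom, ":", start, "-", end))
    locus <- data.frame(chrom = chrom, start = start, end = end,
                        strand = strand, stringsAsFactors = FALSE)
    if (is.null(matures[[nm]])) {
      matures[[nm]] <- list(name = nm, sequence = seq, loci = locus,
                            parents = character(0),
                            offsets = data.frame(parent = character(0),
                                                 start = integer(0),
                                                 end = integer(0),
                                                 stringsAsFactors = FALSE))
    } else {
      assert_that(matures[[nm]]$sequence == seq,
                  paste0("mature '", nm, "' has inconsistent sequences across loci"))
      matures[[nm]]$loci <- rbind(matures[[nm]]$loci, locus)
    }
    # parent resolution by same-strand genomic containment
    for (hp in hairpins) {
      if (hp$chrom == chrom && hp$strand == strand &&
          hp$start <= start && end <= hp$end) {
        off <- regexpr(seq, hp$sequence, fixed = TRUE)
        assert_that(off > 0L,
                    paste0("mature '", nm, "' is not a substring of its parent hairpin '",
                           hp$name, "'"))
        if (!(hp$name %in% matures[[nm]]$parents)) {
          matures[[nm]]$parents <- c(matures[[nm]]$parents, hp$name)
          matures[[nm]]$offsets <- rbind(
            matures[[nm]]$offsets,
            data.frame(parent = hp$name, start = as.integer(off),
                       end = as.integer(off) + nchar(seq) - 1L,
                       stringsAsFactors = FALSE))
        }
      }
    }
  }
  list(matures = matures, hairpins = hairpins)
}

# miRBase FASTA files use the RNA alphabet; rewrite to a temporary DNA copy so
# Biostrings can parse either alphabet uniformly.
#' @keywords internal
#' @noRd
normalize_fasta_alphabet <- function(path) {
  lines <- readLines(path)
  body <- !startsWith(lines, ">")
  lines[body] <- chartr("Uu", "Tt", lines[body])
  tmp <- tempfile(fileext = ".fa")
  writeLines(lines, tmp)
  tmp
}

#' Map VCF variants onto mature miRNAs
#'
#' Intersects single-nucleotide variants with the genomic loci of mature
#' miRNAs and returns one polymiR record per mature that carries at least one
#' variant. Offsets are 0-based from the 5' end of the mature. On minus-strand
#' loci the offset is mirrored (`end - position`) and the alleles are
#' complemented onto the mature strand. A variant inside two overlapping
#' opposite-strand matures contributes to both polymiRs. Variants that fall
#' outside every mature locus are dropped with a warning; non-SNV records are
#' rejected.
#'
#' @param variants Data frame with columns `id`, `chrom`, `pos`, `ref`, `alt`
#'   (`alt` may be a comma-separated list), as returned by [load_variants()].
#' @param matures Named list of mature records from [load_reference()].
#' @return Named list of polymiR records; each has `mature_name`, a `variants`
#'   data frame (`variant_id`, `offset`, `ref_mature`, `alts_mature`,
#'   `ref_vcf`, `alts_vcf`, `strand`) and `has_nonpolymorphic_paralog`.
#' @export
map_variants <- function(variants, matures) {
  if (nrow(variants) > 0) {
    bad <- nchar(variants$ref) != 1L |
      vapply(strsplit(variants$alt, ",", fixed = TRUE),
             function(a) any(nchar(a) != 1L), logical(1))
    assert_that(!any(bad),
                paste0("only single-nucleotide variants are supported; offending: ",
                       paste(variants$id[bad], collapse = ", ")))
  }
  polymirs <- list()
  hit <- rep(FALSE, nrow(variants))
  for (m in matures) {
    rows <- NULL
    for (li in seq_len(nrow(m$loci))) {
      loc <- m$loci[li, ]
      in_locus <- which(variants$chrom == loc$chrom &
                        variants$pos >= loc$start & variants$pos <= loc$end)
      if (length(in_locus) == 0) next
      hit[in_locus] <- TRUE
      for (vi in in_locus) {
        v <- variants[vi, ]
        alts_vcf <- strsplit(v$alt, ",", fixed = TRUE)[[1]]
        if (loc$strand == "-") {
          offset <- loc$end - v$pos
          ref_m <- dna_complement(v$ref)
          alts_m <- dna_complement(alts_vcf)
        } else {
          offset <- v$pos - loc$start
          ref_m <- v$ref
          alts_m <- alts_vcf
        }
        row <- data.frame(variant_id = v$id, offset = as.integer(offset),
                          ref_mature = ref_m,
                          alts_mature = paste(alts_m, collapse = ","),
                          ref_vcf = v$ref, alts_vcf = paste(alts_vcf, collapse = ","),
                          strand = loc$strand, stringsAsFactors = FALSE)
        rows <- rbind(rows, row)
      }
    }
    if (is.null(rows)) next
    rows <- unique(rows)
    assert_that(all(rows$offset >= 0 & rows$offset < nchar(m$sequence)),
                paste0("variant offset out of range on ", m$name))
    rows <- rows[order(rows$offset, rows$variant_id), , drop = FALSE]
    # a mature with several loci where at least one locus lacks the variant
    # keeps producing reference-allele reads from the variant-free copy
    n_loci <- nrow(m$loci)
    n_loci_with_variant <- max(table(rows$variant_id))
    polymirs[[m$name]] <- list(
      mature_name = m$name,
      variants = rows,
      has_nonpolymorphic_paralog = n_loci > 1 && n_loci_with_variant < n_loci)
  }
  if (any(!hit) && nrow(variants) > 0) {
    warning(sum(!hit), " variant(s) outside all mature loci were excluded: ",
            paste(variants$id[!hit], collapse = ", "), call. = FALSE)
  }
  polymirs
}

#' Read variants (and genotypes, if present) from a VCF
#'
#' @param vcf_path Path to a VCF v4.x file, plain or gzipped.
#' @return A list with `variants` (data frame: `id`, `chrom`, `pos`, `ref`,
#'   `alt`) and `genotypes` (character matrix of GT strings, variants x
#'   samples, or `NULL` when the VCF has no sample columns).
#' @export
load_variants <- function(vcf_path) {
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  id <- fix$ID
  missing_id <- is.na(id) | id == "."
  id[missing_id] <- paste0(fix$CHROM[missing_id], ":", fix$POS[missing_id])
  variants <- data.frame(id = id, chrom = fix$CHROM,
                         pos = as.integer(fix$POS),
                         ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)
  genotypes <- NULL
  if (ncol(vcf@gt) > 1) {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    rownames(gt) <- variants$id
    genotypes <- gt
  }
  list(variants = variants, genotypes = genotypes)
}

#' Enumerate haplotype sequences of a polymiR
#'
#' Generates one library entry per haplotype over the Cartesian product of the
#' alleles of every variant on the mature, including the canonical
#' (all-reference) entry. Alternative entries are named
#' `<mature>|<rsID><allele>[,...]` with variants ordered by offset; the
#' canonical entry keeps the bare mature name.
#'
#' @param polymir A polymiR record from [map_variants()] (or `NULL` for a
#'   non-polymorphic mature).
#' @param mature The matching mature record.
#' @return Data frame of entries: `entry_name`, `mature_name`, `sequence`,
#'   `is_canonical`, `haplotype` (string `rsID=allele;...` on the mature
#'   strand; empty for variant-free matures).
#' @export
enumerate_haplotypes <- function(polymir, mature) {
  canonical <- data.frame(entry_name = mature$name, mature_name = mature$name,
                          sequence = mature$sequence, is_canonical = TRUE,
                          haplotype = "", stringsAsFactors = FALSE)
  if (is.null(polymir) || nrow(polymir$variants) == 0) return(canonical)
  v <- polymir$variants
  allele_sets <- lapply(seq_len(nrow(v)), function(i)
    c(v$ref_mature[i], strsplit(v$alts_mature[i], ",", fixed = TRUE)[[1]]))
  names(allele_sets) <- v$variant_id
  grid <- expand.grid(rev(allele_sets), stringsAsFactors = FALSE)
  grid <- grid[, rev(seq_len(ncol(grid))), drop = FALSE]  # variant order by offset
  entries <- NULL
  for (g in seq_len(nrow(grid))) {
    alleles <- as.character(grid[g, ])
    is_ref <- alleles == v$ref_mature
    seq <- mature$sequence
    for (i in seq_len(nrow(v))) {
      substr(seq, v$offset[i] + 1L, v$offset[i] + 1L) <- alleles[i]
    }
    if (all(is_ref)) {
      canonical$sequence <- seq  # identical to mature by construction
      next
    }
    tag <- paste0(v$variant_id[!is_ref], alleles[!is_ref], collapse = ",")
    entries <- rbind(entries, data.frame(
      entry_name = paste0(mature$name, "|", tag),
      mature_name = mature$name, sequence = seq, is_canonical = FALSE,
      haplotype = paste0(v$variant_id, "=", alleles, collapse = ";"),
      stringsAsFactors = FALSE))
  }
  canonical$haplotype <- paste0(v$variant_id, "=", v$ref_mature, collapse = ";")
  out <- rbind(canonical, entries[order(entries$entry_name), , drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Build the augmented alignment library
#'
#' Assembles the full set of alignment targets — one canonical entry per
#' mature plus one entry per alternative haplotype of every polymiR — and
#' optionally serializes it as a FASTA with a sidecar TSV of entry metadata.
#' Output files are byte-stable across reruns on identical inputs.
#'
#' @param reference Reference bundle from [load_reference()].
#' @param polymirs PolymiR list from [map_variants()] (may be empty).
#' @param fasta_out,metadata_out Optional output paths.
#' @return A library object: data frame of entries (`entry_name`,
#'   `mature_name`, `sequence`, `is_canonical`, `haplotype`,
#'   `has_nonpolymorphic_paralog`, `parents`) with the polymiR list and the
#'   reference attached as attributes.
#' @export
build_library <- function(reference, polymirs = list(),
                          fasta_out = NULL, metadata_out = NULL) {
  entries <- NULL
  for (m in reference$matures) {
    ent <- enumerate_haplotypes(polymirs[[m$name]], m)
    ent$has_nonpolymorphic_paralog <-
      !is.null(polymirs[[m$name]]) && polymirs[[m$name]]$has_nonpolymorphic_paralog
    ent$parents <- paste(m$parents, collapse = ",")
    entries <- rbind(entries, ent)
  }
  entries <- entries[order(entries$mature_name, !entries$is_canonical,
                           entries$entry_name), , drop = FALSE]
  rownames(entries) <- NULL
  assert_that(!anyDuplicated(entries$entry_name),
              "duplicate entry names in alignment library")
  lib <- entries
  attr(lib, "polymirs") <- polymirs
  attr(lib, "reference") <- reference
  class(lib) <- c("mirna_library", class(lib))
  if (!is.null(fasta_out)) {
    writeLines(paste0(">", entries$entry_name, "\n", entries$sequence), fasta_out)
  }
  if (!is.null(metadata_out)) {
    meta <- entries[, c("entry_name", "mature_name", "is_canonical",
                        "haplotype", "parents", "has_nonpolymorphic_paralog")]
    write_tsv_file(meta, metadata_out)
  }
  lib
}
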
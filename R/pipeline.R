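#' Pipeline configuration
#'
#' Bundles every tunable of the workflow with its default: 5' event weight 4,
#' score threshold 9, seed length 17, at most 10 soft-clipped bases per end,
#' 15--27 nt insert window, Phred floor 28, the standard 3' adapter, and the
#' 1% / 5-read / 500-read genotype-consistency thresholds. Every field can be
#' overridden.
#'
#' @param W5,score_threshold,iso5p_sign See [scoring_config()].
#' @param seed_len Seed length (minimum exact-match core).
#' @param max_clip Maximum soft-clipped bases per read end.
#' @param min_len,max_len,min_quality,adapter3 See [preprocess_config()].
#' @param rate_threshold,min_reads,low_count_total See [consistency_config()].
#' @param pre_trimmed Treat FASTQ input as already adapter/quality trimmed.
#' @param sample_map Optional named vector mapping pipeline sample ids to VCF
#'   sample names.
#' @return A `pipeline_config` list with the three stage configs attached.
#' @export
pipeline_config <- function(W5 = 4L, score_threshold = 9L,
                            iso5p_sign = "trim-positive",
                            seed_len = 17L, max_clip = 10L,
                            min_len = 15L, max_len = 27L, min_quality = 28L,
                            adapter3 = "GATCGGAAGAGCACACGTCTGAACTCCAGTCAC",
                            rate_threshold = 0.01, min_reads = 5,
                            low_count_total = 500, pre_trimmed = FALSE,
                            sample_map = NULL) {
  structure(list(
    seed_len = as.integer(seed_len), max_clip = as.integer(max_clip),
    pre_trimmed = pre_trimmed, sample_map = sample_map,
    preprocess = preprocess_config(adapter3 = adapter3,
                                   min_quality = min_quality,
                                   min_len = min_len, max_len = max_len),
    scoring = scoring_config(W5 = W5, score_threshold = score_threshold,
                             iso5p_sign = iso5p_sign),
    consistency = consistency_config(rate_threshold = rate_threshold,
                                     min_reads = min_reads,
                                     low_count_total = low_count_total)),
    class = "pipeline_config")
}

#' Run the full workflow
#'
#' Reference loading, library augmentation, preprocessing, alignment, editing
#' annotation and scoring, cross-mapping disambiguation, score filtering,
#' genotype-consistency filtering (skipped when no genotypes are available),
#' and output generation. All output files are deterministic: two runs on
#' identical inputs are byte identical.
#'
#' Files written to `out_dir`: `library.fa` + `library_metadata.tsv`,
#' `abundance_merged.tsv`, `abundance_polymir.tsv`, `abundance_isomir.tsv`,
#' `results.gff3` (mirGFF3), `remaining_ambiguous.annot`,
#' `expressed_hairpins.annot`, `consistency_table.annot`,
#' `inconsistents.sam`, `run_summary.json`.
#'
#' @param mature_fasta,hairpin_fasta,coords_gff3 Reference inputs.
#' @param fastqs Named character vector of FASTQ paths; names are sample ids
#'   (file stems when unnamed).
#' @param vcf Optional VCF of variants (with or without genotype columns).
#' @param out_dir Output directory.
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the library, all intermediate alignment
#'   tables (`candidates`, `scored`, `retained`, `score_discarded`, `kept`,
#'   `inconsistent`), consistency `decisions`, abundance `counts`, the
#'   per-sample stage `ledger` and `out_dir`.
#' @export
run_pipeline <- function(mature_fasta, hairpin_fasta, coords_gff3, fastqs,
                         vcf = NULL, out_dir = "polymir_out",
                         config = pipeline_config()) {
  assert_that(length(fastqs) >= 1, "at least one FASTQ is required")
  if (is.null(names(fastqs)) || any(names(fastqs) == "")) {
    names(fastqs) <- sub("\\.(fastq|fq)(\\.gz)?$", "", basename(fastqs))
  }
  samples <- names(fastqs)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  reference <- load_reference(mature_fasta, hairpin_fasta, coords_gff3)
  polymirs <- list(); genotypes <- NULL; variants <- NULL
  if (!is.null(vcf)) {
    lv <- load_variants(vcf)
    variants <- lv$variants
    polymirs <- map_variants(lv$variants, reference$matures)
    genotypes <- lv$genotypes
  }
  library <- build_library(reference, polymirs,
                           fasta_out = file.path(out_dir, "library.fa"),
                           metadata_out = file.path(out_dir, "library_metadata.tsv"))
  index <- build_seed_index(library, k = config$seed_len)

  reads <- list(); ledger <- list()
  for (s in samples) {
    rd <- preprocess_fastq(fastqs[[s]], s, config$preprocess,
                           pre_trimmed = config$pre_trimmed)
    reads[[s]] <- rd
    ledger[[s]] <- list(raw = attr(rd, "n_raw"), post_filter = sum(rd$count))
  }
  all_reads <- do.call(rbind, reads)
  candidates <- align_reads(all_reads, index, max_clip = config$max_clip)
  scored <- annotate_alignments(candidates, library, config$scoring)
  retained <- disambiguate(scored, library)
  fs <- filter_by_score(retained, config$scoring)
  calls <- if (!is.null(genotypes))
    load_genotypes(genotypes, variants, samples, config$sample_map) else NULL
  cc <- check_consistency(fs$passed, library, calls, config$consistency)
  if (cc$skipped && !is.null(vcf)) {
    message("VCF has no genotype columns; consistency step skipped")
  }
  kept <- cc$kept

  for (s in samples) {
    cand_s <- candidates[candidates$sample_id == s, , drop = FALSE]
    ret_s <- retained[retained$sample_id == s, , drop = FALSE]
    ledger[[s]]$mapped <- sum(all_reads$count[all_reads$sample_id == s &
                                  all_reads$sequence %in% cand_s$sequence])
    ledger[[s]]$ambiguous <- sum(ret_s$count[ret_s$ambiguous] *
                                   ret_s$weight[ret_s$ambiguous])
    ledger[[s]]$score_discarded <- sum(
      fs$discarded$count[fs$discarded$sample_id == s] *
        fs$discarded$weight[fs$discarded$sample_id == s])
    ledger[[s]]$consistency_discarded <- sum(
      cc$discarded$count[cc$discarded$sample_id == s] *
        cc$discarded$weight[cc$discarded$sample_id == s])
    ledger[[s]]$final <- sum(kept$count[kept$sample_id == s] *
                               kept$weight[kept$sample_id == s])
  }

  counts <- merge_counts(kept, library, samples)
  write_count_table <- function(df, path) {
    for (s in samples) df[[s]] <- vapply(df[[s]], render_weight, character(1))
    write_tsv_file(df, path)
  }
  write_count_table(counts$merged, file.path(out_dir, "abundance_merged.tsv"))
  write_count_table(counts$polymir, file.path(out_dir, "abundance_polymir.tsv"))
  write_count_table(counts$isomir, file.path(out_dir, "abundance_isomir.tsv"))
  write_mirgff3(kept, file.path(out_dir, "results.gff3"), samples)
  write_annotations(kept, cc$decisions, library, out_dir)
  write_sam(cc$discarded, library, file.path(out_dir, "inconsistents.sam"))

  summary <- list(
    samples = as.list(stats::setNames(
      lapply(ledger, function(l) lapply(l, function(x) round(x, 4))), samples)),
    n_library_entries = nrow(library),
    n_polymirs = length(polymirs),
    consistency_skipped = cc$skipped)
  jsonlite::write_json(summary, file.path(out_dir, "run_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(library = library, candidates = candidates, scored = scored,
                 retained = retained, score_discarded = fs$discarded,
                 kept = kept, inconsistent = cc$discarded,
                 decisions = cc$decisions, skipped_consistency = cc$skipped,
                 counts = counts, ledger = ledger, out_dir = out_dir))
}
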
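#' Genotype-consistency configuration
#'
#' An alternative (or unexpected) allele observed in a sample that should not
#' carry it is called plausible — and therefore reported for investigation —
#' when it is supported by more than `rate_threshold` of the
#' allele-informative reads on that polymiR. Because a percentage is
#' unstable at low depth, polymiRs with fewer than `low_count_total`
#' informative reads switch to an absolute floor of `min_reads` supporting
#' reads.
#'
#' @param rate_threshold Fraction of total reads above which an unexpected
#'   allele is plausible (default 0.01).
#' @param min_reads Supporting-read floor used at low depth (default 5).
#' @param low_count_total Depth below which the absolute floor applies
#'   (default 500).
#' @return A `consistency_config` list.
#' @export
consistency_config <- function(rate_threshold = 0.01, min_reads = 5,
                               low_count_total = 500) {
  assert_that(rate_threshold > 0 && min_reads > 0 && low_count_total > 0,
              "all consistency thresholds must be positive")
  structure(list(rate_threshold = rate_threshold, min_reads = min_reads,
                 low_count_total = low_count_total),
            class = "consistency_config")
}

#' Parse per-sample genotype calls from a GT matrix
#'
#' @param genotypes GT character matrix (variants x samples) as returned by
#'   [load_variants()], or `NULL`.
#' @param variants Variant table from [load_variants()] (for allele strings).
#' @param samples Sample ids requested; absent samples yield missing calls.
#' @param sample_map Optional named character vector translating pipeline
#'   sample ids to VCF sample names (e.g. after prefix stripping).
#' @return Nested list `calls[[sample]][[variant_id]]` with fields `type`
#'   (`hom_ref`, `het`, `hom_alt`, `missing`) and `alleles` (VCF-scale allele
#'   strings present in the genotype), or `NULL` when `genotypes` is `NULL`.
#' @export
load_genotypes <- function(genotypes, variants, samples,
                           sample_map = NULL) {
  if (is.null(genotypes)) return(NULL)
  calls <- list()
  for (s in samples) {
    vcf_name <- if (!is.null(sample_map) && s %in% names(sample_map))
      sample_map[[s]] else s
    calls[[s]] <- list()
    for (vi in seq_len(nrow(variants))) {
      vid <- variants$id[vi]
      gt <- if (vcf_name %in% colnames(genotypes) && vid %in% rownames(genotypes))
        genotypes[vid, vcf_name] else NA_character_
      calls[[s]][[vid]] <- parse_gt_call(gt, variants$ref[vi], variants$alt[vi])
    }
  }
  calls
}

#' @keywords internal
#' @noRd
parse_gt_call <- function(gt, ref, alt) {
  missing_call <- list(type = "missing", alleles = character(0))
  if (is.na(gt) || gt == "") return(missing_call)
  idx <- strsplit(gt, "[/|]")[[1]]
  if (any(idx == ".") || length(idx) == 0) return(missing_call)
  idx <- suppressWarnings(as.integer(idx))
  allele_strings <- c(ref, strsplit(alt, ",", fixed = TRUE)[[1]])
  if (anyNA(idx) || any(idx < 0) || any(idx >= length(allele_strings))) {
    warning("malformed GT '", gt, "' treated as missing", call. = FALSE)
    return(missing_call)
  }
  alleles <- unique(allele_strings[idx + 1L])
  type <- if (all(idx == 0)) "hom_ref"
  else if (all(idx == idx[1])) "hom_alt"
  else "het"
  list(type = type, alleles = alleles)
}

# haplotype string "rs1=A;rs2=G" -> named character vector (mature strand)
#' @keywords internal
#' @noRd
parse_haplotype <- function(hap) {
  if (is.na(hap) || hap == "") return(stats::setNames(character(0), character(0)))
  kv <- strsplit(strsplit(hap, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
  stats::setNames(vapply(kv, `[`, character(1), 2L),
                  vapply(kv, `[`, character(1), 1L))
}

#' Allele evidence carried by one polymiR alignment
#'
#' A read supports an allele at a variant only when its exactly matched core
#' covers the variant's position on the mature; variants outside the span
#' contribute no evidence.
#'
#' @param alignment One annotated alignment row (with `ref_start`,
#'   `ref_end`).
#' @param polymir The polymiR record for the alignment's mature.
#' @param haplotype Named mature-strand allele vector of the aligned entry
#'   (from the library `haplotype` column via the internal parser).
#' @return Named character vector: covered `variant_id` -> mature-strand
#'   allele carried by the entry; empty when no variant is covered.
#' @export
infer_supported_allele <- function(alignment, polymir, haplotype) {
  off <- covered_variant_offsets(alignment, polymir)
  if (length(off) == 0) return(stats::setNames(character(0), character(0)))
  ids <- polymir$variants$variant_id[match(off, polymir$variants$offset)]
  haplotype[ids]
}

#' Check polymiR alignments against sample genotypes
#'
#' Compares the allele implied by every polymiR alignment with the sample's
#' genotype. An alignment is inconsistent — and discarded — when any variant
#' covered by its core carries an allele absent from the genotype. Two
#' exceptions: a missing genotype never triggers a discard, and when the
#' mature has a non-polymorphic paralog locus, reference-allele reads are
#' always kept (they can originate from the variant-free copy regardless of
#' the genotype). Discarded allele groups are labelled plausible per
#' [consistency_config()] and surface in the consistency table for manual
#' follow-up.
#'
#' Supporting and total tallies use weighted read counts (collapsed
#' multiplicity times disambiguation weight) over allele-informative reads
#' only, i.e. reads whose core covers the variant.
#'
#' @param alignments Score-filtered alignment table (any number of samples).
#' @param library Library from [build_library()].
#' @param genotype_calls Output of [load_genotypes()]; `NULL` skips the step.
#' @param config A [consistency_config()].
#' @return List: `kept` and `discarded` alignment tables (discarded rows gain
#'   a `reason` column), `decisions` data frame (sample, mature, variant,
#'   allele on both strands, genotype, expected, supporting, total, rate,
#'   plausible, action) and `skipped` flag.
#' @export
check_consistency <- function(alignments, library, genotype_calls,
                              config = consistency_config()) {
  empty_dec <- data.frame(
    sample_id = character(0), mature_name = character(0),
    variant_id = character(0), allele_mature = character(0),
    allele_vcf = character(0), genotype = character(0), expected = logical(0),
    supporting = numeric(0), total = numeric(0), rate = numeric(0),
    plausible = logical(0), action = character(0), stringsAsFactors = FALSE)
  if (is.null(genotype_calls)) {
    return(list(kept = alignments, discarded = alignments[0, , drop = FALSE],
                decisions = empty_dec, skipped = TRUE))
  }
  polymirs <- attr(library, "polymirs")
  lib_df <- as.data.frame(library)
  n <- nrow(alignments)
  discard <- rep(FALSE, n); reason <- rep(NA_character_, n)
  decisions <- list()
  if (n > 0) {
    hap_by_entry <- lapply(
      stats::setNames(lib_df$haplotype, lib_df$entry_name), parse_haplotype)
    # evidence per row: covered variant -> allele
    evidence <- lapply(seq_len(n), function(i) {
      pm <- polymirs[[alignments$mature_name[i]]]
      if (is.null(pm)) return(stats::setNames(character(0), character(0)))
      infer_supported_allele(alignments[i, ], pm,
                             hap_by_entry[[alignments$entry_name[i]]])
    })
    w <- alignments$count * alignments$weight
    groups <- split(seq_len(n),
                    paste(alignments$sample_id, alignments$mature_name, sep = "\r"))
    for (idx in groups) {
      s <- alignments$sample_id[idx[1]]
      m <- alignments$mature_name[idx[1]]
      pm <- polymirs[[m]]
      if (is.null(pm)) next
      for (vi in seq_len(nrow(pm$variants))) {
        vid <- pm$variants$variant_id[vi]
        ref_m <- pm$variants$ref_mature[vi]
        alts_m <- strsplit(pm$variants$alts_mature[vi], ",", fixed = TRUE)[[1]]
        alts_v <- strsplit(pm$variants$alts_vcf[vi], ",", fixed = TRUE)[[1]]
        to_vcf <- stats::setNames(c(pm$variants$ref_vcf[vi], alts_v),
                                  c(ref_m, alts_m))
        covering <- idx[vapply(idx, function(i) vid %in% names(evidence[[i]]),
                               logical(1))]
        if (length(covering) == 0) next
        allele_of <- vapply(covering, function(i) evidence[[i]][[vid]], character(1))
        total <- sum(w[covering])
        call <- genotype_calls[[s]][[vid]]
        if (is.null(call)) call <- list(type = "missing", alleles = character(0))
        expected_m <- names(to_vcf)[to_vcf %in% call$alleles]
        for (al in sort(unique(allele_of))) {
          rows <- covering[allele_of == al]
          supporting <- sum(w[rows])
          expected <- call$type == "missing" || al %in% expected_m
          protected <- pm$has_nonpolymorphic_paralog && al == ref_m
          plausible <- NA
          action <- "keep"
          if (!expected && !protected) {
            plausible <- if (total >= config$low_count_total)
              supporting / total > config$rate_threshold
            else supporting >= config$min_reads
            action <- if (plausible) "discard+report" else "discard+silent"
            discard[rows] <- TRUE
            reason[rows] <- paste0(vid, ":", al, " absent from genotype")
          }
          decisions[[length(decisions) + 1L]] <- data.frame(
            sample_id = s, mature_name = m, variant_id = vid,
            allele_mature = al, allele_vcf = unname(to_vcf[al]),
            genotype = call$type, expected = expected,
            supporting = supporting, total = total,
            rate = supporting / total, plausible = plausible, action = action,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  dec <- if (length(decisions)) do.call(rbind, decisions) else empty_dec
  dec <- dec[order(dec$sample_id, dec$mature_name, dec$variant_id,
                   dec$allele_mature, method = "radix"), , drop = FALSE]
  rownames(dec) <- NULL
  discarded <- alignments[discard, , drop = FALSE]
  if (nrow(discarded) > 0) discarded$reason <- reason[discard]
  list(kept = alignments[!discard, , drop = FALSE], discarded = discarded,
       decisions = dec, skipped = FALSE)
}
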
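#' Preprocessing configuration
#'
#' Defaults reflect a typical NEBNext-style small-RNA library: the printed 3'
#' adapter, a Phred quality floor of 28 for 3'-end trimming, and the
#' 15--27 nt insert window that captures mature miRNAs.
#'
#' @param adapter3 3' adapter sequence searched (as a prefix) in the read.
#' @param min_quality Phred threshold; the maximal 3' suffix of bases below it
#'   is removed before adapter search.
#' @param min_len,max_len Inclusive insert-length window kept for alignment.
#' @param min_overlap Minimum read/adapter overlap for adapter removal.
#' @param max_error_rate Mismatch fraction tolerated over the overlap.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(adapter3 = "GATCGGAAGAGCACACGTCTGAACTCCAGTCAC",
                              min_quality = 28L, min_len = 15L, max_len = 27L,
                              min_overlap = 3L, max_error_rate = 0.1) {
  assert_that(nchar(adapter3) > 0, "adapter3 must be non-empty")
  assert_that(min_len <= max_len, "min_len must be <= max_len")
  structure(list(adapter3 = normalize_dna(adapter3),
                 min_quality = as.integer(min_quality),
                 min_len = as.integer(min_len), max_len = as.integer(max_len),
                 min_overlap = as.integer(min_overlap),
                 max_error_rate = max_error_rate),
            class = "preprocess_config")
}

#' Trim quality and adapter from one read
#'
#' First removes the maximal 3' suffix whose bases are all below
#' `min_quality`, then searches for the 3' adapter: the earliest read position
#' where a prefix of the adapter matches the remaining read suffix with at
#' most `max_error_rate` mismatches over an overlap of at least `min_overlap`
#' bases. Everything from that position on is removed. Full-length adapter
#' occurrences and run-through partial prefixes are both caught.
#'
#' @param read_seq Read sequence (character).
#' @param read_qual Integer vector of Phred scores, same length as the read,
#'   or `NULL` to skip quality trimming.
#' @param config A [preprocess_config()].
#' @return The trimmed insert, or `NA_character_` if nothing remains.
#' @export
trim_adapter <- function(read_seq, read_qual = NULL, config = preprocess_config()) {
  read_seq <- normalize_dna(read_seq)
  n <- nchar(read_seq)
  if (!is.null(read_qual)) {
    assert_that(length(read_qual) == n,
                "sequence and quality strings must have equal length")
    keep <- n
    while (keep > 0 && read_qual[keep] < config$min_quality) keep <- keep - 1L
    if (keep == 0) return(NA_character_)
    read_seq <- substr(read_seq, 1L, keep)
    n <- keep
  }
  rv <- strsplit(read_seq, "", fixed = TRUE)[[1]]
  av <- strsplit(config$adapter3, "", fixed = TRUE)[[1]]
  for (start in seq_len(n)) {
    ov <- min(n - start + 1L, length(av))
    if (ov < config$min_overlap) break
    mism <- sum(rv[start:(start + ov - 1L)] != av[seq_len(ov)])
    if (mism <= floor(config$max_error_rate * ov)) {
      if (start == 1L) return(NA_character_)
      return(substr(read_seq, 1L, start - 1L))
    }
  }
  read_seq
}

#' Length-filter and collapse trimmed reads
#'
#' Discards inserts outside the configured length window, groups identical
#' sequences and sums their multiplicities. Output rows are sorted
#' lexicographically by sequence so results are deterministic.
#'
#' @param seqs Character vector of trimmed inserts (`NA`s are dropped).
#' @param sample_id Sample label attached to every collapsed read.
#' @param config A [preprocess_config()].
#' @param counts Optional multiplicities per input sequence (default 1 each).
#' @return Data frame of processed reads: `sequence`, `count`, `sample_id`.
#' @export
filter_and_collapse <- function(seqs, sample_id = "sample",
                                config = preprocess_config(), counts = NULL) {
  if (is.null(counts)) counts <- rep(1L, length(seqs))
  keep <- !is.na(seqs)
  seqs <- normalize_dna(seqs[keep]); counts <- counts[keep]
  len <- nchar(seqs)
  keep <- len >= config$min_len & len <= config$max_len
  seqs <- seqs[keep]; counts <- counts[keep]
  if (length(seqs) == 0) {
    return(data.frame(sequence = character(0), count = integer(0),
                      sample_id = character(0), stringsAsFactors = FALSE))
  }
  agg <- stats::aggregate(list(count = counts), by = list(sequence = seqs), FUN = sum)
  agg <- agg[order(agg$sequence, method = "radix"), , drop = FALSE]
  rownames(agg) <- NULL
  agg$sample_id <- sample_id
  agg
}

#' Preprocess a FASTQ file into collapsed reads
#'
#' Runs [trim_adapter()] and [filter_and_collapse()] over a (optionally
#' gzipped) FASTQ. With `pre_trimmed = TRUE` the adapter/quality step is
#' skipped and reads are only length-filtered and collapsed, which matches
#' input that was already trimmed upstream.
#'
#' @param fastq Path to the FASTQ file.
#' @param sample_id Sample label; defaults to the file name stem.
#' @param config A [preprocess_config()].
#' @param pre_trimmed Skip adapter and quality trimming.
#' @return Data frame of processed reads (`sequence`, `count`, `sample_id`)
#'   with the raw read count in attribute `n_raw`.
#' @export
preprocess_fastq <- function(fastq, sample_id = NULL,
                             config = preprocess_config(), pre_trimmed = FALSE) {
  if (is.null(sample_id)) {
    sample_id <- sub("\\.(fastq|fq)(\\.gz)?$", "", basename(fastq))
  }
  # the reader warns about dropping (empty) metadata columns; harmless
  rd <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(fastq))
  seqs <- as.character(rd)
  if (pre_trimmed) {
    trimmed <- seqs
  } else {
    quals <- as(Biostrings::quality(rd), "IntegerList")
    trimmed <- vapply(seq_along(seqs), function(i)
      trim_adapter(seqs[[i]], quals[[i]], config), character(1))
  }
  out <- filter_and_collapse(trimmed, sample_id, config)
  attr(out, "n_raw") <- length(seqs)
  out
}
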
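#' Build a k-mer seed index over the alignment library
#'
#' Indexes every k-mer of every library entry. A read can only align if it
#' shares at least one exact k-mer with an entry, which is what the seed
#' length enforces: the matched core of any reported alignment is at least
#' `k` consecutive, perfectly matching nucleotides.
#'
#' @param library Library data frame from [build_library()] (or any data
#'   frame with `entry_name` and `sequence`).
#' @param k Seed length (default 17).
#' @return A `seed_index` object.
#' @export
build_seed_index <- function(library, k = 17L) {
  assert_that(k >= 1L, "seed length k must be >= 1")
  assert_that(nrow(library) >= 1L, "empty alignment library")
  k <- as.integer(k)
  short <- nchar(library$sequence) < k
  if (any(short)) {
    warning("skipping ", sum(short), " entries shorter than the seed length: ",
            paste(library$entry_name[short], collapse = ", "), call. = FALSE)
    library <- library[!short, , drop = FALSE]
  }
  assert_that(nrow(library) >= 1L, "no library entries of at least seed length")
  n_each <- nchar(library$sequence) - k + 1L
  all_kmers <- character(sum(n_each)); all_entries <- integer(sum(n_each))
  all_offsets <- integer(sum(n_each))
  pos <- 1L
  for (i in seq_len(nrow(library))) {
    s <- library$sequence[i]
    for (o in seq_len(n_each[i])) {
      all_kmers[pos] <- substr(s, o, o + k - 1L)
      all_entries[pos] <- i
      all_offsets[pos] <- o
      pos <- pos + 1L
    }
  }
  postings <- split(data.frame(entry = all_entries, offset = all_offsets),
                    all_kmers)
  keep_cols <- intersect(c("entry_name", "mature_name", "sequence",
                           "is_canonical", "haplotype"), names(library))
  structure(list(k = k, postings = postings,
                 entries = as.data.frame(library)[, keep_cols, drop = FALSE],
                 entry_chars = strsplit(library$sequence, "", fixed = TRUE),
                 full_library = library),
            class = "seed_index")
}

#' Align one read against the library
#'
#' Seed-and-extend exact-core local alignment on the forward strand only.
#' Every shared 17-mer (seed) between read and entry is extended greedily in
#' both directions while bases keep matching; the maximal cores found this
#' way are the only alignments considered. A candidate is reported when its
#' core is at least the seed length and no more than `max_clip` read bases
#' hang over at either end (soft clips). Per entry, a single candidate is
#' kept: longest core, ties broken by smallest reference start, then smallest
#' read start. The core never contains a mismatch; trimming and tailing are
#' inferred downstream from the core bounds and the clipped bases.
#'
#' @param read_seq Read sequence (15--27 nt after preprocessing).
#' @param index A [build_seed_index()] object.
#' @param max_clip Maximum soft-clipped bases per read end (default 10).
#' @return Data frame of candidates with 1-based inclusive coordinates:
#'   `entry_name`, `read_start`, `read_end`, `ref_start`, `ref_end`, `clip5`,
#'   `clip3`, `core_len`. Zero rows when the read does not align.
#' @export
align_read <- function(read_seq, index, max_clip = 10L) {
  read_seq <- normalize_dna(read_seq)
  k <- index$k
  n <- nchar(read_seq)
  empty <- data.frame(entry_name = character(0), read_start = integer(0),
                      read_end = integer(0), ref_start = integer(0),
                      ref_end = integer(0), clip5 = character(0),
                      clip3 = character(0), core_len = integer(0),
                      stringsAsFactors = FALSE)
  if (n < k) return(empty)
  rv <- strsplit(read_seq, "", fixed = TRUE)[[1]]
  hits <- list()  # per entry: set of diagonals already extended
  best <- list()  # per entry index: best candidate row
  for (s in seq_len(n - k + 1L)) {
    posting <- index$postings[[substr(read_seq, s, s + k - 1L)]]
    if (is.null(posting)) next
    for (p in seq_len(nrow(posting))) {
      ei <- posting$entry[p]
      ref_off <- posting$offset[p]
      diag_id <- paste0(ei, ":", s - ref_off)
      if (!is.null(hits[[diag_id]])) next
      hits[[diag_id]] <- TRUE
      ev <- index$entry_chars[[ei]]
      # maximal extension of this seed along its diagonal
      rs <- s; es <- ref_off
      while (rs > 1L && es > 1L && rv[rs - 1L] == ev[es - 1L]) {
        rs <- rs - 1L; es <- es - 1L
      }
      re <- s + k - 1L; ee <- ref_off + k - 1L
      while (re < n && ee < length(ev) && rv[re + 1L] == ev[ee + 1L]) {
        re <- re + 1L; ee <- ee + 1L
      }
      core_len <- re - rs + 1L
      if (core_len < k) next
      if (rs - 1L > max_clip || n - re > max_clip) next
      cand <- list(rs = rs, re = re, es = es, ee = ee, core_len = core_len)
      cur <- best[[as.character(ei)]]
      if (is.null(cur) ||
          cand$core_len > cur$core_len ||
          (cand$core_len == cur$core_len && cand$es < cur$es) ||
          (cand$core_len == cur$core_len && cand$es == cur$es && cand$rs < cur$rs)) {
        best[[as.character(ei)]] <- cand
      }
    }
  }
  if (length(best) == 0) return(empty)
  ei <- as.integer(names(best))
  ord <- order(index$entries$entry_name[ei], method = "radix")
  rows <- lapply(ei[ord], function(i) {
    b <- best[[as.character(i)]]
    data.frame(entry_name = index$entries$entry_name[i],
               read_start = b$rs, read_end = b$re,
               ref_start = b$es, ref_end = b$ee,
               clip5 = substr(read_seq, 1L, b$rs - 1L),
               clip3 = substr(read_seq, b$re + 1L, n),
               core_len = b$core_len, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Align a table of processed reads
#'
#' @param reads Data frame from [filter_and_collapse()] /
#'   [preprocess_fastq()].
#' @param index A [build_seed_index()] object.
#' @param max_clip Maximum soft-clipped bases per end.
#' @return Data frame of candidates with the read's `sequence`, `count` and
#'   `sample_id` joined on.
#' @export
align_reads <- function(reads, index, max_clip = 10L) {
  out <- lapply(seq_len(nrow(reads)), function(i) {
    cand <- align_read(reads$sequence[i], index, max_clip)
    if (nrow(cand) == 0) return(NULL)
    cand$sequence <- reads$sequence[i]
    cand$count <- reads$count[i]
    cand$sample_id <- reads$sample_id[i]
    cand
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(entry_name = character(0), read_start = integer(0),
                      read_end = integer(0), ref_start = integer(0),
                      ref_end = integer(0), clip5 = character(0),
                      clip3 = character(0), core_len = integer(0),
                      sequence = character(0), count = integer(0),
                      sample_id = character(0), stringsAsFactors = FALSE)
  }
  out
}

#' Import bowtie2-style local alignments from a SAM file
#'
#' Converts SAM records whose CIGAR contains only soft clips and aligned
#' blocks (`S`, `M`, `=`) into alignment candidates, re-validating the
#' exact-core policy against the library: records whose aligned block
#' contains any mismatch to the library entry, whose core is shorter than the
#' seed length, or whose clips exceed `max_clip` are discarded.
#'
#' @param sam_path Path to a SAM file aligned against the augmented library.
#' @param index A [build_seed_index()] built from the same library.
#' @param sample_id Sample label for the imported reads.
#' @param max_clip Maximum soft-clipped bases per end.
#' @return Candidate data frame in the [align_reads()] layout.
#' @export
import_sam_alignments <- function(sam_path, index, sample_id = "sample",
                                  max_clip = 10L) {
  lines <- readLines(sam_path)
  lines <- lines[!startsWith(lines, "@")]
  rows <- list()
  entseq <- stats::setNames(index$entries$sequence, index$entries$entry_name)
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 10) next
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 4L) != 0L || bitwAnd(flag, 16L) != 0L) next  # unmapped/reverse
    entry <- f[3]; pos <- as.integer(f[4]); cigar <- f[6]; seq <- normalize_dna(f[10])
    if (!entry %in% names(entseq)) next
    ops <- regmatches(cigar, gregexpr("[0-9]+[A-Z=]", cigar))[[1]]
    lens <- as.integer(sub("[A-Z=]", "", ops)); typ <- sub("[0-9]+", "", ops)
    if (!all(typ %in% c("S", "M", "="))) next
    m <- typ %in% c("M", "=")
    if (sum(m) != 1L) next
    clip5_len <- if (typ[1] == "S") lens[1] else 0L
    core_len <- lens[m]
    clip3_len <- if (typ[length(typ)] == "S" && length(typ) > 1L) lens[length(typ)] else 0L
    if (clip5_len + core_len + clip3_len != nchar(seq)) next
    if (core_len < index$k || clip5_len > max_clip || clip3_len > max_clip) next
    core <- substr(seq, clip5_len + 1L, clip5_len + core_len)
    ref_core <- substr(entseq[[entry]], pos, pos + core_len - 1L)
    if (core != ref_core) next  # internal mismatch: violates the exact-core rule
    rows[[length(rows) + 1L]] <- data.frame(
      entry_name = entry, read_start = clip5_len + 1L,
      read_end = clip5_len + core_len, ref_start = pos,
      ref_end = pos + core_len - 1L,
      clip5 = substr(seq, 1L, clip5_len),
      clip3 = substr(seq, clip5_len + core_len + 1L, nchar(seq)),
      core_len = core_len, sequence = seq, count = 1L,
      sample_id = sample_id, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- align_reads(
    data.frame(sequence = character(0), count = integer(0),
               sample_id = character(0)), index, max_clip)
  out
}
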
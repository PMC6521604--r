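#' Scoring configuration
#'
#' @param W5 Weight multiplying 5' editing events. 5' ends of mature miRNAs
#'   are rarely edited, so 5' events are penalized more heavily; the default
#'   of 4 resolves most cross-mapping ties without swamping 3' information.
#' @param score_threshold Alignments scoring strictly above this are discarded
#'   as unreliable isomiRs (default 9; the threshold itself is kept).
#' @param iso5p_sign Sign convention for 5' isomiR labels:
#'   `"trim-positive"` writes `iso_5p:+N` for trimming and `iso_5p:-N` for
#'   templated tailing; `"mirgff3"` flips the 5' signs to match the mirGFF3
#'   community convention. 3' labels are identical in both.
#' @return A `scoring_config` list.
#' @export
scoring_config <- function(W5 = 4L, score_threshold = 9L,
                           iso5p_sign = c("trim-positive", "mirgff3")) {
  assert_that(W5 >= 1, "W5 must be a positive integer")
  assert_that(score_threshold > 0, "score_threshold must be positive")
  structure(list(W5 = as.integer(W5),
                 score_threshold = as.integer(score_threshold),
                 iso5p_sign = match.arg(iso5p_sign)),
            class = "scoring_config")
}

# Per-mature hairpin flank table: for every parent hairpin, the sequence
# immediately upstream of the mature 5' end and immediately downstream of its
# 3' end. Templated tails are read off these flanks.
#' @keywords internal
#' @noRd
mature_flanks <- function(reference) {
  out <- list()
  for (m in reference$matures) {
    fl <- list()
    if (nrow(m$offsets) > 0) {
      for (i in seq_len(nrow(m$offsets))) {
        p <- m$offsets$parent[i]
        hp <- reference$hairpins[[p]]$sequence
        fl[[p]] <- list(
          up = substr(hp, 1L, m$offsets$start[i] - 1L),
          down = if (m$offsets$end[i] < nchar(hp))
            substr(hp, m$offsets$end[i] + 1L, nchar(hp)) else "")
      }
    }
    out[[m$name]] <- fl
  }
  out
}

# Number of leading clip3 bases that match the downstream flank base-by-base
# from the junction outward.
#' @keywords internal
#' @noRd
templated_len_3p <- function(clip3, down_flank) {
  common_prefix_len(clip3, down_flank)
}

# Mirror rule at 5': compare clip5 backwards from the junction against the
# end of the upstream flank.
#' @keywords internal
#' @noRd
templated_len_5p <- function(clip5, up_flank) {
  n <- min(nchar(clip5), nchar(up_flank))
  if (n == 0L) return(0L)
  cv <- rev(strsplit(clip5, "", fixed = TRUE)[[1]])
  fv <- rev(strsplit(up_flank, "", fixed = TRUE)[[1]])
  t <- 0L
  while (t < n && cv[t + 1L] == fv[t + 1L]) t <- t + 1L
  t
}

#' Annotate alignments with 5'/3' editing events and scores
#'
#' For every candidate alignment this computes trimming (reference bases
#' missing from the read core at either end), splits the soft-clipped tails
#' into templated and non-templated bases, assigns isomiR labels, scores the
#' alignment and attributes a hairpin of origin.
#'
#' A 3' tail base run is templated only when the 3' end is untrimmed and the
#' run matches, base by base from the junction, the parent hairpin sequence
#' immediately downstream of the mature (mirror rule at 5' with the upstream
#' flank); leading matching bases are templated, the remainder is not.
#' Because the aligner extends cores maximally, a clip adjacent to a nonzero
#' trim always starts with a mismatch to the reference and is entirely
#' non-templated. Templated bases validate the read's parentage and are not
#' counted as editing events; with several parent hairpins the parent
#' explaining the most templated bases determines the counts, and the set of
#' parents explaining all templated bases becomes the hairpin attribution
#' (`all parents` collapses to `undetermined`).
#'
#' The score is `N5 * W5 + N3` with `N5 = trim5 + nontemplated 5' tail` and
#' `N3 = trim3 + nontemplated 3' tail`, counted per base.
#'
#' @param candidates Candidate data frame from [align_reads()].
#' @param library Library from [build_library()] (carries the reference).
#' @param config A [scoring_config()].
#' @return The candidate table with annotation columns appended: `mature_name`,
#'   `is_canonical`, `trim5`, `trim3`, `tail5_templated`,
#'   `tail5_nontemplated`, `tail3_templated`, `tail3_nontemplated`, `N5`,
#'   `N3`, `score`, `label`, `hairpin_origin`.
#' @export
annotate_alignments <- function(candidates, library, config = scoring_config()) {
  reference <- attr(library, "reference")
  assert_that(!is.null(reference), "library does not carry its reference bundle")
  flanks <- mature_flanks(reference)
  lib_df <- as.data.frame(library)
  entry_row <- match(candidates$entry_name, lib_df$entry_name)
  assert_that(!anyNA(entry_row), "candidate references an unknown library entry")
  n <- nrow(candidates)
  out <- candidates
  out$mature_name <- lib_df$mature_name[entry_row]
  out$is_canonical <- lib_df$is_canonical[entry_row]
  entry_len <- nchar(lib_df$sequence[entry_row])
  out$trim5 <- out$ref_start - 1L
  out$trim3 <- entry_len - out$ref_end
  out$tail5_templated <- 0L; out$tail5_nontemplated <- 0L
  out$tail3_templated <- 0L; out$tail3_nontemplated <- 0L
  out$hairpin_origin <- NA_character_
  edge_warned <- FALSE
  for (i in seq_len(n)) {
    fl <- flanks[[out$mature_name[i]]]
    parents <- names(fl)
    if (length(parents) == 0) {
      if (!edge_warned && (nchar(out$clip5[i]) > 0 || nchar(out$clip3[i]) > 0)) {
        warning("mature '", out$mature_name[i],
                "' has no parent hairpin flanks; tails treated as non-templated",
                call. = FALSE)
        edge_warned <- TRUE
      }
      t5 <- stats::setNames(integer(0), character(0)); t3 <- t5
    } else {
      t5 <- vapply(fl, function(f) templated_len_5p(out$clip5[i], f$up), integer(1))
      t3 <- vapply(fl, function(f) templated_len_3p(out$clip3[i], f$down), integer(1))
    }
    t5max <- if (out$trim5[i] == 0L && length(t5)) max(t5) else 0L
    t3max <- if (out$trim3[i] == 0L && length(t3)) max(t3) else 0L
    out$tail5_templated[i] <- t5max
    out$tail5_nontemplated[i] <- nchar(out$clip5[i]) - t5max
    out$tail3_templated[i] <- t3max
    out$tail3_nontemplated[i] <- nchar(out$clip3[i]) - t3max
    # hairpin attribution: parents whose flanks explain every templated base
    if (length(parents) <= 1L) {
      out$hairpin_origin[i] <- if (length(parents)) parents else "undetermined"
    } else {
      ok <- parents[(if (t5max > 0) t5 >= t5max else TRUE) &
                    (if (t3max > 0) t3 >= t3max else TRUE)]
      out$hairpin_origin[i] <- if (length(ok) == 0L || length(ok) == length(parents))
        "undetermined" else paste(sort(ok), collapse = ",")
    }
  }
  out$N5 <- out$trim5 + out$tail5_nontemplated
  out$N3 <- out$trim3 + out$tail3_nontemplated
  out$score <- alignment_score(out$N5, out$N3, config$W5)
  out$label <- isomir_label(out$trim5, out$tail5_templated, out$tail5_nontemplated,
                            out$trim3, out$tail3_templated, out$tail3_nontemplated,
                            config$iso5p_sign)
  out
}

#' Alignment score from editing-event counts
#'
#' @param N5,N3 Numbers of editing events (trimmed plus non-templated tailed
#'   bases) at the 5' and 3' read ends.
#' @param W5 Weight applied to 5' events.
#' @return Integer score `N5 * W5 + N3`.
#' @export
alignment_score <- function(N5, N3, W5 = 4L) {
  as.integer(N5) * as.integer(W5) + as.integer(N3)
}

#' isomiR label from event counts
#'
#' Builds the trimming/tailing label taxonomy: `iso_3p:-N` (3' trimming),
#' `iso_3p:+N` (templated 3' tailing), `iso_add3p` (non-templated 3'
#' tailing), their combinations, the 5' counterparts, and `canonical` when
#' nothing is edited.
#'
#' @param trim5,tail5_templated,tail5_nontemplated,trim3,tail3_templated,tail3_nontemplated
#'   Per-end event counts.
#' @param iso5p_sign 5' sign convention (see [scoring_config()]).
#' @return Character vector of comma-joined labels.
#' @export
isomir_label <- function(trim5, tail5_templated, tail5_nontemplated,
                         trim3, tail3_templated, tail3_nontemplated,
                         iso5p_sign = "trim-positive") {
  n <- length(trim5)
  flip <- identical(iso5p_sign, "mirgff3")
  vapply(seq_len(n), function(i) {
    parts <- character(0)
    if (trim5[i] > 0)
      parts <- c(parts, paste0("iso_5p:", if (flip) "-" else "+", trim5[i]))
    if (tail5_templated[i] > 0)
      parts <- c(parts, paste0("iso_5p:", if (flip) "+" else "-", tail5_templated[i]))
    if (tail5_nontemplated[i] > 0) parts <- c(parts, "iso_add5p")
    if (trim3[i] > 0) parts <- c(parts, paste0("iso_3p:-", trim3[i]))
    if (tail3_templated[i] > 0) parts <- c(parts, paste0("iso_3p:+", tail3_templated[i]))
    if (tail3_nontemplated[i] > 0) parts <- c(parts, "iso_add3p")
    if (length(parts) == 0) "canonical" else paste(parts, collapse = ",")
  }, character(1))
}

# Variant offsets (0-based) covered by an alignment's core on its mature.
#' @keywords internal
#' @noRd
covered_variant_offsets <- function(row, polymir) {
  if (is.null(polymir)) return(integer(0))
  off <- polymir$variants$offset
  off[row$ref_start <= off + 1L & off + 1L <= row$ref_end]
}

#' Disambiguate cross-mapping reads
#'
#' For every read (per sample), keeps only the minimum-score alignments.
#' Tied haplotype entries of the same polymiR whose cores do not cover any
#' variant position are indistinguishable over the read span and collapse to
#' the canonical entry; this avoids fabricating alternative-allele evidence
#' from reads that never see the variant. Each of the `n` alignments retained
#' after collapsing gets weight `1/n`; reads left with `n > 1` alignments are
#' flagged ambiguous.
#'
#' @param scored Annotated alignment table from [annotate_alignments()].
#' @param library Library from [build_library()].
#' @return `scored` restricted to retained rows, with `weight` and
#'   `ambiguous` columns appended.
#' @export
disambiguate <- function(scored, library) {
  polymirs <- attr(library, "polymirs")
  if (nrow(scored) == 0) {
    scored$weight <- numeric(0); scored$ambiguous <- logical(0)
    return(scored)
  }
  key <- paste(scored$sample_id, scored$sequence, sep = "\r")
  pieces <- lapply(split(seq_len(nrow(scored)), key), function(idx) {
    grp <- scored[idx, , drop = FALSE]
    grp <- grp[grp$score == min(grp$score), , drop = FALSE]
    # collapse variant-blind ties across haplotype entries of one polymiR
    keep <- rep(TRUE, nrow(grp))
    for (m in unique(grp$mature_name)) {
      rows <- which(grp$mature_name == m)
      if (length(rows) < 2L) next
      pm <- polymirs[[m]]
      if (is.null(pm)) next
      covers <- vapply(rows, function(r)
        length(covered_variant_offsets(grp[r, ], pm)) > 0, logical(1))
      if (!any(covers) && any(grp$is_canonical[rows])) {
        keep[rows] <- grp$is_canonical[rows]
      }
    }
    grp <- grp[keep, , drop = FALSE]
    grp$weight <- 1 / nrow(grp)
    grp$ambiguous <- nrow(grp) > 1L
    grp
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out[order(out$sample_id, out$sequence, out$entry_name, method = "radix"), ,
      drop = FALSE]
}

#' Filter retained alignments by score
#'
#' @param retained Disambiguated alignment table.
#' @param config A [scoring_config()]; rows with
#'   `score > config$score_threshold` are removed.
#' @return List with `passed` and `discarded` tables.
#' @export
filter_by_score <- function(retained, config = scoring_config()) {
  keep <- retained$score <= config$score_threshold
  list(passed = retained[keep, , drop = FALSE],
       discarded = retained[!keep, , drop = FALSE])
}
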
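#' Aggregate retained alignments into abundance tables
#'
#' Produces the three abundance views: merged per-mature counts (isomiR and
#' polymiR reads folded into their mature), per-polymiR-entry counts
#' (reference and alternative haplotype sequences separately), and
#' per-isomiR counts keyed on (mature, label, read sequence). All counts are
#' weighted: collapsed read multiplicity times disambiguation weight, so a
#' read split over n matures contributes 1/n to each.
#'
#' @param alignments Final kept alignment table (annotated, weighted).
#' @param library Library from [build_library()]; its polymiR list decides
#'   which matures appear in the polymiR-specific table.
#' @param samples Sample ids defining column order; defaults to the sorted
#'   samples present.
#' @return List of data frames `merged`, `polymir`, `isomir`, each with key
#'   columns followed by one numeric column per sample.
#' @export
merge_counts <- function(alignments, library = NULL, samples = NULL) {
  if (is.null(samples)) samples <- sort(unique(alignments$sample_id))
  pm_names <- if (!is.null(library)) names(attr(library, "polymirs"))
  else unique(alignments$mature_name[alignments$entry_name !=
                                       alignments$mature_name])
  tab <- function(al, keys) {
    if (nrow(al) == 0) {
      out <- al[, keys, drop = FALSE]
      for (s in samples) out[[s]] <- numeric(0)
      return(out)
    }
    w <- al$count * al$weight
    agg <- stats::aggregate(
      list(weighted = w),
      by = c(as.list(al[, keys, drop = FALSE]),
             list(sample_id = al$sample_id)), FUN = sum)
    out <- unique(agg[, keys, drop = FALSE])
    out <- out[do.call(order, c(unname(as.list(out)), list(method = "radix"))), ,
               drop = FALSE]
    rownames(out) <- NULL
    for (s in samples) out[[s]] <- 0
    rowkey <- do.call(paste, c(unname(as.list(out[, keys, drop = FALSE])),
                               list(sep = "\r")))
    aggkey <- do.call(paste, c(unname(as.list(agg[, keys, drop = FALSE])),
                               list(sep = "\r")))
    for (r in seq_len(nrow(agg))) {
      if (!agg$sample_id[r] %in% samples) next
      out[[agg$sample_id[r]]][rowkey == aggkey[r]] <- agg$weighted[r]
    }
    out
  }
  list(merged = tab(alignments, "mature_name"),
       polymir = tab(alignments[alignments$mature_name %in% pm_names, ,
                                drop = FALSE],
                     c("mature_name", "entry_name")),
       isomir = tab(alignments, c("mature_name", "label", "sequence")))
}

#' Write retained alignments as mirGFF3
#'
#' One feature line per distinct (read sequence, mature), with the standard
#' attributes: `UID` (deterministic sequence tag), `Read`, `Name` (mature),
#' `Parent` (hairpin attribution), `Variant` (isomiR labels, `NA` for
#' canonical reads), `Expression` (weighted counts in the `COLDATA` sample
#' order) and `Filter`. Coordinates are the matched core on the mature
#' reference, 1-based.
#'
#' @param alignments Final kept alignment table.
#' @param path Output file.
#' @param samples Sample order for the Expression column.
#' @return `path`, invisibly.
#' @export
write_mirgff3 <- function(alignments, path, samples = NULL) {
  if (is.null(samples)) samples <- sort(unique(alignments$sample_id))
  header <- c("## mirGFF3. VERSION 1.2",
              "## source-ontology: polymiR",
              paste0("## COLDATA: ", paste(samples, collapse = ",")))
  if (nrow(alignments) == 0) {
    writeLines(header, path)
    return(invisible(path))
  }
  w <- alignments$count * alignments$weight
  key <- paste(alignments$sequence, alignments$mature_name, sep = "\r")
  lines <- character(0)
  for (k in sort(unique(key))) {
    rows <- which(key == k)
    a <- alignments[rows[1], ]
    expr <- vapply(samples, function(s)
      sum(w[rows][alignments$sample_id[rows] == s]), numeric(1))
    variant <- if (a$label == "canonical") "NA" else a$label
    type <- if (a$label == "canonical") "ref_miRNA" else "isomiR"
    attrs <- paste0(
      "UID=", sequence_uid(a$sequence),
      "; Read=", a$sequence,
      "; Name=", a$mature_name,
      "; Parent=", a$hairpin_origin,
      "; Variant=", variant,
      "; Expression=", paste(render_weight(expr), collapse = ","),
      "; Filter=Pass")
    lines <- c(lines, paste(a$mature_name, "polymiR", type, a$ref_start,
                            a$ref_end, ".", "+", ".", attrs, sep = "\t"))
  }
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Read a mirGFF3 file written by [write_mirgff3()]
#'
#' @param path mirGFF3 file.
#' @return List with `samples` (COLDATA order) and `records`: a data frame
#'   with seqid, type, start, end and the parsed UID/Read/Name/Parent/Variant
#'   attributes plus one expression column per sample.
#' @export
read_mirgff3 <- function(path) {
  lines <- readLines(path)
  coldata <- grep("^## COLDATA:", lines, value = TRUE)
  samples <- if (length(coldata))
    strsplit(sub("^## COLDATA:\\s*", "", coldata[1]), ",", fixed = TRUE)[[1]]
  else character(0)
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  recs <- lapply(body, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    attrs <- strsplit(f[9], ";\\s*")[[1]]
    kv <- strsplit(attrs, "=", fixed = TRUE)
    vals <- stats::setNames(vapply(kv, `[`, character(1), 2L),
                            vapply(kv, `[`, character(1), 1L))
    expr <- as.numeric(strsplit(vals[["Expression"]], ",", fixed = TRUE)[[1]])
    row <- data.frame(seqid = f[1], type = f[3], start = as.integer(f[4]),
                      end = as.integer(f[5]), uid = vals[["UID"]],
                      read = vals[["Read"]], name = vals[["Name"]],
                      parent = vals[["Parent"]], variant = vals[["Variant"]],
                      stringsAsFactors = FALSE)
    for (i in seq_along(samples)) row[[samples[i]]] <- expr[i]
    row
  })
  records <- if (length(recs)) do.call(rbind, recs) else NULL
  list(samples = samples, records = records)
}

#' Write alignments as a minimal SAM file
#'
#' Soft-clipped local alignments against the augmented library; score,
#' weight, isomiR label and (for inconsistent reads) the discard reason are
#' carried in optional tags `XS`, `XW`, `XL`, `XR`.
#'
#' @param alignments Alignment table (annotated; `reason` column optional).
#' @param library Library from [build_library()] (for `@SQ` lengths).
#' @param path Output SAM path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, library, path) {
  lib_df <- as.data.frame(library)
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              paste0("@SQ\tSN:", lib_df$entry_name, "\tLN:",
                     nchar(lib_df$sequence)),
              "@PG\tID:polymiR\tPN:polymiR")
  recs <- character(0)
  if (nrow(alignments) > 0) {
    ord <- order(alignments$sample_id, alignments$sequence,
                 alignments$entry_name, method = "radix")
    al <- alignments[ord, , drop = FALSE]
    for (i in seq_len(nrow(al))) {
      a <- al[i, ]
      cigar <- paste0(
        if (nchar(a$clip5) > 0) paste0(nchar(a$clip5), "S") else "",
        a$core_len, "M",
        if (nchar(a$clip3) > 0) paste0(nchar(a$clip3), "S") else "")
      tags <- c(paste0("XS:i:", a$score),
                paste0("XW:f:", render_weight(a$weight)),
                paste0("XL:Z:", a$label),
                paste0("XC:i:", a$count),
                paste0("XB:Z:", a$sample_id))
      if (!is.null(al$reason) && !is.na(a$reason))
        tags <- c(tags, paste0("XR:Z:", a$reason))
      recs <- c(recs, paste(c(paste0(a$sample_id, ":", sequence_uid(a$sequence)),
                              "0", a$entry_name, a$ref_start, "255", cigar,
                              "*", "0", "0", a$sequence, "*", tags),
                            collapse = "\t"))
    }
  }
  writeLines(c(header, recs), path)
  invisible(path)
}

#' Write the annotation side files
#'
#' Deterministic, sorted TSVs: `remaining_ambiguous.annot` (reads still
#' carrying multiple equal-score alignments, one row per retained
#' alignment), `expressed_hairpins.annot` (per-sample weighted counts
#' attributed to parent hairpins; reads whose templated tails single out a
#' parent are `deduced`, reads compatible with a proper subset are
#' `ambiguous`, untagged reads count once toward every parent as
#' `undetermined`) and `consistency_table.annot` (per-allele genotype
#' consistency decisions).
#'
#' @param retained Final kept alignment table.
#' @param decisions Consistency decisions from [check_consistency()].
#' @param library Library from [build_library()].
#' @param dir Output directory.
#' @return Character vector of file paths, invisibly.
#' @export
write_annotations <- function(retained, decisions, library, dir) {
  reference <- attr(library, "reference")
  amb_path <- file.path(dir, "remaining_ambiguous.annot")
  hp_path <- file.path(dir, "expressed_hairpins.annot")
  cons_path <- file.path(dir, "consistency_table.annot")

  amb_cols <- c("sample_id", "sequence", "count", "entry_name", "mature_name",
                "score", "weight")
  amb <- retained[retained$ambiguous, amb_cols, drop = FALSE]
  amb <- amb[order(amb$sample_id, amb$sequence, amb$entry_name,
                   method = "radix"), , drop = FALSE]
  write_tsv_file(amb, amb_path)

  rows <- list()
  if (nrow(retained) > 0) {
    w <- retained$count * retained$weight
    for (i in seq_len(nrow(retained))) {
      m <- reference$matures[[retained$mature_name[i]]]
      origin <- retained$hairpin_origin[i]
      if (identical(origin, "undetermined")) {
        hps <- m$parents
        att <- "undetermined"
      } else {
        hps <- strsplit(origin, ",", fixed = TRUE)[[1]]
        att <- if (length(hps) == 1L && length(m$parents) > 1L) "deduced"
        else if (length(hps) < length(m$parents)) "ambiguous"
        else "single-parent"
      }
      for (hp in hps) {
        key <- paste(retained$sample_id[i], retained$mature_name[i], hp, att,
                     sep = "\r")
        rows[[key]] <- (if (is.null(rows[[key]])) 0 else rows[[key]]) + w[i]
      }
    }
  }
  if (length(rows)) {
    parts <- strsplit(names(rows), "\r", fixed = TRUE)
    hp_df <- data.frame(
      sample_id = vapply(parts, `[`, character(1), 1L),
      mature_name = vapply(parts, `[`, character(1), 2L),
      hairpin = vapply(parts, `[`, character(1), 3L),
      attribution = vapply(parts, `[`, character(1), 4L),
      weighted_count = vapply(unname(rows), render_weight, character(1)),
      stringsAsFactors = FALSE)
    hp_df <- hp_df[order(hp_df$sample_id, hp_df$mature_name, hp_df$hairpin,
                         hp_df$attribution, method = "radix"), , drop = FALSE]
  } else {
    hp_df <- data.frame(sample_id = character(0), mature_name = character(0),
                        hairpin = character(0), attribution = character(0),
                        weighted_count = character(0), stringsAsFactors = FALSE)
  }
  write_tsv_file(hp_df, hp_path)

  dec <- decisions
  if (nrow(dec) > 0) {
    dec$supporting <- vapply(dec$supporting, render_weight, character(1))
    dec$total <- vapply(dec$total, render_weight, character(1))
    dec$rate <- sprintf("%.6f", dec$rate)
  }
  write_tsv_file(dec, cons_path)
  invisible(c(amb_path, hp_path, cons_path))
}
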
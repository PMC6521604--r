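# Internal string helpers. Alignment-facing code works on plain character
# vectors; Biostrings is used at the file-format boundary.

#' @keywords internal
#' @noRd
dna_revcomp <- function(x) {
  vapply(x, function(s) {
    if (is.na(s)) return(NA_character_)
    paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "", fixed = TRUE)[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' @keywords internal
#' @noRd
dna_complement <- function(x) {
  chartr("ACGTacgt", "TGCAtgca", x)
}

# Normalize RNA/DNA input to an uppercase DNA alphabet (U -> T).
#' @keywords internal
#' @noRd
normalize_dna <- function(x) {
  chartr("U", "T", toupper(x))
}

#' @keywords internal
#' @noRd
assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

# Length of the common prefix of two strings, comparing base by base.
#' @keywords internal
#' @noRd
common_prefix_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  av <- strsplit(substr(a, 1L, n), "", fixed = TRUE)[[1]]
  bv <- strsplit(substr(b, 1L, n), "", fixed = TRUE)[[1]]
  neq <- which(av != bv)
  if (length(neq) == 0L) n else neq[1L] - 1L
}

# Deterministic, filesystem-safe tag for a read sequence (used as mirGFF3 UID).
#' @keywords internal
#' @noRd
sequence_uid <- function(seq) {
  paste0("iso-", nchar(seq), "-", seq)
}

# Write a data.frame as a deterministic TSV (no quoting, no row names).
#' @keywords internal
#' @noRd
write_tsv_file <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# Render weighted counts (sums of 1/n weights) with fixed precision so that
# reruns are byte identical.
#' @keywords internal
#' @noRd
render_weight <- function(x) {
  sub("\\.?0+$", "", sprintf("%.4f", x))
}
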
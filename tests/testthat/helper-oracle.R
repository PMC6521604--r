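# Exhaustive alignment oracle: for every (read position, reference position)
# pair, extend the exact match as far as it goes; admissible candidates need
# a core of at least k and clips of at most max_clip; per entry the longest
# core wins, ties by smallest reference start then smallest read start.
# Independent of the package's seed-and-extend path.
oracle_align <- function(read_seq, entries, k = 17L, max_clip = 10L) {
  rv <- strsplit(read_seq, "", fixed = TRUE)[[1]]
  n <- length(rv)
  rows <- list()
  for (e in seq_len(nrow(entries))) {
    ev <- strsplit(entries$sequence[e], "", fixed = TRUE)[[1]]
    m <- length(ev)
    best <- NULL
    for (i in seq_len(n)) {
      for (p in seq_len(m)) {
        maxL <- min(n - i + 1L, m - p + 1L)
        if (maxL < k) next
        eq <- rv[i:(i + maxL - 1L)] == ev[p:(p + maxL - 1L)]
        L <- if (all(eq)) maxL else which(!eq)[1] - 1L
        # a shorter L at the same (i, p) only enlarges the 3' clip, so the
        # maximal run is the only candidate that can win here
        if (L < k) next
        if ((i - 1L) > max_clip || (n - (i + L - 1L)) > max_clip) next
        cand <- c(i = i, p = p, L = L)
        if (is.null(best) || L > best["L"] ||
            (L == best["L"] && p < best["p"]) ||
            (L == best["L"] && p == best["p"] && i < best["i"])) {
          best <- cand
        }
      }
    }
    if (!is.null(best)) {
      rows[[length(rows) + 1L]] <- data.frame(
        entry_name = entries$entry_name[e],
        read_start = unname(best["i"]),
        read_end = unname(best["i"] + best["L"] - 1L),
        ref_start = unname(best["p"]),
        ref_end = unname(best["p"] + best["L"] - 1L),
        core_len = unname(best["L"]), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(entry_name = character(0), read_start = integer(0),
                      read_end = integer(0), ref_start = integer(0),
                      ref_end = integer(0), core_len = integer(0),
                      stringsAsFactors = FALSE)
  }
  out[order(out$entry_name, method = "radix"), , drop = FALSE]
}

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# random library + read likely to share seeds with it
random_align_case <- function(max_entries = 8L) {
  n_entries <- sample.int(max_entries, 1L)
  entries <- data.frame(
    entry_name = paste0("e", seq_len(n_entries)),
    sequence = vapply(seq_len(n_entries), function(i)
      rand_seq(sample(18:26, 1L)), character(1)),
    stringsAsFactors = FALSE)
  style <- sample(c("derived", "chimera", "random"), 1L,
                  prob = c(0.6, 0.2, 0.2))
  read <- if (style == "derived") {
    base <- entries$sequence[sample.int(n_entries, 1L)]
    n <- nchar(base)
    s <- sample.int(min(4L, n - 17L + 1L), 1L)
    e <- n - sample.int(max(1L, min(4L, n - (s - 1L) - 17L + 1L)), 1L) + 1L
    core <- substr(base, s, min(e, n))
    paste0(if (stats::runif(1) < 0.5) rand_seq(sample.int(3L, 1L)) else "",
           core,
           if (stats::runif(1) < 0.5) rand_seq(sample.int(3L, 1L)) else "")
  } else if (style == "chimera") {
    a <- entries$sequence[sample.int(n_entries, 1L)]
    paste0(substr(a, 1L, 18L), rand_seq(sample.int(6L, 1L)))
  } else {
    rand_seq(sample(15:27, 1L))
  }
  if (nchar(read) > 27L) read <- substr(read, 1L, 27L)
  if (nchar(read) < 15L) read <- paste0(read, rand_seq(15L - nchar(read)))
  list(entries = entries, read = read)
}
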
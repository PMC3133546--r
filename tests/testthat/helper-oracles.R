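# Independent oracles: brute-force re-implementations, kept deliberately
# naive and separate from the package's algorithms, used to cross-check
# results on small instances.

# Union length via a per-base boolean mask.
oracle_union_length <- function(intervals, L) {
  mask <- logical(L)
  for (i in seq_len(nrow(intervals))) {
    s <- intervals[i, 1]; e <- intervals[i, 2]
    if (e > s) mask[(s + 1):e] <- TRUE
  }
  sum(mask)
}

# Complement of covered bases, as maximal runs, via the same mask.
oracle_uncovered <- function(intervals, L, min_len) {
  mask <- logical(L)
  for (i in seq_len(nrow(intervals))) {
    s <- intervals[i, 1]; e <- intervals[i, 2]
    if (e > s) mask[(s + 1):e] <- TRUE
  }
  r <- rle(!mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values & r$lengths >= min_len
  cbind(start = starts[keep], end = ends[keep])
}

# All maximal exact matches >= k between q and s (one strand), by scanning
# every diagonal with per-base comparison; non-ACGT never matches.
oracle_mem <- function(q, s, k) {
  qc <- strsplit(q, "")[[1]]
  sc <- strsplit(s, "")[[1]]
  qc[!qc %in% c("A", "C", "G", "T")] <- "?"
  sc[!sc %in% c("A", "C", "G", "T")] <- "!"
  nq <- length(qc); ns <- length(sc)
  out <- list()
  for (d in (-(nq - k)):(ns - k)) {
    lo <- max(0L, -d); hi <- min(nq - 1L, ns - 1L - d)
    if (hi - lo + 1L < k) next
    idx <- lo:hi
    eq <- qc[idx + 1L] == sc[idx + d + 1L]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    for (j in seq_along(r$lengths)) {
      if (r$values[j] && r$lengths[j] >= k)
        out[[length(out) + 1L]] <- data.frame(
          q = lo + starts[j], s = lo + starts[j] + d, len = r$lengths[j])
    }
  }
  if (!length(out))
    return(data.frame(q = integer(), s = integer(), len = integer()))
  res <- do.call(rbind, out)
  res[order(res$q, res$s), , drop = FALSE]
}

# Best chain score by exhaustive enumeration of all co-linear chains.
oracle_best_chain_score <- function(a, max_gap, max_drift) {
  n <- nrow(a)
  chainable <- function(i, j) {
    a$q[i] < a$q[j] && a$s[i] < a$s[j] &&
      a$q[j] - (a$q[i] + a$len[i]) <= max_gap &&
      a$s[j] - (a$s[i] + a$len[i]) <= max_gap &&
      abs((a$s[j] - a$q[j]) - (a$s[i] - a$q[i])) <= max_drift
  }
  best <- 0
  rec <- function(last, score) {
    best <<- max(best, score)
    for (j in seq_len(n))
      if (chainable(last, j)) rec(j, score + a$len[j])
  }
  for (j in seq_len(n)) rec(j, a$len[j])
  best
}

# Optimal local alignment score by enumerating all monotone matchings of
# aligned residue pairs; between consecutive pairs, each side's skipped run
# is one affine gap (open + extend * length). Exact for short strings.
oracle_sw_score <- function(q, t, mat, open = 11, ext = 1) {
  qc <- strsplit(q, "")[[1]]
  tc <- strsplit(t, "")[[1]]
  best <- 0
  rec <- function(qi, ti, score) {
    best <<- max(best, score)
    if (qi >= length(qc) || ti >= length(tc)) return()
    for (a in (qi + 1):length(qc)) {
      for (b in (ti + 1):length(tc)) {
        ga <- a - qi - 1L; gb <- b - ti - 1L
        pen <- (ga > 0) * (open + ext * ga) + (gb > 0) * (open + ext * gb)
        rec(a, b, score + mat[qc[a], tc[b]] - pen)
      }
    }
  }
  for (a in seq_along(qc))
    for (b in seq_along(tc))
      rec(a, b, mat[qc[a], tc[b]])
  best
}

# Naive overlapping occurrence count (primer + its reverse complement) by
# comparing every window of every contig.
oracle_occurrences <- function(primer, contigs) {
  rc <- refscaf::reverse_complement(primer)
  L <- nchar(primer)
  total <- 0L
  for (s in contigs$sequence) {
    n <- nchar(s)
    if (n < L) next
    wins <- substring(s, 1:(n - L + 1L), L:n)
    total <- total + sum(wins == primer)
    if (rc != primer) total <- total + sum(wins == rc)
  }
  total
}

# Strict grammar check for the EMBL feature-table subset the package emits.
# Returns character(0) when clean, else the offending lines.
embl_tab_violations <- function(lines) {
  bad <- character()
  seen_feature <- FALSE
  for (ln in lines) {
    if (grepl("^FT   \\S", ln)) {
      key <- substr(ln, 6L, 21L)
      loc <- substr(ln, 22L, nchar(ln))
      ok <- grepl("^\\S+ *$", key) &&
        grepl("^(complement\\()?\\d+\\.\\.\\d+\\)?$", loc)
      if (ok) {
        se <- as.integer(regmatches(loc, gregexpr("\\d+", loc))[[1L]])
        ok <- length(se) == 2L && se[1L] <= se[2L] && se[1L] >= 1L &&
          (grepl("^complement\\(", loc) == grepl("\\)$", loc))
      }
      if (!ok) bad <- c(bad, ln)
      seen_feature <- TRUE
    } else if (grepl("^FT {19}/", ln)) {
      qual <- substr(ln, 22L, nchar(ln))
      if (!seen_feature ||
          !grepl("^/[A-Za-z0-9_]+=(-?\\d+|\"[^\"]*\")$", qual))
        bad <- c(bad, ln)
    } else {
      bad <- c(bad, ln)
    }
  }
  bad
}
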
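# Native seed-and-chain aligner.
#
# Contigs are aligned to each reference replicon by (1) indexing all exact
# k-mers of the replicon, (2) finding maximal exact matches (anchors) seeded
# by shared k-mers on both contig strands, (3) chaining co-linear anchors by
# sparse dynamic programming, and (4) reporting each chain as one local
# alignment hit. Identity is an exact-match proxy (chained matched bases over
# the longer of the two spans), sufficient for profiling and placement
# without genome-scale gapped DP. Only A/C/G/T participate in matches; N and
# other IUPAC ambiguity letters are treated as mismatches everywhere.

#' Reverse-complement a DNA sequence
#'
#' Complements IUPAC ambiguity codes (N stays N) and reverses the string.
#'
#' @param seq A DNA string over the IUPAC alphabet.
#' @return The reverse complement.
#' @examples
#' reverse_complement("AAAACC")  # "GGTTTT"
#' @export
reverse_complement <- function(seq) {
  validate_dna(seq)
  str_rev(chartr(IUPAC_FROM, IUPAC_TO, seq))
}

# All k-mers of seq as a character vector (position i = 0-based offset i-1).
extract_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character())
  substring(seq, 1:(n - k + 1L), k:n)
}

# Raw byte vector with every non-ACGT byte replaced so it matches nothing,
# not even itself; `fill` differs between query and reference.
masked_raw <- function(seq, fill) {
  r <- charToRaw(seq)
  r[!r %in% charToRaw("ACGT")] <- fill
  r
}

#' Build a k-mer seed index for one reference replicon
#'
#' Indexes every k-mer of the replicon made solely of A/C/G/T, recording all
#' its 0-based offsets. K-mers occurring more than `max_occurrences` times
#' (repeat families) are dropped from seeding.
#'
#' @param replicon One-row record data.frame (the reference replicon).
#' @param k Seed length (default 15, minimum 8).
#' @param max_occurrences Repeat guard: k-mers with more reference
#'   occurrences than this are not seeded (default 50).
#' @return A seed index (list) consumed by [find_anchors()].
#' @export
build_index <- function(replicon, k = 15L, max_occurrences = 50L) {
  k <- assert_scalar_int(k, "k", min = 8)
  stopifnot(nrow(replicon) == 1L)
  seq <- replicon$sequence
  if (nchar(seq) < k)
    stopf("replicon '%s' is shorter than k = %d", replicon$id, k)
  km <- extract_kmers(seq, k)
  keep <- !grepl("[^ACGT]", km)
  pos <- split(seq_along(km)[keep] - 1L, km[keep])
  n_occ <- lengths(pos)
  pos <- pos[n_occ <= max_occurrences]
  list(k = k,
       keys = names(pos),
       pos = unname(pos),
       replicon_id = replicon$id,
       replicon_length = nchar(seq),
       sequence = seq,
       raw = masked_raw(seq, as.raw(0xFE)))
}

#' Find maximal exact-match anchors of a contig against an indexed replicon
#'
#' Seeds exact k-mer matches on both contig strands and extends each to its
#' maximal exact match; runs of consecutive seeds on one diagonal are merged
#' before extension, and duplicate anchors are removed.
#'
#' @param contig One-row record data.frame.
#' @param index Seed index from [build_index()].
#' @return A data.frame with columns `q` (0-based offset on the stated
#'   strand's contig sequence: the reverse complement for `-`), `s` (0-based
#'   reference offset), `len`, `strand`. Empty when nothing matches.
#' @export
find_anchors <- function(contig, index) {
  stopifnot(nrow(contig) == 1L)
  out <- list()
  for (strand in c("+", "-")) {
    qseq <- if (strand == "+") contig$sequence
            else reverse_complement(contig$sequence)
    a <- anchors_one_strand(qseq, index)
    if (nrow(a)) {
      a$strand <- strand
      out[[strand]] <- a
    }
  }
  if (!length(out))
    return(data.frame(q = integer(), s = integer(), len = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

anchors_one_strand <- function(qseq, index) {
  empty <- data.frame(q = integer(), s = integer(), len = integer())
  k <- index$k
  if (nchar(qseq) < k) return(empty)
  qk <- extract_kmers(qseq, k)
  m <- match(qk, index$keys)
  hit <- which(!is.na(m))
  if (!length(hit)) return(empty)
  slist <- index$pos[m[hit]]
  reps <- lengths(slist)
  qv <- rep(hit - 1L, reps)          # 0-based query offsets
  sv <- unlist(slist, use.names = FALSE)
  dg <- sv - qv
  o <- order(dg, qv)
  qv <- qv[o]; sv <- sv[o]; dg <- dg[o]
  # merge runs of consecutive seeds on the same diagonal
  new_grp <- c(TRUE, diff(dg) != 0L | diff(qv) != 1L)
  grp <- cumsum(new_grp)
  qs <- tapply(qv, grp, min)
  qe <- tapply(qv, grp, max) + k     # half-open end
  ss <- tapply(sv, grp, min)
  q0 <- as.integer(qs); s0 <- as.integer(ss); len <- as.integer(qe - qs)
  # maximal exact extension, char by char (non-ACGT never matches)
  qraw <- masked_raw(qseq, as.raw(0x00))
  rraw <- index$raw
  nq <- length(qraw); nr <- length(rraw)
  for (i in seq_along(q0)) {
    while (q0[i] > 0L && s0[i] > 0L && qraw[q0[i]] == rraw[s0[i]]) {
      q0[i] <- q0[i] - 1L; s0[i] <- s0[i] - 1L; len[i] <- len[i] + 1L
    }
    while (q0[i] + len[i] < nq && s0[i] + len[i] < nr &&
           qraw[q0[i] + len[i] + 1L] == rraw[s0[i] + len[i] + 1L]) {
      len[i] <- len[i] + 1L
    }
  }
  unique(data.frame(q = q0, s = s0, len = len))
}

#' Chain co-linear anchors by sparse dynamic programming
#'
#' Two anchors are chainable iff both query and subject starts strictly
#' increase, both coordinate gaps are at most `max_gap`, and the diagonal
#' shift is at most `max_diag_drift`. Chain score is the summed anchor
#' lengths; disjoint chains are extracted greedily in descending score.
#'
#' @param anchors Data.frame from [find_anchors()] (one contig/replicon pair;
#'   strands are chained separately).
#' @param max_gap Maximum query/subject gap between chained anchors (bp).
#' @param max_diag_drift Maximum diagonal shift between chained anchors (bp).
#' @return A list of chains, each a data.frame of anchors in chain order with
#'   attribute `score`; ordered by descending score.
#' @export
chain_anchors <- function(anchors, max_gap = 1000L, max_diag_drift = 200L) {
  chains <- list()
  for (strand in unique(anchors$strand %||% "+")) {
    a <- if (is.null(anchors$strand)) anchors
         else anchors[anchors$strand == strand, , drop = FALSE]
    chains <- c(chains, chain_one_strand(a, max_gap, max_diag_drift))
  }
  chains[order(-vapply(chains, attr, numeric(1), "score"))]
}

chain_one_strand <- function(a, max_gap, max_diag_drift) {
  if (!nrow(a)) return(list())
  a <- a[order(a$q, a$s), , drop = FALSE]
  remaining <- rep(TRUE, nrow(a))
  out <- list()
  while (any(remaining)) {
    idx <- which(remaining)
    q <- a$q[idx]; s <- a$s[idx]; len <- a$len[idx]
    n <- length(idx)
    dp <- as.numeric(len); prev <- rep(0L, n)
    if (n > 1L) {
      for (j in 2L:n) {
        for (i in 1L:(j - 1L)) {
          if (q[i] < q[j] && s[i] < s[j] &&
              q[j] - (q[i] + len[i]) <= max_gap &&
              s[j] - (s[i] + len[i]) <= max_gap &&
              abs((s[j] - q[j]) - (s[i] - q[i])) <= max_diag_drift) {
            cand <- dp[i] + len[j]
            if (cand > dp[j]) { dp[j] <- cand; prev[j] <- i }
          }
        }
      }
    }
    best <- which.max(dp)
    path <- integer()
    node <- best
    while (node != 0L) { path <- c(node, path); node <- prev[node] }
    chain <- a[idx[path], , drop = FALSE]
    rownames(chain) <- NULL
    attr(chain, "score") <- dp[best]
    out[[length(out) + 1L]] <- chain
    remaining[idx[path]] <- FALSE
  }
  out
}

#' Align one contig against an indexed replicon
#'
#' Runs anchor finding and chaining, then converts each chain into one local
#' alignment hit spanning its first to last anchor. `matched` is the summed
#' anchor length clipped for anchor overlap; `identity = matched /
#' max(query span, subject span)`.
#'
#' @param contig One-row record data.frame.
#' @param index Seed index from [build_index()].
#' @param min_hit_len Minimum query span to report a hit (bp, default 100).
#' @param min_identity Minimum identity to report a hit (default 0.80).
#' @param max_gap,max_diag_drift Chaining parameters, see [chain_anchors()].
#' @return A data.frame of hits sorted by descending score, with columns
#'   `contig_id`, `replicon_id`, `qstart`, `qend` (0-based half-open on the
#'   forward contig), `sstart`, `send` (0-based half-open on the reference),
#'   `strand`, `matched`, `span`, `identity`, `score`.
#' @export
align_contig <- function(contig, index, min_hit_len = 100L,
                         min_identity = 0.80, max_gap = 1000L,
                         max_diag_drift = 200L) {
  anchors <- find_anchors(contig, index)
  hits <- empty_hits()
  if (!nrow(anchors)) return(hits)
  chains <- chain_anchors(anchors, max_gap = max_gap,
                          max_diag_drift = max_diag_drift)
  lc <- nchar(contig$sequence)
  rows <- lapply(chains, function(ch) {
    qs <- min(ch$q); qe <- max(ch$q + ch$len)
    ss <- min(ch$s); se <- max(ch$s + ch$len)
    o <- order(ch$q)
    q <- ch$q[o]; s <- ch$s[o]; len <- ch$len[o]
    over <- pmax(0L, pmax(c(-Inf, q[-length(q)] + len[-length(len)]) - q,
                          c(-Inf, s[-length(s)] + len[-length(len)]) - s))
    matched <- sum(pmax(0L, len - over))
    span_q <- qe - qs; span_s <- se - ss
    strand <- ch$strand[1L] %||% "+"
    if (strand == "-") { tmp <- qs; qs <- lc - qe; qe <- lc - tmp }
    data.frame(contig_id = contig$id, replicon_id = index$replicon_id,
               qstart = qs, qend = qe, sstart = ss, send = se,
               strand = strand, matched = matched, span = span_q,
               identity = matched / max(span_q, span_s), score = matched,
               stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, rows)
  hits <- hits[hits$span >= min_hit_len & hits$identity >= min_identity, ,
               drop = FALSE]
  hits <- hits[order(-hits$score, hits$sstart, hits$qstart), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

empty_hits <- function() {
  data.frame(contig_id = character(), replicon_id = character(),
             qstart = integer(), qend = integer(), sstart = integer(),
             send = integer(), strand = character(), matched = integer(),
             span = integer(), identity = numeric(), score = integer(),
             stringsAsFactors = FALSE)
}

#' Align all contigs against all reference replicons
#'
#' @param contigs Record data.frame of draft contigs.
#' @param references Record data.frame of reference replicons (one row each).
#' @param k,max_occurrences Index parameters, see [build_index()].
#' @param ... Passed to [align_contig()].
#' @return A data.frame of all hits (see [align_contig()]).
#' @export
align_contigs <- function(contigs, references, k = 15L,
                          max_occurrences = 50L, ...) {
  all_hits <- list()
  for (r in seq_len(nrow(references))) {
    index <- build_index(references[r, , drop = FALSE], k = k,
                         max_occurrences = max_occurrences)
    for (i in seq_len(nrow(contigs))) {
      h <- align_contig(contigs[i, , drop = FALSE], index, ...)
      if (nrow(h)) all_hits[[length(all_hits) + 1L]] <- h
    }
  }
  if (!length(all_hits)) return(empty_hits())
  res <- do.call(rbind, all_hits)
  rownames(res) <- NULL
  res
}
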
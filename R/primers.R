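# Gap-closure PCR primer design.
#
# For every N-gap of a pseudocontig, candidate left primers are enumerated
# from the last `window` bp of the upstream contig and candidate right
# primers from the reverse complement of the first `window` bp of the
# downstream contig. Candidates must pass length/Tm/GC/homopolymer/3'-end
# complementarity filters and occur exactly once (counting both strands)
# across the full input contig set, so every emitted pair amplifies a single
# locus. The emitted pair per gap minimises |Tm_left - Tm_right|, then
# product size. The Tm model is the classic GC-fraction approximation
# (Marmur/Wallace-style), deterministic and parameter-free; it is a
# screening Tm, not a nearest-neighbour thermodynamic one.

#' Default primer design constraints
#'
#' @param length_min,length_max Primer length range (nt).
#' @param tm_min,tm_max Melting temperature range (degrees C).
#' @param gc_min,gc_max GC content range (fractions of 1).
#' @param max_homopolymer Longest allowed single-base run.
#' @param max_end_complementarity Maximum 3'-end complementarity score (the
#'   longest 3'-terminal suffix whose reverse complement occurs in the primer
#'   itself or in its partner).
#' @param window Search window at each flanking contig end (bp).
#' @param max_product Maximum product size including the N-gap (bp).
#' @return A list of constraints for [design_gap_primers()].
#' @export
primer_constraints <- function(length_min = 18L, length_max = 25L,
                               tm_min = 57, tm_max = 63,
                               gc_min = 0.30, gc_max = 0.70,
                               max_homopolymer = 4L,
                               max_end_complementarity = 3L,
                               window = 500L, max_product = 4000L) {
  stopifnot(length_min <= length_max, tm_min <= tm_max, gc_min <= gc_max,
            window >= length_max)
  list(length_min = as.integer(length_min), length_max = as.integer(length_max),
       tm_min = tm_min, tm_max = tm_max, gc_min = gc_min, gc_max = gc_max,
       max_homopolymer = as.integer(max_homopolymer),
       max_end_complementarity = as.integer(max_end_complementarity),
       window = as.integer(window), max_product = as.integer(max_product))
}

#' GC fraction of a sequence
#'
#' @param seq Non-empty DNA string.
#' @return `(G + C) / length`.
#' @export
gc_fraction <- function(seq) {
  if (!nzchar(seq)) stopf("gc_fraction: empty sequence")
  (nchar(seq) - nchar(gsub("[GC]", "", seq))) / nchar(seq)
}

#' Screening melting temperature
#'
#' `Tm = 64.9 + 41 * (nGC - 16.4) / length`, rounded to 0.01 degrees C. A
#' GC-count approximation adequate for ranking gap primers; valid for
#' oligos of 10-40 nt.
#'
#' @param seq DNA string of length 10 to 40.
#' @return Tm in degrees C.
#' @export
melting_temperature <- function(seq) {
  n <- nchar(seq)
  if (n < 10L || n > 40L)
    stopf("melting_temperature: length %d outside 10..40", n)
  ngc <- n * gc_fraction(seq)
  round(64.9 + 41 * (ngc - 16.4) / n, 2)
}

# 3'-end complementarity score: the longest suffix of `primer` whose reverse
# complement occurs in `target`. Monotone in the suffix length, so a
# threshold test only needs the (threshold+1)-mer.
end_complementarity_exceeds <- function(primer, target, threshold) {
  s <- threshold + 1L
  n <- nchar(primer)
  if (n < s) return(FALSE)
  tail_rc <- reverse_complement(substr(primer, n - s + 1L, n))
  grepl(tail_rc, target, fixed = TRUE)
}

#' Single-primer filter
#'
#' Checks length, Tm, GC, homopolymer-run and 3'-end self-complementarity
#' constraints; candidates containing N (or any ambiguity letter) fail.
#'
#' @param seq Candidate primer sequence.
#' @param constraints From [primer_constraints()].
#' @return Logical.
#' @export
passes_filters <- function(seq, constraints = primer_constraints()) {
  n <- nchar(seq)
  if (n < constraints$length_min || n > constraints$length_max) return(FALSE)
  if (grepl("[^ACGT]", seq)) return(FALSE)
  tm <- melting_temperature(seq)
  if (tm < constraints$tm_min || tm > constraints$tm_max) return(FALSE)
  gc <- gc_fraction(seq)
  if (gc < constraints$gc_min || gc > constraints$gc_max) return(FALSE)
  run <- constraints$max_homopolymer + 1L
  if (grepl(sprintf("A{%d}|C{%d}|G{%d}|T{%d}", run, run, run, run), seq))
    return(FALSE)
  !end_complementarity_exceeds(seq, seq, constraints$max_end_complementarity)
}

#' Exact occurrence count of a primer across the input contigs
#'
#' Counts exact, possibly overlapping occurrences of the primer and of its
#' reverse complement over all contigs. A primer suitable for PCR must
#' return 1 (its own site).
#'
#' @param primer Primer sequence.
#' @param contigs Record data.frame of all input contigs.
#' @return Integer occurrence count.
#' @export
occurrence_count <- function(primer, contigs) {
  if (!nzchar(primer)) stopf("occurrence_count: empty primer")
  count_in <- function(pat, seqs) {
    re <- paste0("(?=", pat, ")")
    sum(vapply(seqs, function(s) {
      m <- gregexpr(re, s, perl = TRUE)[[1L]]
      if (m[1L] == -1L) 0L else length(m)
    }, integer(1)))
  }
  rc <- reverse_complement(primer)
  n <- count_in(primer, contigs$sequence)
  if (rc != primer) n <- n + count_in(rc, contigs$sequence)
  n
}

# Enumerate filtered candidates from a window sequence. Returns a data.frame
# with the candidate sequence, its 0-based start offset within the window,
# its length and Tm. `window_seq` is read on the strand the primer will have.
candidate_primers <- function(window_seq, constraints) {
  n <- nchar(window_seq)
  cands <- list()
  for (len in seq(constraints$length_min, constraints$length_max)) {
    if (n < len) next
    starts <- 0:(n - len)
    seqs <- substring(window_seq, starts + 1L, starts + len)
    keep <- vapply(seqs, passes_filters, logical(1),
                   constraints = constraints, USE.NAMES = FALSE)
    if (any(keep))
      cands[[length(cands) + 1L]] <- data.frame(
        seq = seqs[keep], start = starts[keep], len = len,
        tm = vapply(seqs[keep], melting_temperature, numeric(1),
                    USE.NAMES = FALSE),
        stringsAsFactors = FALSE)
  }
  if (!length(cands))
    return(data.frame(seq = character(), start = integer(), len = integer(),
                      tm = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, cands)
}

#' Design one uniqueness-verified primer pair per pseudocontig gap
#'
#' See the module header for the candidate windows and the selection
#' objective. Uniqueness ([occurrence_count()] equal to 1 over all input
#' contigs, both strands) and pair 3'-end complementarity are verified
#' lazily in objective order, so the emitted pair is the best valid one.
#' Gaps without a valid pair are reported with `status = "unpaired"`.
#'
#' @param pseudocontig A pseudocontig list from [build_pseudocontig()].
#' @param contigs Record data.frame of ALL input contigs (mapped and
#'   excluded) — the uniqueness universe.
#' @param constraints From [primer_constraints()].
#' @return A data.frame with one row per gap: `gap_id`, `status`
#'   (`"designed"`/`"unpaired"`), `left_seq`, `right_seq`, `left_start`,
#'   `right_start` (0-based pseudocontig coordinates of each primer's
#'   5'-most base on its own strand... left primer: forward strand; right
#'   primer: its 5' end is the rightmost base of its site), `tm_left`,
#'   `tm_right`, `gc_left`, `gc_right`, `product_size`, `unique`.
#' @export
design_gap_primers <- function(pseudocontig, contigs,
                               constraints = primer_constraints()) {
  placements <- pseudocontig$placements
  gaps <- pseudocontig$gaps
  out <- list()
  occ_cache <- new.env(parent = emptyenv())
  occ1 <- function(p) {
    if (is.null(occ_cache[[p]]))
      occ_cache[[p]] <- occurrence_count(p, contigs) == 1L
    occ_cache[[p]]
  }
  for (g in seq_len(nrow(gaps))) {
    up <- placements[placements$order_index == gaps$after_order_index[g], ]
    down <- placements[placements$order_index == gaps$after_order_index[g] + 1L, ]
    gap_id <- sprintf("%s_gap_%03d", pseudocontig$replicon_id, g)
    w <- constraints$window
    up_len <- up$pseudo_end - up$pseudo_start
    down_len <- down$pseudo_end - down$pseudo_start
    wl <- min(w, up_len); wr <- min(w, down_len)
    left_win_start <- up$pseudo_end - wl
    left_win <- substr(pseudocontig$sequence, left_win_start + 1L, up$pseudo_end)
    right_win <- substr(pseudocontig$sequence, down$pseudo_start + 1L,
                        down$pseudo_start + wr)
    lc <- candidate_primers(left_win, constraints)
    rc <- candidate_primers(reverse_complement(right_win), constraints)
    row <- unpaired_row(gap_id)
    if (nrow(lc) && nrow(rc)) {
      # pseudocontig coordinates: left primer 5' end (forward strand);
      # right primer 3' end is its leftmost base on the forward strand.
      lc$p5 <- left_win_start + lc$start                 # 0-based 5' base
      lc$end3 <- lc$p5 + lc$len                          # half-open 3' edge
      rc$p5 <- down$pseudo_start + wr - rc$start         # half-open 5' edge
      rc$start3 <- rc$p5 - rc$len                        # 0-based 3'-most base
      pair_i <- rep(seq_len(nrow(lc)), times = nrow(rc))
      pair_j <- rep(seq_len(nrow(rc)), each = nrow(lc))
      dtm <- abs(lc$tm[pair_i] - rc$tm[pair_j])
      product <- rc$p5[pair_j] - lc$p5[pair_i]
      keep <- dtm <= 5 & product <= constraints$max_product
      pair_i <- pair_i[keep]; pair_j <- pair_j[keep]
      dtm <- dtm[keep]; product <- product[keep]
      o <- order(dtm, product, lc$p5[pair_i], rc$p5[pair_j])
      for (idx in o) {
        i <- pair_i[idx]; j <- pair_j[idx]
        if (end_complementarity_exceeds(lc$seq[i], rc$seq[j],
                                        constraints$max_end_complementarity) ||
            end_complementarity_exceeds(rc$seq[j], lc$seq[i],
                                        constraints$max_end_complementarity))
          next
        if (!occ1(lc$seq[i]) || !occ1(rc$seq[j])) next
        row <- data.frame(
          gap_id = gap_id, status = "designed",
          left_seq = lc$seq[i], right_seq = rc$seq[j],
          left_start = lc$p5[i], right_start = rc$p5[j] - 1L,
          tm_left = lc$tm[i], tm_right = rc$tm[j],
          gc_left = gc_fraction(lc$seq[i]), gc_right = gc_fraction(rc$seq[j]),
          product_size = product[idx], unique = TRUE,
          stringsAsFactors = FALSE)
        break
      }
    }
    out[[g]] <- row
  }
  if (!length(out)) return(unpaired_row(character(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

unpaired_row <- function(gap_id) {
  n <- length(gap_id)
  data.frame(gap_id = gap_id,
             status = rep("unpaired", n),
             left_seq = rep(NA_character_, n), right_seq = rep(NA_character_, n),
             left_start = rep(NA_integer_, n), right_start = rep(NA_integer_, n),
             tm_left = rep(NA_real_, n), tm_right = rep(NA_real_, n),
             gc_left = rep(NA_real_, n), gc_right = rep(NA_real_, n),
             product_size = rep(NA_integer_, n), unique = rep(NA, n),
             stringsAsFactors = FALSE)
}

#' Count putatively closed gaps
#'
#' A gap is putatively closed when its two flanking contigs are adjacent
#' under the supplied relation (e.g. true adjacency from the synthetic
#' generator, or proximity of projections on the reference) AND a primer
#' pair was designed for it.
#'
#' @param placements Ordered placement data.frame of one pseudocontig.
#' @param pairs Result of [design_gap_primers()] for that pseudocontig.
#' @param adjacency Data.frame with columns `left_id`, `right_id` (unordered
#'   contig-id pairs considered adjacent).
#' @return Integer count.
#' @export
count_putatively_closed <- function(placements, pairs, adjacency) {
  if (!nrow(pairs)) return(0L)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  adj <- key(adjacency$left_id, adjacency$right_id)
  n <- 0L
  ord <- placements[order(placements$order_index), , drop = FALSE]
  for (g in seq_len(nrow(pairs))) {
    if (pairs$status[g] != "designed") next
    up <- ord$contig_id[g]; down <- ord$contig_id[g + 1L]
    if (key(up, down) %in% adj) n <- n + 1L
  }
  n
}
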
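# Ordering, orienting and concatenating mapped contigs into one N-gapped
# pseudocontig per replicon. Placements are anchored at the contig's
# projected left edge on the reference (from its best hit), which keeps the
# inter-contig gap estimates close to the true unsequenced distances.
# Contigs spanning the origin of a circular replicon are split so the map
# stays linear: the part matching the reference start is pinned to the head
# of the molecule, the part matching the reference end to its tail.

#' Orientation of a contig on its assigned replicon
#'
#' The strand carrying the greater total of matched bases wins; ties go to
#' `"+"`.
#'
#' @param hits Hit data.frame for one contig on its assigned replicon.
#' @return `"+"` or `"-"`.
#' @export
determine_orientation <- function(hits) {
  if (!nrow(hits)) stopf("determine_orientation needs at least one hit")
  plus <- sum(hits$matched[hits$strand == "+"])
  minus <- sum(hits$matched[hits$strand == "-"])
  if (minus > plus) "-" else "+"
}

# Best hit under a deterministic tie-break.
best_hit <- function(hits) {
  hits[order(-hits$score, hits$sstart, hits$qstart), , drop = FALSE][1L, ]
}

#' Projected left edge of a contig on the reference
#'
#' Takes the highest-scoring hit and subtracts the hit's query offset
#' (orientation-aware), projecting where the contig's first placed base
#' falls on the reference; clamped to the replicon.
#'
#' @param hits Hit data.frame for one contig on its assigned replicon.
#' @param orientation `"+"` or `"-"` from [determine_orientation()].
#' @param contig_length Contig length (bp).
#' @param replicon_length Replicon length (bp).
#' @return 0-based reference coordinate of the projected contig start.
#' @export
anchor_position <- function(hits, orientation, contig_length,
                            replicon_length) {
  h <- best_hit(hits)
  off <- if (orientation == "+") h$qstart else contig_length - h$qend
  min(max(h$sstart - off, 0L), replicon_length - 1L)
}

#' Does a contig span the origin of a circular replicon?
#'
#' True iff the contig has hits of at least `min_hit_len` bp both fully
#' inside the first and fully inside the last `w` bp of the reference, with
#' disjoint query intervals, where `w` is `origin_window` capped at a
#' quarter of the replicon.
#'
#' @param hits Hit data.frame for one contig on its assigned replicon.
#' @param replicon_length Replicon length (bp).
#' @param circular Is the reference circular? (`FALSE` short-circuits.)
#' @param origin_window Window size at each reference end (bp, default 30000).
#' @param min_hit_len Minimum hit span to count as evidence (default 100).
#' @return Logical.
#' @export
detect_origin_spanning <- function(hits, replicon_length, circular = TRUE,
                                   origin_window = 30000L,
                                   min_hit_len = 100L) {
  if (!circular || !nrow(hits)) return(FALSE)
  w <- min(origin_window, replicon_length %/% 4L)
  strong <- hits[hits$span >= min_hit_len, , drop = FALSE]
  head_hits <- strong[strong$send <= w, , drop = FALSE]
  tail_hits <- strong[strong$sstart >= replicon_length - w, , drop = FALSE]
  if (!nrow(head_hits) || !nrow(tail_hits)) return(FALSE)
  for (i in seq_len(nrow(tail_hits))) {
    disjoint <- head_hits$qstart >= tail_hits$qend[i] |
      head_hits$qend <= tail_hits$qstart[i]
    if (any(disjoint)) return(TRUE)
  }
  FALSE
}

# Hits with query intervals mapped onto the oriented contig (the sequence as
# it will be placed); strand labels are dropped.
orient_hits <- function(hits, orientation, contig_length) {
  if (orientation == "-") {
    tmp <- hits$qstart
    hits$qstart <- contig_length - hits$qend
    hits$qend <- contig_length - tmp
  }
  hits
}

#' Split an origin-spanning contig into head and tail parts
#'
#' Cuts the (oriented) contig at the boundary between the query interval
#' matching the reference end and the one matching the reference start. The
#' start-matching part is pinned to the head of the pseudocontig, the
#' end-matching part to its tail. Both part sequences are returned already
#' oriented; their concatenation `tail + head` equals the oriented contig.
#'
#' @param contig One-row record data.frame.
#' @param hits Hit data.frame for this contig on its assigned replicon.
#' @param replicon_length Replicon length (bp).
#' @inheritParams detect_origin_spanning
#' @return A list with `head` and `tail` (each `sequence`, `anchor`,
#'   `split_part`) and `orientation`, or `NULL` with a warning when the cut
#'   is ambiguous (overlapping query intervals).
#' @export
split_origin_contig <- function(contig, hits, replicon_length,
                                origin_window = 30000L, min_hit_len = 100L) {
  o <- determine_orientation(hits)
  lc <- nchar(contig$sequence)
  oh <- orient_hits(hits, o, lc)
  w <- min(origin_window, replicon_length %/% 4L)
  strong <- oh[oh$span >= min_hit_len, , drop = FALSE]
  hs <- strong[strong$send <= w, , drop = FALSE]               # matches ref start
  he <- strong[strong$sstart >= replicon_length - w, , drop = FALSE]  # ref end
  if (!nrow(hs) || !nrow(he)) {
    warnf("contig '%s': origin split requested but zone hits missing", contig$id)
    return(NULL)
  }
  hs <- best_hit(hs); he <- best_hit(he)
  if (he$qend > hs$qstart) {
    warnf("contig '%s': ambiguous origin cut (overlapping query intervals)",
          contig$id)
    return(NULL)
  }
  oriented <- if (o == "-") reverse_complement(contig$sequence)
              else contig$sequence
  cut <- he$qend
  tail_seq <- substr(oriented, 1L, cut)
  head_seq <- substr(oriented, cut + 1L, lc)
  list(head = list(sequence = head_seq,
                   anchor = max(hs$sstart - (hs$qstart - cut), 0L),
                   split_part = "head"),
       tail = list(sequence = tail_seq,
                   anchor = max(he$sstart - he$qstart, 0L),
                   split_part = "tail"),
       orientation = o)
}

#' Order placements along the replicon
#'
#' Sorts by anchor (ascending), ties by contig id; origin-split head parts
#' are pinned to the first positions and tail parts to the last.
#'
#' @param placements Placement data.frame (columns `contig_id`, `anchor`,
#'   `split_part`, ...).
#' @return The placements sorted, with `order_index` set to `0..n-1`.
#' @export
order_contigs <- function(placements) {
  pin <- match(placements$split_part, c("head", "none", "tail"))
  o <- order(pin, placements$anchor, placements$contig_id)
  placements <- placements[o, , drop = FALSE]
  placements$order_index <- seq_len(nrow(placements)) - 1L
  rownames(placements) <- NULL
  placements
}

#' Estimated gap between two consecutive placements
#'
#' The gap is the distance between the upstream contig's projected right
#' edge and the downstream contig's projected left edge on the reference
#' (negative when the projections overlap). The N spacer is the estimated
#' gap, floored at `min_spacer`.
#'
#' @param prev,nxt One-row placement data.frames (need `anchor`, `length`).
#' @param min_spacer Minimum N-run length between contigs (default 100).
#' @return A list with `gap_bp` (may be negative) and `n_count`.
#' @export
estimate_gap <- function(prev, nxt, min_spacer = 100L) {
  gap <- as.integer(nxt$anchor - (prev$anchor + prev$length))
  list(gap_bp = gap, n_count = max(gap, as.integer(min_spacer)))
}

#' Concatenate ordered placements into a pseudocontig
#'
#' Joins the placed sequences (reverse-complemented where orientation is
#' `"-"`; origin-split parts arrive pre-oriented) with runs of N between
#' consecutive placements, and fills each placement's pseudocontig
#' coordinates.
#'
#' @param placements Ordered placement data.frame (from [order_contigs()])
#'   with a `sequence` column.
#' @param gaps Data.frame with one row per inter-contig junction
#'   (`after_order_index`, `gap_bp`, `n_count`).
#' @param replicon_id Id of the replicon the molecule belongs to.
#' @return A list with `replicon_id`, `sequence`, `placements` (with
#'   `pseudo_start`/`pseudo_end` filled), `gaps`.
#' @export
build_pseudocontig <- function(placements, gaps, replicon_id) {
  n <- nrow(placements)
  stopifnot(n >= 1L, nrow(gaps) == n - 1L)
  seqs <- ifelse(placements$orientation == "-" & placements$split_part == "none",
                 vapply(placements$sequence, reverse_complement, character(1)),
                 placements$sequence)
  lens <- nchar(seqs)
  spacers <- c(gaps$n_count, 0L)
  starts <- cumsum(c(0L, (lens + spacers)[-n]))
  placements$pseudo_start <- as.integer(starts)
  placements$pseudo_end <- as.integer(starts + lens)
  pieces <- character(2L * n - 1L)
  pieces[seq(1L, 2L * n - 1L, by = 2L)] <- seqs
  if (n > 1L) pieces[seq(2L, 2L * n - 2L, by = 2L)] <- strrep("N", gaps$n_count)
  list(replicon_id = replicon_id,
       sequence = paste(pieces, collapse = ""),
       placements = placements,
       gaps = gaps)
}

#' Scaffold all contigs assigned to one replicon
#'
#' Runs orientation, anchoring, origin splitting, ordering, gap estimation
#' and concatenation for the set of contigs assigned to one reference
#' replicon.
#'
#' @param contigs Record data.frame of the assigned contigs.
#' @param hits Hit data.frame restricted to these contigs on this replicon.
#' @param replicon One-row record data.frame (the reference).
#' @param circular Treat the reference as circular (default TRUE).
#' @param origin_window,min_hit_len See [detect_origin_spanning()].
#' @param min_spacer See [estimate_gap()].
#' @return A pseudocontig list as from [build_pseudocontig()], or `NULL`
#'   when no contig is assigned.
#' @export
scaffold_replicon <- function(contigs, hits, replicon, circular = TRUE,
                              origin_window = 30000L, min_hit_len = 100L,
                              min_spacer = 100L) {
  if (!nrow(contigs)) return(NULL)
  lr <- nchar(replicon$sequence)
  rows <- list()
  for (i in seq_len(nrow(contigs))) {
    ctg <- contigs[i, , drop = FALSE]
    h <- hits[hits$contig_id == ctg$id, , drop = FALSE]
    if (!nrow(h)) next
    lc <- nchar(ctg$sequence)
    split <- NULL
    if (circular && detect_origin_spanning(h, lr, circular, origin_window,
                                           min_hit_len))
      split <- split_origin_contig(ctg, h, lr, origin_window, min_hit_len)
    if (!is.null(split)) {
      for (part in list(split$head, split$tail)) {
        rows[[length(rows) + 1L]] <- data.frame(
          contig_id = ctg$id, replicon_id = replicon$id,
          orientation = split$orientation, anchor = part$anchor,
          length = nchar(part$sequence), split_part = part$split_part,
          sequence = part$sequence, stringsAsFactors = FALSE)
      }
    } else {
      o <- determine_orientation(h)
      rows[[length(rows) + 1L]] <- data.frame(
        contig_id = ctg$id, replicon_id = replicon$id, orientation = o,
        anchor = anchor_position(h, o, lc, lr), length = lc,
        split_part = "none", sequence = ctg$sequence,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(NULL)
  placements <- order_contigs(do.call(rbind, rows))
  n <- nrow(placements)
  gaps <- data.frame(after_order_index = integer(), gap_bp = integer(),
                     n_count = integer())
  if (n > 1L) {
    est <- lapply(seq_len(n - 1L), function(i)
      estimate_gap(placements[i, ], placements[i + 1L, ], min_spacer))
    gaps <- data.frame(
      after_order_index = seq_len(n - 1L) - 1L,
      gap_bp = vapply(est, `[[`, integer(1), "gap_bp"),
      n_count = vapply(est, `[[`, integer(1), "n_count"))
  }
  build_pseudocontig(placements, gaps, replicon$id)
}
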
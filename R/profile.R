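# Contig profiling and multipartite replicon assignment.
#
# Each contig is classified as mapped or excluded (too short / no hit / low
# coverage) from the union of its hit intervals per replicon, and every
# mapped contig is assigned to exactly one replicon: the one with the
# greatest aligned base count, ties broken lexicographically. This is the
# guarantee that no contig of a multipartite genome is placed twice.

#' Total length of a union of intervals
#'
#' @param intervals A two-column matrix or data.frame of 0-based half-open
#'   `[start, end)` intervals.
#' @return The length of their union, in bp.
#' @examples
#' interval_union_length(rbind(c(0, 50), c(25, 75)))  # 75
#' @export
interval_union_length <- function(intervals) {
  m <- merge_intervals(intervals)
  if (!nrow(m)) return(0L)
  as.integer(sum(m[, 2L] - m[, 1L]))
}

# Sorted, disjoint merge of 0-based half-open intervals (matrix in/out).
merge_intervals <- function(intervals) {
  m <- as.matrix(intervals)
  if (!nrow(m)) return(matrix(integer(), ncol = 2L))
  m <- m[order(m[, 1L], m[, 2L]), , drop = FALSE]
  end_run <- cummax(m[, 2L])
  new_block <- c(TRUE, m[-1L, 1L] > end_run[-nrow(m)])
  grp <- cumsum(new_block)
  cbind(start = tapply(m[, 1L], grp, min),
        end = tapply(end_run, grp, max))
}

#' Profile one contig from its alignment hits
#'
#' Computes per-replicon coverage (union of hit query intervals over contig
#' length) and a mapping status: `excluded_short` when the contig is below
#' `min_contig_length`, `excluded_no_hit` when nothing aligned,
#' `excluded_low_coverage` when the best coverage is below `min_coverage`,
#' else `mapped` with `best_replicon` set (greatest aligned bp, ties broken
#' by lexicographically smallest replicon id).
#'
#' @param contig One-row record data.frame.
#' @param hits Hit data.frame for this contig (any subset of replicons).
#' @param min_contig_length Minimum contig length to map (bp, default 1000).
#' @param min_coverage Minimum fraction of the contig covered by hits on its
#'   best replicon (default 0.20).
#' @return A list with `contig_id`, `length`, `coverage_by_replicon`,
#'   `aligned_bp_by_replicon` (named numerics), `best_replicon` (NA unless
#'   mapped), `status`.
#' @export
profile_contig <- function(contig, hits, min_contig_length = 1000L,
                           min_coverage = 0.20) {
  stopifnot(nrow(contig) == 1L)
  if (nrow(hits) && any(hits$contig_id != contig$id))
    stopf("hits for a different contig passed to profile_contig")
  len <- nchar(contig$sequence)
  aligned <- numeric()
  if (nrow(hits)) {
    aligned <- vapply(split(seq_len(nrow(hits)), hits$replicon_id),
                      function(i) interval_union_length(
                        cbind(hits$qstart[i], hits$qend[i])),
                      numeric(1))
  }
  coverage <- aligned / len
  status <- if (len < min_contig_length) "excluded_short"
    else if (!length(aligned)) "excluded_no_hit"
    else if (max(coverage) < min_coverage) "excluded_low_coverage"
    else "mapped"
  best <- NA_character_
  if (status == "mapped") {
    ids <- names(aligned)
    best <- ids[order(-aligned, ids)][1L]
  }
  list(contig_id = contig$id, length = len,
       coverage_by_replicon = coverage,
       aligned_bp_by_replicon = aligned,
       best_replicon = best, status = status)
}

#' Replicon assignment of a profiled contig
#'
#' @param profile A profile from [profile_contig()].
#' @return The assigned replicon id, or `NA` for excluded contigs.
#' @export
assign_replicon <- function(profile) profile$best_replicon

#' Profile every contig and assign replicons
#'
#' @param contigs Record data.frame of all draft contigs.
#' @param hits Hit data.frame from [align_contigs()].
#' @inheritParams profile_contig
#' @return A data.frame with one row per contig: `contig_id`, `length`,
#'   `best_replicon`, `best_coverage`, `aligned_bp`, `status`. Each contig id
#'   occurs exactly once, so no contig can be placed on two replicons.
#' @export
profile_contigs <- function(contigs, hits, min_contig_length = 1000L,
                            min_coverage = 0.20) {
  rows <- lapply(seq_len(nrow(contigs)), function(i) {
    h <- hits[hits$contig_id == contigs$id[i], , drop = FALSE]
    p <- profile_contig(contigs[i, , drop = FALSE], h,
                        min_contig_length, min_coverage)
    data.frame(contig_id = p$contig_id, length = p$length,
               best_replicon = p$best_replicon,
               best_coverage = if (length(p$coverage_by_replicon))
                 max(p$coverage_by_replicon) else 0,
               aligned_bp = if (is.na(p$best_replicon)) 0L
                 else as.integer(p$aligned_bp_by_replicon[[p$best_replicon]]),
               status = p$status, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Reference regions with no contig homology
#'
#' Complements the union of subject intervals of the replicon's hits,
#' keeping regions of at least `min_region_length` bp. These are the
#' candidate gain/loss regions whose proteins are rescanned against excluded
#' contigs by [scan_excluded_contigs()].
#'
#' @param hits Hit data.frame restricted to one replicon.
#' @param replicon_length Length of the replicon (bp).
#' @param min_region_length Minimum reported region length (bp, default 1000).
#' @return A data.frame of disjoint sorted 0-based half-open `start`/`end`
#'   intervals with a `length` column.
#' @export
unaligned_reference_regions <- function(hits, replicon_length,
                                        min_region_length = 1000L) {
  cov <- if (nrow(hits)) merge_intervals(cbind(hits$sstart, hits$send))
         else matrix(integer(), ncol = 2L)
  bounds <- c(0L, as.vector(t(cov)), replicon_length)
  start <- bounds[seq(1L, length(bounds), by = 2L)]
  end <- bounds[seq(2L, length(bounds), by = 2L)]
  keep <- end - start >= min_region_length
  data.frame(start = as.integer(start[keep]), end = as.integer(end[keep]),
             length = as.integer(end[keep] - start[keep]))
}
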
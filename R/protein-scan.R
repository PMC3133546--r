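# Six-frame protein scan of excluded contigs.
#
# Reference proteins lying wholly inside unaligned reference regions are
# locally aligned (Smith-Waterman, BLOSUM62, affine gaps) against all six
# frame translations of every excluded contig — a native stand-in for a
# translated nucleotide search. Full DP is affordable because the excluded
# set is small by construction. Stop codons translate to '*' and score -4
# against everything, so they truncate rather than break alignments.

# Bacterial genetic code (translation table 11; identical codon->aa map to
# the standard code, bacterial start-codon policy is irrelevant here).
genetic_code_11 <- local({
  code <- NULL
  function() {
    if (is.null(code)) code <<- Biostrings::getGeneticCode("11")
    code
  }
})

blosum62 <- local({
  mat <- NULL
  function() {
    if (is.null(mat)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      m <- e$BLOSUM62
      m["*", ] <- -4L
      m[, "*"] <- -4L
      mat <<- m
    }
    mat
  }
})

# Translate a DNA string (frame 0, dangling bases dropped); codons containing
# non-ACGT letters become 'X'.
translate_dna <- function(seq) {
  n_codons <- nchar(seq) %/% 3L
  if (!n_codons) return("")
  starts <- seq(1L, by = 3L, length.out = n_codons)
  codons <- substring(seq, starts, starts + 2L)
  aa <- unname(genetic_code_11()[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Translate a contig in all six frames
#'
#' Frames +1/+2/+3 translate the forward sequence at offsets 0/1/2; frames
#' -1/-2/-3 translate the reverse complement likewise. Amino acid `i`
#' (0-based) of frame `f` maps back to forward-strand nucleotides via
#' [frame_nt_interval()].
#'
#' @param contig One-row record data.frame (length >= 3).
#' @return A list of six entries (`"+1"`..`"-3"`), each with `contig_id`,
#'   `frame`, `offset`, `aa`.
#' @export
six_frame_translate <- function(contig) {
  stopifnot(nrow(contig) == 1L, nchar(contig$sequence) >= 3L)
  fwd <- contig$sequence
  rev <- reverse_complement(fwd)
  out <- list()
  for (f in 1:3) {
    out[[paste0("+", f)]] <- list(contig_id = contig$id, frame = f,
                                  offset = f - 1L,
                                  aa = translate_dna(substring(fwd, f)))
    out[[paste0("-", f)]] <- list(contig_id = contig$id, frame = -f,
                                  offset = f - 1L,
                                  aa = translate_dna(substring(rev, f)))
  }
  out
}

#' Forward-strand nucleotide interval of a frame-translation span
#'
#' @param frame Frame in `+1..+3, -1..-3`.
#' @param aa_start,aa_end 0-based half-open amino-acid interval within the
#'   frame translation.
#' @param contig_length Contig length (bp).
#' @return Integer vector `c(start, end)`, 0-based half-open on the forward
#'   contig strand.
#' @export
frame_nt_interval <- function(frame, aa_start, aa_end, contig_length) {
  off <- abs(frame) - 1L
  s <- off + 3L * aa_start
  e <- off + 3L * aa_end
  if (frame > 0) c(s, e) else c(contig_length - e, contig_length - s)
}

#' Reference proteins wholly inside unaligned regions
#'
#' @param features PTT feature data.frame (1-based inclusive coordinates).
#' @param regions Unaligned-region data.frame from
#'   [unaligned_reference_regions()] (0-based half-open).
#' @return The subset of `features` contained in some region.
#' @export
select_unmapped_proteins <- function(features, regions) {
  if (!nrow(features) || !nrow(regions))
    return(features[integer(), , drop = FALSE])
  inside <- vapply(seq_len(nrow(features)), function(i)
    any(features$start[i] - 1L >= regions$start & features$end[i] <= regions$end),
    logical(1))
  features[inside, , drop = FALSE]
}

#' Local protein alignment (Smith-Waterman, affine gaps)
#'
#' Optimal local alignment under BLOSUM62 (with `*` forced to -4 against
#' everything) and affine gap cost `gap_open + gap_extend * L` for a gap of
#' length `L`.
#'
#' @param query,target Non-empty protein strings.
#' @param gap_open,gap_extend Affine gap parameters (defaults 11 / 1).
#' @param matrix Substitution matrix (default the adjusted BLOSUM62).
#' @return A list: `score`, `q_start`, `q_end`, `t_start`, `t_end` (0-based
#'   half-open), `identity` (identical residues over alignment columns).
#'   A best score of 0 or less is reported as `score = 0` with empty
#'   intervals.
#' @export
local_align_protein <- function(query, target, gap_open = 11, gap_extend = 1,
                                matrix = NULL) {
  stopifnot(nzchar(query), nzchar(target))
  if (is.null(matrix)) matrix <- blosum62()
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(query),
    subject = Biostrings::AAString(target),
    type = "local", substitutionMatrix = matrix,
    gapOpening = gap_open, gapExtension = gap_extend)
  sc <- Biostrings::score(aln)
  if (sc <= 0)
    return(list(score = 0, q_start = 0L, q_end = 0L, t_start = 0L,
                t_end = 0L, identity = 0))
  p <- Biostrings::pattern(aln)
  s <- Biostrings::subject(aln)
  list(score = sc,
       q_start = Biostrings::start(p) - 1L, q_end = Biostrings::end(p),
       t_start = Biostrings::start(s) - 1L, t_end = Biostrings::end(s),
       identity = Biostrings::nmatch(aln) / Biostrings::nchar(aln))
}

#' Scan excluded contigs for reference proteins from unaligned regions
#'
#' Aligns each selected protein against all six frame translations of every
#' excluded contig and reports hits reaching `min_score`.
#'
#' @param proteins PTT feature data.frame with an `aa` column (see
#'   [translate_features()] and [select_unmapped_proteins()]).
#' @param excluded Record data.frame of excluded contigs.
#' @param min_score Minimum Smith-Waterman score to report (default 50).
#' @return A data.frame of hits: `pid`, `ref_id`, `ref_start`, `ref_end`,
#'   `contig_id`, `frame`, `aa_start`, `aa_end` (0-based half-open on the
#'   protein), `nt_start`, `nt_end` (0-based half-open, forward contig
#'   strand), `score`, `identity`.
#' @export
scan_excluded_contigs <- function(proteins, excluded, min_score = 50) {
  rows <- list()
  for (ci in seq_len(nrow(excluded))) {
    ctg <- excluded[ci, , drop = FALSE]
    if (nchar(ctg$sequence) < 3L) next
    frames <- six_frame_translate(ctg)
    for (pi in seq_len(nrow(proteins))) {
      aa <- proteins$aa[pi]
      if (!nzchar(aa)) next
      for (fr in frames) {
        if (!nzchar(fr$aa)) next
        al <- local_align_protein(aa, fr$aa)
        if (al$score < min_score) next
        nt <- frame_nt_interval(fr$frame, al$t_start, al$t_end,
                                nchar(ctg$sequence))
        rows[[length(rows) + 1L]] <- data.frame(
          pid = proteins$pid[pi], ref_id = proteins$ref_id[pi],
          ref_start = proteins$start[pi], ref_end = proteins$end[pi],
          contig_id = ctg$id, frame = fr$frame,
          aa_start = al$q_start, aa_end = al$q_end,
          nt_start = nt[1L], nt_end = nt[2L],
          score = al$score, identity = al$identity,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(pid = character(), ref_id = character(),
                      ref_start = integer(), ref_end = integer(),
                      contig_id = character(), frame = integer(),
                      aa_start = integer(), aa_end = integer(),
                      nt_start = integer(), nt_end = integer(),
                      score = numeric(), identity = numeric(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, rows)
  res <- res[order(-res$score, res$pid, res$contig_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}
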
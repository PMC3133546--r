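# Synthetic genomes with recorded ground truth.
#
# The generator emulates the situation the pipeline is built for: a draft
# assembly of a multipartite bacterial genome sequenced against a close
# reference. Replicons are i.i.d. base sequences at a chosen GC content;
# contigs are ordered reference fragments separated by geometric gaps,
# independently inverted and point-mutated (substitutions only — strain-level
# divergence without indels), optionally including one fragment built across
# the origin of the first replicon and contaminant contigs guaranteed to
# share no seed k-mer with the reference. Everything is deterministic under
# the seed, and the truth table suffices to reconstruct the reference
# intervals exactly when the mutation rate is zero.

#' Generate a random multi-replicon reference genome
#'
#' @param replicon_lengths Integer vector of replicon lengths (bp, each
#'   >= 10000).
#' @param gc Target GC content (default 0.5).
#' @param seed RNG seed (required; the caller's RNG state is untouched).
#' @return A record data.frame with one row per replicon
#'   (`replicon_01`, `replicon_02`, ...).
#' @export
generate_genome <- function(replicon_lengths, gc = 0.5, seed) {
  stopifnot(all(replicon_lengths >= 10000L), gc > 0, gc < 1)
  with_seed(seed, {
    seqs <- vapply(replicon_lengths, function(n)
      paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                   prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
            collapse = ""), character(1))
    data.frame(id = sprintf("replicon_%02d", seq_along(replicon_lengths)),
               description = sprintf("synthetic replicon (%d bp)",
                                     replicon_lengths),
               sequence = seqs, stringsAsFactors = FALSE)
  })
}

mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  n <- nchar(seq)
  n_mut <- stats::rbinom(1L, n, rate)
  if (!n_mut) return(seq)
  pos <- sample.int(n, n_mut)
  chars <- strsplit(seq, "")[[1L]]
  bases <- c("A", "C", "G", "T")
  for (p in pos) {
    alt <- setdiff(bases, chars[p])
    chars[p] <- alt[sample.int(length(alt), 1L)]
  }
  paste(chars, collapse = "")
}

# Fragment lengths summing exactly to `total`, each >= min_fragment.
random_composition <- function(total, n, min_fragment) {
  extra <- total - n * min_fragment
  if (extra < 0) stopf("fragmentation infeasible: %d bp for %d fragments of >= %d",
                       total, n, min_fragment)
  if (n == 1L) return(total)
  parts <- diff(c(0, sort(stats::runif(n - 1L)), 1))
  lens <- min_fragment + floor(parts * extra)
  rem <- total - sum(lens)
  if (rem > 0) lens[seq_len(rem)] <- lens[seq_len(rem)] + 1L
  as.integer(lens)
}

#' Fragment a synthetic genome into a draft contig set with known truth
#'
#' @param genome Record data.frame from [generate_genome()].
#' @param n_contigs Total number of genuine contigs (distributed over
#'   replicons proportionally to length, at least 2 each).
#' @param gap_mean Mean unsequenced gap between consecutive fragments (bp;
#'   gaps are geometric with minimum 1).
#' @param inversion_prob Probability a fragment is reverse-complemented.
#' @param mutation_rate Per-base substitution rate applied to each fragment.
#' @param n_contaminants Number of contaminant contigs (random sequences
#'   rejection-sampled to share no 15-mer, either strand, with the
#'   reference).
#' @param origin_spanner Plant one fragment crossing the origin of the first
#'   replicon.
#' @param seed RNG seed.
#' @param min_fragment Minimum fragment length (bp, default 1500).
#' @param contaminant_length_range Length range for contaminants.
#' @return A list with `contigs` (record data.frame, shuffled order) and
#'   `truth`: `$contigs` (per contig: `contig_id`, `replicon_id`, `start`,
#'   `end` 0-based half-open on the reference — for the origin spanner
#'   `start > end`, meaning it wraps —, `strand`, `contaminant`,
#'   `origin_spanning`) and `$adjacency` (per adjacent pair on the
#'   reference: `replicon_id`, `left_id`, `right_id`, `gap_bp`).
#' @export
fragment_genome <- function(genome, n_contigs, gap_mean = 500,
                            inversion_prob = 0.2, mutation_rate = 0.01,
                            n_contaminants = 0L, origin_spanner = FALSE,
                            seed, min_fragment = 1500L,
                            contaminant_length_range = c(1500L, 3000L)) {
  stopifnot(n_contigs >= 2L * nrow(genome))
  with_seed(seed, {
    lens <- nchar(genome$sequence)
    n_per <- pmax(2L, round(n_contigs * lens / sum(lens)))
    while (sum(n_per) != n_contigs) {
      i <- if (sum(n_per) > n_contigs) which.max(n_per) else which.min(n_per)
      n_per[i] <- n_per[i] + sign(n_contigs - sum(n_per))
    }
    seqs <- character(); truth <- list(); adj <- list()
    tag <- 0L
    for (r in seq_len(nrow(genome))) {
      S <- genome$sequence[r]; L <- lens[r]
      has_span <- origin_spanner && r == 1L
      n_f <- n_per[r] - has_span
      if (has_span) {
        a <- sample(1000:2500, 1L); b <- sample(1000:2500, 1L)
        region <- c(b, L - a)
      } else region <- c(0L, L)
      n_gaps <- n_f - 1L + 2L * has_span
      g <- if (n_gaps > 0) 1L + stats::rgeom(n_gaps, 1 / gap_mean) else integer()
      frag_total <- region[2L] - region[1L] - sum(g)
      flens <- random_composition(frag_total, n_f, min_fragment)
      ids_here <- character()
      pos <- region[1L]
      if (has_span) {
        tag <- tag + 1L
        span_seq <- paste0(substr(S, L - a + 1L, L), substr(S, 1L, b))
        strand <- if (stats::runif(1L) < inversion_prob) "-" else "+"
        sq <- mutate_seq(span_seq, mutation_rate)
        if (strand == "-") sq <- reverse_complement(sq)
        seqs[tag] <- sq
        truth[[tag]] <- data.frame(tmp_id = tag, replicon_id = genome$id[r],
                                   start = L - a, end = b, strand = strand,
                                   contaminant = FALSE, origin_spanning = TRUE,
                                   stringsAsFactors = FALSE)
        ids_here <- c(ids_here, tag)
        pos <- pos + g[1L]
      }
      for (i in seq_len(n_f)) {
        tag <- tag + 1L
        st <- pos; en <- pos + flens[i]
        strand <- if (stats::runif(1L) < inversion_prob) "-" else "+"
        sq <- mutate_seq(substr(S, st + 1L, en), mutation_rate)
        if (strand == "-") sq <- reverse_complement(sq)
        seqs[tag] <- sq
        truth[[tag]] <- data.frame(tmp_id = tag, replicon_id = genome$id[r],
                                   start = st, end = en, strand = strand,
                                   contaminant = FALSE, origin_spanning = FALSE,
                                   stringsAsFactors = FALSE)
        ids_here <- c(ids_here, tag)
        pos <- en + if (i < n_f || has_span) g[i + has_span] else 0L
      }
      if (has_span) ids_here <- c(ids_here, ids_here[1L])  # wraps to tail
      gap_seq <- g
      for (i in seq_along(ids_here)[-1L]) {
        adj[[length(adj) + 1L]] <- data.frame(
          replicon_id = genome$id[r],
          left_tmp = as.integer(ids_here[i - 1L]),
          right_tmp = as.integer(ids_here[i]),
          gap_bp = gap_seq[i - 1L], stringsAsFactors = FALSE)
      }
    }
    # contaminants: no 15-mer shared with the reference on either strand
    if (n_contaminants > 0L) {
      ref_kmers <- unique(unlist(lapply(genome$sequence, extract_kmers, k = 15L)))
      for (j in seq_len(n_contaminants)) {
        len <- sample(contaminant_length_range[1L]:contaminant_length_range[2L], 1L)
        repeat {
          cand <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                        collapse = "")
          km <- c(extract_kmers(cand, 15L),
                  extract_kmers(reverse_complement(cand), 15L))
          if (!any(km %in% ref_kmers)) break
        }
        tag <- tag + 1L
        seqs[tag] <- cand
        truth[[tag]] <- data.frame(tmp_id = tag, replicon_id = NA_character_,
                                   start = NA_integer_, end = NA_integer_,
                                   strand = NA_character_, contaminant = TRUE,
                                   origin_spanning = FALSE,
                                   stringsAsFactors = FALSE)
      }
    }
    truth_df <- do.call(rbind, truth)
    perm <- sample.int(tag)
    # the contig at shuffled position i is named contig_<i>
    name_of <- character(tag)
    name_of[perm] <- sprintf("contig_%04d", seq_len(tag))
    contigs <- data.frame(id = name_of[perm],
                          description = "synthetic draft contig",
                          sequence = seqs[perm], stringsAsFactors = FALSE)
    truth_df$contig_id <- name_of[truth_df$tmp_id]
    truth_df$tmp_id <- NULL
    truth_df <- truth_df[, c("contig_id", "replicon_id", "start", "end",
                             "strand", "contaminant", "origin_spanning")]
    adj_df <- if (length(adj)) {
      a <- do.call(rbind, adj)
      data.frame(replicon_id = a$replicon_id,
                 left_id = name_of[a$left_tmp],
                 right_id = name_of[a$right_tmp],
                 gap_bp = a$gap_bp, stringsAsFactors = FALSE)
    } else data.frame(replicon_id = character(), left_id = character(),
                      right_id = character(), gap_bp = integer(),
                      stringsAsFactors = FALSE)
    list(contigs = contigs, truth = list(contigs = truth_df, adjacency = adj_df))
  })
}

#' Random protein features for a synthetic replicon
#'
#' Draws non-overlapping CDS spans (length a multiple of 3) on random
#' strands, for building PTT fixtures.
#'
#' @param replicon One-row record data.frame.
#' @param n Number of features.
#' @param aa_len_range Protein length range (residues).
#' @param seed RNG seed.
#' @return A PTT feature data.frame (1-based inclusive coordinates) as
#'   returned by [read_ptt()].
#' @export
random_protein_features <- function(replicon, n = 10L,
                                    aa_len_range = c(80L, 200L), seed) {
  L <- nchar(replicon$sequence)
  with_seed(seed, {
    spans <- matrix(integer(), ncol = 2L)
    guard <- 0L
    while (nrow(spans) < n && guard < 1000L) {
      guard <- guard + 1L
      aa <- sample(aa_len_range[1L]:aa_len_range[2L], 1L)
      len <- 3L * (aa + 1L)
      st <- sample.int(L - len, 1L)          # 1-based start
      en <- st + len - 1L
      if (!nrow(spans) || all(en < spans[, 1L] | st > spans[, 2L]))
        spans <- rbind(spans, c(st, en))
    }
    spans <- spans[order(spans[, 1L]), , drop = FALSE]
    data.frame(ref_id = replicon$id,
               start = spans[, 1L], end = spans[, 2L],
               strand = sample(c("+", "-"), nrow(spans), replace = TRUE),
               pid = sprintf("9%07d", seq_len(nrow(spans))),
               gene = sprintf("syn%03d", seq_len(nrow(spans))),
               product = "synthetic protein", stringsAsFactors = FALSE)
  })
}
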
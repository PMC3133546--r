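# End-to-end pipeline: align -> profile/assign -> scaffold -> primers ->
# protein scan -> write. One output directory per reference replicon, with
# the ACT-loadable file set (Reference.fsa, PseudoContig.fsa,
# PseudoContig.crunch, ReferenceHits.tab, PseudoContig.tab, and optionally
# PCRProducts.tab / PrimerPairs.tsv / ReferenceProteinHits.tab), plus a
# top-level UnMappedContigs.txt and run summary.

# Feature colours used in the .tab entries (Artemis colour numbers):
# mapped contig 4 (blue), origin-split part 9 (light blue), reference hit 10
# (orange), PCR product 2 (red), protein hit 3 (green).
TAB_COLOURS <- c(contig = "4", split = "9", refhit = "10", pcr = "2",
                 protein = "3")

#' Assemble the default pipeline options
#'
#' All thresholds of the individual stages in one validated list; every
#' entry is overridable from [run_pipeline()] and the command line.
#'
#' @param k,max_occurrences Seed index parameters ([build_index()]).
#' @param min_hit_len,min_identity,max_gap,max_diag_drift Aligner thresholds
#'   ([align_contig()]).
#' @param min_contig_length,min_coverage Profiling thresholds
#'   ([profile_contigs()]).
#' @param circular,origin_window,min_spacer Scaffolding parameters
#'   ([scaffold_replicon()]).
#' @param primers Run the primer-design stage (default TRUE).
#' @param constraints Primer constraints ([primer_constraints()]).
#' @param protein_scan Run the six-frame protein scan of excluded contigs
#'   (needs PTT tables; default FALSE).
#' @param min_region_length Minimum unaligned-region length
#'   ([unaligned_reference_regions()]).
#' @param min_protein_score Minimum Smith-Waterman score
#'   ([scan_excluded_contigs()]).
#' @return A named list of options.
#' @export
pipeline_options <- function(k = 15L, max_occurrences = 50L,
                             min_hit_len = 100L, min_identity = 0.80,
                             max_gap = 1000L, max_diag_drift = 200L,
                             min_contig_length = 1000L, min_coverage = 0.20,
                             circular = TRUE, origin_window = 30000L,
                             min_spacer = 100L, primers = TRUE,
                             constraints = primer_constraints(),
                             protein_scan = FALSE,
                             min_region_length = 1000L,
                             min_protein_score = 50) {
  stopifnot(min_identity > 0, min_identity <= 1,
            min_coverage >= 0, min_coverage <= 1)
  list(k = as.integer(k), max_occurrences = as.integer(max_occurrences),
       min_hit_len = as.integer(min_hit_len), min_identity = min_identity,
       max_gap = as.integer(max_gap),
       max_diag_drift = as.integer(max_diag_drift),
       min_contig_length = as.integer(min_contig_length),
       min_coverage = min_coverage, circular = isTRUE(circular),
       origin_window = as.integer(origin_window),
       min_spacer = as.integer(min_spacer), primers = isTRUE(primers),
       constraints = constraints, protein_scan = isTRUE(protein_scan),
       min_region_length = as.integer(min_region_length),
       min_protein_score = min_protein_score)
}

#' Run the full finishing pipeline in memory
#'
#' @param contigs Record data.frame of draft contigs.
#' @param references Record data.frame of reference replicons.
#' @param ptt Optional named list of PTT feature data.frames, one per
#'   replicon id (required when `options$protein_scan`).
#' @param options From [pipeline_options()].
#' @return A list: `hits`, `profiles`, `replicons` (per replicon id:
#'   `pseudocontig`, `pairs`, `regions`, `protein_hits`, `crunch`),
#'   `summary` (per-replicon counts data.frame).
#' @export
finish_genome <- function(contigs, references, ptt = NULL,
                          options = pipeline_options()) {
  if (options$protein_scan && is.null(ptt))
    stopf("protein scan requested but no PTT tables given; omit the stage or supply them")
  if (any(duplicated(contigs$id))) stopf("duplicate contig ids in input")
  if (any(duplicated(references$id))) stopf("duplicate replicon ids in input")
  indexes <- lapply(seq_len(nrow(references)), function(r)
    build_index(references[r, , drop = FALSE], k = options$k,
                max_occurrences = options$max_occurrences))
  names(indexes) <- references$id
  hits <- list()
  for (index in indexes) {
    for (i in seq_len(nrow(contigs))) {
      h <- align_contig(contigs[i, , drop = FALSE], index,
                        min_hit_len = options$min_hit_len,
                        min_identity = options$min_identity,
                        max_gap = options$max_gap,
                        max_diag_drift = options$max_diag_drift)
      if (nrow(h)) hits[[length(hits) + 1L]] <- h
    }
  }
  hits <- if (length(hits)) do.call(rbind, hits) else empty_hits()
  profiles <- profile_contigs(contigs, hits,
                              min_contig_length = options$min_contig_length,
                              min_coverage = options$min_coverage)
  excluded <- contigs[contigs$id %in%
                        profiles$contig_id[profiles$status != "mapped"], ,
                      drop = FALSE]
  replicons <- list()
  for (r in seq_len(nrow(references))) {
    rid <- references$id[r]
    assigned_ids <- profiles$contig_id[profiles$status == "mapped" &
                                         profiles$best_replicon == rid]
    rhits <- hits[hits$replicon_id == rid, , drop = FALSE]
    ahits <- rhits[rhits$contig_id %in% assigned_ids, , drop = FALSE]
    pc <- scaffold_replicon(contigs[contigs$id %in% assigned_ids, ,
                                    drop = FALSE],
                            ahits, references[r, , drop = FALSE],
                            circular = options$circular,
                            origin_window = options$origin_window,
                            min_hit_len = options$min_hit_len,
                            min_spacer = options$min_spacer)
    pairs <- NULL
    if (!is.null(pc) && options$primers)
      pairs <- design_gap_primers(pc, contigs, options$constraints)
    # regions with no homolog among the PLACED contigs (hits of excluded
    # contigs must not mask a region, or the rescan could never fire)
    regions <- unaligned_reference_regions(ahits, nchar(references$sequence[r]),
                                           options$min_region_length)
    protein_hits <- NULL
    if (options$protein_scan) {
      feats <- ptt[[rid]]
      if (is.null(feats))
        stopf("protein scan requested but no PTT table for replicon '%s'", rid)
      feats <- translate_features(feats, references[r, , drop = FALSE])
      sel <- select_unmapped_proteins(feats, regions)
      protein_hits <- scan_excluded_contigs(sel, excluded,
                                            options$min_protein_score)
    }
    crunch <- if (is.null(pc)) NULL
      else pseudocontig_crunch(pc, ahits, indexes[[rid]], options)
    replicons[[rid]] <- list(pseudocontig = pc, pairs = pairs,
                             regions = regions, protein_hits = protein_hits,
                             crunch = crunch)
  }
  summary <- pipeline_summary(profiles, replicons, options)
  list(hits = hits, profiles = profiles, replicons = replicons,
       summary = summary)
}

# Crunch rows for one pseudocontig: every alignment hit of a placed contig,
# with query coordinates projected into the pseudocontig. Origin-split parts
# are realigned (their coordinates changed when the contig was cut).
pseudocontig_crunch <- function(pc, hits, index, options) {
  rows <- list()
  for (i in seq_len(nrow(pc$placements))) {
    p <- pc$placements[i, , drop = FALSE]
    lp <- p$pseudo_end - p$pseudo_start
    if (p$split_part == "none") {
      h <- hits[hits$contig_id == p$contig_id, , drop = FALSE]
      if (!nrow(h)) next
      if (p$orientation == "-") {
        qs <- p$pseudo_start + (lp - h$qend)
        qe <- p$pseudo_start + (lp - h$qstart)
        strand <- ifelse(h$strand == "+", "-", "+")
      } else {
        qs <- p$pseudo_start + h$qstart
        qe <- p$pseudo_start + h$qend
        strand <- h$strand
      }
    } else {
      part <- seq_record(p$contig_id, p$sequence)
      h <- align_contig(part, index, min_hit_len = options$min_hit_len,
                        min_identity = options$min_identity,
                        max_gap = options$max_gap,
                        max_diag_drift = options$max_diag_drift)
      if (!nrow(h)) next
      qs <- p$pseudo_start + h$qstart
      qe <- p$pseudo_start + h$qend
      strand <- h$strand
    }
    rows[[length(rows) + 1L]] <-
      as_crunch(h$score, 100 * h$identity, qs, qe, "PseudoContig",
                h$sstart, h$send, pc$replicon_id, strand)
  }
  if (!length(rows)) return(NULL)
  res <- do.call(rbind, rows)
  res[order(res$qstart), , drop = FALSE]
}

#' Adjacency of consecutive placements on the reference
#'
#' Two placed contigs are considered near each other when they are
#' consecutive in the pseudocontig and their projected reference gap is at
#' most `max_gap_bp` (default: the maximum PCR product size, since a larger
#' gap cannot be closed by one reaction anyway).
#'
#' @param pseudocontig A pseudocontig list.
#' @param max_gap_bp Maximum projected gap (bp).
#' @return Data.frame with `left_id`, `right_id`.
#' @export
placement_adjacency <- function(pseudocontig, max_gap_bp = 4000L) {
  g <- pseudocontig$gaps
  ord <- pseudocontig$placements[order(pseudocontig$placements$order_index), ]
  keep <- g$gap_bp <= max_gap_bp
  data.frame(left_id = ord$contig_id[g$after_order_index[keep] + 1L],
             right_id = ord$contig_id[g$after_order_index[keep] + 2L],
             stringsAsFactors = FALSE)
}

pipeline_summary <- function(profiles, replicons, options) {
  rows <- lapply(names(replicons), function(rid) {
    rr <- replicons[[rid]]
    n_mapped <- sum(profiles$status == "mapped" &
                      profiles$best_replicon == rid, na.rm = TRUE)
    n_gaps <- if (is.null(rr$pseudocontig)) 0L else nrow(rr$pseudocontig$gaps)
    n_pairs <- if (is.null(rr$pairs)) 0L else sum(rr$pairs$status == "designed")
    n_closed <- if (is.null(rr$pairs) || is.null(rr$pseudocontig)) 0L
      else count_putatively_closed(
        rr$pseudocontig$placements, rr$pairs,
        placement_adjacency(rr$pseudocontig,
                            options$constraints$max_product))
    data.frame(replicon_id = rid, mapped_contigs = n_mapped, gaps = n_gaps,
               primer_pairs = n_pairs, putatively_closed = n_closed,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  attr(res, "excluded") <- table(profiles$status[profiles$status != "mapped"])
  res
}

sanitize_id <- function(x) gsub("[^A-Za-z0-9._-]", "_", x)

#' Run the pipeline on files and write the ACT output tree
#'
#' @param contigs_path Multi-FASTA of draft contigs.
#' @param reference_paths Character vector of reference FASTA files (their
#'   records are pooled; multipartite references may come as one multi-FASTA
#'   or one file per replicon).
#' @param outdir Output directory (created; one subdirectory per replicon).
#' @param ptt_paths Optional PTT files, parallel to the replicons in input
#'   order (enables the protein scan when `options$protein_scan`).
#' @param options From [pipeline_options()].
#' @param quiet Suppress progress messages.
#' @return The [finish_genome()] result, invisibly.
#' @export
run_pipeline <- function(contigs_path, reference_paths, outdir,
                         ptt_paths = NULL, options = pipeline_options(),
                         quiet = FALSE) {
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  contigs <- read_fasta(contigs_path)
  if (!nrow(contigs)) stopf("no contigs in %s", contigs_path)
  references <- do.call(rbind, lapply(reference_paths, read_fasta))
  if (!nrow(references)) stopf("no reference replicons given")
  ptt <- NULL
  if (!is.null(ptt_paths)) {
    if (length(ptt_paths) != nrow(references))
      stopf("need one PTT file per reference replicon (%d given, %d replicons)",
            length(ptt_paths), nrow(references))
    ptt <- lapply(seq_along(ptt_paths), function(i)
      read_ptt(ptt_paths[i], ref_id = references$id[i]))
    names(ptt) <- references$id
  }
  say("aligning %d contigs against %d replicon(s)", nrow(contigs),
      nrow(references))
  res <- finish_genome(contigs, references, ptt = ptt, options = options)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_outputs(res, contigs, references, outdir, options)
  log_lines <- c(sprintf("refscaf run: %d contigs, %d replicon(s)",
                         nrow(contigs), nrow(references)),
                 utils::capture.output(print(res$summary, row.names = FALSE)))
  writeLines(log_lines, file.path(outdir, "run.log"))
  say("%s", paste(log_lines, collapse = "\n"))
  invisible(res)
}

write_outputs <- function(res, contigs, references, outdir, options) {
  profiles <- res$profiles
  unmapped <- profiles[profiles$status != "mapped", , drop = FALSE]
  writeLines(sprintf("%s\t%s\t%.3f", unmapped$contig_id, unmapped$status,
                     unmapped$best_coverage),
             file.path(outdir, "UnMappedContigs.txt"))
  utils::write.table(res$summary, file.path(outdir, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(utils::capture.output(print(res$summary, row.names = FALSE)),
             file.path(outdir, "summary.txt"))
  for (rid in names(res$replicons)) {
    rr <- res$replicons[[rid]]
    if (is.null(rr$pseudocontig)) next      # nothing mapped to this replicon
    rdir <- file.path(outdir, sanitize_id(rid))
    dir.create(rdir, showWarnings = FALSE)
    ref <- references[references$id == rid, , drop = FALSE]
    write_fasta(ref, file.path(rdir, "Reference.fsa"))
    pc <- rr$pseudocontig
    write_fasta(seq_record("PseudoContig",
                           pc$sequence,
                           sprintf("pseudocontig of %s", rid)),
                file.path(rdir, "PseudoContig.fsa"))
    if (!is.null(rr$crunch))
      write_crunch(rr$crunch, file.path(rdir, "PseudoContig.crunch"))
    # contig placements on the pseudocontig
    feats <- list()
    for (i in seq_len(nrow(pc$placements))) {
      p <- pc$placements[i, ]
      lab <- p$contig_id
      if (p$split_part != "none") lab <- paste0(lab, "_", p$split_part)
      col <- if (p$split_part == "none") TAB_COLOURS[["contig"]]
             else TAB_COLOURS[["split"]]
      feats <- c(feats, tab_feature("misc_feature", p$pseudo_start,
                                    p$pseudo_end, p$orientation,
                                    c(label = lab, colour = col)))
    }
    write_tab(feats, file.path(rdir, "PseudoContig.tab"))
    # alignment hits on the reference
    rhits <- res$hits[res$hits$replicon_id == rid, , drop = FALSE]
    feats <- list()
    for (i in seq_len(nrow(rhits))) {
      h <- rhits[i, ]
      feats <- c(feats, tab_feature(
        "misc_feature", h$sstart, h$send, h$strand,
        c(label = h$contig_id, colour = TAB_COLOURS[["refhit"]],
          note = sprintf("score %d, identity %.1f%%", h$score,
                         100 * h$identity))))
    }
    write_tab(feats, file.path(rdir, "ReferenceHits.tab"))
    if (!is.null(rr$pairs)) {
      designed <- rr$pairs[rr$pairs$status == "designed", , drop = FALSE]
      feats <- list()
      for (i in seq_len(nrow(designed))) {
        q <- designed[i, ]
        feats <- c(feats, tab_feature(
          "misc_feature", q$left_start, q$right_start + 1L, "+",
          c(label = q$gap_id, colour = TAB_COLOURS[["pcr"]],
            note = sprintf("%s,%s", q$left_seq, q$right_seq),
            note2 = sprintf("Tm %.2f/%.2f, product %d bp", q$tm_left,
                            q$tm_right, q$product_size))))
      }
      write_tab(feats, file.path(rdir, "PCRProducts.tab"))
      utils::write.table(rr$pairs, file.path(rdir, "PrimerPairs.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(rr$protein_hits)) {
      ph <- rr$protein_hits
      feats <- list()
      for (i in seq_len(nrow(ph))) {
        feats <- c(feats, tab_feature(
          "misc_feature", ph$ref_start[i] - 1L, ph$ref_end[i], "+",
          c(label = ph$pid[i], colour = TAB_COLOURS[["protein"]],
            note = sprintf("matches excluded contig %s (frame %+d, score %.0f)",
                           ph$contig_id[i], ph$frame[i], ph$score[i]))))
      }
      write_tab(feats, file.path(rdir, "ReferenceProteinHits.tab"))
    }
  }
  invisible(NULL)
}

#' Command-line entry point
#'
#' Parses `--contigs`, `--reference` (repeatable), `--ptt` (repeatable),
#' `--outdir` and threshold flags, then calls [run_pipeline()]. Installed as
#' `inst/scripts/refscaf` (run with `Rscript`).
#'
#' @param args Character vector of CLI arguments (default: the command
#'   line).
#' @return Exit status, invisibly (0 on success).
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: refscaf --contigs FASTA --reference FASTA [--reference FASTA ...]",
    "  --outdir DIR [--ptt PTT ...] [--min-contig-length N] [--min-coverage F]",
    "  [--min-hit-length N] [--min-identity F] [--kmer N] [--linear]",
    "  [--no-primers] [--protein-scan] [--window N] [--tm-range LO,HI]",
    "  [--gc-range LO,HI] [--product-max N] [--min-spacer N] [--quiet]",
    sep = "\n")
  vals <- list(reference = character(), ptt = character())
  flags <- list()
  i <- 1L
  take <- function() { i <<- i + 1L; if (i > length(args)) stop(usage, call. = FALSE); args[[i]] }
  while (i <= length(args)) {
    a <- args[[i]]
    switch(a,
      "--contigs" = { vals$contigs <- take() },
      "--reference" = { vals$reference <- c(vals$reference, take()) },
      "--ptt" = { vals$ptt <- c(vals$ptt, take()) },
      "--outdir" = { vals$outdir <- take() },
      "--min-contig-length" = { flags$min_contig_length <- as.integer(take()) },
      "--min-coverage" = { flags$min_coverage <- as.numeric(take()) },
      "--min-hit-length" = { flags$min_hit_len <- as.integer(take()) },
      "--min-identity" = { flags$min_identity <- as.numeric(take()) },
      "--kmer" = { flags$k <- as.integer(take()) },
      "--linear" = { flags$circular <- FALSE },
      "--no-primers" = { flags$primers <- FALSE },
      "--protein-scan" = { flags$protein_scan <- TRUE },
      "--window" = { flags$window <- as.integer(take()) },
      "--tm-range" = { flags$tm_range <- as.numeric(strsplit(take(), ",")[[1L]]) },
      "--gc-range" = { flags$gc_range <- as.numeric(strsplit(take(), ",")[[1L]]) },
      "--product-max" = { flags$max_product <- as.integer(take()) },
      "--min-spacer" = { flags$min_spacer <- as.integer(take()) },
      "--quiet" = { vals$quiet <- TRUE },
      "--help" = { message(usage); return(invisible(0L)) },
      stop(sprintf("unknown argument '%s'\n%s", a, usage), call. = FALSE))
    i <- i + 1L
  }
  if (is.null(vals$contigs) || !length(vals$reference) || is.null(vals$outdir))
    stop(usage, call. = FALSE)
  cons_args <- list()
  if (!is.null(flags$window)) cons_args$window <- flags$window
  if (!is.null(flags$max_product)) cons_args$max_product <- flags$max_product
  if (!is.null(flags$tm_range)) {
    cons_args$tm_min <- flags$tm_range[1L]; cons_args$tm_max <- flags$tm_range[2L]
  }
  if (!is.null(flags$gc_range)) {
    cons_args$gc_min <- flags$gc_range[1L]; cons_args$gc_max <- flags$gc_range[2L]
  }
  opt_args <- flags[setdiff(names(flags),
                            c("window", "max_product", "tm_range", "gc_range"))]
  opt_args$constraints <- do.call(primer_constraints, cons_args)
  options <- do.call(pipeline_options, opt_args)
  run_pipeline(vals$contigs, vals$reference, vals$outdir,
               ptt_paths = if (length(vals$ptt)) vals$ptt else NULL,
               options = options, quiet = isTRUE(vals$quiet))
  invisible(0L)
}
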
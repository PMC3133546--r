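sc_hits <- function(qstart, qend, sstart, send, strand = "+",
                    matched = qend - qstart, score = matched) {
  data.frame(contig_id = "c", replicon_id = "r",
             qstart = as.integer(qstart), qend = as.integer(qend),
             sstart = as.integer(sstart), send = as.integer(send),
             strand = strand, matched = as.integer(matched),
             span = as.integer(qend - qstart), identity = 1,
             score = as.integer(score), stringsAsFactors = FALSE)
}

test_that("determine_orientation follows the matched-bp majority", {
  expect_equal(determine_orientation(sc_hits(0, 100, 0, 100, "+")), "+")
  h <- rbind(sc_hits(0, 300, 0, 300, "+"),
             sc_hits(400, 1000, 400, 1000, "-"))
  expect_equal(determine_orientation(h), "-")
  tie <- rbind(sc_hits(0, 500, 0, 500, "+"), sc_hits(0, 500, 0, 500, "-"))
  expect_equal(determine_orientation(tie), "+")
  expect_error(determine_orientation(sc_hits(integer(), integer(),
                                             integer(), integer())))
})

test_that("anchor_position projects the contig's left edge", {
  expect_equal(anchor_position(sc_hits(0, 500, 1000, 1500), "+", 800, 50000),
               1000L)
  expect_equal(anchor_position(sc_hits(200, 700, 1000, 1500), "+", 800, 50000),
               800L)
  # clamped at zero
  expect_equal(anchor_position(sc_hits(200, 700, 50, 550), "+", 800, 50000), 0L)
})

test_that("anchors recover the true cut position despite fragmentation", {
  ref <- record("r", small_genome$sequence[1])
  idx <- build_index(ref)
  ctg <- record("c", substr(ref$sequence, 5001, 8000))
  h <- align_contig(ctg, idx)
  o <- determine_orientation(h)
  expect_equal(anchor_position(h, o, 3000, nchar(ref$sequence)), 5000L)
  # and for the reverse complement
  ctg_rc <- record("c", reverse_complement(ctg$sequence))
  h2 <- align_contig(ctg_rc, idx)
  o2 <- determine_orientation(h2)
  expect_equal(o2, "-")
  expect_equal(anchor_position(h2, o2, 3000, nchar(ref$sequence)), 5000L)
})

test_that("detect_origin_spanning requires disjoint hits in both end zones", {
  h <- rbind(sc_hits(0, 100, 4900, 5000), sc_hits(100, 200, 0, 100))
  expect_true(detect_origin_spanning(h, 5000L))
  internal <- sc_hits(0, 1000, 2000, 3000)
  expect_false(detect_origin_spanning(internal, 5000L))
  expect_false(detect_origin_spanning(h, 5000L, circular = FALSE))
})

test_that("origin-split parts reunite to the original contig", {
  for (seed in c(3, 4, 5)) {
    fr <- fragment_genome(small_genome[1, ], 6, origin_spanner = TRUE,
                          inversion_prob = 0.5, mutation_rate = 0,
                          seed = seed)
    truth <- fr$truth$contigs
    sp_id <- truth$contig_id[truth$origin_spanning]
    ref <- small_genome[1, ]
    idx <- build_index(ref)
    ctg <- fr$contigs[fr$contigs$id == sp_id, ]
    h <- align_contig(ctg, idx)
    expect_true(detect_origin_spanning(h, nchar(ref$sequence)))
    sp <- split_origin_contig(ctg, h, nchar(ref$sequence))
    expect_false(is.null(sp))
    reunited <- paste0(sp$tail$sequence, sp$head$sequence)
    if (sp$orientation == "-") reunited <- reverse_complement(reunited)
    expect_equal(reunited, ctg$sequence, info = paste("seed", seed))
    expect_lt(sp$head$anchor, 3000)
  }
})

test_that("order_contigs sorts by anchor with pinned split parts", {
  pl <- data.frame(contig_id = c("a", "b", "c"),
                   anchor = c(5000L, 100L, 2000L), split_part = "none",
                   stringsAsFactors = FALSE)
  expect_equal(order_contigs(pl)$contig_id, c("b", "c", "a"))

  tie <- data.frame(contig_id = c("z", "a"), anchor = c(10L, 10L),
                    split_part = "none", stringsAsFactors = FALSE)
  expect_equal(order_contigs(tie)$contig_id, c("a", "z"))

  pinned <- data.frame(contig_id = c("mid", "sp", "sp", "early"),
                       anchor = c(500L, 9000L, 2L, 100L),
                       split_part = c("none", "tail", "head", "none"),
                       stringsAsFactors = FALSE)
  out <- order_contigs(pinned)
  expect_equal(out$split_part, c("head", "none", "none", "tail"))
  expect_equal(out$order_index, 0:3)
})

test_that("estimate_gap returns the projected distance, floored N count", {
  prev <- data.frame(anchor = 0L, length = 1000L)
  nxt <- data.frame(anchor = 1500L)
  expect_equal(estimate_gap(prev, nxt), list(gap_bp = 500L, n_count = 500L))
  over <- data.frame(anchor = 800L)
  expect_equal(estimate_gap(prev, over), list(gap_bp = -200L, n_count = 100L))
})

test_that("build_pseudocontig concatenates with N runs and fills coords", {
  pl <- data.frame(contig_id = c("a", "b"), replicon_id = "r",
                   orientation = c("+", "-"), anchor = c(0L, 150L),
                   length = c(100L, 150L), split_part = "none",
                   sequence = c(random_dna(100, 1), random_dna(150, 2)),
                   order_index = 0:1, stringsAsFactors = FALSE)
  gaps <- data.frame(after_order_index = 0L, gap_bp = 50L, n_count = 50L)
  pc <- build_pseudocontig(pl, gaps, "r")
  expect_equal(nchar(pc$sequence), 300L)
  expect_equal(pc$placements$pseudo_start, c(0L, 150L))
  expect_equal(pc$placements$pseudo_end, c(100L, 300L))
  expect_equal(substr(pc$sequence, 101, 150), strrep("N", 50))
  expect_equal(substr(pc$sequence, 151, 300),
               reverse_complement(pl$sequence[2]))
  # placement intervals contain no N
  for (i in 1:2)
    expect_false(grepl("N", substr(pc$sequence,
                                   pc$placements$pseudo_start[i] + 1,
                                   pc$placements$pseudo_end[i])))
  single <- build_pseudocontig(pl[1, ], gaps[0, ], "r")
  expect_equal(single$sequence, pl$sequence[1])
})

test_that("clean fragmentation is reconstructed exactly", {
  hits <- align_contigs(small_clean$contigs, small_genome)
  prof <- profile_contigs(small_clean$contigs, hits)
  truth <- small_clean$truth$contigs
  for (r in seq_len(nrow(small_genome))) {
    rid <- small_genome$id[r]
    ids <- prof$contig_id[prof$status == "mapped" & prof$best_replicon == rid]
    pc <- scaffold_replicon(
      small_clean$contigs[small_clean$contigs$id %in% ids, ],
      hits[hits$replicon_id == rid & hits$contig_id %in% ids, ],
      small_genome[r, ])
    # length conservation
    expect_equal(nchar(pc$sequence),
                 sum(pc$placements$length) + sum(pc$gaps$n_count))
    # every placed span equals its true reference interval
    t2 <- truth[match(pc$placements$contig_id, truth$contig_id), ]
    expect_equal(pc$placements$anchor, t2$start)
    for (i in seq_len(nrow(pc$placements))) {
      p <- pc$placements[i, ]
      expect_equal(substr(pc$sequence, p$pseudo_start + 1, p$pseudo_end),
                   substr(small_genome$sequence[r], t2$start[i] + 1,
                          t2$end[i]))
    }
  }
})
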
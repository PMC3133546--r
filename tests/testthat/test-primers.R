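test_that("gc_fraction and melting_temperature follow their definitions", {
  expect_equal(gc_fraction("GGCC"), 1.0)
  expect_equal(gc_fraction("ATAT"), 0.0)
  expect_equal(gc_fraction("ACGT"), 0.5)
  expect_error(gc_fraction(""), "empty")

  # 20-mer with 10 G/C: 64.9 + 41 * (10 - 16.4) / 20
  s10 <- paste0(strrep("AT", 5), strrep("GC", 5))
  expect_equal(melting_temperature(s10), 51.78)
  # adding one G to a 20-mer raises Tm by 41/20
  s11 <- paste0(strrep("AT", 5), strrep("GC", 5), "G")
  s20_11 <- paste0("G", substr(s10, 2, 20))
  expect_equal(melting_temperature(s20_11) - melting_temperature(s10),
               round(41 / 20, 2), tolerance = 0.011)
  # Tm depends only on (length, GC count)
  expect_equal(melting_temperature("ACGTACGTACGTACGTACGT"),
               melting_temperature("GTCAGTCAGTCAGTCAGTCA"))
  expect_error(melting_temperature("ACGTACGTA"), "outside")
})

test_that("passes_filters enforces each constraint", {
  cons <- primer_constraints()
  expect_false(passes_filters("ACGTACGTACGTACGTACGT", cons))  # Tm 51.78 < 57
  expect_false(passes_filters(paste0("AAAAA", strrep("GC", 8)), cons))
  expect_false(passes_filters(paste0("ACGTN", strrep("GC", 8)), cons))
  expect_true(passes_filters("AGCTGGACTACGGACTACGGAC", cons))
})

test_that("accepted 18-mers of a window equal an independent re-check", {
  cons <- primer_constraints()
  win <- random_dna(60, 71)
  for (st in 0:(60 - 18)) {
    cand <- substr(win, st + 1, st + 18)
    ngc <- nchar(gsub("[AT]", "", cand))
    tm <- round(64.9 + 41 * (ngc - 16.4) / 18, 2)
    max_run <- max(rle(strsplit(cand, "")[[1]])$lengths)
    rc4 <- reverse_complement(substr(cand, 15, 18))
    indep <- tm >= cons$tm_min && tm <= cons$tm_max &&
      ngc / 18 >= cons$gc_min && ngc / 18 <= cons$gc_max &&
      max_run <= cons$max_homopolymer &&
      !grepl(rc4, cand, fixed = TRUE)
    expect_equal(passes_filters(cand, cons), indep, info = cand)
  }
})

test_that("occurrence_count counts both strands, overlapping, everywhere", {
  ctgs <- rbind(record("a", paste0(random_dna(200, 81), "ACGGATCCATTTGA",
                                   random_dna(200, 82))),
                record("b", random_dna(300, 83)))
  expect_equal(occurrence_count("ACGGATCCATTTGA", ctgs), 1L)
  # plant the reverse complement on the other contig
  ctgs$sequence[2] <- paste0(ctgs$sequence[2],
                             reverse_complement("ACGGATCCATTTGA"))
  expect_equal(occurrence_count("ACGGATCCATTTGA", ctgs), 2L)
  # overlapping occurrences: AAAA in AAAAAA occurs 3 times (+ revcomp TTTT 0)
  expect_equal(occurrence_count("AAAA", record("c", "AAAAAA")), 3L)
  # random primers match the naive sliding-window oracle
  set.seed(84)
  for (i in 1:10) {
    p <- random_dna(sample(18:25, 1), 840 + i)
    expect_equal(occurrence_count(p, ctgs), oracle_occurrences(p, ctgs))
  }
  sub <- substr(ctgs$sequence[1], 150, 172)
  expect_equal(occurrence_count(sub, ctgs), oracle_occurrences(sub, ctgs))
})

test_that("design_gap_primers emits one verified pair per closable gap", {
  set.seed(7)
  ctgs <- rbind(record("u", random_dna(2000, 701)),
                record("d", random_dna(2000, 702)))
  pl <- data.frame(contig_id = c("u", "d"), replicon_id = "r",
                   orientation = "+", anchor = c(0L, 2300L),
                   length = 2000L, split_part = "none",
                   sequence = ctgs$sequence, order_index = 0:1,
                   stringsAsFactors = FALSE)
  gaps <- data.frame(after_order_index = 0L, gap_bp = 300L, n_count = 300L)
  pc <- build_pseudocontig(pl, gaps, "r")
  pairs <- design_gap_primers(pc, ctgs)
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$status, "designed")
  expect_lte(pairs$product_size, 300 + 2 * 500)
  expect_equal(pairs$product_size, pairs$right_start - pairs$left_start + 1L)
  expect_lte(abs(pairs$tm_left - pairs$tm_right), 5)
  expect_true(passes_filters(pairs$left_seq))
  expect_true(passes_filters(pairs$right_seq))
  expect_equal(occurrence_count(pairs$left_seq, ctgs), 1L)
  expect_equal(occurrence_count(pairs$right_seq, ctgs), 1L)
  # left primer lies on the pseudocontig forward strand
  expect_equal(substr(pc$sequence, pairs$left_start + 1,
                      pairs$left_start + nchar(pairs$left_seq)),
               pairs$left_seq)
  # right primer is the reverse complement of its forward-strand site
  expect_equal(reverse_complement(
    substr(pc$sequence, pairs$right_start - nchar(pairs$right_seq) + 2,
           pairs$right_start + 1)), pairs$right_seq)

  # determinism
  expect_identical(pairs, design_gap_primers(pc, ctgs))

  # zero gaps -> zero rows
  single <- build_pseudocontig(pl[1, ], gaps[0, ], "r")
  expect_equal(nrow(design_gap_primers(single, ctgs)), 0L)
})

test_that("a duplicated flank defeats uniqueness and the gap stays open", {
  set.seed(8)
  ctgs <- rbind(record("u", random_dna(2000, 801)),
                record("d", random_dna(2000, 802)))
  # a third contig carrying an exact copy of the upstream flank window
  dup <- record("dup", paste0(random_dna(300, 803),
                              substr(ctgs$sequence[1], 1401, 2000),
                              random_dna(300, 804)))
  all_ctgs <- rbind(ctgs, dup)
  pl <- data.frame(contig_id = c("u", "d"), replicon_id = "r",
                   orientation = "+", anchor = c(0L, 2300L), length = 2000L,
                   split_part = "none", sequence = ctgs$sequence,
                   order_index = 0:1, stringsAsFactors = FALSE)
  gaps <- data.frame(after_order_index = 0L, gap_bp = 300L, n_count = 300L)
  pc <- build_pseudocontig(pl, gaps, "r")
  pairs <- design_gap_primers(pc, all_ctgs)
  expect_equal(pairs$status, "unpaired")
})

test_that("count_putatively_closed intersects design with adjacency", {
  pl <- data.frame(contig_id = c("a", "b", "c"), order_index = 0:2,
                   stringsAsFactors = FALSE)
  pairs <- data.frame(gap_id = c("g1", "g2"),
                      status = c("designed", "designed"),
                      stringsAsFactors = FALSE)
  adj <- data.frame(left_id = "a", right_id = "b", stringsAsFactors = FALSE)
  expect_equal(count_putatively_closed(pl, pairs, adj), 1L)
  pairs$status[1] <- "unpaired"
  expect_equal(count_putatively_closed(pl, pairs, adj), 0L)
  adj2 <- data.frame(left_id = c("a", "c"), right_id = c("b", "b"),
                     stringsAsFactors = FALSE)
  pairs$status <- "designed"
  expect_equal(count_putatively_closed(pl, pairs, adj2), 2L)
})
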
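blosum <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  m <- e$BLOSUM62
  m["*", ] <- -4L
  m[, "*"] <- -4L
  m
})

genetic_code_11_for_test <- function(codon)
  Biostrings::getGeneticCode("11")[codon]

test_that("six_frame_translate uses the bacterial code and frame offsets", {
  ctg <- record("c", "ATGGCC")
  fr <- six_frame_translate(ctg)
  expect_equal(fr[["+1"]]$aa, "MA")
  expect_equal(fr[["+2"]]$aa, "W")       # TGG; dangling CC dropped
  expect_equal(fr[["+3"]]$aa, "G")       # GGC
  # frames -1..-3 equal frames +1..+3 of the reverse complement
  rc <- record("c_rc", reverse_complement(random_dna(101, 91)))
  fwd <- record("c_f", reverse_complement(rc$sequence))
  f1 <- six_frame_translate(fwd)
  f2 <- six_frame_translate(record("x", reverse_complement(fwd$sequence)))
  for (k in 1:3)
    expect_equal(f1[[paste0("-", k)]]$aa, f2[[paste0("+", k)]]$aa)
})

test_that("frame_nt_interval inverts the translation coordinate map", {
  seq <- random_dna(60, 92)
  ctg <- record("c", seq)
  fr <- six_frame_translate(ctg)
  for (f in c(1, 2, 3, -1, -2, -3)) {
    tr <- fr[[sprintf("%+d", f)]]
    aa_n <- nchar(tr$aa)
    i <- 2L  # third residue
    nt <- frame_nt_interval(f, i, i + 1L, 60L)
    piece <- substr(seq, nt[1] + 1, nt[2])
    if (f < 0) piece <- reverse_complement(piece)
    expect_equal(unname(genetic_code_11_for_test(piece)),
                 substr(tr$aa, i + 1, i + 1), info = paste("frame", f))
  }
})

test_that("select_unmapped_proteins keeps only wholly contained features", {
  feats <- data.frame(ref_id = "r", start = c(600L, 450L, 1200L),
                      end = c(900L, 700L, 1400L), strand = "+",
                      pid = c("p1", "p2", "p3"), gene = "", product = "",
                      stringsAsFactors = FALSE)
  regions <- data.frame(start = c(500L, 1100L), end = c(1000L, 1500L),
                        length = c(500L, 400L))
  sel <- select_unmapped_proteins(feats, regions)
  expect_equal(sel$pid, c("p1", "p3"))  # p2 straddles a boundary

  # random features/regions vs a brute-force containment test
  set.seed(93)
  fs <- sample(1:5000, 40)
  feats2 <- data.frame(ref_id = "r", start = fs, end = fs + sample(50:400, 40,
                       replace = TRUE), strand = "+",
                       pid = sprintf("q%02d", 1:40), gene = "", product = "",
                       stringsAsFactors = FALSE)
  rs <- seq(0, 5200, by = 650)
  regions2 <- data.frame(start = rs, end = rs + 300,
                         length = 300L)
  sel2 <- select_unmapped_proteins(feats2, regions2)
  brute <- vapply(seq_len(nrow(feats2)), function(i) {
    any(vapply(seq_len(nrow(regions2)), function(j)
      feats2$start[i] - 1 >= regions2$start[j] &&
        feats2$end[i] <= regions2$end[j], logical(1)))
  }, logical(1))
  expect_equal(sel2$pid, feats2$pid[brute])
})

test_that("local_align_protein scores match the matrix and brute force", {
  q <- "MKTAYIAKQR"
  self <- local_align_protein(q, q)
  diag_sum <- sum(blosum[cbind(strsplit(q, "")[[1]], strsplit(q, "")[[1]])])
  expect_equal(self$score, diag_sum)
  expect_equal(self$identity, 1.0)
  expect_equal(c(self$q_start, self$q_end), c(0L, 10L))

  # nothing positive against a foreign composition
  none <- local_align_protein("MKTAYIAKQR", strrep("P", 10))
  expect_equal(none$score, 0)

  # brute-force equivalence on short strings
  set.seed(94)
  aas <- rownames(blosum)[1:20]
  for (i in 1:5) {
    a <- paste(sample(aas, 8, replace = TRUE), collapse = "")
    b <- paste(sample(aas, 8, replace = TRUE), collapse = "")
    got <- local_align_protein(a, b)$score
    expect_equal(got, max(0, oracle_sw_score(a, b, blosum)),
                 info = paste(a, b))
  }
})

test_that("scan_excluded_contigs recovers planted genes in excluded contigs", {
  ref <- small_genome[1, ]
  feats <- random_protein_features(ref, n = 4, seed = 95)
  feats <- translate_features(feats, ref)
  # an excluded contig carrying an exact copy of the second CDS
  cds <- substr(ref$sequence, feats$start[2], feats$end[2])
  if (feats$strand[2] == "-") cds <- reverse_complement(cds)
  contig <- record("ex1", paste0(random_dna(400, 96), cds, random_dna(400, 97)))
  hits <- scan_excluded_contigs(feats, contig, min_score = 50)
  top <- hits[hits$pid == feats$pid[2], ][1, ]
  expect_equal(top$identity, 1.0)
  expect_equal(top$contig_id, "ex1")
  # frame consistency: translating the reported nt interval in the reported
  # frame reproduces the aligned residues
  piece <- substr(contig$sequence, top$nt_start + 1, top$nt_end)
  if (top$frame < 0) piece <- reverse_complement(piece)
  aa <- vapply(seq(1, nchar(piece) - 2, by = 3),
               function(s) unname(genetic_code_11_for_test(
                 substr(piece, s, s + 2))), character(1))
  expect_equal(paste(aa, collapse = ""),
               substr(feats$aa[2], top$aa_start + 1, top$aa_end))

  # no excluded contigs -> no hits
  expect_equal(nrow(scan_excluded_contigs(feats, contig[0, ])), 0L)
})

test_that("diverged planted genes are recovered with faithful identity", {
  ref <- small_genome[1, ]
  feats <- translate_features(random_protein_features(ref, n = 1, seed = 98),
                              ref)
  cds <- substr(ref$sequence, feats$start[1], feats$end[1])
  if (feats$strand[1] == "-") cds <- reverse_complement(cds)
  # substitute ~10% of codons by random codons (aa identity ~0.85-0.95)
  set.seed(99)
  codons <- substring(cds, seq(1, nchar(cds) - 2, 3), seq(3, nchar(cds), 3))
  swap <- which(runif(length(codons)) < 0.15)
  bases <- c("A", "C", "G", "T")
  codons[swap] <- vapply(swap, function(i)
    paste(sample(bases, 3, replace = TRUE), collapse = ""), character(1))
  mut_aa <- refscaf:::translate_dna(paste(codons, collapse = ""))
  truth_id <- mean(strsplit(mut_aa, "")[[1]] == strsplit(
    paste0(feats$aa[1], "*"), "")[[1]][seq_len(nchar(mut_aa))])
  contig <- record("ex2", paste0(random_dna(200, 991),
                                 paste(codons, collapse = ""),
                                 random_dna(200, 992)))
  hits <- scan_excluded_contigs(feats, contig, min_score = 50)
  expect_gte(nrow(hits), 1L)
  expect_lt(abs(hits$identity[1] - truth_id), 0.1)
})
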
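test_that("local alignment reproduces hand-computable scores and edge cases", {
  expect_equal(local_align("MFRW", "MFRW")$score, 5 + 6 + 5 + 11)
  expect_equal(local_align("MFRW", "")$score, 0)
  expect_equal(local_align("", "MFRW")$score, 0)
})

test_that("local alignment agrees with an exhaustive DP oracle and is symmetric", {
  set.seed(21)
  data("BLOSUM62", package = "Biostrings", envir = environment())
  for (i in 1:60) {
    q <- random_peptide(sample(2:8, 1))
    t <- random_peptide(sample(2:8, 1))
    s <- local_align(q, t)$score
    expect_equal(s, oracle_sw_score(q, t, BLOSUM62), info = paste(q, t))
    expect_equal(s, local_align(t, q)$score, info = paste(q, t))
  }
})

test_that("E-values follow the Karlin-Altschul form", {
  cfg <- search_config()
  expect_equal(evalue(100, 350, 10000, cfg),
               0.041 * 350 * 10000 * exp(-26.7), tolerance = 1e-12)
  expect_equal(evalue(80, 300, 20000, cfg), 2 * evalue(80, 300, 10000, cfg))
  expect_lt(evalue(90, 300, 10000, cfg), evalue(80, 300, 10000, cfg))
  expect_error(evalue(50, 0, 100, cfg), "positive")
})

test_that("a planted bait ORF is recovered with a covering hit on the right strand", {
  set.seed(31)
  bait <- random_peptide(300)
  cds <- paste(vapply(strsplit(bait, "")[[1]], function(a) {
    opts <- names(ORACLE_GC)[ORACLE_GC == a]
    opts[sample.int(length(opts), 1)]
  }, ""), collapse = "")
  bg1 <- paste(sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = "")
  bg2 <- paste(sample(c("A", "C", "G", "T"), 1500, TRUE), collapse = "")
  contig <- paste0(bg1, reverse_complement(cds), bg2)
  hits <- search_contig(c(b1 = bait), contig, "c1")
  expect_gte(nrow(hits), 1)
  top <- hits[which.min(hits$evalue), ]
  expect_identical(top$strand, "-")
  expect_lte(top$start, 2000 + 5)
  expect_gte(top$end, 2000 + nchar(cds) - 5)
  expect_lt(top$evalue, 1e-50)
})

test_that("random contigs yield no hits at the stringent cutoff", {
  set.seed(32)
  bait <- random_peptide(330)
  for (i in 1:5) {
    contig <- paste(sample(c("A", "C", "G", "T"), 10000, TRUE), collapse = "")
    hits <- search_contig(c(b = bait), contig, "r")
    expect_identical(nrow(hits), 0L)
  }
})

test_that("hit merging respects distance, strand and contig boundaries", {
  h <- function(contig, strand, start, end) data.frame(
    contig_id = contig, bait_id = "b", role = "positive", frame = 1L,
    strand = strand, start = start, end = end, qstart = 1L, qend = 50L,
    bait_len = 100L, score = 500, bitscore = 190, evalue = 1e-60,
    stringsAsFactors = FALSE)
  # two same-strand hits 100 nt apart -> one locus
  loci <- merge_hits(rbind(h("c", "+", 1000, 1300), h("c", "+", 1400, 1700)))
  expect_length(loci, 1)
  expect_equal(c(loci[[1]]$start, loci[[1]]$end), c(1000, 1700))
  # opposite strands at the same position -> two loci
  loci <- merge_hits(rbind(h("c", "+", 1000, 1300), h("c", "-", 1000, 1300)))
  expect_length(loci, 2)
  # 5000 nt apart with merge_gap 2000 -> two loci
  loci <- merge_hits(rbind(h("c", "+", 1000, 1300), h("c", "+", 6300, 6600)))
  expect_length(loci, 2)
  # different contigs never merge
  loci <- merge_hits(rbind(h("c1", "+", 1000, 1300), h("c2", "+", 1000, 1300)))
  expect_length(loci, 2)
})

test_that("the bait filter applies both criteria and records rejection reasons", {
  mk <- function(pos_e, neg_e) list(
    contig_id = "c", strand = "+", start = 0, end = 100,
    best_positive = data.frame(bait_id = "b", evalue = pos_e),
    best_positive_evalue = pos_e, best_negative_evalue = neg_e)
  out <- bait_filter(list(mk(1e-60, NA), mk(1e-60, 1e-55), mk(1e-40, NA)))
  expect_length(out$retained, 1)
  expect_identical(out$rejected$reason,
                   c("negative_bait_match", "fails_positive_cutoff"))
  # negative hit above the cutoff does not reject
  out <- bait_filter(list(mk(1e-60, 1e-10)))
  expect_length(out$retained, 1)
})

test_that("locus construction is independent of hit-list order", {
  set.seed(33)
  h <- data.frame(
    contig_id = sample(c("c1", "c2"), 12, TRUE), bait_id = "b",
    role = "positive", frame = 1L,
    strand = sample(c("+", "-"), 12, TRUE),
    start = sample(seq(0, 20000, 500), 12), qstart = 1L, qend = 50L,
    bait_len = 100L, score = 500, bitscore = 190,
    evalue = 10^-runif(12, 51, 80), stringsAsFactors = FALSE)
  h$end <- h$start + 300L
  key <- function(loci) sort(vapply(loci, function(l)
    paste(l$contig_id, l$strand, l$start, l$end), ""))
  ref <- key(merge_hits(h))
  for (i in 1:10)
    expect_identical(key(merge_hits(h[sample(nrow(h)), ])), ref)
})
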
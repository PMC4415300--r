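test_that("translation follows the standard genetic code for all 64 codons", {
  bases <- c("A", "C", "G", "T")
  for (a in bases) for (b in bases) for (c in bases) {
    codon <- paste0(a, b, c)
    expect_identical(translate_cds(codon), unname(ORACLE_GC[[codon]]),
                     info = codon)
  }
  expect_identical(translate_cds("ATGTTTAGA"), "MFR")
  expect_identical(translate_cds("ATGTAA"), "M*")
  expect_identical(translate_cds("ATGNNT"), "MX")
  expect_error(translate_cds("ATGA"), "multiple of 3")
})

test_that("reverse complement is an involution and handles N and empty input", {
  expect_identical(reverse_complement("ATGC"), "GCAT")
  expect_identical(reverse_complement(""), "")
  expect_identical(reverse_complement("AANT"), "ANTT")
  expect_error(reverse_complement("AXU"), "invalid")
  set.seed(11)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T", "N"), sample(1:60, 1), TRUE),
               collapse = "")
    expect_identical(reverse_complement(reverse_complement(s)), s)
  }
})

test_that("six-frame translation has correct frame lengths and coordinate maps", {
  s <- "ATGGCCTAA"  # 9 nt
  fr <- six_frame_translate(s, "c")
  lens <- vapply(fr, function(f) nchar(f$protein), 0L)
  names(lens) <- vapply(fr, function(f) as.character(f$frame), "")
  expect_identical(unname(lens[c("1", "2", "3")]), c(3L, 2L, 2L))
  # residue 1 of frame +2 maps to interval (1, 4, +)
  f2 <- Filter(function(f) f$frame == 2L, fr)[[1]]
  gi <- frame_interval(f2, 1)
  expect_equal(c(gi$start, gi$end), c(1, 4))
  expect_identical(gi$strand, "+")
})

test_that("six-frame coordinate maps reconstruct the frame protein from the genome", {
  set.seed(5)
  s <- paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = "")
  for (fr in six_frame_translate(s, "c")) {
    n <- nchar(fr$protein)
    if (n == 0) next
    for (pos in unique(c(1L, sample(seq_len(n), 5), n))) {
      gi <- frame_interval(fr, pos)
      expect_equal(gi$end - gi$start, 3)
      codon <- substr(s, gi$start + 1, gi$end)
      if (gi$strand == "-") codon <- reverse_complement(codon)
      expect_identical(translate_cds(codon),
                       substr(fr$protein, pos, pos))
    }
  }
})

test_that("a contig and its reverse complement swap forward and reverse frames", {
  set.seed(6)
  s <- paste(sample(c("A", "C", "G", "T"), 61, TRUE), collapse = "")
  f1 <- six_frame_translate(s, "c")
  f2 <- six_frame_translate(reverse_complement(s), "c")
  fwd1 <- sort(vapply(Filter(function(f) f$strand == "+", f1),
                      `[[`, "", "protein"))
  rev2 <- sort(vapply(Filter(function(f) f$strand == "-", f2),
                      `[[`, "", "protein"))
  expect_identical(fwd1, rev2)
})

test_that("FASTA write/read round-trips ids and sequences byte-exactly", {
  seqs <- c(alpha = "ATGAAATTTCCC", beta = strrep("ACGT", 40), gamma = "TTA")
  path <- withr::local_tempfile(fileext = ".fa")
  write_fasta(seqs, path)
  back <- read_fasta(path, type = "DNA")
  expect_identical(back, seqs)
  # duplicate ids rejected
  writeLines(c(">x", "AAA", ">x", "CCC"), path)
  expect_error(read_fasta(path), "duplicate")
})

test_that("GFF3 output is 1-based, phase 0, and parseable by an independent reader", {
  skip_if_not_installed("rtracklayer")
  models <- list(
    list(name = "g1", contig_id = "c1", strand = "-", status = "complete_2exon",
         junction = "FR",
         exons = list(list(start = 500, end = 665), list(start = 0, end = 120))),
    list(name = "g2", contig_id = "c2", strand = "+", status = "complete_1exon",
         junction = NULL,
         exons = list(list(start = 10, end = 1000))))
  path <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(models, path)
  gr <- rtracklayer::import(path)
  cds <- gr[gr$type == "CDS"]
  expect_identical(length(cds), 3L)
  g1 <- cds[GenomicRanges::seqnames(cds) == "c1"]
  expect_setequal(GenomicRanges::start(g1), c(501L, 1L))  # 0 -> 1-based
  expect_setequal(GenomicRanges::end(g1), c(665L, 120L))
  expect_true(all(as.character(GenomicRanges::strand(g1)) == "-"))
  expect_true(all(gr$phase[gr$type == "CDS"] == 0L))
  genes <- gr[gr$type == "gene"]
  expect_setequal(genes$status, c("complete_2exon", "complete_1exon"))
})
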
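test_that("hydropathy segmentation finds planted hydrophobic runs and nothing else", {
  prot <- paste0(strrep("D", 30), strrep("I", 25), strrep("D", 30))
  seg <- tm_segments(prot)
  expect_identical(nrow(seg), 1L)
  expect_lte(abs(seg$start - 30), 10)
  expect_lte(abs(seg$end - 55), 10)
  expect_gte(seg$mean_hydropathy, 1.5)
  expect_identical(nrow(tm_segments(strrep("G", 100))), 0L)
  expect_warning(seg0 <- tm_segments("MILV"), "shorter")
  expect_identical(nrow(seg0), 0L)
})

test_that("synthetic receptors present seven transmembrane segments", {
  sim <- small_sim()
  tr <- sim$truth
  prot <- tr$protein[tr$status == "complete_1exon"]
  n7 <- vapply(prot, function(p) nrow(tm_segments(p)), 0L)
  expect_true(all(n7 == 7))
})

test_that("sequon scanning implements N-X-[S/T] with X != P", {
  expect_equal(sequon_scan("MNGSA")$position, 1)
  expect_identical(sequon_scan("MNGSA")$triplet, "NGS")
  expect_identical(nrow(sequon_scan("MNPSA")), 0L)
  s <- sequon_scan("NGSNGT")
  expect_equal(s$position, c(0, 3))
  expect_identical(nrow(sequon_scan("NG")), 0L)
  expect_equal(sequon_scan("AANFTAANYS", n_terminal_window = 5)$position, 2)
})

test_that("motif discovery returns the planted conserved window first", {
  set.seed(61)
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  block <- "WCDEHKFM"
  rows <- vapply(1:40, function(i) {
    left <- paste(sample(aa, 10, TRUE), collapse = "")
    right <- paste(sample(aa, 22, TRUE), collapse = "")
    paste0(left, block, right)
  }, "")
  motifs <- conserved_motifs(rows, k = 3, widths = 8)
  expect_lte(length(motifs), 3)
  top <- motifs[[1]]
  expect_identical(top$start, 10L)
  expect_identical(top$consensus, block)
  expect_equal(top$ic_per_column, log2(20), tolerance = 1e-9)
  # pwm rows are distributions
  for (m in motifs) expect_equal(rowSums(m$pwm), rep(1, m$width),
                                 tolerance = 1e-9)
  # deterministic
  motifs2 <- conserved_motifs(rows, k = 3, widths = 8)
  expect_identical(motifs, motifs2)
  expect_error(conserved_motifs(rows[1:4]), "5")
})

test_that("motifs of a fully random alignment stay weak and non-overlapping", {
  set.seed(62)
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  rows <- vapply(1:200, function(i) paste(sample(aa, 60, TRUE), collapse = ""), "")
  motifs <- conserved_motifs(rows, k = 5, widths = 6:10)
  expect_lte(length(motifs), 5)
  for (m in motifs) expect_lt(m$ic_per_column, 1)
  spans <- lapply(motifs, function(m) (m$start + 1):(m$start + m$width))
  expect_identical(anyDuplicated(unlist(spans)), 0L)
})

test_that("the planted motif blocks are recovered from the mined repertoire", {
  sim <- small_sim()
  rep <- small_rep()
  expect_false(is.null(rep$motifs))
  planted <- sim$ancestors$layout$motif_blocks
  planted_iv <- lapply(planted, function(b) c(min(b) - 1, max(b)))  # 0-based
  hits <- 0
  for (m in rep$motifs) {
    span <- c(m$start, m$start + m$width)
    ov <- vapply(planted_iv, function(p)
      max(0, min(span[2], p[2]) - max(span[1], p[1])) /
        max(1, span[2] - span[1]), 0)
    if (max(ov) >= 0.8) hits <- hits + 1
  }
  expect_gte(hits, length(rep$motifs) - 1)
})

test_that("splice logos carry the canonical GT/AG consensus", {
  sim <- small_sim()
  rep <- small_rep()
  logos <- rep$logos
  expect_false(is.null(logos))
  expect_identical(substr(logos$donor$consensus, 4, 5), "GT")
  expect_identical(substr(logos$acceptor$consensus, 11, 12), "AG")
  # invariant splice dinucleotides have maximal information content
  expect_equal(logos$donor$ic[4:5], c(2, 2), tolerance = 1e-9)
  expect_equal(logos$acceptor$ic[11:12], c(2, 2), tolerance = 1e-9)
  expect_equal(rowSums(logos$donor$pfm), rep(1, 9), tolerance = 1e-9)
  expect_equal(rowSums(logos$acceptor$pfm), rep(1, 15), tolerance = 1e-9)
  expect_error(splice_logo(list(list(status = "complete_1exon")), character(0)),
               "no two-exon")
})
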
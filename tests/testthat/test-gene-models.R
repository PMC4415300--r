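test_that("gene names follow the species/status/family scheme", {
  expect_identical(name_gene("Bri", "edge", "A", 5), "BriTARe.A005")
  expect_identical(name_gene("Til", "pseudogene", "A", 22), "TilTARp.A022")
  expect_identical(name_gene("Bur", "complete_2exon", "A", 16), "BurTARs.A016")
  expect_identical(name_gene("Til", "complete_1exon", "B", 3), "TilTAR.B003")
  expect_identical(name_gene("Zeb", "fragment", "C", 999), "ZebTARf.C999")
  expect_error(name_gene("Til", "edge", "A", 1000), "range")
  expect_error(name_gene("Til", "edge", "AB", 1), "single letter")
})

test_that("junction census counts dipeptides and the aromatic-basic fraction", {
  mk <- function(j) list(status = "complete_2exon", junction = j)
  cen <- junction_census(list(mk("FR"), mk("FR"), mk("FK")))
  expect_identical(cen$counts, c(FR = 2L, FK = 1L))
  expect_equal(cen$aromatic_basic_fraction, 1)
  cen2 <- junction_census(list(mk("FR"), mk("LT"),
                               list(status = "complete_1exon")))
  expect_identical(cen2$n, 2L)
  expect_equal(cen2$aromatic_basic_fraction, 0.5)
  empty <- junction_census(list())
  expect_identical(empty$n, 0L)
  expect_identical(length(empty$counts), 0L)
})

test_that("adjacency report classifies orientation patterns and distances", {
  mk <- function(name, contig, strand, s, e)
    list(name = name, contig_id = contig, strand = strand,
         exons = list(list(start = s, end = e)))
  models <- list(mk("g1", "c1", "+", 1000, 2000),
                 mk("g2", "c1", "+", 3500, 4500),   # tail-to-head, 1500
                 mk("g3", "c1", "-", 5000, 6000),   # "+" then "-": tail-to-tail
                 mk("g4", "c2", "-", 100, 900),
                 mk("g5", "c2", "+", 950, 1800),    # "-" then "+": head-to-head
                 mk("solo", "c3", "+", 10, 500))
  adj <- adjacency_report(models)
  expect_identical(nrow(adj), 3L)
  r12 <- adj[adj$gene1 == "g1", ]
  expect_identical(r12$orientation, "tail-to-head")
  expect_equal(r12$distance, 1500)
  expect_identical(adj$orientation[adj$gene1 == "g2"], "tail-to-tail")
  expect_identical(adj$orientation[adj$gene1 == "g4"], "head-to-head")
  expect_false(any(adj$contig_id == "c3"))
  # overlapping models: distance 0 with a flag
  adj2 <- adjacency_report(list(mk("a", "c", "+", 100, 900),
                                mk("b", "c", "+", 700, 1500)))
  expect_equal(adj2$distance, 0)
  expect_true(adj2$overlap)
})

test_that("planted statuses are recovered with exact two-exon boundaries", {
  sim <- small_sim()
  rep <- small_rep()
  ev <- evaluate_against_truth(rep, sim$truth)
  expect_true(all(ev$status_recall >= 0.9, na.rm = TRUE))
  expect_equal(ev$decoy_rejection_rate, 1)
  expect_equal(ev$boundary_exact_rate, 1)
  expect_true(ev$junction_exact)
})

test_that("recovered two-exon models have canonical phase-0 GT-AG introns", {
  sim <- small_sim()
  rep <- small_rep()
  spliced <- Filter(function(m) identical(m$status, "complete_2exon"),
                    rep$models)
  expect_gt(length(spliced), 0)
  for (m in spliced) {
    expect_identical(m$splice$donor_dinuc, "GT")
    expect_identical(m$splice$acceptor_dinuc, "AG")
    e1 <- m$exons[[1]]
    expect_identical((e1$end - e1$start) %% 3, 0)   # phase 0
    expect_false(grepl("*", m$protein, fixed = TRUE))
    expect_identical(3L * m$intron_codon_index, (e1$end - e1$start))
  }
})

test_that("complete models translate cleanly and pseudogenes carry disruptions", {
  rep <- small_rep()
  for (m in rep$models) {
    if (m$status %in% c("complete_1exon", "complete_2exon")) {
      expect_false(grepl("*", m$protein, fixed = TRUE))
      expect_identical(substr(m$protein, 1, 1), "M")
    }
    if (identical(m$status, "pseudogene"))
      expect_gte(length(m$disruptions), 1)
  }
})

test_that("planted disruption positions are recovered within two codons", {
  sim <- small_sim()
  rep <- small_rep()
  tr <- sim$truth
  ps <- which(tr$status == "pseudogene")
  mod_df <- data.frame(
    contig = vapply(rep$models, `[[`, "", "contig_id"),
    start = vapply(rep$models, function(m)
      min(vapply(m$exons, `[[`, 0, "start")), 0),
    end = vapply(rep$models, function(m)
      max(vapply(m$exons, `[[`, 0, "end")), 0))
  for (i in ps) {
    hit <- which(mod_df$contig == tr$contig[i] &
                 mod_df$start < tr$end[i] & mod_df$end > tr$start[i])
    expect_length(hit, 1)
    m <- rep$models[[hit]]
    expect_identical(m$status, "pseudogene")
    kinds <- vapply(m$disruptions, `[[`, "", "kind")
    expect_true(tr$pseudo_kind[i] %in% kinds)
    pos <- vapply(m$disruptions, `[[`, 0L, "position")
    tol <- if (tr$pseudo_kind[i] == "in_frame_stop") 2 else 8
    expect_lte(min(abs(pos - tr$pseudo_position[i])), tol)
  }
})
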
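test_that("simulation is byte-identical for a fixed seed", {
  cfg <- synth_config(seed = 13, species = "Til",
                      counts = c(complete_2exon = 2L, complete_1exon = 1L,
                                 pseudogene_frameshift = 1L,
                                 pseudogene_stop = 0L, edge = 1L,
                                 fragment = 0L, decoy_gpcr = 1L),
                      ortholog_pairs = 0L, ortholog_triplets = 0L)
  s1 <- simulate_repertoire(cfg)
  s2 <- simulate_repertoire(cfg)
  expect_identical(s1$assemblies, s2$assemblies)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$pos_baits, s2$pos_baits)
})

test_that("the truth table reflects the planted counts", {
  sim <- small_sim()
  tab <- table(sim$truth$species, sim$truth$status)
  for (sp in c("Til", "Bur")) {
    expect_identical(unname(tab[sp, "complete_2exon"]), 4L)
    expect_identical(unname(tab[sp, "complete_1exon"]), 2L)
    expect_identical(unname(tab[sp, "pseudogene"]), 3L)
    expect_identical(unname(tab[sp, "edge"]), 2L)
    expect_identical(unname(tab[sp, "fragment"]), 1L)
    expect_identical(unname(tab[sp, "decoy"]), 2L)
  }
})

test_that("truth coordinates re-extract to the recorded coding sequences", {
  sim <- small_sim()
  tr <- sim$truth
  for (i in which(tr$status %in% c("complete_1exon", "complete_2exon"))) {
    contig <- sim$assemblies[[tr$species[i]]][[tr$contig[i]]]
    parts <- strsplit(strsplit(tr$exons[i], ";")[[1]], "-")
    cds <- paste(vapply(parts, function(p) {
      taarminer:::.extract_strand(contig, as.integer(p[1]), as.integer(p[2]),
                                  tr$strand[i])
    }, ""), collapse = "")
    expect_identical(cds, tr$cds[i], info = tr$gene[i])
    prot <- translate_cds(cds)
    expect_identical(substr(prot, nchar(prot), nchar(prot)), "*")
    expect_false(grepl("*", substr(prot, 1, nchar(prot) - 1), fixed = TRUE))
  }
  # pseudogenes: the planted genomic element translates with a disruption
  for (i in which(tr$status == "pseudogene")) {
    expect_true(tr$pseudo_kind[i] %in% c("frameshift", "in_frame_stop"))
    expect_true(tr$pseudo_position[i] >= 1)
  }
})

test_that("evolution hits the identity target within the stated band", {
  set.seed(71)
  anc <- oracle_random_cds(300)
  for (target in c(90, 70)) {
    for (rep in 1:5) {
      der <- evolve_to_identity(anc, target, omega = 0.5)
      id <- pairwise_identity(
        translate_cds(anc), translate_cds(der))
      expect_gte(id, target - 3)
      expect_lte(id, target + 3)
    }
  }
})

test_that("target identity 100 leaves the input unchanged", {
  set.seed(72)
  anc <- oracle_random_cds(60)
  expect_identical(evolve_to_identity(anc, 100, omega = 0.5), anc)
})

test_that("purely synonymous evolution leaves the protein intact and dN near zero", {
  set.seed(73)
  anc <- oracle_random_cds(200)
  der <- evolve_to_identity(anc, 95, omega = 0, budget_per_codon = 2L)
  expect_identical(translate_cds(anc), translate_cds(der))
  expect_false(identical(anc, der))
  rec <- ng86_pair(anc, der)
  # multi-hit codons can route pathway averaging through nonsynonymous
  # intermediates, so dN is near-zero rather than exactly zero
  expect_lte(rec$dN, 0.01)
  expect_gt(rec$dS, 10 * rec$dN)
})

test_that("pseudogenizing mutations have the declared structure", {
  set.seed(74)
  cds <- paste0(oracle_random_cds(329), "TAA")
  for (i in 1:10) {
    fs <- pseudogenize(cds, "frameshift")
    expect_true(abs(nchar(fs$seq) - nchar(cds)) %in% 1:2)
    st <- pseudogenize(cds, "in_frame_stop")
    expect_identical(nchar(st$seq), nchar(cds))
    prot <- translate_cds(st$seq)
    expect_true(grepl("*", substr(prot, 1, nchar(prot) - 1), fixed = TRUE))
    expect_identical(substr(st$seq, 3 * st$position - 2, 3 * st$position),
                     st$detail)
  }
})

test_that("edge truncation keeps a codon-aligned remnant of the right side", {
  set.seed(75)
  cds <- paste0(oracle_random_cds(329), "TAA")
  n <- nchar(cds)
  tn <- truncate_to_edge(cds, "N", 0.6)
  expect_lte(abs(nchar(tn$seq) / n - 0.6), 0.01)
  expect_identical(tn$seq, substr(cds, n - nchar(tn$seq) + 1, n))
  tc <- truncate_to_edge(cds, "C", 0.45)
  expect_identical(tc$seq, substr(cds, 1, nchar(tc$seq)))
  expect_identical(nchar(tc$seq) %% 3L, 0L)
  expect_error(truncate_to_edge(cds, "N", 0.2), "0.3")
  expect_error(truncate_to_edge(cds, "N", 0.8), "0.3")
})

test_that("the omega-pair simulator respects its acceptance ratio qualitatively", {
  set.seed(76)
  om0 <- mean(replicate(3, {
    p <- simulate_omega_pair(200, rho = 0, n_prop = 60)
    ng86_pair(p[1], p[2])$dN
  }))
  expect_equal(om0, 0)
})
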
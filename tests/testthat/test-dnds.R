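test_that("codon site counts match hand enumeration and sum to 3 for every R", {
  expect_equal(codon_site_counts("TTT")$s, 1 / 3)
  expect_equal(codon_site_counts("ATG")$s, 0)
  expect_equal(codon_site_counts("ATG")$n, 3)
  # transition weighting: at TTT position 3 only the transition T->C is
  # synonymous, so s = R / (R + 2)  * 1 ... with R = 2: 2/4
  expect_equal(codon_site_counts("TTT", R = 2)$s, 0.5)
  for (codon in sample(ORACLE_SENSE, 25)) {
    for (R in c(0.5, 1, 2, 7)) {
      sc <- codon_site_counts(codon, R = R)
      expect_equal(sc$s + sc$n, 3, tolerance = 1e-9, info = codon)
    }
    expect_equal(codon_site_counts(codon)$s, oracle_sites(codon)[["s"]],
                 tolerance = 1e-12, info = codon)
  }
  expect_error(codon_site_counts("TAA"), "stop")
  expect_error(codon_site_counts("ANT"), "codon")
})

test_that("pathway differences average over orderings and respect identity", {
  expect_equal(pathway_differences("GTG", "GTA"), list(sd = 1, nd = 0))
  expect_equal(pathway_differences("TTT", "TTT"), list(sd = 0, nd = 0))
  d <- pathway_differences("TTT", "GTA")
  expect_equal(d$sd, 0.5)
  expect_equal(d$nd, 1.5)
  set.seed(41)
  for (i in 1:40) {
    c1 <- sample(ORACLE_SENSE, 1); c2 <- sample(ORACLE_SENSE, 1)
    d <- pathway_differences(c1, c2)
    expect_equal(d$sd + d$nd,
                 sum(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]]),
                 tolerance = 1e-9, info = paste(c1, c2))
    o <- oracle_path_diffs(c1, c2)
    expect_equal(d$sd, o[["sd"]], tolerance = 1e-9, info = paste(c1, c2))
  }
})

test_that("the worked pair decomposes into the expected sites and distances", {
  rec <- ng86_pair("ATGTTTGTGCTG", "ATGTTTGTACTG")
  expect_equal(rec$S, 8 / 3, tolerance = 1e-12)
  expect_equal(rec$N, 28 / 3, tolerance = 1e-12)
  expect_equal(rec$Sd, 1)
  expect_equal(rec$Nd, 0)
  expect_equal(rec$pS, 0.375)
  expect_equal(rec$dS, -0.75 * log(1 - 0.5), tolerance = 1e-9)
  expect_equal(rec$dN, 0)
  expect_equal(rec$omega, 0)
})

test_that("ng86_pair flags degenerate outcomes instead of failing", {
  cds <- "ATGTTTGTGCTG"
  rec <- ng86_pair(cds, cds)
  expect_true("omega_zero_zero" %in% rec$flags)
  # one nonsynonymous difference, no synonymous one -> unbounded omega
  rec <- ng86_pair("ATGTTT", "ATGTGT")
  expect_true("omega_unbounded" %in% rec$flags)
  expect_true(is.na(rec$omega))
  expect_error(ng86_pair("ATGTTT", "ATGTT"), "length")
  expect_error(ng86_pair("ATGTAATTT", "ATGTGGTTT"), "stop")
})

test_that("ng86_pair is symmetric and invariant under codon permutation", {
  set.seed(42)
  for (i in 1:20) {
    a <- oracle_random_cds(30)
    b <- oracle_random_cds(30)
    r1 <- ng86_pair(a, b); r2 <- ng86_pair(b, a)
    for (f in c("S", "N", "Sd", "Nd", "dS", "dN"))
      expect_equal(r1[[f]], r2[[f]], tolerance = 1e-12, info = f)
    perm <- sample(30)
    pa <- paste(substring(a, 3 * perm - 2, 3 * perm), collapse = "")
    pb <- paste(substring(b, 3 * perm - 2, 3 * perm), collapse = "")
    r3 <- ng86_pair(pa, pb)
    expect_equal(r1$dS, r3$dS, tolerance = 1e-12)
    expect_equal(r1$dN, r3$dN, tolerance = 1e-12)
  }
})

test_that("codon-aligned pairs with different lengths are aligned through proteins", {
  a <- "ATGTTTGGGAAACCC"      # M F G K P
  b <- "ATGTTTAAACCC"         # M F K P   (G codon deleted)
  ab <- align_codons(a, b)
  expect_identical(nchar(ab[1]), nchar(ab[2]))
  expect_identical(ab[2], b)
  expect_identical(ab[1], "ATGTTTAAACCC")
})

test_that("family summaries separate finite and unbounded ratios", {
  rec <- data.frame(gene1 = c("a", "a", "b", "x"), gene2 = c("b", "c", "c", "y"),
                    omega = c(0.2, 0.4, 0.6, NA),
                    flags = c("", "", "", "omega_unbounded"),
                    stringsAsFactors = FALSE)
  asn <- data.frame(gene = c("a", "b", "c", "x", "y"),
                    family = c("A", "A", "A", "B", "B"),
                    stringsAsFactors = FALSE)
  fs <- family_summary(rec, asn)
  a <- fs[fs$family == "A", ]
  expect_equal(c(a$mean_omega, a$min_omega, a$max_omega), c(0.4, 0.2, 0.6))
  expect_equal(a$n_unbounded, 0)
  b <- fs[fs$family == "B", ]
  expect_equal(b$n_unbounded, 1)
  expect_true(is.na(b$mean_omega))
})

test_that("intra/inter species means are split correctly", {
  rec <- data.frame(gene1 = c("t1", "t1", "b1"), gene2 = c("t2", "b1", "b2"),
                    omega = c(0.2, 0.4, 0.6), flags = "",
                    stringsAsFactors = FALSE)
  sp <- c(t1 = "Til", t2 = "Til", b1 = "Bur", b2 = "Bur")
  tab <- intra_inter_summary(rec, sp)
  til <- tab[tab$species == "Til", ]
  expect_equal(til$mean_intra, 0.2)
  expect_equal(til$mean_inter, 0.4)
  bur <- tab[tab$species == "Bur", ]
  expect_equal(bur$mean_intra, 0.6)
  expect_equal(bur$mean_inter, 0.4)
})
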
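test_that("pairwise identity matches simple cases and is symmetric", {
  expect_equal(pairwise_identity("MFR", "MFR"), 100)
  expect_equal(pairwise_identity("MFRW", "MFRY"), 75)
  expect_error(pairwise_identity("", "MFR"), "empty")
  set.seed(51)
  for (i in 1:50) {
    a <- random_peptide(sample(10:40, 1))
    b <- random_peptide(sample(10:40, 1))
    expect_equal(pairwise_identity(a, b), pairwise_identity(b, a),
                 tolerance = 1e-9)
  }
})

test_that("threshold clustering separates families and subfamilies", {
  m <- matrix(c(100, 65, 45,
                65, 100, 45,
                45, 45, 100), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  asn <- cluster_families(m)
  expect_identical(unique(asn$family), "A")           # one family
  sub <- stats::setNames(asn$subfamily, asn$gene)
  expect_identical(sub[["a"]], sub[["b"]])
  expect_false(sub[["a"]] == sub[["c"]])
  # all below the family threshold: singleton families
  m2 <- matrix(30, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(m2) <- 100
  asn2 <- cluster_families(m2)
  expect_identical(sort(asn2$family), c("A", "B", "C", "D"))
})

test_that("subfamily partition refines the family partition", {
  set.seed(52)
  for (rep in 1:10) {
    n <- 12
    m <- matrix(runif(n * n, 10, 95), n, n)
    m <- (m + t(m)) / 2; diag(m) <- 100
    dimnames(m) <- list(paste0("g", 1:n), paste0("g", 1:n))
    asn <- cluster_families(m)
    # same subfamily (within a family) implies same family by construction;
    # verify each subfamily's members share their family label
    key <- paste(asn$family, asn$subfamily)
    for (k in unique(key))
      expect_length(unique(asn$family[key == k]), 1)
  }
})

test_that("clustering labels are invariant under input permutation", {
  set.seed(53)
  n <- 10
  m <- matrix(runif(n * n, 20, 90), n, n)
  m <- (m + t(m)) / 2; diag(m) <- 100
  dimnames(m) <- list(paste0("g", 1:n), paste0("g", 1:n))
  ref <- cluster_families(m)
  ref <- ref[order(ref$gene), ]
  for (i in 1:20) {
    p <- sample(n)
    got <- cluster_families(m[p, p])
    got <- got[order(got$gene), ]
    expect_identical(got$family, ref$family)
    expect_identical(got$subfamily, ref$subfamily)
  }
})

test_that("ortholog detection finds pairs and triplets above the identity bar", {
  ids <- c("TilA", "BurA", "NyeA", "TilB", "BurB", "TilC")
  m <- matrix(50, 6, 6, dimnames = list(ids, ids))
  diag(m) <- 100
  set_id <- function(a, b, v) m[a, b] <<- m[b, a] <<- v
  set_id("TilA", "BurA", 99.6); set_id("TilA", "NyeA", 99.4)
  set_id("BurA", "NyeA", 99.2)                       # triplet
  set_id("TilB", "BurB", 99.5)                       # pair
  set_id("TilC", "BurB", 98.9)                       # below threshold
  sp <- stats::setNames(substr(ids, 1, 3), ids)
  og <- find_orthologs(m, sp)
  expect_identical(nrow(og), 2L)
  tri <- og[og$size == 3, ]
  expect_identical(tri$members, "BurA,NyeA,TilA")
  expect_identical(tri$type, "ortholog")
  pair <- og[og$size == 2, ]
  expect_identical(pair$members, "BurB,TilB")
  # same-species near-duplicates are labelled paralogs
  set_id("TilB", "BurB", 50); set_id("TilB", "TilC", 99.3)
  og2 <- find_orthologs(m, sp)
  expect_true("paralog" %in% og2$type[og2$members == "TilB,TilC"])
})

test_that("neighbor joining recovers closed-form and additive distances", {
  # 2 taxa: single split of total length d
  m2 <- matrix(c(100, 70, 70, 100), 2, 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  tr <- nj_tree(m2)
  expect_equal(sum(tr$edge.length), 0.3, tolerance = 1e-9)
  # 3 taxa closed form: a = (dAB + dAC - dBC)/2 etc.
  d3 <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  d3["a", "b"] <- d3["b", "a"] <- 0.4
  d3["a", "c"] <- d3["c", "a"] <- 0.6
  d3["b", "c"] <- d3["c", "b"] <- 0.8
  tr3 <- nj_tree(d3, is_distance = TRUE)
  bl <- stats::setNames(
    tr3$edge.length[match(seq_len(3), tr3$edge[, 2])], tr3$tip.label)
  expect_equal(unname(bl[c("a", "b", "c")]), c(0.1, 0.3, 0.5),
               tolerance = 1e-9)
  expect_error(nj_tree(matrix(1, 1, 1)), "2 taxa")
  asym <- d3; asym[1, 2] <- 0.5
  expect_error(nj_tree(asym, is_distance = TRUE), "symmetric")
})

test_that("NJ reproduces path distances of random additive matrices exactly", {
  set.seed(54)
  for (i in 1:25) {
    d <- oracle_additive_matrix(sample(6:10, 1))
    tr <- nj_tree(d, is_distance = TRUE)
    got <- ape::cophenetic.phylo(tr)
    got <- got[rownames(d), colnames(d)]
    expect_equal(got, d, tolerance = 1e-8)
  }
})

test_that("Newick output round-trips through an independent parser", {
  d <- oracle_additive_matrix(7)
  tr <- nj_tree(d, is_distance = TRUE)
  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, path)
  back <- ape::read.tree(path)
  expect_setequal(back$tip.label, rownames(d))
  got <- ape::cophenetic.phylo(back)[rownames(d), colnames(d)]
  expect_equal(got, d, tolerance = 1e-6)
})
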
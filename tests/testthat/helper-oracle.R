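# Independent oracles used across the suite. These reimplement the checked
# quantities from first principles (exhaustive enumeration / plain DP) and
# deliberately share no code with the package internals.

ORACLE_GC <- Biostrings::GENETIC_CODE
ORACLE_STOPS <- names(ORACLE_GC)[ORACLE_GC == "*"]
ORACLE_SENSE <- setdiff(names(ORACLE_GC), ORACLE_STOPS)

oracle_random_cds <- function(n_codons) {
  paste(sample(ORACLE_SENSE, n_codons, replace = TRUE), collapse = "")
}

# --- NG86 (R = 1) by exhaustive enumeration --------------------------------

oracle_sites <- function(codon) {
  s <- 0
  for (pos in 1:3) {
    syn <- 0
    for (b in c("A", "C", "G", "T")) {
      if (b == substr(codon, pos, pos)) next
      mut <- codon
      substr(mut, pos, pos) <- b
      if (!(mut %in% ORACLE_STOPS) &&
          ORACLE_GC[[mut]] == ORACLE_GC[[codon]]) syn <- syn + 1
    }
    s <- s + syn / 3
  }
  c(s = s, n = 3 - s)
}

# all orderings of the differing positions, stop-passing paths excluded
oracle_path_diffs <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (!length(pos)) return(c(sd = 0, nd = 0))
  perms <- if (length(pos) == 1) list(pos) else {
    idx <- seq_along(pos)
    prm <- list()
    rec <- function(acc, rest) {
      if (!length(rest)) { prm[[length(prm) + 1]] <<- pos[acc]; return() }
      for (r in seq_along(rest)) rec(c(acc, rest[r]), rest[-r])
    }
    rec(integer(0), idx)
    prm
  }
  sds <- c(); nds <- c()
  for (ord in perms) {
    cur <- c1; sd <- 0; nd <- 0; ok <- TRUE
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (nxt %in% ORACLE_STOPS) { ok <- FALSE; break }
      if (ORACLE_GC[[cur]] == ORACLE_GC[[nxt]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    if (ok) { sds <- c(sds, sd); nds <- c(nds, nd) }
  }
  if (!length(sds)) {
    # all paths blocked: count steps through stops as nonsynonymous
    for (ord in perms) {
      cur <- c1; sd <- 0; nd <- 0
      for (p in ord) {
        nxt <- cur
        substr(nxt, p, p) <- substr(c2, p, p)
        syn <- !(cur %in% ORACLE_STOPS) && !(nxt %in% ORACLE_STOPS) &&
          ORACLE_GC[[cur]] == ORACLE_GC[[nxt]]
        if (syn) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      sds <- c(sds, sd); nds <- c(nds, nd)
    }
  }
  c(sd = mean(sds), nd = mean(nds))
}

oracle_ng86 <- function(cds1, cds2) {
  n <- nchar(cds1) / 3
  S1 <- 0; S2 <- 0; Sd <- 0; Nd <- 0
  for (i in seq_len(n)) {
    c1 <- substr(cds1, 3 * i - 2, 3 * i)
    c2 <- substr(cds2, 3 * i - 2, 3 * i)
    S1 <- S1 + oracle_sites(c1)[["s"]]
    S2 <- S2 + oracle_sites(c2)[["s"]]
    d <- oracle_path_diffs(c1, c2)
    Sd <- Sd + d[["sd"]]; Nd <- Nd + d[["nd"]]
  }
  S <- (S1 + S2) / 2
  N <- 3 * n - S
  pS <- Sd / S; pN <- Nd / N
  jc <- function(p) if (p < 0.75) -0.75 * log(1 - 4 * p / 3) else NA_real_
  list(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
       dS = jc(pS), dN = jc(pN))
}

# --- exhaustive affine-gap Smith-Waterman in plain R -----------------------

oracle_sw_score <- function(q, t, mat, go = 11, ge = 1) {
  qs <- strsplit(q, "")[[1]]; ts <- strsplit(t, "")[[1]]
  m <- length(qs); n <- length(ts)
  NEG <- -1e9
  M <- matrix(0, m + 1, n + 1)
  X <- matrix(NEG, m + 1, n + 1)
  Y <- matrix(NEG, m + 1, n + 1)
  best <- 0
  for (i in 2:(m + 1)) for (j in 2:(n + 1)) {
    X[i, j] <- max(M[i - 1, j] - go - ge, X[i - 1, j] - ge)
    Y[i, j] <- max(M[i, j - 1] - go - ge, Y[i, j - 1] - ge)
    M[i, j] <- max(0, M[i - 1, j - 1] + mat[qs[i - 1], ts[j - 1]],
                   X[i, j], Y[i, j])
    best <- max(best, M[i, j])
  }
  best
}

# --- random additive tree distances ----------------------------------------

oracle_additive_matrix <- function(n_taxa) {
  tr <- ape::rtree(n_taxa, br = stats::runif)
  d <- ape::cophenetic.phylo(tr)
  d[order(rownames(d)), order(colnames(d))]
}

random_peptide <- function(n) {
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  paste(sample(aa, n, replace = TRUE), collapse = "")
}
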
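# Alignment primitives shared by the search, clustering and dN/dS stages.

.tm_env <- new.env(parent = emptyenv())

.blosum62 <- function() {
  m <- .tm_env$BLOSUM62
  if (is.null(m)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    m <- e$BLOSUM62
    storage.mode(m) <- "integer"
    .tm_env$BLOSUM62 <- m
  }
  m
}

.encode_aa <- function(seq, alphabet) {
  idx <- match(strsplit(seq, "", fixed = TRUE)[[1]], alphabet)
  if (anyNA(idx)) {
    # unknown residues behave like 'X'
    idx[is.na(idx)] <- match("X", alphabet)
  }
  idx - 1L
}

#' Search configuration
#'
#' Scoring and filtering parameters of the translated homology search.
#'
#' @param matrix Substitution matrix name (only \code{"BLOSUM62"} is shipped).
#' @param gap_open,gap_extend Affine gap penalties (positive; a gap of length
#'   L costs \code{gap_open + L * gap_extend}).
#' @param lambda,K Karlin--Altschul parameters used to convert raw scores to
#'   E-values (defaults are the gapped BLOSUM62 11/1 values).
#' @param e_pos,e_neg E-value cutoffs for the positive and negative bait sets.
#' @param merge_gap Maximum nt separation at which same-strand hits are merged
#'   into one locus.
#' @param max_hits_per_frame Upper bound on masked re-scans per
#'   (bait, frame) pair.
#' @return A list of class \code{search_config}.
#' @export
search_config <- function(matrix = "BLOSUM62", gap_open = 11, gap_extend = 1,
                          lambda = 0.267, K = 0.041,
                          e_pos = 1e-50, e_neg = 1e-50, merge_gap = 2000,
                          max_hits_per_frame = 8L) {
  stopifnot(e_pos > 0, e_pos <= 1, e_neg > 0, e_neg <= 1,
            lambda > 0, K > 0, gap_open > 0, gap_extend > 0)
  if (matrix != "BLOSUM62") stop("only BLOSUM62 is available")
  structure(list(matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend, lambda = lambda, K = K,
                 e_pos = e_pos, e_neg = e_neg, merge_gap = merge_gap,
                 max_hits_per_frame = as.integer(max_hits_per_frame)),
            class = "search_config")
}

#' Local protein alignment (Smith--Waterman, affine gaps)
#'
#' @param query,target Protein strings (may contain \code{X} and \code{*}).
#' @param config A [search_config()] supplying matrix and gap penalties.
#' @return A list: \code{score} (raw, substitution-matrix units),
#'   \code{qstart}, \code{qend}, \code{tstart}, \code{tend} (1-based inclusive
#'   spans of the aligned region) and \code{qaln}/\code{taln} (aligned strings
#'   with \code{-} gaps). An empty input gives score 0 and an empty alignment.
#' @examples
#' local_align("MFRW", "MFRW")$score  # 27 under BLOSUM62
#' @export
local_align <- function(query, target, config = search_config()) {
  if (nchar(query) == 0L || nchar(target) == 0L)
    return(list(score = 0, qstart = 0L, qend = 0L, tstart = 0L, tend = 0L,
                qaln = "", taln = ""))
  m <- .blosum62()
  alpha <- rownames(m)
  res <- .sw_align_cpp(.encode_aa(query, alpha), .encode_aa(target, alpha),
                       m, config$gap_open, config$gap_extend)
  decode <- function(v) paste(ifelse(v < 0, "-", alpha[v + 1L]), collapse = "")
  list(score = res$score, qstart = res$qstart, qend = res$qend,
       tstart = res$tstart, tend = res$tend,
       qaln = decode(res$qaln), taln = decode(res$taln))
}

.local_score_end <- function(query, target, config) {
  if (nchar(query) == 0L || nchar(target) == 0L) return(c(0, 0, 0))
  m <- .blosum62()
  alpha <- rownames(m)
  .sw_score_end_cpp(.encode_aa(query, alpha), .encode_aa(target, alpha),
                    m, config$gap_open, config$gap_extend)
}

.local_score <- function(query, target, config) {
  if (nchar(query) == 0L || nchar(target) == 0L) return(0)
  m <- .blosum62()
  alpha <- rownames(m)
  .sw_score_cpp(.encode_aa(query, alpha), .encode_aa(target, alpha),
                m, config$gap_open, config$gap_extend)
}

# Global (Needleman-Wunsch, affine gaps, end gaps penalized) alignment;
# returns the two aligned strings. Used for percent identity and codon
# back-threading.
.nw_align <- function(a, b, gap_open = 10, gap_extend = 1) {
  m <- .blosum62()
  alpha <- rownames(m)
  res <- .nw_align_cpp(.encode_aa(a, alpha), .encode_aa(b, alpha),
                       m, gap_open, gap_extend)
  decode <- function(v) paste(ifelse(v < 0, "-", alpha[v + 1L]), collapse = "")
  c(decode(res$qaln), decode(res$taln))
}

#' Karlin--Altschul E-value
#'
#' \eqn{E = K m n e^{-\lambda S}} for a raw local-alignment score \eqn{S}
#' against a search space of \eqn{m \times n} residues.
#'
#' @param raw_score Raw alignment score.
#' @param m Query length (residues).
#' @param n Searched residues.
#' @param config A [search_config()] supplying \code{lambda} and \code{K}.
#' @return The expected number of chance hits at or above the score.
#' @export
evalue <- function(raw_score, m, n, config = search_config()) {
  if (m <= 0 || n <= 0) stop("search-space dimensions must be positive")
  config$K * m * n * exp(-config$lambda * raw_score)
}

# Raw score needed for E <= cutoff in an m x n space.
.score_cutoff <- function(cutoff, m, n, config) {
  (log(config$K * m * n) - log(cutoff)) / config$lambda
}

#' Percent amino-acid identity of two proteins
#'
#' Global alignment (BLOSUM62, affine gaps 10/1); identity is 100 times the
#' number of identical columns over the columns where both sequences are
#' non-gap.
#'
#' @param a,b Non-empty protein strings.
#' @return Percent identity in \code{[0, 100]}.
#' @export
pairwise_identity <- function(a, b) {
  if (nchar(a) == 0L || nchar(b) == 0L)
    stop("empty protein sequence")
  al <- .nw_align(a, b)
  x <- strsplit(al[1], "", fixed = TRUE)[[1]]
  y <- strsplit(al[2], "", fixed = TRUE)[[1]]
  both <- x != "-" & y != "-"
  if (!any(both)) return(0)
  100 * sum(x[both] == y[both]) / sum(both)
}

#' Pairwise identity matrix over a set of proteins
#'
#' @param proteins Named character vector of protein sequences.
#' @return A symmetric matrix of percent identities with 100 on the diagonal.
#' @export
identity_matrix <- function(proteins) {
  ids <- names(proteins)
  n <- length(proteins)
  m <- matrix(100, n, n, dimnames = list(ids, ids))
  if (n < 2) return(m)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    v <- pairwise_identity(proteins[[i]], proteins[[j]])
    m[i, j] <- v; m[j, i] <- v
  }
  m
}
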
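# Structural annotation: hydropathy-based transmembrane segments,
# N-glycosylation sequons, conserved-motif discovery over an alignment, and
# donor/acceptor splice-site logos.

# Kyte-Doolittle hydropathy scale
.KD <- c(A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
         Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
         L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
         S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2)

#' Transmembrane segments by sliding-window hydropathy
#'
#' Maximal runs of residues whose centred Kyte--Doolittle window mean is at
#' or above the threshold; runs separated by fewer than \code{merge_below}
#' residues are merged, runs shorter than the band minimum dropped, and runs
#' longer than the band maximum trimmed (centred on the hydropathy peak).
#' Segments of 21-28 residues are flagged canonical for this receptor class.
#'
#' @param protein Protein string (unknown residues score 0).
#' @param window Sliding-window width (odd).
#' @param threshold Minimum windowed mean hydropathy.
#' @param band Accepted segment length range.
#' @param merge_below Merge runs separated by fewer than this many residues.
#' @return A data.frame: \code{start}, \code{end} (0-based half-open),
#'   \code{length}, \code{mean_hydropathy}, \code{canonical} (21-28 aa).
#' @export
tm_segments <- function(protein, window = 19L, threshold = 1.5,
                        band = c(17L, 35L), merge_below = 5L) {
  n <- nchar(protein)
  empty <- data.frame(start = integer(0), end = integer(0),
                      length = integer(0), mean_hydropathy = numeric(0),
                      canonical = logical(0))
  if (n <= window) {
    warning("protein shorter than the hydropathy window")
    return(empty)
  }
  h <- .KD[strsplit(protein, "", fixed = TRUE)[[1]]]
  h[is.na(h)] <- 0
  half <- window %/% 2L
  wm <- stats::filter(h, rep(1 / window, window), sides = 2)
  above <- !is.na(wm) & wm >= threshold
  r <- rle(as.vector(above))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values])
  if (!nrow(runs)) return(empty)
  merged <- runs[1, , drop = FALSE]
  if (nrow(runs) > 1) for (i in 2:nrow(runs)) {
    if (runs[i, 1] - merged[nrow(merged), 2] - 1L < merge_below)
      merged[nrow(merged), 2] <- runs[i, 2]
    else merged <- rbind(merged, runs[i, ])
  }
  rows <- list()
  for (i in seq_len(nrow(merged))) {
    s <- merged[i, 1]; e <- merged[i, 2]
    len <- e - s + 1L
    if (len < band[1]) next
    if (len > band[2]) {
      peak <- s - 1L + which.max(wm[s:e])
      s <- max(s, peak - band[2] %/% 2L)
      e <- min(e, s + band[2] - 1L)
      s <- max(1L, e - band[2] + 1L)
      len <- e - s + 1L
    }
    rows[[length(rows) + 1L]] <- data.frame(
      start = s - 1L, end = e, length = len,
      mean_hydropathy = mean(h[s:e]),
      canonical = len >= 21L && len <= 28L)
  }
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}

#' N-glycosylation sequon scan
#'
#' All matches of the sequon grammar \code{N-X-[S/T]} with \code{X != P}
#' (overlaps allowed). This is the sequence grammar only, not a glycosylation
#' propensity score.
#'
#' @param protein Protein string.
#' @param n_terminal_window Optional: restrict to Asn positions within the
#'   first \code{n_terminal_window} residues.
#' @return A data.frame: \code{position} (0-based index of the Asn),
#'   \code{triplet}.
#' @export
sequon_scan <- function(protein, n_terminal_window = NULL) {
  n <- nchar(protein)
  pos <- integer(0); trip <- character(0)
  if (n >= 3) {
    chars <- strsplit(protein, "", fixed = TRUE)[[1]]
    for (i in seq_len(n - 2L)) {
      if (chars[i] == "N" && chars[i + 1L] != "P" &&
          chars[i + 2L] %in% c("S", "T")) {
        pos <- c(pos, i - 1L)
        trip <- c(trip, paste0(chars[i:(i + 2L)], collapse = ""))
      }
    }
  }
  out <- data.frame(position = pos, triplet = trip, stringsAsFactors = FALSE)
  if (!is.null(n_terminal_window))
    out <- out[out$position < n_terminal_window, , drop = FALSE]
  out
}

# per-column residue frequencies of an alignment (rows = sequences);
# returns list(freq 20 x width matrix over AA_ALPHABET, gap_frac)
.column_profile <- function(cols) {
  t(vapply(seq_len(ncol(cols)), function(j) {
    tab <- table(factor(cols[, j], levels = AA_ALPHABET))
    as.numeric(tab)
  }, numeric(length(AA_ALPHABET))))
}

#' Conserved-motif discovery over a protein alignment
#'
#' Scores every ungapped window of each candidate width by its mean column
#' information content (bits; gap-containing columns are down-weighted by
#' their non-gap fraction) and greedily selects the top \code{k}
#' non-overlapping windows. Deterministic for identical input.
#'
#' @param alignment Character vector of aligned, equal-length protein strings
#'   (gaps \code{-}), or a character matrix (rows = sequences).
#' @param k Number of motifs to report.
#' @param widths Candidate widths (residues).
#' @return A list of up to \code{k} motif models, each with \code{start}
#'   (0-based column), \code{width}, \code{ic_per_column} (mean bits),
#'   \code{pwm} (width x 20 frequency matrix, rows sum to 1) and
#'   \code{consensus}; ordered by decreasing information content.
#' @export
conserved_motifs <- function(alignment, k = 5L, widths = 6:15) {
  M <- if (is.matrix(alignment)) alignment else {
    lens <- nchar(alignment)
    if (length(unique(lens)) != 1L)
      stop("alignment rows differ in length")
    do.call(rbind, strsplit(alignment, "", fixed = TRUE))
  }
  if (nrow(M) < 5L) stop("at least 5 aligned sequences required")
  ncols <- ncol(M)
  # per-column IC, gap-weighted
  ic <- numeric(ncols)
  pwm_cols <- vector("list", ncols)
  for (j in seq_len(ncols)) {
    col <- M[, j]
    nongap <- col[col %in% AA_ALPHABET]
    if (!length(nongap)) { ic[j] <- 0; next }
    f <- as.numeric(table(factor(nongap, levels = AA_ALPHABET))) /
      length(nongap)
    ent <- -sum(ifelse(f > 0, f * log2(f), 0))
    ic[j] <- (log2(20) - ent) * (length(nongap) / nrow(M))
    pwm_cols[[j]] <- f
  }
  cand <- list()
  for (w in as.integer(widths)) {
    if (w > ncols) next
    run <- stats::filter(ic, rep(1 / w, w), sides = 1)
    for (s in seq_len(ncols - w + 1L)) {
      cand[[length(cand) + 1L]] <- list(start = s - 1L, width = w,
                                        ic_per_column = run[s + w - 1L])
    }
  }
  if (!length(cand)) return(list())
  scores <- vapply(cand, `[[`, 0, "ic_per_column")
  starts <- vapply(cand, `[[`, 0L, "start")
  widthv <- vapply(cand, `[[`, 0L, "width")
  ord <- order(-scores, starts, widthv)
  chosen <- list()
  taken <- rep(FALSE, ncols)
  for (i in ord) {
    s <- starts[i]; w <- widthv[i]
    span <- (s + 1L):(s + w)
    if (any(taken[span])) next
    taken[span] <- TRUE
    pwm <- do.call(rbind, pwm_cols[span])
    colnames(pwm) <- AA_ALPHABET
    cons <- paste(AA_ALPHABET[apply(pwm, 1, which.max)], collapse = "")
    chosen[[length(chosen) + 1L]] <- list(
      start = s, width = w, ic_per_column = scores[i],
      pwm = pwm, consensus = cons)
    if (length(chosen) >= k) break
  }
  chosen
}

#' Donor and acceptor splice-site logos
#'
#' Builds position-frequency matrices over fixed windows around the splice
#' sites of two-exon models: donor = last 3 exon nt + first 6 intron nt
#' (width 9), acceptor = last 12 intron nt + first 3 exon nt (width 15).
#'
#' @param models Gene models (only \code{complete_2exon} ones are used).
#' @param assembly Named character vector of contig sequences.
#' @return A list with elements \code{donor} and \code{acceptor}, each a list
#'   with \code{pfm} (width x 4 frequencies), \code{ic} (2 - entropy bits per
#'   position), \code{consensus} and \code{n}.
#' @export
splice_logo <- function(models, assembly) {
  spl <- Filter(function(m) identical(m$status, "complete_2exon"), models)
  if (!length(spl)) stop("no two-exon models: cannot build splice logos")
  donors <- character(0); acceptors <- character(0)
  for (m in spl) {
    contig <- assembly[[m$contig_id]]
    ex <- m$exons
    if (m$strand == "+") {
      d0 <- ex[[1]]$end          # 0-based start of the intron
      a1 <- ex[[2]]$start        # 0-based end(excl) of the intron
      don <- substr(contig, d0 - 3L + 1L, d0 + 6L)
      acc <- substr(contig, a1 - 12L + 1L, a1 + 3L)
    } else {
      # coding-strand windows on the reverse strand
      d0 <- ex[[1]]$start        # forward coord of intron end (excl on fwd)
      a1 <- ex[[2]]$end
      don <- reverse_complement(substr(contig, d0 - 6L + 1L, d0 + 3L))
      acc <- reverse_complement(substr(contig, a1 - 3L + 1L, a1 + 12L))
    }
    if (nchar(don) == 9L) donors <- c(donors, don)
    if (nchar(acc) == 15L) acceptors <- c(acceptors, acc)
  }
  list(donor = .dna_logo(donors), acceptor = .dna_logo(acceptors))
}

.dna_logo <- function(seqs) {
  M <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  bases <- c("A", "C", "G", "T")
  pfm <- t(vapply(seq_len(ncol(M)), function(j) {
    as.numeric(table(factor(M[, j], levels = bases))) / nrow(M)
  }, numeric(4)))
  colnames(pfm) <- bases
  ent <- apply(pfm, 1, function(f) -sum(ifelse(f > 0, f * log2(f), 0)))
  list(pfm = pfm, ic = 2 - ent,
       consensus = paste(bases[apply(pfm, 1, which.max)], collapse = ""),
       n = nrow(M))
}
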
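# Translated homology search: baits vs six-frame contig translations, hit
# merging into loci, and the positive/negative bait filter.

#' Search one contig with a set of bait proteins
#'
#' Aligns every bait against all six frame translations of the contig
#' (Smith--Waterman, affine gaps) and keeps hits whose Karlin--Altschul
#' E-value passes the looser of the two configured cutoffs. After each hit
#' the matched frame segment is masked and the frame re-scanned, so several
#' genes in the same frame are all found.
#'
#' @param baits Named character vector of bait proteins.
#' @param contig_seq Contig DNA string.
#' @param contig_id Contig identifier.
#' @param config A [search_config()].
#' @param role Label stored on each hit (\code{"positive"} or
#'   \code{"negative"}).
#' @return A data.frame of hits: \code{contig_id}, \code{bait_id},
#'   \code{role}, \code{frame}, \code{strand}, \code{start}, \code{end}
#'   (0-based half-open, forward strand), \code{qstart}, \code{qend} (bait
#'   span), \code{score}, \code{bitscore}, \code{evalue}.
#' @export
search_contig <- function(baits, contig_seq, contig_id = "contig",
                          config = search_config(), role = "positive") {
  if (nchar(contig_seq) < 3L) return(.empty_hits())
  frames <- six_frame_translate(contig_seq, id = contig_id)
  cutoff <- max(config$e_pos, config$e_neg)
  rows <- list()
  for (fr in frames) {
    n_res <- nchar(fr$protein)
    if (n_res == 0L) next
    for (b in seq_along(baits)) {
      bait <- baits[[b]]
      prot <- fr$protein
      min_score <- .score_cutoff(cutoff, nchar(bait), n_res, config)
      for (round in seq_len(config$max_hits_per_frame)) {
        # fast score+endpoint pass over the whole frame, then a traceback
        # alignment restricted to a window that safely contains the optimum
        se <- .local_score_end(bait, prot, config)
        if (se[1] < min_score) break
        w1 <- max(1L, as.integer(se[3]) - 3L * nchar(bait))
        al <- local_align(bait, substr(prot, w1, as.integer(se[3])), config)
        al$tstart <- al$tstart + w1 - 1L
        al$tend <- al$tend + w1 - 1L
        ev <- evalue(al$score, nchar(bait), n_res, config)
        if (ev > cutoff || al$score < min_score) break
        gi <- frame_interval(fr, al$tstart, al$tend)
        rows[[length(rows) + 1L]] <- data.frame(
          contig_id = contig_id, bait_id = names(baits)[b], role = role,
          frame = fr$frame, strand = fr$strand,
          start = gi$start, end = gi$end,
          qstart = al$qstart, qend = al$qend, bait_len = nchar(bait),
          score = al$score,
          bitscore = (config$lambda * al$score - log(config$K)) / log(2),
          evalue = ev, stringsAsFactors = FALSE)
        # mask the matched segment and rescan for further genes in this frame
        prot <- paste0(substr(prot, 1L, al$tstart - 1L),
                       strrep("X", al$tend - al$tstart + 1L),
                       substr(prot, al$tend + 1L, n_res))
      }
    }
  }
  if (!length(rows)) return(.empty_hits())
  do.call(rbind, rows)
}

.empty_hits <- function() {
  data.frame(contig_id = character(0), bait_id = character(0),
             role = character(0), frame = integer(0), strand = character(0),
             start = integer(0), end = integer(0), qstart = integer(0),
             qend = integer(0), bait_len = integer(0), score = numeric(0),
             bitscore = numeric(0), evalue = numeric(0),
             stringsAsFactors = FALSE)
}

#' Search a whole assembly with the positive bait set
#'
#' @param assembly Named character vector of contig sequences.
#' @param baits Named character vector of positive bait proteins.
#' @param config A [search_config()].
#' @return Row-bound [search_contig()] hits over all contigs.
#' @export
search_assembly <- function(assembly, baits, config = search_config()) {
  out <- lapply(names(assembly), function(id)
    search_contig(baits, assembly[[id]], id, config, role = "positive"))
  do.call(rbind, out)
}

#' Merge hits into candidate loci
#'
#' Hits on the same contig and strand whose genomic intervals are within
#' \code{merge_gap} nt of each other are merged into one locus (the union
#' span). A two-exon gene typically leaves one strong hit per exon, often in
#' different frames; merging reunites them.
#'
#' @param hits A hit data.frame from [search_contig()]/[search_assembly()].
#' @param merge_gap Maximum nt gap bridged (default from [search_config()]).
#' @return A list of loci; each locus is a list with \code{contig_id},
#'   \code{strand}, \code{start}, \code{end}, \code{hits} (the member rows),
#'   \code{best_positive} (row index of the minimum-E positive hit),
#'   \code{best_positive_evalue} and \code{best_negative_evalue} (NA until
#'   [bait_filter()] fills it).
#' @export
merge_hits <- function(hits, merge_gap = 2000) {
  if (!nrow(hits)) return(list())
  ord <- order(hits$contig_id, hits$strand, hits$start)
  hits <- hits[ord, , drop = FALSE]
  loci <- list()
  cur <- NULL
  flush <- function(cur, loci) {
    if (is.null(cur)) return(loci)
    pos <- cur$hits[cur$hits$role == "positive", , drop = FALSE]
    bp <- if (nrow(pos)) pos[which.min(pos$evalue), , drop = FALSE] else NULL
    cur$best_positive <- bp
    cur$best_positive_evalue <- if (is.null(bp)) NA_real_ else bp$evalue
    cur$best_negative_evalue <- NA_real_
    c(loci, list(cur))
  }
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, , drop = FALSE]
    if (!is.null(cur) && h$contig_id == cur$contig_id &&
        h$strand == cur$strand && h$start <= cur$end + merge_gap) {
      cur$end <- max(cur$end, h$end)
      cur$hits <- rbind(cur$hits, h)
    } else {
      loci <- flush(cur, loci)
      cur <- list(contig_id = h$contig_id, strand = h$strand,
                  start = h$start, end = h$end, hits = h)
    }
  }
  flush(cur, loci)
}

#' Score candidate loci against the negative bait set
#'
#' Aligns each negative bait against the (padded) locus region on both
#' strands and records the best (lowest) E-value per locus. Only candidate
#' regions are scanned, mirroring the two-pass bait strategy.
#'
#' @param loci Loci from [merge_hits()].
#' @param assembly Named character vector of contig sequences.
#' @param neg_baits Named character vector of negative bait proteins.
#' @param config A [search_config()].
#' @param pad Nt added on both sides of the locus span before scanning.
#' @return The loci with \code{best_negative_evalue} filled in.
#' @export
score_negative <- function(loci, assembly, neg_baits,
                           config = search_config(), pad = 1000L) {
  for (k in seq_along(loci)) {
    loc <- loci[[k]]
    contig <- assembly[[loc$contig_id]]
    s <- max(0L, loc$start - pad)
    e <- min(nchar(contig), loc$end + pad)
    region <- substr(contig, s + 1L, e)
    best <- Inf
    frames <- six_frame_translate(region, id = loc$contig_id)
    for (fr in frames) {
      if (nchar(fr$protein) == 0L) next
      for (b in seq_along(neg_baits)) {
        sc <- .local_score(neg_baits[[b]], fr$protein, config)
        ev <- evalue(sc, nchar(neg_baits[[b]]), nchar(fr$protein), config)
        if (ev < best) best <- ev
      }
    }
    loci[[k]]$best_negative_evalue <- if (is.finite(best)) best else NA_real_
  }
  loci
}

#' Positive/negative bait filter
#'
#' Retains loci with (1) a positive-bait match at \code{E <= e_pos} and
#' (2) no negative-bait match at \code{E <= e_neg}.
#'
#' @param loci Loci from [merge_hits()], with negative E-values filled by
#'   [score_negative()] (an \code{NA} negative E-value means no negative hit
#'   was scored).
#' @param config A [search_config()].
#' @return A list with \code{retained} (loci) and \code{rejected} (data.frame
#'   of contig/strand/span plus a \code{reason}:
#'   \code{"fails_positive_cutoff"} or \code{"negative_bait_match"}).
#' @export
bait_filter <- function(loci, config = search_config()) {
  retained <- list()
  rej <- list()
  for (loc in loci) {
    pos_ok <- !is.na(loc$best_positive_evalue) &&
      loc$best_positive_evalue <= config$e_pos
    neg_hit <- !is.na(loc$best_negative_evalue) &&
      loc$best_negative_evalue <= config$e_neg
    if (pos_ok && !neg_hit) {
      retained[[length(retained) + 1L]] <- loc
    } else {
      rej[[length(rej) + 1L]] <- data.frame(
        contig_id = loc$contig_id, strand = loc$strand,
        start = loc$start, end = loc$end,
        reason = if (!pos_ok) "fails_positive_cutoff"
                 else "negative_bait_match",
        stringsAsFactors = FALSE)
    }
  }
  list(retained = retained,
       rejected = if (length(rej)) do.call(rbind, rej) else
         data.frame(contig_id = character(0), strand = character(0),
                    start = integer(0), end = integer(0),
                    reason = character(0), stringsAsFactors = FALSE))
}
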
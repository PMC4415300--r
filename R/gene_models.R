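# Gene-model reconstruction: single-exon ORFs, two-exon spliced models with
# canonical GT-AG phase-0 introns, disruption detection and status calls.

#' Gene-model reconstruction parameters
#'
#' @param min_codons,max_codons Accepted ORF length window (codons, excluding
#'   the stop). Receptors of this family run ~330-350 aa.
#' @param donor_window Codon range (1-based, relative to the ATG) in which the
#'   phase-0 donor site is searched first; introns of this family fall close
#'   to codon 55.
#' @param donor_window_ext Fallback codon range searched when the primary
#'   window yields no model; such models are flagged \code{atypical_junction}.
#' @param intron_range Allowed intron length in nt.
#' @param edge_margin Maximum distance (nt) between an alignment end and a
#'   contig boundary for an incomplete gene to be called an edge gene.
#' @param min_hit_overlap Minimum fraction of the best positive hit a
#'   single-exon ORF must overlap.
#' @param single_exon_accept_cov Bait-coverage fraction above which a
#'   single-exon model is accepted without attempting a spliced model.
#' @param min_model_coverage Minimum bait-coverage fraction for any model to
#'   be called complete; models below it fall through to the
#'   pseudogene/edge/fragment classification.
#' @param junction_tie_margin Score margin (substitution-matrix units) within
#'   which competing splice candidates count as near-tied and the junction
#'   composition prior (aromatic before, basic after the intron) decides.
#' @param upstream_pad,downstream_pad Nt of context added around a locus (in
#'   coding orientation) before model search; the upstream pad must bridge
#'   the longest intron plus exon 1.
#' @return A list of class \code{model_config}.
#' @export
model_config <- function(min_codons = 250L, max_codons = 400L,
                         donor_window = c(40L, 80L),
                         donor_window_ext = c(10L, 150L),
                         intron_range = c(50L, 5000L),
                         edge_margin = 10L, min_hit_overlap = 0.8,
                         single_exon_accept_cov = 0.95,
                         min_model_coverage = 0.9,
                         junction_tie_margin = 12,
                         upstream_pad = 6000L, downstream_pad = 1500L) {
  structure(as.list(environment()), class = "model_config")
}

# Locus region in coding orientation with coordinate mapping back to the
# forward strand. r is 0-based within the region string.
.locus_region <- function(locus, contig, mcfg) {
  L <- nchar(contig)
  if (locus$strand == "+") {
    s <- max(0L, locus$start - mcfg$upstream_pad)
    e <- min(L, locus$end + mcfg$downstream_pad)
  } else {
    s <- max(0L, locus$start - mcfg$downstream_pad)
    e <- min(L, locus$end + mcfg$upstream_pad)
  }
  seq <- .extract_strand(contig, s, e, locus$strand)
  list(seq = seq, start = s, end = e, strand = locus$strand,
       contig_length = L,
       # forward-strand half-open interval of region positions [r1, r2)
       to_fwd = if (locus$strand == "+")
         function(r1, r2) c(s + r1, s + r2)
       else
         function(r1, r2) c(e - r2, e - r1))
}

.bait_of <- function(locus, baits) {
  bp <- locus$best_positive
  baits[[bp$bait_id]]
}

# All ORFs (ATG..stop) in the region within the codon window; returns a list
# of candidates with region coordinates. Among the ATGs of one stop-free
# segment the one whose protein length is closest to target_len wins
# (an upstream in-frame ATG only adds unaligned leader).
.find_orfs <- function(region, mcfg, target_len = NULL) {
  n <- nchar(region)
  out <- list()
  for (f in 0:2) {
    ncod <- (n - f) %/% 3L
    if (ncod < 1L) next
    prot <- translate_cds(substr(region, f + 1L, f + 3L * ncod))
    stops <- c(gregexpr("\\*", prot)[[1]])
    stops <- stops[stops > 0]
    seg_start <- 1L
    for (sp in stops) {
      seg <- substr(prot, seg_start, sp - 1L)
      m <- gregexpr("M", seg, fixed = TRUE)[[1]]
      if (m[1] > 0) {
        lens <- (sp - 1L) - (seg_start + m - 1L) + 1L  # codons, no stop
        feas <- which(lens >= mcfg$min_codons & lens <= mcfg$max_codons)
        if (length(feas)) {
          pick <- if (is.null(target_len)) feas[1]
                  else feas[which.min(abs(lens[feas] - target_len))]
          atg <- m[pick]; len <- lens[pick]
          c0 <- seg_start + atg - 1L                       # 1-based codon
          r1 <- f + 3L * (c0 - 1L)                         # 0-based region nt
          r2 <- f + 3L * sp                                # includes stop
          out[[length(out) + 1L]] <- list(
            r1 = r1, r2 = r2, codons = len,
            protein = substr(prot, c0, sp - 1L))
        }
      }
      seg_start <- sp + 1L
    }
  }
  out
}

#' Reconstruct a single-exon gene model at a locus
#'
#' Scans the locus strand for complete ORFs (ATG to stop) in the configured
#' length window that overlap at least \code{min_hit_overlap} of the best
#' positive hit; the longest such ORF wins (ties: smallest start).
#'
#' @param locus A retained locus (from [bait_filter()]).
#' @param contig The contig DNA string.
#' @param bait The best-matching positive bait protein.
#' @param mcfg A [model_config()].
#' @param scfg A [search_config()] (alignment scoring).
#' @return A gene-model list (status \code{complete_1exon}) or \code{NULL}.
#' @export
build_single_exon_model <- function(locus, contig, bait,
                                    mcfg = model_config(),
                                    scfg = search_config()) {
  reg <- .locus_region(locus, contig, mcfg)
  orfs <- .find_orfs(reg$seq, mcfg, target_len = nchar(bait))
  if (!length(orfs)) return(NULL)
  bp <- locus$best_positive
  cand <- list()
  for (o in orfs) {
    fwd <- reg$to_fwd(o$r1, o$r2)
    ov <- min(fwd[2], bp$end) - max(fwd[1], bp$start)
    if (ov < mcfg$min_hit_overlap * (bp$end - bp$start)) next
    cand[[length(cand) + 1L]] <- c(o, list(fwd = fwd))
  }
  if (!length(cand)) return(NULL)
  lens <- vapply(cand, `[[`, 0L, "codons")
  starts <- vapply(cand, function(x) x$fwd[1], 0)
  best <- cand[[order(-lens, starts)[1]]]
  al <- local_align(bait, best$protein, scfg)
  cds <- substr(reg$seq, best$r1 + 1L, best$r2)
  list(contig_id = locus$contig_id, strand = locus$strand,
       exons = list(list(start = best$fwd[1], end = best$fwd[2])),
       cds = cds, protein = best$protein,
       status = "complete_1exon", pseudo_type = "none",
       junction = NULL, intron_codon_index = NULL, splice = NULL,
       atypical_junction = FALSE, bait_id = bp$bait_id,
       score = al$score,
       bait_coverage = (al$qend - al$qstart + 1) / nchar(bait))
}

# next in-frame stop lookup: for each frame f (0:2) a function mapping a
# 0-based region position p (p %% 3 == f) to the 0-based position of the next
# stop codon at/after p, or NA.
.stop_index <- function(region) {
  n <- nchar(region)
  lapply(0:2, function(f) {
    ncod <- (n - f) %/% 3L
    if (ncod < 1L) return(integer(0))
    prot <- translate_cds(substr(region, f + 1L, f + 3L * ncod))
    stops <- c(gregexpr("\\*", prot)[[1]])
    stops <- stops[stops > 0]
    f + 3L * (stops - 1L)  # 0-based nt position of each stop codon
  })
}

#' Infer a two-exon spliced gene model
#'
#' Searches for exon 1 starting at an ATG, a canonical \code{GT} donor at a
#' codon boundary (phase 0) inside the donor window, an \code{AG} acceptor
#' within the intron-length range, and an in-frame exon 2 running to a stop,
#' with total length inside the codon window. Among candidates the
#' bait-alignment score of the spliced protein decides; ties go to the
#' shorter intron, then the smaller donor coordinate.
#'
#' @inheritParams build_single_exon_model
#' @return A gene-model list (status \code{complete_2exon}) with splice-site
#'   and junction-dipeptide annotation, or \code{NULL}.
#' @export
infer_spliced_model <- function(locus, contig, bait,
                                mcfg = model_config(),
                                scfg = search_config()) {
  reg <- .locus_region(locus, contig, mcfg)
  res <- .spliced_search(reg, bait, mcfg, scfg, mcfg$donor_window)
  atyp <- FALSE
  if (is.null(res)) {
    res <- .spliced_search(reg, bait, mcfg, scfg, mcfg$donor_window_ext)
    atyp <- TRUE
  }
  if (is.null(res)) return(NULL)
  bp <- locus$best_positive
  ex1 <- reg$to_fwd(res$a, res$d)
  ex2 <- reg$to_fwd(res$acc2, res$stop_end)
  exons <- list(list(start = ex1[1], end = ex1[2]),
                list(start = ex2[1], end = ex2[2]))
  cds <- paste0(substr(reg$seq, res$a + 1L, res$d),
                substr(reg$seq, res$acc2 + 1L, res$stop_end))
  protein <- translate_cds(cds)
  protein <- substr(protein, 1L, nchar(protein) - 1L)
  jl <- substr(protein, res$j, res$j)
  jr <- substr(protein, res$j + 1L, res$j + 1L)
  donor_fwd <- reg$to_fwd(res$d, res$d + 2L)
  acc_fwd <- reg$to_fwd(res$acc2 - 2L, res$acc2)
  list(contig_id = locus$contig_id, strand = locus$strand,
       exons = exons, cds = cds, protein = protein,
       status = "complete_2exon", pseudo_type = "none",
       junction = paste0(jl, jr), intron_codon_index = res$j,
       splice = list(donor_pos = donor_fwd[1], acceptor_pos = acc_fwd[1],
                     donor_dinuc = substr(reg$seq, res$d + 1L, res$d + 2L),
                     acceptor_dinuc = substr(reg$seq, res$acc2 - 1L, res$acc2),
                     intron_length = res$acc2 - res$d),
       atypical_junction = atyp, bait_id = bp$bait_id,
       score = res$score,
       bait_coverage = res$coverage)
}

.spliced_search <- function(reg, bait, mcfg, scfg, jwin) {
  region <- reg$seq
  n <- nchar(region)
  stop_idx <- .stop_index(region)
  ag_pos <- c(gregexpr("AG", region, fixed = TRUE)[[1]])  # 1-based
  ag_pos <- ag_pos[ag_pos > 0]
  atg_pos <- c(gregexpr("ATG", region, fixed = TRUE)[[1]])
  atg_pos <- atg_pos[atg_pos > 0] - 1L                    # 0-based
  cands <- list()
  for (a in atg_pos) {
    # exon-1 codons 1..j; donor GT immediately after codon j
    f <- a %% 3L
    stops_f <- stop_idx[[f + 1L]]
    first_stop <- stops_f[stops_f >= a][1]
    max_j_nostop <- if (is.na(first_stop)) Inf else (first_stop - a) %/% 3L
    for (j in jwin[1]:jwin[2]) {
      if (j > max_j_nostop) break
      d <- a + 3L * j                     # 0-based donor position (first nt of intron)
      if (d + 2L > n) break
      if (substr(region, d + 1L, d + 2L) != "GT") next
      # acceptor AG ending an intron of allowed length:
      # exon 2 starts (0-based) at q + 1 for a 1-based AG match at q
      acc <- ag_pos[ag_pos >= d + mcfg$intron_range[1] - 1L &
                    ag_pos <= d + mcfg$intron_range[2] - 1L &
                    ag_pos + 1L <= n - 3L]
      for (q in acc) {
        e2 <- q + 1L                       # 0-based start of exon 2
        ilen <- e2 - d
        f2 <- e2 %% 3L
        stops2 <- stop_idx[[f2 + 1L]]
        st <- stops2[stops2 >= e2][1]
        if (is.na(st)) next
        total <- j + (st - e2) %/% 3L
        if (total < mcfg$min_codons || total > mcfg$max_codons) next
        cds <- paste0(substr(region, a + 1L, d),
                      substr(region, e2 + 1L, st + 3L))
        prot <- translate_cds(cds)
        prot <- substr(prot, 1L, nchar(prot) - 1L)
        al <- local_align(bait, prot, scfg)
        jl <- substr(prot, j, j); jr <- substr(prot, j + 1L, j + 1L)
        cands[[length(cands) + 1L]] <-
          list(a = a, d = d, j = j, acc2 = e2, stop_end = st + 3L,
               score = al$score,
               arobas = (jl %in% c("F", "Y", "W")) && (jr %in% c("R", "K", "H")),
               lenoff = abs(total - nchar(bait)), ilen = ilen,
               coverage = (al$qend - al$qstart + 1) / nchar(bait))
      }
    }
  }
  if (!length(cands)) return(NULL)
  # near-tied candidates (within junction_tie_margin of the best score) are
  # re-ranked by the family's junction signature: an aromatic residue before
  # and a basic residue after the intron; score then breaks remaining ties,
  # then the shorter intron, then the smaller donor coordinate
  smax <- max(vapply(cands, `[[`, 0, "score"))
  near <- Filter(function(cn) cn$score >= smax - mcfg$junction_tie_margin, cands)
  keys <- lapply(near, function(cn)
    c(-as.numeric(cn$arobas), cn$lenoff, -cn$score, cn$ilen, cn$d))
  best <- near[[1L]]; bkey <- keys[[1L]]
  for (k in seq_along(near)[-1L]) {
    if (.lex_less(keys[[k]], bkey)) { best <- near[[k]]; bkey <- keys[[k]] }
  }
  best
}

.lex_less <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  FALSE
}

#' Detect reading-frame disruptions at a locus
#'
#' Aligns the bait against the three coding-strand frame translations of the
#' locus region. An in-frame stop aligned within the bait body is reported as
#' \code{in_frame_stop}. A frame change between complementary bait segments
#' is reported as \code{frameshift} only when the two genomic segments are
#' contiguous (separated by less than the minimum intron length); a frame
#' change across a wider genomic gap is what an intron looks like and is not
#' a disruption. Positions are approximate codon indices on the bait.
#'
#' @inheritParams build_single_exon_model
#' @return A list of disruptions, each \code{list(kind, position, detail)};
#'   empty for an intact gene.
#' @export
detect_disruptions <- function(locus, contig, bait,
                               mcfg = model_config(),
                               scfg = search_config()) {
  mcfg2 <- mcfg
  mcfg2$upstream_pad <- 300L; mcfg2$downstream_pad <- 300L
  reg <- .locus_region(locus, contig, mcfg2)
  n <- nchar(reg$seq)
  als <- list()
  for (f in 0:2) {
    ncod <- (n - f) %/% 3L
    if (ncod < 1L) next
    prot <- translate_cds(substr(reg$seq, f + 1L, f + 3L * ncod))
    al <- local_align(bait, prot, scfg)
    al$frame <- f; al$prot <- prot
    als[[length(als) + 1L]] <- al
  }
  if (!length(als)) return(list())
  scores <- vapply(als, `[[`, 0, "score")
  ord <- order(-scores)
  main <- als[[ord[1]]]
  out <- list()
  # in-frame stops aligned against a bait residue in the dominant frame
  # (stops inside alignment gaps belong to skipped segments such as introns
  # and are not disruptions)
  qa <- strsplit(main$qaln, "", fixed = TRUE)[[1]]
  ta <- strsplit(main$taln, "", fixed = TRUE)[[1]]
  # per-column alignment scores: a stop is only called inside well-supported
  # alignment (both flanks contribute real score), not in the weak tails a
  # local alignment can drag over intron or flank sequence
  blo <- .blosum62()
  colscore <- numeric(length(qa))
  for (k in seq_along(qa)) {
    colscore[k] <- if (qa[k] == "-" || ta[k] == "-") -scfg$gap_extend
                   else blo[qa[k], ta[k]]
  }
  cum <- cumsum(colscore)
  total <- cum[length(cum)]
  support <- 40
  qpos <- main$qstart - 1L
  for (k in seq_along(qa)) {
    if (qa[k] != "-") qpos <- qpos + 1L
    if (ta[k] == "*" && qa[k] != "-" && qpos < nchar(bait) &&
        cum[k] >= support && total - cum[k] >= support) {
      out[[length(out) + 1L]] <- list(kind = "in_frame_stop",
                                      position = qpos,
                                      detail = "internal stop codon")
    }
  }
  # frameshift: a second frame covering a complementary part of the bait,
  # genomically contiguous with the main segment
  cov_main <- main$qend - main$qstart + 1L
  if (cov_main < 0.9 * nchar(bait)) {
    thr <- .score_cutoff(1e-6, nchar(bait), n / 3, scfg)
    for (k in ord[-1]) {
      alt <- als[[k]]
      if (alt$score < thr) next
      new_cov <- max(0L, alt$qend - max(alt$qstart, main$qend)) +
                 max(0L, min(alt$qend, main$qstart) - alt$qstart)
      if (new_cov < 0.1 * nchar(bait)) next
      # region-nt coordinates of the facing segment ends
      if (alt$qstart > main$qstart) {
        gap_nt <- (alt$frame + 3L * (alt$tstart - 1L)) -
                  (main$frame + 3L * main$tend)
        boundary <- round((main$qend + alt$qstart) / 2)
      } else {
        gap_nt <- (main$frame + 3L * (main$tstart - 1L)) -
                  (alt$frame + 3L * alt$tend)
        boundary <- round((alt$qend + main$qstart) / 2)
      }
      # alignment slop makes the two segments overlap (negative gap) at a
      # real frameshift; a positive gap approaching the minimum intron
      # length is what an intron looks like and is vetoed
      if (gap_nt >= mcfg$intron_range[1] / 2) next
      out[[length(out) + 1L]] <- list(kind = "frameshift",
                                      position = as.integer(boundary),
                                      detail = sprintf("frame %d -> %d",
                                                       main$frame, alt$frame))
      break
    }
  }
  out
}

#' Classify the status of a locus
#'
#' @param locus A retained locus.
#' @param model A complete gene model or \code{NULL}.
#' @param disruptions Result of [detect_disruptions()] (may be empty).
#' @param contig_length Length of the contig (nt).
#' @param mcfg A [model_config()].
#' @return A list with \code{status} (\code{complete_1exon},
#'   \code{complete_2exon}, \code{pseudogene}, \code{edge}, \code{fragment})
#'   and \code{pseudo_type} (\code{frameshift}, \code{in_frame_stop},
#'   \code{both}, \code{none}).
#' @export
classify_status <- function(locus, model, disruptions, contig_length,
                            mcfg = model_config()) {
  if (!is.null(model))
    return(list(status = model$status, pseudo_type = "none"))
  bp <- locus$best_positive
  at_edge <- (bp$start <= mcfg$edge_margin &&
                .missing_terminal(bp, locus$strand, "upstream")) ||
             (bp$end >= contig_length - mcfg$edge_margin &&
                .missing_terminal(bp, locus$strand, "downstream"))
  if (length(disruptions) && !at_edge) {
    kinds <- unique(vapply(disruptions, `[[`, "", "kind"))
    pt <- if (all(kinds == "frameshift")) "frameshift"
          else if (all(kinds == "in_frame_stop")) "in_frame_stop"
          else "both"
    return(list(status = "pseudogene", pseudo_type = pt))
  }
  if (at_edge) return(list(status = "edge", pseudo_type = "none"))
  list(status = "fragment", pseudo_type = "none")
}

# does the hit lack bait coverage on the side facing the given genomic
# direction? ("upstream" = towards forward position 0)
.missing_terminal <- function(hit, strand, side, min_missing = 10L) {
  n_missing <- hit$qstart - 1L                    # bait residues missing at N
  c_missing <- hit$bait_len - hit$qend            # missing at C
  towards_n <- (strand == "+" && side == "upstream") ||
               (strand == "-" && side == "downstream")
  if (towards_n) n_missing >= min_missing else c_missing >= min_missing
}

#' Build and classify gene models for all retained loci
#'
#' Runs single-exon and spliced reconstruction, falls back to disruption
#' detection, classifies each locus and assembles partial-model records for
#' pseudogenes, edge genes and fragments.
#'
#' @param loci Retained loci from [bait_filter()].
#' @param assembly Named character vector of contig sequences.
#' @param baits Named character vector of positive bait proteins.
#' @param mcfg A [model_config()].
#' @param scfg A [search_config()].
#' @return A list of gene-model lists, each with at least \code{contig_id},
#'   \code{strand}, \code{exons}, \code{status}, \code{pseudo_type},
#'   \code{bait_id}.
#' @export
build_gene_models <- function(loci, assembly, baits,
                              mcfg = model_config(),
                              scfg = search_config()) {
  models <- vector("list", length(loci))
  for (k in seq_along(loci)) {
    loc <- loci[[k]]
    contig <- assembly[[loc$contig_id]]
    bait <- .bait_of(loc, baits)
    m1 <- build_single_exon_model(loc, contig, bait, mcfg, scfg)
    model <- NULL
    disr <- list()
    if (!is.null(m1) && m1$bait_coverage >= mcfg$single_exon_accept_cov) {
      model <- m1
    } else {
      # a frameshift or in-frame stop rules the locus out before any spliced
      # rescue: a contiguous frame switch must not be modelled as an intron
      disr <- detect_disruptions(loc, contig, bait, mcfg, scfg)
      if (!length(disr)) {
        m2 <- infer_spliced_model(loc, contig, bait, mcfg, scfg)
        model <- if (is.null(m1)) m2
                 else if (is.null(m2)) m1
                 else if (m2$score > m1$score) m2 else m1
      }
    }
    if (!is.null(model) &&
        model$bait_coverage < mcfg$min_model_coverage) model <- NULL
    if (!is.null(model)) disr <- list()
    cls <- classify_status(loc, model, disr, nchar(contig), mcfg)
    if (is.null(model)) {
      bp <- loc$best_positive
      model <- list(contig_id = loc$contig_id, strand = loc$strand,
                    exons = list(list(start = bp$start, end = bp$end)),
                    cds = NULL, protein = NULL,
                    junction = NULL, intron_codon_index = NULL, splice = NULL,
                    atypical_junction = FALSE, bait_id = bp$bait_id,
                    score = bp$score, bait_coverage =
                      (bp$qend - bp$qstart + 1) / bp$bait_len)
    }
    model$status <- cls$status
    model$pseudo_type <- cls$pseudo_type
    model$disruptions <- disr
    models[[k]] <- model
  }
  models
}

#' Name a gene by species, status, family and index
#'
#' Names follow the field's scheme: species symbol, \code{TAR}, a status
#' letter (\code{s} spliced, \code{p} pseudogene, \code{e} edge,
#' \code{f} fragment; none for complete single-exon genes), a dot, the family
#' letter and a zero-padded three-digit index, e.g. \code{BriTARe.A005}.
#'
#' @param species Species symbol (e.g. \code{"Bur"}).
#' @param status One of the five gene statuses.
#' @param family Family letter \code{A}-\code{Z}, or \code{"U"} (unassigned).
#' @param index Integer 1-999.
#' @return The gene name string.
#' @examples
#' name_gene("Bri", "edge", "A", 5)          # "BriTARe.A005"
#' name_gene("Bur", "complete_2exon", "A", 16)  # "BurTARs.A016"
#' @export
name_gene <- function(species, status, family, index) {
  if (index < 1 || index > 999) stop("gene index out of range 1-999")
  if (!grepl("^[A-Z]$", family)) stop("family must be a single letter A-Z")
  letter <- switch(status,
                   complete_1exon = "",
                   complete_2exon = "s",
                   pseudogene = "p",
                   edge = "e",
                   fragment = "f",
                   stop("unknown status: ", status))
  sprintf("%sTAR%s.%s%03d", species, letter, family, index)
}

#' Junction-dipeptide census
#'
#' Counts the dipeptides encoded across the splice junction of two-exon
#' models and the fraction with an aromatic (F/Y/W) left residue and a basic
#' (R/K/H) right residue.
#'
#' @param models A list of gene models ([build_gene_models()]).
#' @return A list with \code{counts} (named integer vector, decreasing),
#'   \code{n} and \code{aromatic_basic_fraction} (NaN when no spliced model).
#' @export
junction_census <- function(models) {
  j <- unlist(lapply(models, function(m)
    if (identical(m$status, "complete_2exon")) m$junction else NULL))
  if (!length(j))
    return(list(counts = integer(0), n = 0L, aromatic_basic_fraction = NaN))
  counts <- sort(table(j), decreasing = TRUE)
  arom <- substr(j, 1, 1) %in% c("F", "Y", "W") &
          substr(j, 2, 2) %in% c("R", "K", "H")
  list(counts = stats::setNames(as.integer(counts), names(counts)),
       n = length(j), aromatic_basic_fraction = mean(arom))
}

#' Contig adjacency and orientation report
#'
#' For every pair of neighbouring models on a contig, reports the orientation
#' pattern and the intergenic distance.
#'
#' @param models A list of named gene models.
#' @return A data.frame: \code{contig_id}, \code{gene1}, \code{gene2},
#'   \code{orientation} (\code{tail-to-head}, \code{head-to-head},
#'   \code{tail-to-tail}), \code{distance} (nt; 0 with \code{overlap = TRUE}
#'   for overlapping models).
#' @export
adjacency_report <- function(models) {
  if (!length(models)) return(.empty_adjacency())
  df <- data.frame(
    name = vapply(models, function(m) m$name %||% "", ""),
    contig_id = vapply(models, `[[`, "", "contig_id"),
    strand = vapply(models, `[[`, "", "strand"),
    start = vapply(models, function(m)
      min(vapply(m$exons, `[[`, 0, "start")), 0),
    end = vapply(models, function(m)
      max(vapply(m$exons, `[[`, 0, "end")), 0),
    stringsAsFactors = FALSE)
  rows <- list()
  for (cid in unique(df$contig_id)) {
    d <- df[df$contig_id == cid, , drop = FALSE]
    if (nrow(d) < 2) next
    d <- d[order(d$start), , drop = FALSE]
    for (i in seq_len(nrow(d) - 1L)) {
      s1 <- d$strand[i]; s2 <- d$strand[i + 1L]
      orient <- if (s1 == s2) "tail-to-head"
                else if (s1 == "+" && s2 == "-") "tail-to-tail"
                else "head-to-head"
      gap <- d$start[i + 1L] - d$end[i]
      rows[[length(rows) + 1L]] <- data.frame(
        contig_id = cid, gene1 = d$name[i], gene2 = d$name[i + 1L],
        orientation = orient, distance = max(0, gap), overlap = gap < 0,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(.empty_adjacency())
  do.call(rbind, rows)
}

.empty_adjacency <- function() {
  data.frame(contig_id = character(0), gene1 = character(0),
             gene2 = character(0), orientation = character(0),
             distance = numeric(0), overlap = logical(0),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
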
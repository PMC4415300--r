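#' dN/dS configuration
#'
#' Parameters of the Nei--Gojobori pairwise estimator with Zhang's
#' transition/transversion weighting of potential-site counts.
#'
#' @param R Transition/transversion weight applied when counting potential
#'   synonymous sites: each of a codon position's three alternative bases is
#'   weighted \code{R} if it is a transition, 1 if a transversion.
#'   \code{R = 1} is the unmodified NG86 estimator.
#' @param stop_pathways How mutational pathways passing through a stop codon
#'   are treated when averaging pathway differences: \code{"exclude"}
#'   (default; excluded and the remaining pathways renormalized) or
#'   \code{"count"} (steps through stops counted like any other).
#' @param max_p Upper bound of the Jukes--Cantor domain; proportions at or
#'   above it are flagged rather than corrected.
#' @return A list of class \code{dnds_config}.
#' @export
dnds_config <- function(R = 1, stop_pathways = c("exclude", "count"),
                        max_p = 0.749999) {
  stopifnot(is.numeric(R), R >= 0)
  structure(list(R = R, stop_pathways = match.arg(stop_pathways),
                 max_p = max_p), class = "dnds_config")
}

.BASES <- c("A", "C", "G", "T")
.is_transition <- function(a, b) {
  (a %in% c("A", "G") && b %in% c("A", "G")) ||
    (a %in% c("C", "T") && b %in% c("C", "T"))
}
.STOPS <- c("TAA", "TAG", "TGA")
.is_stop <- function(codon) codon %in% .STOPS

.aa_of <- function(codon) .codon_table[[codon]]

.check_sense_codon <- function(codon) {
  if (!grepl("^[ACGT]{3}$", codon))
    stop("not an unambiguous codon: ", codon)
  if (.is_stop(codon))
    stop("stop codon not allowed here: ", codon)
  invisible(codon)
}

#' Potential synonymous/nonsynonymous sites of a codon
#'
#' For each of the three positions, the three alternative bases are weighted
#' \code{R} (transition) or 1 (transversion); the position's synonymous-site
#' contribution is the weighted fraction of alternatives that preserve the
#' amino acid. Changes creating a stop codon count as nonsynonymous.
#' \code{s + n = 3} for every codon and every \code{R}.
#'
#' @param codon A sense codon (3-letter DNA string, no \code{N}).
#' @param R Transition/transversion weight (see [dnds_config()]).
#' @return A list with \code{s} and \code{n}.
#' @examples
#' codon_site_counts("TTT")          # s = 1/3
#' codon_site_counts("TTT", R = 2)   # s = 0.5
#' @export
codon_site_counts <- function(codon, R = 1) {
  .check_sense_codon(codon)
  aa0 <- .aa_of(codon)
  ch <- strsplit(codon, "", fixed = TRUE)[[1]]
  s <- 0
  for (pos in 1:3) {
    wsum <- 0; wsyn <- 0
    for (b in setdiff(.BASES, ch[pos])) {
      mut <- ch; mut[pos] <- b
      mutc <- paste(mut, collapse = "")
      w <- if (.is_transition(ch[pos], b)) R else 1
      wsum <- wsum + w
      if (!.is_stop(mutc) && .aa_of(mutc) == aa0) wsyn <- wsyn + w
    }
    s <- s + if (wsum > 0) wsyn / wsum else 0
  }
  list(s = s, n = 3 - s)
}

#' Pathway-averaged synonymous/nonsynonymous differences between two codons
#'
#' Averages, over all orderings of the differing positions (1, 2 or 6
#' pathways), the number of synonymous and nonsynonymous single-base steps.
#' Pathways passing through a stop codon are excluded and the average
#' renormalized (configurable); if every pathway is blocked the estimator
#' falls back to counting them.
#'
#' @param codon1,codon2 Sense codons.
#' @param stop_pathways \code{"exclude"} or \code{"count"}.
#' @return A list with \code{sd} and \code{nd}; \code{sd + nd} equals the
#'   number of differing positions.
#' @examples
#' pathway_differences("TTT", "GTA")  # sd = 0.5, nd = 1.5
#' @export
pathway_differences <- function(codon1, codon2,
                                stop_pathways = c("exclude", "count")) {
  stop_pathways <- match.arg(stop_pathways)
  .check_sense_codon(codon1)
  .check_sense_codon(codon2)
  c1 <- strsplit(codon1, "", fixed = TRUE)[[1]]
  c2 <- strsplit(codon2, "", fixed = TRUE)[[1]]
  diffpos <- which(c1 != c2)
  nd_tot <- length(diffpos)
  if (nd_tot == 0L) return(list(sd = 0, nd = 0))
  perms <- .permutations(diffpos)
  sds <- numeric(0); nds <- numeric(0)
  for (ord in perms) {
    cur <- c1; sd <- 0; nd <- 0; blocked <- FALSE
    for (pos in ord) {
      nxt <- cur; nxt[pos] <- c2[pos]
      nxtc <- paste(nxt, collapse = "")
      if (.is_stop(nxtc) && stop_pathways == "exclude" &&
          nxtc != codon2) { # terminal codon is sense by precondition anyway
        blocked <- TRUE; break
      }
      curc <- paste(cur, collapse = "")
      if (.is_stop(nxtc) || .is_stop(curc)) {
        # only reachable under stop_pathways = "count": call the step
        # nonsynonymous (a stop is not an amino acid)
        nd <- nd + 1
      } else if (.aa_of(curc) == .aa_of(nxtc)) {
        sd <- sd + 1
      } else {
        nd <- nd + 1
      }
      cur <- nxt
    }
    if (!blocked) { sds <- c(sds, sd); nds <- c(nds, nd) }
  }
  if (!length(sds)) {
    # all pathways pass through stops: count them instead of failing
    return(pathway_differences(codon1, codon2, stop_pathways = "count"))
  }
  list(sd = mean(sds), nd = mean(nds))
}

.permutations <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x))
    for (rest in .permutations(x[-i]))
      out <- c(out, list(c(x[i], rest)))
  out
}

#' Jukes--Cantor distance
#' @param p Proportion of differences per site.
#' @keywords internal
.jc_distance <- function(p) -0.75 * log(1 - 4 * p / 3) + 0  # +0 avoids -0

#' Pairwise dN/dS (Nei--Gojobori, Zhang-modified)
#'
#' Computes synonymous/nonsynonymous site and difference counts over a
#' codon-aligned pair of coding sequences, Jukes--Cantor-corrected distances
#' and their ratio \eqn{\omega = dN/dS}.
#'
#' @param cds1,cds2 Gap-free, codon-aligned DNA strings of equal length
#'   (a multiple of 3) with no internal stop codons. Codons containing
#'   \code{N} in either sequence are dropped from the computation.
#' @param config A [dnds_config()].
#' @return A list of class \code{dnds_record}: \code{S}, \code{N} (mean
#'   potential sites over the two sequences), \code{Sd}, \code{Nd}
#'   (pathway-averaged differences), \code{pS}, \code{pN}, \code{dS},
#'   \code{dN}, \code{omega} (NA when flagged), \code{flags} (subset of
#'   \code{omega_unbounded}, \code{jc_undefined}, \code{omega_zero_zero}),
#'   and \code{codons} used.
#' @examples
#' rec <- ng86_pair("ATGTTTGTGCTG", "ATGTTTGTACTG")
#' rec$S   # 8/3
#' rec$dN  # 0
#' @export
ng86_pair <- function(cds1, cds2, config = dnds_config()) {
  if (nchar(cds1) != nchar(cds2))
    stop("coding sequences differ in length")
  if (nchar(cds1) %% 3L != 0L)
    stop("length is not a multiple of 3")
  n <- nchar(cds1)
  cod1 <- substring(cds1, seq(1L, n, 3L), seq(3L, n, 3L))
  cod2 <- substring(cds2, seq(1L, n, 3L), seq(3L, n, 3L))
  keep <- grepl("^[ACGT]{3}$", cod1) & grepl("^[ACGT]{3}$", cod2)
  cod1 <- cod1[keep]; cod2 <- cod2[keep]
  if (any(.is_stop(cod1)) || any(.is_stop(cod2)))
    stop("internal stop codon in input; strip or pseudogene-handle first")
  S1 <- 0; S2 <- 0; Sd <- 0; Nd <- 0
  site_cache <- new.env(parent = emptyenv())
  site <- function(cod) {
    v <- site_cache[[cod]]
    if (is.null(v)) {
      v <- codon_site_counts(cod, R = config$R)$s
      site_cache[[cod]] <- v
    }
    v
  }
  for (i in seq_along(cod1)) {
    S1 <- S1 + site(cod1[i])
    S2 <- S2 + site(cod2[i])
    if (cod1[i] != cod2[i]) {
      d <- pathway_differences(cod1[i], cod2[i],
                               stop_pathways = config$stop_pathways)
      Sd <- Sd + d$sd; Nd <- Nd + d$nd
    }
  }
  S <- (S1 + S2) / 2
  N <- 3 * length(cod1) - S
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  flags <- character(0)
  dS <- dN <- NA_real_
  if (pS < config$max_p) dS <- .jc_distance(pS)
  if (pN < config$max_p) dN <- .jc_distance(pN)
  if (is.na(dS) || is.na(dN)) flags <- c(flags, "jc_undefined")
  omega <- NA_real_
  if (!is.na(dS) && !is.na(dN)) {
    if (dS > 0) {
      omega <- dN / dS
    } else if (dN > 0) {
      flags <- c(flags, "omega_unbounded")
    } else {
      flags <- c(flags, "omega_zero_zero")
    }
  }
  structure(list(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
                 dS = dS, dN = dN, omega = omega, flags = flags,
                 codons = length(cod1)),
            class = "dnds_record")
}

#' @export
print.dnds_record <- function(x, ...) {
  cat(sprintf("dN/dS record over %d codons\n", x$codons))
  cat(sprintf("  S = %.3f  N = %.3f  Sd = %.3f  Nd = %.3f\n",
              x$S, x$N, x$Sd, x$Nd))
  om <- if (!is.na(x$omega)) sprintf("%.4f", x$omega)
        else if ("omega_unbounded" %in% x$flags) ">10 (unbounded)"
        else paste(x$flags, collapse = ",")
  cat(sprintf("  dS = %s  dN = %s  omega = %s\n",
              format(x$dS), format(x$dN), om))
  invisible(x)
}

#' All within-family pairwise dN/dS records
#'
#' @param cds Named character vector of codon-aligned (equal-length per
#'   compared pair) coding sequences without terminal stop codons. Pairs of
#'   unequal length are aligned codon-wise through their protein global
#'   alignment first (gapped codons dropped from both).
#' @param pairs Two-column matrix of gene-name pairs to compare; default all
#'   unordered pairs.
#' @param config A [dnds_config()].
#' @return A data.frame with one row per pair: the record fields plus
#'   \code{gene1}, \code{gene2} and a comma-joined \code{flags} column.
#' @export
dnds_pairs <- function(cds, pairs = NULL, config = dnds_config()) {
  ids <- names(cds)
  if (is.null(pairs)) {
    if (length(ids) < 2) return(.empty_dnds_df())
    pairs <- t(utils::combn(ids, 2))
  }
  rows <- vector("list", nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    a <- pairs[k, 1]; b <- pairs[k, 2]
    ab <- align_codons(cds[[a]], cds[[b]])
    rec <- ng86_pair(ab[1], ab[2], config)
    rows[[k]] <- data.frame(gene1 = a, gene2 = b, S = rec$S, N = rec$N,
                            Sd = rec$Sd, Nd = rec$Nd, pS = rec$pS, pN = rec$pN,
                            dS = rec$dS, dN = rec$dN, omega = rec$omega,
                            flags = paste(rec$flags, collapse = ","),
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

.empty_dnds_df <- function() {
  data.frame(gene1 = character(0), gene2 = character(0), S = numeric(0),
             N = numeric(0), Sd = numeric(0), Nd = numeric(0),
             pS = numeric(0), pN = numeric(0), dS = numeric(0),
             dN = numeric(0), omega = numeric(0), flags = character(0),
             stringsAsFactors = FALSE)
}

#' Codon-align two coding sequences through their protein alignment
#'
#' Globally aligns the translations and back-threads the alignment onto the
#' codons; codon columns opposite a gap are dropped from both sequences.
#' Terminal stop codons are removed before alignment.
#'
#' @param cds1,cds2 DNA coding sequences (lengths multiples of 3).
#' @return A character vector of two equal-length, gap-free DNA strings.
#' @export
align_codons <- function(cds1, cds2) {
  strip_stop <- function(x) {
    p <- translate_cds(x)
    if (nchar(p) > 0 && substr(p, nchar(p), nchar(p)) == "*")
      substr(x, 1L, nchar(x) - 3L) else x
  }
  cds1 <- strip_stop(cds1); cds2 <- strip_stop(cds2)
  p1 <- translate_cds(cds1); p2 <- translate_cds(cds2)
  if (nchar(cds1) == nchar(cds2) && !grepl("\\*", p1) && !grepl("\\*", p2))
    return(c(cds1, cds2))  # already codon-aligned
  al <- .nw_align(p1, p2)
  a1 <- strsplit(al[1], "", fixed = TRUE)[[1]]
  a2 <- strsplit(al[2], "", fixed = TRUE)[[1]]
  i <- 0L; j <- 0L; out1 <- character(0); out2 <- character(0)
  for (k in seq_along(a1)) {
    g1 <- a1[k] == "-"; g2 <- a2[k] == "-"
    if (!g1) i <- i + 1L
    if (!g2) j <- j + 1L
    if (!g1 && !g2) {
      out1 <- c(out1, substr(cds1, 3L * i - 2L, 3L * i))
      out2 <- c(out2, substr(cds2, 3L * j - 2L, 3L * j))
    }
  }
  c(paste(out1, collapse = ""), paste(out2, collapse = ""))
}

#' Per-family dN/dS summary
#'
#' Mean/min/max of the finite omegas per family, with the number of
#' unbounded (\code{dS = 0, dN > 0}) pairs reported separately.
#'
#' @param records A data.frame from [dnds_pairs()].
#' @param assignments A data.frame with columns \code{gene} and \code{family};
#'   only pairs whose two genes share a family are summarized.
#' @return A data.frame with one row per family: \code{family}, \code{n_pairs},
#'   \code{mean_omega}, \code{min_omega}, \code{max_omega},
#'   \code{n_unbounded}.
#' @export
family_summary <- function(records, assignments) {
  fam <- stats::setNames(assignments$family, assignments$gene)
  f1 <- fam[records$gene1]; f2 <- fam[records$gene2]
  keep <- !is.na(f1) & !is.na(f2) & f1 == f2
  recs <- records[keep, , drop = FALSE]
  recs$family <- f1[keep]
  out <- lapply(split(recs, recs$family), function(d) {
    fin <- d$omega[is.finite(d$omega)]
    data.frame(family = d$family[1], n_pairs = nrow(d),
               mean_omega = if (length(fin)) mean(fin) else NA_real_,
               min_omega = if (length(fin)) min(fin) else NA_real_,
               max_omega = if (length(fin)) max(fin) else NA_real_,
               n_unbounded = sum(grepl("omega_unbounded", d$flags)),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Intra- versus inter-species dN/dS means
#'
#' @param records A data.frame from [dnds_pairs()].
#' @param species Named character vector: gene name -> species label.
#' @param assignments Optional family assignments; when given, summaries are
#'   per (species, family), otherwise per species.
#' @return A data.frame with columns \code{species}, \code{family},
#'   \code{mean_intra}, \code{n_intra}, \code{mean_inter}, \code{n_inter};
#'   cells with no pairs are \code{NA}.
#' @export
intra_inter_summary <- function(records, species, assignments = NULL) {
  s1 <- species[records$gene1]; s2 <- species[records$gene2]
  fam <- if (is.null(assignments)) rep("all", nrow(records)) else {
    f <- stats::setNames(assignments$family, assignments$gene)
    fv1 <- f[records$gene1]; fv2 <- f[records$gene2]
    ifelse(!is.na(fv1) & !is.na(fv2) & fv1 == fv2, fv1, NA_character_)
  }
  ok <- !is.na(fam) & is.finite(records$omega)
  sp_all <- sort(unique(c(s1, s2)))
  fams <- sort(unique(fam[ok]))
  rows <- list()
  for (f in fams) for (sp in sp_all) {
    intra <- ok & fam == f & s1 == sp & s2 == sp
    inter <- ok & fam == f & xor(s1 == sp, s2 == sp)
    rows[[length(rows) + 1L]] <- data.frame(
      species = sp, family = f,
      mean_intra = if (any(intra)) mean(records$omega[intra]) else NA_real_,
      n_intra = sum(intra),
      mean_inter = if (any(inter)) mean(records$omega[inter]) else NA_real_,
      n_inter = sum(inter), stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
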
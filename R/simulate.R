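# Synthetic genome assemblies with planted receptor repertoires and full
# ground truth. The generator emulates the structures the miner must detect:
# one- and two-exon receptor genes with GT-AG phase-0 introns near codon 55
# and aromatic-basic junction dipeptides, frameshift/stop pseudogenes,
# edge-truncated genes, internal fragments, decoy GPCRs, and a
# family/subfamily identity hierarchy with planted cross-species orthologs.

#' Synthetic repertoire configuration
#'
#' Defaults define the reference study conditions: five species, ~34 planted
#' elements each over ~150 contigs with a ~25 kb median contig length.
#'
#' @param seed Integer seed; the whole simulation is deterministic given it.
#' @param species Species symbols.
#' @param counts Named integer vector of per-species planted elements.
#' @param n_codons Receptor length in codons (excluding the stop); fixed so
#'   that planted proteins form an ungapped alignment.
#' @param contig_meanlog,contig_sdlog Log-normal contig-length parameters
#'   (median \code{exp(meanlog)}).
#' @param n_empty_contigs Gene-free contigs added per species.
#' @param gc Background GC content.
#' @param family_plan Named integer vector: subfamilies per family; gene
#'   assignments cycle through subfamilies proportionally to
#'   \code{family_weights}.
#' @param family_weights Relative share of genes per family.
#' @param gene_div,sub_div,fam_div Target protein identity (percent) of a
#'   gene to its subfamily ancestor, a subfamily to its family ancestor, and
#'   a family to the root ancestor; calibrated to give ~70/50/30 percent
#'   within-subfamily/within-family/between-family pairwise identity.
#' @param bait_div Identity of each positive bait to its subfamily ancestor.
#' @param intron_range Intron length range (nt).
#' @param intron_codon_mean,intron_codon_sd,intron_codon_clip Intron position
#'   (codon after which the intron falls): clipped normal.
#' @param junction_mix Probabilities of the junction dipeptides.
#' @param omega Nonsynonymous acceptance probability during gene evolution.
#' @param tstv Transition/transversion proposal weight.
#' @param ortholog_pairs,ortholog_triplets Cross-species near-identical
#'   groups planted (at \code{ortholog_identity} percent).
#' @param ortholog_identity Target identity of an ortholog-pair partner to
#'   its base gene (triplet partners diverge by exactly one residue each so
#'   that all three within-triplet pairs stay above 99 percent).
#' @param edge_fraction,fragment_fraction Range of the CDS fraction retained
#'   by edge genes / internal fragments.
#' @param n_decoy_ancestors Independent decoy GPCR ancestors (negative
#'   baits derive from these).
#' @return A list of class \code{synth_config}.
#' @export
synth_config <- function(seed = 1L,
                         species = c("Til", "Bur", "Nye", "Bri", "Zeb"),
                         counts = c(complete_2exon = 14L, complete_1exon = 4L,
                                    pseudogene_frameshift = 4L,
                                    pseudogene_stop = 2L,
                                    edge = 4L, fragment = 2L,
                                    decoy_gpcr = 4L),
                         n_codons = 330L,
                         contig_meanlog = log(25000), contig_sdlog = 0.35,
                         n_empty_contigs = 2L,
                         gc = 0.42,
                         family_plan = c(A = 4L, B = 2L, C = 1L),
                         family_weights = c(A = 0.65, B = 0.25, C = 0.10),
                         gene_div = 85, sub_div = 71, fam_div = 25,
                         bait_div = 80,
                         intron_range = c(70L, 3000L),
                         intron_codon_mean = 55, intron_codon_sd = 6,
                         intron_codon_clip = c(42L, 75L),
                         junction_mix = c(FR = 0.79, FK = 0.14, YR = 0.04,
                                          LT = 0.03),
                         omega = 0.4, tstv = 2,
                         ortholog_pairs = 6L, ortholog_triplets = 2L,
                         ortholog_identity = 99.3,
                         edge_fraction = c(0.55, 0.7),
                         fragment_fraction = c(0.55, 0.75),
                         n_decoy_ancestors = 5L) {
  stopifnot(abs(sum(junction_mix) - 1) < 1e-9)
  if (!(fam_div <= sub_div && sub_div <= 100 && gene_div <= 100))
    stop("divergence levels must satisfy family <= subfamily <= 100")
  structure(as.list(environment()), class = "synth_config")
}

# --- receptor architecture ------------------------------------------------
# Fixed layout (1-based codon positions) for a 330-codon receptor: 7 TM
# blocks of 28 hydrophobic residues, 12-residue internal/external loops,
# 5 frozen 6-residue motif blocks in the loops and termini.
.receptor_layout <- function(n_codons = 330L) {
  stopifnot(n_codons == 330L)  # the default architecture; lengths are fixed
  tm_starts <- c(21L, 61L, 101L, 141L, 181L, 221L, 261L)
  tm <- unlist(lapply(tm_starts, function(s) s:(s + 27L)))
  motifs <- list(9:14, 130:135, 170:175, 210:215, 295:300)
  list(tm = tm, motif_blocks = motifs, motif = unlist(motifs),
       tm_starts = tm_starts)
}

.HYDRO <- c("I", "L", "V", "F", "M", "A", "C")
.HYDRO_W <- c(3, 3, 3, 1, 0.5, 0.5, 0.5)
.LOOP_AA <- c("G", "S", "T", "N", "Q", "P", "D", "E", "K", "R", "H", "Y")
.LOOP_W  <- c(1, 1, 1, 2, 2, 1, 2, 2, 2, 2, 1, 0.5)

.codons_of <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      gc <- Biostrings::GENETIC_CODE
      tab <<- split(names(gc), unname(gc))
    }
    tab
  }
})

.random_codon_for <- function(aa) {
  opts <- .codons_of()[[aa]]
  opts[sample.int(length(opts), 1L)]
}

# Random ancestor CDS with receptor architecture (no stop codon appended).
.make_ancestor <- function(n_codons, layout, motif_override = NULL) {
  aa <- character(n_codons)
  aa[1] <- "M"
  loop_pos <- setdiff(2:n_codons, layout$tm)
  aa[layout$tm] <- sample(.HYDRO, length(layout$tm), TRUE, prob = .HYDRO_W)
  aa[loop_pos] <- sample(.LOOP_AA, length(loop_pos), TRUE, prob = .LOOP_W)
  if (!is.null(motif_override)) {
    for (k in seq_along(layout$motif_blocks))
      aa[layout$motif_blocks[[k]]] <-
        strsplit(motif_override[k], "", fixed = TRUE)[[1]]
  }
  paste(vapply(aa, .random_codon_for, ""), collapse = "")
}

#' Evolve a coding sequence to a target protein identity
#'
#' Codon-level proposal/acceptance process: a random non-frozen codon
#' position and base change are proposed (transitions weighted \code{tstv}),
#' proposals creating stop codons are rejected, synonymous proposals are
#' accepted, nonsynonymous ones with probability \code{omega} (and, at
#' hydrophobicity-constrained positions, only if the new residue stays
#' hydrophobic). Evolution stops when the protein identity to the input
#' drops to the target. With \code{omega = 0} the protein cannot diverge;
#' the proposal budget is then spent on synonymous drift and the sequence
#' is returned (all fixed differences synonymous).
#'
#' @param cds Coding DNA (length a multiple of 3, no internal stop).
#' @param target_identity Target percent protein identity to the input.
#' @param omega Nonsynonymous acceptance probability.
#' @param tstv Transition/transversion proposal weight.
#' @param frozen Integer codon positions never mutated.
#' @param hydro Integer codon positions restricted to hydrophobic residues
#'   (transmembrane segments keep their hydropathy).
#' @param polar Integer codon positions restricted to polar/loop residues
#'   (loops between segments stay hydrophilic).
#' @param budget_per_codon Proposal budget multiplier.
#' @return The evolved CDS string.
#' @export
evolve_to_identity <- function(cds, target_identity, omega = 0.4, tstv = 2,
                               frozen = integer(0), hydro = integer(0),
                               polar = integer(0), budget_per_codon = 80L) {
  if (target_identity <= 0 || target_identity > 100)
    stop("target identity must be in (0, 100]")
  n <- nchar(cds) %/% 3L
  codons <- substring(cds, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  aa0 <- vapply(codons, function(cd) .codon_table[[cd]], "")
  aa <- aa0
  mutable <- setdiff(seq_len(n), union(frozen, 1L))
  hydro_set <- .HYDRO
  n_ident <- n
  target_n <- target_identity / 100 * n
  budget <- budget_per_codon * n
  trans <- c(A = "G", G = "A", C = "T", T = "C")
  for (it in seq_len(budget)) {
    if (n_ident <= target_n) break
    ci <- mutable[sample.int(length(mutable), 1L)]
    cod <- strsplit(codons[ci], "", fixed = TRUE)[[1]]
    p <- sample.int(3L, 1L)
    alts <- setdiff(.BASES, cod[p])
    w <- ifelse(alts == trans[cod[p]], tstv, 1)
    b <- alts[sample.int(3L, 1L, prob = w)]
    newcod <- cod; newcod[p] <- b
    newc <- paste(newcod, collapse = "")
    if (.is_stop(newc)) next
    new_aa <- .codon_table[[newc]]
    if (new_aa != aa[ci]) {
      if (stats::runif(1) > omega) next
      if (ci %in% hydro && !(new_aa %in% hydro_set)) next
      if (ci %in% polar && !(new_aa %in% .LOOP_AA)) next
      was <- aa[ci] == aa0[ci]
      aa[ci] <- new_aa
      is_now <- aa[ci] == aa0[ci]
      n_ident <- n_ident - (was - is_now)
    }
    codons[ci] <- newc
  }
  if (n_ident > target_n + 0.03 * n && omega > 0)
    stop("target identity ", target_identity,
         "% unreachable within the proposal budget at this length")
  paste(codons, collapse = "")
}

#' Plant a disrupting mutation in a coding sequence
#'
#' @param cds Coding DNA (with or without terminal stop).
#' @param kind \code{"frameshift"} (insert or delete 1-2 nt) or
#'   \code{"in_frame_stop"} (mutate a sense codon to TAA/TAG/TGA).
#' @param codon_range Codon positions eligible for the disruption.
#' @return A list: \code{seq} (mutated genomic sequence), \code{kind},
#'   \code{position} (codon index), \code{detail}.
#' @export
pseudogenize <- function(cds, kind = c("frameshift", "in_frame_stop"),
                         codon_range = c(45L, 285L)) {
  kind <- match.arg(kind)
  n <- nchar(cds) %/% 3L
  hi <- min(codon_range[2], n - 2L)
  pos <- sample(codon_range[1]:hi, 1L)
  if (kind == "frameshift") {
    k <- sample(1:2, 1L)
    if (stats::runif(1) < 0.5) {  # insertion
      ins <- paste(sample(.BASES, k, TRUE), collapse = "")
      at <- 3L * (pos - 1L) + sample.int(3L, 1L)
      seq <- paste0(substr(cds, 1L, at), ins, substr(cds, at + 1L, nchar(cds)))
      detail <- sprintf("+%dnt", k)
    } else {                       # deletion
      at <- 3L * (pos - 1L) + 1L
      seq <- paste0(substr(cds, 1L, at - 1L),
                    substr(cds, at + k, nchar(cds)))
      detail <- sprintf("-%dnt", k)
    }
  } else {
    stopc <- sample(.STOPS, 1L)
    seq <- paste0(substr(cds, 1L, 3L * (pos - 1L)), stopc,
                  substr(cds, 3L * pos + 1L, nchar(cds)))
    detail <- stopc
  }
  list(seq = seq, kind = kind, position = pos, detail = detail)
}

#' Truncate a gene for placement at a contig boundary
#'
#' @param genomic Full genomic gene sequence (coding orientation).
#' @param side Which part is lost: \code{"N"} (5'/N-terminal) or \code{"C"}.
#' @param fraction Fraction of the sequence retained (must lie in
#'   \code{[0.3, 0.7]}).
#' @return A list: \code{seq} (the remnant, coding orientation), \code{side},
#'   \code{fraction}.
#' @export
truncate_to_edge <- function(genomic, side = c("N", "C"), fraction = 0.6) {
  side <- match.arg(side)
  if (fraction < 0.3 || fraction > 0.7)
    stop("edge remnant fraction must be within [0.3, 0.7]")
  n <- nchar(genomic)
  keep <- round(fraction * n)
  keep <- keep - keep %% 3L  # keep the remnant codon-aligned
  seq <- if (side == "N") substr(genomic, n - keep + 1L, n)
         else substr(genomic, 1L, keep)
  list(seq = seq, side = side, fraction = keep / n)
}

.random_dna <- function(n, gc = 0.42) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, TRUE, prob = p), collapse = "")
}

# Random intron: starts GT, ends AG, no other AG within the 6 nt upstream of
# the terminal AG (avoids acceptor ambiguity), length in range.
.random_intron <- function(len, gc = 0.42) {
  stopifnot(len >= 12)
  repeat {
    mid <- .random_dna(len - 4L, gc)
    tail6 <- substr(mid, nchar(mid) - 5L, nchar(mid))
    if (!grepl("AG", tail6, fixed = TRUE)) break
  }
  paste0("GT", mid, "AG")
}

.sample_junction <- function(mix) {
  names(mix)[sample.int(length(mix), 1L, prob = mix)]
}

.sample_intron_codon <- function(cfg) {
  j <- round(stats::rnorm(1, cfg$intron_codon_mean, cfg$intron_codon_sd))
  as.integer(min(max(j, cfg$intron_codon_clip[1]), cfg$intron_codon_clip[2]))
}

# overwrite codons j, j+1 with codons for the junction dipeptide
.apply_junction <- function(cds, j, dipep) {
  left <- .random_codon_for(substr(dipep, 1, 1))
  right <- .random_codon_for(substr(dipep, 2, 2))
  paste0(substr(cds, 1L, 3L * (j - 1L)), left, right,
         substr(cds, 3L * (j + 1L) + 1L, nchar(cds)))
}

#' Generate synthetic assemblies with a planted receptor repertoire
#'
#' Builds the ancestor hierarchy (root, family, subfamily ancestors), evolves
#' per-species genes from it, realizes each planted status (intron insertion,
#' pseudogenizing mutation, boundary truncation, internal fragment, decoy),
#' embeds everything in random-background contigs and records full ground
#' truth.
#'
#' @param config A [synth_config()].
#' @return A list of class \code{synth_repertoire}: \code{assemblies} (list
#'   per species of named contig vectors), \code{pos_baits},
#'   \code{neg_baits}, \code{truth} (data.frame; one row per planted
#'   element), \code{ancestors}, \code{config}.
#' @export
simulate_repertoire <- function(config = synth_config()) {
  set.seed(config$seed)
  layout <- .receptor_layout(config$n_codons)
  frozen <- sort(unique(c(1L, layout$motif)))
  hydro <- layout$tm
  polar <- setdiff(seq_len(config$n_codons), c(1L, layout$tm, layout$motif))

  # --- ancestor hierarchy -------------------------------------------------
  # family ancestors form a chain, each evolved to fam_div percent identity
  # of the previous one, so no between-family pair exceeds fam_div
  root <- .make_ancestor(config$n_codons, layout)
  fams <- names(config$family_plan)
  fam_anc <- list()
  prev <- root
  for (f in fams) {
    prev <- evolve_to_identity(prev, config$fam_div, omega = config$omega,
                               tstv = config$tstv, frozen = frozen,
                               hydro = hydro, polar = polar,
                               budget_per_codon = 200L)
    fam_anc[[f]] <- prev
  }
  sub_anc <- list()
  for (f in fams) for (s in seq_len(config$family_plan[[f]]))
    sub_anc[[paste0(f, s)]] <-
      evolve_to_identity(fam_anc[[f]], config$sub_div, omega = config$omega,
                         tstv = config$tstv, frozen = frozen, hydro = hydro,
                         polar = polar)

  # --- baits --------------------------------------------------------------
  pos_baits <- vapply(names(sub_anc), function(sf) {
    cds <- evolve_to_identity(sub_anc[[sf]], config$bait_div,
                              omega = config$omega, tstv = config$tstv,
                              frozen = frozen, hydro = hydro, polar = polar)
    translate_cds(cds)
  }, "")
  names(pos_baits) <- paste0("posbait_", names(sub_anc))
  decoy_anc <- replicate(config$n_decoy_ancestors,
                         .make_ancestor(config$n_codons, layout))
  neg_baits <- vapply(seq_along(decoy_anc), function(i)
    translate_cds(evolve_to_identity(decoy_anc[[i]], config$bait_div,
                                     omega = config$omega,
                                     tstv = config$tstv, hydro = hydro,
                                     polar = polar)), "")
  names(neg_baits) <- paste0("negbait_", seq_along(decoy_anc))

  # --- gene plan ----------------------------------------------------------
  subfams <- names(sub_anc)
  subfam_weights <- unlist(lapply(fams, function(f)
    rep(config$family_weights[[f]] / config$family_plan[[f]],
        config$family_plan[[f]])))
  names(subfam_weights) <- subfams

  draw_subfam <- function() subfams[sample.int(length(subfams), 1L,
                                               prob = subfam_weights)]
  new_gene <- function(sf)
    evolve_to_identity(sub_anc[[sf]], config$gene_div, omega = config$omega,
                       tstv = config$tstv, frozen = frozen, hydro = hydro,
                       polar = polar)

  plan <- list()   # one entry per planted element
  add <- function(species, status, ...) {
    plan[[length(plan) + 1L]] <<- c(list(species = species, status = status),
                                    list(...))
  }
  counts <- config$counts
  # ortholog groups consume complete_2exon slots across species
  remaining2 <- stats::setNames(rep(counts[["complete_2exon"]],
                                    length(config$species)), config$species)
  og_id <- 0L
  og_specs <- c(rep(2L, config$ortholog_pairs),
                rep(3L, config$ortholog_triplets))
  for (gsize in og_specs) {
    og_id <- og_id + 1L
    sp_ok <- names(remaining2)[remaining2 > 0]
    if (length(sp_ok) < gsize) break
    sps <- sample(sp_ok, gsize)
    sf <- draw_subfam()
    base <- new_gene(sf)
    j <- .sample_intron_codon(config)
    dipep <- .sample_junction(config$junction_mix)
    # triplet partners: exactly one residue from the base each, so every
    # within-triplet pair stays above the 99 percent bar
    step <- if (gsize == 2L) config$ortholog_identity
            else 100 * (config$n_codons - 1) / config$n_codons
    for (i in seq_along(sps)) {
      cds <- if (i == 1L) base
             else evolve_to_identity(base, step, omega = 1,
                                     tstv = config$tstv, frozen = frozen,
                                     hydro = hydro, polar = polar)
      add(sps[i], "complete_2exon", subfam = sf, cds = cds, j = j,
          dipep = dipep, ortholog_group = og_id)
      remaining2[sps[i]] <- remaining2[sps[i]] - 1L
    }
  }
  for (sp in config$species) {
    for (i in seq_len(remaining2[[sp]])) {
      sf <- draw_subfam()
      add(sp, "complete_2exon", subfam = sf, cds = new_gene(sf),
          j = .sample_intron_codon(config),
          dipep = .sample_junction(config$junction_mix), ortholog_group = NA)
    }
    for (i in seq_len(counts[["complete_1exon"]])) {
      sf <- draw_subfam()
      add(sp, "complete_1exon", subfam = sf, cds = new_gene(sf),
          ortholog_group = NA)
    }
    for (i in seq_len(counts[["pseudogene_frameshift"]])) {
      sf <- draw_subfam()
      add(sp, "pseudogene", subfam = sf, cds = new_gene(sf),
          pseudo_kind = "frameshift", ortholog_group = NA)
    }
    for (i in seq_len(counts[["pseudogene_stop"]])) {
      sf <- draw_subfam()
      add(sp, "pseudogene", subfam = sf, cds = new_gene(sf),
          pseudo_kind = "in_frame_stop", ortholog_group = NA)
    }
    for (i in seq_len(counts[["edge"]])) {
      sf <- draw_subfam()
      add(sp, "edge", subfam = sf, cds = new_gene(sf),
          side = sample(c("N", "C"), 1L),
          fraction = stats::runif(1, config$edge_fraction[1],
                                  config$edge_fraction[2]),
          ortholog_group = NA)
    }
    for (i in seq_len(counts[["fragment"]])) {
      sf <- draw_subfam()
      add(sp, "fragment", subfam = sf, cds = new_gene(sf),
          fraction = stats::runif(1, config$fragment_fraction[1],
                                  config$fragment_fraction[2]),
          ortholog_group = NA)
    }
    for (i in seq_len(counts[["decoy_gpcr"]])) {
      k <- sample.int(length(decoy_anc), 1L)
      add(sp, "decoy", subfam = NA_character_,
          cds = evolve_to_identity(decoy_anc[[k]], 85, omega = config$omega,
                                   tstv = config$tstv, hydro = hydro,
                                   polar = polar),
          ortholog_group = NA)
    }
  }

  # --- realize genomic sequences ------------------------------------------
  elements <- lapply(plan, function(p) .realize_element(p, config))

  # --- place on contigs ---------------------------------------------------
  out <- .place_elements(plan, elements, config)
  truth <- out$truth
  # planted gene names: per species, per status, indexed in planting order
  truth$family <- ifelse(is.na(truth$subfam), NA_character_,
                         substr(truth$subfam, 1, 1))
  truth$subfamily <- ifelse(is.na(truth$subfam), NA_integer_,
                            as.integer(substr(truth$subfam, 2, 2)))
  nm <- character(nrow(truth))
  for (i in seq_len(nrow(truth))) {
    if (truth$status[i] == "decoy") { nm[i] <- sprintf("decoy_%03d", i); next }
    nm[i] <- name_gene(truth$species[i], truth$status[i], truth$family[i], i)
  }
  truth$gene <- nm

  structure(list(assemblies = out$assemblies, pos_baits = pos_baits,
                 neg_baits = neg_baits, truth = truth,
                 ancestors = list(root = root, family = fam_anc,
                                  subfamily = sub_anc, decoy = decoy_anc,
                                  layout = layout),
                 config = config),
            class = "synth_repertoire")
}

# Turn a planned element into its genomic (coding-orientation) sequence plus
# bookkeeping needed for truth coordinates.
.realize_element <- function(p, config) {
  stop_codon <- sample(.STOPS, 1L)
  if (identical(p$status, "complete_2exon")) {
    cds <- .apply_junction(p$cds, p$j, p$dipep)
    cds_stop <- paste0(cds, stop_codon)
    ilen <- sample(config$intron_range[1]:config$intron_range[2], 1L)
    intron <- .random_intron(ilen, config$gc)
    ex1 <- substr(cds_stop, 1L, 3L * p$j)
    ex2 <- substr(cds_stop, 3L * p$j + 1L, nchar(cds_stop))
    list(seq = paste0(ex1, intron, ex2), cds = cds_stop,
         exon_nt = c(nchar(ex1), nchar(ex2)), intron_len = ilen,
         j = p$j, dipep = p$dipep)
  } else if (identical(p$status, "complete_1exon") ||
             identical(p$status, "decoy")) {
    cds_stop <- paste0(p$cds, stop_codon)
    list(seq = cds_stop, cds = cds_stop, exon_nt = nchar(cds_stop),
         intron_len = NA, j = NA, dipep = NA)
  } else if (identical(p$status, "pseudogene")) {
    cds_stop <- paste0(p$cds, stop_codon)
    ps <- pseudogenize(cds_stop, p$pseudo_kind)
    list(seq = ps$seq, cds = cds_stop, exon_nt = nchar(ps$seq),
         intron_len = NA, j = NA, dipep = NA,
         pseudo_kind = ps$kind, pseudo_position = ps$position)
  } else if (identical(p$status, "edge")) {
    cds_stop <- paste0(p$cds, stop_codon)
    tr <- truncate_to_edge(cds_stop, p$side, p$fraction)
    list(seq = tr$seq, cds = cds_stop, exon_nt = nchar(tr$seq),
         intron_len = NA, j = NA, dipep = NA, side = tr$side)
  } else if (identical(p$status, "fragment")) {
    n <- nchar(p$cds)
    keep <- round(p$fraction * n); keep <- keep - keep %% 3L
    start <- 3L * sample(15:((n - keep) %/% 3L - 5L), 1L)
    list(seq = substr(p$cds, start + 1L, start + keep), cds = p$cds,
         exon_nt = keep, intron_len = NA, j = NA, dipep = NA)
  } else stop("unknown status in plan")
}

.place_elements <- function(plan, elements, config) {
  assemblies <- list()
  rows <- list()
  for (sp in config$species) {
    idx <- which(vapply(plan, `[[`, "", "species") == sp)
    # pair some same-strand complete genes onto shared contigs (tail-to-head)
    complete_idx <- idx[vapply(plan[idx], function(p)
      p$status %in% c("complete_1exon", "complete_2exon"), TRUE)]
    n_pairs <- min(2L, length(complete_idx) %/% 2L)
    paired <- if (n_pairs > 0)
      matrix(complete_idx[seq_len(2L * n_pairs)], ncol = 2L, byrow = TRUE)
    else matrix(integer(0), ncol = 2L)
    single <- setdiff(idx, as.vector(paired))
    contigs <- character(0)
    cnum <- 0L
    new_cid <- function() {
      cnum <<- cnum + 1L
      sprintf("%s_contig%03d", sp, cnum)
    }
    emit <- function(cid, seqv) contigs[[cid]] <<- seqv

    place_single <- function(i) {
      el <- elements[[i]]; p <- plan[[i]]
      glen <- nchar(el$seq)
      L <- max(glen + 4000L,
               round(stats::rlnorm(1, config$contig_meanlog,
                                   config$contig_sdlog)))
      strand <- sample(c("+", "-"), 1L)
      cid <- new_cid()
      if (identical(p$status, "edge")) {
        at_left <- (el$side == "N" && strand == "+") ||
                   (el$side == "C" && strand == "-")
        off <- if (at_left) 0L else L - glen
      } else {
        off <- sample(1500:(L - glen - 1500L), 1L)
      }
      ins <- if (strand == "+") el$seq else reverse_complement(el$seq)
      seqv <- paste0(.random_dna(off, config$gc), ins,
                     .random_dna(L - off - glen, config$gc))
      emit(cid, seqv)
      rows[[length(rows) + 1L]] <<- .truth_row(p, el, cid, off, strand, L)
    }
    place_pair <- function(i1, i2) {
      el1 <- elements[[i1]]; el2 <- elements[[i2]]
      g1 <- nchar(el1$seq); g2 <- nchar(el2$seq)
      gap <- sample(2500:6000, 1L)
      L <- max(g1 + g2 + gap + 6000L,
               round(stats::rlnorm(1, config$contig_meanlog,
                                   config$contig_sdlog)))
      strand <- sample(c("+", "-"), 1L)
      off1 <- sample(1500:(L - g1 - g2 - gap - 1500L), 1L)
      off2 <- off1 + g1 + gap
      cid <- new_cid()
      s1 <- if (strand == "+") el1$seq else reverse_complement(el1$seq)
      s2 <- if (strand == "+") el2$seq else reverse_complement(el2$seq)
      seqv <- paste0(.random_dna(off1, config$gc), s1,
                     .random_dna(gap, config$gc), s2,
                     .random_dna(L - off2 - g2, config$gc))
      emit(cid, seqv)
      rows[[length(rows) + 1L]] <<-
        .truth_row(plan[[i1]], el1, cid, off1, strand, L)
      rows[[length(rows) + 1L]] <<-
        .truth_row(plan[[i2]], el2, cid, off2, strand, L)
    }
    for (r in seq_len(nrow(paired))) place_pair(paired[r, 1], paired[r, 2])
    for (i in single) place_single(i)
    for (k in seq_len(config$n_empty_contigs))
      emit(new_cid(), .random_dna(round(stats::rlnorm(
        1, config$contig_meanlog, config$contig_sdlog)), config$gc))
    assemblies[[sp]] <- unlist(contigs)
  }
  list(assemblies = assemblies, truth = do.call(rbind, rows))
}

# truth coordinates: the element occupies forward interval [off, off+glen)
# on `strand`; for two-exon genes the exon split is recorded in coding
# orientation and converted to forward coordinates.
.truth_row <- function(p, el, cid, off, strand, L) {
  glen <- nchar(el$seq)
  if (identical(p$status, "complete_2exon")) {
    e1 <- el$exon_nt[1]; e2 <- el$exon_nt[2]
    if (strand == "+") {
      ex <- sprintf("%d-%d;%d-%d", off, off + e1,
                    off + e1 + el$intron_len, off + glen)
    } else {
      ex <- sprintf("%d-%d;%d-%d", off + glen - e1, off + glen,
                    off, off + e2)
    }
  } else {
    ex <- sprintf("%d-%d", off, off + glen)
  }
  data.frame(species = p$species, status = p$status,
             pseudo_kind = el$pseudo_kind %||% NA_character_,
             pseudo_position = el$pseudo_position %||% NA_integer_,
             contig = cid, strand = strand, exons = ex,
             start = off, end = off + glen,
             intron_codon = el$j %||% NA_integer_,
             junction = el$dipep %||% NA_character_,
             subfam = p$subfam,
             ortholog_group = p$ortholog_group,
             cds = el$cds, protein = sub("\\*$", "", translate_cds(el$cds)),
             stringsAsFactors = FALSE)
}

#' Simulate a codon-sequence pair under a fixed nonsynonymous acceptance ratio
#'
#' Two lineages evolve independently from a random sense-codon ancestor:
#' single-base proposals (uniform positions; transitions weighted
#' \code{tstv}) are rejected if they create a stop, accepted if synonymous,
#' and accepted with probability \code{rho} if nonsynonymous. With uniform
#' proposals and \code{tstv = 1} the expected pairwise dN/dS of the pair
#' equals \code{rho}.
#'
#' @param n_codons Sequence length in codons.
#' @param rho Nonsynonymous acceptance probability in \code{[0, 1]}.
#' @param n_prop Proposals per lineage.
#' @param tstv Transition/transversion proposal weight.
#' @return Character vector of the two coding sequences.
#' @export
simulate_omega_pair <- function(n_codons = 300L, rho = 0.5, n_prop = 120L,
                                tstv = 1) {
  anc <- paste(sample(setdiff(names(.codon_table),
                              c(.STOPS, grep("N", names(.codon_table),
                                             value = TRUE))),
                      n_codons, replace = TRUE), collapse = "")
  evolve_one <- function() {
    codons <- substring(anc, 3L * seq_len(n_codons) - 2L,
                        3L * seq_len(n_codons))
    trans <- c(A = "G", G = "A", C = "T", T = "C")
    acc <- 0L
    while (acc < n_prop) {
      ci <- sample.int(n_codons, 1L)
      cod <- strsplit(codons[ci], "", fixed = TRUE)[[1]]
      p <- sample.int(3L, 1L)
      alts <- setdiff(.BASES, cod[p])
      w <- ifelse(alts == trans[cod[p]], tstv, 1)
      b <- alts[sample.int(3L, 1L, prob = w)]
      newcod <- cod; newcod[p] <- b
      newc <- paste(newcod, collapse = "")
      acc <- acc + 1L   # a proposal is consumed whether or not it fixes
      if (.is_stop(newc)) next
      if (.codon_table[[newc]] != .codon_table[[codons[ci]]] &&
          stats::runif(1) > rho) next
      codons[ci] <- newc
    }
    paste(codons, collapse = "")
  }
  c(evolve_one(), evolve_one())
}
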
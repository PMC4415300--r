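# End-to-end orchestration: search -> loci -> gene models -> clustering ->
# orthologs -> dN/dS -> features, bundled into a repertoire report.

#' Mine receptor repertoires from genome assemblies
#'
#' Runs the full pipeline over one or more species assemblies: six-frame
#' translated search with the positive baits, locus merging, negative-bait
#' screening of candidates, bait filtering, gene-model reconstruction and
#' classification, family/subfamily clustering of the complete proteins,
#' ortholog detection, within-family dN/dS, neighbor-joining tree, conserved
#' motifs, splice-site logos and structural annotation.
#'
#' @param assemblies Named list (species -> named character vector of contig
#'   sequences). Contig ids must be unique across species.
#' @param pos_baits,neg_baits Named character vectors of bait proteins.
#' @param scfg A [search_config()].
#' @param mcfg A [model_config()].
#' @param dcfg A [dnds_config()].
#' @param family_thr,subfamily_thr,ortholog_thr Percent-identity thresholds.
#' @param max_dnds_genes_per_family Cap on genes entering the all-pairs
#'   dN/dS stage per family (largest families are subsampled
#'   deterministically by name order beyond the cap).
#' @return An object of class \code{taar_repertoire}; see
#'   [summary.taar_repertoire()].
#' @export
mine_repertoire <- function(assemblies, pos_baits, neg_baits,
                            scfg = search_config(), mcfg = model_config(),
                            dcfg = dnds_config(),
                            family_thr = 40, subfamily_thr = 60,
                            ortholog_thr = 99,
                            max_dnds_genes_per_family = 40L) {
  if (!length(pos_baits)) stop("search stage: empty positive bait set")
  if (!length(neg_baits)) stop("search stage: empty negative bait set")
  models <- list()
  rejected <- list()
  species_of_contig <- list()
  for (sp in names(assemblies)) {
    asm <- assemblies[[sp]]
    for (cid in names(asm)) species_of_contig[[cid]] <- sp
    hits <- search_assembly(asm, pos_baits, scfg)
    loci <- merge_hits(hits, scfg$merge_gap)
    loci <- score_negative(loci, asm, neg_baits, scfg)
    flt <- bait_filter(loci, scfg)
    rejected[[sp]] <- flt$rejected
    sp_models <- build_gene_models(flt$retained, asm, pos_baits, mcfg, scfg)
    for (m in seq_along(sp_models)) sp_models[[m]]$species <- sp
    models <- c(models, sp_models)
  }

  complete <- Filter(function(m)
    m$status %in% c("complete_1exon", "complete_2exon"), models)
  proteins <- vapply(complete, `[[`, "", "protein")
  names(proteins) <- sprintf("g%03d", seq_along(complete))

  assignments <- NULL; idm <- NULL; orthologs <- NULL; tree <- NULL
  dnds_fam <- NULL; dnds_ii <- NULL; dnds_records <- NULL
  if (length(complete) >= 2) {
    idm <- identity_matrix(proteins)
    assignments <- cluster_families(idm, family_thr, subfamily_thr)
    # final names use the clustered family letter
    fam_of <- stats::setNames(assignments$family, assignments$gene)
    for (k in seq_along(complete)) {
      complete[[k]]$family <- fam_of[[names(proteins)[k]]]
      complete[[k]]$name <- name_gene(complete[[k]]$species,
                                      complete[[k]]$status,
                                      complete[[k]]$family, k)
    }
    newnames <- vapply(complete, `[[`, "", "name")
    rownames(idm) <- colnames(idm) <- newnames
    names(proteins) <- newnames
    assignments$gene <- newnames[match(assignments$gene,
                                       sprintf("g%03d", seq_along(complete)))]
    species_vec <- stats::setNames(vapply(complete, `[[`, "", "species"),
                                   newnames)
    orthologs <- find_orthologs(idm, species_vec, ortholog_thr)
    if (length(complete) >= 3) tree <- nj_tree(idm)
    cds_vec <- stats::setNames(vapply(complete, `[[`, "", "cds"), newnames)
    cds_vec <- vapply(cds_vec, function(x) sub("(TAA|TAG|TGA)$", "", x), "")
    dnds_records <- .family_dnds(cds_vec, assignments, dcfg,
                                 max_dnds_genes_per_family)
    if (nrow(dnds_records)) {
      dnds_fam <- family_summary(dnds_records, assignments)
      dnds_ii <- intra_inter_summary(dnds_records, species_vec, assignments)
    }
  }
  # write the clustered models back (including their names) over the
  # unclassified complete entries
  ci <- 1L
  for (k in seq_along(models)) {
    if (models[[k]]$status %in% c("complete_1exon", "complete_2exon")) {
      models[[k]] <- complete[[ci]]; ci <- ci + 1L
    } else {
      models[[k]]$family <- "U"
      models[[k]]$name <- sprintf("%sTAR%s.U%03d", models[[k]]$species,
                                  switch(models[[k]]$status,
                                         pseudogene = "p", edge = "e",
                                         fragment = "f", "x"), k)
    }
  }

  motifs <- NULL
  prot_lens <- nchar(proteins)
  if (length(proteins) >= 5) {
    modal <- as.integer(names(sort(table(prot_lens), decreasing = TRUE))[1])
    aln <- proteins[prot_lens == modal]
    if (length(aln) >= 5) motifs <- conserved_motifs(unname(aln))
  }
  logos <- tryCatch({
    asm_all <- do.call(c, unname(assemblies))
    splice_logo(models, asm_all)
  }, error = function(e) NULL)

  status_table <- .status_table(models)
  pseudo_table <- .pseudo_table(models)
  junction <- junction_census(models)
  adjacency <- adjacency_report(models)
  features <- .feature_tables(complete)
  family_table <- if (!is.null(assignments))
    family_species_table(assignments,
                         stats::setNames(vapply(complete, `[[`, "", "species"),
                                         vapply(complete, `[[`, "", "name")))
  else NULL

  rep <- structure(list(models = models, status_table = status_table,
                        pseudo_table = pseudo_table, junction = junction,
                        assignments = assignments, identity = idm,
                        family_table = family_table, orthologs = orthologs,
                        tree = tree, dnds_records = dnds_records,
                        dnds_family = dnds_fam, dnds_intra_inter = dnds_ii,
                        motifs = motifs, logos = logos,
                        adjacency = adjacency, features = features,
                        rejected = do.call(rbind, rejected),
                        manifest = list(
                          n_species = length(assemblies),
                          n_contigs = sum(lengths(assemblies)),
                          thresholds = c(family = family_thr,
                                         subfamily = subfamily_thr,
                                         ortholog = ortholog_thr),
                          e_pos = scfg$e_pos, e_neg = scfg$e_neg)),
                   class = "taar_repertoire")
  .check_consistency(rep)
  rep
}

.family_dnds <- function(cds_vec, assignments, dcfg, cap) {
  fam <- stats::setNames(assignments$family, assignments$gene)
  pairs <- list()
  for (f in unique(fam)) {
    g <- sort(names(fam)[fam == f])
    if (length(g) > cap) g <- g[seq_len(cap)]
    if (length(g) >= 2) pairs[[f]] <- t(utils::combn(g, 2))
  }
  if (!length(pairs)) return(.empty_dnds_df())
  dnds_pairs(cds_vec, do.call(rbind, pairs), dcfg)
}

.status_table <- function(models) {
  sp <- vapply(models, `[[`, "", "species")
  st <- factor(vapply(models, `[[`, "", "status"),
               levels = c("complete_1exon", "complete_2exon", "pseudogene",
                          "edge", "fragment"))
  table(status = st, species = sp)
}

.pseudo_table <- function(models) {
  ps <- Filter(function(m) identical(m$status, "pseudogene"), models)
  if (!length(ps))
    return(table(pseudo_type = factor(character(0),
                                      levels = c("frameshift",
                                                 "in_frame_stop", "both")),
                 species = character(0)))
  table(pseudo_type = factor(vapply(ps, `[[`, "", "pseudo_type"),
                             levels = c("frameshift", "in_frame_stop",
                                        "both")),
        species = vapply(ps, `[[`, "", "species"))
}

.feature_tables <- function(complete) {
  tm <- list(); sq <- list()
  for (m in complete) {
    nm <- m$name %||% "?"
    t1 <- tm_segments(m$protein)
    if (nrow(t1)) { t1$gene <- nm; tm[[length(tm) + 1L]] <- t1 }
    s1 <- sequon_scan(m$protein)
    if (nrow(s1)) { s1$gene <- nm; sq[[length(sq) + 1L]] <- s1 }
  }
  list(tm = if (length(tm)) do.call(rbind, tm) else NULL,
       sequons = if (length(sq)) do.call(rbind, sq) else NULL)
}

# cross-table consistency, asserted on every run
.check_consistency <- function(rep) {
  n_spliced <- sum(vapply(rep$models, function(m)
    identical(m$status, "complete_2exon"), TRUE))
  stopifnot(rep$junction$n == n_spliced)
  if (!is.null(rep$assignments)) {
    n_complete <- sum(rep$status_table[c("complete_1exon",
                                         "complete_2exon"), ])
    stopifnot(nrow(rep$assignments) == n_complete)
  }
  invisible(TRUE)
}

#' @export
print.taar_repertoire <- function(x, ...) {
  cat("TAAR repertoire report\n")
  cat(sprintf("  %d gene models over %d species\n",
              length(x$models), ncol(x$status_table)))
  print(x$status_table)
  if (!is.null(x$assignments))
    cat(sprintf("  %d families, %d subfamilies over %d complete genes\n",
                length(unique(x$assignments$family)),
                nrow(unique(x$assignments[c("family", "subfamily")])),
                nrow(x$assignments)))
  if (x$junction$n > 0) {
    cat(sprintf("  %d spliced genes; junction dipeptides: %s\n",
                x$junction$n,
                paste(names(x$junction$counts), x$junction$counts,
                      sep = ":", collapse = " ")))
  }
  invisible(x)
}

#' Summarize a mined repertoire
#' @param object A \code{taar_repertoire}.
#' @param ... Unused.
#' @export
summary.taar_repertoire <- function(object, ...) {
  print(object)
  if (!is.null(object$dnds_family)) {
    cat("within-family dN/dS:\n")
    print(object$dnds_family)
  }
  if (!is.null(object$logos)) {
    cat(sprintf("donor consensus:    %s\n", object$logos$donor$consensus))
    cat(sprintf("acceptor consensus: %s\n", object$logos$acceptor$consensus))
  }
  invisible(object)
}

#' Write report tables and artifacts to a directory
#'
#' @param rep A \code{taar_repertoire}.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_repertoire <- function(rep, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  w(as.data.frame(rep$status_table), "status_table.tsv")
  w(as.data.frame(rep$pseudo_table), "pseudogene_table.tsv")
  if (length(rep$junction$counts))
    w(data.frame(dipeptide = names(rep$junction$counts),
                 count = rep$junction$counts), "junction_census.tsv")
  if (!is.null(rep$assignments)) w(rep$assignments, "families.tsv")
  if (!is.null(rep$family_table))
    w(as.data.frame(rep$family_table), "family_by_species.tsv")
  if (!is.null(rep$orthologs)) w(rep$orthologs, "orthologs.tsv")
  if (!is.null(rep$dnds_records)) w(rep$dnds_records, "dnds_pairs.tsv")
  if (!is.null(rep$dnds_family)) w(rep$dnds_family, "dnds_family.tsv")
  if (!is.null(rep$dnds_intra_inter))
    w(rep$dnds_intra_inter, "dnds_intra_inter.tsv")
  if (nrow(rep$adjacency)) w(rep$adjacency, "adjacency.tsv")
  if (!is.null(rep$tree)) write_newick(rep$tree, file.path(dir, "tree.nwk"))
  named <- Filter(function(m) !is.null(m$cds), rep$models)
  if (length(named)) {
    prots <- stats::setNames(vapply(named, `[[`, "", "protein"),
                             vapply(named, `[[`, "", "name"))
    write_fasta(prots, file.path(dir, "complete_proteins.faa"))
    write_gff3(named, file.path(dir, "gene_models.gff3"))
  }
  invisible(dir)
}

#' Classify an existing gene catalogue (reproduction mode)
#'
#' Skips the search and gene-model stages and runs clustering, ortholog
#' detection, dN/dS and motif discovery directly on supplied protein (and
#' optionally coding) sequences, e.g. a published gene catalogue.
#'
#' @param proteins Named character vector of receptor proteins.
#' @param cds Optional named character vector of matching coding sequences
#'   (enables the dN/dS tables).
#' @param species Named character vector mapping gene name to species; by
#'   default the first three characters of the gene name.
#' @param family_thr,subfamily_thr,ortholog_thr Percent-identity thresholds.
#' @param dcfg A [dnds_config()].
#' @return A list: \code{assignments}, \code{identity}, \code{family_table},
#'   \code{orthologs}, \code{tree}, \code{dnds_records}, \code{dnds_family},
#'   \code{dnds_intra_inter}, \code{motifs}.
#' @export
reproduce_catalogue <- function(proteins, cds = NULL, species = NULL,
                                family_thr = 40, subfamily_thr = 60,
                                ortholog_thr = 99, dcfg = dnds_config()) {
  if (length(proteins) < 2) stop("catalogue must contain at least 2 proteins")
  bad <- names(proteins)[grepl("\\*", proteins)]
  if (length(bad))
    stop("catalogue proteins contain internal stops: ",
         paste(bad, collapse = ", "))
  if (is.null(species))
    species <- stats::setNames(substr(names(proteins), 1, 3), names(proteins))
  idm <- identity_matrix(proteins)
  assignments <- cluster_families(idm, family_thr, subfamily_thr)
  orthologs <- find_orthologs(idm, species, ortholog_thr)
  tree <- if (length(proteins) >= 3) nj_tree(idm) else NULL
  dnds_records <- NULL; dnds_fam <- NULL; dnds_ii <- NULL
  if (!is.null(cds)) {
    cds <- vapply(cds, function(x) sub("(TAA|TAG|TGA)$", "", x), "")
    dnds_records <- .family_dnds(cds, assignments, dcfg, 40L)
    if (nrow(dnds_records)) {
      dnds_fam <- family_summary(dnds_records, assignments)
      dnds_ii <- intra_inter_summary(dnds_records, species, assignments)
    }
  }
  motifs <- NULL
  lens <- nchar(proteins)
  modal <- as.integer(names(sort(table(lens), decreasing = TRUE))[1])
  if (sum(lens == modal) >= 5)
    motifs <- conserved_motifs(unname(proteins[lens == modal]))
  list(assignments = assignments, identity = idm,
       family_table = family_species_table(assignments, species),
       orthologs = orthologs, tree = tree, dnds_records = dnds_records,
       dnds_family = dnds_fam, dnds_intra_inter = dnds_ii, motifs = motifs)
}

# ---- evaluation against planted truth ------------------------------------

#' Evaluate a mined repertoire against planted truth
#'
#' Matches recovered models to truth records by contig, strand and interval
#' overlap, and computes per-class status recall, the family-partition Rand
#' index over recovered complete genes, junction-census agreement, ortholog
#' recovery and two-exon boundary exactness.
#'
#' @param rep A \code{taar_repertoire} from [mine_repertoire()].
#' @param truth The truth data.frame from [simulate_repertoire()].
#' @return A list: \code{matches} (data.frame truth row x recovered status),
#'   \code{status_recall} (named vector), \code{decoy_rejection_rate},
#'   \code{rand_index}, \code{junction_exact}, \code{boundary_exact_rate},
#'   \code{orthologs_exact}.
#' @export
evaluate_against_truth <- function(rep, truth) {
  mod_df <- data.frame(
    idx = seq_along(rep$models),
    contig = vapply(rep$models, `[[`, "", "contig_id"),
    strand = vapply(rep$models, `[[`, "", "strand"),
    start = vapply(rep$models, function(m)
      min(vapply(m$exons, `[[`, 0, "start")), 0),
    end = vapply(rep$models, function(m)
      max(vapply(m$exons, `[[`, 0, "end")), 0),
    status = vapply(rep$models, `[[`, "", "status"),
    stringsAsFactors = FALSE)
  match_of <- integer(nrow(truth))
  for (i in seq_len(nrow(truth))) {
    cand <- which(mod_df$contig == truth$contig[i] &
                  mod_df$strand == truth$strand[i] &
                  pmin(mod_df$end, truth$end[i]) -
                    pmax(mod_df$start, truth$start[i]) >
                    0.3 * (truth$end[i] - truth$start[i]))
    match_of[i] <- if (length(cand)) cand[1] else NA_integer_
  }
  recovered_status <- ifelse(is.na(match_of), "missed",
                             mod_df$status[match_of])
  classes <- c("complete_1exon", "complete_2exon", "pseudogene", "edge",
               "fragment")
  recall <- vapply(classes, function(cl) {
    idx <- truth$status == cl
    if (!any(idx)) return(NA_real_)
    mean(recovered_status[idx] == cl)
  }, 0)
  decoy_idx <- truth$status == "decoy"
  decoy_rej <- if (any(decoy_idx)) mean(is.na(match_of[decoy_idx])) else NA

  # family partition over truth complete genes recovered as complete
  rand <- NA_real_
  ok <- truth$status %in% c("complete_1exon", "complete_2exon") &
    !is.na(match_of) & recovered_status == truth$status
  if (!is.null(rep$assignments) && sum(ok) >= 2) {
    mod_names <- vapply(rep$models, function(m) m$name %||% "", "")
    rec_fam <- stats::setNames(rep$assignments$family, rep$assignments$gene)
    pred <- rec_fam[mod_names[match_of[ok]]]
    truth_fam <- substr(truth$subfam[ok], 1, 1)
    rand <- .rand_index(truth_fam, paste0("f", pred))
  }

  # junction census agreement (planted vs recovered dipeptide tallies)
  truth_j <- table(truth$junction[truth$status == "complete_2exon"])
  rec_j <- rep$junction$counts
  junction_exact <- length(truth_j) == length(rec_j) &&
    all(sort(names(truth_j)) == sort(names(rec_j))) &&
    all(as.integer(truth_j[names(rec_j)]) == as.integer(rec_j))

  # planted two-exon boundary exactness
  two <- which(truth$status == "complete_2exon" & !is.na(match_of))
  bexact <- vapply(two, function(i) {
    m <- rep$models[[match_of[i]]]
    if (!identical(m$status, "complete_2exon")) return(FALSE)
    got <- paste(vapply(m$exons, function(e)
      sprintf("%d-%d", e$start, e$end), ""), collapse = ";")
    identical(got, truth$exons[i])
  }, TRUE)
  boundary_exact_rate <- if (length(bexact)) mean(bexact) else NA_real_

  # ortholog groups: compare member sets via truth ortholog_group ids
  orthologs_exact <- NA
  if (!is.null(rep$orthologs)) {
    mod_names <- vapply(rep$models, function(m) m$name %||% "", "")
    truth_groups <- split(seq_len(nrow(truth)),
                          truth$ortholog_group)
    planted <- sort(vapply(truth_groups, function(ix) {
      nm <- ifelse(is.na(match_of[ix]), "MISSED", mod_names[match_of[ix]])
      paste(sort(nm), collapse = ",")
    }, ""))
    found <- sort(rep$orthologs$members[rep$orthologs$type == "ortholog"])
    orthologs_exact <- identical(unname(planted), unname(found))
  }
  list(matches = data.frame(truth_gene = truth$gene,
                            planted = truth$status,
                            recovered = recovered_status,
                            stringsAsFactors = FALSE),
       status_recall = recall, decoy_rejection_rate = decoy_rej,
       rand_index = rand, junction_exact = junction_exact,
       boundary_exact_rate = boundary_exact_rate,
       orthologs_exact = orthologs_exact)
}

# Rand index of two labelings of the same elements
.rand_index <- function(a, b) {
  n <- length(a)
  if (n < 2) return(NA_real_)
  agree <- 0; total <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    same_a <- a[i] == a[j]; same_b <- b[i] == b[j]
    agree <- agree + (same_a == same_b)
    total <- total + 1
  }
  agree / total
}
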
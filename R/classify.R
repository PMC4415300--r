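# Family/subfamily clustering at identity thresholds, ortholog detection,
# and a neighbor-joining tree over the repertoire.

#' Cluster genes into families and subfamilies by percent identity
#'
#' Families are the connected components (single linkage) of the graph
#' linking gene pairs at identity >= \code{family_thr}; subfamilies are the
#' components at >= \code{subfamily_thr} within each family. Families are
#' lettered \code{A, B, ...} by decreasing size (ties: lexicographically
#' smallest member), subfamilies numbered likewise, so the labels are
#' permutation-invariant.
#'
#' @param m A symmetric percent-identity matrix with gene names as dimnames
#'   (see [identity_matrix()]).
#' @param family_thr,subfamily_thr Percent-identity thresholds.
#' @return A data.frame with columns \code{gene}, \code{family} (letter),
#'   \code{subfamily} (integer within family).
#' @export
cluster_families <- function(m, family_thr = 40, subfamily_thr = 60) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m),
            !is.null(rownames(m)), all(rownames(m) == colnames(m)))
  ids <- rownames(m)
  fam_comp <- .components(m >= family_thr)
  fam_order <- .order_components(fam_comp, ids)
  if (length(fam_order) > 26L)
    stop("more than 26 families; widen the labelling scheme")
  out <- data.frame(gene = ids, family = NA_character_,
                    subfamily = NA_integer_, stringsAsFactors = FALSE)
  for (fi in seq_along(fam_order)) {
    members <- fam_order[[fi]]
    out$family[match(members, ids)] <- LETTERS[fi]
    sub <- m[members, members, drop = FALSE]
    sub_comp <- .components(sub >= subfamily_thr)
    sub_order <- .order_components(sub_comp, members)
    for (si in seq_along(sub_order))
      out$subfamily[match(sub_order[[si]], ids)] <- si
  }
  out
}

# connected components of a logical adjacency matrix (self-links implied)
.components <- function(adj) {
  n <- nrow(adj)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cur <- cur + 1L
    queue <- i
    comp[i] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(adj[v, ] & is.na(comp))
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

# components as lists of member ids, ordered by decreasing size then by
# lexicographically smallest member
.order_components <- function(comp, ids) {
  groups <- split(ids, comp)
  key_min <- vapply(groups, function(g) min(g), "")
  ord <- order(-lengths(groups), key_min)
  unname(groups[ord])
}

#' Find ortholog/paralog groups of near-identical genes
#'
#' Reports all maximal cliques of size 2 or 3 in the graph linking genes at
#' identity >= \code{threshold}. Groups spanning two or more species are
#' labelled orthologs, single-species groups paralogs. Pairs contained in a
#' reported triplet are not reported again.
#'
#' @param m A symmetric percent-identity matrix with gene-name dimnames.
#' @param species Named character vector mapping gene name to species label.
#' @param threshold Minimum pairwise identity within a group.
#' @return A data.frame: \code{members} (comma-joined names), \code{size},
#'   \code{species} (comma-joined set), \code{min_identity}, \code{type}
#'   (\code{ortholog}/\code{paralog}).
#' @export
find_orthologs <- function(m, species, threshold = 99) {
  ids <- rownames(m)
  n <- length(ids)
  adj <- m >= threshold
  diag(adj) <- FALSE
  rows <- list()
  used_pair <- matrix(FALSE, n, n)
  # triplets first (maximal cliques of size 3; receptor repertoires do not
  # contain larger near-identical groups, and larger cliques are reported as
  # their triplets)
  if (n >= 3) for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) {
    if (!adj[i, j]) next
    for (k in (j + 1):n) {
      if (adj[i, k] && adj[j, k]) {
        idx <- c(i, j, k)
        rows[[length(rows) + 1L]] <- .group_row(idx, ids, species, m)
        for (p in list(c(i, j), c(i, k), c(j, k)))
          used_pair[p[1], p[2]] <- used_pair[p[2], p[1]] <- TRUE
      }
    }
  }
  if (n >= 2) for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (adj[i, j] && !used_pair[i, j])
      rows[[length(rows) + 1L]] <- .group_row(c(i, j), ids, species, m)
  }
  if (!length(rows))
    return(data.frame(members = character(0), size = integer(0),
                      species = character(0), min_identity = numeric(0),
                      type = character(0), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

.group_row <- function(idx, ids, species, m) {
  sub <- m[idx, idx]
  sp <- unique(species[ids[idx]])
  data.frame(members = paste(sort(ids[idx]), collapse = ","),
             size = length(idx),
             species = paste(sort(sp), collapse = ","),
             min_identity = min(sub[upper.tri(sub)]),
             type = if (length(sp) >= 2) "ortholog" else "paralog",
             stringsAsFactors = FALSE)
}

#' Neighbor-joining tree from an identity or distance matrix
#'
#' Distances default to \code{1 - identity/100}. Negative branch-length
#' estimates are clamped to zero and flagged.
#'
#' @param m Symmetric matrix: percent identities (default) or distances.
#' @param is_distance Set \code{TRUE} if \code{m} already holds distances.
#' @return An [ape::nj()] \code{phylo} tree with an added logical attribute
#'   \code{clamped} (any negative branch length was clamped).
#' @export
nj_tree <- function(m, is_distance = FALSE) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  if (nrow(m) < 2) stop("at least 2 taxa required")
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8)))
    stop("matrix is not symmetric")
  d <- if (is_distance) m else 1 - m / 100
  if (nrow(d) == 2) {
    # ape::nj needs >= 3 taxa; a 2-taxon tree is a single split
    tr <- ape::read.tree(text = sprintf("(%s:%f,%s:%f);",
                                        rownames(d)[1], d[1, 2] / 2,
                                        rownames(d)[2], d[1, 2] / 2))
    attr(tr, "clamped") <- FALSE
    return(tr)
  }
  tr <- ape::nj(stats::as.dist(d))
  clamped <- any(tr$edge.length < 0)
  tr$edge.length[tr$edge.length < 0] <- 0
  attr(tr, "clamped") <- clamped
  tr
}

#' Write a tree in Newick format
#' @param tree A \code{phylo} tree.
#' @param path Output path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Family-by-species count table
#'
#' @param assignments Output of [cluster_families()].
#' @param species Named character vector: gene -> species label.
#' @return A contingency table (families x species).
#' @export
family_species_table <- function(assignments, species) {
  table(family = assignments$family, species = species[assignments$gene])
}
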
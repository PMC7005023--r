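# Neighbour-joining placement of new lineages. Tree construction and
# column-resampling bootstrap are delegated to ape behind this surface.

#' Neighbour-joining tree from a K2P distance matrix
#'
#' @param dist_matrix Symmetric matrix with zero diagonal and at least three
#'   labelled rows.
#' @param labels Optional labels overriding the matrix dimnames.
#' @return An unrooted `phylo` tree (ape).
#' @export
nj_tree <- function(dist_matrix, labels = NULL) {
  m <- as.matrix(dist_matrix)
  if (!is.null(labels)) dimnames(m) <- list(labels, labels)
  if (nrow(m) != ncol(m) || !isTRUE(all.equal(m, t(m), tolerance = 1e-8)) ||
      any(diag(m) != 0) || any(m < 0)) {
    stop("invalid distance matrix")
  }
  if (nrow(m) < 3) stop("invalid distance matrix")
  ape::nj(as.dist(m))
}

#' Write a tree in newick format
#'
#' @param tree A `phylo`.
#' @param path Output file.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Bootstrap support for a neighbour-joining tree
#'
#' Alignment columns are resampled with replacement (default 1,000
#' replicates); support of an internal edge is the fraction of replicate
#' trees containing its bipartition.
#'
#' @param seqs Named character vector of aligned, equal-length sequences.
#' @param n_boot Number of replicates.
#' @param min_sites Minimum compared sites per pairwise distance.
#' @param seed Integer seed for the resampling.
#' @return List: `tree` (phylo built from the full alignment) and `support`
#'   (fraction per internal node, ape node order).
#' @export
nj_bootstrap <- function(seqs, n_boot = 1000L, min_sites = 100L, seed = 1L) {
  aln <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  rownames(aln) <- names(seqs)
  build <- function(x) {
    nj_tree(k2p_matrix_from_alignment(x, min_sites = min(min_sites, ncol(x))))
  }
  tree <- build(aln)
  set.seed(seed)
  counts <- ape::boot.phylo(tree, aln, build, B = n_boot, quiet = TRUE,
                            rooted = FALSE)
  list(tree = tree, support = counts / n_boot)
}

# tip indices below each node of a phylo (simple post-order accumulation)
node_tip_sets <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  sets <- vector("list", ntip + nnode)
  for (i in seq_len(ntip)) sets[[i]] <- i
  edges <- tree$edge[order(tree$edge[, 1], decreasing = TRUE), , drop = FALSE]
  # children have larger numbers than... not guaranteed; iterate to fixpoint
  repeat {
    changed <- FALSE
    for (k in seq_len(nrow(edges))) {
      p <- edges[k, 1]; ch <- edges[k, 2]
      if (!is.null(sets[[ch]]) &&
          !all(sets[[ch]] %in% (sets[[p]] %||% integer(0)))) {
        sets[[p]] <- sort(unique(c(sets[[p]], sets[[ch]])))
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  sets
}

#' Place a new lineage at family/subfamily level by tree support
#'
#' Builds a neighbour-joining tree over the reference barcodes plus the
#' query, bootstraps it, and returns the family/subfamily of the smallest
#' reference group that sides with the query across an internal edge with
#' bootstrap support at or above `support_min` and whose members all belong
#' to one family/subfamily. If no such group exists the placement is
#' `"incertae sedis"`.
#'
#' @param new_barcode DNA string of the unassigned lineage.
#' @param db `reference_db` with at least three records spanning at least
#'   two families.
#' @param support_min Minimum bootstrap support (fraction).
#' @param n_boot Bootstrap replicates.
#' @param seed Integer seed.
#' @return Character scalar: family/subfamily label or `"incertae sedis"`.
#' @export
place_new_lineage <- function(new_barcode, db, support_min = 0.70,
                              n_boot = 1000L, seed = 1L) {
  stopifnot(inherits(db, "reference_db"))
  rec <- db$records
  fams <- unname(family_of_group[rec$group])
  if (nrow(rec) < 3 || length(unique(fams)) < 2) {
    stop("reference database too small for tree placement")
  }
  qlab <- "__query__"
  seqs <- c(setNames(rec$sequence, rec$lineage_id),
            setNames(new_barcode, qlab))
  bs <- nj_bootstrap(seqs, n_boot = n_boot, seed = seed)
  tree <- bs$tree
  ntip <- length(tree$tip.label)
  qtip <- match(qlab, tree$tip.label)
  fam_of_tip <- fams[match(tree$tip.label, rec$lineage_id)]
  sets <- node_tip_sets(tree)

  best <- NULL
  for (nd in seq_len(tree$Nnode)) {
    node <- ntip + nd
    below <- sets[[node]]
    if (length(below) >= ntip) next  # root bipartition is trivial
    side <- if (qtip %in% below) below else setdiff(seq_len(ntip), below)
    refs <- setdiff(side, qtip)
    if (!length(refs)) next
    fam <- unique(fam_of_tip[refs])
    if (length(fam) != 1 || fam == "other") next
    if (bs$support[nd] < support_min) next
    if (is.null(best) || length(refs) < best$size) {
      best <- list(size = length(refs), family = fam)
    }
  }
  if (is.null(best)) "incertae sedis" else best$family
}
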
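#' Read a rooted taxonomy/phylogeny for taxon-depth operations
#'
#' Reads a Newick tree (via \pkg{ape}); branch lengths and internal node labels
#' are tolerated and ignored: only the topology is used. Node depth is the
#' number of edges from the root (root = 0). Count-table taxa without a
#' matching leaf are reported and attached directly under the root at depth 1.
#'
#' @param path Newick file path.
#' @param taxon_ids optional character vector of count-table taxa to reconcile
#'   against the leaf set.
#' @return An object of class \code{taxon_tree}: list with the \code{phylo}
#'   tree, per-node integer \code{depth} (tips first, ape numbering),
#'   \code{leaf_depth} named by leaf label, \code{node_label} for internal
#'   nodes, and \code{extra_taxa} attached at depth 1.
#' @export
read_taxon_tree <- function(path, taxon_ids = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stop("Newick parse error: ",
                                          conditionMessage(e)))
  if (is.null(tr)) stop("Newick parse error: no tree in file")
  taxon_tree(tr, taxon_ids = taxon_ids)
}

#' @rdname read_taxon_tree
#' @param tree an \code{ape::phylo} object (rooted).
#' @export
taxon_tree <- function(tree, taxon_ids = NULL) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  # topology-only depth: unit edge lengths
  tr1 <- tree
  tr1$edge.length <- rep(1, nrow(tree$edge))
  depth <- as.integer(round(ape::node.depth.edgelength(tr1)))
  leaf_depth <- stats::setNames(depth[seq_len(ntip)], tree$tip.label)
  node_label <- tree$node.label
  if (is.null(node_label) || length(node_label) != nnode ||
      any(!nzchar(node_label)) || anyDuplicated(node_label))
    node_label <- paste0("node", seq_len(nnode) + ntip)
  extra <- character(0)
  if (!is.null(taxon_ids)) {
    matched <- intersect(taxon_ids, tree$tip.label)
    if (length(matched) == 0L)
      stop_validation("no count-table taxon matches any tree leaf")
    extra <- setdiff(taxon_ids, tree$tip.label)
    if (length(extra))
      warning(sprintf("%d taxa not in tree attached at root (depth 1): %s%s",
                      length(extra), paste(utils::head(extra, 3), collapse = ", "),
                      if (length(extra) > 3) ", ..." else ""))
  }
  structure(list(tree = tree, depth = depth, leaf_depth = leaf_depth,
                 node_label = node_label, extra_taxa = extra,
                 max_depth = max(leaf_depth,
                                 if (length(extra)) 1L else NULL)),
            class = "taxon_tree")
}

#' @export
print.taxon_tree <- function(x, ...) {
  cat(sprintf("taxon_tree: %d leaves, %d internal nodes, max depth %d%s\n",
              length(x$tree$tip.label), x$tree$Nnode, x$max_depth,
              if (length(x$extra_taxa))
                sprintf(" (+%d taxa attached at root)", length(x$extra_taxa))
              else ""))
  invisible(x)
}

# For each taxon id, the label of its ancestor node at depth C (the taxon
# itself if its leaf is at depth <= C; extra taxa sit at depth 1). C = 0 maps
# everything to the root.
ancestor_labels_at_depth <- function(tt, taxon_ids, C) {
  stopifnot(inherits(tt, "taxon_tree"), C >= 0)
  tr <- tt$tree
  ntip <- length(tr$tip.label)
  root <- ntip + 1L
  parent <- integer(ntip + tr$Nnode)
  parent[tr$edge[, 2L]] <- tr$edge[, 1L]
  lab_of <- function(node) if (node <= ntip) tr$tip.label[node] else
    tt$node_label[node - ntip]
  vapply(taxon_ids, function(tx) {
    if (C == 0L) return(tt$node_label[1L])  # root label
    if (tx %in% tt$extra_taxa) return(tx)   # depth 1 under root
    node <- match(tx, tr$tip.label)
    if (is.na(node)) stop_validation("taxon not covered by tree: ", tx)
    while (tt$depth[node] > C) node <- parent[node]
    lab_of(node)
  }, character(1))
}
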
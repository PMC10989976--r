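# Taxonomy tree: a small rooted tree of taxids with rank labels. The root
# is its own parent. Species nodes anchor taxonomy reads (TRs); reads from
# inter-species repeats land on internal (LCA) nodes above species rank.

#' Construct a taxonomy tree
#'
#' @param taxid,parent_taxid,rank,name parallel vectors describing the
#'   nodes; exactly one node must be its own parent (the root).
#' @return an object of class \code{taxonomy_tree} with a node table,
#'   precomputed root paths, and depth per node.
#' @export
taxonomy_tree <- function(taxid, parent_taxid, rank, name) {
  taxid <- as.integer(taxid)
  parent_taxid <- as.integer(parent_taxid)
  if (anyDuplicated(taxid)) stop("duplicate taxid in taxonomy")
  root <- taxid[taxid == parent_taxid]
  if (length(root) != 1L) {
    stop(sprintf("taxonomy must have exactly one root, found %d",
                 length(root)))
  }
  if (!all(parent_taxid %in% taxid)) {
    bad <- parent_taxid[!(parent_taxid %in% taxid)][1]
    stop(sprintf("orphan node: parent taxid %d not in table", bad))
  }
  parent <- setNames(parent_taxid, as.character(taxid))
  # root paths (root first, node last); detects cycles
  paths <- vector("list", length(taxid))
  names(paths) <- as.character(taxid)
  for (i in seq_along(taxid)) {
    node <- taxid[i]
    path <- node
    while (node != root) {
      node <- parent[[as.character(node)]]
      if (node %in% path) stop("cycle detected in taxonomy")
      path <- c(node, path)
    }
    paths[[i]] <- path
  }
  nodes <- data.table::data.table(
    taxid = taxid, parent_taxid = parent_taxid,
    rank = as.character(rank), name = as.character(name),
    depth = lengths(paths) - 1L
  )
  data.table::setkey(nodes, taxid)
  structure(list(nodes = nodes, root = root, paths = paths),
            class = "taxonomy_tree")
}

#' @export
print.taxonomy_tree <- function(x, ...) {
  cat(sprintf("taxonomy_tree: %d nodes, root taxid %d, %d species\n",
              nrow(x$nodes), x$root, length(species_taxids(x))))
  invisible(x)
}

#' Read a taxonomy table (TSV: taxid, parent_taxid, rank, name)
#'
#' @param path TSV path with a one-line header.
#' @return a [taxonomy_tree()].
#' @export
parse_taxonomy_table <- function(path) {
  tab <- data.table::fread(path, sep = "\t", header = TRUE,
                           colClasses = list(character = c("rank", "name")))
  need <- c("taxid", "parent_taxid", "rank", "name")
  if (!all(need %in% names(tab))) {
    stop("taxonomy table must have columns taxid, parent_taxid, rank, name")
  }
  taxonomy_tree(tab$taxid, tab$parent_taxid, tab$rank, tab$name)
}

#' Write a taxonomy tree as TSV
#' @param tree a [taxonomy_tree()].
#' @param path output path.
#' @export
write_taxonomy_table <- function(tree, path) {
  data.table::fwrite(tree$nodes[, c("taxid", "parent_taxid", "rank", "name")],
                     path, sep = "\t")
  invisible(path)
}

tax_rank <- function(tree, taxid) {
  tree$nodes$rank[match(as.integer(taxid), tree$nodes$taxid)]
}

#' Species-rank taxids of a tree
#' @param tree a [taxonomy_tree()].
#' @return integer vector of species-rank taxids, sorted.
#' @export
species_taxids <- function(tree) {
  sort(tree$nodes[rank == "species", taxid])
}

# Path from root to node (root first).
root_path <- function(tree, taxid) {
  p <- tree$paths[[as.character(taxid)]]
  if (is.null(p)) stop(sprintf("unknown taxid %s", taxid))
  p
}

#' Lowest common ancestor of a set of taxids
#'
#' @param tree a [taxonomy_tree()].
#' @param taxids non-empty set of taxids present in the tree.
#' @return the deepest taxid ancestral to (or equal to) every input.
#' @export
lca <- function(tree, taxids) {
  taxids <- unique(as.integer(taxids))
  if (length(taxids) == 0L) stop("lca of an empty taxid set")
  common <- root_path(tree, taxids[1])
  for (t in taxids[-1]) {
    p <- root_path(tree, t)
    n <- min(length(common), length(p))
    eq <- common[seq_len(n)] == p[seq_len(n)]
    common <- common[seq_len(if (all(eq)) n else which(!eq)[1] - 1L)]
  }
  common[length(common)]
}

# Map each node to the species-rank taxids at or below it.
species_under <- function(tree) {
  sp <- species_taxids(tree)
  out <- setNames(vector("list", nrow(tree$nodes)),
                  as.character(tree$nodes$taxid))
  for (nm in names(out)) out[[nm]] <- integer(0)
  for (s in sp) {
    for (anc in root_path(tree, s)) {
      key <- as.character(anc)
      out[[key]] <- c(out[[key]], s)
    }
  }
  out
}

#' Lift strain-level assignments to their species ancestor
#'
#' Classifier output against strain-resolved databases can carry taxids
#' below species rank; refinement treats a taxonomy read as one assigned
#' exactly to a species node, so sub-species assignments are lifted to the
#' nearest species-rank ancestor. Taxids at or above species rank are
#' returned unchanged, as are taxid 0 (unclassified) and taxids absent from
#' the tree.
#'
#' @param tree a [taxonomy_tree()].
#' @param taxids integer vector.
#' @return integer vector of the same length.
#' @export
lift_to_species <- function(tree, taxids) {
  taxids <- as.integer(taxids)
  known <- taxids %in% tree$nodes$taxid
  out <- taxids
  for (i in which(known & taxids != 0L)) {
    path <- root_path(tree, taxids[i])
    ranks <- tax_rank(tree, path)
    sp <- which(ranks == "species")
    if (length(sp) && sp[1] < length(path)) out[i] <- path[sp[1]]
  }
  out
}
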
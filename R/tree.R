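# Planted binary trees and the sigma (LCA) map.
#
# A planted tree is a rooted binary tree with an extra degree-1 vertex, the
# planted root, attached above the root, so that the root has an incoming
# edge. Both gene trees and species trees are planted here. Vertices are
# integer ids; leaf labels are strings.

#' Construct a planted binary tree
#'
#' Low-level constructor. Most users will call [read_newick_planted()]
#' instead. Vertex ids are integers `1..nv`; the planted root must have
#' exactly one child (the root) and no parent; every other internal vertex
#' has exactly two children.
#'
#' @param parent Integer vector of length `nv`; `parent[v]` is the parent of
#'   vertex `v`, `NA` for the planted root.
#' @param labels Character vector of length `nv`; leaf labels for leaves,
#'   `NA` for internal vertices. Leaf labels must be unique.
#' @param edge_length Optional numeric vector of length `nv`; the length of
#'   the edge above each vertex (`NA` for the planted root). For species
#'   trees these are time spans, for gene trees expected substitutions per
#'   site.
#' @return An object of class `planted_tree` with components `nv`, `parent`,
#'   `children` (an `nv x 2` integer matrix, `NA` rows for leaves), `root`,
#'   `planted_root`, `is_leaf`, `labels`, `edge_length` and `postorder`
#'   (vertices ordered children-before-parents, planted root last).
#' @export
planted_tree <- function(parent, labels, edge_length = NULL) {
  nv <- length(parent)
  stopifnot(length(labels) == nv)
  planted <- which(is.na(parent))
  if (length(planted) != 1L)
    stop("a planted tree has exactly one parentless vertex (the planted root)")
  kids <- vector("list", nv)
  for (v in seq_len(nv)[-planted]) {
    p <- parent[v]
    if (p < 1L || p > nv) stop("parent index out of range for vertex ", v)
    kids[[p]] <- c(kids[[p]], v)
  }
  deg <- lengths(kids)
  if (deg[planted] != 1L)
    stop("planted root must have exactly one child")
  bad <- which(deg != 0L & deg != 2L & seq_len(nv) != planted)
  if (length(bad))
    stop("non-binary vertex: ", bad[1L], " has ", deg[bad[1L]], " children")
  is_leaf <- deg == 0L
  if (any(is_leaf & is.na(labels)))
    stop("every leaf needs a label")
  ll <- labels[is_leaf]
  if (anyDuplicated(ll))
    stop("duplicate leaf label: ", ll[duplicated(ll)][1L])
  children <- matrix(NA_integer_, nv, 2L)
  for (v in which(deg == 2L)) children[v, ] <- kids[[v]]
  children[planted, 1L] <- kids[[planted]]
  # postorder via iterative DFS
  post <- integer(nv)
  stack <- planted
  i <- nv
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    post[i] <- v
    i <- i - 1L
    stack <- c(stack, kids[[v]])
  }
  if (i != 0L) stop("tree is not connected")
  if (is.null(edge_length)) edge_length <- rep(NA_real_, nv)
  structure(
    list(nv = nv, parent = as.integer(parent), children = children,
         planted_root = planted, root = kids[[planted]],
         is_leaf = is_leaf, labels = as.character(labels),
         edge_length = as.numeric(edge_length), postorder = post),
    class = "planted_tree")
}

#' @export
print.planted_tree <- function(x, ...) {
  cat("planted binary tree:", sum(x$is_leaf), "leaves,", x$nv,
      "vertices (incl. planted root)\n")
  cat("  leaves:", paste(sort(x$labels[x$is_leaf]), collapse = " "), "\n")
  invisible(x)
}

#' Number of leaves of a planted tree
#' @param tree A `planted_tree`.
#' @return Integer leaf count.
#' @export
n_leaves <- function(tree) sum(tree$is_leaf)

#' Read a planted binary tree from Newick
#'
#' Parses a Newick string (or file) describing a rooted binary tree and adds
#' a planted root above the Newick root. A root edge length (the `:x` after
#' the outermost group, as in `"((A:1,B:1):1);"`) becomes the length of the
#' planted edge; it may be absent, in which case the planted edge length is
#' `NA`.
#'
#' @param text Newick string.
#' @param file Path to a Newick file (alternative to `text`).
#' @return A `planted_tree`; branch lengths, if present, are stored in
#'   `$edge_length` (length of the edge above each vertex).
#' @export
read_newick_planted <- function(text = NULL, file = NULL) {
  phy <- if (is.null(text)) ape::read.tree(file = file)
         else ape::read.tree(text = text)
  if (is.null(phy)) stop("could not parse Newick input")
  phylo_to_planted(phy)
}

# Convert an ape phylo object to a planted_tree (internal). A singleton
# outer node (as in "((A:1,B:1):1);") is the planted root idiom: collapse
# it into the root edge.
phylo_to_planted <- function(phy) {
  if (length(phy$tip.label) < 2L)
    stop("non-binary vertex: tree must have at least 2 leaves")
  phy <- ape::collapse.singles(phy, root.edge = TRUE)
  ntip <- length(phy$tip.label)
  if (ntip < 2L) stop("non-binary vertex: tree must have at least 2 leaves")
  if (anyDuplicated(phy$tip.label))
    stop("duplicate leaf label: ",
         phy$tip.label[duplicated(phy$tip.label)][1L])
  nnode_expect <- ntip - 1L
  tab <- tabulate(phy$edge[, 1L], nbins = ntip + phy$Nnode)
  if (phy$Nnode != nnode_expect || any(tab[tab > 0L] != 2L)) {
    bad <- which(tab > 2L | (tab == 1L))[1L]
    stop("non-binary vertex: node ", bad, " has ", tab[bad], " children")
  }
  nv <- ntip + phy$Nnode + 1L        # + planted root
  planted <- nv
  parent <- rep(NA_integer_, nv)
  parent[phy$edge[, 2L]] <- phy$edge[, 1L]
  root <- ntip + 1L
  parent[root] <- planted
  labels <- rep(NA_character_, nv)
  labels[seq_len(ntip)] <- phy$tip.label
  el <- rep(NA_real_, nv)
  if (!is.null(phy$edge.length)) el[phy$edge[, 2L]] <- phy$edge.length
  if (!is.null(phy$root.edge)) el[root] <- phy$root.edge
  planted_tree(parent, labels, el)
}

# Convert a planted_tree (+ lengths) back to ape phylo (internal).
planted_to_phylo <- function(tree, lengths = tree$edge_length) {
  ntip <- sum(tree$is_leaf)
  old <- c(which(tree$is_leaf), tree$root,
           setdiff(which(!tree$is_leaf),
                   c(tree$root, tree$planted_root)))
  newid <- integer(tree$nv)
  newid[old] <- seq_along(old)
  keep <- setdiff(seq_len(tree$nv), c(tree$planted_root, tree$root))
  edge <- cbind(newid[tree$parent[keep]], newid[keep])
  phy <- list(edge = edge, tip.label = tree$labels[tree$is_leaf][
                order(newid[which(tree$is_leaf)])],
              Nnode = ntip - 1L)
  phy$tip.label <- tree$labels[old[seq_len(ntip)]]
  if (!all(is.na(lengths))) {
    phy$edge.length <- lengths[keep]
    if (!is.na(lengths[tree$root])) phy$root.edge <- lengths[tree$root]
  }
  class(phy) <- "phylo"
  attr(phy, "order") <- NULL
  phy
}

#' Write a planted tree as Newick
#'
#' @param tree A `planted_tree`.
#' @param lengths Per-vertex lengths of the edge above each vertex; defaults
#'   to `tree$edge_length`. The root's entry becomes the Newick root edge.
#' @return A Newick string.
#' @export
write_newick_planted <- function(tree, lengths = tree$edge_length) {
  ape::write.tree(planted_to_phylo(tree, lengths))
}

# Depth (number of edges from planted root) of every vertex (internal).
vertex_depths <- function(tree) {
  depth <- integer(tree$nv)
  for (v in rev(tree$postorder)) {
    p <- tree$parent[v]
    depth[v] <- if (is.na(p)) 0L else depth[p] + 1L
  }
  depth
}

# LCA of two vertices by walking up (internal; trees here are small).
lca_pair <- function(tree, depth, a, b) {
  while (a != b) {
    if (depth[a] >= depth[b]) a <- tree$parent[a] else b <- tree$parent[b]
  }
  a
}

#' The sigma (LCA) map from gene tree to species tree
#'
#' For a gene leaf, `sigma` is the species leaf hosting the gene; for an
#' internal gene vertex `u`, it is the least common ancestor in the species
#' tree of the species hosting the leaves of the subtree below `u`. The
#' planted root of the gene tree is assigned the same value as the gene root.
#'
#' @param gene_tree,species_tree `planted_tree` objects.
#' @param leaf_map Named character vector mapping gene leaf labels to species
#'   leaf labels.
#' @return Integer vector of species-tree vertex ids, one per gene vertex.
#' @export
sigma_map <- function(gene_tree, species_tree, leaf_map) {
  sp_leaf_id <- match(leaf_map, species_tree$labels)
  if (anyNA(sp_leaf_id))
    stop("leaf map names unknown species: ",
         paste(leaf_map[is.na(sp_leaf_id)], collapse = ", "))
  names(sp_leaf_id) <- names(leaf_map)
  depth <- vertex_depths(species_tree)
  sig <- integer(gene_tree$nv)
  for (u in gene_tree$postorder) {
    if (gene_tree$is_leaf[u]) {
      lab <- gene_tree$labels[u]
      if (is.na(match(lab, names(leaf_map))))
        stop("gene leaf not in leaf map: ", lab)
      sig[u] <- sp_leaf_id[[lab]]
    } else if (u == gene_tree$planted_root) {
      sig[u] <- sig[gene_tree$root]
    } else {
      ch <- gene_tree$children[u, ]
      sig[u] <- lca_pair(species_tree, depth, sig[ch[1L]], sig[ch[2L]])
    }
  }
  sig
}

#' Read a gene-to-species leaf mapping file
#'
#' Two whitespace-separated columns, `gene species`; lines starting with `#`
#' (and blank lines) are ignored.
#'
#' @param file Path to the mapping file.
#' @return Named character vector (names = gene labels, values = species
#'   labels).
#' @export
read_leaf_map <- function(file) {
  ln <- readLines(file)
  ln <- trimws(ln)
  ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  parts <- strsplit(ln, "[ \t]+")
  bad <- lengths(parts) != 2L
  if (any(bad)) stop("malformed mapping line: ", ln[bad][1L])
  stats::setNames(vapply(parts, `[`, "", 2L), vapply(parts, `[`, "", 1L))
}

#' Write a gene-to-species leaf mapping file
#' @param leaf_map Named character vector (gene -> species).
#' @param file Output path.
#' @export
write_leaf_map <- function(leaf_map, file) {
  writeLines(paste(names(leaf_map), leaf_map), file)
}

# Stable identifier of a gene vertex: the sorted leaf labels of its subtree,
# comma-joined (internal; used in serialized realizations).
subtree_leafset_labels <- function(tree) {
  sets <- vector("list", tree$nv)
  for (v in tree$postorder) {
    sets[[v]] <- if (tree$is_leaf[v]) tree$labels[v]
                 else sort(unlist(sets[tree$children[v, ][
                   !is.na(tree$children[v, ])]]))
  }
  vapply(sets, paste, "", collapse = ",")
}
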
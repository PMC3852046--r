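# Most parsimonious reconciliation and reconciliation distances.
#
# The MPR is the LCA mapping: a gene vertex is a duplication exactly when
# its sigma equals the sigma of one of its children; duplications are
# placed on the species edge immediately above sigma(u). Distances between
# two reconciliations are built from an atomary distance between objects of
# the species tree (vertices and edges):
#
#   d(a, b) = l + 1 - |{a, b} ∩ V(S)| / 2 - |{a, b} ∩ E(S)|
#
# with l the edge count of the minimum-length path of S containing both
# objects and the intersection counted with multiplicity, so that
# d(a, a) = 0, a vertex and its parent edge are 0.5 apart, and two adjacent
# edges are 1 apart.

#' Most parsimonious reconciliation
#'
#' @param gene_tree A `planted_tree`.
#' @param S A `timed_species_tree` (only its topology is used).
#' @param leaf_map Named character vector, gene leaf -> species leaf.
#' @return List of class `mpr_result` with `reconciliation` (a
#'   [reconciliation()]) and `duplication_count`.
#' @export
mpr <- function(gene_tree, S, leaf_map) {
  st <- S$tree
  sig <- sigma_map(gene_tree, st, leaf_map)
  type <- rep("vertex", gene_tree$nv)
  id <- sig
  for (u in seq_len(gene_tree$nv)) {
    if (gene_tree$is_leaf[u] || u == gene_tree$planted_root) next
    ch <- gene_tree$children[u, ]
    if (sig[u] == sig[ch[1L]] || sig[u] == sig[ch[2L]]) {
      type[u] <- "edge"          # duplication on the edge above sigma(u)
      id[u] <- sig[u]
    }
  }
  type[gene_tree$planted_root] <- "vertex"
  id[gene_tree$planted_root] <- st$planted_root
  rec <- reconciliation(type, id, gene_tree)
  structure(list(reconciliation = rec,
                 duplication_count = sum(type == "edge")),
            class = "mpr_result")
}

#' @export
print.mpr_result <- function(x, ...) {
  cat("most parsimonious reconciliation:", x$duplication_count,
      "duplication(s)\n")
  invisible(x)
}

# Vertex set of the tree path between two vertices (internal).
path_vertices <- function(tree, depth, a, b) {
  pa <- a; pb <- b
  upa <- a; upb <- b
  while (depth[pa] > depth[pb]) { pa <- tree$parent[pa]; upa <- c(upa, pa) }
  while (depth[pb] > depth[pa]) { pb <- tree$parent[pb]; upb <- c(upb, pb) }
  while (pa != pb) {
    pa <- tree$parent[pa]; upa <- c(upa, pa)
    pb <- tree$parent[pb]; upb <- c(upb, pb)
  }
  union(upa, upb)
}

#' Atomary distance between two species tree objects
#'
#' Implements the elementary distance between vertices/edges of the species
#' tree used to compare reconciliations: `l + 1 - |{a,b} ∩ V|/2 -
#' |{a,b} ∩ E|`, where `l` is the number of edges of the shortest path of S
#' containing both objects.
#'
#' @param a_type,b_type `"vertex"` or `"edge"`.
#' @param a_id,b_id Species vertex id, or lower endpoint id for an edge.
#' @param S A `timed_species_tree`.
#' @return Nonnegative distance (0 iff the objects coincide).
#' @export
atomary_distance <- function(a_type, a_id, b_type, b_id, S) {
  tree <- S$tree
  depth <- vertex_depths(tree)
  ends <- function(type, id) {
    if (type == "vertex") id else c(id, tree$parent[id])
  }
  ea <- ends(a_type, a_id)
  eb <- ends(b_type, b_id)
  need <- union(ea, eb)
  best <- Inf
  for (x in ea) for (y in eb) {
    pv <- path_vertices(tree, depth, x, y)
    if (all(need %in% pv)) best <- min(best, length(pv) - 1L)
  }
  if (!is.finite(best)) {
    # neither endpoint pair's path covers both objects (e.g. one object
    # hangs off the path): extend over all endpoint pairs of the union
    for (x in need) for (y in need) {
      pv <- path_vertices(tree, depth, x, y)
      if (all(need %in% pv)) best <- min(best, length(pv) - 1L)
    }
  }
  if (!is.finite(best)) stop("objects do not lie on a common path")
  nv <- (a_type == "vertex") + (b_type == "vertex")
  ne <- (a_type == "edge") + (b_type == "edge")
  best + 1 - nv / 2 - ne
}

# Per-gene-vertex atomary distances between two reconciliations (internal).
recon_vertex_distances <- function(gamma, gamma_prime, S) {
  if (!identical(gamma$gene_tree$labels, gamma_prime$gene_tree$labels))
    stop("reconciliations refer to different gene trees")
  vapply(seq_len(gamma$gene_tree$nv), function(u)
    atomary_distance(gamma$type[u], gamma$id[u],
                     gamma_prime$type[u], gamma_prime$id[u], S),
    0.0)
}

#' Maximum and average distance between two reconciliations
#'
#' `distance_max` is the largest atomary distance over gene vertices;
#' `distance_avg` sums the atomary distance over all gene vertices (leaf
#' and planted-root terms are 0 for sound reconciliations) and divides by
#' the number of internal vertices, the planted root excluded.
#'
#' @param gamma,gamma_prime `reconciliation` objects over the same gene
#'   tree.
#' @param S The `timed_species_tree`.
#' @return A single nonnegative number.
#' @export
distance_max <- function(gamma, gamma_prime, S) {
  max(recon_vertex_distances(gamma, gamma_prime, S))
}

#' @rdname distance_max
#' @export
distance_avg <- function(gamma, gamma_prime, S) {
  gt <- gamma$gene_tree
  n_int <- sum(!gt$is_leaf) - 1L      # internal vertices, planted root excluded
  sum(recon_vertex_distances(gamma, gamma_prime, S)) / n_int
}
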
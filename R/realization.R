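# Discretized realizations and reconciliations.
#
# A d-realization alpha maps every gene tree vertex to a vertex of the
# discretized species tree S' (the planted gene root to the planted species
# root, leaves to their host species leaves); it pins every duplication to a
# time slice. Projecting interior placements to their species edge yields
# the unique associated reconciliation gamma: vertices mapped to species
# vertices are speciations, vertices mapped to edges are duplications.

#' Sample d-realizations from their posterior given (G, l, theta)
#'
#' Draws the gene root's placement from the normalized root-placement
#' distribution, then each child's placement conditional on its parent's,
#' exactly per the factorization of the dynamic program. Uses the current R
#' random number stream, so results are reproducible under `set.seed()`.
#'
#' @param dp A `"sum"`-variant [dlrs_tables()] object.
#' @param n Number of independent draws.
#' @return For `n = 1` a `d_realization` (list with `mapping`, the S'
#'   vertex id per gene vertex, and `gene_tree`); otherwise a list of them.
#' @export
sample_drealization <- function(dp, n = 1) {
  stopifnot(inherits(dp, "dlrs_dp"), dp$variant == "sum")
  Sd <- dp$Sd
  gt <- dp$family$gene_tree
  if (!any(dp$rootw > 0))
    stop("no sound d-realization exists at this discretization ",
         "(a chain of nested events may need more points per edge; ",
         "increase k)")
  map <- matrix(NA_integer_, n, gt$nv)
  map[, gt$planted_root] <- Sd$sindex[Sd$species$tree$planted_root]
  gr <- dp$g_root + 1L
  map[, gr] <- sample.int(Sd$n, n, replace = TRUE, prob = dp$rootw)
  for (u in rev(gt$postorder)) {
    if (gt$is_leaf[u] || u == gt$planted_root) next
    for (c0 in gt$children[u, ]) {
      if (gt$is_leaf[c0]) { map[, c0] <- dp$sigma[c0]; next }
      ys <- map[, u]
      for (y in unique(ys)) {
        rows <- which(ys == y)
        ds <- Sd$desc[[y]]
        wt <- dp$C[y, ds] *
          edge_length_density(dp$family$lengths[c0],
                              Sd$times[y] - Sd$times[ds],
                              dp$params$rates) *
          dp$diag[ds, c0]
        if (!any(wt > 0))
          stop("inconsistent table: all-zero placement conditional")
        map[rows, c0] <- ds[sample.int(length(ds), length(rows),
                                       replace = TRUE, prob = wt)]
      }
    }
  }
  out <- lapply(seq_len(n), function(i)
    structure(list(mapping = map[i, ], gene_tree = gt),
              class = "d_realization"))
  if (n == 1L) out[[1L]] else out
}

#' The MAP d-realization by backpointer traceback
#'
#' @param dp A `"max"`-variant [dlrs_tables()] object.
#' @return A `d_realization` with attribute `log_density`, the log density
#'   `max_alpha p(G, l, alpha | theta, S)`.
#' @export
map_drealization <- function(dp) {
  stopifnot(inherits(dp, "dlrs_dp"), dp$variant == "max")
  if (dp$root_argmax < 0) stop("no realization has positive density")
  Sd <- dp$Sd
  gt <- dp$family$gene_tree
  mapping <- rep(NA_integer_, gt$nv)
  mapping[gt$planted_root] <- Sd$sindex[Sd$species$tree$planted_root]
  mapping[dp$g_root + 1L] <- dp$root_argmax + 1L
  for (u in rev(gt$postorder)) {
    if (gt$is_leaf[u] || u == gt$planted_root) next
    y <- mapping[u]
    mapping[gt$children[u, 1L]] <- dp$bp1[y, u] + 1L
    mapping[gt$children[u, 2L]] <- dp$bp2[y, u] + 1L
  }
  structure(list(mapping = mapping, gene_tree = gt),
            class = "d_realization", log_density = dp$loggen)
}

#' @export
print.d_realization <- function(x, ...) {
  cat("d-realization of", sum(x$gene_tree$is_leaf), "leaf gene tree;",
      "placements:", paste(x$mapping, collapse = " "), "\n")
  invisible(x)
}

#' Construct a reconciliation
#'
#' @param type Character vector, one entry per gene vertex: `"vertex"`
#'   (speciation, mapped to a species vertex) or `"edge"` (duplication,
#'   mapped to a species edge).
#' @param id Integer vector of species vertex ids; for `"edge"` entries the
#'   edge's lower (child) endpoint.
#' @param gene_tree The `planted_tree` the mapping refers to.
#' @return Object of class `reconciliation`.
#' @export
reconciliation <- function(type, id, gene_tree) {
  stopifnot(length(type) == gene_tree$nv, length(id) == gene_tree$nv,
            all(type %in% c("vertex", "edge")))
  structure(list(type = type, id = as.integer(id), gene_tree = gene_tree),
            class = "reconciliation")
}

#' @export
print.reconciliation <- function(x, ...) {
  nd <- sum(x$type == "edge")
  cat("reconciliation:", nd, "duplication(s),",
      sum(x$type == "vertex"), "speciation placement(s)\n")
  invisible(x)
}

#' Project a d-realization to its reconciliation
#'
#' Every realization determines a unique reconciliation: a gene vertex
#' placed on a species vertex maps to that vertex (a speciation); a vertex
#' placed on any interior discretization point of an edge maps to that edge
#' (a duplication), regardless of which interior point.
#'
#' @param alpha A `d_realization`.
#' @param Sd The `discretized_species_tree` the placements refer to.
#' @return A `reconciliation`.
#' @export
to_reconciliation <- function(alpha, Sd) {
  m <- alpha$mapping
  isv <- Sd$is_species[m]
  reconciliation(type = ifelse(isv, "vertex", "edge"),
                 id = ifelse(isv, Sd$sp_vertex[m], Sd$sp_edge[m]),
                 gene_tree = alpha$gene_tree)
}

#' Are two reconciliations identical?
#' @param a,b `reconciliation` objects over the same gene tree.
#' @return Logical.
#' @export
reconciliations_equal <- function(a, b) {
  identical(a$type, b$type) && identical(a$id, b$id)
}

# Position interval of a reconciliation image in the species tree: for a
# vertex x, (top = x, bottom = x); for an edge, (top = parent of lower
# endpoint, bottom = lower endpoint) (internal).
recon_interval <- function(type, id, S) {
  if (type == "vertex") c(top = id, bottom = id)
  else c(top = S$tree$parent[id], bottom = id)
}

# Is vertex `a` a descendant-or-self of vertex `b` in tree? (internal)
is_desc_or_self <- function(tree, depth, a, b) {
  while (depth[a] > depth[b]) a <- tree$parent[a]
  a == b
}

#' Validate soundness of a reconciliation
#'
#' Checks that the planted gene root maps to the planted species root, that
#' gene leaves map to their host species leaves, and that no gene vertex is
#' mapped closer to the species root than its parent's image (two vertices
#' on the same edge are allowed; a vertex and its parent on the same species
#' vertex are not).
#'
#' @param gamma A `reconciliation`.
#' @param family The `gene_family` it reconciles.
#' @param S The `timed_species_tree`.
#' @return Invisibly `TRUE`; errors otherwise.
#' @export
validate_reconciliation <- function(gamma, family, S) {
  gt <- family$gene_tree
  stopifnot(identical(gamma$gene_tree$labels, gt$labels))
  sig <- sigma_map(gt, S$tree, family$leaf_map)
  pr <- gt$planted_root
  if (gamma$type[pr] != "vertex" || gamma$id[pr] != S$tree$planted_root)
    stop("unsound reconciliation: planted root must map to the planted species root")
  for (u in which(gt$is_leaf))
    if (gamma$type[u] != "vertex" || gamma$id[u] != sig[u])
      stop("unsound reconciliation: gene leaf ", gt$labels[u],
           " must map to its host species leaf")
  depth <- vertex_depths(S$tree)
  for (u in seq_len(gt$nv)) {
    p <- gt$parent[u]
    if (is.na(p)) next
    same_edge <- gamma$type[u] == "edge" && gamma$type[p] == "edge" &&
      gamma$id[u] == gamma$id[p]
    if (same_edge) next
    if (gamma$type[u] == "vertex" && gamma$type[p] == "vertex" &&
        gamma$id[u] == gamma$id[p])
      stop("unsound reconciliation: a vertex and its parent share a species vertex")
    iu <- recon_interval(gamma$type[u], gamma$id[u], S)
    ip <- recon_interval(gamma$type[p], gamma$id[p], S)
    if (!is_desc_or_self(S$tree, depth, iu[["top"]], ip[["bottom"]]))
      stop("unsound reconciliation: gene vertex ", u,
           " is mapped above its parent's image")
  }
  invisible(TRUE)
}

# 0/1 diagonal mask restricting each gene vertex's event placement to the
# S' image of gamma(u) (internal).
reconciliation_mask <- function(gamma, gene_tree, Sd) {
  mask <- matrix(0L, Sd$n, gene_tree$nv)
  for (u in seq_len(gene_tree$nv)) {
    allowed <- if (gamma$type[u] == "vertex") Sd$sindex[gamma$id[u]]
               else r_map(Sd, edge = gamma$id[u])
    mask[allowed, u] <- 1L
  }
  mask
}

#' Posterior probability density of a fixed reconciliation
#'
#' Runs the generation-probability recursion with every placement sum
#' restricted to the species vertices or edge interiors prescribed by
#' `gamma`, yielding `p(G, l, gamma | theta, S)`. Summing this quantity
#' over all sound reconciliations recovers `p(G, l | theta, S)`.
#'
#' @inheritParams dlrs_tables
#' @param gamma A sound `reconciliation` (validated before computation).
#' @param log Return the log density?
#' @return The (log) probability density (0 for reconciliations whose
#'   placements admit no realization).
#' @export
reconciliation_probability <- function(family, gamma, params, Sd,
                                       log = FALSE, bd = NULL, C = NULL) {
  dp <- dlrs_tables(family, params, Sd, variant = "sum", gamma = gamma,
                    bd = bd, C = C)
  if (log) dp$loggen else exp(dp$loggen)
}

#' Serialize a d-realization or reconciliation to TSV
#'
#' Gene vertices are identified by the sorted comma-joined leaf labels of
#' their subtree (stable across isomorphic trees); species positions by the
#' same convention on the species tree, edges as `edge_above:<lower-end>`.
#' Realizations additionally record the within-edge discretization point
#' index, counted from the lower end (`NA` at species vertices).
#'
#' @param x A `d_realization` or `reconciliation`.
#' @param Sd A `discretized_species_tree` (needed for realizations and for
#'   labeling species positions).
#' @param file Output path.
#' @return Invisibly, the data frame written.
#' @export
write_mapping_tsv <- function(x, Sd, file) {
  gt <- x$gene_tree
  gid <- subtree_leafset_labels(gt)
  slab <- subtree_leafset_labels(Sd$species$tree)
  if (inherits(x, "d_realization")) {
    g <- to_reconciliation(x, Sd)
    # within-edge index from the lower end
    pt <- vapply(x$mapping, function(v) {
      if (Sd$is_species[v]) return(NA_integer_)
      match(v, r_map(Sd, edge = Sd$sp_edge[v]))
    }, 0L)
  } else {
    g <- x
    pt <- rep(NA_integer_, gt$nv)
  }
  kind <- ifelse(g$type == "edge", "duplication", "speciation")
  pos <- ifelse(g$type == "edge", paste0("edge_above:", slab[g$id]),
                slab[g$id])
  # the planted roots share their subtree leaf set with the true roots:
  # mark them explicitly so the mapping reads back unambiguously
  gid[gt$planted_root] <- "PLANTED_ROOT"
  if (g$type[gt$planted_root] == "vertex" &&
      g$id[gt$planted_root] == Sd$species$tree$planted_root)
    pos[gt$planted_root] <- "PLANTED_ROOT"
  df <- data.frame(gene_vertex = gid, kind = kind,
                   species_vertex_or_edge = pos,
                   discretization_point = pt)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Read a reconciliation back from TSV
#'
#' @param file Path written by [write_mapping_tsv()].
#' @param gene_tree The `planted_tree` the mapping refers to.
#' @param S The `timed_species_tree`.
#' @return A `reconciliation`.
#' @export
read_reconciliation_tsv <- function(file, gene_tree, S) {
  df <- utils::read.table(file, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  gid <- subtree_leafset_labels(gene_tree)
  gid[gene_tree$planted_root] <- "PLANTED_ROOT"
  slab <- subtree_leafset_labels(S$tree)
  at <- match(gid, df$gene_vertex)
  if (anyNA(at)) stop("TSV does not cover every gene vertex")
  pos <- df$species_vertex_or_edge[at]
  isedge <- startsWith(pos, "edge_above:")
  id <- match(sub("^edge_above:", "", pos), slab)
  id[pos == "PLANTED_ROOT"] <- S$tree$planted_root
  if (anyNA(id)) stop("unknown species position in TSV")
  reconciliation(ifelse(isedge, "edge", "vertex"), id, gene_tree)
}
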
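# Dated (ultrametric) species trees and their discretization.
#
# Vertex "time" is age before present: leaves sit at 0 and times strictly
# increase towards the planted root. The discretized tree S' carries, on
# every edge of S (the planted edge included), k extra vertices equidistant
# in time between the edge's endpoints. All dynamic programming downstream
# indexes discretization vertices by integer id, never by floating-point
# time.

#' Build a dated species tree
#'
#' @param x A Newick string/`planted_tree` with branch lengths interpreted as
#'   time spans. The Newick root edge gives the span of the planted edge and
#'   must be present and positive.
#' @param tol Relative tolerance for the ultrametricity check.
#' @return An object of class `timed_species_tree`: list with `tree` (the
#'   `planted_tree`) and `times` (per-vertex ages before present; leaves 0).
#' @export
timed_species_tree <- function(x, tol = 1e-6) {
  tree <- if (inherits(x, "planted_tree")) x else read_newick_planted(text = x)
  el <- tree$edge_length
  if (anyNA(el[-tree$planted_root]))
    stop("species tree needs a time span on every edge, planted edge included")
  if (el[tree$root] <= 0)
    stop("planted edge span must be positive")
  times <- rep(NA_real_, tree$nv)
  for (v in tree$postorder) {
    if (tree$is_leaf[v]) { times[v] <- 0; next }
    ch <- tree$children[v, ]
    ch <- ch[!is.na(ch)]
    tv <- times[ch] + el[ch]
    if (diff(range(tv)) > tol * max(tv, 1e-12))
      stop("species tree is not ultrametric at vertex ", v)
    times[v] <- mean(tv)
  }
  if (any(el[-tree$planted_root] <= 0))
    stop("all time spans must be positive")
  structure(list(tree = tree, times = times), class = "timed_species_tree")
}

#' @export
print.timed_species_tree <- function(x, ...) {
  cat("dated species tree:", sum(x$tree$is_leaf), "leaves, height",
      format(x$times[x$tree$root]), ", planted root at",
      format(x$times[x$tree$planted_root]), "\n")
  invisible(x)
}

#' Discretize a dated species tree
#'
#' Augments every edge of the species tree (including the planted edge) with
#' `k` interior vertices, equidistant in time between the edge's endpoints.
#' The result has `|V(S)| + k * |E(S)|` vertices.
#'
#' @param S A `timed_species_tree`.
#' @param k Number of interior discretization points per edge (>= 1).
#' @return An object of class `discretized_species_tree`: list with
#'   \describe{
#'     \item{species}{the input `timed_species_tree`}
#'     \item{n}{number of vertices of S'}
#'     \item{parent, times}{structure and ages of S' vertices}
#'     \item{children}{list of child id vectors per S' vertex}
#'     \item{is_species}{logical; `TRUE` for vertices of S}
#'     \item{sp_vertex}{for species vertices, the id in S; else `NA`}
#'     \item{sp_edge}{for interior vertices, the S edge they subdivide,
#'       identified by the edge's lower (child) S vertex id; else `NA`}
#'     \item{sindex}{map S vertex id -> S' vertex id}
#'     \item{slice}{per interior vertex, the time width of its slice
#'       (edge span / (k+1)); `NA` for species vertices}
#'     \item{postorder}{S' vertices, children before parents}
#'     \item{desc}{list of proper descendants per S' vertex}
#'   }
#' @export
discretize <- function(S, k = 10L) {
  stopifnot(inherits(S, "timed_species_tree"))
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be a positive integer")
  tr <- S$tree
  ne <- tr$nv - 1L
  n <- tr$nv + k * ne
  parent <- rep(NA_integer_, n)
  times <- numeric(n)
  is_species <- logical(n)
  sp_vertex <- rep(NA_integer_, n)
  sp_edge <- rep(NA_integer_, n)
  slice <- rep(NA_real_, n)
  sindex <- integer(tr$nv)

  sindex[] <- seq_len(tr$nv)          # species vertices keep their ids 1..nv
  is_species[seq_len(tr$nv)] <- TRUE
  sp_vertex[seq_len(tr$nv)] <- seq_len(tr$nv)
  times[seq_len(tr$nv)] <- S$times
  nxt <- tr$nv
  for (v in seq_len(tr$nv)) {
    p <- tr$parent[v]
    if (is.na(p)) next
    span <- S$times[p] - S$times[v]
    delta <- span / (k + 1)
    below <- sindex[v]                # current lower endpoint, climbing up
    for (j in seq_len(k)) {
      nxt <- nxt + 1L
      parent[below] <- nxt
      times[nxt] <- S$times[v] + j * delta
      sp_edge[nxt] <- v
      slice[nxt] <- delta
      below <- nxt
    }
    parent[below] <- sindex[p]
  }
  children <- vector("list", n)
  for (v in seq_len(n)) {
    p <- parent[v]
    if (!is.na(p)) children[[p]] <- c(children[[p]], v)
  }
  post <- integer(n)
  stack <- sindex[tr$planted_root]
  i <- n
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    post[i] <- v; i <- i - 1L
    stack <- c(stack, children[[v]])
  }
  desc <- vector("list", n)
  for (v in post) {
    d <- integer(0)
    for (c0 in children[[v]]) d <- c(d, c0, desc[[c0]])
    desc[[v]] <- d
  }
  structure(
    list(species = S, n = n, k = k, parent = parent, times = times,
         children = children, is_species = is_species,
         sp_vertex = sp_vertex, sp_edge = sp_edge, sindex = sindex,
         slice = slice, postorder = post, desc = desc),
    class = "discretized_species_tree")
}

#' @export
print.discretized_species_tree <- function(x, ...) {
  cat("discretized species tree: ", x$n, " vertices (",
      sum(x$is_species), " species vertices, k = ", x$k,
      " points per edge)\n", sep = "")
  invisible(x)
}

#' Interior discretization vertices of a species edge
#'
#' The `R` map restricted to edges: for an edge of S, identified by its lower
#' (child) vertex, the ids in S' of its interior discretization points; for a
#' vertex of S, the singleton of its S' id.
#'
#' @param Sd A `discretized_species_tree`.
#' @param vertex,edge Exactly one of: an S vertex id, or an S edge given by
#'   its lower endpoint's S vertex id.
#' @return Integer vector of S' vertex ids.
#' @export
r_map <- function(Sd, vertex = NULL, edge = NULL) {
  if (is.null(vertex) == is.null(edge))
    stop("give exactly one of `vertex` or `edge`")
  if (!is.null(vertex)) return(Sd$sindex[vertex])
  which(!is.na(Sd$sp_edge) & Sd$sp_edge == edge)
}
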
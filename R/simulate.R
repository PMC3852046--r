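# Generative simulator: gene families evolving inside a dated species tree.
#
# One gene lineage starts at the planted root. Along a species edge it
# duplicates at rate lambda (splitting into two independent lineages on the
# same edge) or is lost at rate mu; at a speciation vertex it splits into
# one lineage per child edge. Lineages reaching the leaves are extant.
# Lost subtrees are pruned and pass-through vertices contracted, yielding
# the observed planted gene tree. Each pruned-tree edge gets an iid Gamma
# substitution rate; its length is rate times realized time span. Sequences
# then evolve down the tree under the substitution model.

# Recursively evolve one lineage heading down the edge above `sp_child`,
# starting at `t_start` (internal). Returns a nested event-node list.
sim_evolve_edge <- function(S, lambda, mu, sp_child, t_start) {
  t_end <- S$times[sp_child]
  total <- lambda + mu
  wait <- if (total > 0) stats::rexp(1, total) else Inf
  if (t_start - wait > t_end) {
    te <- t_start - wait
    if (stats::runif(1) < lambda / total) {
      list(type = "dup", time = te, sp_edge = sp_child,
           children = list(sim_evolve_edge(S, lambda, mu, sp_child, te),
                           sim_evolve_edge(S, lambda, mu, sp_child, te)))
    } else {
      list(type = "loss", time = te)
    }
  } else {
    ch <- S$tree$children[sp_child, ]
    if (is.na(ch[1L])) {
      list(type = "leaf", time = t_end, sp_vertex = sp_child)
    } else {
      list(type = "spec", time = t_end, sp_vertex = sp_child,
           children = list(sim_evolve_edge(S, lambda, mu, ch[1L], t_end),
                           sim_evolve_edge(S, lambda, mu, ch[2L], t_end)))
    }
  }
}

# Prune lost subtrees and contract single-child vertices (internal).
sim_prune <- function(node) {
  if (node$type == "loss") return(NULL)
  if (node$type == "leaf") return(node)
  kids <- Filter(Negate(is.null), lapply(node$children, sim_prune))
  if (length(kids) == 0L) return(NULL)
  if (length(kids) == 1L) return(kids[[1L]])
  node$children <- kids
  node
}

#' Simulate one gene family under the duplication-loss-rates model
#'
#' @param S A `timed_species_tree`.
#' @param params A `model_params` (`lambda`, `mu`, rate mean/variance, and
#'   the substitution model for sequences).
#' @param seq_length Alignment columns to simulate (0 skips sequences).
#' @param seed Optional integer; when given, `set.seed(seed)` is called
#'   first. Otherwise the current R random number stream is used.
#' @return Object of class `simulated_family`: list with
#'   \describe{
#'     \item{degenerate}{`TRUE` when fewer than 2 lineages survive (then
#'       `family` is `NULL`)}
#'     \item{n_leaves}{surviving gene count}
#'     \item{family}{a `gene_family` (alignment included when requested)}
#'     \item{true_rates}{per-vertex edge rates actually drawn}
#'     \item{events}{data frame of the true realization in continuous time:
#'       per gene vertex its event `type` (`speciation`/`duplication`/
#'       `leaf`), `time`, and species position (`sp_vertex` or `sp_edge`)}
#'   }
#' @export
simulate_family <- function(S, params, seq_length = 100L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tr <- S$tree
  top <- sim_evolve_edge(S, params$lambda, params$mu, tr$root,
                         S$times[tr$planted_root])
  root <- sim_prune(top)
  n_leaves <- if (is.null(root)) 0L else {
    cnt <- function(n) if (n$type == "leaf") 1L else
      sum(vapply(n$children, cnt, 0L))
    cnt(root)
  }
  if (n_leaves < 2L)
    return(structure(list(degenerate = TRUE, n_leaves = n_leaves,
                          family = NULL), class = "simulated_family"))

  # flatten the pruned event tree into planted_tree arrays
  nv <- 0L
  count_v <- function(n) {
    nv <<- nv + 1L
    if (!is.null(n$children)) lapply(n$children, count_v)
    invisible(NULL)
  }
  count_v(root)
  nv <- nv + 1L                       # + planted root
  parent <- rep(NA_integer_, nv)
  labels <- rep(NA_character_, nv)
  vtime <- numeric(nv)
  vtype <- character(nv)
  vpos <- integer(nv)
  sp_count <- integer(tr$nv)
  idx <- 0L
  assign_v <- function(n, par) {
    idx <<- idx + 1L
    me <- idx
    parent[me] <<- par
    vtime[me] <<- n$time
    if (n$type == "leaf") {
      sp_count[n$sp_vertex] <<- sp_count[n$sp_vertex] + 1L
      labels[me] <<- paste0(tr$labels[n$sp_vertex], "_",
                            sp_count[n$sp_vertex])
      vtype[me] <<- "leaf"; vpos[me] <<- n$sp_vertex
    } else if (n$type == "spec") {
      vtype[me] <<- "speciation"; vpos[me] <<- n$sp_vertex
      lapply(n$children, assign_v, par = me)
    } else {
      vtype[me] <<- "duplication"; vpos[me] <<- n$sp_edge
      lapply(n$children, assign_v, par = me)
    }
    invisible(NULL)
  }
  assign_v(root, nv)
  vtime[nv] <- S$times[tr$planted_root]
  vtype[nv] <- "planted_root"; vpos[nv] <- tr$planted_root
  gt <- planted_tree(parent, labels)

  rates <- rep(NA_real_, nv)
  lengths <- rep(NA_real_, nv)
  for (v in seq_len(nv - 1L)) {
    span <- vtime[parent[v]] - vtime[v]
    rates[v] <- stats::rgamma(1, shape = params$rates$shape,
                              rate = params$rates$rate)
    lengths[v] <- max(rates[v] * span, 1e-9)
  }
  leaf_map <- stats::setNames(tr$labels[vpos[gt$is_leaf]],
                              labels[gt$is_leaf])
  aln <- if (seq_length >= 1L)
    simulate_sequences(gt, lengths, seq_length, params_model(params))
  fam <- gene_family(gt, lengths, leaf_map, aln)
  structure(list(degenerate = FALSE, n_leaves = n_leaves, family = fam,
                 true_rates = rates,
                 events = data.frame(vertex = seq_len(nv), type = vtype,
                                     time = vtime, position = vpos)),
            class = "simulated_family")
}

#' @export
print.simulated_family <- function(x, ...) {
  if (x$degenerate) cat("simulated family: degenerate (", x$n_leaves,
                        "surviving lineage(s) )\n")
  else cat("simulated family:", x$n_leaves, "genes,",
           sum(x$events$type == "duplication"), "duplication(s)\n")
  invisible(x)
}

#' True realization of a simulated family on a discretized species tree
#'
#' Converts the recorded continuous-time events to a d-realization by
#' mapping speciations to their species vertices and each duplication to
#' the nearest-in-time interior discretization point of its species edge
#' (ties rounded toward the leaf side).
#'
#' @param sim A non-degenerate `simulated_family`.
#' @param Sd A `discretized_species_tree` of the same species tree.
#' @return A `d_realization`.
#' @export
true_drealization <- function(sim, Sd) {
  stopifnot(!sim$degenerate)
  ev <- sim$events
  mapping <- integer(nrow(ev))
  for (i in seq_len(nrow(ev))) {
    mapping[i] <- switch(
      ev$type[i],
      leaf = ,
      speciation = ,
      planted_root = Sd$sindex[ev$position[i]],
      duplication = {
        pts <- r_map(Sd, edge = ev$position[i])   # ordered bottom-up
        gap <- abs(Sd$times[pts] - ev$time[i])
        pts[which(gap <= min(gap) + 1e-12)[1L]]   # tie -> leafward point
      })
  }
  structure(list(mapping = mapping, gene_tree = sim$family$gene_tree),
            class = "d_realization")
}

#' Simulate a cohort of gene families
#'
#' @inheritParams simulate_family
#' @param n_families Families to generate.
#' @param keep_degenerate Keep families with fewer than 2 survivors in the
#'   returned list (they are always counted in the manifest).
#' @return List with `families` (list of `simulated_family`), `manifest`
#'   (data frame: id, n_leaves, n_duplications, degenerate), and
#'   `n_degenerate`.
#' @export
simulate_cohort <- function(S, params, n_families, seq_length = 100L,
                            seed = NULL, keep_degenerate = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  fams <- vector("list", n_families)
  man <- data.frame(id = seq_len(n_families),
                    n_leaves = integer(n_families),
                    n_duplications = rep(NA_integer_, n_families),
                    degenerate = logical(n_families))
  for (i in seq_len(n_families)) {
    sim <- simulate_family(S, params, seq_length = seq_length)
    man$n_leaves[i] <- sim$n_leaves
    man$degenerate[i] <- sim$degenerate
    if (!sim$degenerate)
      man$n_duplications[i] <- sum(sim$events$type == "duplication")
    fams[[i]] <- sim
  }
  keep <- if (keep_degenerate) rep(TRUE, n_families) else !man$degenerate
  list(families = fams[keep], manifest = man,
       n_degenerate = sum(man$degenerate))
}

#' Write a simulated family to files
#'
#' Emits the observed data exactly as the inference side reads it: a FASTA
#' alignment, a Newick gene tree with lengths, a two-column leaf mapping,
#' and a TSV of the true events.
#'
#' @param sim A non-degenerate `simulated_family`.
#' @param prefix Path prefix; suffixes `.fasta`, `.nwk`, `.map`,
#'   `.events.tsv` are appended.
#' @return Invisibly, the file paths.
#' @export
write_simulated_family <- function(sim, prefix) {
  stopifnot(!sim$degenerate)
  fam <- sim$family
  paths <- paste0(prefix, c(".fasta", ".nwk", ".map", ".events.tsv"))
  if (!is.null(fam$alignment)) write_fasta_alignment(fam$alignment, paths[1])
  writeLines(write_newick_planted(fam$gene_tree, fam$lengths), paths[2])
  write_leaf_map(fam$leaf_map, paths[3])
  utils::write.table(sim$events, paths[4], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
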
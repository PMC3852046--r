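# Independent oracles used across the suite: exhaustive enumeration of
# sound d-realizations and reconciliations with a direct product-form
# density per realization (no use of the dynamic programming tables), plus
# small fixture builders.

sp2 <- function(k = 2) discretize(timed_species_tree("((A:1,B:1):1);"), k)

# Ancestors of an S' vertex, bottom-up (closest first).
oracle_ancestors <- function(Sd, v) {
  out <- integer(0)
  p <- Sd$parent[v]
  while (!is.na(p)) { out <- c(out, p); p <- Sd$parent[p] }
  out
}

# All sound d-realizations of a family: list of integer mappings.
enumerate_drealizations <- function(fam, Sd) {
  gt <- fam$gene_tree
  sig <- Sd$sindex[sigma_map(gt, Sd$species$tree, fam$leaf_map)]
  sproot <- Sd$sindex[Sd$species$tree$planted_root]
  cand <- vector("list", gt$nv)
  for (u in seq_len(gt$nv)) {
    if (u == gt$planted_root) { cand[[u]] <- sproot; next }
    if (gt$is_leaf[u]) { cand[[u]] <- sig[u]; next }
    anc <- oracle_ancestors(Sd, sig[u])
    ok_spec <- Sd$is_species[sig[u]] && length(Sd$children[[sig[u]]]) == 2L
    cand[[u]] <- c(if (ok_spec) sig[u], anc[!Sd$is_species[anc]])
  }
  topdown <- rev(gt$postorder)
  res <- list()
  alpha <- integer(gt$nv)
  recurse <- function(i) {
    if (i > length(topdown)) { res[[length(res) + 1L]] <<- alpha; return() }
    u <- topdown[i]
    for (y in cand[[u]]) {
      p <- gt$parent[u]
      if (!is.na(p) && !(y %in% Sd$desc[[alpha[p]]])) next
      alpha[u] <<- y
      recurse(i + 1L)
    }
  }
  recurse(1L)
  res
}

# Density p(G, l, alpha | theta, S) of one mapping, by direct product over
# gene edges: per-segment survival chain factors, one edge-length density
# per gene edge, a 2*lambda*slice factor per duplication, and the
# opposite-sides constraint at speciation events.
drealization_density <- function(alpha, fam, params, Sd,
                                 bd = build_bd_tables(Sd, params$lambda,
                                                      params$mu)) {
  gt <- fam$gene_tree
  dens <- 1
  for (u in seq_len(gt$nv)) {
    if (u == gt$planted_root) next
    y <- alpha[u]
    x <- alpha[gt$parent[u]]
    if (!(y %in% Sd$desc[[x]])) return(0)
    if (!gt$is_leaf[u] && !Sd$is_species[y])
      dens <- dens * 2 * params$lambda * Sd$slice[y]
    v <- y
    while (v != x) {
      p <- Sd$parent[v]
      dens <- dens * bd$p11[v]
      # sibling-extinction only at speciation vertices passed through
      # without an event (never at the chain start x itself)
      if (p != x && length(Sd$children[[p]]) == 2L)
        dens <- dens * bd$eps_bar[v]
      v <- p
    }
    dens <- dens * dlrs:::edge_length_density(
      fam$lengths[u], Sd$times[x] - Sd$times[y], params$rates)
  }
  for (u in seq_len(gt$nv)) {
    if (gt$is_leaf[u] || u == gt$planted_root) next
    y <- alpha[u]
    if (!Sd$is_species[y]) next
    first_step <- vapply(gt$children[u, ], function(c0) {
      v <- alpha[c0]
      while (Sd$parent[v] != y) v <- Sd$parent[v]
      v
    }, 0L)
    if (first_step[1L] == first_step[2L]) return(0)
  }
  dens
}

# All reconciliation candidates sound enough to carry probability (a
# superset is fine: impossible ones evaluate to 0).
enumerate_reconciliations <- function(fam, S) {
  gt <- fam$gene_tree
  st <- S$tree
  sig <- sigma_map(gt, st, fam$leaf_map)
  # per vertex: list of (type, id) candidates
  cand <- vector("list", gt$nv)
  for (u in seq_len(gt$nv)) {
    if (u == gt$planted_root) {
      cand[[u]] <- list(c("vertex", st$planted_root)); next
    }
    if (gt$is_leaf[u]) { cand[[u]] <- list(c("vertex", sig[u])); next }
    cc <- list()
    if (!st$is_leaf[sig[u]]) cc[[1L]] <- c("vertex", sig[u])
    v <- sig[u]
    while (!is.na(st$parent[v])) {              # edges above sigma(u)
      cc[[length(cc) + 1L]] <- c("edge", v)
      v <- st$parent[v]
    }
    cand[[u]] <- cc
  }
  depth <- dlrs:::vertex_depths(st)
  below_ok <- function(child, par) {
    if (identical(child, par)) return(child[1L] == "edge")
    itop <- if (child[1L] == "vertex") as.integer(child[2L]) else
      st$parent[as.integer(child[2L])]
    ibot <- as.integer(par[2L])
    dlrs:::is_desc_or_self(st, depth, itop, ibot)
  }
  topdown <- rev(gt$postorder)
  res <- list()
  cur <- vector("list", gt$nv)
  recurse <- function(i) {
    if (i > length(topdown)) {
      res[[length(res) + 1L]] <<- reconciliation(
        vapply(cur, `[`, "", 1L), as.integer(vapply(cur, `[`, "", 2L)), gt)
      return()
    }
    u <- topdown[i]
    for (cc in cand[[u]]) {
      p <- gt$parent[u]
      if (!is.na(p) && !below_ok(cc, cur[[p]])) next
      cur[[u]] <<- cc
      recurse(i + 1L)
    }
  }
  recurse(1L)
  res
}

# --- fixture builders -----------------------------------------------------

# Random tiny instance: species tree with <=3 leaves, gene family with
# n_genes leaves, random positive lengths.
random_tiny_instance <- function(n_species = 2, n_genes = 3) {
  snwk <- switch(as.character(n_species),
                 "1" = NULL,
                 "2" = "((A:1,B:1):1);",
                 "3" = "(((A:0.6,B:0.6):0.9,C:1.5):0.8);")
  S <- timed_species_tree(snwk)
  sp <- S$tree$labels[S$tree$is_leaf]
  host <- sample(sp, n_genes, replace = TRUE)
  labs <- paste0(tolower(host), seq_len(n_genes))
  gt <- random_gene_topology(labs)
  lens <- stats::setNames(rep(NA_real_, gt$nv), NULL)
  lens[-gt$planted_root] <- stats::runif(gt$nv - 1L, 0.2, 1.5)
  fam <- gene_family(gt, lens, stats::setNames(host, labs))
  list(S = S, fam = fam)
}

# Uniform-ish random rooted binary topology over the given leaf labels.
random_gene_topology <- function(labs) {
  n <- length(labs)
  stopifnot(n >= 2)
  nv <- 2L * n
  parent <- rep(NA_integer_, nv)
  labels <- c(labs, rep(NA_character_, n))
  roots <- seq_len(n)                # live subtree roots
  nxt <- n
  while (length(roots) > 1L) {
    nxt <- nxt + 1L
    pick <- sample.int(length(roots), 2L)
    parent[roots[pick]] <- nxt
    roots <- c(roots[-pick], nxt)
  }
  parent[roots] <- nv
  planted_tree(parent, labels)
}

# All rooted binary topologies over the labels (as planted_trees).
all_gene_topologies <- function(labs) {
  # enumerate by recursive splitting; the first label always goes left so
  # each unordered split is produced once
  enum <- function(set) {
    if (length(set) == 1L) return(list(set))
    out <- list()
    # split: first element goes left; any nonempty proper subset of the
    # rest joins it
    rest <- set[-1L]
    for (m in 0:(2^length(rest) - 1L)) {
      left <- c(set[1L], rest[bitwAnd(m, 2^(seq_along(rest) - 1L)) > 0])
      right <- setdiff(set, left)
      if (!length(right)) next
      for (L in enum(left)) for (R in enum(right))
        out[[length(out) + 1L]] <- list(L, R)
    }
    out
  }
  lapply(enum(labs), nested_to_planted)
}

# Convert nested list-of-lists (leaves = character) to a planted_tree.
nested_to_planted <- function(nst) {
  parent <- integer(0); labels <- character(0)
  new_v <- function(lab) {
    parent[length(parent) + 1L] <<- NA_integer_
    labels[length(labels) + 1L] <<- lab
    length(parent)
  }
  rec <- function(node) {
    if (is.character(node) && length(node) == 1L) return(new_v(node))
    kids <- vapply(node, rec, 0L)
    me <- new_v(NA_character_)
    parent[kids] <<- me
    me
  }
  r <- rec(nst)
  pl <- new_v(NA_character_)
  parent[r] <- pl
  planted_tree(parent, labels)
}

# Congruent one-gene-per-species family over a species tree, with given
# per-vertex lengths (defaults: rate 1 times each time span).
congruent_family <- function(S, lengths = NULL) {
  st <- S$tree
  labs <- ifelse(st$is_leaf, paste0(tolower(st$labels), "1"), NA)
  gt <- planted_tree(st$parent, labs)
  if (is.null(lengths)) {
    lengths <- rep(NA_real_, st$nv)
    for (v in seq_len(st$nv)[-st$planted_root])
      lengths[v] <- S$times[st$parent[v]] - S$times[v]
  }
  lm <- stats::setNames(st$labels[st$is_leaf], labs[st$is_leaf])
  gene_family(gt, lengths, lm)
}
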
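# Duplication heatmaps over the species tree and cohort summaries of the
# distance between sampled reconciliations and the MPR.

#' Expected duplication counts per discretization vertex
#'
#' Each family's sampled realizations contribute their duplication
#' placements with weight 1/(number of samples of that family), so the
#' result estimates the expected number of duplications at every
#' discretization vertex, summed over families.
#'
#' @param samples List over families; each element a list of
#'   `d_realization` objects over the common `Sd`.
#' @param Sd The `discretized_species_tree`.
#' @return Numeric vector of length `Sd$n` (species vertices always 0).
#' @export
accumulate_duplications <- function(samples, Sd) {
  counts <- numeric(Sd$n)
  for (fam in samples) {
    if (!length(fam)) next
    w <- 1 / length(fam)
    for (al in fam) {
      if (max(al$mapping) > Sd$n)
        stop("realization refers to a different discretization")
      gt <- al$gene_tree
      dup <- al$mapping[!gt$is_leaf & seq_len(gt$nv) != gt$planted_root]
      dup <- dup[!Sd$is_species[dup]]
      for (v in dup) counts[v] <- counts[v] + w
    }
  }
  counts
}

#' Bin duplication counts into 11 heatmap levels
#'
#' Linear equal-width binning of counts into levels 0..10 over the chosen
#' normalization domain: the whole tree (`"global"`), the whole tree minus
#' the interior points of excluded edges (`"global-excluding-edges"`, those
#' points get `NA`), or each species edge independently (`"per-edge"`). The
#' maximum count of a domain maps to level 10 and zero to level 0; an
#' all-zero domain is all level 0.
#'
#' @param counts Numeric vector from [accumulate_duplications()].
#' @param Sd The `discretized_species_tree`.
#' @param mode Normalization mode.
#' @param excluded_edges Integer S vertex ids identifying edges (by lower
#'   endpoint) to exclude in `"global-excluding-edges"` mode.
#' @return Integer levels in 0..10 per S' vertex (`NA` for excluded
#'   points).
#' @export
normalize_heatmap <- function(counts, Sd,
                              mode = c("global", "global-excluding-edges",
                                       "per-edge"),
                              excluded_edges = integer(0)) {
  mode <- match.arg(mode)
  stopifnot(length(counts) == Sd$n, all(counts >= 0))
  bin <- function(x, mx) {
    if (mx <= 0) return(rep(0L, length(x)))
    pmin(10L, as.integer(floor(x / (mx / 11))))
  }
  if (mode == "global") return(bin(counts, max(counts)))
  if (mode == "global-excluding-edges") {
    excl <- !is.na(Sd$sp_edge) & Sd$sp_edge %in% excluded_edges
    lev <- rep(NA_integer_, Sd$n)
    lev[!excl] <- bin(counts[!excl], max(counts[!excl]))
    return(lev)
  }
  lev <- integer(Sd$n)
  for (e in unique(Sd$sp_edge[!is.na(Sd$sp_edge)])) {
    at <- which(!is.na(Sd$sp_edge) & Sd$sp_edge == e)
    lev[at] <- bin(counts[at], max(counts[at]))
  }
  lev
}

#' Write a duplication heatmap
#'
#' Emits a TSV (vertex, species position, age, count, level) and an
#' annotated Newick of the species tree in which each branch carries its
#' interior-point levels, ordered root-to-leaf, as a comment
#' `[&levels=...]`.
#'
#' @param counts,levels As from [accumulate_duplications()] and
#'   [normalize_heatmap()].
#' @param Sd The `discretized_species_tree`.
#' @param file_tsv,file_newick Output paths (`NULL` skips either).
#' @return Invisibly, the annotated Newick string.
#' @export
write_heatmap <- function(counts, levels, Sd, file_tsv = NULL,
                          file_newick = NULL) {
  slab <- subtree_leafset_labels(Sd$species$tree)
  pos <- ifelse(Sd$is_species, slab[Sd$sp_vertex],
                paste0("edge_above:", slab[Sd$sp_edge]))
  if (!is.null(file_tsv))
    utils::write.table(
      data.frame(vertex = seq_len(Sd$n), position = pos, age = Sd$times,
                 count = counts, level = levels),
      file_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  tr <- Sd$species$tree
  lev_str <- function(v) {        # interior levels of edge above v, top first
    pts <- rev(r_map(Sd, edge = v))
    paste(levels[pts], collapse = "|")
  }
  build <- function(v) {
    el <- Sd$species$times[tr$parent[v]] - Sd$species$times[v]
    core <- if (tr$is_leaf[v]) tr$labels[v] else {
      ch <- tr$children[v, ]
      paste0("(", build(ch[1L]), ",", build(ch[2L]), ")")
    }
    paste0(core, ":", format(el), "[&levels=", lev_str(v), "]")
  }
  nwk <- paste0("(", build(tr$root), ");")
  if (!is.null(file_newick)) writeLines(nwk, file_newick)
  invisible(nwk)
}

#' Summarize sampled reconciliations against the MPR
#'
#' For each family, compares every sampled reconciliation with the most
#' parsimonious reconciliation of its own gene tree (topologies may vary
#' across posterior samples, so the MPR is recomputed per sampled tree) and
#' reports the expected average distance, expected maximum distance and the
#' fraction of samples identical to the MPR; cohort-wide, the fraction of
#' all samples differing from their MPR.
#'
#' @param samples List over families; each element a list of
#'   `reconciliation` objects (each carrying its gene tree).
#' @param leaf_maps List of named character vectors (gene -> species), one
#'   per family.
#' @param S The `timed_species_tree`.
#' @return List with `families` (data frame: family, n_samples,
#'   expected_avg_distance, expected_max_distance, frac_identical_mpr) and
#'   `cohort` (list: frac_samples_differing, mean_expected_avg_distance,
#'   mean_expected_max_distance, frac_families_max_ge_0.5).
#' @export
mpr_summary <- function(samples, leaf_maps, S) {
  nf <- length(samples)
  stopifnot(length(leaf_maps) == nf)
  df <- data.frame(family = seq_len(nf), n_samples = integer(nf),
                   expected_avg_distance = rep(NA_real_, nf),
                   expected_max_distance = rep(NA_real_, nf),
                   frac_identical_mpr = rep(NA_real_, nf))
  for (f in seq_len(nf)) {
    recs <- samples[[f]]
    if (!length(recs)) next
    mpr_cache <- new.env(parent = emptyenv())
    davg <- dmax <- numeric(length(recs))
    same <- logical(length(recs))
    for (i in seq_along(recs)) {
      g <- recs[[i]]
      key <- write_newick_planted(g$gene_tree,
                                  rep(1, g$gene_tree$nv))
      m <- mpr_cache[[key]]
      if (is.null(m)) {
        m <- mpr(g$gene_tree, S, leaf_maps[[f]])
        mpr_cache[[key]] <- m
      }
      same[i] <- reconciliations_equal(g, m$reconciliation)
      if (same[i]) { davg[i] <- 0; dmax[i] <- 0 } else {
        dd <- recon_vertex_distances(g, m$reconciliation, S)
        davg[i] <- sum(dd) / (sum(!g$gene_tree$is_leaf) - 1L)
        dmax[i] <- max(dd)
      }
    }
    df$n_samples[f] <- length(recs)
    df$expected_avg_distance[f] <- mean(davg)
    df$expected_max_distance[f] <- mean(dmax)
    df$frac_identical_mpr[f] <- mean(same)
  }
  ok <- df$n_samples > 0
  tot <- sum(df$n_samples[ok])
  list(families = df,
       cohort = list(
         frac_samples_differing =
           sum((1 - df$frac_identical_mpr[ok]) * df$n_samples[ok]) / tot,
         mean_expected_avg_distance = mean(df$expected_avg_distance[ok]),
         mean_expected_max_distance = mean(df$expected_max_distance[ok]),
         frac_families_max_ge_0.5 =
           mean(df$expected_max_distance[ok] >= 0.5)))
}
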
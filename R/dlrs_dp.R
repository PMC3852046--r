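# R-side driver of the generation-probability dynamic program.
#
# `dlrs_tables()` marshals a gene family, model parameters and a discretized
# species tree into the compiled recursion and returns the table object that
# sampling, MAP traceback and probability queries consume. The recursion
# evaluates gene vertices bottom-up; for each gene vertex it fills the
# diagonal s(y, y, u) over all event placements y, with off-diagonal entries
# reconstructed on demand from the chain-factor matrix (one per-segment
# p11 * eps_bar factor per step) and a single edge-length density factor per
# gene edge over its full realized time span.

#' Compute the DLRS dynamic programming tables
#'
#' Runs the recursion for the probability density `p(G, l | theta, S)` that
#' the duplication-loss process with iid Gamma edge rates generates the
#' family's gene tree with its edge lengths inside the dated species tree.
#' With `variant = "max"` every sum over placements becomes a maximum and
#' argmax backpointers are recorded (for the MAP realization); with a
#' `gamma` reconciliation supplied, event placements are restricted to the
#' species vertices/edge interiors that `gamma` prescribes, which turns the
#' result into `p(G, l, gamma | theta, S)`.
#'
#' @param family A `gene_family` (alignment not required).
#' @param params A `model_params`.
#' @param Sd A `discretized_species_tree`.
#' @param variant `"sum"` (marginal probability; default) or `"max"` (MAP).
#' @param gamma Optional `reconciliation` restricting event placements.
#' @param bd,C Optional precomputed [build_bd_tables()] result and chain
#'   matrix for this `(Sd, lambda, mu)` (reused across families in MCMC).
#' @param instance Optional internal marshaling cache for this
#'   `(family, Sd)` pair, for tight loops; computed when `NULL`.
#' @return Object of class `dlrs_dp`: the scaled diagonal table, per-column
#'   log scales, root placement weights, `loggen` (the log probability
#'   density), backpointers for `"max"`, and the inputs needed by
#'   [sample_drealization()] and [map_drealization()].
#' @export
dlrs_tables <- function(family, params, Sd, variant = c("sum", "max"),
                        gamma = NULL, bd = NULL, C = NULL,
                        instance = NULL) {
  variant <- match.arg(variant)
  stopifnot(inherits(family, "gene_family"),
            inherits(params, "model_params"),
            inherits(Sd, "discretized_species_tree"))
  if (is.null(bd)) bd <- build_bd_tables(Sd, params$lambda, params$mu)
  if (is.null(C)) C <- chain_matrix(Sd, bd)
  if (is.null(instance)) instance <- dp_instance(family, Sd)
  gt <- family$gene_tree
  mask <- NULL
  if (!is.null(gamma)) {
    validate_reconciliation(gamma, family, Sd$species)
    mask <- reconciliation_mask(gamma, gt, Sd)
  }
  dupfac <- instance$slice2 * params$lambda
  res <- dlrs_dp_cpp(
    n = Sd$n, sp_parent = instance$sp_parent, sp_time = Sd$times,
    n_child = instance$n_child, is_species = instance$is_species,
    s_post = instance$s_post, desc_ptr = instance$desc_ptr,
    desc_idx = instance$desc_idx, dupfac = dupfac, C = C,
    sp_root = instance$sp_root,
    m = gt$nv, g_parent = instance$g_parent,
    g_child1 = instance$g_child1, g_child2 = instance$g_child2,
    g_post = instance$g_post, sigma = instance$sigma0,
    glen = ifelse(is.na(family$lengths), 0, family$lengths),
    shape = params$rates$shape, gam_rate = params$rates$rate,
    use_max = identical(variant, "max"), mask_ = mask)
  structure(c(res, list(family = family, params = params, Sd = Sd, bd = bd,
                        C = C, sigma = instance$sigma0 + 1L,
                        variant = variant, gamma = gamma)),
            class = "dlrs_dp")
}

# Precomputed integer marshaling of one (family, Sd) pair, reused across
# repeated DP evaluations in MCMC (internal).
dp_instance <- function(family, Sd) {
  gt <- family$gene_tree
  sig <- Sd$sindex[sigma_map(gt, Sd$species$tree, family$leaf_map)]
  slice2 <- 2 * Sd$slice
  slice2[is.na(slice2)] <- 0
  list(
    sp_parent = ifelse(is.na(Sd$parent), -1L, Sd$parent - 1L),
    n_child = lengths(Sd$children),
    is_species = as.integer(Sd$is_species),
    s_post = Sd$postorder - 1L,
    desc_ptr = c(0L, cumsum(lengths(Sd$desc))),
    desc_idx = as.integer(unlist(Sd$desc, use.names = FALSE)) - 1L,
    slice2 = slice2,
    sp_root = Sd$sindex[Sd$species$tree$planted_root] - 1L,
    g_parent = ifelse(is.na(gt$parent), -1L, gt$parent - 1L),
    g_child1 = ifelse(is.na(gt$children[, 1L]), -1L, gt$children[, 1L] - 1L),
    g_child2 = ifelse(is.na(gt$children[, 2L]), -1L, gt$children[, 2L] - 1L),
    g_post = gt$postorder - 1L,
    sigma0 = sig - 1L)
}

#' @export
print.dlrs_dp <- function(x, ...) {
  cat("DLRS ", if (x$variant == "max") "MAP " else "",
      "table: log density = ", format(x$loggen), "\n", sep = "")
  invisible(x)
}

#' Gene tree generation probability
#'
#' The probability density `p(G, l | theta, S)` that the duplication-loss
#' process generates the family's gene tree and edge lengths, summed over
#' all realizations, obtained by closing the recursion at the planted root
#' of the species tree.
#'
#' @inheritParams dlrs_tables
#' @param log Return the log density?
#' @param dp Optionally, a precomputed `"sum"`-variant [dlrs_tables()]
#'   object (the other arguments are then ignored).
#' @return The (log) probability density.
#' @export
generation_probability <- function(family, params, Sd, log = FALSE,
                                   dp = NULL) {
  if (is.null(dp)) dp <- dlrs_tables(family, params, Sd, variant = "sum")
  stopifnot(dp$variant == "sum")
  if (log) dp$loggen else exp(dp$loggen)
}

#' Dump a DLRS table as a data frame
#'
#' Reconstructs the full table `s(x, y, u)` (or `m`) over ancestor pairs of
#' S' vertices from the stored diagonal and chain factors, mainly for
#' debugging and the `dump-table` command-line subcommand. Values are on the
#' true (unscaled) scale, so tiny instances are assumed.
#'
#' @param dp A [dlrs_tables()] result.
#' @return `data.frame` with columns `x`, `y`, `u`, `value` (nonzero
#'   entries only).
#' @export
dp_table_frame <- function(dp) {
  Sd <- dp$Sd; gt <- dp$family$gene_tree
  out <- list()
  cum <- dp$cumlog
  kids <- gt$children
  for (u in seq_len(gt$nv)) {
    if (u == gt$planted_root) next
    own <- cum[u]
    if (!gt$is_leaf[u]) own <- own - cum[kids[u, 1L]] - cum[kids[u, 2L]]
    for (y in which(dp$diag[, u] > 0)) {
      anc <- y
      repeat {
        val <- if (anc == y) dp$diag[y, u] * exp(cum[u]) else
          dp$C[anc, y] *
            edge_length_density(dp$family$lengths[u],
                                Sd$times[anc] - Sd$times[y],
                                dp$params$rates) *
            dp$diag[y, u] * exp(cum[u])
        out[[length(out) + 1L]] <- data.frame(x = anc, y = y, u = u,
                                              value = val)
        anc <- Sd$parent[anc]
        if (is.na(anc)) break
      }
    }
  }
  do.call(rbind, out)
}
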
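# Gene families and model parameter containers.

#' Bundle a gene family
#'
#' A gene family is a planted gene tree with positive lengths on every edge
#' (the planted edge included), a map from gene leaves to species leaves,
#' and optionally an amino-acid alignment over the gene leaves.
#'
#' @param gene_tree A `planted_tree`.
#' @param lengths Per-vertex lengths of the edge above each vertex (`NA`
#'   only at the planted root); defaults to `gene_tree$edge_length`.
#' @param leaf_map Named character vector, gene leaf label -> species leaf
#'   label.
#' @param alignment Optional named character vector of aligned sequences,
#'   one per gene leaf.
#' @return Object of class `gene_family`.
#' @export
gene_family <- function(gene_tree, lengths = gene_tree$edge_length,
                        leaf_map, alignment = NULL) {
  stopifnot(inherits(gene_tree, "planted_tree"))
  lens <- as.numeric(lengths)
  chk <- lens[-gene_tree$planted_root]
  if (anyNA(chk) || any(chk <= 0))
    stop("every gene tree edge (planted edge included) needs a positive length")
  leaves <- gene_tree$labels[gene_tree$is_leaf]
  if (!all(leaves %in% names(leaf_map)))
    stop("leaf map misses gene leaves: ",
         paste(setdiff(leaves, names(leaf_map)), collapse = ", "))
  if (!is.null(alignment)) {
    if (!setequal(names(alignment), leaves))
      stop("alignment names must equal the gene leaf labels")
    if (length(unique(nchar(alignment))) != 1L)
      stop("alignment sequences differ in length")
  }
  structure(list(gene_tree = gene_tree, lengths = lens,
                 leaf_map = leaf_map[leaves], alignment = alignment),
            class = "gene_family")
}

#' @export
print.gene_family <- function(x, ...) {
  cat("gene family:", sum(x$gene_tree$is_leaf), "genes in",
      length(unique(x$leaf_map)), "species",
      if (!is.null(x$alignment))
        paste0("; alignment ", nchar(x$alignment[1]), " aa"), "\n")
  invisible(x)
}

#' DLRS model parameters
#'
#' @param lambda Gene duplication rate (events per time unit, >= 0).
#' @param mu Gene loss rate (>= 0).
#' @param rate_mean,rate_var Mean and variance of the iid Gamma edge rate
#'   distribution (> 0).
#' @param model A `subst_model` (only needed when sequences are involved);
#'   defaults to the packaged JTT model, loaded lazily.
#' @return Object of class `model_params`.
#' @export
model_params <- function(lambda, mu, rate_mean, rate_var, model = NULL) {
  if (lambda < 0 || mu < 0) stop("duplication and loss rates must be >= 0")
  structure(list(lambda = lambda, mu = mu,
                 rates = rate_params(rate_mean, rate_var),
                 model = model),
            class = "model_params")
}

# Fetch (and cache) the substitution model of a model_params (internal).
params_model <- function(params) {
  if (is.null(params$model)) subst_model("JTT") else params$model
}
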
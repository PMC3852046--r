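# Amino-acid sequence evolution: empirical exchangeability models (JTT by
# default), transition matrices via the spectral decomposition of Q, the
# pruning-algorithm likelihood P(D | G, l), and sequence simulation.
#
# The planted edge of the gene tree carries a length and contributes a
# transition; the stationary distribution enters at the planted root. No
# among-site rate variation is modeled: the relaxed clock varies rates
# across edges, not across sites.

AA_LETTERS <- c("A","R","N","D","C","Q","E","G","H","I",
                "L","K","M","F","P","S","T","W","Y","V")

#' Load an empirical amino-acid substitution model
#'
#' Reads a PAML-format `.dat` file (19 lower-triangle exchangeability rows
#' followed by 20 stationary frequencies) and builds the normalized rate
#' matrix `Q` (one expected substitution per unit branch length) together
#' with its cached spectral decomposition. The packaged `"JTT"` matrix is
#' the canonical Jones-Taylor-Thornton (1992) model.
#'
#' @param name Name of a packaged model (currently `"JTT"`), ignored when
#'   `file` is given.
#' @param file Optional path to a PAML `.dat` file with a custom model.
#' @return Object of class `subst_model`: list with `name`, `freq` (20
#'   stationary frequencies), `exch` (symmetric exchangeabilities), `Q`, and
#'   the eigendecomposition used by [transition_matrix()].
#' @export
subst_model <- function(name = "JTT", file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", paste0(tolower(name), ".dat"),
                        package = "dlrs")
    if (!nzchar(file)) stop("no packaged model named ", name)
  }
  ln <- readLines(file)
  ln <- ln[!startsWith(trimws(ln), "//")]
  toks <- as.numeric(unlist(strsplit(trimws(ln[nzchar(trimws(ln))]),
                                     "[ \t]+")))
  if (length(toks) < 210) stop("malformed PAML dat file: ", file)
  ex <- matrix(0, 20, 20)
  k <- 1L
  for (i in 2:20) for (j in 1:(i - 1)) {
    ex[i, j] <- ex[j, i] <- toks[k]; k <- k + 1L
  }
  freq <- toks[k:(k + 19L)]
  freq <- freq / sum(freq)
  Q <- ex * rep(freq, each = 20)
  diag(Q) <- -rowSums(Q)
  scale <- -sum(freq * diag(Q))
  Q <- Q / scale
  # reversible Q: symmetrize with sqrt(pi) for a stable eigendecomposition
  sq <- sqrt(freq)
  B <- Q * (sq / rep(sq, each = 20))    # B[i,j] = sq[i] Q[i,j] / sq[j]
  eig <- eigen((B + t(B)) / 2, symmetric = TRUE)
  structure(list(name = name, freq = freq, exch = ex, Q = Q,
                 eig_val = eig$values,
                 eig_left = eig$vectors / sq,          # D^{-1/2} U
                 eig_right = t(eig$vectors * sq)),     # U' D^{1/2}
            class = "subst_model")
}

#' @export
print.subst_model <- function(x, ...) {
  cat("amino-acid substitution model", x$name,
      "(reversible, Q normalized to 1 substitution/unit length)\n")
  invisible(x)
}

#' Transition probability matrix over a branch
#' @param model A `subst_model`.
#' @param l Nonnegative branch length (expected substitutions per site).
#' @return 20x20 stochastic matrix `exp(Q l)`.
#' @export
transition_matrix <- function(model, l) {
  if (l < 0) stop("negative branch length")
  P <- model$eig_left %*% (exp(model$eig_val * l) * model$eig_right)
  P[P < 0] <- 0
  P / rowSums(P)
}

# Alignment (named character vector of equal-length strings) -> integer
# matrix leaves x sites, 1..20 or NA for gaps/ambiguity (internal).
alignment_to_indices <- function(alignment) {
  if (is.null(names(alignment)) || anyNA(names(alignment)))
    stop("alignment sequences must be named by gene leaf label")
  L <- unique(nchar(alignment))
  if (length(L) != 1L) stop("alignment sequences differ in length")
  if (L == 0L) stop("alignment has zero columns")
  m <- do.call(rbind, lapply(strsplit(toupper(alignment), ""),
                             match, table = AA_LETTERS))
  rownames(m) <- names(alignment)
  m
}

#' Log-likelihood of an alignment on a planted gene tree
#'
#' The pruning-algorithm likelihood `log P(D | G, l)`, summed over alignment
#' columns. Partial likelihoods propagate bottom-up; at the top the root
#' partials are pushed through the planted edge's transition and closed with
#' the stationary frequencies. Gaps and unrecognized residues are missing
#' data (partial vector of ones).
#'
#' @param gene_tree A `planted_tree` whose leaves appear in the alignment.
#' @param lengths Per-vertex lengths of the edge above each vertex; the
#'   entry for the gene root is the planted edge length.
#' @param alignment Named character vector of aligned amino-acid strings.
#' @param model A `subst_model`.
#' @return The log-likelihood (a single number).
#' @export
felsenstein_loglik <- function(gene_tree, lengths, alignment, model) {
  idx <- alignment_to_indices(alignment)
  L <- ncol(idx)
  miss <- setdiff(gene_tree$labels[gene_tree$is_leaf], rownames(idx))
  if (length(miss)) stop("alignment lacks sequences for: ",
                         paste(miss, collapse = ", "))
  part <- vector("list", gene_tree$nv)
  logscale <- 0
  for (v in gene_tree$postorder) {
    if (v == gene_tree$planted_root) next
    if (gene_tree$is_leaf[v]) {
      m <- matrix(0, 20, L)
      states <- idx[gene_tree$labels[v], ]
      ok <- !is.na(states)
      m[cbind(states[ok], which(ok))] <- 1
      m[, !ok] <- 1
      part[[v]] <- m
    } else {
      ch <- gene_tree$children[v, ]
      m <- (transition_matrix(model, lengths[ch[1L]]) %*% part[[ch[1L]]]) *
           (transition_matrix(model, lengths[ch[2L]]) %*% part[[ch[2L]]])
      sc <- max(m)
      if (sc <= 0) return(-Inf)
      part[[v]] <- m / sc
      logscale <- logscale + L * log(sc)
    }
  }
  r <- gene_tree$root
  top <- transition_matrix(model, lengths[r]) %*% part[[r]]
  sum(log(colSums(model$freq * top))) + logscale
}

#' Simulate sequences down a planted gene tree
#'
#' Draws the planted-root state from the stationary frequencies of the model
#' and evolves it down every edge (the planted edge included) with the
#' edge's transition matrix. Uses the current R random number stream.
#'
#' @param gene_tree A `planted_tree`.
#' @param lengths Per-vertex edge lengths as in [felsenstein_loglik()].
#' @param n_sites Number of alignment columns to simulate.
#' @param model A `subst_model`.
#' @return Named character vector of leaf sequences.
#' @export
simulate_sequences <- function(gene_tree, lengths, n_sites, model) {
  stopifnot(n_sites >= 1)
  states <- vector("list", gene_tree$nv)
  pr <- gene_tree$planted_root
  states[[pr]] <- sample.int(20L, n_sites, replace = TRUE, prob = model$freq)
  for (v in rev(gene_tree$postorder)) {
    if (v == pr) next
    P <- transition_matrix(model, lengths[v])
    par_states <- states[[gene_tree$parent[v]]]
    out <- integer(n_sites)
    for (s in unique(par_states)) {
      at <- par_states == s
      out[at] <- sample.int(20L, sum(at), replace = TRUE, prob = P[s, ])
    }
    states[[v]] <- out
  }
  leaves <- which(gene_tree$is_leaf)
  stats::setNames(
    vapply(leaves,
           function(v) paste(AA_LETTERS[states[[v]]], collapse = ""), ""),
    gene_tree$labels[leaves])
}

#' Read a protein alignment from FASTA
#' @param file Path to a FASTA file.
#' @return Named character vector of aligned sequences.
#' @export
read_fasta_alignment <- function(file) {
  x <- Biostrings::readAAStringSet(file)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write a protein alignment to FASTA
#' @param alignment Named character vector of sequences.
#' @param file Output path.
#' @export
write_fasta_alignment <- function(alignment, file) {
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(alignment), filepath = file)
}
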
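# Metropolis-Hastings sampling of (G, l, theta) given alignments and a
# dated species tree.
#
# The target is the unnormalized posterior
#   P(D | G, l) * p(G, l | theta, S) * p(theta),
# the sequence likelihood times the generation probability times the prior.
# One move class is chosen per iteration: a log-scale Gaussian random walk
# on one of (lambda, mu, rate mean, rate variance); a log-normal multiplier
# on one edge length of one family; or a rooted nearest-neighbor
# interchange on one family's topology (symmetric: every rooted binary
# topology on n leaves has the same proposal count). The species tree and
# its divergence times are fixed throughout.

#' MCMC run configuration
#'
#' @param iterations Total proposals.
#' @param burnin_frac Fraction of iterations discarded from the front.
#' @param thin Keep every `thin`-th iteration after burn-in.
#' @param k Discretization points per species edge.
#' @param move_weights Named numeric weights for move classes `length`,
#'   `topology`, `params` (renormalized; classes disabled by `fix_*` get 0).
#' @param sd_log_length,sd_log_param Random-walk standard deviations on the
#'   log scale.
#' @param prior_means Named means of the independent exponential priors on
#'   `lambda`, `mu`, `rate_mean`, `rate_var`.
#' @param init Named starting values for the four parameters.
#' @param fix_topology Keep every family's topology at its initial value.
#' @param fix_lengths Keep edge lengths at their initial values.
#' @param fix_params Character subset of the four parameter names to hold
#'   fixed at their initial values.
#' @param flat_target Replace the posterior by a constant (proposal
#'   diagnostics only).
#' @param n_unobserved Number of families of the cohort that were discarded
#'   as degenerate (at most one surviving gene). When positive, the target
#'   includes the ascertainment term
#'   `n_unobserved * log(unobservable_probability(S, lambda, mu))`, so rate
#'   estimates are not biased by conditioning on observability.
#' @param store_trees Record per-family Newick strings in the trace.
#' @return A config list.
#' @export
mcmc_config <- function(iterations = 10000L, burnin_frac = 0.25, thin = 10L,
                        k = 10L,
                        move_weights = c(length = 0.55, topology = 0.2,
                                         params = 0.25),
                        sd_log_length = 0.5, sd_log_param = 0.3,
                        prior_means = c(lambda = 1, mu = 1, rate_mean = 1,
                                        rate_var = 1),
                        init = c(lambda = 0.5, mu = 0.5, rate_mean = 1,
                                 rate_var = 0.5),
                        fix_topology = FALSE, fix_lengths = FALSE,
                        fix_params = character(0), flat_target = FALSE,
                        n_unobserved = 0L, store_trees = TRUE) {
  list(iterations = as.integer(iterations), burnin_frac = burnin_frac,
       thin = as.integer(thin), k = as.integer(k),
       move_weights = move_weights, sd_log_length = sd_log_length,
       sd_log_param = sd_log_param, prior_means = prior_means, init = init,
       fix_topology = fix_topology, fix_lengths = fix_lengths,
       fix_params = fix_params, flat_target = flat_target,
       n_unobserved = as.integer(n_unobserved), store_trees = store_trees)
}

#' Log posterior density of an MCMC state
#'
#' `log P(D | G, l) + log p(G, l | theta, S) + log p(theta)` for a set of
#' families sharing one parameter vector. Families without an alignment
#' contribute only the generation term.
#'
#' @param families List of `gene_family` objects (current `G`, `l`).
#' @param params A `model_params`.
#' @param Sd A `discretized_species_tree`.
#' @param prior_means Means of the exponential priors (see [mcmc_config()]).
#' @return The log target density.
#' @export
dlrs_log_target <- function(families, params, Sd,
                            prior_means = c(lambda = 1, mu = 1,
                                            rate_mean = 1, rate_var = 1)) {
  model <- params_model(params)
  bd <- build_bd_tables(Sd, params$lambda, params$mu)
  C <- chain_matrix(Sd, bd)
  ll <- 0
  for (fam in families) {
    ll <- ll + generation_probability(fam, params, Sd, log = TRUE,
                                      dp = dlrs_tables(fam, params, Sd,
                                                       bd = bd, C = C))
    if (!is.null(fam$alignment))
      ll <- ll + felsenstein_loglik(fam$gene_tree, fam$lengths,
                                    fam$alignment, model)
  }
  ll + mcmc_log_prior(params, prior_means)
}

mcmc_log_prior <- function(params, prior_means) {
  x <- c(params$lambda, params$mu, params$rates$mean, params$rates$var)
  m <- prior_means[c("lambda", "mu", "rate_mean", "rate_var")]
  # exponential priors; a zero rate (e.g. lambda = mu = 0 limits) sits on
  # the support boundary and is given the density at 0
  sum(stats::dexp(pmax(x, 0), rate = 1 / m, log = TRUE))
}

# Build an initial gene family from an alignment by average-linkage
# clustering of corrected pairwise distances (internal).
init_gene_family <- function(alignment, leaf_map) {
  labs <- names(alignment)
  n <- length(labs)
  if (n < 2L) stop("need at least 2 sequences")
  mat <- do.call(rbind, strsplit(toupper(alignment), ""))
  D <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- mat[i, ] %in% AA_LETTERS & mat[j, ] %in% AA_LETTERS
    p <- if (any(ok)) mean(mat[i, ok] != mat[j, ok]) else 0
    d <- -log(max(1 - p * 20 / 19, 0.05)) * 19 / 20   # Poisson correction
    D[i, j] <- D[j, i] <- max(d, 1e-3)
  }
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  phy <- ape::as.phylo(hc)
  phy$edge.length <- pmax(phy$edge.length, 1e-3)
  phy$root.edge <- max(mean(phy$edge.length), 1e-3)
  tree <- phylo_to_planted(phy)
  gene_family(tree, leaf_map = leaf_map, alignment = alignment)
}

# Rooted NNI: swap a random child of a random internal non-root vertex with
# that vertex's sibling; lengths travel with their subtrees (internal).
propose_nni <- function(tree, lengths) {
  cand <- which(!tree$is_leaf &
                seq_len(tree$nv) != tree$root &
                seq_len(tree$nv) != tree$planted_root)
  if (!length(cand)) return(NULL)
  v <- cand[sample.int(length(cand), 1L)]
  p <- tree$parent[v]
  sib <- setdiff(tree$children[p, ], v)
  c0 <- tree$children[v, sample.int(2L, 1L)]
  parent <- tree$parent
  parent[c0] <- p
  parent[sib] <- v
  planted_tree(parent, tree$labels, lengths)
}

#' Run the Metropolis-Hastings sampler
#'
#' Samples gene trees, edge lengths and the duplication/loss/rate
#' parameters from their joint posterior given alignments and the dated
#' species tree. Several families share one parameter vector (use a list of
#' length 1 for the single-family posterior the model is usually applied
#' to).
#'
#' @param families List of `gene_family` objects with alignments (initial
#'   states), or lists with elements `alignment` and `leaf_map`, in which
#'   case a starting tree is built by distance clustering.
#' @param S A `timed_species_tree`.
#' @param config A [mcmc_config()] list.
#' @param seed Integer seed (the run is reproducible given it).
#' @return Object of class `dlrs_trace`: list with `params` (data frame:
#'   iteration, log_target, lambda, mu, rate_mean, rate_var), `trees`
#'   (per family, Newick strings per retained sample when
#'   `store_trees`), `acceptance` (per move class), `config`, `Sd`.
#' @export
run_mcmc <- function(families, S, config = mcmc_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length(families) >= 1L)
  families <- lapply(families, function(f) {
    if (inherits(f, "gene_family")) f
    else init_gene_family(f$alignment, f$leaf_map)
  })
  nf <- length(families)
  Sd <- discretize(S, config$k)
  model <- subst_model("JTT")
  init <- config$init
  params <- model_params(init[["lambda"]], init[["mu"]],
                         init[["rate_mean"]], init[["rate_var"]],
                         model = model)
  flat <- isTRUE(config$flat_target)

  inst <- lapply(families, dp_instance, Sd = Sd)
  recompute_gen <- function(fam, bd, C, instance) {
    if (flat) 0 else
      dlrs_tables(fam, params, Sd, bd = bd, C = C,
                  instance = instance)$loggen
  }
  ascert <- function(p) {
    if (flat || config$n_unobserved <= 0L) 0 else
      config$n_unobserved * log(unobservable_probability(S, p$lambda, p$mu))
  }
  bd <- if (flat) NULL else build_bd_tables(Sd, params$lambda, params$mu)
  C <- if (flat) NULL else chain_matrix(Sd, bd)
  gen <- vapply(seq_len(nf), function(i)
    recompute_gen(families[[i]], bd, C, inst[[i]]), 0.0)
  asc <- ascert(params)
  seqll <- vapply(families, function(f) {
    if (flat || is.null(f$alignment)) 0
    else felsenstein_loglik(f$gene_tree, f$lengths, f$alignment, model)
  }, 0.0)
  logprior <- if (flat) 0 else mcmc_log_prior(params, config$prior_means)
  if (any(!is.finite(c(gen, seqll))))
    stop("initial state has zero posterior density; check inputs")

  w <- config$move_weights[c("length", "topology", "params")]
  if (config$fix_lengths) w["length"] <- 0
  if (config$fix_topology) w["topology"] <- 0
  if (length(config$fix_params) >= 4L) w["params"] <- 0
  if (all(w <= 0)) stop("all move classes disabled")
  w <- w / sum(w)
  free_params <- setdiff(c("lambda", "mu", "rate_mean", "rate_var"),
                         config$fix_params)

  n_it <- config$iterations
  burn <- floor(config$burnin_frac * n_it)
  keep_at <- seq_len(n_it) > burn & (seq_len(n_it) %% config$thin == 0L)
  nkeep <- sum(keep_at)
  out <- data.frame(iteration = integer(nkeep), log_target = numeric(nkeep),
                    lambda = numeric(nkeep), mu = numeric(nkeep),
                    rate_mean = numeric(nkeep), rate_var = numeric(nkeep))
  trees <- if (config$store_trees)
    replicate(nf, character(nkeep), simplify = FALSE) else NULL
  acc <- c(length = 0, topology = 0, params = 0)
  try_ <- c(length = 0, topology = 0, params = 0)
  ki <- 0L

  for (it in seq_len(n_it)) {
    move <- sample(names(w), 1L, prob = w)
    try_[move] <- try_[move] + 1
    if (move == "params") {
      pn <- free_params[sample.int(length(free_params), 1L)]
      cur <- switch(pn, lambda = params$lambda, mu = params$mu,
                    rate_mean = params$rates$mean,
                    rate_var = params$rates$var)
      prop <- cur * exp(stats::rnorm(1, 0, config$sd_log_param))
      newp <- model_params(
        if (pn == "lambda") prop else params$lambda,
        if (pn == "mu") prop else params$mu,
        if (pn == "rate_mean") prop else params$rates$mean,
        if (pn == "rate_var") prop else params$rates$var, model = model)
      if (flat) {
        new_gen <- gen; new_prior <- 0; new_asc <- 0
        bd2 <- NULL; C2 <- NULL
      } else {
        bd2 <- build_bd_tables(Sd, newp$lambda, newp$mu)
        C2 <- chain_matrix(Sd, bd2)
        new_gen <- vapply(seq_len(nf), function(i)
          dlrs_tables(families[[i]], newp, Sd, bd = bd2, C = C2,
                      instance = inst[[i]])$loggen, 0.0)
        new_prior <- mcmc_log_prior(newp, config$prior_means)
        new_asc <- ascert(newp)
      }
      logA <- sum(new_gen) - sum(gen) + new_prior - logprior +
        new_asc - asc + log(prop / cur)
      if (is.finite(logA) && log(stats::runif(1)) < logA) {
        params <- newp; gen <- new_gen; logprior <- new_prior; asc <- new_asc
        bd <- bd2; C <- C2
        acc[move] <- acc[move] + 1
      }
    } else if (move == "length") {
      fi <- sample.int(nf, 1L)
      fam <- families[[fi]]
      vs <- setdiff(seq_len(fam$gene_tree$nv), fam$gene_tree$planted_root)
      v <- vs[sample.int(length(vs), 1L)]
      newfam <- fam
      newfam$lengths[v] <- fam$lengths[v] *
        exp(stats::rnorm(1, 0, config$sd_log_length))
      new_gen <- recompute_gen(newfam, bd, C, inst[[fi]])
      new_ll <- if (flat || is.null(fam$alignment)) 0 else
        felsenstein_loglik(newfam$gene_tree, newfam$lengths,
                           fam$alignment, model)
      logA <- new_gen + new_ll - gen[fi] - seqll[fi] +
        log(newfam$lengths[v] / fam$lengths[v])
      if (is.finite(logA) && log(stats::runif(1)) < logA) {
        families[[fi]] <- newfam; gen[fi] <- new_gen; seqll[fi] <- new_ll
        acc[move] <- acc[move] + 1
      }
    } else {                                   # topology
      fi <- sample.int(nf, 1L)
      fam <- families[[fi]]
      nt <- propose_nni(fam$gene_tree, fam$lengths)
      if (!is.null(nt)) {
        newfam <- fam
        newfam$gene_tree <- nt
        newfam$lengths <- nt$edge_length
        newinst <- if (flat) NULL else dp_instance(newfam, Sd)
        new_gen <- recompute_gen(newfam, bd, C, newinst)
        new_ll <- if (flat || is.null(fam$alignment)) 0 else
          felsenstein_loglik(nt, newfam$lengths, fam$alignment, model)
        logA <- new_gen + new_ll - gen[fi] - seqll[fi]
        if (is.finite(logA) && log(stats::runif(1)) < logA) {
          families[[fi]] <- newfam; gen[fi] <- new_gen; seqll[fi] <- new_ll
          inst[[fi]] <- newinst
          acc[move] <- acc[move] + 1
        }
      }
    }
    if (keep_at[it]) {
      ki <- ki + 1L
      out$iteration[ki] <- it
      out$log_target[ki] <- sum(gen) + sum(seqll) + logprior + asc
      out$lambda[ki] <- params$lambda
      out$mu[ki] <- params$mu
      out$rate_mean[ki] <- params$rates$mean
      out$rate_var[ki] <- params$rates$var
      if (config$store_trees)
        for (fi in seq_len(nf))
          trees[[fi]][ki] <- write_newick_planted(
            families[[fi]]$gene_tree, families[[fi]]$lengths)
    }
  }
  structure(list(params = out, trees = trees,
                 acceptance = ifelse(try_ > 0, acc / pmax(try_, 1), NA),
                 n_proposed = try_, families_final = families,
                 config = config, Sd = Sd),
            class = "dlrs_trace")
}

#' @export
print.dlrs_trace <- function(x, ...) {
  cat("MCMC trace:", nrow(x$params), "retained samples;",
      "acceptance:", paste(names(x$n_proposed), "=",
                           round(x$acceptance, 2), collapse = ", "), "\n")
  invisible(x)
}

#' Write a trace as TSV
#' @param trace A `dlrs_trace`.
#' @param file Output path. Tree strings of family 1 are appended as a
#'   column when stored.
#' @export
write_trace_tsv <- function(trace, file) {
  df <- trace$params
  if (!is.null(trace$trees)) df$tree <- trace$trees[[1L]]
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Sample reconciliations along a posterior trace
#'
#' Implements the two-stage posterior sampling over realizations: for each
#' retained MCMC sample `(G_i, l_i, theta_i)` of one family, draws
#' `per_sample` d-realizations from `p(alpha | G_i, l_i, theta_i, S)` and
#' projects them to reconciliations.
#'
#' @param trace A `dlrs_trace` from [run_mcmc()] with `store_trees = TRUE`.
#' @param family_index Which family of the run to process.
#' @param leaf_map The family's gene-to-species leaf map.
#' @param per_sample Realizations drawn per posterior sample.
#' @return List with `realizations` and `reconciliations` (flat lists) and
#'   `sample_index` mapping each draw to its trace row.
#' @export
sample_reconciliations_from_trace <- function(trace, family_index = 1L,
                                              leaf_map, per_sample = 1L) {
  stopifnot(!is.null(trace$trees))
  Sd <- trace$Sd
  nwk <- trace$trees[[family_index]]
  pars <- trace$params
  reals <- list(); recs <- list(); idx <- integer(0)
  for (i in seq_along(nwk)) {
    gt <- read_newick_planted(text = nwk[i])
    fam <- gene_family(gt, leaf_map = leaf_map)
    params <- model_params(pars$lambda[i], pars$mu[i], pars$rate_mean[i],
                           pars$rate_var[i])
    dp <- dlrs_tables(fam, params, Sd)
    al <- sample_drealization(dp, n = per_sample)
    if (per_sample == 1L) al <- list(al)
    for (a in al) {
      reals[[length(reals) + 1L]] <- a
      recs[[length(recs) + 1L]] <- to_reconciliation(a, Sd)
      idx <- c(idx, i)
    }
  }
  list(realizations = reals, reconciliations = recs, sample_index = idx)
}

#' Posterior support of the modal gene tree topology
#'
#' The fraction of retained samples whose topology equals the most
#' frequent sampled topology of a family — usable to restrict downstream
#' summaries (e.g. duplication heatmaps) to families whose maximum a
#' posteriori gene tree is well supported.
#'
#' @param trace A `dlrs_trace` with `store_trees = TRUE`.
#' @param family_index Which family of the run.
#' @return List with `newick` (a representative sample of the modal
#'   topology, with its lengths) and `support` (its posterior frequency).
#' @export
map_topology_support <- function(trace, family_index = 1L) {
  stopifnot(!is.null(trace$trees))
  nwk <- trace$trees[[family_index]]
  key <- vapply(nwk, function(x) {
    g <- read_newick_planted(text = x)
    paste(sort(subtree_leafset_labels(g)[!g$is_leaf]), collapse = ";")
  }, "")
  tab <- sort(table(key), decreasing = TRUE)
  modal <- names(tab)[1L]
  list(newick = nwk[match(modal, key)],
       support = as.numeric(tab[1L]) / length(key))
}
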
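# Metropolis-Hastings sampler.

test_that("log target composes likelihood, generation probability and prior", {
  S <- timed_species_tree("(((A:1,B:1):1,C:2):1);")
  set.seed(8)
  fam <- congruent_family(S)
  fam$lengths[-fam$gene_tree$planted_root] <-
    runif(fam$gene_tree$nv - 1, 0.3, 1.2)
  m <- subst_model("JTT")
  fam$alignment <- simulate_sequences(fam$gene_tree, fam$lengths, 20, m)
  pp <- model_params(0, 0, 1.1, 0.4, model = m)
  Sd <- discretize(S, 3)
  pm <- c(lambda = 1, mu = 1, rate_mean = 1, rate_var = 1)
  lt <- dlrs_log_target(list(fam), pp, Sd, pm)
  closed <- generation_probability(fam, pp, Sd, log = TRUE) +
    felsenstein_loglik(fam$gene_tree, fam$lengths, fam$alignment, m) +
    sum(dexp(c(0, 0, 1.1, 0.4), 1, log = TRUE))
  expect_equal(lt, closed, tolerance = 1e-10)
  # perturbing one length away from its clock-consistent value with a
  # tight variance lowers the target
  tight <- model_params(0, 0, 1, 1e-3, model = m)
  fam2 <- congruent_family(S)   # lengths = spans, i.e. rate exactly 1
  fam2$alignment <- fam$alignment
  base <- dlrs_log_target(list(fam2), tight, Sd, pm)
  fam3 <- fam2
  fam3$lengths[1] <- fam3$lengths[1] * 3
  expect_lt(dlrs_log_target(list(fam3), tight, Sd, pm), base)
})

test_that("runs are reproducible given the seed", {
  S <- timed_species_tree("((A:1,B:1):1);")
  set.seed(5)
  repeat {
    sim <- simulate_family(S, model_params(0.3, 0.2, 1, 0.4), 30)
    if (!sim$degenerate) break
  }
  cfg <- mcmc_config(iterations = 300, burnin_frac = 0.2, thin = 2, k = 2,
                     store_trees = TRUE)
  t1 <- run_mcmc(list(sim$family), S, cfg, seed = 77)
  t2 <- run_mcmc(list(sim$family), S, cfg, seed = 77)
  expect_identical(t1$params, t2$params)
  expect_identical(t1$trees, t2$trees)
})

test_that("with a flat target the NNI chain is uniform over topologies", {
  S <- timed_species_tree("(((A:1,B:1):1,(C:1,D:1):1):1);")
  gt0 <- read_newick_planted("(((a1:1,b1:1):1,(c1:1,d1:1):1):1);")
  fam <- gene_family(gt0, leaf_map = c(a1 = "A", b1 = "B",
                                       c1 = "C", d1 = "D"))
  cfg <- mcmc_config(iterations = 16000, burnin_frac = 0.1, thin = 4,
                     move_weights = c(length = 0, topology = 1, params = 0),
                     flat_target = TRUE, k = 1, store_trees = TRUE)
  tr <- run_mcmc(list(fam), S, cfg, seed = 99)
  topo_id <- function(nwk) {
    g <- read_newick_planted(text = nwk)
    paste(sort(dlrs:::subtree_leafset_labels(g)[!g$is_leaf]),
          collapse = ";")
  }
  tab <- table(vapply(tr$trees[[1]], topo_id, ""))
  expect_equal(length(tab), 15L)        # all rooted 4-leaf topologies
  expect_gt(chisq.test(tab)$p.value, 0.001)
})

test_that("fixed topology, no duplication/loss: edge rates are recovered", {
  S <- timed_species_tree("(((A:1,B:1):1,C:2):1);")
  set.seed(16)
  truth <- model_params(0, 0, 1, 0.2)
  fam <- congruent_family(S)
  true_rates <- rgamma(fam$gene_tree$nv, 1 / 0.2, 1 / 0.2)
  spans <- S$times[S$tree$parent] - S$times
  fam$lengths <- true_rates * spans          # planted root span is NA
  m <- subst_model("JTT")
  fam$alignment <- simulate_sequences(fam$gene_tree, fam$lengths, 400, m)
  cfg <- mcmc_config(iterations = 5000, burnin_frac = 0.3, thin = 3, k = 2,
                     move_weights = c(length = 0.8, topology = 0,
                                      params = 0.2),
                     sd_log_length = 0.15,
                     fix_topology = TRUE,
                     fix_params = c("lambda", "mu"),
                     init = c(lambda = 0, mu = 0, rate_mean = 1,
                              rate_var = 0.5),
                     store_trees = TRUE)
  tr <- run_mcmc(list(fam), S, cfg, seed = 6)
  # posterior mean lengths track the true lengths (vertices are matched by
  # the leaf set of their subtree, since parsing may renumber them)
  gt <- fam$gene_tree
  key0 <- dlrs:::subtree_leafset_labels(gt)[-gt$planted_root]
  acc <- numeric(length(key0))
  for (nwk in tr$trees[[1]]) {
    g <- read_newick_planted(text = nwk)
    key <- dlrs:::subtree_leafset_labels(g)[-g$planted_root]
    el <- g$edge_length[-g$planted_root]
    acc <- acc + el[match(key0, key)]
  }
  est <- acc / length(tr$trees[[1]])
  expect_gt(cor(est, fam$lengths[-gt$planted_root]), 0.9)
})

test_that("two chains agree on the duplication rate posterior", {
  S <- timed_species_tree("((A:1,B:1):1);")
  set.seed(44)
  truth <- model_params(0.4, 0.2, 1, 0.3)
  co <- simulate_cohort(S, truth, 12, seq_length = 0)
  fams <- lapply(co$families, `[[`, "family")
  cfg <- mcmc_config(iterations = 1500, burnin_frac = 0.3, thin = 3, k = 3,
                     move_weights = c(length = 0.5, topology = 0,
                                      params = 0.5),
                     fix_topology = TRUE, n_unobserved = co$n_degenerate,
                     store_trees = FALSE)
  tr1 <- run_mcmc(fams, S, cfg, seed = 1)
  tr2 <- run_mcmc(fams, S, cfg, seed = 2)
  m1 <- mean(tr1$params$lambda); m2 <- mean(tr2$params$lambda)
  s1 <- sd(tr1$params$lambda); s2 <- sd(tr2$params$lambda)
  expect_lt(abs(m1 - m2), 2 * (s1 + s2))
})

test_that("an initial gene tree can be built from the alignment alone", {
  S <- timed_species_tree("(((A:1,B:1):1,C:2):1);")
  set.seed(9)
  sim <- simulate_family(S, model_params(0.2, 0.1, 1, 0.3), 50)
  cfg <- mcmc_config(iterations = 200, burnin_frac = 0.25, thin = 2, k = 2)
  tr <- run_mcmc(list(list(alignment = sim$family$alignment,
                           leaf_map = sim$family$leaf_map)),
                 S, cfg, seed = 3)
  expect_s3_class(tr, "dlrs_trace")
  expect_true(all(is.finite(tr$params$log_target)))
})
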
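# Sampling, MAP traceback, reconciliation projection, and the restricted
# recursion.

test_that("sampling is deterministic given the seed", {
  inst <- random_tiny_instance(3, 3)
  Sd <- discretize(inst$S, 2)
  dp <- dlrs_tables(inst$fam, model_params(0.5, 0.3, 1, 0.5), Sd)
  set.seed(33); a1 <- sample_drealization(dp, 4)
  set.seed(33); a2 <- sample_drealization(dp, 4)
  expect_identical(lapply(a1, `[[`, "mapping"),
                   lapply(a2, `[[`, "mapping"))
})

test_that("with lambda = 0 the congruent family has a single realization", {
  S <- timed_species_tree("(((A:0.6,B:0.6):0.9,C:1.5):0.8);")
  fam <- congruent_family(S)
  Sd <- discretize(S, 3)
  dp <- dlrs_tables(fam, model_params(0, 0.2, 1, 0.5), Sd)
  set.seed(1)
  expected <- Sd$sindex[sigma_map(fam$gene_tree, S$tree, fam$leaf_map)]
  expected[fam$gene_tree$planted_root] <- Sd$sindex[S$tree$planted_root]
  for (a in sample_drealization(dp, 5))
    expect_identical(a$mapping, expected)
})

test_that("sampled realizations are sound and match enumerated frequencies", {
  set.seed(12)
  inst <- random_tiny_instance(2, 3)
  Sd <- discretize(inst$S, 3)
  pp <- model_params(0.6, 0.4, 1, 0.5)
  dp <- dlrs_tables(inst$fam, pp, Sd)
  als <- enumerate_drealizations(inst$fam, Sd)
  dens <- vapply(als, drealization_density, 0.0, fam = inst$fam,
                 params = pp, Sd = Sd, bd = dp$bd)
  n <- 8000
  draws <- sample_drealization(dp, n)
  keys <- vapply(draws, function(a) paste(a$mapping, collapse = ","), "")
  ekeys <- vapply(als, paste, "", collapse = ",")
  expect_true(all(keys %in% ekeys[dens > 0]))          # soundness
  pr <- dens / sum(dens)
  keep <- pr > 20 / n
  obs <- as.numeric(table(factor(keys, levels = ekeys))[keep])
  chi <- sum((obs - n * pr[keep])^2 / (n * pr[keep]))
  expect_gt(pchisq(chi, sum(keep) - 1, lower.tail = FALSE), 0.001)
})

test_that("MAP traceback equals the enumeration argmax", {
  set.seed(14)
  done <- 0
  while (done < 4) {
    inst <- random_tiny_instance(sample(2:3, 1), 3)
    Sd <- discretize(inst$S, 2)
    pp <- model_params(runif(1, 0.2, 0.8), runif(1, 0.1, 0.6), 1, 0.5)
    dpm <- dlrs_tables(inst$fam, pp, Sd, variant = "max")
    if (!is.finite(dpm$loggen)) next
    done <- done + 1
    amap <- map_drealization(dpm)
    als <- enumerate_drealizations(inst$fam, Sd)
    dens <- vapply(als, drealization_density, 0.0, fam = inst$fam,
                   params = pp, Sd = Sd, bd = dpm$bd)
    expect_identical(amap$mapping, als[[which.max(dens)]])
    expect_lt(abs(exp(attr(amap, "log_density")) - max(dens)) / max(dens),
              1e-10)
    # max over realizations can never exceed the marginal
    ptot <- generation_probability(inst$fam, pp, Sd)
    expect_lte(max(dens), ptot * (1 + 1e-12))
  }
})

test_that("projection to a reconciliation is the edge-interior quotient", {
  S <- timed_species_tree("((A:1,B:1):1);")
  Sd <- discretize(S, 3)
  gt <- read_newick_planted("((a1:0.5,b1:0.5):0.5);")
  # place the root at each interior point of the planted edge in turn
  pts <- r_map(Sd, edge = S$tree$root)
  base <- Sd$sindex[sigma_map(gt, S$tree, c(a1 = "A", b1 = "B"))]
  recs <- lapply(pts, function(y) {
    al <- structure(list(mapping = replace(
      replace(base, gt$root, y),
      gt$planted_root, Sd$sindex[S$tree$planted_root]),
      gene_tree = gt), class = "d_realization")
    to_reconciliation(al, Sd)
  })
  for (g in recs) {
    expect_equal(g$type[gt$root], "edge")
    expect_equal(g$id[gt$root], S$tree$root)   # the planted edge
  }
  for (i in 2:length(recs))
    expect_true(reconciliations_equal(recs[[1]], recs[[i]]))
  # a vertex placed on a species vertex stays a speciation
  al <- structure(list(mapping = replace(base, gt$planted_root,
                                         Sd$sindex[S$tree$planted_root]),
                       gene_tree = gt), class = "d_realization")
  g <- to_reconciliation(al, Sd)
  expect_equal(g$type[gt$root], "vertex")
  expect_equal(g$id[gt$root], S$tree$root)
})

test_that("reconciliation probabilities renormalize to the marginal", {
  set.seed(18)
  done <- 0
  while (done < 4) {
    inst <- random_tiny_instance(sample(2:3, 1), 3)
    Sd <- discretize(inst$S, 2)
    pp <- model_params(runif(1, 0.2, 0.8), runif(1, 0.1, 0.6), 1, 0.5)
    if (!is.finite(generation_probability(inst$fam, pp, Sd, log = TRUE)))
      next
    done <- done + 1
    bd <- build_bd_tables(Sd, pp$lambda, pp$mu)
    C <- dlrs:::chain_matrix(Sd, bd)
    gams <- enumerate_reconciliations(inst$fam, inst$S)
    tot <- sum(vapply(gams, function(g)
      reconciliation_probability(inst$fam, g, pp, Sd, bd = bd, C = C), 0.0))
    ptot <- generation_probability(inst$fam, pp, Sd)
    expect_lt(abs(tot - ptot) / ptot, 1e-10)
  }
})

test_that("restricted recursion recovers degenerate and zero cases", {
  S <- timed_species_tree("(((A:0.6,B:0.6):0.9,C:1.5):0.8);")
  fam <- congruent_family(S)
  Sd <- discretize(S, 3)
  pp <- model_params(0, 0.2, 1, 0.5)
  # the projection of the only realization carries the whole mass
  sig <- sigma_map(fam$gene_tree, S$tree, fam$leaf_map)
  gam <- reconciliation(rep("vertex", fam$gene_tree$nv), sig,
                        fam$gene_tree)
  gam$id[fam$gene_tree$planted_root] <- S$tree$planted_root
  ptot <- generation_probability(fam, pp, Sd)
  expect_equal(reconciliation_probability(fam, gam, pp, Sd), ptot,
               tolerance = 1e-12)
  # moving the root onto the planted edge demands a duplication: with
  # lambda = 0 the restricted probability is 0
  gam2 <- gam
  gam2$type[fam$gene_tree$root] <- "edge"
  gam2$id[fam$gene_tree$root] <- S$tree$root
  expect_equal(reconciliation_probability(fam, gam2, pp, Sd), 0)
  # unsound reconciliations are rejected before computation
  gam3 <- gam
  gam3$id[fam$gene_tree$planted_root] <- S$tree$root
  expect_error(reconciliation_probability(fam, gam3, pp, Sd), "unsound")
})

test_that("realization and reconciliation TSVs round-trip", {
  set.seed(3)
  inst <- random_tiny_instance(3, 3)
  Sd <- discretize(inst$S, 2)
  dp <- dlrs_tables(inst$fam, model_params(0.5, 0.3, 1, 0.5), Sd)
  al <- sample_drealization(dp)
  f <- withr::local_tempfile(fileext = ".tsv")
  df <- write_mapping_tsv(al, Sd, f)
  expect_true(all(c("gene_vertex", "kind", "species_vertex_or_edge",
                    "discretization_point") %in% names(df)))
  g <- to_reconciliation(al, Sd)
  g2 <- read_reconciliation_tsv(f, inst$fam$gene_tree, inst$S)
  expect_true(reconciliations_equal(g, g2))
})
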
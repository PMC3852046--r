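# Duplication heatmaps and MPR distance summaries.

make_realization <- function(gt, mapping) {
  structure(list(mapping = mapping, gene_tree = gt),
            class = "d_realization")
}

test_that("duplication counts accumulate with per-family sample weights", {
  S <- timed_species_tree("((A:1,B:1):1);")
  Sd <- discretize(S, 3)
  gt <- read_newick_planted("(((a1:1,b1:1):1,(a2:1,b2:1):1):1);")
  sig <- Sd$sindex[sigma_map(gt, S$tree,
                             c(a1 = "A", b1 = "B", a2 = "A", b2 = "B"))]
  pts <- r_map(Sd, edge = S$tree$root)      # planted edge interior
  base <- sig
  base[gt$planted_root] <- Sd$sindex[S$tree$planted_root]
  al1 <- make_realization(gt, replace(base, gt$root, pts[1]))
  al2 <- make_realization(gt, replace(base, gt$root, pts[2]))
  # no duplications anywhere
  fam0 <- congruent_family(S)
  sig0 <- Sd$sindex[sigma_map(fam0$gene_tree, S$tree, fam0$leaf_map)]
  sig0[fam0$gene_tree$planted_root] <- Sd$sindex[S$tree$planted_root]
  counts0 <- accumulate_duplications(
    list(list(make_realization(fam0$gene_tree, sig0))), Sd)
  expect_true(all(counts0 == 0))
  # one family, one sample, one duplication: an indicator
  counts1 <- accumulate_duplications(list(list(al1)), Sd)
  expect_equal(counts1[pts[1]], 1)
  expect_equal(sum(counts1), 1)
  # two samples of one family are weighted 1/2; mass is conserved
  counts2 <- accumulate_duplications(list(list(al1, al2), list(al1)), Sd)
  expect_equal(sum(counts2), 2)             # one expected dup per family
  expect_equal(counts2[pts[1]], 0.5 + 1)
  expect_equal(counts2[pts[2]], 0.5)
})

test_that("heatmap levels bin linearly into 11 levels", {
  S <- timed_species_tree("((A:1,B:1):1);")
  Sd <- discretize(S, 3)
  counts <- numeric(Sd$n)
  interior <- which(!Sd$is_species)
  counts[interior] <- seq(0, length(interior) - 1)
  lev <- normalize_heatmap(counts, Sd, mode = "global")
  expect_equal(min(lev), 0L)
  expect_equal(max(lev), 10L)
  expect_equal(lev[which.max(counts)], 10L)
  # monotone in counts
  o <- order(counts)
  expect_true(all(diff(lev[o]) >= 0))
  # all-zero domain
  expect_true(all(normalize_heatmap(numeric(Sd$n), Sd) == 0L))
})

test_that("per-edge and exclusion modes", {
  S <- timed_species_tree("((A:1,B:1):1);")
  Sd <- discretize(S, 2)
  counts <- numeric(Sd$n)
  a_pts <- r_map(Sd, edge = which(S$tree$labels == "A"))
  top_pts <- r_map(Sd, edge = S$tree$root)
  counts[a_pts] <- c(2, 4)
  counts[top_pts] <- 40                   # uniform on the planted edge
  lev <- normalize_heatmap(counts, Sd, mode = "per-edge")
  expect_equal(lev[a_pts], c(5L, 10L))
  expect_true(all(lev[top_pts] == 10L))   # constant positive edge -> top
  # excluding the dominating edge re-bins the rest as if it were deleted
  lev2 <- normalize_heatmap(counts, Sd, mode = "global-excluding-edges",
                            excluded_edges = S$tree$root)
  expect_true(all(is.na(lev2[top_pts])))
  sub <- counts[setdiff(seq_len(Sd$n), top_pts)]
  expect_equal(lev2[setdiff(seq_len(Sd$n), top_pts)],
               normalize_heatmap(sub, structure(list(
                 n = length(sub), is_species = Sd$is_species[-top_pts],
                 sp_edge = Sd$sp_edge[-top_pts]),
                 class = "discretized_species_tree"), mode = "global"))
})

test_that("heatmap files carry counts, levels, and per-edge annotations", {
  S <- timed_species_tree("((A:1,B:1):1);")
  Sd <- discretize(S, 2)
  counts <- numeric(Sd$n); counts[r_map(Sd, edge = S$tree$root)] <- c(1, 3)
  lev <- normalize_heatmap(counts, Sd)
  f <- withr::local_tempfile(fileext = ".tsv")
  nwk <- write_heatmap(counts, lev, Sd, file_tsv = f)
  df <- read.delim(f)
  expect_equal(nrow(df), Sd$n)
  expect_equal(df$count, counts)
  expect_true(grepl("\\[&levels=", nwk))
})

test_that("MPR summaries aggregate per family and cohort-wide", {
  S <- timed_species_tree("((A:1,B:1):1);")
  Sd <- discretize(S, 3)
  lm <- c(a1 = "A", b1 = "B", a2 = "A", b2 = "B")
  gt <- read_newick_planted("(((a1:1,b1:1):1,(a2:1,b2:1):1):1);")
  m <- mpr(gt, S, lm)$reconciliation
  # family 1: both samples identical to MPR; family 2: one of two differs
  # by moving the root duplication one edge down
  g2 <- m
  g2$id[gt$root] <- S$tree$children[S$tree$root, 1L]
  sm <- mpr_summary(list(list(m, m), list(m, g2)), list(lm, lm), S)
  expect_equal(sm$families$frac_identical_mpr, c(1, 0.5))
  expect_equal(sm$cohort$frac_samples_differing, 0.25)
  expect_equal(sm$families$expected_max_distance[1], 0)
  expect_gt(sm$families$expected_max_distance[2], 0)
  # algebraic identity: cohort fraction differing is 1 minus the
  # sample-weighted mean of the per-family identical fractions
  w <- sm$families$n_samples
  expect_equal(sm$cohort$frac_samples_differing,
               1 - sum(sm$families$frac_identical_mpr * w) / sum(w))
})

test_that("duplication-free cohorts are identical to MPR end to end", {
  S <- timed_species_tree("((A:1,B:1):1);")
  Sd <- discretize(S, 3)
  pp <- model_params(0, 0.3, 1, 0.5)
  set.seed(29)
  co <- simulate_cohort(S, pp, 12, seq_length = 0)
  recs <- list(); lms <- list()
  for (i in seq_along(co$families)) {
    fam <- co$families[[i]]$family
    dp <- dlrs_tables(fam, pp, Sd)
    recs[[i]] <- lapply(sample_drealization(dp, 5), to_reconciliation,
                        Sd = Sd)
    lms[[i]] <- fam$leaf_map
  }
  sm <- mpr_summary(recs, lms, S)
  expect_true(all(sm$families$frac_identical_mpr == 1))
  expect_equal(sm$cohort$frac_samples_differing, 0)
  expect_true(all(sm$families$expected_avg_distance == 0))
})

test_that("inferred duplication counts track the truth on a busy cohort", {
  S <- timed_species_tree("((A:1,B:1):1);")
  Sd <- discretize(S, 4)
  pp <- model_params(0.9, 0.1, 1, 0.4)
  set.seed(41)
  co <- simulate_cohort(S, pp, 40, seq_length = 0)
  true_s <- list(); inf_s <- list()
  for (i in seq_along(co$families)) {
    fam <- co$families[[i]]$family
    dp <- dlrs_tables(fam, pp, Sd)
    if (!is.finite(dp$loggen)) next
    true_s[[length(true_s) + 1L]] <-
      list(true_drealization(co$families[[i]], Sd))
    inf_s[[length(inf_s) + 1L]] <- sample_drealization(dp, 10)
  }
  ct <- accumulate_duplications(true_s, Sd)
  ci <- accumulate_duplications(inf_s, Sd)
  expect_gt(sum(ct), 20)                 # enough events for a signal
  expect_gt(cor(ct, ci, method = "spearman"), 0)
})
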
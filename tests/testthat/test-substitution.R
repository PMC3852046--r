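# Amino-acid substitution model and the pruning likelihood.

test_that("the packaged JTT model is a valid normalized reversible model", {
  m <- subst_model("JTT")
  expect_equal(sum(m$freq), 1, tolerance = 1e-12)
  expect_equal(max(abs(m$exch - t(m$exch))), 0)
  expect_equal(rowSums(m$Q), rep(0, 20), tolerance = 1e-12)
  expect_equal(as.numeric(m$freq %*% m$Q), rep(0, 20), tolerance = 1e-12)
  expect_equal(-sum(m$freq * diag(m$Q)), 1, tolerance = 1e-12)
})

test_that("transition matrices are stochastic with the right limits", {
  m <- subst_model("JTT")
  expect_equal(transition_matrix(m, 0), diag(20), tolerance = 1e-10)
  P <- transition_matrix(m, 0.7)
  expect_equal(rowSums(P), rep(1, 20), tolerance = 1e-12)
  expect_true(all(P >= 0))
  # ergodic limit: every row converges to the stationary frequencies
  Pinf <- transition_matrix(m, 400)
  expect_lt(max(abs(sweep(Pinf, 2, m$freq))), 1e-6)
  # Chapman-Kolmogorov
  expect_lt(max(abs(transition_matrix(m, 0.3) %*% transition_matrix(m, 0.4) -
                    transition_matrix(m, 0.7))), 1e-8)
  expect_error(transition_matrix(m, -0.1), "negative")
})

test_that("pruning likelihood matches the exhaustive state sum", {
  m <- subst_model("JTT")
  gt <- read_newick_planted("((x:0.3,y:0.5):0.2,z:0.7):0.4;")
  lens <- gt$edge_length
  aln <- c(x = "A", y = "R", z = "W")
  ll <- felsenstein_loglik(gt, lens, aln, m)
  Pr <- transition_matrix(m, lens[gt$root])
  iv <- setdiff(which(!gt$is_leaf), c(gt$root, gt$planted_root))
  Pin <- transition_matrix(m, lens[iv])
  Px <- transition_matrix(m, lens[which(gt$labels == "x")])
  Py <- transition_matrix(m, lens[which(gt$labels == "y")])
  Pz <- transition_matrix(m, lens[which(gt$labels == "z")])
  st <- match(c("A", "R", "W"), dlrs:::AA_LETTERS)
  tot <- 0
  for (a in 1:20) for (b in 1:20) for (r0 in 1:20)
    tot <- tot + m$freq[a] * Pr[a, r0] * Pin[r0, b] *
      Px[b, st[1]] * Py[b, st[2]] * Pz[r0, st[3]]
  expect_lt(abs(ll - log(tot)), 1e-10)
})

test_that("pruning likelihood agrees with an independent implementation", {
  skip_if_not_installed("phangorn")
  m <- subst_model("JTT")
  set.seed(9)
  gt <- read_newick_planted("(((x:0.2,y:0.4):0.3,(z:0.6,w:0.1):0.2):0.5);")
  aln <- simulate_sequences(gt, gt$edge_length, 40, m)
  ll <- felsenstein_loglik(gt, gt$edge_length, aln, m)
  phy <- ape::read.tree(text = "(((x:0.2,y:0.4):0.3,(z:0.6,w:0.1):0.2):0.5);")
  dat <- phangorn::phyDat(
    do.call(rbind, strsplit(tolower(aln), ""))[phy$tip.label, ,
                                               drop = FALSE],
    type = "AA")
  fit <- phangorn::pml(phy, dat, model = "JTT")
  expect_lt(abs(ll - fit$logLik), 1e-5)
})

test_that("degenerate likelihood cases", {
  m <- subst_model("JTT")
  # identical residues at zero lengths reduce to the stationary frequency
  gt <- read_newick_planted("((x:1,y:1):1);")
  ll0 <- felsenstein_loglik(gt, c(0, 0, 0, NA), c(x = "AA", y = "AA"), m)
  expect_equal(ll0, 2 * log(m$freq[1]), tolerance = 1e-12)
  # gaps and unknown residues are missing data
  llg <- felsenstein_loglik(gt, gt$edge_length, c(x = "A-", y = "AX"), m)
  ll1 <- felsenstein_loglik(gt, gt$edge_length, c(x = "A", y = "A"), m)
  expect_equal(llg, ll1, tolerance = 1e-9)   # the all-missing column adds 0
  expect_error(felsenstein_loglik(gt, gt$edge_length,
                                  c(x = "", y = ""), m), "zero columns")
  expect_error(felsenstein_loglik(gt, gt$edge_length, c(x = "AA"), m),
               "lacks")
})

test_that("column independence: concatenation adds log-likelihoods", {
  m <- subst_model("JTT")
  set.seed(21)
  gt <- read_newick_planted("((x:0.3,y:0.5):0.2,z:0.7):0.4;")
  a1 <- simulate_sequences(gt, gt$edge_length, 7, m)
  a2 <- simulate_sequences(gt, gt$edge_length, 5, m)
  cat12 <- paste0(a1, a2[names(a1)])
  names(cat12) <- names(a1)
  expect_equal(felsenstein_loglik(gt, gt$edge_length, cat12, m),
               felsenstein_loglik(gt, gt$edge_length, a1, m) +
               felsenstein_loglik(gt, gt$edge_length, a2, m),
               tolerance = 1e-10)
})

test_that("alignment FASTA round-trips", {
  aln <- c(g1 = "ACDEF", g2 = "ACDEY")
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta_alignment(aln, f)
  expect_equal(read_fasta_alignment(f), aln)
})

test_that("a missing-column likelihood equals the gap partial convention", {
  # one leaf, one column: log pi_a
  m <- subst_model("JTT")
  gt <- read_newick_planted("((x:1,y:1):1);")
  # residue A at x, gap at y: the y partial is all ones
  ll <- felsenstein_loglik(gt, c(0.4, 0.4, 0.3, NA),
                           c(x = "A", y = "-"), m)
  # brute force: sum over root/internal states with y marginalized out
  Pr <- transition_matrix(m, 0.3)
  Px <- transition_matrix(m, 0.4)
  tot <- sum(m$freq %*% Pr %*% Px[, match("A", dlrs:::AA_LETTERS)])
  expect_equal(ll, log(tot), tolerance = 1e-12)
})
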
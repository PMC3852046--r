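---
title: "The DLRS model and its implementation in dlrs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The DLRS model and its implementation in dlrs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dlrs)
```

## The model

DLRS couples three processes inside a dated (ultrametric) species tree
`S`:

* **Duplication and loss (DL).** A single gene lineage enters the species
  tree at its planted root (a degree-1 vertex added above the root, so the
  root has an incoming edge). Along any species edge the lineage
  duplicates at rate `lambda` (splitting into two independent lineages on
  the same edge) and dies at rate `mu` — a linear birth–death process. At
  a speciation vertex the lineage splits deterministically into one copy
  per descendant edge. Lineages that reach the present are extant genes;
  pruning all extinct subtrees and contracting pass-through vertices
  yields the observed planted gene tree `G`.
* **Rates (R).** Each edge of the *pruned* gene tree carries its own
  substitution rate, drawn iid from a Gamma distribution parameterized by
  mean `m` and variance `v` (shape `m^2/v`, rate `m/v`) — a relaxed
  molecular clock. An edge spanning time `t` with rate `r` has length
  `l = r * t` expected substitutions per site.
* **Sequences (S).** An empirical amino-acid model (JTT by default, any
  PAML-format matrix can be supplied) generates an alignment down `G`
  with branch lengths `l`; the planted edge carries a length and the
  stationary distribution enters at the planted root.

The joint posterior over gene trees, lengths and parameters given an
alignment `D` and the species tree factorizes as
`P(D | G, l) * p(G, l | theta, S) * p(theta)`, with
`theta = (lambda, mu, m, v, M)`. `P(D | G, l)` is the pruning-algorithm
likelihood; the package's core is the middle factor, the **generation
probability** `p(G, l | theta, S)`.

## Discretization and the dynamic program

Every edge of `S` (planted edge included) is augmented with `k`
equidistant interior vertices, giving the discretized tree `S'`
(`discretize()`). A **d-realization** maps every gene vertex to a vertex
of `S'`: leaves to their host species leaves, speciations to species
vertices, duplications to interior points — it pins each event into a
time slice. Projecting interior points to their edge yields the unique
associated **reconciliation**.

`dlrs_tables()` computes the table `s(x, y, u)` — the density that a
single lineage starting at `x` generates the planted gene subtree at `u`
with the event of `u` at `y` — but stores only its diagonal
`d[y][u] = s(y, y, u)`, because every off-diagonal entry factors as

```
s(x, y, u) = C[x][y] * rho_l(l_u; t(x) - t(y)) * s(y, y, u)
```

where `C[x][y]` multiplies one `p11` survival factor per segment of the
`S'` path from `x` down to `y` (exactly one designated descendant
survives; side lineages die out below) and one sibling-extinction factor
`eps_bar` per speciation vertex *passed through without an event*, and
`rho_l(l; t) = Gamma_pdf(l/t; m, v) / t` is the density of the edge's
length over the candidate time span. Diagonal entries multiply the two
children's placement sums; duplication points carry an extra
`2 * lambda * delta` factor with `delta` the point's slice width.

Three modeling choices deserve explicit statement, because the recursion
can be (and in places has been) written in superficially different forms:

1. **One rate factor per gene edge.** Naively chaining per-segment
   recursions would multiply a rate density at every step. We arrange the
   chaining so the factors telescope: the net contribution of gene edge
   `(p(u), u)` realized from `x` down to `y` is the single factor
   `rho_l(l; t(x, y))` over the full span. This matches the model
   semantics — one iid rate per pruned-tree edge.
2. **Sibling extinction only at pass-through speciations.** When the
   event at a speciation vertex *is* the gene vertex, its two children
   occupy both descendant edges and no sibling copy needs to die; the
   `eps_bar` factor applies only when a lineage crosses a speciation
   vertex silently. Without this distinction the no-loss limit would
   assign probability 0 to a perfectly congruent family, contradicting
   the closed form below.
3. **Lengths are a density; slices are a measure.** The `1/t` Jacobian in
   `rho_l` makes `p(G, l | theta, S)` a proper density over lengths, and
   the `delta` slice width makes the sum over duplication placements a
   midpoint-rule approximation of the underlying time integral — so the
   generation probability converges at rate `O(1/k)` as the
   discretization refines, and slices of unequal width across edges are
   weighted correctly. Both factors cancel from all *conditional*
   quantities on a fixed discretization, but matter for parameter
   inference and for convergence in `k`.

In the no-duplication, no-loss limit with a congruent family the whole
DP collapses to a closed form, `p(G, l | theta, S) = prod_e rho_l(l_e;
t_e)`, which the test suite checks to 1e-10, and on instances small
enough to enumerate, the DP total equals the sum of the independently
computed densities of all sound d-realizations to the same tolerance —
that enumeration (a direct product over gene edges, written without any
reference to the DP tables) is the suite's central oracle.

## Sampling, MAP, and fixed reconciliations

* `sample_drealization()` draws the gene root's placement from the
  normalized root distribution and then each child conditional on its
  parent, exactly per the DP factorization; 20,000 draws on enumerable
  instances pass a chi-squared test against exact probabilities.
* `dlrs_tables(variant = "max")` replaces sums by maxima, records argmax
  backpointers, and `map_drealization()` traces them to the MAP
  d-realization. Ties break toward the lowest vertex index, so the MAP
  output is deterministic.
* `reconciliation_probability()` computes `p(G, l, gamma | theta, S)` for
  a fixed reconciliation `gamma` by masking the diagonal: event
  placements of each gene vertex are restricted to the `S'` image of
  `gamma(u)` (a species vertex, or the interior points of an edge).
  Summing over all sound reconciliations recovers the marginal exactly.

A reconciliation's posterior probability is approximated by the summed
posterior of its d-realizations; the most frequent projected
reconciliation across samples and the projection of the MAP
d-realization are both available and need not coincide — the package
reports whichever the caller asks for, clearly separated.

## MPR and distances

`mpr()` is the classical LCA mapping: `u` is a duplication exactly when
`sigma(u)` equals the sigma of one of its children, and duplications are
placed on the edge immediately above `sigma(u)` (any higher placement
would only add implied losses). Distances between reconciliations are
built from the atomary distance between species tree objects,
`d(a, b) = l + 1 - |{a,b} ∩ V|/2 - |{a,b} ∩ E|`, where `l` counts the
edges of the shortest path containing both objects, the path must contain
an edge-object's both endpoints, and the intersection is counted with
multiplicity (so `d(a, a) = 0`). `distance_max` takes the maximum over
gene vertices; `distance_avg` sums over all of `V(G)` and divides by the
number of internal vertices. The planted root is excluded from that
denominator: its term is identically 0 (both reconciliations pin it to
the planted species root), so including it would only dilute the average
by bookkeeping.

## MCMC

`run_mcmc()` is a Metropolis–Hastings sampler over `(G, l, theta)` with
the species tree fixed. Moves: log-scale Gaussian walks on one of
`lambda, mu, m, v` (multiplicative, Hastings ratio `x'/x`); log-normal
multipliers on a single edge length of one family; and rooted
nearest-neighbor interchanges on one family's topology. Rooted NNI is
irreducible on rooted binary topologies and — because every topology on
`n` leaves offers the same number of NNI moves — symmetric, which the
flat-target test exploits: with the posterior overridden to a constant,
the chain visits all 15 rooted 4-leaf topologies uniformly. NNI is the
only topology move; a subtree-prune-regraft kernel would shorten mixing
paths on large trees but adds Hastings bookkeeping without changing the
stationary distribution, and the desk-scale suite mixes fully with NNI
alone.

Priors are independent exponentials with configurable means (default 1)
on all four parameters — deliberately weakly informative and trivially
computable. Several families may share one `theta`; only the family a
proposal touches is recomputed, and the birth–death tables and chain
factors are rebuilt once per parameter proposal and shared across
families.

**Ascertainment.** A cohort analysis usually discards families with
fewer than two surviving genes, which biases loss-rate estimates
downward if ignored. `mcmc_config(n_unobserved = ...)` adds
`n_unobserved * log P(at most one extant gene | theta, S)` to the
target (`unobservable_probability()`, computed exactly from the
birth–death recursion); the recovery experiment below depends on it.

## The simulator

`simulate_family()` runs the generative process exactly as specified:
exponential waiting times at rate `lambda + mu` along edges, duplication
with probability `lambda/(lambda+mu)`, deterministic splits at
speciations, pruning and contraction of extinct parts, iid Gamma rates on
the pruned edges, lengths = rate × span, sequences from the substitution
model. True events are recorded in continuous time;
`true_drealization()` rounds duplications to the nearest interior point
of their edge (ties toward the leaves). Families with fewer than two
survivors are flagged degenerate and excluded from cohorts by default,
with the count reported — mirroring the observability filter any real
pipeline applies.

What the simulator deliberately does **not** emulate: alignment and
orthology-assignment errors, among-site rate variation, gene conversion
or transfer, per-family rate heterogeneity beyond `(m, v)`, and any
genome-scale family-selection filtering. Passing tests therefore
demonstrate internal consistency of model, algorithms and inference —
not robustness to the violations real data commit.

## Numerical choices and degenerate inputs

* All tables are kept in linear space with per-gene-vertex rescaling (the
  maximum of each column is divided out and re-accumulated in log space),
  so desk-scale and moderately large families are computed without
  underflow; results are returned as log densities.
* `lambda = mu` and `lambda -> 0` / `mu -> 0` limits of the birth–death
  forms are implemented as explicit branches and tested for continuity;
  probabilities are clipped to `[0, 1]` after each closed-form
  evaluation.
* Zero-length gene edges are rejected at input: the rate density sits on
  a support boundary there and the recursions assume positive lengths.
* A family whose gene tree requires a longer chain of stacked events than
  one edge's `k` interior points can host has **no** sound d-realization
  at that discretization; the sampler reports this explicitly and the
  cohort experiments either raise `k` or skip the family with a note.
  The default `k = 10` (configurable everywhere, stated per analysis) is
  far from this regime for the duplication rates considered here.
* MAP tie-breaks: lowest `S'` vertex index wins, deterministically.

## Problem sizes in the shipped experiments

The test suite's calibration experiments are sized for a desk run, as a
package choice: conservation/normalization/MAP identities on 20 random
instances with at most 4 genes, 3 species and `k <= 3` (exhaustive
enumeration stays in the hundreds of mappings); sampler calibration with
20,000 draws on 5 instances; rate recovery on 20 replicates of 50
families over a 4-species tree with 100-residue alignments, fixed
topologies and `k = 3`; and the MPR-disagreement trend on cohorts of 60
families at `lambda` in {0, 0.05, 0.3, 0.8} with `k = 12`. The
genome-scale analyses the model was designed for (tens of thousands of
families, nine species) are out of scope here; nothing in the
implementation is specific to the desk scale except run time.

## Known limitations

* One global `(lambda, mu)` pair — no per-edge or time-varying rates, no
  transfer events, no polytomies or unrooted inputs.
* The reconciliation posterior is approximated through d-realizations,
  so its resolution in time is bounded by `k`.
* `distance_avg` compares reconciliations of the *same* gene tree
  topology; across-topology samples are compared each against the MPR of
  their own tree, as in `mpr_summary()`.
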
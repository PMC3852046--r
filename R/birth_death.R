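# Linear birth-death machinery on the discretized species tree.
#
# Along a species tree edge, a gene lineage duplicates at rate lambda and is
# lost at rate mu (a linear birth-death process). The dynamic programs need,
# for every vertex of S', the probability that a single lineage starting
# there leaves no extant descendant (`ext`), and for every parent-child pair
# of adjacent S' vertices the probability `p11` that exactly one designated
# descendant lineage reaches the child while every side lineage created on
# the way goes extinct below it. At a speciation vertex the designated
# lineage enters one child edge and its sibling copy must die out:
# `eps_bar` is that sibling extinction probability.

#' Classical linear birth-death quantities over one time segment
#'
#' For a single lineage evolving for duration `t` with birth (duplication)
#' rate `lambda` and death (loss) rate `mu`, the number of descendants at
#' `t` is 0 with probability `p_ext`, and `n >= 1` with probability
#' `(1 - p_ext) * (1 - geom) * geom^(n-1)`. The limiting forms at
#' `lambda == mu` and at `lambda == 0` or `mu == 0` are handled explicitly;
#' the functions are continuous in all arguments.
#'
#' @param lambda,mu Nonnegative duplication and loss rates (per time unit).
#' @param t Nonnegative duration.
#' @return List with `p_ext` (probability of 0 descendants), `p11_raw`
#'   (probability of exactly 1 descendant, `(1-p_ext)*(1-geom)`), and `geom`
#'   (the geometric tail parameter of the descendant count).
#' @export
bd_segment <- function(lambda, mu, t) {
  if (t < 0) stop("negative duration")
  if (lambda < 0 || mu < 0) stop("rates must be nonnegative")
  r <- lambda - mu
  if (t == 0 || (lambda == 0 && mu == 0)) {
    a <- 0; b <- 0
  } else if (abs(r) * t < 1e-10) {
    # lambda == mu limit (also covers tiny |lambda - mu| * t)
    a <- lambda * t / (1 + lambda * t)
    b <- a
  } else {
    em <- exp(-r * t)
    denom <- lambda - mu * em
    a <- mu * (1 - em) / denom
    b <- lambda * (1 - em) / denom
  }
  a <- min(max(a, 0), 1)
  b <- min(max(b, 0), 1)
  list(p_ext = a, p11_raw = (1 - a) * (1 - b), geom = b)
}

# One-segment extinction-below and p11 given the extinction probability D at
# the segment's lower end (internal).
bd_step <- function(lambda, mu, t, D) {
  s <- bd_segment(lambda, mu, t)
  denom <- 1 - s$geom * D
  ext <- s$p_ext + (1 - s$p_ext) * (1 - s$geom) * D / denom
  p11 <- (1 - s$p_ext) * (1 - s$geom) / denom^2
  c(ext = min(max(ext, 0), 1), p11 = min(max(p11, 0), 1))
}

#' Birth-death tables over a discretized species tree
#'
#' Computes, bottom-up over S', the extinction probability of a single
#' lineage at every vertex, and for every non-root vertex `v` the one-to-one
#' survival probability `p11` of the segment from `parent(v)` to `v` (side
#' lineages extinct below `v`), together with `eps_bar`, the probability that
#' the sibling copy spawned when the parent is a speciation vertex leaves no
#' extant descendant (1 where the parent has a single child in S').
#' The chains assembled from these factors apply `eps_bar` only at
#' speciation vertices passed through without an event.
#'
#' @param Sd A `discretized_species_tree`.
#' @param lambda,mu Duplication and loss rates.
#' @return Object of class `bd_tables`: list with `ext`, `p11`, `eps_bar`,
#'   (all length `Sd$n`; `p11` and `eps_bar` are `NA` at the planted
#'   root), and `lambda`, `mu`.
#' @export
build_bd_tables <- function(Sd, lambda, mu) {
  n <- Sd$n
  ext <- numeric(n)
  p11 <- rep(NA_real_, n)
  eps <- rep(NA_real_, n)
  for (v in Sd$postorder) {
    ch <- Sd$children[[v]]
    if (!length(ch)) { ext[v] <- 0; next }   # extant species leaf
    e <- 1
    for (c0 in ch) {
      st <- bd_step(lambda, mu, Sd$times[v] - Sd$times[c0], ext[c0])
      p11[c0] <- st[["p11"]]
      e <- e * st[["ext"]]
    }
    ext[v] <- e
    if (length(ch) == 2L) {
      for (i in 1:2) {
        sib <- ch[3L - i]
        st <- bd_step(lambda, mu, Sd$times[v] - Sd$times[sib], ext[sib])
        eps[ch[i]] <- st[["ext"]]
      }
    } else {
      eps[ch] <- 1
    }
  }
  structure(list(ext = ext, p11 = p11, eps_bar = eps,
                 lambda = lambda, mu = mu),
            class = "bd_tables")
}

# Chain factor matrix: C[x, y] = probability factor for one gene lineage
# leaving x (where an event just happened, or the planted root) and
# reaching y with all side lineages extinct: a p11 factor per segment, and
# an eps_bar sibling-extinction factor for every speciation vertex passed
# through WITHOUT an event (strictly between x and y). No eps_bar applies
# at x itself: when the event at x is a speciation, its two gene children
# occupy both sides, so no sibling copy has to die there. 0 when y is not
# a descendant of x; 1 on the diagonal (internal).
chain_matrix <- function(Sd, bd) {
  n <- Sd$n
  C <- matrix(0, n, n)
  diag(C) <- 1
  two <- lengths(Sd$children) == 2L
  for (y in seq_len(n)) {
    acc <- 1
    v <- y
    p <- Sd$parent[v]
    while (!is.na(p)) {
      C[p, y] <- acc * bd$p11[v]          # chain starting exactly at p
      acc <- acc * bd$p11[v] * if (two[p]) bd$eps_bar[v] else 1
      v <- p
      p <- Sd$parent[v]
    }
  }
  C
}

#' Probability that a gene family is unobservable
#'
#' The probability that a single gene lineage starting at the planted root
#' leaves at most one extant descendant, i.e. that the family would be
#' discarded as degenerate. Used as an ascertainment correction when
#' inferring rates from cohorts in which such families are unobserved.
#'
#' @param S A `timed_species_tree`.
#' @param lambda,mu Duplication and loss rates.
#' @return Probability in [0, 1].
#' @export
unobservable_probability <- function(S, lambda, mu) {
  tr <- S$tree
  ext <- numeric(tr$nv)
  one <- numeric(tr$nv)
  for (v in tr$postorder) {
    if (tr$is_leaf[v]) { ext[v] <- 0; one[v] <- 1; next }
    ch <- tr$children[v, ]
    ch <- ch[!is.na(ch)]
    E <- O <- numeric(length(ch))
    for (i in seq_along(ch)) {
      c0 <- ch[i]
      st <- bd_step(lambda, mu, S$times[v] - S$times[c0], ext[c0])
      E[i] <- st[["ext"]]
      O[i] <- st[["p11"]] * one[c0]
    }
    if (length(ch) == 2L) {
      ext[v] <- E[1L] * E[2L]
      one[v] <- O[1L] * E[2L] + E[1L] * O[2L]
    } else {
      ext[v] <- E[1L]
      one[v] <- O[1L]
    }
  }
  p <- tr$planted_root
  min(max(ext[p] + one[p], 0), 1)
}
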
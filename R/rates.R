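# The iid-Gamma relaxed molecular clock.
#
# Each edge of the (pruned) gene tree carries its own substitution rate,
# drawn independently from a Gamma distribution parameterized by mean `m`
# and variance `v` (shape m^2/v, rate m/v). An edge spanning time `t` with
# rate `r` has expected length `l = r * t`; the dynamic programs weight a
# candidate time span by the density of the implied rate `l / t`.

#' Rate model parameters
#' @param mean,var Positive mean and variance of the edge rate distribution.
#' @return Object of class `rate_params` with `mean`, `var`, and the induced
#'   Gamma `shape` and `rate`.
#' @export
rate_params <- function(mean, var) {
  if (mean <= 0 || var <= 0) stop("rate mean and variance must be positive")
  structure(list(mean = mean, var = var,
                 shape = mean^2 / var, rate = mean / var),
            class = "rate_params")
}

#' Density of an edge substitution rate
#' @param r Rate value(s); the density is 0 for `r <= 0`.
#' @param p A `rate_params`.
#' @return Gamma density with the requested mean and variance.
#' @export
rate_density <- function(r, p) {
  out <- numeric(length(r))
  ok <- r > 0
  out[ok] <- stats::dgamma(r[ok], shape = p$shape, rate = p$rate)
  out
}

#' Implied rate of a gene edge over a candidate time span
#' @param l Positive edge length (expected substitutions per site).
#' @param t Positive time span.
#' @return `l / t`.
#' @export
edge_rate <- function(l, t) {
  if (any(t <= 0))
    stop("zero time span: a realization must separate a vertex from its parent in time")
  if (any(l <= 0)) stop("edge lengths must be positive")
  l / t
}

# Density of an edge LENGTH over time span t: Gamma density of the implied
# rate l/t with the change-of-variables factor 1/t, so that it integrates to
# one over l (internal; this is the rho-factor every recursion multiplies
# in, exactly once per gene tree edge).
edge_length_density <- function(l, t, p) {
  stats::dgamma(l / t, shape = p$shape, rate = p$rate) / t
}
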
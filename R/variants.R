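# The eight model variants of the adaptation rate.
#
# Each variant is assembled from three pgf building blocks:
#   growth   -- the law of the mutant count at the end of a growth phase
#               (stochastic: geometric; deterministic: a point mass at the
#               real-valued expectation, entering the pgfs as a real
#               exponent),
#   sampling -- the bottleneck transition applied to that count (binomial
#               thinning pgf 1 - D + D z, or the Poisson approximation
#               exp(D (z - 1)) of the earlier literature),
#   metric   -- per unit time, or per transfer (the per-time rate times tau).
#
# A lineage starting from one cell at a phase start has per-cycle offspring
# pgf G(z) = G_grow(h(z)); its eventual extinction probability is the
# smallest fixed point q = G(q) in [0, 1]. A mutation arising at time t
# inside a phase is propagated through the remainder of that phase and its
# first bottleneck, each survivor then being an independent phase-start
# lineage: V(t, s) = G_first(h(q)).

# Sampling pgf applied to a post-growth count.
.sampling_pgf <- function(z, D, sampling) {
  if (sampling == "binomial") 1 - D + D * z else exp(D * (z - 1))
}

# pgf of the phase-end count of a lineage growing from one cell for
# `elapsed` hours at rate r (1 + s), evaluated at y.
.growth_pgf <- function(y, s, r, elapsed, growth) {
  if (growth == "stochastic") {
    beta <- exp(-r * (1 + s) * elapsed)
    beta * y / (1 - (1 - beta) * y)
  } else {
    m <- exp(r * (1 + s) * elapsed) # real-valued point mass
    y^m
  }
}

# Smallest fixed point of the per-cycle offspring pgf on [0, 1]: the
# per-cycle extinction probability of a phase-start lineage. G is monotone
# and convex on [0, 1] with G(1) = 1, so the sub-1 root (when the mean
# offspring number D^-s exceeds 1) is bracketed and found by Brent search.
.cycle_extinction <- function(s, D, tau, r, growth, sampling) {
  if (s <= 0) return(1)
  G <- function(q) .growth_pgf(.sampling_pgf(q, D, sampling), s, r, tau, growth)
  f <- function(q) q - G(q)
  if (f(1 - 1e-9) <= 0) return(1) # (sub)critical: extinction is certain
  out <- stats::uniroot(f, c(0, 1 - 1e-9), tol = 1e-13)
  if (abs(out$f.root) > 1e-9) {
    stop(sprintf("extinction fixed point did not converge (residual %g)",
                 out$f.root))
  }
  out$root
}

#' Adaptation rate under one of the eight assumption triples
#'
#' Computes the rate of beneficial mutations destined to fix under a chosen
#' combination of optimization metric, growth law, and bottleneck sampling
#' law (see [variant_spec]). Survival probabilities come from the fixed
#' point of the per-cycle offspring pgf; the rate is the same double
#' integral over origin times and selective effects as
#' [fixation_rate_exact], which the `(per_time, stochastic, binomial)`
#' variant reproduces exactly.
#'
#' @param params a [core_params] object with the stable-population
#'   constraint `D = exp(-r tau)`.
#' @param variant a [variant_spec].
#' @return A `rate_result`; `gamma` is per hour, or per transfer when
#'   `variant$metric == "per_transfer"`.
#' @examples
#' p <- core_params(D = 0.1)
#' variant_rate(p, variant_spec("per_time", "stochastic", "binomial"))
#' @export
variant_rate <- function(params, variant) {
  stopifnot(inherits(params, "core_params"), inherits(variant, "variant_spec"))
  if (abs(params$D - exp(-params$r * params$tau)) > 1e-12 * params$D) {
    stop("variant_rate requires the stable-population constraint D = exp(-r tau)")
  }
  r <- params$r; tau <- params$tau; D <- params$D
  growth <- variant$growth; sampling <- variant$sampling
  if (params$mu == 0) return(rate_result(0, "variant_integral", params, variant))
  q_cache <- new.env(parent = emptyenv())
  Vts <- function(t, s) {
    key <- format(s, digits = 17)
    q <- q_cache[[key]]
    if (is.null(q)) {
      q <- .cycle_extinction(s, D, tau, r, growth, sampling)
      q_cache[[key]] <- q
    }
    .growth_pgf(.sampling_pgf(q, D, sampling), s, r, tau - t, growth)
  }
  g <- .rate_double_integral(params, Vts)
  if (variant$metric == "per_transfer") g <- g * tau
  rate_result(g, "variant_integral", params, variant)
}

#' Optimal D for a model variant
#'
#' Maximizes [variant_rate] over `D` with `tau = log(1/D)/r` coupled by the
#' stable-population constraint, by bounded scalar search on the `ln D`
#' scale (ties broken toward larger D; the per-time binomial objective is
#' flat near `D -> 1`).
#'
#' @param variant a [variant_spec].
#' @param r,mu,N,omega model parameters, as in [core_params].
#' @param interval search range for D (kept away from the 0/0 endpoints).
#' @return A list with `D_star`, `ratio`, and `gamma_star`.
#' @export
optimal_D_variant <- function(variant, r = 1, mu = 1e-9, N = 1e9,
                              omega = 0.1, interval = c(1e-4, 0.999)) {
  obj <- function(lD) {
    D <- exp(lD)
    variant_rate(core_params(r = r, mu = mu, N = N, omega = omega, D = D),
                 variant)$gamma
  }
  op <- stats::optimize(obj, log(interval), maximum = TRUE, tol = 1e-9)
  D_star <- exp(op$maximum)
  # tie-break toward larger D on a flat shoulder: if the endpoint value is
  # within numerical tolerance of the interior "maximum", report the endpoint
  hi <- obj(log(interval[2]))
  if (hi >= op$objective * (1 - 1e-9)) D_star <- interval[2]
  list(D_star = D_star, ratio = 1 / D_star,
       gamma_star = max(op$objective, hi))
}
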
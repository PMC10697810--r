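#' Size distribution of a pure-birth (Yule) lineage
#'
#' The number of cells descended from one founder after `elapsed` hours of
#' pure-birth growth at per-capita rate `growth_rate` is geometrically
#' distributed on \{1, 2, ...\} with parameter `exp(-growth_rate * elapsed)`;
#' a pure-birth lineage can never reach size zero.
#'
#' @param growth_rate per-capita division rate (per hour), > 0.
#' @param elapsed elapsed time (hours), >= 0.
#' @param count lineage size(s) at which to evaluate the pmf; positive
#'   integers.
#' @return `P(X(elapsed) = count)`, vectorised over `count`.
#' @examples
#' yule_size_pmf(1, log(2), 1)  # 0.5
#' @export
yule_size_pmf <- function(growth_rate, elapsed, count) {
  stopifnot(growth_rate > 0)
  if (elapsed < 0) stop("elapsed time must be nonnegative")
  if (any(count < 1) || any(count != round(count))) {
    stop("count is outside the support {1, 2, ...} of a pure-birth process")
  }
  beta <- exp(-growth_rate * elapsed)
  beta * (1 - beta)^(count - 1)
}

#' Mutant count distribution across one bottleneck
#'
#' A mutant lineage of geometric size (parameter `beta`, see
#' [mutation_context]) passes a bottleneck in which each cell survives
#' independently with probability `D`. The post-bottleneck count follows the
#' geometric law compounded with binomial thinning; its probability
#' generating function is the geometric pgf composed with `1 - D + D z`,
#' which yields the closed form used here:
#' `P_0 = beta (1 - D) / a` and, for `i >= 1`,
#' `P_i = (beta / a) * ((1 - D) q^i + D q^(i-1))` with
#' `a = 1 - (1 - beta)(1 - D)` and `q = (1 - beta) D / a`.
#'
#' @param ctx a [mutation_context], or any list with a `beta` field in
#'   (0, 1].
#' @param D per-cell bottleneck survival probability, in (0, 1).
#' @param i post-bottleneck count(s), nonnegative integers.
#' @return `P(M(tau+) = i)`, vectorised over `i`.
#' @export
bottleneck_transition_pmf <- function(ctx, D, i) {
  beta <- if (is.list(ctx)) ctx$beta else ctx
  stopifnot(beta > 0, beta <= 1, D > 0, D < 1)
  if (any(i < 0) || any(i != round(i))) stop("i must be a nonnegative integer")
  if (beta == 1) { # the lineage is a single cell facing a Bernoulli(D) draw
    return(ifelse(i == 0, 1 - D, ifelse(i == 1, D, 0)))
  }
  a <- 1 - (1 - beta) * (1 - D)
  q <- (1 - beta) * D / a
  ifelse(i == 0, beta * (1 - D) / a,
         (beta / a) * ((1 - D) * q^i + D * q^(i - 1)))
}

#' Extinction probability of a mutation arising at the start of a growth
#' phase
#'
#' For a mutant with selective effect `s` arising exactly at the start of a
#' growth phase, under the stable-population constraint the probability that
#' the lineage eventually leaves no descendants is
#' `V(0, s) = (1/D - 1) / (D^-(1+s) - 1)`. A neutral lineage (`s = 0`) goes
#' extinct almost surely; the removable singularity is handled analytically.
#'
#' @param s selective effect, > -1.
#' @param D per-cell bottleneck survival probability, in (0, 1).
#' @return The eventual extinction probability, in (0, 1].
#' @examples
#' survival_initial(1, 0.5)  # 1/3
#' @export
survival_initial <- function(s, D) {
  if (D <= 0 || D >= 1) stop("D must lie strictly inside (0, 1)")
  stopifnot(s > -1)
  if (s <= 0) return(1)
  (1 / D - 1) / (D^-(1 + s) - 1)
}

#' Extinction probability of a mutation arising at time t in a growth phase
#'
#' General solution for the eventual extinction probability of a mutant
#' lineage founded at time `t` within a growth phase:
#' `V(t, s) = 1 / (1 + (1 - D^s) / (beta (1/D - 1)))` with
#' `beta = exp(-r (1 + s)(tau - t))`. It equals the post-bottleneck pgf of
#' the lineage evaluated at `V(0, s)` (each cell surviving the first
#' bottleneck starts an independent copy of the phase-start problem).
#' Requires the stable-population constraint `D = exp(-r tau)`.
#'
#' @param t origin time within the growth phase, in `[0, tau)` hours.
#' @param s selective effect, >= 0.
#' @param core a [core_params] object (with `stable = TRUE`).
#' @return The eventual extinction probability `V(t, s)`.
#' @export
survival_at_time <- function(t, s, core) {
  stopifnot(inherits(core, "core_params"))
  if (abs(core$D - exp(-core$r * core$tau)) > 1e-12 * core$D) {
    stop("survival_at_time requires the stable-population constraint D = exp(-r tau)")
  }
  if (any(t < 0) || any(t >= core$tau)) stop("origin time t must lie in [0, tau)")
  if (s <= 0) return(rep_len(1, length(t)))
  D <- core$D
  beta <- exp(-core$r * (1 + s) * (core$tau - t))
  1 / (1 + (1 - D^s) / (beta * (1 / D - 1)))
}

# Fail loudly if adaptive quadrature did not converge.
.integrate_checked <- function(f, lower, upper, what,
                               rel.tol = 1e-9, abs.tol = 1e-12) {
  out <- stats::integrate(f, lower, upper, rel.tol = rel.tol,
                          abs.tol = abs.tol, stop.on.error = FALSE)
  if (out$message != "OK") {
    stop(sprintf("quadrature for %s did not converge (%s; abs.error = %g)",
                 what, out$message, out$abs.error))
  }
  out$value
}

# Shared double integral: gamma = (1/tau) int_s w(s) int_t mu N D r e^(rt)
# (1 - V(t, s)) dt ds, with V(t, s) supplied per variant. The s-integral is
# truncated at 40 omega, where the exponential weight's tail mass is < 1e-10
# of the total.
.rate_double_integral <- function(params, Vts) {
  r <- params$r; tau <- params$tau; D <- params$D
  inner <- function(s) {
    f <- function(t) params$mu * params$N * D * r * exp(r * t) * (1 - Vts(t, s))
    .integrate_checked(Vectorize(f), 0, tau, "the origin-time integral")
  }
  outer <- function(s) stats::dexp(s, 1 / params$omega) * inner(s)
  .integrate_checked(Vectorize(outer), 0, 40 * params$omega,
                     "the selective-effect integral", rel.tol = 1e-8) / tau
}

#' Adaptation rate: exact double integral
#'
#' Expected number of beneficial mutations per hour that are destined to
#' fix, integrating the mutation supply `mu N D r e^(r t)` against the
#' survival probability `1 - V(t, s)` over origin times in the growth phase
#' and exponentially distributed selective effects.
#'
#' @param params a [core_params] object with the stable-population
#'   constraint.
#' @return A `rate_result` with `method = "exact_integral"`.
#' @seealso [fixation_rate_approx] for the closed-form approximation.
#' @export
fixation_rate_exact <- function(params) {
  stopifnot(inherits(params, "core_params"))
  if (abs(params$D - exp(-params$r * params$tau)) > 1e-12 * params$D) {
    stop("fixation_rate_exact requires the stable-population constraint D = exp(-r tau)")
  }
  if (params$mu == 0) return(rate_result(0, "exact_integral", params))
  g <- .rate_double_integral(params, function(t, s)
    survival_at_time(t, s, params))
  rate_result(g, "exact_integral", params)
}

#' Adaptation rate: closed-form approximation
#'
#' `gamma ~ r mu N * omega/(1 + omega) * ln(1/D)/(1/D - 1)`, the closed-form
#' approximation to the exact double integral. The `omega/(1+omega)` factor
#' stands in for the exact average survival `E[s/(1+s)]` of exponentially
#' distributed effects, so the approximation overshoots by roughly a factor
#' `(1 + omega) E[1/(1+s)]` (about 1% at `omega = 0.01`, 8% at
#' `omega = 0.1`); the D-dependence `ln(1/D)/(1/D - 1)` is excellent
#' throughout. Monotonically increasing in D: the continuous-culture limit
#' `D -> 1` gives the rate `r*mu*N*omega/(1+omega)` and maximizes the adaptation
#' rate per unit time.
#'
#' @inheritParams fixation_rate_exact
#' @return A `rate_result` with `method = "approximation"`.
#' @export
fixation_rate_approx <- function(params) {
  stopifnot(inherits(params, "core_params"))
  D <- params$D
  g <- params$r * params$mu * params$N * params$omega / (1 + params$omega) *
    log(1 / D) / (1 / D - 1)
  rate_result(g, "approximation", params)
}

#' Adaptation effective population size
#'
#' Size of an idealized constant population that would adapt at the same
#' rate as the serially bottlenecked one, obtained by equating the
#' closed-form adaptation rate with `gamma = Ne mu 2 omega`:
#' `Ne ~ N r ln(1/D) / (2 (1/D - 1))`.
#'
#' Note a transcription ambiguity in the source formula: as printed it tends
#' to `N r / 2` (not `N`) in the continuous-culture limit `D -> 1` at
#' `r` = 1, while the surrounding text asserts the limit is `N`. The printed
#' form is implemented verbatim; the factor-2 discrepancy is exposed (not
#' silently corrected) and flagged in the test suite.
#'
#' @inheritParams fixation_rate_exact
#' @return The adaptation effective population size (cells).
#' @export
ne_effective <- function(params) {
  stopifnot(inherits(params, "core_params"))
  D <- params$D
  params$N * params$r * log(1 / D) / (2 * (1 / D - 1))
}

#' Adaptation rate general to resource-constrained growth
#'
#' With resource-limited (or any sub-exponential) growth the exponential
#' model applies with the average growth rate `rbar = ln(1/D)/tau` and the
#' equilibrium pre-bottleneck population size `N*` in place of `r` and `N`:
#' `gamma ~ (1/tau) mu N* omega/(1+omega) (ln D)^2 / (1/D - 1)`. When
#' `N* = N` and `tau = ln(1/D)/r` this reduces exactly to
#' [fixation_rate_approx].
#'
#' @param tau growth-period length (hours), > 0.
#' @param mu beneficial mutation probability per division.
#' @param N_star equilibrium pre-bottleneck population size, > 0.
#' @param omega mean selective effect, > 0.
#' @param D per-cell bottleneck survival probability, in (0, 1).
#' @return A `rate_result` (fixations per hour).
#' @export
fixation_rate_general <- function(tau, mu, N_star, omega, D) {
  stopifnot(tau > 0, mu >= 0, N_star > 0, omega > 0, D > 0, D < 1)
  g <- mu * N_star * omega / (1 + omega) * log(D)^2 / (1 / D - 1) / tau
  params <- core_params(r = log(1 / D) / tau, mu = mu, N = N_star,
                        omega = omega, D = D, tau = tau)
  rate_result(g, "approximation", params)
}

#' Optimal bottleneck survival probability at fixed growth period
#'
#' Maximizes the D-dependent factor `(ln D)^2 / (1/D - 1)` of
#' [fixation_rate_general] over `D` (bounded scalar search on the `ln D`
#' scale), treating the equilibrium population size as independent of `D`.
#' The optimum is the root of `2(e^x - 1) = x e^x` with `x = ln(1/D)`,
#' `D* ~ 0.2032` -- a dilution ratio of about 5:1 -- independent of `tau`.
#'
#' @param tau growth-period length (hours); affects the attained rate but
#'   not the argmax.
#' @param mu,N_star,omega passed to [fixation_rate_general]; defaults give
#'   the rate scale of the standard parameter set.
#' @return A list with `D_star`, `ratio` (`1/D_star`), and `gamma_star`
#'   (the attained rate, fixations per hour).
#' @examples
#' optimal_D_fixed_tau(24)$ratio  # ~ 4.92, i.e. ~5:1
#' @export
optimal_D_fixed_tau <- function(tau = 24, mu = 1e-9, N_star = 1e9,
                                omega = 0.1) {
  obj <- function(lD) {
    fixation_rate_general(tau, mu, N_star, omega, exp(lD))$gamma
  }
  op <- stats::optimize(obj, c(log(1e-6), log(1 - 1e-6)), maximum = TRUE,
                        tol = 1e-12)
  if (!is.finite(op$objective)) stop("optimization over D failed to converge")
  D_star <- exp(op$maximum)
  list(D_star = D_star, ratio = 1 / D_star, gamma_star = op$objective)
}
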
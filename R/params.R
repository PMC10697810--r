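#' Core parameters of the exponential-growth serial-passage model
#'
#' Bundles the parameters of the resource-unconstrained model: a clonal
#' wild-type population grows exponentially at rate `r` for `tau` hours up to
#' `N` cells, then each cell independently survives a transfer bottleneck
#' with probability `D`. Beneficial mutations arise at cell divisions with
#' probability `mu`, with selective effects drawn from an exponential
#' distribution with mean `omega` (a mutant grows at rate `r(1+s)`).
#'
#' By default `tau` is coupled to the bottleneck by the stable-population
#' constraint `D = exp(-r tau)`, so the population returns to `D N` after
#' each transfer. Supplying `tau` explicitly with `stable = FALSE` decouples
#' the two (used by the resource-explicit machinery, where `r` is the
#' average growth rate).
#'
#' @param r maximum wild-type growth rate (per hour), > 0.
#' @param mu beneficial mutation probability per cell division, >= 0.
#' @param N maximum (pre-bottleneck) wild-type population size (cells), > 0.
#' @param omega mean selective effect of beneficial mutations, > 0.
#' @param D per-cell bottleneck survival probability, in (0, 1). The
#'   dilution ratio of laboratory usage is `1/D` (100:1 passaging is
#'   `D = 0.01`).
#' @param tau growth-period length (hours). Defaults to `log(1/D)/r`, the
#'   value implied by the stable-population constraint.
#' @param stable enforce `D = exp(-r tau)` (relative tolerance 1e-12)?
#' @return An object of class `core_params`.
#' @examples
#' p <- core_params(r = 1, mu = 1e-9, N = 1e9, omega = 0.1, D = 0.1)
#' p$tau  # log(10)
#' @export
core_params <- function(r = 1, mu = 1e-9, N = 1e9, omega = 0.1, D = 0.1,
                        tau = NULL, stable = TRUE) {
  stopifnot(r > 0, mu >= 0, N > 0, omega > 0)
  if (D <= 0 || D >= 1) {
    stop("D must lie strictly inside (0, 1); treat continuous culture (D -> 1) as an analytic limit")
  }
  if (is.null(tau)) tau <- log(1 / D) / r
  stopifnot(tau > 0)
  if (stable && abs(D - exp(-r * tau)) > 1e-12 * D) {
    stop("stable-population constraint violated: D must equal exp(-r * tau)")
  }
  structure(list(r = r, mu = mu, N = N, omega = omega, D = D, tau = tau,
                 stable = stable),
            class = "core_params")
}

#' @export
print.core_params <- function(x, ...) {
  cat(sprintf(
    "serial-passage parameters: r = %g /h, mu = %g, N = %g, omega = %g, D = %g (%.3g:1), tau = %g h\n",
    x$r, x$mu, x$N, x$omega, x$D, 1 / x$D, x$tau))
  invisible(x)
}

#' Context of a single beneficial mutation
#'
#' A mutation of selective effect `s` arising at time `t` within a growth
#' phase founds a pure-birth lineage growing at rate `r(1+s)`. Its size
#' at the end of the phase is geometric with parameter
#' `beta = exp(-r (1 + s) (tau - t))`.
#'
#' @param s selective effect (>= 0; 0 is a neutral lineage).
#' @param t origin time within the growth phase, in `[0, tau)` hours.
#' @param core a [core_params] object supplying `r` and `tau`.
#' @return An object of class `mutation_context` with fields `s`, `t`,
#'   `beta`.
#' @export
mutation_context <- function(s, t, core) {
  stopifnot(inherits(core, "core_params"), s >= 0)
  if (t < 0 || t >= core$tau) stop("origin time t must lie in [0, tau)")
  beta <- exp(-core$r * (1 + s) * (core$tau - t))
  structure(list(s = s, t = t, beta = beta, r = core$r, tau = core$tau),
            class = "mutation_context")
}

#' Assumption triple selecting one of the eight model variants
#'
#' The adaptation rate can be computed under each combination of three
#' modelling choices that distinguish this model from the earlier
#' literature: the optimization metric (per unit time vs per transfer),
#' the growth law of mutant lineages (stochastic pure birth vs
#' deterministic exponential), and the bottleneck sampling law (binomial
#' thinning vs the Poisson approximation). The triple
#' `(per_time, stochastic, binomial)` is the model advocated here; the
#' classical analyses were `(per_transfer, deterministic, poisson)`.
#'
#' @param metric `"per_time"` or `"per_transfer"`.
#' @param growth `"stochastic"` or `"deterministic"`.
#' @param sampling `"binomial"` or `"poisson"`.
#' @return An object of class `variant_spec`.
#' @export
variant_spec <- function(metric = c("per_time", "per_transfer"),
                         growth = c("stochastic", "deterministic"),
                         sampling = c("binomial", "poisson")) {
  structure(list(metric = match.arg(metric), growth = match.arg(growth),
                 sampling = match.arg(sampling)),
            class = "variant_spec")
}

#' @export
format.variant_spec <- function(x, ...) {
  paste(x$metric, x$growth, x$sampling, sep = "/")
}

#' @export
print.variant_spec <- function(x, ...) {
  cat("model variant:", format(x), "\n")
  invisible(x)
}

#' All eight model variants
#'
#' @return A list of the eight [variant_spec] combinations.
#' @export
all_variants <- function() {
  out <- list()
  for (m in c("per_time", "per_transfer"))
    for (g in c("stochastic", "deterministic"))
      for (sm in c("binomial", "poisson"))
        out[[length(out) + 1]] <- variant_spec(m, g, sm)
  out
}

#' Parameters of Monod resource-limited growth
#'
#' In the resource-explicit model the per-cell division rate is
#' `r_max R / (k + R)` where `R` is the concentration of a single
#' growth-limiting resource; every division consumes one resource unit.
#' Serial mode dilutes the culture by `D` into fresh media of concentration
#' `R0` every `tau` hours; chemostat mode exchanges media continuously at
#' per-hour rate `dilution_rate` (outflow removes cells and spent media,
#' inflow supplies fresh media).
#'
#' @param r_max maximum growth rate (per hour), > 0.
#' @param k half-saturation resource concentration, > 0.
#' @param R0 fresh-media resource concentration, > 0.
#' @param mode `"serial"` or `"chemostat"`.
#' @param dilution_rate chemostat outflow rate Phi (per hour); must satisfy
#'   `Phi < r_max R0 / (k + R0)` or the culture washes out.
#' @return An object of class `resource_params`.
#' @export
resource_params <- function(r_max = 3, k = 1e9, R0 = 1e9,
                            mode = c("serial", "chemostat"),
                            dilution_rate = NULL) {
  mode <- match.arg(mode)
  stopifnot(r_max > 0, k > 0, R0 > 0)
  if (mode == "chemostat") {
    if (is.null(dilution_rate) || dilution_rate <= 0) {
      stop("chemostat mode requires a positive dilution_rate")
    }
  }
  structure(list(r_max = r_max, k = k, R0 = R0, mode = mode,
                 dilution_rate = dilution_rate),
            class = "resource_params")
}

#' @export
print.resource_params <- function(x, ...) {
  cat(sprintf("Monod resource model: r_max = %g /h, k = %g, R0 = %g, mode = %s",
              x$r_max, x$k, x$R0, x$mode))
  if (x$mode == "chemostat") cat(sprintf(", Phi = %g /h", x$dilution_rate))
  cat("\n")
  invisible(x)
}

# Wrap an adaptation-rate value with its provenance.
rate_result <- function(gamma, method, params, variant = NULL) {
  stopifnot(gamma >= -1e-15)
  structure(list(gamma = max(0, gamma), method = method, params = params,
                 variant = variant),
            class = "rate_result")
}

#' @export
print.rate_result <- function(x, ...) {
  unit <- if (!is.null(x$variant) && x$variant$metric == "per_transfer")
    "fixations per transfer" else "fixations per hour"
  cat(sprintf("adaptation rate gamma = %.6g %s [%s%s]\n", x$gamma, unit,
              x$method,
              if (is.null(x$variant)) "" else paste0(", ", format(x$variant))))
  invisible(x)
}
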
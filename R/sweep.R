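# Orchestration: parameter sweeps over bottleneck regimes, the eight-variant
# comparison table, fixture generation and flat config parsing.

#' Specification of a simulation sweep over bottleneck regimes
#'
#' @param model `"exp"`, `"resource"`, `"chemostat"` or `"genotype"`.
#' @param D_grid bottleneck survival probabilities to scan (all in (0, 1));
#'   for the chemostat model the grid is interpreted through matched average
#'   growth: `Phi = r` and the `D` column is reported as 1.
#' @param tau_grid growth periods (hours), or `"coupled"` for
#'   `tau = log(1/D)/r`.
#' @param replicates replicates per grid point.
#' @param t_end simulated hours per replicate (exp/chemostat/genotype); for
#'   the resource model the number of measured cycles is `t_end/tau`,
#'   rounded up.
#' @param seed root seed; every grid point receives an independently derived
#'   seed, so results are reproducible from `(spec, seed)` alone.
#' @param r,mu,N,omega core model parameters.
#' @param resource a [resource_params] for the resource/chemostat models.
#' @return An object of class `sweep_spec`.
#' @export
sweep_spec <- function(model = c("exp", "resource", "chemostat", "genotype"),
                       D_grid, tau_grid = "coupled", replicates = 200,
                       t_end = 50, seed = 1, r = 1, mu = 1e-9, N = 1e9,
                       omega = 0.1, resource = NULL) {
  model <- match.arg(model)
  if (!length(D_grid)) stop("D_grid must be non-empty")
  if (any(D_grid <= 0) || any(D_grid >= 1)) stop("all D must lie in (0, 1)")
  if (!identical(tau_grid, "coupled")) {
    if (!length(tau_grid) || any(tau_grid <= 0)) {
      stop("tau_grid must be 'coupled' or positive values")
    }
  }
  if (model %in% c("resource", "chemostat") && is.null(resource)) {
    resource <- resource_params(mode = if (model == "chemostat") "chemostat"
                                       else "serial",
                                dilution_rate = if (model == "chemostat") r)
  }
  structure(list(model = model, D_grid = D_grid, tau_grid = tau_grid,
                 replicates = replicates, t_end = t_end, seed = seed, r = r,
                 mu = mu, N = N, omega = omega, resource = resource),
            class = "sweep_spec")
}

#' Run a sweep and tabulate simulated against theoretical adaptation rates
#'
#' Runs the requested simulator at every grid point and attaches the
#' matching theoretical rate: the closed-form exponential approximation for
#' the `exp` model, the general resource-constrained formula evaluated at
#' the measured equilibrium size `N*` for the `resource` model, and the
#' continuous-culture limit for the `chemostat` model. Failures at a grid
#' point are recorded in the `error` column and the sweep continues.
#'
#' @param spec a [sweep_spec].
#' @return A data frame of class `sweep_result` with columns `model`, `D`,
#'   `tau`, `gamma_hat`, `se`, `ci_lo`, `ci_hi` (mean +/- 1.96 se),
#'   `gamma_theory`, `n_star`, `n_established`, `error`, ordered by
#'   `(D, tau)`; the spec and seed are attached as attributes.
#' @export
run_sweep <- function(spec) {
  stopifnot(inherits(spec, "sweep_spec"))
  taus <- function(D) {
    if (identical(spec$tau_grid, "coupled")) log(1 / D) / spec$r
    else spec$tau_grid
  }
  grid <- do.call(rbind, lapply(sort(spec$D_grid), function(D) {
    data.frame(D = D, tau = taus(D))
  }))
  seeds <- derive_seeds(spec$seed, nrow(grid))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    D <- grid$D[i]; tau <- grid$tau[i]
    row <- data.frame(model = spec$model, D = D, tau = tau,
                      gamma_hat = NA_real_, se = NA_real_, ci_lo = NA_real_,
                      ci_hi = NA_real_, gamma_theory = NA_real_,
                      n_star = NA_real_, n_established = NA_integer_,
                      error = "")
    out <- tryCatch({
      if (spec$model == "exp") {
        core <- core_params(r = spec$r, mu = spec$mu, N = spec$N,
                            omega = spec$omega, D = D, tau = tau,
                            stable = abs(D - exp(-spec$r * tau)) < 1e-9 * D)
        res <- run_experiment(sim_config(core, t_end = spec$t_end,
                                         n_replicates = spec$replicates,
                                         seed = seeds[i]))
        row$gamma_hat <- res$gamma_hat; row$se <- res$se
        row$n_established <- res$n_established
        row$n_star <- spec$N
        row$gamma_theory <- fixation_rate_approx(core)$gamma
      } else if (spec$model == "resource") {
        res <- run_serial_resource(D, tau, spec$resource, mu = spec$mu,
                                   omega = spec$omega,
                                   n_cycles = ceiling(spec$t_end / tau),
                                   n_replicates = spec$replicates,
                                   seed = seeds[i])
        row$gamma_hat <- res$gamma_hat; row$se <- res$se
        row$n_established <- res$n_established
        row$n_star <- res$equilibrium$N_star
        row$gamma_theory <- fixation_rate_general(tau, spec$mu,
                                                  res$equilibrium$N_star,
                                                  spec$omega, D)$gamma
      } else if (spec$model == "chemostat") {
        res <- run_chemostat(spec$resource, mu = spec$mu, omega = spec$omega,
                             t_end = spec$t_end,
                             n_replicates = spec$replicates, seed = seeds[i])
        row$D <- NA_real_; row$tau <- NA_real_
        row$gamma_hat <- res$gamma_hat; row$se <- res$se
        row$n_established <- res$n_established
        row$n_star <- res$W_eq
        row$gamma_theory <- spec$resource$dilution_rate * spec$mu * res$W_eq *
          spec$omega / (1 + spec$omega)
      } else {
        env <- genotype_env(D, tau,
                            resource = spec$resource %||% resource_params())
        res <- run_genotype_experiment(genotype_config(omega = spec$omega,
                                                       mu = spec$mu),
                                       env, t_end = spec$t_end,
                                       n_replicates = spec$replicates,
                                       seed = seeds[i])
        row$gamma_hat <- res$establishments_per_hour
        row$n_established <- round(res$establishments_per_hour *
                                     spec$replicates * spec$t_end)
      }
      row
    }, error = function(e) { row$error <- conditionMessage(e); row })
    out
  })
  res <- do.call(rbind, rows)
  res$ci_lo <- res$gamma_hat - 1.96 * res$se
  res$ci_hi <- res$gamma_hat + 1.96 * res$se
  attr(res, "spec") <- spec
  class(res) <- c("sweep_result", "data.frame")
  res
}

#' Tabulate the adaptation rate under all eight model variants
#'
#' Evaluates [variant_rate] for every assumption triple over a grid of
#' bottleneck sizes (with `tau = log(1/D)/r` coupled), and reports each
#' variant's argmax-in-D over the grid.
#'
#' @param core a [core_params] object supplying `r`, `mu`, `N`, `omega`
#'   (its own `D` is ignored).
#' @param D_grid bottleneck survival probabilities.
#' @return A data frame with columns `D`, `tau`, `metric`, `growth`,
#'   `sampling`, `gamma`, `method`, ordered by variant then `D`; the per-
#'   variant argmax table is attached as `attr(, "argmax")`.
#' @export
compare_variants <- function(core, D_grid) {
  stopifnot(inherits(core, "core_params"))
  if (!length(D_grid)) stop("D_grid must be non-empty")
  rows <- list()
  argmax <- list()
  for (v in all_variants()) {
    g <- vapply(sort(D_grid), function(D) {
      p <- core_params(r = core$r, mu = core$mu, N = core$N,
                       omega = core$omega, D = D)
      variant_rate(p, v)$gamma
    }, 0)
    Ds <- sort(D_grid)
    rows[[length(rows) + 1]] <- data.frame(
      D = Ds, tau = log(1 / Ds) / core$r, metric = v$metric,
      growth = v$growth, sampling = v$sampling, gamma = g,
      method = "variant_integral")
    argmax[[length(argmax) + 1]] <- data.frame(
      metric = v$metric, growth = v$growth, sampling = v$sampling,
      D_argmax = Ds[which.max(g)], gamma_max = max(g))
  }
  out <- do.call(rbind, rows)
  attr(out, "argmax") <- do.call(rbind, argmax)
  out
}

#' Generate small deterministic fixture runs
#'
#' Writes seeded, reduced-scale runs (small populations, inflated mutation
#' rates) as plain TSV files for regression testing: an example trajectory
#' of the exponential model, its established-lineage summary, and a small D
#' sweep. Doubles as the package's synthetic-data generator: given the same
#' seed the bytes are identical on every platform.
#'
#' @param seed root RNG seed.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths of the written files.
#' @export
make_fixtures <- function(seed = 0, dir = tempdir()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  core <- core_params(r = 1, mu = 2e-4, N = 1e4, omega = 0.1, D = 0.1)
  cfg <- sim_config(core, t_end = 10 * core$tau, n_replicates = 3,
                    seed = seed, record_trajectory = TRUE)
  res <- run_experiment(cfg)
  paths <- file.path(dir, c("fixture_trajectory.tsv", "fixture_summary.tsv",
                            "fixture_sweep.tsv"))
  utils::write.table(res$trajectory, paths[1], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(D = core$D, tau = core$tau, replicates = cfg$n_replicates,
               gamma_hat = res$gamma_hat, se = res$se,
               n_established = res$n_established,
               mean_fixed_s = if (res$n_established) mean(res$fixed_effects)
                              else NA_real_),
    paths[2], sep = "\t", quote = FALSE, row.names = FALSE)
  sw <- run_sweep(sweep_spec("exp", D_grid = c(0.1, 0.5), replicates = 3,
                             t_end = 12, seed = seed, r = 1, mu = 2e-4,
                             N = 1e4, omega = 0.1))
  utils::write.table(as.data.frame(sw), paths[3], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' Read a flat key-value configuration file
#'
#' Lines of the form `key = value` (or `key: value`); `#` starts a comment.
#' Values that parse as numbers are returned numeric.
#'
#' @param path file path.
#' @return A named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z_][A-Za-z0-9_.]*)\\s*[=:]\\s*(.*)$", ln))[[1]]
    if (length(m) != 3) stop("cannot parse config line: ", ln)
    val <- trimws(m[3])
    num <- suppressWarnings(as.numeric(val))
    out[[m[2]]] <- if (!is.na(num)) num else val
  }
  out
}
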
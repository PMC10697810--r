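#' Configuration of a resource-unconstrained serial-passage simulation
#'
#' @param core a [core_params] object.
#' @param t_end total simulated hours during which mutations may arise;
#'   must be at least one growth period. Lineages still segregating at
#'   `t_end` are followed (without new mutations) until they resolve, so the
#'   estimated rate refers to mutations *occurring* before `t_end` that are
#'   destined to fix.
#' @param n_replicates number of independent replicate runs.
#' @param seed root RNG seed; each replicate uses an independently derived
#'   seed.
#' @param exact_mode simulate every division as an individual Gillespie
#'   event (feasible only for small `N`; the default samples exact
#'   phase-level transition laws instead, which follow the same process).
#' @param establish_threshold_prob a lineage is classified as established
#'   (destined to fix) when its eventual extinction probability
#'   `V(0, s)^size`, evaluated at a phase start, drops below this cutoff.
#' @param effect_dist `"exponential"` draws selective effects from
#'   `Exp(mean = omega)`; `"fixed"` uses the single value `fixed_s`
#'   (point-mass effects, used for cross-model checks).
#' @param fixed_s selective effect used when `effect_dist = "fixed"`.
#' @param record_trajectory record per-phase population sizes (wild type
#'   and each lineage) in long format.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(core, t_end = 50, n_replicates = 200, seed = 1,
                       exact_mode = FALSE, establish_threshold_prob = 1e-6,
                       effect_dist = c("exponential", "fixed"),
                       fixed_s = NULL, record_trajectory = FALSE) {
  stopifnot(inherits(core, "core_params"), n_replicates >= 1,
            establish_threshold_prob > 0, establish_threshold_prob < 1)
  if (t_end < core$tau) stop("t_end must cover at least one growth period")
  effect_dist <- match.arg(effect_dist)
  if (effect_dist == "fixed" && (is.null(fixed_s) || fixed_s <= 0)) {
    stop("effect_dist = \"fixed\" requires a positive fixed_s")
  }
  structure(list(core = core, t_end = t_end, n_replicates = n_replicates,
                 seed = seed, exact_mode = exact_mode,
                 establish_threshold_prob = establish_threshold_prob,
                 effect_dist = effect_dist, fixed_s = fixed_s,
                 record_trajectory = record_trajectory),
            class = "sim_config")
}

#' Initial population state
#'
#' @param wt wild-type cell count at a phase start.
#' @param time current simulation time (hours).
#' @return An object of class `population_state` with an empty lineage set.
#' @export
new_population <- function(wt, time = 0) {
  stopifnot(wt >= 0)
  structure(list(time = time, wt = wt,
                 lin = list(id = integer(0), s = numeric(0),
                            t_origin = numeric(0), size = numeric(0)),
                 next_id = 1L),
            class = "population_state")
}

#' Seed a mutant lineage into a population state
#'
#' @param state a [new_population] state.
#' @param s selective effect of the seeded lineage.
#' @param size initial cell count.
#' @return The updated state.
#' @export
seed_lineage <- function(state, s, size = 1) {
  state$lin$id <- c(state$lin$id, state$next_id)
  state$lin$s <- c(state$lin$s, s)
  state$lin$t_origin <- c(state$lin$t_origin, state$time)
  state$lin$size <- c(state$lin$size, size)
  state$next_id <- state$next_id + 1L
  state
}

# Draw one selective effect under the configured distribution.
.draw_effects <- function(n, config) {
  if (config$effect_dist == "fixed") rep(config$fixed_s, n)
  else stats::rexp(n, 1 / config$core$omega)
}

#' Advance a population through one growth phase
#'
#' Grows the wild type and every mutant lineage for `duration` hours of
#' pure-birth growth (rates `r` and `r(1+s)`), spawning new single-cell
#' mutant lineages at wild-type divisions with probability `mu` per
#' division. By default each compartment is advanced by the exact
#' negative-binomial transition law of the pure-birth process and mutation
#' events arrive as a Poisson process proportional to the realized number of
#' wild-type divisions, with origin times distributed along the exponential
#' growth curve; `exact_mode` instead simulates every division event
#' individually (Gillespie), which is feasible for small populations and is
#' used to validate the default scheme.
#'
#' @param state a `population_state`.
#' @param core a [core_params] object.
#' @param duration hours to advance (default one growth period `tau`).
#' @param mutate allow new mutations during this phase?
#' @param exact_mode per-division event simulation (see [sim_config]).
#' @param config optional [sim_config] controlling the effect distribution;
#'   defaults to exponential effects with mean `core$omega`.
#' @return The updated `population_state`, `duration` hours later.
#' @export
run_growth_phase <- function(state, core, duration = core$tau, mutate = TRUE,
                             exact_mode = FALSE, config = NULL) {
  stopifnot(inherits(state, "population_state"), inherits(core, "core_params"))
  if (duration < 0) stop("duration must be nonnegative")
  if (duration == 0) return(state)
  if (is.null(config)) {
    config <- list(effect_dist = "exponential", core = core)
  }
  if (exact_mode) return(.growth_phase_gillespie(state, core, duration,
                                                 mutate, config))
  r <- core$r
  # existing lineages: exact pure-birth transition over the whole phase
  if (length(state$lin$size)) {
    state$lin$size <- rpurebirth(state$lin$size,
                                 exp(-r * (1 + state$lin$s) * duration))
  }
  w0 <- state$wt
  w1 <- if (w0 > 0) rpurebirth(w0, exp(-r * duration)) else 0
  if (mutate && core$mu > 0 && w1 > w0) {
    n_mut <- stats::rpois(1, core$mu * (w1 - w0))
    if (n_mut > 0) {
      tm <- sample_origin_times(n_mut, r, duration)
      s_new <- .draw_effects(n_mut, config)
      sz <- rpurebirth(rep(1, n_mut), exp(-r * (1 + s_new) * (duration - tm)))
      state$lin$id <- c(state$lin$id, seq(state$next_id, length.out = n_mut))
      state$lin$s <- c(state$lin$s, s_new)
      state$lin$t_origin <- c(state$lin$t_origin, state$time + tm)
      state$lin$size <- c(state$lin$size, sz)
      state$next_id <- state$next_id + n_mut
    }
  }
  state$wt <- w1
  state$time <- state$time + duration
  state
}

# Event-driven per-division simulation of one growth phase (small counts).
.growth_phase_gillespie <- function(state, core, duration, mutate, config) {
  r <- core$r
  t_rel <- 0
  repeat {
    rates <- c(r * state$wt,
               if (length(state$lin$size)) r * (1 + state$lin$s) * state$lin$size)
    total <- sum(rates)
    if (total <= 0) break
    t_rel <- t_rel + stats::rexp(1, total)
    if (t_rel >= duration) break
    which_c <- sample.int(length(rates), 1, prob = rates)
    if (which_c == 1) { # wild-type division
      if (mutate && core$mu > 0 && stats::runif(1) < core$mu) {
        s_new <- .draw_effects(1, config)
        state$lin$id <- c(state$lin$id, state$next_id)
        state$lin$s <- c(state$lin$s, s_new)
        state$lin$t_origin <- c(state$lin$t_origin, state$time + t_rel)
        state$lin$size <- c(state$lin$size, 1)
        state$next_id <- state$next_id + 1L
      } else {
        state$wt <- state$wt + 1
      }
    } else {
      k <- which_c - 1L
      state$lin$size[k] <- state$lin$size[k] + 1
    }
  }
  state$time <- state$time + duration
  state
}

#' Apply a transfer bottleneck
#'
#' Every compartment (wild type and each mutant lineage) is independently
#' thinned by a `Binomial(count, D)` draw: each cell survives the transfer
#' with probability `D`. Unlike the Poisson approximation of the earlier
#' literature, the post-bottleneck count can never exceed the
#' pre-bottleneck count.
#'
#' @param state a `population_state`.
#' @param D per-cell survival probability, in (0, 1).
#' @return The updated state.
#' @export
apply_bottleneck <- function(state, D) {
  stopifnot(inherits(state, "population_state"), D > 0, D < 1)
  if (state$wt > 0) state$wt <- rbinom_large(1, state$wt, D)
  n <- length(state$lin$size)
  if (n) {
    pos <- state$lin$size > 0
    if (any(pos)) {
      state$lin$size[pos] <- stats::rbinom(sum(pos),
                                           as.integer(state$lin$size[pos]), D)
    }
  }
  state
}

# Classify lineages at a phase start: drop extinct, extract established.
# Returns list(state, est = data.frame of established lineages).
.classify_lineages <- function(state, D, threshold) {
  n <- length(state$lin$size)
  if (!n) return(list(state = state, est = NULL))
  v0 <- vapply(state$lin$s, survival_initial, 0, D = D)
  established <- v0^state$lin$size < threshold
  est <- NULL
  if (any(established)) {
    est <- data.frame(id = state$lin$id[established],
                      s = state$lin$s[established],
                      t_origin = state$lin$t_origin[established],
                      size = state$lin$size[established])
  }
  keep <- state$lin$size > 0 & !established
  state$lin <- lapply(state$lin, function(x) x[keep])
  list(state = state, est = est)
}

#' Run the resource-unconstrained serial-passage experiment
#'
#' Alternates [run_growth_phase] and [apply_bottleneck] for
#' `config$t_end` hours per replicate, classifying each mutant lineage at
#' phase starts as established (eventual extinction probability below the
#' configured cutoff), still segregating, or extinct. After `t_end`,
#' phases continue without new mutations until all segregating lineages
#' resolve, so every counted establishment stems from a mutation arising
#' within the measurement window. The adaptation-rate estimate is
#' `gamma_hat = mean(established per replicate) / t_end`.
#'
#' @param config a [sim_config].
#' @return An object of class `sim_result` with fields `gamma_hat`, `se`
#'   (standard error across replicates), `n_established`, `fixed_effects`,
#'   `origin_phases` (origin times within their growth phase),
#'   `per_replicate` (data frame), `trajectory` (long-format data frame or
#'   `NULL`), and `config`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  core <- config$core
  seeds <- derive_seeds(config$seed, config$n_replicates)
  per_rep <- vector("list", config$n_replicates)
  traj <- if (config$record_trajectory) vector("list", config$n_replicates)
  max_phases <- ceiling(config$t_end / core$tau) + 1000L
  for (rep_i in seq_len(config$n_replicates)) {
    set.seed(seeds[rep_i])
    state <- new_population(wt = round(core$D * core$N))
    est_all <- NULL
    rows <- NULL
    phase <- 0L
    repeat {
      phase <- phase + 1L
      cls <- .classify_lineages(state, core$D, config$establish_threshold_prob)
      state <- cls$state
      if (!is.null(cls$est)) est_all <- rbind(est_all, cls$est)
      mutating <- state$time < config$t_end
      if (!mutating && length(state$lin$size) == 0) break
      if (phase > max_phases) break # unresolved stragglers stay segregating
      state <- run_growth_phase(state, core, mutate = mutating,
                                exact_mode = config$exact_mode,
                                config = config)
      if (config$record_trajectory) {
        rows <- rbind(rows, .trajectory_rows(state, rep_i))
      }
      state <- apply_bottleneck(state, core$D)
    }
    n_est <- if (is.null(est_all)) 0L else nrow(est_all)
    per_rep[[rep_i]] <- list(n_established = n_est, est = est_all)
    if (config$record_trajectory) traj[[rep_i]] <- rows
  }
  counts <- vapply(per_rep, `[[`, 0, "n_established")
  est <- do.call(rbind, lapply(per_rep, `[[`, "est"))
  gamma_rep <- counts / config$t_end
  structure(list(
    gamma_hat = mean(gamma_rep),
    se = if (config$n_replicates > 1) stats::sd(gamma_rep) / sqrt(config$n_replicates) else NA_real_,
    n_established = sum(counts),
    fixed_effects = if (is.null(est)) numeric(0) else est$s,
    origin_phases = if (is.null(est)) numeric(0) else est$t_origin %% core$tau,
    per_replicate = data.frame(replicate = seq_along(counts),
                               n_established = counts,
                               gamma = gamma_rep),
    trajectory = if (config$record_trajectory) do.call(rbind, traj) else NULL,
    config = config), class = "sim_result")
}

.trajectory_rows <- function(state, rep_i) {
  n <- length(state$lin$size)
  data.frame(replicate = rep_i, time = state$time,
             compartment = c("wt", if (n) paste0("mut", state$lin$id)),
             type = c("wt", rep("mutant", n)),
             s = c(NA_real_, state$lin$s),
             count = c(state$wt, state$lin$size))
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf(
    "serial-passage simulation: %d replicates, %g h each\n  gamma_hat = %.4g +/- %.2g fixations/h (%d established lineages)\n",
    x$config$n_replicates, x$config$t_end, x$gamma_hat, x$se, x$n_established))
  invisible(x)
}

#' Summaries of mutations destined to fix
#'
#' Mean selective effect of established mutations, its ratio to the mean
#' effect `omega` of all arising mutations (theory: approximately 2), and a
#' Kolmogorov-Smirnov comparison of within-phase origin times against
#' Uniform(0, tau) (theory: approximately uniform, because the rising
#' mutation supply and the falling survival probability nearly cancel).
#'
#' @param result a `sim_result` from [run_experiment] with at least one
#'   established mutation.
#' @param omega mean selective effect of arising mutations; defaults to the
#'   simulated one.
#' @return A list with `mean_fixed_s`, `ratio_to_omega`, `ks_distance`,
#'   `ks_p_value`, and `n`.
#' @export
fixed_mutation_stats <- function(result, omega = result$config$core$omega) {
  stopifnot(inherits(result, "sim_result"))
  s <- result$fixed_effects
  if (!length(s)) stop("no established mutations recorded")
  ks <- suppressWarnings(
    stats::ks.test(result$origin_phases, "punif", 0, result$config$core$tau))
  list(mean_fixed_s = mean(s), ratio_to_omega = mean(s) / omega,
       ks_distance = unname(ks$statistic), ks_p_value = ks$p.value,
       n = length(s))
}
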
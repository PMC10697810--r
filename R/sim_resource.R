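# Resource-explicit growth: Monod-limited divisions consuming one unit of a
# single resource each, serial transfer into fresh media, and a true
# chemostat with continuous media exchange.
#
# Within a growth phase the wild-type count W and the resource R satisfy
# W + R = C exactly (every division consumes one unit), so the deterministic
# bulk dynamics reduce to one dimension with an implicit closed form:
#   r_max t = a ln(W/W0) + b ln((C - W0)/(C - W)),
#   a = (k + C)/C, b = k/C.
# The package uses this closed form for the large wild-type population and
# samples mutant lineages exactly: conditional on the wild-type curve, a
# lineage with effect s grows as a pure-birth process whose integrated
# per-capita rate over any interval is (1 + s) ln(W(t1)/W(t0)), giving a
# negative-binomial transition (time-change property). A fully stochastic
# stepping mode (step_kinetics) is kept for small populations and for the
# resource-conservation checks.

# ---- deterministic within-phase solution -----------------------------------

# time at which the deterministic wild-type count reaches W (hours)
.monod_time_at <- function(W, W0, C, k, r_max) {
  a <- (k + C) / C
  b <- k / C
  (a * log(W / W0) + b * log((C - W0) / (C - W))) / r_max
}

# wild-type count after `t` hours (inverse of .monod_time_at, monotone)
.monod_W_at <- function(t, W0, C, k, r_max) {
  if (t <= 0) return(W0)
  upper <- C - 1e-9 * C
  if (.monod_time_at(upper, W0, C, k, r_max) <= t) return(upper)
  stats::uniroot(function(W) .monod_time_at(W, W0, C, k, r_max) - t,
                 c(W0, upper), tol = 1e-10 * C)$root
}

#' Serial-transfer equilibrium of the Monod model
#'
#' Iterates the deterministic cycle map (grow for `tau` hours under Monod
#' kinetics, transfer a fraction `D` of the culture into fresh media) to its
#' fixed point, yielding the equilibrium pre-bottleneck population size `N*`
#' and the average growth rate `rbar = ln(1/D)/tau`.
#'
#' @param D per-cell transfer survival probability, in (0, 1).
#' @param tau growth-period length (hours).
#' @param resource a [resource_params] object (serial mode).
#' @param transfer resource carry-over at transfer: `"mix"` keeps a fraction
#'   `D` of the spent media (`R <- D R_end + (1 - D) R0`), `"replace"` uses
#'   entirely fresh media (`R <- R0`). The two differ negligibly when the
#'   resource is depleted at transfer.
#' @param N0 starting population size for the iteration.
#' @return A list of class `equilibrium_summary`: `N_star`, `W0`
#'   (post-transfer population), `R_start`, `R_end`, `C` (`W0 + R_start`),
#'   `r_bar`, `burn_in_cycles` (cycles needed to converge to relative
#'   1e-10), and `extinct` (TRUE if the map collapses to zero).
#' @export
serial_equilibrium <- function(D, tau, resource, transfer = c("mix", "replace"),
                               N0 = resource$R0) {
  stopifnot(inherits(resource, "resource_params"), D > 0, D < 1, tau > 0)
  transfer <- match.arg(transfer)
  k <- resource$k; r_max <- resource$r_max; R0 <- resource$R0
  W_end <- N0
  R_end <- 0
  for (cycle in 1:500) {
    W0 <- D * W_end
    R_start <- if (transfer == "mix") D * R_end + (1 - D) * R0 else R0
    C <- W0 + R_start
    if (W0 < 1) {
      return(structure(list(N_star = 0, W0 = 0, R_start = R_start,
                            R_end = R_start, C = C, r_bar = NA_real_,
                            burn_in_cycles = cycle, extinct = TRUE),
                       class = "equilibrium_summary"))
    }
    W_new <- .monod_W_at(tau, W0, C, k, r_max)
    converged <- abs(W_new - W_end) <= 1e-10 * W_new && cycle > 1
    W_end <- W_new
    R_end <- C - W_end
    if (converged) break
  }
  structure(list(N_star = W_end, W0 = D * W_end, R_start = R_start,
                 R_end = R_end, C = C, r_bar = log(W_end / (D * W_end)) / tau,
                 burn_in_cycles = cycle, extinct = FALSE),
            class = "equilibrium_summary")
}

#' @export
print.equilibrium_summary <- function(x, ...) {
  if (x$extinct) cat("serial-transfer equilibrium: population extinct\n")
  else cat(sprintf(
    "serial-transfer equilibrium: N* = %.4g cells, rbar = %.4g /h (converged in %d cycles)\n",
    x$N_star, x$r_bar, x$burn_in_cycles))
  invisible(x)
}

# ---- stochastic stepping (small populations, conservation checks) ----------

#' Initial state for stochastic resource-explicit simulation
#'
#' @param wt wild-type cell count.
#' @param R resource level (units; one unit is consumed per division).
#' @param time simulation time (hours).
#' @return A `resource_state` list; `divisions` accumulates every division
#'   so resource conservation can be asserted exactly.
#' @export
new_resource_state <- function(wt, R, time = 0) {
  stopifnot(wt >= 0, R >= 0)
  structure(list(time = time, wt = wt, R = R, divisions = 0,
                 lin = list(id = integer(0), s = numeric(0),
                            t_origin = numeric(0), size = numeric(0)),
                 next_id = 1L),
            class = "resource_state")
}

#' One stochastic step of Monod-limited growth
#'
#' Advances the population by an adaptively chosen time step: the per-cell
#' division rate is `r_max R / (k + R)` (times `1 + s` for mutants),
#' division counts are Poisson within the step, every division consumes one
#' resource unit, and divisions halt when the resource is exhausted (the
#' step never drives `R` negative: if the drawn divisions exceed the
#' remaining resource, exactly `R` of them are kept, allocated
#' hypergeometrically across compartments).
#'
#' @param state a [new_resource_state].
#' @param resource a [resource_params] object.
#' @param t_stop do not step past this time (e.g. the end of the growth
#'   phase).
#' @param mu mutation probability per wild-type division (new single-cell
#'   lineages; set 0 to disable).
#' @param omega mean selective effect for newly arising mutations.
#' @param step_frac accuracy control: the expected resource consumption per
#'   step is capped at `step_frac * R` and the expected per-cell growth at
#'   `step_frac` (a small batch floor keeps the depletion tail finite).
#' @return The updated state.
#' @export
step_kinetics <- function(state, resource, t_stop, mu = 0, omega = 0.1,
                          step_frac = 0.02) {
  stopifnot(inherits(state, "resource_state"),
            inherits(resource, "resource_params"))
  if (state$time >= t_stop) return(state)
  R <- state$R
  m <- if (R > 0) resource$r_max * R / (resource$k + R) else 0
  sizes <- state$lin$size
  eff <- 1 + state$lin$s
  prop <- m * (state$wt + sum(sizes * eff))
  if (m <= 0 || prop <= 0 || R < 1) { # starved or empty: idle to t_stop
    state$time <- t_stop
    return(state)
  }
  batch <- max(step_frac * R, 25)
  dt <- min(t_stop - state$time, batch / prop, step_frac / (m * max(eff, 1)))
  d_wt <- stats::rpois(1, state$wt * m * dt)
  d_lin <- if (length(sizes)) stats::rpois(length(sizes), sizes * eff * m * dt)
           else integer(0)
  d <- c(d_wt, d_lin)
  total <- sum(d)
  if (total > R) { # keep exactly R divisions, hypergeometric allocation
    keep <- numeric(length(d))
    left <- R
    rest <- total
    for (i in seq_along(d)) {
      rest <- rest - d[i]
      keep[i] <- stats::rhyper(1, d[i], rest, left)
      left <- left - keep[i]
    }
    d <- keep
    total <- R
  }
  n_mut <- if (mu > 0 && d[1] > 0) stats::rbinom(1, d[1], min(1, mu)) else 0
  state$wt <- state$wt + d[1] - n_mut
  if (length(sizes)) state$lin$size <- sizes + d[-1]
  if (n_mut > 0) {
    state$lin$id <- c(state$lin$id, seq(state$next_id, length.out = n_mut))
    state$lin$s <- c(state$lin$s, stats::rexp(n_mut, 1 / omega))
    state$lin$t_origin <- c(state$lin$t_origin,
                            rep(state$time + dt / 2, n_mut))
    state$lin$size <- c(state$lin$size, rep(1, n_mut))
    state$next_id <- state$next_id + n_mut
  }
  state$R <- R - total
  state$divisions <- state$divisions + total
  state$time <- state$time + dt
  state
}

# one full stochastic growth phase
.resource_phase_stochastic <- function(state, resource, tau, mu, omega,
                                       step_frac = 0.02) {
  t_stop <- state$time + tau
  while (state$time < t_stop) {
    state <- step_kinetics(state, resource, t_stop, mu, omega, step_frac)
  }
  state
}

# ---- serial-transfer experiment --------------------------------------------

#' Run the resource-explicit serial-passage experiment
#'
#' Monod-limited growth for `tau` hours, then transfer: every compartment is
#' thinned by `Binomial(count, D)` and the resource is refreshed
#' (`D R_end + (1 - D) R0` under volumetric mixing). `D` and `tau` vary
#' independently here; the average realized growth rate is
#' `rbar = ln(1/D)/tau`.
#'
#' Two wild-type engines are available. `"deterministic"` (default for
#' populations above 1e6 cells, where wild-type noise is negligible)
#' computes the equilibrium wild-type/resource curve once from the
#' closed-form cycle solution and simulates only mutant lineages
#' stochastically -- exactly, via the time-changed pure-birth transition
#' law. `"stochastic"` steps everything through [step_kinetics] (small
#' populations; used to validate the deterministic engine and the resource
#' conservation identity). Establishment uses the same extinction-probability
#' cutoff as [run_experiment], with the average-growth-rate theory supplying
#' `V(0, s)`.
#'
#' @param D per-cell transfer survival probability.
#' @param tau growth period (hours).
#' @param resource a [resource_params] (serial mode).
#' @param mu mutation probability per division.
#' @param omega mean selective effect.
#' @param n_cycles measured transfer cycles per replicate (after burn-in).
#' @param n_replicates independent replicates.
#' @param seed root RNG seed.
#' @param wt_mode `"auto"`, `"deterministic"` or `"stochastic"`.
#' @param transfer resource carry-over rule, see [serial_equilibrium].
#' @param burn_in burn-in transfer cycles before measuring (stochastic
#'   mode; the deterministic engine equilibrates by fixed-point iteration).
#' @param establish_threshold_prob extinction-probability cutoff defining
#'   establishment.
#' @param N0 initial population size.
#' @param step_frac stepping accuracy for the stochastic engine.
#' @return A list of class `resource_sim_result`: `gamma_hat`, `se`,
#'   `n_established`, `fixed_effects`, `origin_phases`, `per_replicate`,
#'   `equilibrium` (an `equilibrium_summary`), `extinct_fraction`, and the
#'   call parameters.
#' @export
run_serial_resource <- function(D, tau, resource, mu = 1e-9, omega = 0.1,
                                n_cycles = 20, n_replicates = 20, seed = 1,
                                wt_mode = c("auto", "deterministic",
                                            "stochastic"),
                                transfer = c("mix", "replace"), burn_in = 10,
                                establish_threshold_prob = 1e-6,
                                N0 = resource$R0, step_frac = 0.02) {
  stopifnot(inherits(resource, "resource_params"), D > 0, D < 1, tau > 0)
  wt_mode <- match.arg(wt_mode)
  transfer <- match.arg(transfer)
  if (wt_mode == "auto") {
    wt_mode <- if (D * N0 > 1e6) "deterministic" else "stochastic"
  }
  seeds <- derive_seeds(seed, n_replicates)
  t_meas <- n_cycles * tau
  eq <- serial_equilibrium(D, tau, resource, transfer, N0)
  if (wt_mode == "deterministic" && eq$extinct) {
    # extinction is a flagged outcome, not an exception
    return(structure(list(
      gamma_hat = NA_real_, se = NA_real_, n_established = 0L,
      fixed_effects = numeric(0), origin_phases = numeric(0),
      per_replicate = NULL, equilibrium = eq, extinct_fraction = 1,
      N_star_observed = 0, D = D, tau = tau, mu = mu, omega = omega,
      resource = resource, n_cycles = n_cycles,
      n_replicates = n_replicates, wt_mode = wt_mode),
      class = "resource_sim_result"))
  }
  runs <- vector("list", n_replicates)
  for (rep_i in seq_len(n_replicates)) {
    set.seed(seeds[rep_i])
    runs[[rep_i]] <- if (wt_mode == "deterministic") {
      .serial_resource_rep_det(eq, D, tau, resource, mu, omega, n_cycles,
                               establish_threshold_prob)
    } else {
      .serial_resource_rep_stoch(D, tau, resource, mu, omega, n_cycles,
                                 burn_in, establish_threshold_prob, N0,
                                 transfer, step_frac)
    }
  }
  counts <- vapply(runs, `[[`, 0, "n_established")
  extinct <- vapply(runs, `[[`, TRUE, "extinct")
  est <- do.call(rbind, lapply(runs, `[[`, "est"))
  gamma_rep <- counts / t_meas
  structure(list(
    gamma_hat = if (all(extinct)) NA_real_ else mean(gamma_rep),
    se = if (n_replicates > 1) stats::sd(gamma_rep) / sqrt(n_replicates) else NA_real_,
    n_established = sum(counts),
    fixed_effects = if (is.null(est)) numeric(0) else est$s,
    origin_phases = if (is.null(est)) numeric(0) else est$t_origin %% tau,
    per_replicate = data.frame(replicate = seq_along(counts),
                               n_established = counts, gamma = gamma_rep,
                               extinct = extinct),
    equilibrium = eq,
    extinct_fraction = mean(extinct),
    N_star_observed = mean(vapply(runs, `[[`, 0, "N_star_obs")),
    D = D, tau = tau, mu = mu, omega = omega, resource = resource,
    n_cycles = n_cycles, n_replicates = n_replicates, wt_mode = wt_mode),
    class = "resource_sim_result")
}

#' @export
print.resource_sim_result <- function(x, ...) {
  cat(sprintf(
    "resource-explicit serial passage (D = %g, tau = %g h, %s wild type):\n  gamma_hat = %.4g +/- %.2g fixations/h, N* = %.4g, %d established\n",
    x$D, x$tau, x$wt_mode, x$gamma_hat, x$se, x$equilibrium$N_star,
    x$n_established))
  invisible(x)
}

# deterministic wild-type engine: lineages ride the equilibrium growth curve
.serial_resource_rep_det <- function(eq, D, tau, resource, mu, omega,
                                     n_cycles, thr) {
  W0 <- eq$W0; N_star <- eq$N_star
  B <- N_star - W0 # divisions per cycle
  sz <- numeric(0); ss <- numeric(0); tor <- numeric(0)
  est <- NULL
  n_est <- 0L
  cycle <- 0L
  repeat {
    cycle <- cycle + 1L
    # classify at the phase start
    if (length(sz)) {
      v0 <- vapply(ss, survival_initial, 0, D = D)
      e <- v0^sz < thr
      if (any(e)) {
        n_est <- n_est + sum(e)
        est <- rbind(est, data.frame(s = ss[e], t_origin = tor[e]))
      }
      keep <- sz > 0 & !e
      sz <- sz[keep]; ss <- ss[keep]; tor <- tor[keep]
    }
    mutating <- cycle <= n_cycles
    if (!mutating && !length(sz)) break
    if (cycle > n_cycles + 1000L) break
    # existing lineages: exact full-phase growth factor D^(1+s)
    if (length(sz)) sz <- rpurebirth(sz, D^(1 + ss))
    if (mutating && mu > 0) {
      n_mut <- stats::rpois(1, mu * B)
      if (n_mut > 0) {
        s_new <- stats::rexp(n_mut, 1 / omega)
        Wu <- W0 + stats::runif(n_mut) * B # wild-type count at origin
        p_first <- (Wu / N_star)^(1 + s_new)
        sz_new <- rpurebirth(rep(1, n_mut), p_first)
        t_new <- (cycle - 1) * tau + vapply(Wu, .monod_time_at, 0, W0 = W0,
                                            C = eq$C, k = resource$k,
                                            r_max = resource$r_max)
        sz <- c(sz, sz_new); ss <- c(ss, s_new); tor <- c(tor, t_new)
      }
    }
    if (length(sz)) sz <- stats::rbinom(length(sz), as.integer(sz), D)
  }
  list(n_established = n_est, est = est, extinct = FALSE, N_star_obs = N_star)
}

# fully stochastic engine (small populations)
.serial_resource_rep_stoch <- function(D, tau, resource, mu, omega, n_cycles,
                                       burn_in, thr, N0, transfer, step_frac) {
  state <- new_resource_state(wt = round(D * N0), R = resource$R0)
  est <- NULL
  n_est <- 0L
  n_star_acc <- numeric(0)
  cycle <- 0L
  t0_meas <- NA_real_
  repeat {
    cycle <- cycle + 1L
    measuring <- cycle > burn_in
    mutating <- measuring && cycle <= burn_in + n_cycles
    if (measuring && is.na(t0_meas)) t0_meas <- state$time
    if (length(state$lin$size)) {
      v0 <- vapply(state$lin$s, survival_initial, 0, D = D)
      e <- v0^state$lin$size < thr
      if (any(e)) {
        n_est <- n_est + sum(e)
        est <- rbind(est, data.frame(s = state$lin$s[e],
                                     t_origin = state$lin$t_origin[e] - t0_meas))
      }
      keep <- state$lin$size > 0 & !e
      state$lin <- lapply(state$lin, function(x) x[keep])
    }
    if (cycle > burn_in + n_cycles && !length(state$lin$size)) break
    if (cycle > burn_in + n_cycles + 1000L) break
    if (state$wt == 0 && !length(state$lin$size)) {
      return(list(n_established = n_est, est = est, extinct = TRUE,
                  N_star_obs = 0))
    }
    state <- .resource_phase_stochastic(state, resource, tau,
                                        if (mutating) mu else 0, omega,
                                        step_frac)
    if (measuring) n_star_acc <- c(n_star_acc, state$wt)
    # transfer
    if (state$wt > 0) state$wt <- rbinom_large(1, state$wt, D)
    if (length(state$lin$size)) {
      state$lin$size <- stats::rbinom(length(state$lin$size),
                                      as.integer(state$lin$size), D)
    }
    state$R <- if (transfer == "mix") D * state$R + (1 - D) * resource$R0
               else resource$R0
  }
  list(n_established = n_est, est = est, extinct = state$wt == 0,
       N_star_obs = if (length(n_star_acc)) mean(n_star_acc) else NA_real_)
}

# ---- chemostat --------------------------------------------------------------

#' Run the continuous-culture (chemostat) experiment
#'
#' Constant-volume culture with media exchanged at per-hour rate `Phi =
#' dilution_rate`: cells wash out at per-capita rate `Phi`, fresh resource
#' flows in at `Phi R0`, spent media out at `Phi R`, and each division
#' consumes one resource unit. At equilibrium the Monod rate equals `Phi`,
#' so `R_eq = k Phi / (r_max - Phi)` and the population holds
#' `W_eq = R0 - R_eq` cells. The deterministic engine treats the bulk
#' culture as sitting at this equilibrium and simulates each mutant lineage
#' as an exact linear birth-death process (birth `Phi (1 + s)`, death
#' `Phi`); the stochastic engine steps the full system and is used for the
#' equilibrium invariants at small populations. Washout (`Phi` at or above
#' the maximum Monod rate, or population loss in stochastic mode) is
#' reported as a flag, not an error.
#'
#' @param resource a [resource_params] with `mode = "chemostat"`.
#' @param mu mutation probability per division.
#' @param omega mean selective effect.
#' @param t_end measured hours per replicate.
#' @param n_replicates independent replicates.
#' @param seed root RNG seed.
#' @param wt_mode `"deterministic"` (default) or `"stochastic"`.
#' @param establish_threshold_prob extinction-probability cutoff; a lineage
#'   of size `n` is established when `(1/(1+s))^n` falls below it.
#' @param N0 initial population for the stochastic engine.
#' @param burn_in_hours discarded before measuring (stochastic engine).
#' @param step_frac stepping accuracy (stochastic engine).
#' @return A list of class `chemostat_sim_result` with `gamma_hat`, `se`,
#'   `n_established`, `washout`, `R_eq`, `W_eq`, `per_replicate`, and for
#'   the stochastic engine the observed mean population and resource.
#' @export
run_chemostat <- function(resource, mu = 1e-9, omega = 0.1, t_end = 500,
                          n_replicates = 10, seed = 1,
                          wt_mode = c("deterministic", "stochastic"),
                          establish_threshold_prob = 1e-6, N0 = NULL,
                          burn_in_hours = NULL, step_frac = 0.02) {
  stopifnot(inherits(resource, "resource_params"),
            resource$mode == "chemostat")
  wt_mode <- match.arg(wt_mode)
  phi <- resource$dilution_rate
  max_rate <- resource$r_max * resource$R0 / (resource$k + resource$R0)
  if (phi >= max_rate) {
    return(structure(list(gamma_hat = 0, se = NA_real_, n_established = 0L,
                          washout = TRUE, R_eq = NA_real_, W_eq = 0,
                          per_replicate = NULL, resource = resource),
                     class = "chemostat_sim_result"))
  }
  R_eq <- resource$k * phi / (resource$r_max - phi)
  W_eq <- resource$R0 - R_eq
  seeds <- derive_seeds(seed, n_replicates)
  thr <- establish_threshold_prob
  if (wt_mode == "deterministic") {
    counts <- numeric(n_replicates)
    s_fix <- vector("list", n_replicates)
    for (rep_i in seq_len(n_replicates)) {
      set.seed(seeds[rep_i])
      n_mut <- stats::rpois(1, mu * phi * W_eq * t_end)
      s_new <- if (n_mut) stats::rexp(n_mut, 1 / omega) else numeric(0)
      fixed <- logical(n_mut)
      for (j in seq_len(n_mut)) {
        fixed[j] <- .chemostat_lineage_established(s_new[j], phi, thr)
      }
      counts[rep_i] <- sum(fixed)
      s_fix[[rep_i]] <- s_new[fixed]
    }
    obs <- NULL
  } else {
    if (is.null(N0)) N0 <- round(W_eq)
    if (is.null(burn_in_hours)) burn_in_hours <- 10 / phi
    runs <- lapply(seq_len(n_replicates), function(rep_i) {
      set.seed(seeds[rep_i])
      .chemostat_rep_stoch(resource, mu, omega, t_end, burn_in_hours, thr,
                           N0, step_frac)
    })
    counts <- vapply(runs, `[[`, 0, "n_established")
    s_fix <- lapply(runs, `[[`, "s_fixed")
    if (any(vapply(runs, `[[`, TRUE, "washout"))) {
      # population lost in at least one replicate
      obs <- list(washout_fraction = mean(vapply(runs, `[[`, TRUE, "washout")))
    } else obs <- NULL
    obs <- c(obs, list(
      mean_population = mean(vapply(runs, `[[`, 0, "mean_pop")),
      mean_resource = mean(vapply(runs, `[[`, 0, "mean_R"))))
  }
  gamma_rep <- counts / t_end
  structure(list(
    gamma_hat = mean(gamma_rep),
    se = if (n_replicates > 1) stats::sd(gamma_rep) / sqrt(n_replicates) else NA_real_,
    n_established = sum(counts),
    fixed_effects = unlist(s_fix),
    washout = FALSE, R_eq = R_eq, W_eq = W_eq, observed = obs,
    per_replicate = data.frame(replicate = seq_along(counts),
                               n_established = counts, gamma = gamma_rep),
    resource = resource, mu = mu, omega = omega, t_end = t_end,
    wt_mode = wt_mode), class = "chemostat_sim_result")
}

#' @export
print.chemostat_sim_result <- function(x, ...) {
  if (x$washout) {
    cat("chemostat: washout (dilution rate exceeds the maximum growth rate)\n")
  } else {
    cat(sprintf(
      "chemostat (Phi = %g /h): gamma_hat = %.4g +/- %.2g fixations/h (R_eq = %.4g, W_eq = %.4g)\n",
      x$resource$dilution_rate, x$gamma_hat, x$se, x$R_eq, x$W_eq))
  }
  invisible(x)
}

# Follow one mutant lineage (birth Phi (1+s), death Phi per capita) by its
# exact transition law until extinction or establishment.
.chemostat_lineage_established <- function(s, phi, thr) {
  if (s <= 0) return(FALSE)
  q1 <- 1 / (1 + s) # single-cell extinction probability
  n <- 1
  b <- phi * (1 + s)
  for (i in 1:100000) {
    if (n == 0) return(FALSE)
    if (q1^n < thr) return(TRUE)
    n <- rbirthdeath(n, b, phi, 1 / phi)
  }
  FALSE
}

# fully stochastic chemostat (small populations)
.chemostat_rep_stoch <- function(resource, mu, omega, t_end, burn_in, thr,
                                 N0, step_frac) {
  phi <- resource$dilution_rate
  state <- new_resource_state(wt = N0, R = resource$R0)
  horizon <- burn_in + t_end
  n_est <- 0L
  s_fixed <- numeric(0)
  pop_acc <- R_acc <- numeric(0)
  t_last_obs <- 0
  while (state$time < horizon + 200 / phi) {
    R <- state$R
    m <- if (R > 0) resource$r_max * R / (resource$k + R) else 0
    sizes <- state$lin$size
    eff <- 1 + state$lin$s
    pop <- state$wt + sum(sizes)
    if (pop == 0) {
      return(list(n_established = n_est, s_fixed = s_fixed, washout = TRUE,
                  mean_pop = 0, mean_R = mean(c(R_acc, R))))
    }
    dt <- min(step_frac / (m * max(eff, 1) + phi), horizon - state$time)
    dt <- max(dt, 1e-6)
    # births (resource-limited), then washout deaths, then media exchange
    d_wt <- if (state$wt > 0 && m > 0) stats::rpois(1, state$wt * m * dt) else 0
    d_lin <- if (length(sizes) && m > 0) stats::rpois(length(sizes),
                                                      sizes * eff * m * dt)
             else integer(0)
    total <- d_wt + sum(d_lin)
    if (total > floor(R)) { # resource cannot cover all drawn divisions
      scale <- floor(R) / total
      d_wt <- stats::rbinom(1, d_wt, scale)
      if (length(d_lin)) d_lin <- stats::rbinom(length(d_lin), d_lin, scale)
      total <- d_wt + sum(d_lin)
    }
    n_mut <- if (mu > 0 && d_wt > 0 && state$time >= burn_in &&
                 state$time < horizon) stats::rbinom(1, d_wt, min(1, mu)) else 0
    state$wt <- state$wt + d_wt - n_mut
    if (length(sizes)) state$lin$size <- sizes + d_lin
    if (n_mut > 0) {
      state$lin$id <- c(state$lin$id, seq(state$next_id, length.out = n_mut))
      state$lin$s <- c(state$lin$s, stats::rexp(n_mut, 1 / omega))
      state$lin$t_origin <- c(state$lin$t_origin, rep(state$time, n_mut))
      state$lin$size <- c(state$lin$size, rep(1, n_mut))
      state$next_id <- state$next_id + n_mut
    }
    p_die <- 1 - exp(-phi * dt)
    if (state$wt > 0) state$wt <- state$wt - rbinom_large(1, state$wt, p_die)
    if (length(state$lin$size)) {
      state$lin$size <- state$lin$size -
        stats::rbinom(length(state$lin$size), as.integer(state$lin$size), p_die)
    }
    state$R <- max(0, R - total + phi * (resource$R0 - R) * dt)
    state$divisions <- state$divisions + total
    state$time <- state$time + dt
    # classification and observation about once per hour
    if (state$time - t_last_obs >= 1) {
      t_last_obs <- state$time
      if (state$time >= burn_in && state$time < horizon) {
        pop_acc <- c(pop_acc, state$wt + sum(state$lin$size))
        R_acc <- c(R_acc, state$R)
      }
      if (length(state$lin$size)) {
        q1 <- 1 / (1 + state$lin$s)
        e <- q1^state$lin$size < thr & state$lin$t_origin < horizon
        if (any(e)) {
          n_est <- n_est + sum(e)
          s_fixed <- c(s_fixed, state$lin$s[e])
        }
        keep <- state$lin$size > 0 & !e
        state$lin <- lapply(state$lin, function(x) x[keep])
      }
      if (state$time >= horizon && !length(state$lin$size)) break
    }
  }
  list(n_established = n_est, s_fixed = s_fixed, washout = FALSE,
       mean_pop = mean(pop_acc), mean_R = mean(R_acc))
}
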
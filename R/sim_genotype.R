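# Multi-locus genotype model: beneficial mutations at a fixed small set of
# loci, multiple segregating mutations per genome, multiplicative fitness.
# Competing beneficial lineages interfere (clonal interference), slowing
# adaptation relative to the independent-lineages theory.

#' Configuration of the genotype-based (clonal interference) model
#'
#' @param n_loci number of beneficial loci (genotypes are subsets of mutated
#'   loci; no back mutation).
#' @param omega mean of the exponential distribution from which per-locus
#'   effects are drawn (once per run: quenched effects).
#' @param locus_effects optional fixed per-locus selective effects,
#'   overriding the exponential draw (length `n_loci`).
#' @param mu per-locus mutation probability per cell division.
#' @param fix_threshold mutant-allele frequency above which a locus counts
#'   as fixed.
#' @param establish_threshold_prob extinction-probability cutoff for the
#'   establishment metric (per-locus allele counts, same rule as
#'   [run_experiment]).
#' @return An object of class `genotype_config`.
#' @export
genotype_config <- function(n_loci = 10, omega = 0.1, locus_effects = NULL,
                            mu = 1e-9, fix_threshold = 0.99,
                            establish_threshold_prob = 1e-6) {
  stopifnot(n_loci >= 1, n_loci <= 16, omega > 0, mu >= 0,
            fix_threshold > 0, fix_threshold < 1)
  if (!is.null(locus_effects)) {
    stopifnot(length(locus_effects) == n_loci, all(locus_effects > 0))
  }
  structure(list(n_loci = as.integer(n_loci), omega = omega,
                 locus_effects = locus_effects, mu = mu,
                 fix_threshold = fix_threshold,
                 establish_threshold_prob = establish_threshold_prob),
            class = "genotype_config")
}

#' Serial-passage environment for the genotype model
#'
#' Two growth laws are available between the binomial `D` bottlenecks.
#' `"exponential"` grows every genotype at rate `r*prod(1+s_i)` for `tau`
#' hours; because adaptation raises mean fitness above the wild-type rate
#' that `D` balances, the population grows across cycles, so this law is
#' meant for short horizons and small mutation supply (it aborts if counts
#' overflow). `"resource"` (default) runs Monod resource-limited growth:
#' all genotypes share one resource pool (one unit per division, fresh media
#' at transfer), which bounds the population near `R0` and makes fitter
#' genotypes suppress others through faster resource consumption -- the
#' mechanism of clonal interference here.
#'
#' @param D per-cell transfer survival probability, in (0, 1).
#' @param tau growth period (hours); defaults to `log(1/D)/r` under the
#'   exponential law and must be given for the resource law.
#' @param growth `"resource"` or `"exponential"`.
#' @param r maximum wild-type growth rate (exponential law), per hour.
#' @param N0 initial (post-transfer) population size.
#' @param resource a [resource_params] for the resource law.
#' @param transfer resource carry-over rule, see [serial_equilibrium].
#' @return An object of class `genotype_env`.
#' @export
genotype_env <- function(D, tau = NULL,
                         growth = c("resource", "exponential"), r = 1,
                         N0 = NULL, resource = NULL,
                         transfer = c("mix", "replace")) {
  growth <- match.arg(growth)
  transfer <- match.arg(transfer)
  stopifnot(D > 0, D < 1)
  if (growth == "exponential") {
    if (is.null(tau)) tau <- log(1 / D) / r
    if (is.null(N0)) N0 <- 1e6
  } else {
    if (is.null(resource)) resource <- resource_params()
    if (is.null(tau)) stop("the resource law needs an explicit tau")
    if (is.null(N0)) N0 <- D * resource$R0
  }
  stopifnot(tau > 0, N0 >= 1)
  structure(list(D = D, tau = tau, growth = growth, r = r, N0 = N0,
                 resource = resource, transfer = transfer),
            class = "genotype_env")
}

#' Run the genotype-based serial-passage experiment
#'
#' Simulates genotype counts (indexed by locus bitmask) through alternating
#' growth phases and binomial bottlenecks. Growth of every genotype over a
#' phase is sampled from the exact pure-birth transition law, conditional on
#' the shared growth environment: under the resource law the integrated
#' Monod exposure of the phase is computed from the deterministic bulk
#' dynamics of the current genotype mix, so fitter genotypes deplete the
#' pool faster and shorten everyone's window -- clonal interference. Per-
#' locus mutations arise at divisions (at most one locus per division;
#' double mutations in one division have probability O(mu^2) and are
#' ignored), founding one cell of the derived genotype that grows for the
#' remainder of the phase. A locus is fixed when its allele frequency
#' exceeds the configured threshold, and established when its allele count
#' makes eventual loss improbable (same extinction-probability rule as the
#' single-lineage simulators, the metric comparable across models).
#'
#' @param gconfig a [genotype_config].
#' @param env a [genotype_env].
#' @param t_end simulated hours per replicate.
#' @param n_replicates independent replicates.
#' @param seed root RNG seed.
#' @return A list of class `genotype_sim_result`: `fixations_per_hour`,
#'   `establishments_per_hour`, `mean_fixed_s`, `locus_summary` (per
#'   replicate and locus: effect, fixation time or NA), `mean_fitness`
#'   (per-phase population mean fitness trajectory), and the inputs.
#' @export
run_genotype_experiment <- function(gconfig, env, t_end = 200,
                                    n_replicates = 10, seed = 1) {
  stopifnot(inherits(gconfig, "genotype_config"), inherits(env, "genotype_env"))
  seeds <- derive_seeds(seed, n_replicates)
  L <- gconfig$n_loci
  n_geno <- 2L^L
  # locus membership of every genotype bitmask
  member <- vapply(seq_len(L), function(l) {
    bitwAnd(seq_len(n_geno) - 1L, bitwShiftL(1L, l - 1L)) > 0L
  }, logical(n_geno))
  if (n_geno == 2) member <- matrix(member, ncol = L)
  runs <- vector("list", n_replicates)
  for (rep_i in seq_len(n_replicates)) {
    set.seed(seeds[rep_i])
    eff <- gconfig$locus_effects %||% stats::rexp(L, 1 / gconfig$omega)
    runs[[rep_i]] <- .genotype_rep(gconfig, env, t_end, eff, member)
  }
  fix_times <- do.call(rbind, lapply(seq_along(runs), function(i) {
    data.frame(replicate = i, locus = seq_len(L), s = runs[[i]]$eff,
               fixed_time = runs[[i]]$fix_time)
  }))
  n_fix <- sum(!is.na(fix_times$fixed_time))
  n_est <- sum(vapply(runs, `[[`, 0, "n_est"))
  structure(list(
    fixations_per_hour = n_fix / (n_replicates * t_end),
    establishments_per_hour = n_est / (n_replicates * t_end),
    mean_fixed_s = if (n_fix) mean(fix_times$s[!is.na(fix_times$fixed_time)])
                   else NA_real_,
    locus_summary = fix_times,
    mean_fitness = do.call(rbind, lapply(seq_along(runs), function(i) {
      cbind(replicate = i, runs[[i]]$fitness)
    })),
    gconfig = gconfig, env = env, t_end = t_end,
    n_replicates = n_replicates), class = "genotype_sim_result")
}

#' @export
print.genotype_sim_result <- function(x, ...) {
  cat(sprintf(
    "genotype model (%d loci, %s growth): %.4g locus fixations/h, %.4g establishments/h\n",
    x$gconfig$n_loci, x$env$growth, x$fixations_per_hour,
    x$establishments_per_hour))
  invisible(x)
}

# Integrated per-capita Monod exposure M = int r_max R/(k+R) dt over one
# phase, from the deterministic bulk dynamics of the current genotype mix
# (each class grows at fit_g times the shared Monod rate and consumes one
# resource unit per division).
.phase_exposure <- function(W, fit, R_start, tau, rp) {
  M <- 0
  t <- 0
  R <- R_start
  fmax <- max(fit)
  while (t < tau) {
    m <- if (R > 0) rp$r_max * R / (rp$k + R) else 0
    if (m <= 0 || R < 1) break
    cons_rate <- m * sum(W * fit)
    dt <- min(tau - t, 0.05 / (m * fmax), max(0.05 * R, 25) / cons_rate)
    growth <- W * fit * m * dt
    gtot <- sum(growth)
    if (gtot > R) { # consume exactly what remains
      dt <- dt * R / gtot
      growth <- growth * R / gtot
      gtot <- R
    }
    W <- W + growth
    R <- R - gtot
    M <- M + m * dt
    t <- t + dt
  }
  M
}

.genotype_rep <- function(gconfig, env, t_end, eff, member) {
  L <- gconfig$n_loci
  D <- env$D; tau <- env$tau
  mu <- gconfig$mu
  fit <- apply(member, 1, function(mm) prod(1 + eff[mm]))
  n_unmut <- rowSums(!member)
  counts <- numeric(2L^L)
  counts[1] <- round(env$N0)
  fix_time <- rep(NA_real_, L)
  est_flag <- rep(FALSE, L)
  n_phases <- ceiling(t_end / tau)
  fitness_rows <- vector("list", n_phases)
  v0 <- vapply(eff, survival_initial, 0, D = D)
  R <- if (env$growth == "resource") env$resource$R0 else Inf
  for (phase in seq_len(n_phases)) {
    live <- which(counts > 0)
    total0 <- sum(counts)
    if (total0 == 0) break
    # shared per-capita exposure of this phase (time-changed Yule clock)
    M <- if (env$growth == "exponential") env$r * tau
         else .phase_exposure(counts[live], fit[live], R, tau, env$resource)
    grown <- counts
    grown[live] <- rpurebirth(counts[live], exp(-fit[live] * M))
    if (env$growth == "exponential" && sum(grown) > 1e12) {
      stop("genotype counts overflowed under the exponential law; use the resource law, a smaller N0 or a shorter t_end")
    }
    divisions <- grown - counts
    if (is.finite(R)) R <- max(0, R - sum(divisions))
    # mutations: at most one new locus per division
    mutable <- live[n_unmut[live] > 0 & divisions[live] > 0]
    for (g in mutable) {
      n_mut <- rbinom_large(1, divisions[g], min(1, mu * n_unmut[g]))
      if (n_mut == 0) next
      free <- which(!member[g, ])
      loci <- if (length(free) == 1) rep(free, n_mut)
              else sample(free, n_mut, replace = TRUE)
      # origin drawn along the genotype's growth curve, in exposure units
      u <- stats::runif(n_mut)
      M_at <- log(1 + u * expm1(fit[g] * M)) / fit[g]
      for (j in seq_len(n_mut)) {
        tgt <- g + bitwShiftL(1L, loci[j] - 1L)
        sz <- rpurebirth(1, exp(-fit[tgt] * (M - M_at[j])))
        grown[tgt] <- grown[tgt] + sz
        grown[g] <- max(0, grown[g] - 1) # the daughter left the parent class
      }
    }
    counts <- grown
    # bottleneck and media transfer
    live <- which(counts > 0)
    counts[live] <- rbinom_large(length(live), counts[live], D)
    if (is.finite(R)) {
      R <- if (env$transfer == "mix") D * R + (1 - D) * env$resource$R0
           else env$resource$R0
    }
    total <- sum(counts)
    if (total == 0) break
    allele <- colSums(counts * member)
    freq <- allele / total
    newly_fixed <- is.na(fix_time) & freq >= gconfig$fix_threshold
    fix_time[newly_fixed] <- phase * tau
    est_flag <- est_flag | (v0^allele < gconfig$establish_threshold_prob)
    fitness_rows[[phase]] <- data.frame(time = phase * tau,
                                        mean_fitness = sum(counts * fit) / total,
                                        population = total)
  }
  list(eff = eff, fix_time = fix_time, n_est = sum(est_flag),
       fitness = do.call(rbind, fitness_rows))
}
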
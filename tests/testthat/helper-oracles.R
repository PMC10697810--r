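# Independent oracles used across the suite. These deliberately avoid the
# package's sampling shortcuts: growth is simulated cell by cell.

# One pure-birth lineage simulated per cell-division event.
sim_yule_percell <- function(lambda, u) {
  n <- 1
  t <- 0
  repeat {
    t <- t + stats::rexp(1, n * lambda)
    if (t > u) return(n)
    n <- n + 1
  }
}

# Per-cell branching simulation of one mutant lineage through repeated
# growth phases and binomial bottlenecks; returns TRUE if the lineage
# reaches `cap` cells at a phase start (survival), FALSE on extinction.
# `t0` is the origin time within the first phase.
sim_lineage_percell <- function(s, D, r, tau, t0 = 0, cap = 100) {
  n <- 1
  rate <- r * (1 + s)
  remaining <- tau - t0
  repeat {
    # grow for `remaining` hours, event by event
    t <- 0
    repeat {
      t <- t + stats::rexp(1, n * rate)
      if (t > remaining) break
      n <- n + 1
    }
    n <- stats::rbinom(1, n, D)
    if (n == 0) return(FALSE)
    if (n >= cap) return(TRUE)
    remaining <- tau
  }
}

# Truncated double sum for the bottleneck transition probabilities
# (geometric growth law compounded with binomial thinning), Eq-style oracle
# for the closed form.
bottleneck_pmf_bruteforce <- function(beta, D, i, j_max = 500) {
  j <- seq_len(j_max)
  sum(beta * (1 - beta)^(j - 1) * stats::dbinom(i, j, D))
}

# Establishment frequency of a single lineage seeded at a phase start,
# using the package's own machinery (exercises the default growth engine).
establishment_freq <- function(s, D, n_rep, r = 1, threshold = 1e-6,
                               seed = 1) {
  core <- core_params(r = r, mu = 0, N = 1e6, omega = 0.1, D = D)
  v0 <- survival_initial(s, D)
  set.seed(seed)
  hits <- vapply(seq_len(n_rep), function(i) {
    st <- new_population(wt = 0)
    st <- seed_lineage(st, s = s, size = 1)
    repeat {
      st <- run_growth_phase(st, core, mutate = FALSE)
      st <- apply_bottleneck(st, D)
      sz <- st$lin$size
      if (sz == 0) return(FALSE)
      if (v0^sz < threshold) return(TRUE)
    }
  }, logical(1))
  mean(hits)
}
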
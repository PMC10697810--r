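# Closed-form theory: growth law, bottleneck transition, survival
# probabilities, adaptation rates, effective population size, optimal D.

test_that("Yule pmf matches the geometric law and normalizes", {
  expect_equal(yule_size_pmf(1, 0, 1), 1)
  expect_equal(yule_size_pmf(1, log(2), 1), 0.5)
  expect_equal(yule_size_pmf(1, log(2), 2), 0.25)
  expect_equal(sum(yule_size_pmf(1, 1, 1:2000)), 1, tolerance = 1e-9)
  expect_error(yule_size_pmf(1, 1, 0), "support")
  expect_error(yule_size_pmf(1, -1, 1), "nonnegative")
})

test_that("Yule pmf matches per-cell-event simulation", {
  set.seed(101)
  sizes <- replicate(20000, sim_yule_percell(1, 1))
  kmax <- 12
  obs <- tabulate(pmin(sizes, kmax + 1), nbins = kmax + 1)
  p <- yule_size_pmf(1, 1, 1:kmax)
  p_all <- c(p, 1 - sum(p)) # tail bin
  chi <- suppressWarnings(stats::chisq.test(obs, p = p_all))
  expect_gt(chi$p.value, 0.001)
})

test_that("bottleneck transition pmf: closed form, oracle, moments", {
  core <- core_params(D = 0.5, r = 1)
  ctx <- mutation_context(s = 0.386, t = 0, core)  # beta = 0.5 at these params
  expect_equal(bottleneck_transition_pmf(list(beta = 0.5), 0.5, 0), 1 / 3,
               tolerance = 1e-12)
  # closed form vs truncated double sum on a (beta, D) grid
  for (beta in c(0.1, 0.5, 0.9)) {
    for (D in c(0.2, 0.5, 0.8)) {
      for (i in c(0, 1, 2, 7)) {
        expect_equal(bottleneck_transition_pmf(list(beta = beta), D, i),
                     bottleneck_pmf_bruteforce(beta, D, i),
                     tolerance = 1e-10)
      }
    }
  }
  # normalization and mean E[M(tau+)] = D / beta
  i <- 0:500
  p <- bottleneck_transition_pmf(list(beta = 0.2), 0.3, i)
  expect_equal(sum(p), 1, tolerance = 1e-9)
  expect_equal(sum(i * p), 0.3 / 0.2, tolerance = 1e-9)
  # beta -> 1: a single Bernoulli(D) cell
  expect_equal(bottleneck_transition_pmf(list(beta = 1), 0.3, 0:2),
               c(0.7, 0.3, 0))
  expect_error(bottleneck_transition_pmf(list(beta = 0.5), 0.5, -1),
               "nonnegative")
})

test_that("phase-start extinction probability: values, limits, Monte Carlo", {
  expect_equal(survival_initial(1, 0.5), 1 / 3, tolerance = 1e-12)
  expect_equal(survival_initial(0, 0.37), 1)
  # continuous-culture limit equals the birth-death extinction probability
  expect_equal(survival_initial(0.5, 1 - 1e-9), 1 / 1.5, tolerance = 1e-6)
  expect_error(survival_initial(1, 1.2), "inside")
  # per-cell branching oracle: P(survive) = 1 - V(0, s) = 2/3 at s=1, D=0.5
  set.seed(77)
  n_rep <- 4000
  surv <- mean(replicate(n_rep, sim_lineage_percell(1, 0.5, 1, log(2))))
  p <- 2 / 3
  expect_lt(abs(surv - p), 3 * sqrt(p * (1 - p) / n_rep))
})

test_that("mid-phase extinction probability: boundaries and pgf identity", {
  core <- core_params(D = 0.1)
  for (s in c(0.05, 0.5, 2)) {
    expect_equal(survival_at_time(0, s, core), survival_initial(s, core$D),
                 tolerance = 1e-12)
    # t -> tau: one cell facing an immediate bottleneck
    v_end <- survival_at_time(core$tau - 1e-11, s, core)
    expect_equal(v_end, (1 - core$D) + core$D * survival_initial(s, core$D),
                 tolerance = 1e-9)
  }
  # compound identity: V(t,s) = sum_i P_i V(0,s)^i over random (t, s, D)
  set.seed(5)
  for (rep in 1:100) {
    D <- stats::runif(1, 0.05, 0.9)
    core <- core_params(D = D)
    s <- stats::rexp(1, 10)
    t <- stats::runif(1, 0, core$tau * 0.999)
    ctx <- mutation_context(s, t, core)
    v0 <- survival_initial(s, D)
    i <- 0:3000
    lhs <- survival_at_time(t, s, core)
    rhs <- sum(bottleneck_transition_pmf(ctx, D, i) * v0^i)
    expect_equal(lhs, rhs, tolerance = 1e-9)
  }
  core_b <- core_params(D = 0.1)
  expect_error(survival_at_time(core_b$tau, 0.1, core_b), "tau")
})

test_that("mid-phase extinction probability matches per-cell simulation", {
  # r = 1, tau = ln 10, D = 0.1, s = 0.1, mutation at t = 1
  core <- core_params(D = 0.1, omega = 0.1)
  v <- survival_at_time(1, 0.1, core)
  set.seed(42)
  n_rep <- 6000
  surv <- mean(replicate(n_rep,
    sim_lineage_percell(0.1, 0.1, 1, log(10), t0 = 1, cap = 200)))
  p <- 1 - v
  expect_lt(abs(surv - p), 3 * sqrt(p * (1 - p) / n_rep))
})

test_that("exact double integral and closed-form approximation", {
  p <- core_params(D = 0.1, omega = 0.1)
  ex <- fixation_rate_exact(p)
  ap <- fixation_rate_approx(p)
  expect_s3_class(ex, "rate_result")
  expect_identical(ex$method, "exact_integral")
  # at omega = 0.01 the approximation is good to < 2% for all D; at
  # omega = 0.1 the omega/(1+omega) factor overshoots E[s/(1+s)] by ~8%
  for (D in c(0.001, 0.01, 0.1, 0.5, 0.9, 0.999)) {
    p001 <- core_params(D = D, omega = 0.01)
    rel <- abs(fixation_rate_approx(p001)$gamma /
                 fixation_rate_exact(p001)$gamma - 1)
    expect_lt(rel, 0.02)
  }
  expect_lt(abs(ap$gamma / ex$gamma - 1), 0.10)
  # no mutations, no fixations
  expect_equal(fixation_rate_exact(core_params(mu = 0, D = 0.1))$gamma, 0)
  # requires the stable-population constraint
  expect_error(fixation_rate_exact(core_params(D = 0.1, tau = 5,
                                               stable = FALSE)), "stable")
})

test_that("approximation is monotone in D with the right limits", {
  for (om in c(0.01, 0.1, 1)) {
    D <- seq(0.001, 0.999, length.out = 60)
    g <- vapply(D, function(d)
      fixation_rate_approx(core_params(D = d, omega = om))$gamma, 0)
    expect_true(all(diff(g) > 0))
    # D -> 1 limit: r mu N omega / (1 + omega)
    expect_equal(g[length(g)], 1 * 1e-9 * 1e9 * om / (1 + om),
                 tolerance = 1e-3)
  }
  # gamma is roughly proportional to D when D is not too small
  D <- seq(0.1, 0.999, length.out = 40)
  gD <- vapply(D, function(d)
    fixation_rate_approx(core_params(D = d))$gamma, 0) / D
  expect_lt(max(gD) / min(gD), 3)
})

test_that("effective population size follows the printed formula", {
  p <- core_params(D = 0.1)
  expect_equal(ne_effective(p), 1e9 * log(10) / 18, tolerance = 1e-12)
  # definitional consistency: Ne 2 mu omega = (1 + omega) gamma_approx
  expect_equal(ne_effective(p) * 2 * p$mu * p$omega,
               fixation_rate_approx(p)$gamma * (1 + p$omega),
               tolerance = 1e-12)
})

test_that("effective population size limit exposes the factor-2 ambiguity", {
  # the printed formula tends to N r / 2 as D -> 1, not to N as the
  # accompanying text asserts; the transcription is implemented verbatim
  p <- core_params(D = 1 - 1e-9)
  expect_equal(ne_effective(p) / (p$N * p$r / 2), 1, tolerance = 1e-6)
  expect_false(isTRUE(all.equal(ne_effective(p) / p$N, 1, tolerance = 0.4)))
})

test_that("general resource-constrained rate reduces to the exponential one", {
  ap <- fixation_rate_approx(core_params(D = 0.1))
  gen <- fixation_rate_general(log(10), 1e-9, 1e9, 0.1, 0.1)
  expect_equal(gen$gamma, ap$gamma, tolerance = 1e-12)
})

test_that("optimal D at fixed tau is the root of 2(e^x - 1) = x e^x", {
  x_star <- uniroot(function(x) 2 * (exp(x) - 1) - x * exp(x), c(1, 2),
                    tol = 1e-12)$root
  opt <- optimal_D_fixed_tau(24)
  expect_equal(opt$D_star, exp(-x_star), tolerance = 1e-6)
  expect_equal(opt$ratio, exp(x_star), tolerance = 1e-6)
  # independent of tau
  expect_equal(optimal_D_fixed_tau(1)$D_star, opt$D_star, tolerance = 1e-6)
  # brute-force grid oracle
  lD <- seq(log(1e-6), log(1 - 1e-6), length.out = 1e5)
  f <- log(exp(lD))^2 / (exp(-lD) - 1)
  expect_lt(abs(lD[which.max(f)] - log(opt$D_star)), diff(lD[1:2]) * 2)
  # the (ln D)^2/(1/D - 1) factor prefers D* over D = e^-2 at fixed tau
  g_at <- function(D) fixation_rate_general(24, 1e-9, 1e9, 0.1, D)$gamma
  expect_gt(g_at(opt$D_star), g_at(exp(-2)))
})
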
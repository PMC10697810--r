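# Resource-unconstrained serial-passage simulator.

test_that("growth phase conserves expectations and handles edge cases", {
  core <- core_params(r = 1, mu = 0, N = 1e5, omega = 0.1, D = 0.1)
  set.seed(11)
  # E[final wild type] = N when starting from D N
  w <- replicate(200, {
    st <- new_population(wt = core$D * core$N)
    run_growth_phase(st, core)$wt
  })
  se <- stats::sd(w) / sqrt(length(w))
  expect_lt(abs(mean(w) - core$N), 3 * se)
  # zero duration is the identity
  st <- new_population(wt = 123)
  expect_identical(run_growth_phase(st, core, duration = 0), st)
  expect_error(run_growth_phase(st, core, duration = -1), "nonnegative")
})

test_that("bottleneck sampling is binomial thinning per compartment", {
  st <- new_population(wt = 0)
  st <- seed_lineage(st, s = 0.1, size = 0)
  set.seed(12)
  expect_equal(apply_bottleneck(st, 0.5)$lin$size, 0)
  # moments at size 1e6, D = 0.1
  draws <- replicate(10000, {
    st <- new_population(wt = 1e6)
    apply_bottleneck(st, 0.1)$wt
  })
  expect_lt(abs(mean(draws) - 1e5), 3 * sqrt(1e6 * 0.1 * 0.9 / 10000))
  expect_equal(stats::var(draws), 1e6 * 0.1 * 0.9, tolerance = 0.05)
  # survivors can never exceed the pre-bottleneck count
  small <- replicate(2000, {
    st <- new_population(wt = 5)
    apply_bottleneck(st, 0.5)$wt
  })
  expect_lte(max(small), 5)
})

test_that("identical seeds give identical results, different seeds differ", {
  core <- core_params(r = 1, mu = 1e-9, N = 1e9, omega = 0.1, D = 0.1)
  cfg <- sim_config(core, t_end = 20, n_replicates = 15, seed = 99)
  a <- run_experiment(cfg)
  b <- run_experiment(cfg)
  expect_identical(a$per_replicate, b$per_replicate)
  expect_identical(a$fixed_effects, b$fixed_effects)
  cfg2 <- sim_config(core, t_end = 20, n_replicates = 15, seed = 100)
  c <- run_experiment(cfg2)
  expect_false(identical(a$per_replicate, c$per_replicate))
})

test_that("no mutations means no fixations, exactly", {
  core <- core_params(mu = 0, D = 0.1)
  res <- run_experiment(sim_config(core, t_end = 10, n_replicates = 5,
                                   seed = 1))
  expect_identical(res$gamma_hat, 0)
  expect_identical(res$n_established, 0)
})

test_that("single-lineage establishment frequency matches the theory", {
  # P(establish) = 1 - V(0, s); default engine
  p_th <- 1 - survival_initial(1, 0.5)
  f <- establishment_freq(s = 1, D = 0.5, n_rep = 3000, seed = 21)
  expect_lt(abs(f - p_th), 3 * sqrt(p_th * (1 - p_th) / 3000))
  p_th2 <- 1 - survival_initial(0.3, 0.1)
  f2 <- establishment_freq(s = 0.3, D = 0.1, n_rep = 3000, seed = 22)
  expect_lt(abs(f2 - p_th2), 3 * sqrt(p_th2 * (1 - p_th2) / 3000))
})

test_that("phase-exact engine and per-division Gillespie agree", {
  # establishment frequency of a seeded lineage under the two engines
  core <- core_params(r = 1, mu = 0, N = 1e3, omega = 0.1, D = 0.2)
  v0 <- survival_initial(0.5, 0.2)
  run_one <- function(exact) {
    st <- new_population(wt = 0)
    st <- seed_lineage(st, s = 0.5, size = 1)
    repeat {
      st <- run_growth_phase(st, core, exact_mode = exact)
      st <- apply_bottleneck(st, core$D)
      if (st$lin$size == 0) return(FALSE)
      if (v0^st$lin$size < 1e-6) return(TRUE)
    }
  }
  set.seed(31)
  n <- 1500
  f_exact <- mean(replicate(n, run_one(TRUE)))
  f_fast <- mean(replicate(n, run_one(FALSE)))
  p <- 1 - v0
  expect_lt(abs(f_exact - p), 3 * sqrt(p * (1 - p) / n))
  expect_lt(abs(f_fast - p), 3 * sqrt(p * (1 - p) / n))
  expect_gt(stats::prop.test(c(round(f_exact * n), round(f_fast * n)),
                             c(n, n))$p.value, 0.01)
})

test_that("full experiments: hybrid and Gillespie modes are indistinguishable", {
  core <- core_params(r = 1, mu = 1e-3, N = 1e3, omega = 0.1, D = 0.1)
  t_end <- 5 * core$tau
  res_f <- run_experiment(sim_config(core, t_end = t_end, n_replicates = 60,
                                     seed = 41))
  res_e <- run_experiment(sim_config(core, t_end = t_end, n_replicates = 60,
                                     seed = 42, exact_mode = TRUE))
  pt <- stats::poisson.test(c(res_f$n_established, res_e$n_established))
  expect_gt(pt$p.value, 0.01)
})

test_that("estimated adaptation rate matches the exact theory", {
  core <- core_params(r = 1, mu = 1e-9, N = 1e9, omega = 0.1, D = 0.5)
  res <- run_experiment(sim_config(core, t_end = 50, n_replicates = 250,
                                   seed = 51))
  g_th <- fixation_rate_exact(core)$gamma
  expect_lt(abs(res$gamma_hat - g_th), 3 * res$se)
})

test_that("summaries of established mutations behave", {
  fake <- structure(list(fixed_effects = 0.3, origin_phases = 1,
                         config = list(core = core_params(D = 0.1))),
                    class = "sim_result")
  st <- fixed_mutation_stats(fake)
  expect_equal(st$mean_fixed_s, 0.3)
  expect_equal(st$ratio_to_omega, 3)
  fake$fixed_effects <- numeric(0)
  expect_error(fixed_mutation_stats(fake), "no established")
})

test_that("trajectories are recorded in long format", {
  core <- core_params(r = 1, mu = 1e-4, N = 1e4, omega = 0.1, D = 0.1)
  res <- run_experiment(sim_config(core, t_end = 3 * core$tau,
                                   n_replicates = 2, seed = 61,
                                   record_trajectory = TRUE))
  tr <- res$trajectory
  expect_true(all(c("replicate", "time", "compartment", "type", "s",
                    "count") %in% names(tr)))
  expect_true(all(tr$type %in% c("wt", "mutant")))
  expect_gte(min(tr$count), 0)
})
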
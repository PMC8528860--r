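# Small fixed trees used throughout
tree3 <- parse_chronogram("((A:5,B:5):5,C:10);", 1)
tree5 <- parse_chronogram("(((A:3,B:3):4,C:7):3,(D:8,E:8):2);", 0.9)

test_that("core quantities reproduce the hand-derived special cases", {
  # pure birth, f = 1: Phi = 0 and Psi(s, t) = exp(-lambda (t - s))
  core <- bd_core_quantities(constant_rates(0.1, 0), f = 1, t_max = 10)
  expect_equal(core$Phi(c(2, 7)), c(0, 0), tolerance = 1e-12)
  expect_equal(core$Psi(c(1, 0), c(4, 10)),
               exp(-0.1 * c(3, 10)), tolerance = 1e-12)
  # lambda = mu, f = 1: R = 0, Phi(t) = lambda t / (1 + lambda t)
  core2 <- bd_core_quantities(constant_rates(0.2, 0.2), f = 1, t_max = 10)
  tt <- c(1, 5, 10)
  expect_equal(core2$Phi(tt), 0.2 * tt / (1 + 0.2 * tt), tolerance = 1e-10)
  expect_equal(core2$R(tt), rep(0, 3), tolerance = 1e-12)
  # Psi(t, t) = 1 for any model
  env <- test_env()
  core3 <- bd_core_quantities(
    env_rates("M4.2", c(alpha1 = 0.2, beta1 = 0.05, alpha2 = 0.05,
                        beta2 = -0.02), env), f = 0.7, t_max = 30)
  expect_equal(core3$Psi(c(0, 3, 17), c(0, 3, 17)), rep(1, 3),
               tolerance = 1e-9)
  # Phi(0) = 1 - f: an extant lineage is unsampled with probability 1 - f
  expect_equal(core3$Phi(0), 0.3, tolerance = 1e-10)
})

test_that("quadrature integrals match an independent ODE solver", {
  skip_if_not_installed("deSolve")
  env <- test_env()
  rate <- env_rates("M2.2", c(alpha = 0.08, beta = 0.06, mu = 0.03), env)
  t_max <- 30
  times <- c(0.7, 3.3, 11.1, 19.9, 28.5, t_max)
  got <- reefdiv:::.bd_RJ(rate, times, t_max, method = "quadrature")
  ode <- deSolve::lsoda(
    y = c(R = 0, J = 0),
    times = c(0, times),
    func = function(t, y, p) {
      lam <- rate_lambda(rate, t); mu <- rate_mu(rate, t)
      list(c(lam - mu, exp(y[1]) * lam))
    },
    rtol = 1e-11, atol = 1e-12)
  expect_equal(got$R, unname(ode[-1, "R"]), tolerance = 1e-8)
  expect_equal(got$J, unname(ode[-1, "J"]), tolerance = 1e-8)
})

test_that("tree log-likelihood matches hand computation and is path-independent", {
  rate <- constant_rates(0.1, 0)
  expected <- log(0.1) - 0.1 * 25    # L = lambda e^{-25 lambda}
  for (m in c("closed", "quadrature", "branches"))
    expect_equal(tree_loglik(tree3, rate, method = m), expected,
                 tolerance = 1e-9, info = m)
  # telescoped and per-branch paths agree on a sampled, extinction-bearing case
  rate2 <- constant_rates(0.25, 0.1)
  expect_equal(tree_loglik(tree5, rate2),
               tree_loglik(tree5, rate2, method = "branches"),
               tolerance = 1e-8)
  env <- test_env()
  rate3 <- env_rates("M4.1", c(alpha1 = 0.2, beta1 = 0.004, alpha2 = 0.02,
                               beta2 = 0.001), env)
  expect_equal(tree_loglik(tree5, rate3),
               tree_loglik(tree5, rate3, method = "branches"),
               tolerance = 1e-8)
})

test_that("environmental models nest the constant model at beta = 0", {
  env <- test_env()
  trees <- sim_trees_m1(5)
  for (ch in trees) {
    base <- tree_loglik(ch, constant_rates(0.17, 0.05))
    expect_equal(tree_loglik(ch, env_rates(
      "M2.1", c(alpha = 0.17, beta = 0, mu = 0.05), env)), base,
      tolerance = 1e-6)
    expect_equal(tree_loglik(ch, env_rates(
      "M3.2", c(alpha = 0.05, beta = 0, lambda = 0.17), env)), base,
      tolerance = 1e-6)
  }
})

test_that("shift likelihood: closed form equals quadrature, degenerate ks collapse", {
  ch <- sim_trees_m1(1)[[1]]
  # k = 0 equals the constant-rate likelihood
  expect_equal(shift_loglik(ch, numeric(0), 0.2, 0.05),
               tree_loglik(ch, constant_rates(0.2, 0.05)), tolerance = 1e-12)
  # k = 2 with equal rates in all intervals equals constant rates
  expect_equal(shift_loglik(ch, c(5, 10), rep(0.2, 3), rep(0.05, 3)),
               tree_loglik(ch, constant_rates(0.2, 0.05)), tolerance = 1e-6)
  # random piecewise configurations: dual-route agreement
  set.seed(42)
  for (i in 1:5) {
    s <- sort(runif(2, 1, ch$crown_age - 1))
    lam <- runif(3, 0.05, 0.5); mu <- runif(3, 0, 0.2)
    expect_equal(shift_loglik(ch, s, lam, mu, method = "closed"),
                 shift_loglik(ch, s, lam, mu, method = "quadrature"),
                 tolerance = 1e-6)
  }
})

test_that("likelihood depends on branching times only, not tip labels", {
  ch <- sim_trees_m1(1)[[1]]
  phy2 <- ch$phy
  set.seed(1)
  phy2$tip.label <- sample(phy2$tip.label)
  ch2 <- parse_chronogram(phy2, ch$sampling_fraction)
  rate <- constant_rates(0.2, 0.07)
  expect_equal(tree_loglik(ch, rate), tree_loglik(ch2, rate),
               tolerance = 1e-12)
})

test_that("quadrature is insensitive to segment refinement", {
  # re-knotting the same piecewise-linear v(t) at half the spacing halves
  # every quadrature segment; logL must not move
  env1 <- test_env()
  fine <- seq(0, 40, by = 0.5)
  env2 <- env_series(fine, env_eval(env1, fine), kind = "patch_count")
  ch <- sim_trees_m1(1)[[1]]
  r1 <- env_rates("M2.2", c(alpha = 0.1, beta = 0.05, mu = 0.04), env1)
  r2 <- env_rates("M2.2", c(alpha = 0.1, beta = 0.05, mu = 0.04), env2)
  expect_equal(tree_loglik(ch, r1), tree_loglik(ch, r2), tolerance = 1e-7)
})

test_that("invalid rates give -Inf, not an exception", {
  env <- test_env()   # v in roughly [4, 16]
  ch <- tree5
  # strongly negative slope drives lambda(t) below zero somewhere
  bad <- env_rates("M2.1", c(alpha = 0.1, beta = -0.1, mu = 0.02), env)
  expect_identical(tree_loglik(ch, bad), -Inf)
  badmu <- env_rates("M3.1", c(alpha = 0.01, beta = -0.05, lambda = 0.2), env)
  expect_identical(tree_loglik(ch, badmu), -Inf)
})

test_that("fitting recovers sensible parameters and handles the Yule boundary", {
  # a pure-birth tree: the mu = 0 boundary is handled without crashing and
  # the optimizer is free to walk to it (mu on the log scale)
  ch <- simulate_tree(constant_rates(0.25, 0), f = 1, crown_age = 18,
                      seed = 31)
  expect_true(is.finite(tree_loglik(ch, constant_rates(0.25, 0))))
  ft <- fit_model(ch, "M1", n_restarts = 4, seed = 1)
  expect_true(is.finite(ft$logL))
  expect_gte(ft$logL, tree_loglik(ch, constant_rates(0.25, 0)) - 1e-6)
  expect_equal(ft$AICc, aicc(ft$logL, 2, length(ch$branching_times)))
  # nesting: richer environmental families can only improve the maximum
  env <- test_env()
  f1 <- fit_model(ch, "M1", n_restarts = 4, seed = 1)
  f21 <- fit_model(ch, "M2.1", env = env, n_restarts = 4, seed = 1)
  f41 <- fit_model(ch, "M4.1", env = env, n_restarts = 4, seed = 1)
  expect_gte(f21$logL, f1$logL - 1e-4)
  expect_gte(f41$logL, f21$logL - 1e-4)
})

test_that("log-likelihood at the truth beats perturbed parameters on average", {
  trees <- sim_trees_m1(8)
  truth <- constant_rates(0.15, 0.04)
  worse <- constant_rates(0.28, 0.12)
  d <- vapply(trees, function(ch)
    tree_loglik(ch, truth) - tree_loglik(ch, worse), numeric(1))
  expect_gt(mean(d), 0)
})
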
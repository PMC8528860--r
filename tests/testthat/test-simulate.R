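test_that("tree simulation is reproducible and respects its conditioning", {
  rate <- constant_rates(0.2, 0.05)
  a <- simulate_tree(rate, f = 0.8, crown_age = 15, seed = 123)
  b <- simulate_tree(rate, f = 0.8, crown_age = 15, seed = 123)
  expect_identical(ape::write.tree(a$phy), ape::write.tree(b$phy))
  c <- simulate_tree(rate, f = 0.8, crown_age = 15, seed = 124)
  expect_false(identical(ape::write.tree(a$phy), ape::write.tree(c$phy)))
  # crown conditioning: the returned crown age equals the requested one
  expect_equal(a$crown_age, 15, tolerance = 1e-6)
  expect_gte(a$n_tips, 2)
  # target_tips solves the expectation 2 f e^{rT} for the crown age
  d <- simulate_tree(rate, f = 1, target_tips = 40, seed = 5)
  expect_equal(d$crown_age, log(20) / 0.15, tolerance = 1e-4)
})

test_that("pure-birth complete-sampling trees match the branching-process mean", {
  lambda <- 0.3; T <- 5
  n <- vapply(1:300, function(i)
    simulate_tree(constant_rates(lambda, 0), f = 1, crown_age = T,
                  seed = 900 + i)$n_tips, numeric(1))
  # with mu = 0 and f = 1 nothing is pruned, so E[n] = 2 e^{lambda T}
  m <- 2 * exp(lambda * T)
  se <- sd(n) / sqrt(length(n))
  expect_lt(abs(mean(n) - m), 3 * se)
})

test_that("a speciation spike in the past concentrates branching times there", {
  spike <- shift_rates(c(8, 10), c(0.05, 0.8, 0.05), c(0, 0, 0))
  flat <- constant_rates(0.18, 0)
  bt_spike <- unlist(lapply(1:10, function(i)
    simulate_tree(spike, f = 1, crown_age = 12,
                  seed = 300 + i)$branching_times))
  bt_flat <- unlist(lapply(1:10, function(i)
    simulate_tree(flat, f = 1, crown_age = 12,
                  seed = 400 + i)$branching_times))
  expect_gt(median(bt_spike), median(bt_flat))
  expect_gt(mean(bt_spike >= 8 & bt_spike <= 10), 0.5)
})

test_that("the score of the likelihood vanishes at the truth (simulator consistency)", {
  lambda <- 0.25; mu <- 0.05
  h <- 1e-4
  score <- vapply(1:40, function(i) {
    ch <- simulate_tree(constant_rates(lambda, mu), f = 1, crown_age = 10,
                        seed = 600 + i)
    (tree_loglik(ch, constant_rates(lambda + h, mu)) -
        tree_loglik(ch, constant_rates(lambda - h, mu))) / (2 * h)
  }, numeric(1))
  se <- sd(score) / sqrt(length(score))
  expect_lt(abs(mean(score)), 3 * se)
})

test_that("habitat simulation hits its truth table exactly", {
  sim <- simulate_habitat_stack(3, k = c(3, 5, 8), seed = 2)
  got <- vapply(sim$stack$slices, count_patches, integer(1))
  expect_equal(got, c(3L, 5L, 8L))
  expect_equal(vapply(sim$stack$slices, count_patches, integer(1),
                      connectivity = 4), c(3L, 5L, 8L))
  es <- build_env_series(sim$stack, "patch_count")
  expect_equal(es$value, c(3, 5, 8))
  expect_equal(vapply(sim$stack$slices, total_area, numeric(1)),
               sim$truth$total_area_km2)
  # zero-blob slice: no patches, no area
  sim0 <- simulate_habitat_stack(2, k = c(0, 1), seed = 4)
  expect_equal(count_patches(sim0$stack$slices[[1]]), 0L)
  expect_equal(sim0$truth$total_area_km2[1], 0)
  # impossible packing errors out at the placement cap
  expect_error(simulate_habitat_stack(1, k = 500, n_lat = 6, n_lon = 12,
                                      seed = 1, max_place_tries = 50),
               "placement cap")
})

test_that("recovery harness tabulates selection frequencies", {
  env <- test_env()
  configs <- list(list(label = "m1", rate = constant_rates(0.2, 0.05),
                       f = 1, crown_age = 14))
  out <- recovery_experiment(configs, n_rep = 4,
                             models = c("M1", "M2.2"), env = env,
                             seed = 2, n_restarts = 2, maxit = 200)
  expect_equal(nrow(out$per_replicate), 4)
  sm <- out$summary[[1]]
  expect_equal(sm$n_ok + sm$n_failed, 4)
  expect_equal(sum(sm$class_freq), 1, tolerance = 1e-12)
  expect_true(all(c("lambda", "mu") %in% names(sm$median_est)))
})
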
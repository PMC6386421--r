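# a minimal converged steady-state object for observable tests
fake_steady <- function(N, R, species_index = seq_along(N)) {
  structure(list(state = community_state(N, R, species_index),
                 survivors = which(N > 0), converged = TRUE,
                 residuals = c(growth = 0, resource_drift = 0),
                 elapsed = 0, energy_balance_gap = 0, n_seeded = length(N)),
            class = "steady_state_result")
}

test_that("flux networks evaluate the community energy conversion matrix", {
  # single species at its closed-form fixed point: J_00 = D l N w c R = 8
  fx <- make_fixture("single_species_closed_form")
  res <- integrate_to_steady_state(fx$state, fx$pool, fx$env)
  fn <- flux_network(res, fx$pool, fx$env)
  expect_equal(fn$flux_matrix[1, 1], 8, tolerance = 1e-6)

  # zero leakage: empty network, trivially acyclic
  pool <- regional_pool(matrix(1, 1, 2), maintenance = 1)
  env0 <- environment_params(matrix(0.5, 2, 2), leakage = 0,
                             supply_rate = c(1, 0))
  st <- fake_steady(3, c(1, 1))
  fn0 <- flux_network(st, pool, env0)
  expect_true(all(fn0$flux_matrix == 0))
  expect_true(fn0$is_dag)
  expect_equal(nrow(fn0$edges), 0)
})

test_that("flux network column sums equal the leaked energy per resource", {
  sys <- tiny_system(M = 7, S = 10, w0k0 = 50, leakage = 0.8, seed = 31)
  st <- fake_steady(runif(10, 0, 5), runif(7, 0, 2))
  fn <- flux_network(st, sys$pool, sys$env)
  jin <- input_fluxes(st$state, sys$pool, sys$env)$incoming
  expected <- sys$env$leakage * colSums(st$state$abundances * jin)
  expect_equal(colSums(fn$flux_matrix), expected, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("cycle detection matches a brute-force oracle on small graphs", {
  cyc <- make_fixture("three_cycle_network")
  adj <- t(cyc) > 0
  expect_true(brute_force_has_cycle(adj))
  expect_false(thermocrm:::is_dag_adjacency(adj))

  set.seed(17)
  for (rep in 1:60) {
    M <- sample(3:8, 1)
    adj <- matrix(runif(M * M) < 0.25, M, M)
    diag(adj) <- FALSE
    expect_identical(thermocrm:::is_dag_adjacency(adj),
                     !brute_force_has_cycle(adj))
  }
})

test_that("Simpson flux diversity recovers specialist and generalist limits", {
  M <- 12
  D <- matrix(1 / M, M, M)
  env <- environment_params(D, leakage = 0.5,
                            supply_rate = c(10, rep(0, M - 1)))
  cmat <- rbind(c(1, rep(0, M - 1)),           # specialist on resource 0
                c(rep(1, 10), 0, 0),           # evenly spread over ten
                c(1, 1, rep(0, M - 2)))        # two-resource split
  pool <- regional_pool(cmat, maintenance = rep(1, 3))
  st <- fake_steady(c(1, 1, 1), rep(1, M))
  meff <- effective_resources(st, pool, env)
  expect_equal(unname(meff), c(1, 10, 2))
  expect_true(all(meff >= 1 & meff <= M))

  # permutation invariance in the resource labels
  perm <- sample(M)
  p2 <- permute_resources(pool, env, st$state, perm)
  st2 <- fake_steady(c(1, 1, 1), st$state$resources[perm])
  expect_equal(effective_resources(st2, p2$pool, p2$env), meff)
})

test_that("energy budgets split external from byproduct energy", {
  fx <- make_fixture("single_species_closed_form")
  res <- integrate_to_steady_state(fx$state, fx$pool, fx$env)
  eb <- energy_budget(res, fx$pool, fx$env)
  expect_equal(unname(eb$total), 1, tolerance = 1e-6)       # equals m
  expect_equal(unname(eb$external_share), 1, tolerance = 1e-12)
})

test_that("empty-chemostat susceptibilities equal the dilution time", {
  fx <- make_fixture("empty_chemostat")
  res <- integrate_to_steady_state(fx$state, fx$pool, fx$env)
  s <- resource_susceptibilities(res, fx$pool, fx$env, resources = 1:3)
  expect_equal(unname(s), rep(fx$env$dilution_time, 3), tolerance = 1e-4)
})

test_that("a pinned resource has zero susceptibility", {
  # one specialist, no leakage: R = m/c is set by the consumer, not kappa
  pool <- regional_pool(rbind(c(1, 0)), maintenance = 1)
  env <- environment_params(diag(2), leakage = 0, supply_rate = c(10, 1))
  res <- integrate_to_steady_state(
    community_state(0.1, c(10, 1), 1L), pool, env)
  expect_true(res$converged)
  expect_equal(res$state$resources[1], 1, tolerance = 1e-6)  # R = m/c
  s <- resource_susceptibilities(res, pool, env, resources = 1L)
  expect_lt(abs(s[["R0"]]), 1e-3)
})

test_that("richness, rank-abundance and availability behave on fixtures", {
  fx <- make_fixture("empty_chemostat")
  res <- integrate_to_steady_state(fx$state, fx$pool, fx$env)
  expect_equal(richness(res), 0)
  expect_length(rank_abundance(res), 0)
  # two of three resources supplied: both above the availability threshold
  expect_equal(available_resources(res, fx$env), 2)

  st <- fake_steady(c(5, 3, 2, 0), rep(1, 4))
  expect_equal(rank_abundance(st), c(0.5, 0.3, 0.2))
  expect_equal(rank_abundance(st, truncate_at = 0.25), c(0.5, 0.3))
  expect_equal(rank_abundance(st, truncate_at = 0.4), 0.5)
})

test_that("zero-leakage communities leave byproducts unavailable", {
  pool <- regional_pool(rbind(c(1, 0.01, 0.01)), maintenance = 1)
  D <- matrix(1 / 3, 3, 3)
  env <- environment_params(D, leakage = 0, supply_rate = c(10, 0, 0))
  res <- integrate_to_steady_state(community_state(0.1, c(10, 0, 0), 1L),
                                   pool, env)
  expect_equal(available_resources(res, env), 1)
})
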
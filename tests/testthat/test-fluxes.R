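one_species_system <- function(l = 0, c = 1, w = 1, kappa = 10, D = matrix(1)) {
  pool <- regional_pool(matrix(c, 1, ncol(D)), maintenance = 1)
  env <- environment_params(D, energy_density = w, leakage = l,
                            supply_rate = kappa)
  list(pool = pool, env = env)
}

test_that("input fluxes follow the functional response", {
  sys <- one_species_system()
  st <- community_state(1, 2)
  expect_equal(input_fluxes(st, sys$pool, sys$env)$incoming[1, 1], 2)

  st0 <- community_state(1, 0)
  expect_true(all(input_fluxes(st0, sys$pool, sys$env)$incoming == 0))

  env_m <- environment_params(matrix(1), leakage = 0, supply_rate = 10,
                              response = "monod", sigma_max = 1)
  expect_equal(input_fluxes(st, sys$pool, env_m)$incoming[1, 1], 2 / 3)
})

test_that("growth fluxes respect leakage bookkeeping", {
  D2 <- matrix(c(0.5, 0.5, 0.5, 0.5), 2, 2)
  pool <- regional_pool(matrix(1, 1, 2), maintenance = 1)
  st <- community_state(1, c(2, 2))
  env0 <- environment_params(D2, leakage = 0, supply_rate = c(1, 0))
  f0 <- growth_fluxes(input_fluxes(st, pool, env0), env0)
  expect_equal(f0$growth, unname(rowSums(f0$incoming)))

  env1 <- environment_params(D2, leakage = 1, supply_rate = c(1, 0))
  expect_equal(growth_fluxes(input_fluxes(st, pool, env1), env1)$growth, 0)

  env <- environment_params(D2, leakage = c(0.5, 0.25), supply_rate = c(1, 0))
  f <- growth_fluxes(input_fluxes(st, pool, env), env)
  expect_equal(f$incoming[1, ], c(2, 2), ignore_attr = TRUE)
  expect_equal(f$growth, 2.5)  # 0.5*2 + 0.75*2
})

test_that("secretion fluxes route leaked energy through D", {
  sys <- one_species_system(l = 0.5)
  st <- community_state(1, 4)  # J_in = 4
  f <- community_fluxes(st, sys$pool, sys$env)
  expect_equal(f$outgoing[1, 1], 2)

  D <- matrix(c(0.3, 0.7, 1, 0), 2, 2)
  env <- environment_params(D, leakage = 1, supply_rate = c(1, 0))
  pool <- regional_pool(matrix(1, 1, 2), maintenance = 1)
  st2 <- community_state(1, c(1, 1))   # incoming row (1, 1)
  f2 <- community_fluxes(st2, pool, env)
  expect_equal(f2$outgoing[1, ], c(1.3, 0.7), ignore_attr = TRUE)
  expect_equal(sum(f2$outgoing), sum(env$leakage * f2$incoming))

  env0 <- environment_params(D, leakage = 0, supply_rate = c(1, 0))
  expect_true(all(community_fluxes(st2, pool, env0)$outgoing == 0))
})

test_that("flux sets satisfy the energy bookkeeping invariants", {
  set.seed(21)
  for (rep in 1:5) {
    sys <- tiny_system(M = 6, S = 9, leakage = runif(1), seed = rep)
    st <- community_state(runif(9), runif(6, 0, 5))
    f <- community_fluxes(st, sys$pool, sys$env)
    expect_equal(f$incoming,
                 f$mass_in * rep(sys$env$energy_density, each = 9))
    expect_equal(f$growth,
                 as.vector(f$incoming %*% (1 - sys$env$leakage)))
    # second law: growth never exceeds total import
    expect_true(all(f$growth <= rowSums(f$incoming) + 1e-12))
    # column-stochastic D conserves leaked energy per species
    expect_lt(max(abs(rowSums(f$outgoing) -
                        as.vector(f$incoming %*% sys$env$leakage))), 1e-10)
  }
})

test_that("dynamics vanish at the closed-form fixed points", {
  # empty chemostat
  fx <- make_fixture("empty_chemostat")
  st <- community_state(0, fx$expected_resources, species_index = 1L)
  d <- dynamics_rhs(st, fx$pool, fx$env)
  expect_equal(d$dR, rep(0, 3))
  expect_equal(d$dN, 0)

  # single species, no leakage: R = m/c = 1, N = (kappa - R/tau)/m = 9
  sys0 <- one_species_system(l = 0)
  d0 <- dynamics_rhs(community_state(9, 1), sys0$pool, sys0$env)
  expect_equal(d0$dN, 0); expect_equal(d0$dR, 0)

  # with l = 0.5 and full self-recycling: R = 2, N = 8
  sys5 <- one_species_system(l = 0.5)
  d5 <- dynamics_rhs(community_state(8, 2), sys5$pool, sys5$env)
  expect_equal(d5$dN, 0, tolerance = 1e-12)
  expect_equal(d5$dR, 0, tolerance = 1e-12)
})

test_that("extinct species stay extinct and zero leakage recovers MacArthur", {
  sys <- tiny_system(M = 5, S = 8, leakage = 0, seed = 3)
  st <- community_state(c(rep(0, 4), runif(4)), runif(5, 0, 2))
  d <- dynamics_rhs(st, sys$pool, sys$env)
  expect_true(all(d$dN[1:4] == 0))
  # no secretion: resource gains only from supply
  f <- community_fluxes(st, sys$pool, sys$env)
  expect_true(all(f$outgoing == 0))
})

test_that("aggregated rhs agrees with explicit per-species bookkeeping", {
  set.seed(5)
  for (rep in 1:4) {
    sys <- tiny_system(M = 5, S = 7, leakage = runif(1), seed = rep + 10)
    st <- community_state(runif(7), runif(5, 0, 3))
    fast <- dynamics_rhs(st, sys$pool, sys$env)
    slow <- loop_rhs(st, sys$pool, sys$env)
    expect_equal(fast$dN, slow$dN, tolerance = 1e-12)
    expect_equal(fast$dR, slow$dR, tolerance = 1e-12)
  }
})

test_that("rhs is equivariant under resource relabeling", {
  set.seed(9)
  for (rep in 1:4) {
    sys <- tiny_system(M = 6, S = 8, leakage = runif(1), seed = rep + 20)
    st <- community_state(runif(8), runif(6, 0, 3))
    perm <- sample(6)
    p2 <- permute_resources(sys$pool, sys$env, st, perm)
    d <- dynamics_rhs(st, sys$pool, sys$env)
    d2 <- dynamics_rhs(p2$state, p2$pool, p2$env)
    expect_equal(d2$dN, d$dN, tolerance = 1e-12)
    expect_equal(d2$dR, d$dR[perm], tolerance = 1e-12)
  }
})

test_that("flux evaluation rejects contract violations", {
  sys <- one_species_system()
  st_bad <- community_state(1, 1)
  st_bad$resources <- -1
  expect_error(input_fluxes(st_bad, sys$pool, sys$env), "negative resource")
  pool_wide <- regional_pool(matrix(1, 1, 2), maintenance = 1)
  expect_error(input_fluxes(community_state(1, c(1, 1)), pool_wide, sys$env),
               "mismatch")
  expect_error(environment_params(matrix(1), leakage = 1.5, supply_rate = 1),
               "leakage")
  expect_error(environment_params(matrix(c(0.5, 0.4, 0.5, 0.6), 2),
                                  leakage = 0, supply_rate = c(1, 0)),
               "sum to 1")
})
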
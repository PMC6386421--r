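test_that("binary consumer matrices have the prescribed structure and moments", {
  spec <- sampling_spec()
  cmat <- sample_consumer_matrix(spec, seed = 42)
  expect_equal(dim(cmat), c(200, 100))
  expect_true(all(cmat %in% c(spec$high_value, spec$baseline_value)))
  # ~10 preferred resources per species; mean over 200 binomial(100, 0.1)
  # rows has SE = 3/sqrt(200)
  high_per_row <- rowSums(cmat == spec$high_value)
  expect_lt(abs(mean(high_per_row) - 10), 3 * 3 / sqrt(200))
  # Bernoulli-mixture first moment <c> = 0.109
  se <- sqrt(0.10009 - 0.109^2) / sqrt(length(cmat))
  expect_lt(abs(mean(cmat) - 0.109), 3 * se)
})

test_that("consumer matrix edge cases behave", {
  all_on <- sampling_spec(n_species = 5, n_resources = 6, mean_preferred = 6,
                          baseline_value = 0)
  expect_true(all(sample_consumer_matrix(all_on, seed = 1) == 1))
  expect_error(sampling_spec(n_resources = 10, mean_preferred = 11),
               "mean_preferred")
})

test_that("gamma scheme matches the binary moments; gaussian is truncated", {
  mu <- 0.109; m2 <- 0.10009
  sp_g <- sampling_spec(n_species = 2000, n_resources = 100,
                        consumer_scheme = "gamma")
  cg <- sample_consumer_matrix(sp_g, seed = 7)
  expect_true(all(cg >= 0))
  expect_lt(abs(mean(cg) - mu) / mu, 0.05)
  expect_lt(abs(mean(cg^2) - m2) / m2, 0.05)

  # gaussian: normal(mu, sd) conditioned positive; compare to the
  # zero-truncated normal's closed-form mean
  sp_n <- sampling_spec(n_species = 2000, n_resources = 100,
                        consumer_scheme = "gaussian")
  cn <- sample_consumer_matrix(sp_n, seed = 7)
  expect_true(all(cn >= 0))
  sd0 <- sqrt(m2 - mu^2)
  a <- -mu / sd0
  mean_trunc <- mu + sd0 * dnorm(a) / (1 - pnorm(a))
  expect_lt(abs(mean(cn) - mean_trunc) / mean_trunc, 0.05)
})

test_that("metabolic matrices are exactly column-stochastic in every scheme", {
  for (scheme in c("sparse", "dense", "uniform")) {
    sp <- sampling_spec(n_resources = 50, d_scheme = scheme)
    D <- sample_metabolic_matrix(sp, seed = 3)
    expect_true(all(D >= 0))
    expect_lt(max(abs(colSums(D) - 1)), 1e-12)
  }
  expect_equal(sample_metabolic_matrix(
    sampling_spec(n_resources = 4, mean_preferred = 2, d_scheme = "uniform")),
    matrix(0.25, 4, 4), ignore_attr = TRUE)
})

test_that("dense Dirichlet columns at M = 2 have Beta(1,1) moments", {
  sp <- sampling_spec(n_resources = 2, mean_preferred = 1, d_scheme = "dense")
  set.seed(11)
  draws <- replicate(1e4, sample_metabolic_matrix(sp)[1, 1])
  expect_lt(abs(mean(draws) - 0.5), 0.015)
})

test_that("sparse scheme concentrates columns on few byproducts", {
  sp <- sampling_spec(n_resources = 100)
  D <- sample_metabolic_matrix(sp, seed = 5)
  col_meff <- 1 / colSums(D^2)  # effective nonzero entries per column
  expect_lt(median(col_meff), 25) # far below the dense limit of ~M/2
})

test_that("maintenance costs have mean 1 and sd 0.1, resampled above 0", {
  sp0 <- sampling_spec(cost_sd = 0)
  cg0 <- sample_costs_and_growth(sp0, seed = 1)
  expect_true(all(cg0$maintenance == 1))
  expect_true(all(cg0$growth_factor == 1))

  cg <- sample_costs_and_growth(sampling_spec(), seed = 8)
  m <- cg$maintenance
  expect_length(m, 200)
  expect_true(all(m > 0))
  expect_lt(abs(mean(m) - 1), 3 * 0.1 / sqrt(200))
  sd_se <- 0.1 / sqrt(2 * (200 - 1))  # large-sample SE of the sd estimator
  expect_lt(abs(sd(m) - 0.1), 3 * sd_se)
})

test_that("niche overlap handles the trivial geometries", {
  expect_equal(mean_niche_overlap(diag(2))$mean, 0)
  same <- matrix(rep(c(1, 2, 3), each = 4), 4, 3)
  expect_equal(mean_niche_overlap(same)$mean, 1)
  expect_error(mean_niche_overlap(rbind(c(1, 0), c(0, 0))), "all-zero")
})

test_that("moment-form overlap matches the Bernoulli-mixture closed form", {
  # <c>^2/<c^2> = 0.109^2 / 0.10009 at the default binary parameters
  expected <- 0.109^2 / 0.10009
  expect_equal(expected, 0.1187031671, tolerance = 1e-9)
  sp <- sampling_spec(n_species = 2000, n_resources = 100)
  ov <- mean_niche_overlap(sample_consumer_matrix(sp, seed = 13))
  expect_lt(abs(ov$moment - expected) / expected, 0.02)
  expect_lt(abs(ov$mean - expected) / expected, 0.02)
})

test_that("overlap tuning hits its target across the attainable range", {
  base <- sampling_spec()
  # fixed point: the default spec's own overlap returns the default params
  ov0 <- 0.109^2 / 0.10009
  sp0 <- spec_for_target_overlap(ov0, base)
  expect_equal(sp0$baseline_value, base$baseline_value, tolerance = 1e-6)
  expect_equal(sp0$high_value, base$high_value, tolerance = 1e-6)
  # degenerate upper bound: all entries equal
  sp1 <- spec_for_target_overlap(1, base)
  expect_equal(sp1$high_value, sp1$baseline_value)
  # generic targets on both branches re-evaluate to the target
  for (target in c(0.05, 0.3, 0.5, 0.9)) {
    sp <- spec_for_target_overlap(target, base)
    p <- sp$mean_preferred / sp$n_resources
    got <- binary_overlap_moment_test(p, sp$high_value, sp$baseline_value)
    expect_equal(got, target, tolerance = 1e-8)
    # capacity conserved
    cap <- sp$mean_preferred * sp$high_value +
      (sp$n_resources - sp$mean_preferred) * sp$baseline_value
    expect_equal(cap, 10.9, tolerance = 1e-8)
  }
  expect_error(spec_for_target_overlap(1.5, base), "attainable")
})

test_that("colonization subsets are uniform, exact-size and reproducible", {
  pool <- sample_pool(sampling_spec(n_species = 200, n_resources = 10,
                                    mean_preferred = 2), seed = 1)
  subs <- draw_community_subsets(pool, 10, 100, seed = 4)
  expect_length(subs, 10)
  for (s in subs) {
    expect_length(s, 100)
    expect_false(any(duplicated(s)))
    expect_true(all(s >= 1 & s <= 200))
  }
  expect_identical(subs, draw_community_subsets(pool, 10, 100, seed = 4))
  full <- draw_community_subsets(pool, 2, 200, seed = 1)
  expect_identical(full[[1]], 1:200)
  expect_error(draw_community_subsets(pool, 1, 201, seed = 1), "subset_size")
})
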
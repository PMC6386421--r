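#' Functional response sigma(x)
#'
#' Type-I is the identity; the Monod response saturates at `sigma_max` and
#' has unit slope at the origin.
#' @param x non-negative uptake argument c_ia * R_a.
#' @param env an `environment_params`.
#' @keywords internal
sigma_response <- function(x, env) {
  switch(env$response,
         type_I = x,
         monod = env$sigma_max * x / (env$sigma_max + x))
}

#' Per-cell resource import fluxes
#'
#' Evaluates the incoming energy flux J_in[i, a] = w_a * sigma(c_ia R_a) and
#' the matching mass flux nu_in[i, a] = sigma(c_ia R_a) for every seeded
#' species and resource.
#'
#' @param state a [community_state()].
#' @param pool a [regional_pool()].
#' @param env an [environment_params()].
#' @return an object of class `flux_set` with `incoming` and `mass_in`
#'   filled; pass it through [growth_fluxes()] and [secretion_fluxes()] to
#'   complete it.
#' @export
input_fluxes <- function(state, pool, env) {
  check_state_dims(state, pool, env)
  R <- state$resources
  if (any(R < 0)) stop("negative resource concentration: integrator contract violated")
  cmat <- pool$consumer_matrix[state$species_index, , drop = FALSE]
  n <- nrow(cmat)
  x <- cmat * rep(R, each = n)
  nu_in <- sigma_response(x, env)
  incoming <- nu_in * rep(env$energy_density, each = n)
  structure(list(incoming = incoming, mass_in = nu_in,
                 growth = NULL, outgoing = NULL, mass_out = NULL),
            class = "flux_set")
}

#' Per-cell growth fluxes after leakage
#'
#' J_grow[i] = sum_a (1 - l_a) J_in[i, a]: the power retained by the cell
#' after a fraction l_a of each imported flux leaks back to the environment.
#' Because l_a is in `[0, 1]`, growth never exceeds total import (no
#' spontaneous generation of usable energy).
#'
#' @param fluxes a `flux_set` with `incoming` filled.
#' @param env an [environment_params()].
#' @return the `flux_set` with `growth` filled.
#' @export
growth_fluxes <- function(fluxes, env) {
  if (is.null(fluxes$incoming)) stop("incoming fluxes not filled")
  l <- env$leakage
  if (any(l < 0 | l > 1)) stop("leakage must lie in [0, 1]")
  fluxes$growth <- as.vector(fluxes$incoming %*% (1 - l))
  fluxes
}

#' Per-cell secretion fluxes
#'
#' The leaked energy l_a J_in[i, a] is partitioned over byproducts by the
#' metabolic matrix: J_out[i, b] = sum_a D_ba l_a J_in[i, a], with mass flux
#' nu_out[i, b] = J_out[i, b] / w_b. Column-stochasticity of D guarantees
#' sum_b J_out[i, b] = sum_a l_a J_in[i, a] (energy bookkeeping).
#'
#' @inheritParams growth_fluxes
#' @return the `flux_set` with `outgoing` and `mass_out` filled.
#' @export
secretion_fluxes <- function(fluxes, env) {
  if (is.null(fluxes$incoming)) stop("incoming fluxes not filled")
  n <- nrow(fluxes$incoming)
  leaked <- fluxes$incoming * rep(env$leakage, each = n)
  outgoing <- leaked %*% t(env$metabolic_matrix)
  fluxes$outgoing <- outgoing
  fluxes$mass_out <- outgoing / rep(env$energy_density, each = n)
  fluxes
}

#' Complete flux bookkeeping for a state
#'
#' @inheritParams input_fluxes
#' @return a `flux_set` with all five components filled.
#' @export
community_fluxes <- function(state, pool, env) {
  secretion_fluxes(growth_fluxes(input_fluxes(state, pool, env), env), env)
}

#' Time derivatives of the consumer-resource dynamics
#'
#' dN_i/dt = g_i N_i (J_grow[i] - m_i);
#' dR_a/dt = kappa_a - R_a / tau_R + sum_j N_j (nu_out[j, a] - nu_in[j, a]).
#' The function is pure: it evaluates the instantaneous rates and performs no
#' clipping (extinct species, N_i = 0, have dN_i/dt = 0 identically).
#'
#' @inheritParams input_fluxes
#' @return list with numeric vectors `dN` and `dR`.
#' @export
dynamics_rhs <- function(state, pool, env) {
  check_state_dims(state, pool, env)
  N <- state$abundances
  R <- state$resources
  cmat <- pool$consumer_matrix[state$species_index, , drop = FALSE]
  m <- pool$maintenance[state$species_index]
  g <- pool$growth_factor[state$species_index]
  rhs_core(N, R, cmat, m, g, env)
}

# aggregated evaluation shared by dynamics_rhs and the integrator: per-cell
# secretion matrices are never materialized, only the community totals
rhs_core <- function(N, R, cmat, m, g, env) {
  n <- length(N)
  w <- env$energy_density
  l <- env$leakage
  if (n == 0L) {
    return(list(dN = numeric(0),
                dR = env$supply_rate - R / env$dilution_time))
  }
  nu_in <- sigma_response(cmat * rep(R, each = n), env)   # n x M mass import
  j_in <- nu_in * rep(w, each = n)
  grow <- as.vector(j_in %*% (1 - l))
  dN <- g * N * (grow - m)
  tot_in <- as.vector(crossprod(nu_in, N))                # total mass uptake per resource
  leaked_energy <- l * w * tot_in
  tot_out <- as.vector(env$metabolic_matrix %*% leaked_energy) / w
  dR <- env$supply_rate - R / env$dilution_time + tot_out - tot_in
  list(dN = dN, dR = dR)
}
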
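#' Solver configuration for steady-state assembly
#'
#' The ODE system is integrated in blocks of `block_time` model time units
#' with a stiff-capable adaptive method; between blocks, species whose
#' abundance has fallen below `extinction_threshold` are set extinct and
#' removed from the active system. Integration stops when the per-capita
#' growth residual of every surviving species (|J_grow - m_i| / m_i) and the
#' relative resource drift both fall below `convergence_tol`, or when
#' `max_time` is exhausted.
#'
#' @param block_time model time per integration block.
#' @param max_time maximum total model time.
#' @param extinction_threshold abundance below which a species is declared
#'   extinct between blocks.
#' @param rel_tol,abs_tol integrator tolerances (deSolve `lsoda`).
#' @param convergence_tol steady-state residual tolerance.
#' @param init_abundance initial abundance of each seeded species.
#' @export
solver_config <- function(block_time = 500, max_time = 1e5,
                          extinction_threshold = 1e-6,
                          rel_tol = 1e-8, abs_tol = 1e-10,
                          convergence_tol = 1e-6,
                          init_abundance = 0.01) {
  cfg <- list(block_time = block_time, max_time = max_time,
              extinction_threshold = extinction_threshold,
              rel_tol = rel_tol, abs_tol = abs_tol,
              convergence_tol = convergence_tol,
              init_abundance = init_abundance)
  if (any(unlist(cfg) <= 0)) stop("all solver_config fields must be > 0")
  structure(cfg, class = "solver_config")
}

#' Integrate one community to its steady state
#'
#' Runs the consumer-resource dynamics from `initial` until the community
#' reaches a steady state (see [solver_config()] for the convergence and
#' extinction rules). Extinct species remain in the returned state with
#' abundance exactly 0; survivors satisfy |J_grow - m_i| <= tol * m_i.
#'
#' @param initial a [community_state()] (seeded species have N > 0).
#' @param pool a [regional_pool()].
#' @param env an [environment_params()].
#' @param cfg a [solver_config()].
#' @return an object of class `steady_state_result`: fields `state`,
#'   `survivors` (local indices with positive abundance), `converged`,
#'   `residuals` (growth and resource-drift residuals), `elapsed` model time,
#'   and `energy_balance_gap`, the relative violation of the steady-state
#'   energy conservation law sum(w kappa) = sum(w R)/tau_R + sum(N m).
#' @export
integrate_to_steady_state <- function(initial, pool, env,
                                      cfg = solver_config()) {
  check_state_dims(initial, pool, env)
  n_seeded <- length(initial$abundances)
  N_full <- pmax(initial$abundances, 0)
  R <- pmax(initial$resources, 0)
  active <- which(N_full > 0)

  elapsed <- 0
  converged <- FALSE
  res_growth <- NA_real_
  res_drift <- NA_real_
  tol <- cfg$convergence_tol

  repeat {
    cmat <- pool$consumer_matrix[initial$species_index[active], , drop = FALSE]
    m <- pool$maintenance[initial$species_index[active]]
    g <- pool$growth_factor[initial$species_index[active]]
    n <- length(active)

    ode_fn <- function(t, y, parms) {
      N <- pmax(y[seq_len(n)], 0)
      Rv <- pmax(y[n + seq_len(env$n_resources)], 0)
      d <- rhs_core(N, Rv, cmat, m, g, env)
      list(c(d$dN, d$dR))
    }
    y0 <- c(N_full[active], R)
    sol <- deSolve::ode(y = y0, times = c(0, cfg$block_time), func = ode_fn,
                        parms = NULL, method = "lsoda",
                        rtol = cfg$rel_tol, atol = cfg$abs_tol)
    yT <- sol[nrow(sol), -1]
    if (any(!is.finite(yT)))
      stop(sprintf(
        "non-finite state during integration at model time %g (n = %d active species)",
        elapsed + cfg$block_time, n))
    elapsed <- elapsed + cfg$block_time

    N_act <- pmax(yT[seq_len(n)], 0)
    R <- pmax(yT[n + seq_len(env$n_resources)], 0)
    N_act[N_act < cfg$extinction_threshold] <- 0
    N_full[active] <- N_act
    alive <- N_act > 0
    active <- active[alive]

    # convergence diagnostics on the thresholded state
    d <- rhs_core(N_full[active], R,
                  pool$consumer_matrix[initial$species_index[active], ,
                                       drop = FALSE],
                  pool$maintenance[initial$species_index[active]],
                  pool$growth_factor[initial$species_index[active]], env)
    if (length(active)) {
      mm <- pool$maintenance[initial$species_index[active]]
      nu <- sigma_response(
        pool$consumer_matrix[initial$species_index[active], , drop = FALSE] *
          rep(R, each = length(active)), env)
      grow <- as.vector((nu * rep(env$energy_density, each = length(active))) %*%
                          (1 - env$leakage))
      res_growth <- max(abs(grow - mm) / mm)
    } else res_growth <- 0
    eps_R <- 1e-8 + 1e-6 * max(R)
    res_drift <- max(abs(d$dR) / (R + eps_R))
    if (res_growth <= tol && res_drift <= tol) { converged <- TRUE; break }
    if (elapsed >= cfg$max_time) break
  }

  final <- community_state(N_full, R, initial$species_index)
  w <- env$energy_density
  supplied <- sum(w * env$supply_rate)
  drained <- sum(w * R) / env$dilution_time +
    sum(N_full * pool$maintenance[initial$species_index])
  structure(list(
    state = final,
    survivors = which(N_full > 0),
    converged = converged,
    residuals = c(growth = res_growth, resource_drift = res_drift),
    elapsed = elapsed,
    energy_balance_gap = abs(supplied - drained) / supplied,
    n_seeded = n_seeded
  ), class = "steady_state_result")
}

#' @export
print.steady_state_result <- function(x, ...) {
  cat(sprintf(
    "<steady_state_result> %d survivors of %d seeded; converged = %s (t = %g)\n",
    length(x$survivors), x$n_seeded, x$converged, x$elapsed))
  cat(sprintf("  residuals: growth %.2e, resource drift %.2e; energy gap %.2e\n",
              x$residuals[["growth"]], x$residuals[["resource_drift"]],
              x$energy_balance_gap))
  invisible(x)
}

#' Default initial state for a colonization subset
#'
#' Fresh chemostat plus inoculum: every seeded species starts at
#' `init_abundance`, the supplied resource at its species-free fixed point
#' kappa_a * tau_R, and all byproducts at zero.
#'
#' @param subset integer indices into the pool.
#' @param env an [environment_params()].
#' @param init_abundance starting abundance per seeded species.
#' @export
initial_state <- function(subset, env, init_abundance = 0.01) {
  community_state(rep(init_abundance, length(subset)),
                  env$supply_rate * env$dilution_time,
                  species_index = subset)
}

#' Assemble an ensemble of communities
#'
#' Integrates one community per colonization subset. The dynamics are
#' deterministic given the initial state, so results are identical however
#' the ensemble is ordered or parallelized. Integration failures are caught
#' and flagged rather than aborting the ensemble.
#'
#' @param pool a [regional_pool()].
#' @param env an [environment_params()].
#' @param subsets list of species-index vectors (see
#'   [draw_community_subsets()]).
#' @param cfg a [solver_config()].
#' @return list of `steady_state_result` (failed runs carry class
#'   `assembly_failure` with the error message).
#' @export
assemble_ensemble <- function(pool, env, subsets, cfg = solver_config()) {
  lapply(subsets, function(subset) {
    st <- initial_state(subset, env, cfg$init_abundance)
    tryCatch(integrate_to_steady_state(st, pool, env, cfg),
             error = function(e) structure(list(message = conditionMessage(e),
                                                subset = subset),
                                           class = "assembly_failure"))
  })
}

#' Pool-indexed abundance matrix of an ensemble
#'
#' @param results list of `steady_state_result` from one pool.
#' @param pool the `regional_pool` the subsets index into.
#' @return communities x species abundance matrix (absent species are 0).
#' @export
abundance_matrix <- function(results, pool) {
  ok <- !vapply(results, inherits, logical(1), "assembly_failure")
  A <- matrix(0, sum(ok), pool$n_species,
              dimnames = list(NULL, species_labels(pool$n_species)))
  row <- 0L
  for (r in results[ok]) {
    row <- row + 1L
    A[row, r$state$species_index] <- r$state$abundances
  }
  A
}
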
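#' Community-scale energy flux network
#'
#' The steady-state energy flux from resource a into resource b, summed over
#' all consumers, is J_ba = D_ba l_a sum_i N_i w_a sigma(c_ia R_a). Edges
#' below `prune_fraction` of the largest entry are pruned (the convention
#' used when drawing these networks). Topology is analyzed on the pruned
#' graph with self-loops removed: `is_dag` reports whether the distinct
#' resources can be put in a definite order of energy succession, and
#' `reachable_nodes` lists the resources connected to the external supply
#' (resource 1) by pruned edges.
#'
#' @param steady a `steady_state_result`.
#' @param pool,env the pool and environment of the run.
#' @param prune_fraction edge-display threshold relative to the maximum flux.
#' @return object of class `flux_network`: `flux_matrix` (M x M), `edges`
#'   (data.frame source, target, flux over pruned edges), `is_dag`,
#'   `reachable_nodes`, `source_index = 1`, `prune_fraction`.
#' @export
flux_network <- function(steady, pool, env, prune_fraction = 0.01) {
  if (!isTRUE(steady$converged))
    warning("flux network computed from a non-converged state")
  state <- steady$state
  n <- length(state$abundances)
  nu_in <- sigma_response(
    pool$consumer_matrix[state$species_index, , drop = FALSE] *
      rep(state$resources, each = n), env)
  tot <- as.vector(crossprod(nu_in, state$abundances))  # sum_i N_i sigma(c_ia R_a)
  col_flux <- env$leakage * env$energy_density * tot
  J <- env$metabolic_matrix * rep(col_flux, each = env$n_resources)
  maxJ <- max(J)
  adj <- if (maxJ > 0) t(J) >= prune_fraction * maxJ else
    matrix(FALSE, env$n_resources, env$n_resources)
  # adj[a, b]: pruned edge a -> b (flux J[b, a]); self-loops dropped for topology
  idx <- which(adj, arr.ind = TRUE)
  edges <- data.frame(source = idx[, 1], target = idx[, 2],
                      flux = J[cbind(idx[, 2], idx[, 1])])
  adj_topo <- adj
  diag(adj_topo) <- FALSE
  structure(list(flux_matrix = J,
                 edges = edges,
                 is_dag = is_dag_adjacency(adj_topo),
                 reachable_nodes = reachable_from(adj, 1L),
                 source_index = 1L,
                 prune_fraction = prune_fraction,
                 converged = isTRUE(steady$converged)),
            class = "flux_network")
}

# Kahn's algorithm on a logical adjacency matrix (adj[a, b] = edge a -> b)
is_dag_adjacency <- function(adj) {
  indeg <- colSums(adj)
  alive <- rep(TRUE, nrow(adj))
  repeat {
    zero <- which(alive & indeg == 0)
    if (!length(zero)) break
    for (v in zero) {
      alive[v] <- FALSE
      out <- which(adj[v, ])
      indeg[out] <- indeg[out] - 1L
    }
  }
  !any(alive)
}

# directed reachability (BFS) from `from`, including the start node
reachable_from <- function(adj, from) {
  seen <- logical(nrow(adj))
  seen[from] <- TRUE
  frontier <- from
  while (length(frontier)) {
    nxt <- unique(unlist(lapply(frontier, function(v) which(adj[v, ]))))
    nxt <- nxt[!seen[nxt]]
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  which(seen)
}

#' @export
print.flux_network <- function(x, ...) {
  cat(sprintf("<flux_network> M = %d, %d pruned edges (>= %.3g of max), %s\n",
              nrow(x$flux_matrix), nrow(x$edges), x$prune_fraction,
              if (x$is_dag) "acyclic" else "contains cycles"))
  invisible(x)
}

#' Simpson diversity of incoming energy fluxes
#'
#' For each survivor, M_eff = 1 / sum_a (J_in[i, a] / J_in[i])^2 — the
#' inverse participation ratio of its incoming flux vector, i.e. the
#' effective number of resources the species lives on. Bounded by 1 (pure
#' specialist) and M (flux spread evenly over all resources).
#'
#' @inheritParams flux_network
#' @return named numeric vector, one entry per survivor.
#' @export
effective_resources <- function(steady, pool, env) {
  surv <- steady$survivors
  if (!length(surv)) return(numeric(0))
  st <- community_state(steady$state$abundances[surv], steady$state$resources,
                        steady$state$species_index[surv])
  jin <- input_fluxes(st, pool, env)$incoming
  tot <- rowSums(jin)
  if (any(tot <= 0))
    stop("survivor with zero total influx: inconsistent steady state")
  meff <- 1 / rowSums((jin / tot)^2)
  names(meff) <- species_labels(pool$n_species)[st$species_index]
  meff
}

#' Per-survivor steady-state energy budgets
#'
#' The retained fluxes (1 - l_a) J_in[i, a] of each survivor, split into the
#' share drawn from the externally supplied resource versus metabolic
#' byproducts. At steady state each row sums to the species' maintenance
#' cost m_i.
#'
#' @inheritParams flux_network
#' @return list with `retained` (survivors x M matrix), `total` (row sums),
#'   `external_share` (fraction from the supplied resource) and
#'   `maintenance` (the m_i, for comparison).
#' @export
energy_budget <- function(steady, pool, env) {
  surv <- steady$survivors
  st <- community_state(steady$state$abundances[surv], steady$state$resources,
                        steady$state$species_index[surv])
  jin <- input_fluxes(st, pool, env)$incoming
  retained <- jin * rep(1 - env$leakage, each = nrow(jin))
  tot <- rowSums(retained)
  list(retained = retained,
       total = tot,
       external_share = if (length(tot)) retained[, 1] / tot else numeric(0),
       maintenance = pool$maintenance[st$species_index])
}

#' Finite-difference resource susceptibilities
#'
#' Measures the response of each steady-state concentration to a small
#' increase of its own external supply rate: for every resource a != the
#' supplied one, kappa_a is raised by `delta_kappa`, the community is
#' re-equilibrated warm-starting from the baseline state (no re-invasion
#' from the regional pool; the seeded set is fixed, and further extinctions
#' are allowed), and dR_a/dkappa_a is estimated as the concentration change
#' over `delta_kappa`. In a species-free chemostat every susceptibility
#' equals tau_R; values far below tau_R indicate resource pinning by the
#' community.
#'
#' @inheritParams flux_network
#' @param cfg a [solver_config()] used for re-equilibration.
#' @param delta_kappa supply perturbation (units of mean maintenance cost).
#' @param resources which resource indices to perturb (default all but the
#'   supplied resource 1).
#' @return named numeric vector of susceptibilities (NA where the perturbed
#'   system failed to re-converge).
#' @export
resource_susceptibilities <- function(steady, pool, env,
                                      cfg = solver_config(),
                                      delta_kappa = 0.1,
                                      resources = NULL) {
  if (is.null(resources)) resources <- setdiff(seq_len(env$n_resources), 1L)
  base_R <- steady$state$resources
  surv <- steady$survivors
  base_state <- community_state(steady$state$abundances[surv], base_R,
                                steady$state$species_index[surv])
  out <- rep(NA_real_, length(resources))
  names(out) <- resource_labels(env$n_resources)[resources]
  for (k in seq_along(resources)) {
    a <- resources[k]
    env2 <- env
    env2$supply_rate[a] <- env2$supply_rate[a] + delta_kappa
    pert <- tryCatch(integrate_to_steady_state(base_state, pool, env2, cfg),
                     error = function(e) NULL)
    if (!is.null(pert) && pert$converged)
      out[k] <- (pert$state$resources[a] - base_R[a]) / delta_kappa
  }
  out
}

#' Steady-state richness
#'
#' Number of species with positive abundance at steady state.
#' @param steady a `steady_state_result`.
#' @export
richness <- function(steady) length(steady$survivors)

#' Rank-abundance curve
#'
#' Relative abundances of the survivors in decreasing order, optionally
#' truncated below a relative-abundance floor (a presentation convention;
#' truncation never affects the survivor set itself).
#'
#' @param steady a `steady_state_result`.
#' @param truncate_at drop entries with relative abundance <= this value.
#' @export
rank_abundance <- function(steady, truncate_at = 0) {
  N <- steady$state$abundances[steady$survivors]
  if (!length(N)) return(numeric(0))
  rel <- sort(N / sum(N), decreasing = TRUE)
  rel[rel > truncate_at]
}

#' Number of resources present at non-negligible levels
#'
#' @param steady a `steady_state_result`.
#' @param env the environment (sets the default threshold).
#' @param threshold concentration floor; default `1e-4` of the supplied
#'   resource's species-free level kappa_0 tau_R.
#' @export
available_resources <- function(steady, env, threshold = NULL) {
  if (is.null(threshold))
    threshold <- 1e-4 * max(env$supply_rate) * env$dilution_time
  sum(steady$state$resources > threshold)
}

#' Maintenance cost versus steady-state abundance
#'
#' Long-format diagnostic table pairing every seeded species' maintenance
#' cost with its final abundance, across an ensemble.
#'
#' @param results list of `steady_state_result`.
#' @param pool the shared `regional_pool`.
#' @return data.frame with columns community, species, maintenance,
#'   abundance, survived.
#' @export
cost_abundance_relation <- function(results, pool) {
  ok <- which(!vapply(results, inherits, logical(1), "assembly_failure"))
  do.call(rbind, lapply(ok, function(i) {
    r <- results[[i]]
    data.frame(community = i,
               species = r$state$species_index,
               maintenance = pool$maintenance[r$state$species_index],
               abundance = r$state$abundances,
               survived = r$state$abundances > 0)
  }))
}
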
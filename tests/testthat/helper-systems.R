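# small reusable systems and independent oracles for the test suite

# a tiny random consumer-resource system (fast to integrate)
tiny_system <- function(M = 8, S = 12, w0k0 = 50, leakage = 0.5, seed = 1) {
  spec <- sampling_spec(n_species = S, n_resources = M,
                        mean_preferred = max(2, round(0.25 * M)))
  pool <- sample_pool(spec, seed = seed)
  D <- sample_metabolic_matrix(spec, seed = seed)
  env <- chemostat_environment(D, w0k0, leakage)
  list(spec = spec, pool = pool, env = env)
}

# brute-force cycle detection by DFS with path marking (oracle for is_dag)
brute_force_has_cycle <- function(adj) {
  n <- nrow(adj)
  color <- integer(n) # 0 white, 1 on path, 2 done
  found <- FALSE
  visit <- function(v) {
    if (found) return()
    color[v] <<- 1L
    for (u in which(adj[v, ])) {
      if (color[u] == 1L) { found <<- TRUE; return() }
      if (color[u] == 0L) visit(u)
    }
    color[v] <<- 2L
  }
  for (v in seq_len(n)) if (color[v] == 0L) visit(v)
  found
}

# explicit per-species flux bookkeeping by loops (oracle for dynamics_rhs)
loop_rhs <- function(state, pool, env) {
  N <- state$abundances; R <- state$resources
  M <- env$n_resources
  cmat <- pool$consumer_matrix[state$species_index, , drop = FALSE]
  m <- pool$maintenance[state$species_index]
  g <- pool$growth_factor[state$species_index]
  sig <- function(x) if (env$response == "type_I") x else
    env$sigma_max * x / (env$sigma_max + x)
  dN <- numeric(length(N)); dR <- numeric(M)
  for (a in seq_len(M)) dR[a] <- env$supply_rate[a] - R[a] / env$dilution_time
  for (i in seq_along(N)) {
    grow <- 0
    nu_out <- numeric(M)
    for (a in seq_len(M)) {
      nu_in <- sig(cmat[i, a] * R[a])
      jin <- env$energy_density[a] * nu_in
      grow <- grow + (1 - env$leakage[a]) * jin
      for (b in seq_len(M))
        nu_out[b] <- nu_out[b] +
          env$metabolic_matrix[b, a] * env$leakage[a] * jin /
            env$energy_density[b]
      dR[a] <- dR[a] - N[i] * nu_in
    }
    dR <- dR + N[i] * nu_out
    dN[i] <- g[i] * N[i] * (grow - m[i])
  }
  list(dN = dN, dR = dR)
}

# moment-form overlap of a binary spec, re-derived independently
binary_overlap_moment_test <- function(p, h, b) {
  (p * h + (1 - p) * b)^2 / (p * h^2 + (1 - p) * b^2)
}

# apply one resource permutation to every resource-indexed object
permute_resources <- function(pool, env, state, perm) {
  pool2 <- pool
  pool2$consumer_matrix <- pool$consumer_matrix[, perm, drop = FALSE]
  env2 <- env
  env2$metabolic_matrix <- env$metabolic_matrix[perm, perm, drop = FALSE]
  env2$energy_density <- env$energy_density[perm]
  env2$leakage <- env$leakage[perm]
  env2$supply_rate <- env$supply_rate[perm]
  state2 <- community_state(state$abundances, state$resources[perm],
                            state$species_index)
  list(pool = pool2, env = env2, state = state2)
}
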
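#' Write a regional pool to a directory
#'
#' Writes `c.csv` (consumer matrix, species rows `S0..`, resource columns
#' `R0..`), `costs.csv` (species, maintenance, growth_factor) and
#' `metadata.json` (sampling spec and seed). Numerics are written with full
#' repr precision so a read-back reproduces the pool bit-exactly.
#'
#' @param pool a [regional_pool()].
#' @param dir output directory (created if needed).
#' @export
write_pool <- function(pool, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix_csv(pool$consumer_matrix, file.path(dir, "c.csv"))
  utils::write.csv(
    data.frame(species = rownames(pool$consumer_matrix),
               maintenance = format_repr(pool$maintenance),
               growth_factor = format_repr(pool$growth_factor)),
    file.path(dir, "costs.csv"), row.names = FALSE, quote = FALSE)
  meta <- list(n_species = pool$n_species, n_resources = pool$n_resources,
               seed = pool$seed, spec = unclass(pool$spec))
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a regional pool written by [write_pool()]
#' @param dir directory containing `c.csv`, `costs.csv`, `metadata.json`.
#' @export
read_pool <- function(dir) {
  cmat <- read_matrix_csv(file.path(dir, "c.csv"))
  costs <- utils::read.csv(file.path(dir, "costs.csv"))
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  spec <- if (!is.null(meta$spec))
    do.call(sampling_spec, meta$spec[setdiff(names(meta$spec), NULL)])
  regional_pool(cmat, costs$maintenance, costs$growth_factor,
                spec = spec, seed = meta$seed)
}

#' Write environment parameters to a directory
#'
#' Writes `D.csv` (metabolic matrix) and `env.json` (all scalar/vector
#' parameters).
#' @param env an [environment_params()].
#' @param dir output directory.
#' @export
write_environment <- function(env, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix_csv(env$metabolic_matrix, file.path(dir, "D.csv"))
  hdr <- list(n_resources = env$n_resources,
              energy_density = env$energy_density,
              leakage = env$leakage, supply_rate = env$supply_rate,
              dilution_time = env$dilution_time, response = env$response,
              sigma_max = env$sigma_max)
  jsonlite::write_json(hdr, file.path(dir, "env.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read environment parameters written by [write_environment()]
#' @param dir directory containing `D.csv` and `env.json`.
#' @export
read_environment <- function(dir) {
  D <- read_matrix_csv(file.path(dir, "D.csv"))
  h <- jsonlite::read_json(file.path(dir, "env.json"), simplifyVector = TRUE)
  environment_params(D, energy_density = h$energy_density,
                     leakage = h$leakage, supply_rate = h$supply_rate,
                     dilution_time = h$dilution_time, response = h$response,
                     sigma_max = h$sigma_max)
}

# full-precision (repr round-trip) CSV matrix writers
format_repr <- function(x) formatC(x, digits = 17, format = "g")

write_matrix_csv <- function(m, path) {
  df <- as.data.frame(apply(m, 2, format_repr), check.names = FALSE,
                      optional = TRUE)
  if (nrow(m) == 1L) df <- as.data.frame(as.list(df), check.names = FALSE)
  df <- cbind(id = rownames(m), df)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

read_matrix_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  m
}

#' Load and validate a JSON run configuration
#'
#' The configuration may contain a `seed` plus optional `sampling`,
#' `solver` and `environment` blocks; unknown keys at either level are
#' rejected with an error naming the key. Missing fields take the package
#' defaults ([sampling_spec()], [solver_config()]).
#'
#' `environment` accepts `w0k0`, `leakage`, `dilution_time`, `response`,
#' `sigma_max` (the metabolic matrix itself is sampled, not configured).
#'
#' @param path path to a JSON file.
#' @return list with `seed`, `sampling` (a `sampling_spec`), `solver`
#'   (a `solver_config`) and `environment` (a plain list of chemostat
#'   settings).
#' @export
load_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known_top <- c("seed", "sampling", "solver", "environment")
  bad <- setdiff(names(raw), known_top)
  if (length(bad))
    stop(sprintf("unknown configuration key(s): %s", paste(bad, collapse = ", ")))
  check_block <- function(block, allowed, label) {
    extra <- setdiff(names(block), allowed)
    if (length(extra))
      stop(sprintf("unknown %s key(s): %s", label, paste(extra, collapse = ", ")))
    block
  }
  sampling_args <- check_block(raw$sampling %||% list(),
                               names(formals(sampling_spec)), "sampling")
  solver_args <- check_block(raw$solver %||% list(),
                             names(formals(solver_config)), "solver")
  env_allowed <- c("w0k0", "leakage", "dilution_time", "response", "sigma_max")
  env_args <- check_block(raw$environment %||% list(), env_allowed,
                          "environment")
  if (!is.null(env_args$leakage) &&
      any(env_args$leakage < 0 | env_args$leakage > 1))
    stop("invalid environment value: leakage must lie in [0, 1]")
  list(seed = raw$seed %||% 1L,
       sampling = do.call(sampling_spec, sampling_args),
       solver = do.call(solver_config, solver_args),
       environment = utils::modifyList(
         list(w0k0 = 1000, leakage = 0.9, dilution_time = 1,
              response = "type_I", sigma_max = 10), env_args))
}

#' Normalized list form of a configuration (for round-trip checks)
#' @param cfg result of [load_config()].
#' @export
dump_config <- function(cfg) {
  list(seed = cfg$seed, sampling = unclass(cfg$sampling),
       solver = unclass(cfg$solver), environment = cfg$environment)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Small self-contained reference systems
#'
#' * `empty_chemostat`: M = 3 resources, no living species; the steady state
#'   is R_a = kappa_a tau_R and every resource susceptibility equals tau_R.
#' * `single_species_closed_form`: M = 1, l = 0.5, D = 1, c = w = g = tau_R =
#'   m = 1, kappa = 10; the algebraic fixed point is R = m/((1-l)c) = 2 and
#'   N = (kappa - R/tau_R)/ (m - l R c ... ) — resource balance gives N = 8.
#' * `triangle_nested_matrix`: perfectly nested 3 x 3 binary matrix
#'   (NODF = 100).
#' * `three_cycle_network`: a 3-resource flux matrix whose pruned edges form
#'   the cycle 1 -> 2 -> 3 -> 1.
#'
#' @param name fixture name.
#' @return list of components appropriate to the fixture.
#' @export
make_fixture <- function(name = c("empty_chemostat",
                                  "single_species_closed_form",
                                  "triangle_nested_matrix",
                                  "three_cycle_network")) {
  name <- match.arg(name)
  switch(name,
    empty_chemostat = {
      D <- matrix(1 / 3, 3, 3)
      env <- environment_params(D, leakage = 0.5,
                                supply_rate = c(10, 2, 0), dilution_time = 1)
      pool <- regional_pool(matrix(1, 1, 3), maintenance = 1)
      state <- community_state(0, rep(0, 3), species_index = 1L)
      list(pool = pool, env = env, state = state,
           expected_resources = env$supply_rate * env$dilution_time)
    },
    single_species_closed_form = {
      env <- environment_params(matrix(1, 1, 1), leakage = 0.5,
                                supply_rate = 10, dilution_time = 1)
      pool <- regional_pool(matrix(1, 1, 1), maintenance = 1)
      state <- community_state(0.01, env$supply_rate, species_index = 1L)
      list(pool = pool, env = env, state = state,
           expected_R = 2, expected_N = 8)
    },
    triangle_nested_matrix =
      matrix(c(1, 1, 1,
               1, 1, 0,
               1, 0, 0), 3, 3, byrow = TRUE),
    three_cycle_network = {
      J <- matrix(0, 3, 3)
      J[2, 1] <- 1; J[3, 2] <- 1; J[1, 3] <- 1  # J[b, a]: flux a -> b
      J
    })
}
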
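#' Abiotic environment of the chemostat
#'
#' Bundles the energy densities w_a, leakage fractions l_a, the
#' column-stochastic metabolic matrix D_ba, external supply rates kappa_a,
#' the dilution timescale tau_R and the functional-response choice. With a
#' Type-I response the uptake of resource a by species i is c_ia * R_a; the
#' Monod option saturates at `sigma_max` via sigma(x) = sigma_max x /
#' (sigma_max + x), which reduces to Type-I for small x.
#'
#' @param metabolic_matrix M x M column-stochastic matrix D_ba (fraction of
#'   energy leaked from resource a re-released as resource b).
#' @param energy_density energy per unit mass of each resource (scalar or
#'   length-M vector, default 1).
#' @param leakage leaked fraction l_a in `[0, 1]` (scalar or vector).
#' @param supply_rate external mass supply kappa_a (length M).
#' @param dilution_time chemostat dilution timescale tau_R.
#' @param response `"type_I"` (linear) or `"monod"`.
#' @param sigma_max saturation scale for the Monod response.
#' @return an object of class `environment_params`.
#' @export
environment_params <- function(metabolic_matrix, energy_density = 1,
                               leakage, supply_rate, dilution_time = 1,
                               response = c("type_I", "monod"),
                               sigma_max = 10) {
  response <- match.arg(response)
  D <- as.matrix(metabolic_matrix)
  M <- nrow(D)
  if (ncol(D) != M) stop("metabolic_matrix must be square")
  colsum_err <- max(abs(colSums(D) - 1))
  if (colsum_err > 1e-12)
    stop(sprintf("metabolic_matrix columns must sum to 1 (max error %.3g)",
                 colsum_err))
  if (any(D < 0)) stop("metabolic_matrix entries must be >= 0")
  w <- rep_len(as.numeric(energy_density), M)
  l <- rep_len(as.numeric(leakage), M)
  kappa <- rep_len(as.numeric(supply_rate), M)
  if (any(w <= 0)) stop("energy_density must be > 0")
  if (any(l < 0 | l > 1)) stop("leakage must lie in [0, 1]")
  if (any(kappa < 0)) stop("supply_rate must be >= 0")
  if (dilution_time <= 0) stop("dilution_time must be > 0")
  if (response == "monod" && sigma_max <= 0)
    stop("monod response requires sigma_max > 0")
  if (is.null(rownames(D))) dimnames(D) <- list(resource_labels(M),
                                                resource_labels(M))
  structure(list(
    n_resources = M,
    energy_density = w,
    leakage = l,
    metabolic_matrix = D,
    supply_rate = kappa,
    dilution_time = dilution_time,
    response = response,
    sigma_max = sigma_max
  ), class = "environment_params")
}

#' Chemostat environment supplied with a single external resource
#'
#' Convenience constructor for the standard study setting: all energy
#' densities equal to 1, uniform leakage, and an external energy flux
#' w_0 kappa_0 delivered entirely through resource 0 (the first resource).
#'
#' @param metabolic_matrix M x M column-stochastic matrix.
#' @param w0k0 externally supplied energy flux w_0 * kappa_0.
#' @param leakage uniform leakage fraction l.
#' @param dilution_time tau_R (default 1).
#' @inheritParams environment_params
#' @export
chemostat_environment <- function(metabolic_matrix, w0k0, leakage,
                                  dilution_time = 1,
                                  response = "type_I", sigma_max = 10) {
  M <- nrow(as.matrix(metabolic_matrix))
  kappa <- c(w0k0, rep(0, M - 1))  # w_0 = 1, so kappa_0 = w0k0
  environment_params(metabolic_matrix, energy_density = 1, leakage = leakage,
                     supply_rate = kappa, dilution_time = dilution_time,
                     response = response, sigma_max = sigma_max)
}

#' @export
print.environment_params <- function(x, ...) {
  cat(sprintf(
    "<environment_params> M = %d, response = %s, tau_R = %g\n",
    x$n_resources, x$response, x$dilution_time))
  cat(sprintf("  total supplied energy flux sum(w*kappa) = %g, mean leakage = %g\n",
              sum(x$energy_density * x$supply_rate), mean(x$leakage)))
  invisible(x)
}

#' Instantaneous community state
#'
#' @param abundances non-negative population sizes N_i of the seeded species.
#' @param resources non-negative resource concentrations R_a (length M).
#' @param species_index mapping from local rows to regional-pool rows.
#' @export
community_state <- function(abundances, resources,
                            species_index = seq_along(abundances)) {
  if (any(abundances < 0)) stop("abundances must be >= 0")
  if (any(resources < 0)) stop("resources must be >= 0")
  if (length(species_index) != length(abundances))
    stop("species_index must match abundances in length")
  structure(list(
    abundances = as.numeric(abundances),
    resources = as.numeric(resources),
    species_index = as.integer(species_index)
  ), class = "community_state")
}

check_state_dims <- function(state, pool, env) {
  if (length(state$resources) != env$n_resources)
    stop("state/environment resource dimension mismatch")
  if (ncol(pool$consumer_matrix) != env$n_resources)
    stop("pool/environment resource dimension mismatch")
  if (any(state$species_index < 1L | state$species_index > pool$n_species))
    stop("species_index out of range for this pool")
  invisible(TRUE)
}
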
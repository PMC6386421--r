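#' The three reference parameter sets
#'
#' Named (w0k0, leakage) combinations used throughout the analyses:
#' `syntrophy_limited` (1000, 0.1) and `energy_limited` (28, 0.6) both lie in
#' the resource-limited regime; `similarity_limited` (1000, 0.9) is the
#' diverse regime.
#' @export
reference_examples <- function() {
  list(syntrophy_limited  = list(w0k0 = 1000, leakage = 0.1, regime = "resource_limited"),
       energy_limited     = list(w0k0 = 28,   leakage = 0.6, regime = "resource_limited"),
       similarity_limited = list(w0k0 = 1000, leakage = 0.9, regime = "diverse"))
}

#' Configuration of a phase-diagram sweep
#'
#' Default grid: 10 log-spaced supplied energy fluxes from 10 to 1000 by 10
#' linearly spaced leakage fractions from 0.05 to 0.95, with the three
#' reference examples appended if the grid does not contain them.
#'
#' @param w0k0_values supplied energy fluxes.
#' @param leakage_values leakage fractions.
#' @param pools_per_point regional pools sampled per grid point.
#' @param communities_per_pool colonization subsets per pool.
#' @param subset_size species seeded per community.
#' @param spec a [sampling_spec()].
#' @param solver a [solver_config()].
#' @param seed master seed.
#' @param include_examples append the reference examples to the grid.
#' @export
sweep_config <- function(w0k0_values = 10^seq(1, 3, length.out = 10),
                         leakage_values = seq(0.05, 0.95, length.out = 10),
                         pools_per_point = 1,
                         communities_per_pool = 10,
                         subset_size = 100,
                         spec = sampling_spec(),
                         solver = solver_config(),
                         seed = 1,
                         include_examples = TRUE) {
  grid <- expand.grid(w0k0 = w0k0_values, leakage = leakage_values,
                      KEEP.OUT.ATTRS = FALSE)
  if (include_examples) {
    ex <- do.call(rbind, lapply(reference_examples(), function(e)
      data.frame(w0k0 = e$w0k0, leakage = e$leakage)))
    for (i in seq_len(nrow(ex)))
      if (!any(abs(grid$w0k0 - ex$w0k0[i]) < 1e-9 &
               abs(grid$leakage - ex$leakage[i]) < 1e-9))
        grid <- rbind(grid, ex[i, ])
  }
  if (!nrow(grid)) stop("empty sweep grid")
  structure(list(grid = grid, pools_per_point = pools_per_point,
                 communities_per_pool = communities_per_pool,
                 subset_size = subset_size, spec = spec, solver = solver,
                 seed = seed),
            class = "sweep_config")
}

# deterministic sub-seed table derived from a master seed
derive_seeds <- function(master, n) {
  set.seed(master)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Run a richness phase diagram over supplied energy and leakage
#'
#' Samples `pools_per_point` replicate regional pools (consumer matrix,
#' costs, and a metabolic matrix each) once, and assembles every pool at
#' every grid point: the same species pool experiences all (w0k0, leakage)
#' combinations, so the resulting communities share a species universe and
#' can be pooled into a single presence/absence matrix for nestedness and
#' beta-diversity analysis. Per grid point and pool, `communities_per_pool`
#' random colonization subsets are integrated to steady state. Failed
#' communities are recorded with `converged = NA`, never dropped silently.
#'
#' @param cfg a [sweep_config()].
#' @return object of class `phase_diagram`: `table` (one row per community:
#'   w0k0, leakage, pool, community, richness, converged, energy_gap,
#'   result_key), `results` (named list of `steady_state_result`, keyed by
#'   `result_key`) and `pools` (the replicate regional pools).
#' @export
run_phase_diagram <- function(cfg) {
  grid <- cfg$grid
  n_pools <- cfg$pools_per_point
  seeds <- derive_seeds(cfg$seed, n_pools + nrow(grid) * n_pools)
  pools <- lapply(seq_len(n_pools), function(p)
    sample_pool(cfg$spec, seed = seeds[p]))
  Ds <- lapply(seq_len(n_pools), function(p)
    sample_metabolic_matrix(cfg$spec, seed = seeds[p]))
  rows <- list(); results <- list()
  draw <- n_pools
  for (gi in seq_len(nrow(grid))) {
    for (p in seq_len(n_pools)) {
      draw <- draw + 1L
      pool <- pools[[p]]
      env <- chemostat_environment(Ds[[p]], grid$w0k0[gi], grid$leakage[gi])
      subsets <- draw_community_subsets(pool, cfg$communities_per_pool,
                                        cfg$subset_size,
                                        seed = seeds[draw])
      res <- assemble_ensemble(pool, env, subsets, cfg$solver)
      for (k in seq_along(res)) {
        key <- sprintf("g%02d_p%02d_c%02d", gi, p, k)
        results[[key]] <- res[[k]]
        failed <- inherits(res[[k]], "assembly_failure")
        rows[[length(rows) + 1L]] <- data.frame(
          w0k0 = grid$w0k0[gi], leakage = grid$leakage[gi],
          pool = p, community = k,
          richness = if (failed) NA_integer_ else richness(res[[k]]),
          converged = if (failed) NA else res[[k]]$converged,
          energy_gap = if (failed) NA_real_ else res[[k]]$energy_balance_gap,
          result_key = key)
      }
    }
  }
  structure(list(table = do.call(rbind, rows), results = results,
                 pools = pools, config = cfg),
            class = "phase_diagram")
}

#' Presence/absence matrix of a whole phase-diagram ensemble
#'
#' Pools every community assembled from one replicate pool across all grid
#' points into a single species x communities presence matrix.
#'
#' @param pd a `phase_diagram`.
#' @param pool_index which replicate pool to extract.
#' @param abundance_threshold relative-abundance cutoff for presence.
#' @export
phase_diagram_presence <- function(pd, pool_index = 1,
                                   abundance_threshold = 0) {
  keys <- pd$table$result_key[pd$table$pool == pool_index &
                                !is.na(pd$table$richness)]
  presence_absence(pd$results[keys], abundance_threshold,
                   pool = pd$pools[[pool_index]])
}

#' Richness versus mean niche overlap
#'
#' For each reference parameter set and each target overlap, tunes the binary
#' sampling scheme to that overlap ([spec_for_target_overlap()]), samples
#' fresh pools and metabolic matrices, assembles communities, and fits an
#' ordinary least-squares regression of richness on overlap per parameter
#' set.
#'
#' @param overlap_values target mean niche overlaps.
#' @param examples named list like [reference_examples()].
#' @param spec_base base binary [sampling_spec()].
#' @param pools_per_point,communities_per_pool,subset_size ensemble sizes.
#' @param solver a [solver_config()].
#' @param seed master seed.
#' @return object of class `overlap_sweep`: `table` (example, regime,
#'   overlap_target, overlap_realized, pool, community, richness) and `fits`
#'   (per-example data.frame with slope, intercept, n; slope is NA and
#'   `degenerate = TRUE` with fewer than 2 distinct overlap values).
#' @export
run_overlap_sweep <- function(overlap_values,
                              examples = reference_examples(),
                              spec_base = sampling_spec(),
                              pools_per_point = 10,
                              communities_per_pool = 10,
                              subset_size = 100,
                              solver = solver_config(),
                              seed = 1) {
  specs <- list()
  for (ov in overlap_values) {
    sp <- tryCatch(spec_for_target_overlap(ov, spec_base),
                   error = function(e) {
                     warning(sprintf("overlap %.3g unreachable: %s", ov,
                                     conditionMessage(e)))
                     NULL
                   })
    if (!is.null(sp)) specs[[length(specs) + 1L]] <- list(target = ov, spec = sp)
  }
  n_draws <- length(specs) * pools_per_point
  seeds <- derive_seeds(seed, 2L * max(n_draws, 1L))
  rows <- list()
  for (ei in seq_along(examples)) {
    ex <- examples[[ei]]
    draw <- 0L
    for (sv in specs) {
      for (p in seq_len(pools_per_point)) {
        draw <- draw + 1L
        pool <- sample_pool(sv$spec, seed = seeds[draw])
        D <- sample_metabolic_matrix(sv$spec, seed = seeds[draw])
        env <- chemostat_environment(D, ex$w0k0, ex$leakage)
        subsets <- draw_community_subsets(pool, communities_per_pool,
                                          subset_size,
                                          seed = seeds[n_draws + draw])
        res <- assemble_ensemble(pool, env, subsets, solver)
        # baseline-0 specs can draw all-zero rows (species that cannot feed);
        # realized overlap is measured over the feeding species
        cm <- pool$consumer_matrix
        cm <- cm[rowSums(cm^2) > 0, , drop = FALSE]
        realized <- mean_niche_overlap(cm)$mean
        for (k in seq_along(res)) {
          failed <- inherits(res[[k]], "assembly_failure")
          rows[[length(rows) + 1L]] <- data.frame(
            example = names(examples)[ei], regime = ex$regime,
            overlap_target = sv$target, overlap_realized = realized,
            pool = p, community = k,
            richness = if (failed) NA_integer_ else richness(res[[k]]))
        }
      }
    }
  }
  tab <- do.call(rbind, rows)
  fits <- do.call(rbind, lapply(split(tab, tab$example), function(d) {
    d <- d[!is.na(d$richness), ]
    degenerate <- length(unique(d$overlap_target)) < 2
    if (degenerate) {
      data.frame(example = d$example[1], regime = d$regime[1],
                 slope = NA_real_, intercept = NA_real_,
                 n = nrow(d), degenerate = TRUE)
    } else {
      fit <- stats::lm(richness ~ overlap_target, data = d)
      data.frame(example = d$example[1], regime = d$regime[1],
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 n = nrow(d), degenerate = FALSE)
    }
  }))
  rownames(fits) <- NULL
  structure(list(table = tab, fits = fits), class = "overlap_sweep")
}

#' Beta-diversity of a freshly assembled ensemble
#'
#' Assembles `n_communities` communities at one parameter set, projects the
#' final compositions onto their first two principal components, and — as a
#' purely descriptive diagnostic — clusters the projections with k-means,
#' choosing k in `k_range` by mean silhouette width.
#'
#' @param w0k0,leakage chemostat parameters.
#' @param n_communities,subset_size ensemble sizes.
#' @param spec a [sampling_spec()].
#' @param solver a [solver_config()].
#' @param seed master seed.
#' @param k_range candidate cluster counts.
#' @return list with `pca` (see [pca_projection()]), `silhouette`, `k`,
#'   `labels`, `richness` (per community) and `table` of coordinates.
#' @export
run_beta_diversity <- function(w0k0, leakage, n_communities = 200,
                               subset_size = 100, spec = sampling_spec(),
                               solver = solver_config(), seed = 1,
                               k_range = 2:8) {
  seeds <- derive_seeds(seed, 3L)
  pool <- sample_pool(spec, seed = seeds[1])
  D <- sample_metabolic_matrix(spec, seed = seeds[1])
  env <- chemostat_environment(D, w0k0, leakage)
  subsets <- draw_community_subsets(pool, n_communities, subset_size,
                                    seed = seeds[2])
  res <- assemble_ensemble(pool, env, subsets, solver)
  pca <- pca_projection(res, pool)
  set.seed(seeds[3])
  sil <- vapply(k_range, function(k) {
    km <- tryCatch(stats::kmeans(pca$coordinates, centers = k, nstart = 10),
                   error = function(e) NULL)
    if (is.null(km)) return(NA_real_)
    silhouette_score(pca$coordinates, km$cluster)
  }, numeric(1))
  best <- which.max(sil)
  km <- stats::kmeans(pca$coordinates, centers = k_range[best], nstart = 10)
  list(pca = pca,
       silhouette = sil[best], k = k_range[best], labels = km$cluster,
       silhouette_by_k = stats::setNames(sil, k_range),
       richness = vapply(res, function(r)
         if (inherits(r, "assembly_failure")) NA_integer_ else richness(r),
         integer(1)),
       table = data.frame(community = seq_len(nrow(pca$coordinates)),
                          PC1 = pca$coordinates[, 1],
                          PC2 = pca$coordinates[, 2]))
}

#' Finite-size scaling of richness with the number of resources
#'
#' Re-runs the reference examples at increasing resource counts M, holding
#' the pool proportions fixed (S = 2M species, colonization subsets of M
#' species, M/10 preferred resources per species), and fits the log-log
#' scaling exponent of mean richness versus M per example.
#'
#' @param M_values resource counts.
#' @param examples named list like [reference_examples()].
#' @param communities_per_M subsets per (M, example).
#' @param solver a [solver_config()].
#' @param seed master seed.
#' @return list with `table` (M, example, regime, community, richness) and
#'   `fits` (per-example log-log slope; NA and degenerate with < 2 M
#'   values).
#' @export
run_size_scaling <- function(M_values, examples = reference_examples(),
                             communities_per_M = 10,
                             solver = solver_config(), seed = 1) {
  seeds <- derive_seeds(seed, 2L * length(M_values))
  rows <- list()
  for (mi in seq_along(M_values)) {
    M <- M_values[mi]
    spec <- sampling_spec(n_species = 2L * M, n_resources = M,
                          mean_preferred = 0.1 * M)
    pool <- sample_pool(spec, seed = seeds[mi])
    D <- sample_metabolic_matrix(spec, seed = seeds[mi])
    subsets <- draw_community_subsets(pool, communities_per_M, M,
                                      seed = seeds[length(M_values) + mi])
    for (ei in seq_along(examples)) {
      ex <- examples[[ei]]
      env <- chemostat_environment(D, ex$w0k0, ex$leakage)
      res <- assemble_ensemble(pool, env, subsets, solver)
      for (k in seq_along(res)) {
        failed <- inherits(res[[k]], "assembly_failure")
        rows[[length(rows) + 1L]] <- data.frame(
          M = M, example = names(examples)[ei], regime = ex$regime,
          community = k,
          richness = if (failed) NA_integer_ else richness(res[[k]]))
      }
    }
  }
  tab <- do.call(rbind, rows)
  fits <- do.call(rbind, lapply(split(tab, tab$example), function(d) {
    d <- d[!is.na(d$richness) & d$richness > 0, ]
    agg <- stats::aggregate(richness ~ M, data = d, FUN = mean)
    if (nrow(agg) < 2) {
      data.frame(example = d$example[1], regime = d$regime[1],
                 exponent = NA_real_, degenerate = TRUE)
    } else {
      fit <- stats::lm(log(richness) ~ log(M), data = agg)
      data.frame(example = d$example[1], regime = d$regime[1],
                 exponent = unname(stats::coef(fit)[2]), degenerate = FALSE)
    }
  }))
  rownames(fits) <- NULL
  list(table = tab, fits = fits)
}
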
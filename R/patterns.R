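#' Presence/absence matrix of an ensemble
#'
#' Converts community abundances to a binary species x communities matrix: a
#' species is present when its relative abundance exceeds
#' `abundance_threshold`. Rows (species) are ordered by decreasing
#' prevalence and columns (communities) by increasing richness, with ties
#' broken by original index (stable sort) — the standard layout for visual
#' and quantitative nestedness analysis.
#'
#' @param x either a list of `steady_state_result` (then `pool` is needed),
#'   or a communities x species abundance matrix, or an already-binary
#'   matrix.
#' @param abundance_threshold relative-abundance cutoff for presence.
#' @param pool optional `regional_pool` when `x` is an ensemble list.
#' @return object of class `presence_matrix`: `matrix` (binary, species x
#'   communities), `row_order`, `col_order` (permutations of the input),
#'   `threshold`.
#' @export
presence_absence <- function(x, abundance_threshold = 0, pool = NULL) {
  if (is.list(x) && !is.matrix(x)) {
    if (is.null(pool)) stop("pool required to index an ensemble list")
    x <- abundance_matrix(x, pool)
  }
  A <- as.matrix(x)
  rel <- A / pmax(rowSums(A), .Machine$double.xmin)
  P <- t(rel > abundance_threshold) * 1L   # species x communities
  prevalence <- rowSums(P)
  rich <- colSums(P)
  row_order <- order(-prevalence, seq_len(nrow(P)))
  col_order <- order(rich, seq_len(ncol(P)))
  structure(list(matrix = P[row_order, col_order, drop = FALSE],
                 row_order = row_order, col_order = col_order,
                 threshold = abundance_threshold),
            class = "presence_matrix")
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat(sprintf("<presence_matrix> %d species x %d communities, fill %.3f\n",
              nrow(x$matrix), ncol(x$matrix), mean(x$matrix)))
  invisible(x)
}

#' NODF nestedness of a binary matrix
#'
#' Nestedness metric based on Overlap and Decreasing Fill. For every
#' unordered pair of rows (and of columns) with strictly different fills,
#' the pair scores 100 x (shared presences) / (fill of the sparser member);
#' equal fills score 0. NODF is the average over all row pairs and column
#' pairs, between 0 (no nesting) and 100 (perfect nesting). The score does
#' not depend on row/column ordering.
#'
#' @param pm binary matrix or a [presence_absence()] object.
#' @return scalar in `[0, 100]`.
#' @export
nodf <- function(pm) {
  m <- if (inherits(pm, "presence_matrix")) pm$matrix else as.matrix(pm)
  if (!all(m %in% c(0, 1))) stop("nodf requires a binary matrix")
  if (nrow(m) < 2 || ncol(m) < 2 || sum(m) == 0)
    stop("nodf requires a non-empty matrix with >= 2 rows and columns")
  pair_score <- function(x) {       # x: entity x feature binary matrix
    fill <- rowSums(x)
    ov <- tcrossprod(x)             # shared presences
    n <- nrow(x)
    tot <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      fi <- fill[i]; fj <- fill[j]
      if (fi == fj) next
      lo <- min(fi, fj)
      if (lo > 0) tot <- tot + 100 * ov[i, j] / lo
    }
    c(sum = tot, pairs = n * (n - 1) / 2)
  }
  r <- pair_score(m)
  cc <- pair_score(t(m))
  (r[["sum"]] + cc[["sum"]]) / (r[["pairs"]] + cc[["pairs"]])
}

#' Null-model z-score of nestedness
#'
#' Compares the observed NODF against randomized matrices. The
#' `equiprobable` null shuffles all entries, preserving only the total fill;
#' the `proportional` null draws each entry as a Bernoulli with probability
#' (row fill / ncol + column fill / nrow) / 2, preserving the marginals in
#' expectation.
#'
#' @param pm binary matrix or `presence_matrix`.
#' @param null_model `"equiprobable"` or `"proportional"`.
#' @param n_null number of null draws.
#' @param seed optional integer seed.
#' @return list with `observed`, `null_mean`, `null_sd`, `z`, `degenerate`
#'   (TRUE when the null distribution has zero spread, in which case `z` is
#'   +/- Inf).
#' @export
nestedness_zscore <- function(pm, null_model = c("equiprobable", "proportional"),
                              n_null = 1000, seed = NULL) {
  null_model <- match.arg(null_model)
  m <- if (inherits(pm, "presence_matrix")) pm$matrix else as.matrix(pm)
  if (!is.null(seed)) set.seed(seed)
  obs <- nodf(m)
  nr <- nrow(m); nc <- ncol(m)
  p_prop <- (rowSums(m)[row(m)] / nc + colSums(m)[col(m)] / nr) / 2
  nulls <- vapply(seq_len(n_null), function(i) {
    nm <- switch(null_model,
      equiprobable = matrix(sample(as.vector(m)), nr, nc),
      proportional = matrix((stats::runif(nr * nc) < p_prop) * 1L, nr, nc))
    tryCatch(nodf(nm), error = function(e) NA_real_)
  }, numeric(1))
  nulls <- nulls[is.finite(nulls)]
  mu <- mean(nulls); sdev <- stats::sd(nulls)
  degenerate <- !is.finite(sdev) || sdev == 0
  z <- if (degenerate) sign(obs - mu) * Inf else (obs - mu) / sdev
  list(observed = obs, null_mean = mu, null_sd = sdev, z = z,
       degenerate = degenerate, null_model = null_model,
       n_null = length(nulls))
}

#' PCA projection of community compositions
#'
#' Converts abundances to relative abundances (compositions), mean-centers
#' across communities, and projects onto the first two principal components.
#' Components follow a deterministic sign convention: the loading with the
#' largest magnitude is positive.
#'
#' @param x communities x species abundance matrix (or list of
#'   `steady_state_result` plus `pool`).
#' @param pool optional `regional_pool` when `x` is an ensemble list.
#' @return list with `coordinates` (n x 2), `variance_explained` (length 2,
#'   fractions of total variance) and `loadings` (species x 2).
#' @export
pca_projection <- function(x, pool = NULL) {
  if (is.list(x) && !is.matrix(x)) {
    if (is.null(pool)) stop("pool required to index an ensemble list")
    x <- abundance_matrix(x, pool)
  }
  A <- as.matrix(x)
  if (nrow(A) < 3) stop("pca_projection requires at least 3 communities")
  comp <- A / pmax(rowSums(A), .Machine$double.xmin)
  if (all(apply(comp, 2, stats::var) < .Machine$double.eps))
    stop("constant compositions: principal components undefined")
  pc <- stats::prcomp(comp, center = TRUE, scale. = FALSE)
  k <- min(2, ncol(pc$rotation))
  load <- pc$rotation[, seq_len(k), drop = FALSE]
  scores <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {                      # sign convention
    lead <- which.max(abs(load[, j]))
    if (load[lead, j] < 0) { load[, j] <- -load[, j]; scores[, j] <- -scores[, j] }
  }
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  list(coordinates = scores, variance_explained = ve[seq_len(k)],
       loadings = load)
}

#' Mean silhouette width of a labelled point set
#'
#' Plain Euclidean silhouette, used as a descriptive diagnostic for how
#' clustered a set of PCA projections is.
#'
#' @param x numeric matrix of coordinates (rows = points).
#' @param labels cluster labels (length nrow(x), >= 2 distinct values).
#' @export
silhouette_score <- function(x, labels) {
  x <- as.matrix(x)
  labels <- as.integer(factor(labels))
  if (length(unique(labels)) < 2) stop("silhouette needs >= 2 clusters")
  d <- as.matrix(stats::dist(x))
  n <- nrow(x)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    a <- if (sum(own) > 1) mean(d[i, own & seq_len(n) != i]) else 0
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(g) mean(d[i, labels == g]), numeric(1)))
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}
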
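#' Configuration of a 3D Kohonen self-organizing map
#'
#' The lattice is `N x N x N`; each lattice element carries an n-dimensional
#' model vector. Learning uses `M` sequential steps with a geometrically
#' decaying learning rate from `L0` to `LM` and a linearly shrinking integer
#' neighborhood radius that reaches 0 after `g` percent of the steps (the
#' remaining steps fine-tune individual model vectors; only the BMU learns
#' at radius 0).
#'
#' @param N lattice side (default 10, i.e. 1000 model vectors).
#' @param M total training steps; `NULL` (default) resolves at training time
#'   to `min(20 * n_training_vectors, 1e5)`.
#' @param L0,LM initial and final learning rates (defaults 1 and 0.01).
#' @param R0 initial neighborhood radius (default `N/2`).
#' @param g percent of `M` after which the radius is 0 (default 66).
#' @param seed integer seed controlling initialization and the training
#'   sequence.
#' @return A list of class `som_config`.
#' @export
som_config <- function(N = 10, M = NULL, L0 = 1, LM = 0.01, R0 = N / 2,
                       g = 66, seed = 1L) {
  stopifnot(N >= 2, LM > 0, LM <= L0, g > 0, g <= 100, R0 >= 0)
  if (!is.null(M)) stopifnot(M >= 1)
  structure(list(N = as.integer(N), M = M, L0 = L0, LM = LM, R0 = R0,
                 g = g, seed = as.integer(seed)),
            class = "som_config")
}

#' Learning rate at a training step
#'
#' Monotone non-increasing geometric interpolation
#' `L(k) = L0 * (LM/L0)^(k/M)`, so `L(0) = L0` and `L(M) = LM`.
#'
#' @param k step in `[0, M]`.
#' @param cfg a [som_config()] with `M` set.
#' @return The learning rate at step `k`.
#' @export
learning_rate <- function(k, cfg) {
  M <- cfg$M
  if (is.null(M)) stop("cfg$M must be set")
  if (any(k < 0 | k > M)) stop("k must be in [0, M]")
  cfg$L0 * (cfg$LM / cfg$L0)^(k / M)
}

#' Neighborhood radius at a training step
#'
#' Linear decay rounded to the nearest integer:
#' `R(k) = round(R0 * max(0, 1 - k / (g * M / 100)))`. The radius is 0 for
#' every `k >= g * M / 100`.
#'
#' @inheritParams learning_rate
#' @return Non-negative integer radius.
#' @export
neighborhood_radius <- function(k, cfg) {
  M <- cfg$M
  if (is.null(M)) stop("cfg$M must be set")
  if (any(k < 0 | k > M)) stop("k must be in [0, M]")
  as.integer(round(cfg$R0 * pmax(0, 1 - k / (cfg$g * M / 100))))
}

lattice_position <- function(id, N) {
  cbind(x = id %% N, y = (id %/% N) %% N, z = id %/% (N * N))
}

lattice_id <- function(pos, N) {
  pos <- rbind(pos)
  as.integer(pos[, 1] + N * pos[, 2] + N * N * pos[, 3])
}

#' Train a 3D Kohonen map on activity vectors
#'
#' At each step a training vector is drawn uniformly with replacement, its
#' best-matching unit (BMU) located, and every model vector within Chebyshev
#' lattice distance `R(k)` of the BMU is moved toward the training vector:
#' `MV <- MV + L(k) * G * (v - MV)`, where `G` is a 3D Gaussian envelope of
#' SD `R(k)/3` in squared Euclidean lattice distance, with `G = 1` at the
#' BMU. Model vectors are initialized uniformly within the per-dimension
#' range of the training set. Training is deterministic under
#' `cfg$seed`.
#'
#' @param vectors numeric matrix (rows = training vectors) or an
#'   `activity_vectors` object, whose trials are row-bound.
#' @param cfg a [som_config()].
#' @param max_train_vectors training sets larger than this are reduced to a
#'   seeded uniform subsample (default 200000); assignment via
#'   [assign_patterns()] always uses all samples.
#' @return An object of class `som_map` with elements `model_vectors`
#'   (`N^3 x n` matrix; row `id + 1` is pattern `id`), `config` (with `M`
#'   resolved), `n`, `N`.
#' @export
train_som <- function(vectors, cfg = som_config(), max_train_vectors = 2e5) {
  x <- as_vector_matrix(vectors)
  if (nrow(x) < 1) stop("need at least one training vector")
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(cfg$seed)
  if (nrow(x) > max_train_vectors)
    x <- x[sample.int(nrow(x), max_train_vectors), , drop = FALSE]
  if (is.null(cfg$M))
    cfg$M <- as.integer(min(20 * nrow(x), 1e5))
  N <- cfg$N
  n <- ncol(x)
  lo <- apply(x, 2, min)
  hi <- apply(x, 2, max)
  P <- N^3
  mv0 <- matrix(stats::runif(P * n), P, n)
  mv0 <- sweep(sweep(mv0, 2, hi - lo, "*"), 2, lo, "+")
  idx <- sample.int(nrow(x), cfg$M, replace = TRUE) - 1L
  mv <- train_som_cpp(mv0, N, x, idx, cfg$L0, cfg$LM, cfg$R0, cfg$g)
  structure(list(model_vectors = mv, config = cfg, n = n, N = N),
            class = "som_map")
}

as_vector_matrix <- function(vectors) {
  if (inherits(vectors, "activity_vectors"))
    return(do.call(rbind, vectors$series))
  m <- as.matrix(vectors)
  storage.mode(m) <- "double"
  m
}

#' @export
print.som_map <- function(x, ...) {
  cat("<som_map> ", x$N, "^3 = ", x$N^3, " model vectors of dimension ",
      x$n, " (M = ", x$config$M, " steps)\n", sep = "")
  invisible(x)
}

#' Best-matching unit of a single vector
#'
#' Exhaustively minimizes the Euclidean distance over the lattice; ties are
#' broken by the lowest linear index.
#'
#' @param map a [train_som()] map.
#' @param v numeric vector of length `map$n`.
#' @return List with `id` (0-based pattern id), `position` (0-based
#'   `(x, y, z)`), and `distance`.
#' @export
find_bmu <- function(map, v) {
  if (length(v) != map$n) stop("dimension mismatch: expected length ", map$n)
  id <- bmu_batch_cpp(map$model_vectors, matrix(as.numeric(v), 1))[1]
  list(id = id,
       position = drop(lattice_position(id, map$N)),
       distance = sqrt(sum((map$model_vectors[id + 1, ] - v)^2)))
}

#' Replace activity vectors by their best-matching patterns
#'
#' Builds model trials: each trial's activity-vector sequence becomes the
#' sequence of 0-based pattern ids of the BMUs.
#'
#' @param map a [train_som()] map (or [kmeans_backend()] model).
#' @param avs an `activity_vectors` object of matching dimensionality.
#' @return An object of class `model_trials`: list with `pattern_ids` (one
#'   integer vector per trial), `trial_id`, `stimulus`, `n_samples`,
#'   `dt_ms`, and `map`.
#' @export
assign_patterns <- function(map, avs) {
  mv <- model_vector_matrix(map)
  if (avs$n != ncol(mv)) stop("dimension mismatch")
  ids <- lapply(avs$series, function(m) bmu_batch_cpp(mv, m))
  structure(list(pattern_ids = ids, trial_id = avs$trial_id,
                 stimulus = avs$stimulus, n_samples = avs$n_samples,
                 dt_ms = avs$dt_ms, map = map),
            class = "model_trials")
}

model_vector_matrix <- function(map) {
  if (inherits(map, "som_map")) map$model_vectors
  else if (inherits(map, "kmeans_model")) map$centers
  else stop("not a pattern model")
}

#' @export
print.model_trials <- function(x, ...) {
  cat("<model_trials> ", length(x$pattern_ids), " trials x ", x$n_samples,
      " samples; ", length(unique(unlist(x$pattern_ids))),
      " distinct patterns expressed\n", sep = "")
  invisible(x)
}

#' Color of a lattice position
#'
#' Maps a 0-based lattice position to RGB in `[0,1]^3` as
#' `(x, y, z)/(N - 1)`, so nearby lattice points (similar patterns, by the
#' map's topological ordering) receive similar colors.
#'
#' @param position integer vector `(x, y, z)`, each in `0:(N-1)`, or a
#'   matrix of such rows.
#' @param N lattice side.
#' @return Numeric RGB triple(s) in `[0, 1]`.
#' @export
pattern_color <- function(position, N) {
  pos <- rbind(position)
  if (any(pos < 0) || any(pos >= N)) stop("position outside lattice")
  col <- pos / (N - 1)
  colnames(col) <- c("r", "g", "b")
  if (is.null(dim(position))) col[1, ] else col
}

#' K-means clustering backend
#'
#' Flat alternative to the Kohonen map (no lattice ordering, hence no color
#' mapping): standard Lloyd iterations via [stats::kmeans()]. The returned
#' model can be used wherever a map is (e.g. [assign_patterns()]); pattern
#' ids are 0-based centroid indices.
#'
#' @param vectors matrix or `activity_vectors`.
#' @param K number of centroids (`>= 1`, at most the number of distinct
#'   vectors).
#' @param seed integer seed.
#' @param iter_max maximum Lloyd iterations.
#' @return An object of class `kmeans_model` with `centers`, `K`, `n`.
#' @export
kmeans_backend <- function(vectors, K, seed = 1L, iter_max = 100) {
  x <- as_vector_matrix(vectors)
  if (K < 1) stop("K must be >= 1")
  if (K > nrow(unique(x))) stop("K exceeds number of distinct vectors")
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  km <- suppressWarnings(
    stats::kmeans(x, centers = K, iter.max = iter_max, algorithm = "Lloyd")
  )
  structure(list(centers = unname(km$centers), K = as.integer(K), n = ncol(x)),
            class = "kmeans_model")
}

#' Mean quantization error of a pattern model
#'
#' Average Euclidean distance from each vector to its best-matching model
#' vector; used to compare trained maps against their initialization.
#'
#' @param map a `som_map` or `kmeans_model`.
#' @param vectors matrix or `activity_vectors`.
#' @return Mean distance (scalar).
#' @export
quantization_error <- function(map, vectors) {
  x <- as_vector_matrix(vectors)
  mv <- model_vector_matrix(map)
  ids <- bmu_batch_cpp(mv, x)
  mean(sqrt(rowSums((x - mv[ids + 1L, , drop = FALSE])^2)))
}
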
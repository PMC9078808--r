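#' Initialize a particle set around a target box
#'
#' Particle centers are drawn from an isotropic Gaussian around the target
#' center (sd `spread`), clipped so every particle's region — a box of the
#' target's size — stays inside the frame. Initial weights are uniform.
#'
#' @param target a `ceus_box`, the region to be tracked.
#' @param frame_shape `c(rows, cols)` of the frames.
#' @param n number of particles (default 100).
#' @param spread positional sd in pixels; default half the box diagonal.
#' @param epsilon kernel width of the weighting step (see [weigh_particles()]).
#' @param jitter_sd post-resampling jitter sd in pixels.
#' @param seed optional RNG seed; when `NULL` the current RNG stream is used.
#' @return list of class `particle_set`: `centers` (n x 2 matrix, row/col),
#'   `weights` (sum 1), `box_size` `c(height, width)`, `frame_shape`,
#'   `epsilon`, `jitter_sd`.
#' @export
init_particles <- function(target, frame_shape, n = 100, spread = NULL,
                           epsilon = 0.2, jitter_sd = 1, seed = NULL) {
  if (n < 1) stop("need at least one particle")
  if (!box_in_frame(target, frame_shape)) stop("target box must lie inside the frame")
  if (epsilon <= 0) stop("epsilon must be positive")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(spread)) spread <- sqrt(target[3]^2 + target[4]^2) / 2
  ctr <- box_center(target)
  centers <- cbind(ctr[1] + stats::rnorm(n, 0, spread),
                   ctr[2] + stats::rnorm(n, 0, spread))
  centers <- clip_centers(centers, c(target[3], target[4]), frame_shape)
  structure(list(centers = centers, weights = rep(1 / n, n),
                 box_size = c(unname(target[3]), unname(target[4])),
                 frame_shape = frame_shape, epsilon = epsilon,
                 jitter_sd = jitter_sd),
            class = "particle_set")
}

# keep centers such that a box_size box at the (rounded) center is in-frame
clip_centers <- function(centers, box_size, frame_shape) {
  half_h <- box_size[1] / 2; half_w <- box_size[2] / 2
  centers[, 1] <- pmin(pmax(centers[, 1], half_h + 0.5),
                       frame_shape[1] - half_h + 0.5)
  centers[, 2] <- pmin(pmax(centers[, 2], half_w + 0.5),
                       frame_shape[2] - half_w + 0.5)
  centers
}

particle_box <- function(pset, i) {
  clip_box(box_at(pset$centers[i, ], pset$box_size), pset$frame_shape)
}

#' Flow-vector similarity
#'
#' Cosine similarity between a particle region's flow vector and the reference
#' (model) flow vector, bounded in `[-1, 1]`; returns 0 when either vector is
#' zero (no motion carries no directional information).
#'
#' @param reference,particle numeric length-2 flow vectors `c(sum_r, sum_c)`.
#' @return similarity score.
#' @export
flow_similarity <- function(reference, particle) {
  nr <- sqrt(sum(reference^2)); np <- sqrt(sum(particle^2))
  if (nr == 0 || np == 0) return(0)
  sum(reference * particle) / (nr * np)
}

#' Weight particles by flow similarity
#'
#' Each particle's regional flow vector is summed from the current flow field
#' over its box; its similarity to the reference flow (the temporally
#' maintained model vector `h`) is scored by [flow_similarity()], and the raw
#' weight is the Gaussian kernel
#' `exp(-(consi_i - consi_max)^2 / (2 epsilon^2))` — the constant prefactor of
#' the Gaussian density cancels under normalization and is dropped. Weights
#' are then normalized to sum to one. If every raw weight underflows to zero
#' the set falls back to uniform weights with a warning.
#'
#' @param pset a `particle_set`.
#' @param model a `flow_model` (its `h` is the reference vector).
#' @param flow a `flow_field` for the current frame transition.
#' @return the particle set with updated `weights` and a `consi` attribute of
#'   per-particle similarities.
#' @export
weigh_particles <- function(pset, model, flow) {
  stopifnot(inherits(pset, "particle_set"), inherits(model, "flow_model"),
            inherits(flow, "flow_field"))
  n <- nrow(pset$centers)
  # integral images make per-particle region sums O(1)
  ir <- integral_image(flow$vr); ic <- integral_image(flow$vc)
  consi <- numeric(n)
  for (i in seq_len(n)) {
    b <- particle_box(pset, i)
    sr <- rect_sum(ir, b[1], b[1] + b[3] - 1, b[2], b[2] + b[4] - 1)
    sc <- rect_sum(ic, b[1], b[1] + b[3] - 1, b[2], b[2] + b[4] - 1)
    consi[i] <- flow_similarity(model$h, c(sr, sc))
  }
  raw <- exp(-(consi - max(consi))^2 / (2 * pset$epsilon^2))
  if (all(raw == 0) || !all(is.finite(raw))) {
    warning("all particle weights degenerate; falling back to uniform")
    raw <- rep(1, n)
  }
  pset$weights <- raw / sum(raw)
  attr(pset, "consi") <- consi
  pset
}

#' Systematic resampling of a particle set
#'
#' Draws offspring proportional to weight with a single stratified uniform
#' (systematic resampling), preserving the particle count, then jitters every
#' offspring by an isotropic Gaussian of sd `jitter_sd` to restore diversity.
#' Weights reset to uniform.
#'
#' @param pset a `particle_set` with normalized weights.
#' @param seed optional RNG seed.
#' @param jitter_sd overrides the set's jitter sd when given.
#' @return the resampled `particle_set`.
#' @export
resample_particles <- function(pset, seed = NULL, jitter_sd = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(jitter_sd)) jitter_sd <- pset$jitter_sd
  n <- nrow(pset$centers)
  u <- (stats::runif(1) + 0:(n - 1)) / n
  idx <- findInterval(u, cumsum(pset$weights)) + 1
  idx[idx > n] <- n  # guard against cumsum rounding
  centers <- pset$centers[idx, , drop = FALSE]
  if (jitter_sd > 0)
    centers <- centers + matrix(stats::rnorm(2 * n, 0, jitter_sd), n, 2)
  pset$centers <- clip_centers(centers, pset$box_size, pset$frame_shape)
  pset$weights <- rep(1 / n, n)
  attr(pset, "parents") <- idx
  pset
}

#' Extract candidate regions from a particle set
#'
#' Returns the regions of the top-`k` particles by weight (ties broken by
#' lower particle index), deduplicated: a particle whose center lies within
#' 1 px of an already selected candidate is skipped.
#'
#' @param pset a `particle_set`.
#' @param k maximum number of candidates (`k <= n`).
#' @return list of class `candidate_set`: `boxes` (list of `ceus_box`),
#'   `centers` (matrix), `weights` (provenance particle weights).
#' @export
candidates <- function(pset, k = 10) {
  n <- nrow(pset$centers)
  if (k > n) stop("k must not exceed the particle count")
  ord <- order(-pset$weights, seq_len(n))
  sel <- integer(0)
  for (i in ord) {
    if (length(sel) >= k) break
    if (length(sel) > 0) {
      d <- sqrt((pset$centers[sel, 1] - pset$centers[i, 1])^2 +
                  (pset$centers[sel, 2] - pset$centers[i, 2])^2)
      if (any(d < 1)) next
    }
    sel <- c(sel, i)
  }
  structure(list(boxes = lapply(sel, function(i) particle_box(pset, i)),
                 centers = pset$centers[sel, , drop = FALSE],
                 weights = pset$weights[sel],
                 index = sel),
            class = "candidate_set")
}
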
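#' Dense differential optical flow (Lucas-Kanade)
#'
#' Estimates per-pixel motion between two frames from spatiotemporal image
#' gradients: both frames are Gaussian pre-smoothed, spatial gradients are
#' taken on their average and the temporal gradient is the frame difference,
#' then each pixel's velocity solves the windowed least-squares normal
#' equations over a `window x window` neighbourhood. Pixels where the
#' structure tensor is (near-)singular — uniform areas and borders — get zero
#' flow. Valid for small displacements (about 2 px/frame or less).
#'
#' @param frame_prev,frame_next two frames of identical shape (RGB frames are
#'   collapsed to their value channel).
#' @param window odd window side length in pixels (default 5).
#' @param sigma Gaussian pre-smoothing sigma in pixels (default 1).
#' @param min_eig smallest-eigenvalue threshold of the structure tensor below
#'   which the solution is deemed unreliable and set to zero.
#' @param iterations warp-and-re-solve refinement passes; each pass warps the
#'   second frame back by the current estimate and solves for the residual
#'   motion, removing the linearization bias of the one-shot solver near the
#'   upper end of the small-motion regime.
#' @param max_flow velocities whose magnitude exceeds this bound (px/frame)
#'   are zeroed: the differential solver is only valid for small motion, so
#'   such values are numerical artifacts of near-singular tensors, not
#'   measurements.
#' @return list of class `flow_field` with matrices `vr` (row velocity,
#'   px/frame, positive = downward) and `vc` (column velocity, positive =
#'   rightward).
#' @export
compute_flow <- function(frame_prev, frame_next, window = 5, sigma = 1,
                         min_eig = 1e-4, iterations = 3, max_flow = 5) {
  p <- frame_gray(frame_prev); q <- frame_gray(frame_next)
  if (!all(dim(p) == dim(q))) stop("frames must have the same shape")
  if (window %% 2 != 1 || window < 3) stop("window must be odd and >= 3")
  p <- gaussian_blur(p, sigma); q <- gaussian_blur(q, sigma)
  k <- (window - 1) / 2
  nr <- nrow(p); nc <- ncol(p)
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  vr <- matrix(0, nr, nc); vc <- vr
  for (it in seq_len(max(1, iterations))) {
    qw <- if (it == 1) q else bilinear_sample(q, rr + vr, cc + vc)
    g <- spatial_gradients((p + qw) / 2)
    It <- qw - p
    Srr <- box_sum(g$dr * g$dr, k)
    Scc <- box_sum(g$dc * g$dc, k)
    Src <- box_sum(g$dr * g$dc, k)
    Srt <- box_sum(g$dr * It, k)
    Sct <- box_sum(g$dc * It, k)
    det <- Srr * Scc - Src^2
    tr <- Srr + Scc
    # smallest eigenvalue of the symmetric 2x2 structure tensor
    lam_min <- tr / 2 - sqrt(pmax(tr^2 / 4 - det, 0))
    ok <- lam_min > min_eig & det > 0
    dvr <- matrix(0, nr, nc); dvc <- dvr
    dvr[ok] <- (-Scc[ok] * Srt[ok] + Src[ok] * Sct[ok]) / det[ok]
    dvc[ok] <- (Src[ok] * Srt[ok] - Srr[ok] * Sct[ok]) / det[ok]
    vr <- vr + dvr; vc <- vc + dvc
  }
  bad <- vr^2 + vc^2 > max_flow^2
  vr[bad] <- 0; vc[bad] <- 0
  structure(list(vr = vr, vc = vc), class = "flow_field")
}

# bilinear interpolation of matrix m at (possibly fractional) coordinates
# (any matrix of positions), clamped to the frame; output shaped like rr
bilinear_sample <- function(m, rr, cc) {
  nr <- nrow(m); nc <- ncol(m)
  out_dim <- dim(rr)
  rr <- pmin(pmax(rr, 1), nr); cc <- pmin(pmax(cc, 1), nc)
  r0 <- pmin(floor(rr), nr - 1); c0 <- pmin(floor(cc), nc - 1)
  fr <- rr - r0; fc <- cc - c0
  i00 <- cbind(as.vector(r0), as.vector(c0))
  i10 <- cbind(as.vector(r0) + 1, as.vector(c0))
  i01 <- cbind(as.vector(r0), as.vector(c0) + 1)
  i11 <- cbind(as.vector(r0) + 1, as.vector(c0) + 1)
  v <- (1 - as.vector(fr)) * (1 - as.vector(fc)) * m[i00] +
    as.vector(fr) * (1 - as.vector(fc)) * m[i10] +
    (1 - as.vector(fr)) * as.vector(fc) * m[i01] +
    as.vector(fr) * as.vector(fc) * m[i11]
  matrix(v, out_dim[1], out_dim[2])
}

#' Regional flow summary
#'
#' Sums the flow components over a bounding-box region: `sum_r` and `sum_c`
#' are the summed row/column velocities, and the motion intensity
#' `w = sqrt(sum_r^2 + sum_c^2) / z` with `z` the number of pixels in the
#' region, i.e. the magnitude of the mean motion vector.
#'
#' @param flow a `flow_field`.
#' @param region a `ceus_box` inside the frame.
#' @return named numeric `c(sum_r, sum_c, w)`.
#' @export
region_flow <- function(flow, region) {
  if (region[3] < 1 || region[4] < 1) stop("empty region")
  if (!box_in_frame(region, dim(flow$vr))) stop("region outside frame")
  sr <- sum(crop_box(flow$vr, region))
  sc <- sum(crop_box(flow$vc, region))
  z <- unname(region[3] * region[4])
  c(sum_r = sr, sum_c = sc, w = sqrt(sr^2 + sc^2) / z)
}

#' Temporally updated flow model
#'
#' Maintains the reference motion of the tracked region across frames: the
#' total flow vector `h` and the motion intensity `w`. [update_flow_model()]
#' blends the previous total flow with the current frame's regional flow as an
#' exponential moving average, `h <- (1 - beta) h_prev + beta h_current`, and
#' replaces the motion intensity by the current one. On the first observation
#' the model adopts the observation outright.
#'
#' @param beta update factor in `[0, 1]`: 0 freezes the model, 1 replaces it
#'   every frame.
#' @param h optional initial total-flow vector `c(sum_r, sum_c)`; when given
#'   the model starts initialized and the first update already blends.
#' @param w initial motion intensity.
#' @return `flow_model()`: list of class `flow_model` with fields `h`
#'   (`c(sum_r, sum_c)`), `w`, `beta`, `z` (pixel count of the observed
#'   region) and `initialized`.
#' @export
flow_model <- function(beta = 0.5, h = NULL, w = 0) {
  if (beta < 0 || beta > 1) stop("beta must be in [0, 1]")
  init <- !is.null(h)
  if (is.null(h)) h <- c(0, 0)
  structure(list(h = c(sum_r = unname(h[1]), sum_c = unname(h[2])), w = w,
                 beta = beta, z = NA_real_, initialized = init),
            class = "flow_model")
}

#' @rdname flow_model
#' @param model a `flow_model`.
#' @param obs a regional flow summary `c(sum_r, sum_c, w)` from [region_flow()],
#'   optionally carrying attribute `z` (region pixel count).
#' @param z pixel count of the observed region (for mean-velocity prediction).
#' @export
update_flow_model <- function(model, obs, z = NULL) {
  stopifnot(inherits(model, "flow_model"))
  h_s <- c(sum_r = unname(obs[1]), sum_c = unname(obs[2]))
  if (!model$initialized) {
    model$h <- h_s
    model$initialized <- TRUE
  } else {
    model$h <- (1 - model$beta) * model$h + model$beta * h_s
  }
  model$w <- unname(obs[3])
  if (!is.null(z)) model$z <- z
  model
}

# mean velocity (px/frame) implied by the model's total flow over a region of
# z pixels; zero before initialization
model_velocity <- function(model) {
  if (!model$initialized || is.na(model$z) || model$z <= 0) return(c(0, 0))
  unname(model$h / model$z)
}

#' Mean-shift points toward the local optical-flow-magnitude centroid
#'
#' For each point, iteratively moves it toward the centroid of the flow
#' magnitude `sqrt(vr^2 + vc^2)` computed over a `window`-sized box around the
#' point. On scenes with a static background, motion energy is concentrated on
#' the moving lesion, so this is a mean-shift ascent of the motion-energy
#' surface: points that start near the lesion converge onto its center. Points
#' in motionless surroundings (total magnitude below `min_mass`) stay put.
#'
#' @param flow a `flow_field`.
#' @param points n x 2 matrix of (row, col) positions.
#' @param window `c(height, width)` of the local window in pixels.
#' @param iterations mean-shift iterations.
#' @param lambda step fraction toward the centroid per iteration.
#' @param step_max cap on the per-iteration step length (px).
#' @param min_mass minimum summed magnitude for a step to be taken.
#' @return n x 2 matrix of shifted positions.
#' @export
flow_mean_shift <- function(flow, points, window, iterations = 2, lambda = 1,
                            step_max = 4, min_mass = 1e-6) {
  nr <- nrow(flow$vr); nc <- ncol(flow$vr)
  mag <- sqrt(flow$vr^2 + flow$vc^2)
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  im <- integral_image(mag)
  imr <- integral_image(mag * rr)
  imc <- integral_image(mag * cc)
  hh <- window[1] / 2; hw <- window[2] / 2
  out <- points
  for (i in seq_len(nrow(points))) {
    ctr <- c(min(max(points[i, 1], 1), nr), min(max(points[i, 2], 1), nc))
    for (it in seq_len(iterations)) {
      r1 <- max(1, round(ctr[1] - hh)); r2 <- min(nr, round(ctr[1] + hh))
      c1 <- max(1, round(ctr[2] - hw)); c2 <- min(nc, round(ctr[2] + hw))
      if (r2 < r1 || c2 < c1) break
      m0 <- rect_sum(im, r1, r2, c1, c2)
      if (m0 < min_mass) break
      cen <- c(rect_sum(imr, r1, r2, c1, c2) / m0,
               rect_sum(imc, r1, r2, c1, c2) / m0)
      step <- lambda * (cen - ctr)
      len <- sqrt(sum(step^2))
      if (len > step_max) step <- step * step_max / len
      ctr <- ctr + step
    }
    out[i, ] <- ctr
  }
  out
}

#' Sample a flow field at (fractional) point positions
#'
#' Bilinear interpolation of both velocity components at the given points,
#' clamped to the frame; used to advect particles with the local motion.
#'
#' @param flow a `flow_field`.
#' @param points n x 2 matrix of (row, col) positions.
#' @return n x 2 matrix of (vr, vc) velocities.
#' @export
flow_at <- function(flow, points) {
  rr <- matrix(points[, 1], ncol = 1); cc <- matrix(points[, 2], ncol = 1)
  cbind(as.vector(bilinear_sample(flow$vr, rr, cc)),
        as.vector(bilinear_sample(flow$vc, rr, cc)))
}
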
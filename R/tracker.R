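#' Tracker configuration
#'
#' Collects the tunable parameters of the tracking loop. Defaults follow the
#' package's standard settings; all are overridable.
#'
#' @param enhance apply MSRCP enhancement to every frame before feature
#'   extraction (`FALSE` reproduces the `--no-enhance` path).
#' @param scales,clip_percentiles MSRCP parameters (see [msrcp_enhance()]).
#' @param flow_window,flow_sigma Lucas-Kanade window and pre-smoothing sigma.
#' @param beta flow-model update factor in `[0, 1]`.
#' @param n_particles particle count.
#' @param epsilon Gaussian kernel width of the particle weighting.
#' @param spread initial particle sd (px); `NULL` = half the box diagonal.
#' @param jitter_sd post-resampling jitter sd (px).
#' @param k_candidates candidate regions passed to the classifier.
#' @param max_step search radius (px): candidates farther than this from the
#'   previous box center are discarded as physically implausible single-frame
#'   displacements (the differential-flow regime assumes small motion). If no
#'   candidate survives, the nearest one is kept.
#' @param ms_iterations,ms_lambda,ms_step_max mean-shift refinement of the
#'   particle positions on the optical-flow-magnitude surface (see
#'   [flow_mean_shift()]); `ms_iterations = 0` disables it.
#' @param ms_window_scale mean-shift window size as a multiple of the box
#'   size; larger windows let particles sense the lesion's motion energy
#'   from farther away.
#' @param cnn_smooth despeckling Gaussian sigma (px) applied to the feature
#'   frame before classifier patches are cut; 0 disables.
#' @param use_cnn `FALSE` gives the flow-only ablation: the final position is
#'   the argmax-weight particle and no network is trained.
#' @param cnn_epochs,cnn_n_pos,cnn_n_neg,cnn_lr classifier training settings.
#' @param pos_jitter positive-patch jitter in px (see [training_patches()]);
#'   small values sharpen the classifier's score peak at the target center.
#' @param augment_times speckle-appearance augmented copies per training patch
#'   (see [augment_patches()]).
#' @param update_interval frames between online classifier adaptations
#'   (0 disables adaptation).
#' @param update_epochs,update_score adaptation epochs and the minimum winning
#'   score required before the current frame's selection is trusted as new
#'   training material.
#' @param patch_size normalized patch size.
#' @param include_incumbent when to offer the previous frame's box to the
#'   classifier as an extra zero-motion candidate: `"auto"` (default) only
#'   while the flow model's motion intensity is below `incumbent_w_max` —
#'   i.e. the scene appears static, which is exactly when the particle cloud
#'   carries no positional information; `TRUE` always; `FALSE` never.
#' @param incumbent_w_max motion-intensity threshold (px/frame) for
#'   `include_incumbent = "auto"`.
#' @return list of class `track_config`.
#' @export
track_config <- function(enhance = TRUE, scales = c(15, 80, 250),
                         clip_percentiles = c(0.01, 0.99),
                         flow_window = 5, flow_sigma = 1, beta = 0.5,
                         n_particles = 100, epsilon = 0.2, spread = NULL,
                         jitter_sd = 1, k_candidates = 10, max_step = 5,
                         ms_iterations = 3, ms_lambda = 1, ms_step_max = 4,
                         ms_window_scale = 2, cnn_smooth = 2,
                         use_cnn = TRUE, cnn_epochs = 40, cnn_n_pos = 12,
                         cnn_n_neg = 12, cnn_lr = 0.05, pos_jitter = 1,
                         augment_times = 1,
                         update_interval = 0, update_epochs = 4,
                         update_score = 0.4,
                         patch_size = c(32, 32), include_incumbent = "auto",
                         incumbent_w_max = 0.05) {
  structure(list(enhance = enhance, scales = scales,
                 clip_percentiles = clip_percentiles,
                 flow_window = flow_window, flow_sigma = flow_sigma,
                 beta = beta, n_particles = n_particles, epsilon = epsilon,
                 spread = spread, jitter_sd = jitter_sd,
                 k_candidates = k_candidates, max_step = max_step,
                 ms_iterations = ms_iterations, ms_lambda = ms_lambda,
                 ms_step_max = ms_step_max, ms_window_scale = ms_window_scale,
                 cnn_smooth = cnn_smooth,
                 use_cnn = use_cnn,
                 cnn_epochs = cnn_epochs, cnn_n_pos = cnn_n_pos,
                 cnn_n_neg = cnn_n_neg, cnn_lr = cnn_lr,
                 pos_jitter = pos_jitter, augment_times = augment_times,
                 update_interval = update_interval,
                 update_epochs = update_epochs, update_score = update_score,
                 patch_size = patch_size,
                 include_incumbent = include_incumbent,
                 incumbent_w_max = incumbent_w_max),
            class = "track_config")
}

#' Track a lesion through a frame sequence
#'
#' Runs the full per-frame loop: MSRCP enhancement, value-channel feature
#' extraction, dense Lucas-Kanade flow against the previous frame, particle
#' propagation by the flow model's mean velocity, flow-similarity weighting,
#' candidate extraction, CNN classification of the candidates, position
#' selection, flow-model update over the selected region, and systematic
#' resampling. The first frame's entry is the manual annotation itself; the
#' classifier is trained once on that annotation. The whole run is
#' deterministic under a fixed seed.
#'
#' @param frames a `ceus_sequence`, or a list of frames (matrices / RGB
#'   arrays) on the `[0, 255]` scale.
#' @param init_box the manually annotated `ceus_box` on the first frame.
#' @param config a [track_config()].
#' @param seed integer seed covering particle initialization, classifier
#'   initialization, training augmentation and resampling.
#' @param verbose print per-frame diagnostics.
#' @return a data.frame of class `ceus_trajectory` with columns
#'   `frame, row, col, height, width, score` (score is the winning candidate's
#'   classifier probability, `NA` on the annotated first frame and in the
#'   flow-only ablation).
#' @export
track_lesion <- function(frames, init_box, config = track_config(),
                         seed = 1L, verbose = FALSE) {
  if (inherits(frames, "ceus_sequence")) frames <- frames$frames
  n <- length(frames)
  if (n < 1) stop("empty sequence")
  fs <- frame_shape(frames[[1]])
  init_box <- ceus_box(init_box[1], init_box[2], init_box[3], init_box[4])
  if (!box_in_frame(init_box, fs)) stop("init_box must lie inside frame 1")
  set.seed(seed)

  # the percentile stretch is computed once, on the first frame, and frozen
  # for the sequence: a per-frame stretch flickers as the lesion moves, and
  # the flow solver reads that flicker as global apparent motion
  msrcp_range <- NULL
  prep <- function(f) {
    if (config$enhance) {
      f <- msrcp_enhance(f, config$scales, config$clip_percentiles,
                         clip_range = msrcp_range)
      if (is.null(msrcp_range))
        msrcp_range <<- attr(f, "msrcp_range")
    }
    g <- frame_gray(f)
    attributes(g) <- attributes(g)["dim"]
    g
  }

  feat_prev <- prep(frames[[1]])
  despeckle <- function(m)
    if (config$cnn_smooth > 0) gaussian_blur(m, config$cnn_smooth) else m
  cnn_img <- despeckle(feat_prev)
  traj <- data.frame(frame = seq_len(n), row = NA_real_, col = NA_real_,
                     height = unname(init_box[3]), width = unname(init_box[4]),
                     score = NA_real_)
  traj[1, c("row", "col")] <- init_box[1:2]

  classifier <- NULL
  pos_anchor <- neg_anchor <- NULL    # first-frame patches, kept for adaptation
  if (config$use_cnn && n > 1) {
    tp <- training_patches(cnn_img,
                           init_box, n_pos = config$cnn_n_pos,
                           n_neg = config$cnn_n_neg,
                           max_shift = config$pos_jitter,
                           out_size = config$patch_size)
    pos_anchor <- tp$positives
    neg_anchor <- tp$negatives
    pos <- c(tp$positives, augment_patches(tp$positives, config$augment_times,
                                           noise_sd = 0.15, grain = 2))
    neg <- c(tp$negatives, augment_patches(tp$negatives, config$augment_times,
                                           noise_sd = 0.15, grain = 2))
    classifier <- train_classifier(pos, neg,
                                   epochs = config$cnn_epochs,
                                   lr = config$cnn_lr, input_norm = "zscore",
                                   seed = sample.int(.Machine$integer.max, 1))
  }

  pset <- init_particles(init_box, fs, n = config$n_particles,
                         spread = config$spread, epsilon = config$epsilon,
                         jitter_sd = config$jitter_sd)
  fmodel <- flow_model(config$beta)
  box <- init_box

  for (s in seq_len(n)[-1]) {
    if (!all(frame_shape(frames[[s]]) == fs))
      stop(sprintf("frame %d has mismatched shape", s))
    feat <- prep(frames[[s]])
    cnn_img <- despeckle(feat)
    flow <- compute_flow(feat_prev, feat, window = config$flow_window,
                         sigma = config$flow_sigma)

    # predict: advect each particle by the local flow at its position (so
    # particles riding the lesion move with it while background particles
    # stay put — the static-background motion model of CEUS speckle), then
    # mean-shift each particle onto the local motion-energy centroid
    pset$centers <- pset$centers + flow_at(flow, pset$centers)
    if (config$ms_iterations > 0)
      pset$centers <- flow_mean_shift(flow, pset$centers,
                                      config$ms_window_scale * pset$box_size,
                                      iterations = config$ms_iterations,
                                      lambda = config$ms_lambda,
                                      step_max = config$ms_step_max)
    pset$centers <- clip_centers(pset$centers, pset$box_size, fs)

    # before the first model update, bootstrap the reference flow from the
    # annotated box's own regional flow
    ref_model <- if (fmodel$initialized) fmodel else
      flow_model(config$beta, h = region_flow(flow, box)[1:2])
    pset <- weigh_particles(pset, ref_model, flow)
    cands <- candidates(pset, k = min(config$k_candidates, config$n_particles))

    # search-radius gate: drop candidates implying implausible per-frame jumps
    if (is.finite(config$max_step) && length(cands$boxes) > 0) {
      ctr <- box_center(box)
      d <- sqrt((cands$centers[, 1] - ctr[1])^2 + (cands$centers[, 2] - ctr[2])^2)
      keep <- if (any(d <= config$max_step)) which(d <= config$max_step)
              else which.min(d)
      cands$boxes <- cands$boxes[keep]
      cands$centers <- cands$centers[keep, , drop = FALSE]
      cands$weights <- cands$weights[keep]
      cands$index <- cands$index[keep]
    }

    if (config$use_cnn && length(cands$boxes) > 0) {
      inc <- config$include_incumbent
      add_inc <- isTRUE(inc) ||
        (identical(inc, "auto") &&
           (!fmodel$initialized || fmodel$w < config$incumbent_w_max))
      if (add_inc) {
        cands$boxes <- c(cands$boxes, list(box))
        cands$centers <- rbind(cands$centers, box_center(box))
        cands$weights <- c(cands$weights, 0)  # wins only on strictly higher score
        cands$index <- c(cands$index, 0L)
      }
      scored <- classify_candidates(classifier, cands, cnn_img)
      box <- scored$boxes[[1]]
      traj$score[s] <- scored$scores[1]
    } else if (length(cands$boxes) > 0) {
      box <- cands$boxes[[1]]        # argmax-weight particle (ablation)
    } else {
      warning(sprintf("frame %d: empty candidate set; carrying box forward", s))
    }
    traj[s, c("row", "col")] <- box[1:2]

    rf <- region_flow(flow, box)
    fmodel <- update_flow_model(fmodel, rf, z = box[3] * box[4])

    pset <- resample_particles(pset)

    # online adaptation: periodically refresh the classifier with patches from
    # the current frame around the (trusted) selected position
    if (config$use_cnn && config$update_interval > 0 &&
        s %% config$update_interval == 0 &&
        !is.na(traj$score[s]) && traj$score[s] >= config$update_score) {
      up <- training_patches(cnn_img, box, n_pos = 8, n_neg = 8,
                             out_size = config$patch_size)
      classifier <- update_classifier(classifier,
                                      c(pos_anchor, up$positives),
                                      c(neg_anchor, up$negatives),
                                      epochs = config$update_epochs)
    }

    if (verbose)
      message(sprintf("frame %3d: box (%g,%g) score %.3f w %.3f",
                      s, box[1], box[2], traj$score[s], fmodel$w))
    feat_prev <- feat
  }
  structure(traj, class = c("ceus_trajectory", "data.frame"),
            config = config, seed = seed)
}

#' @export
print.ceus_trajectory <- function(x, ...) {
  cat(sprintf("<ceus_trajectory: %d frames, %gx%g box>\n",
              nrow(x), x$height[1], x$width[1]))
  print.data.frame(utils::head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat(sprintf("... %d more frames\n", nrow(x) - 5))
  invisible(x)
}

#' @export
summary.ceus_trajectory <- function(object, truth = NULL, frames = NULL, ...) {
  if (!is.null(truth)) return(evaluate_tracking(object, truth, frames))
  path <- sqrt(diff(object$row)^2 + diff(object$col)^2)
  cat(sprintf("Trajectory over %d frames\n", nrow(object)))
  cat(sprintf("  total path length: %.1f px\n", sum(path)))
  cat(sprintf("  mean step: %.2f px, mean score: %.3f\n",
              mean(path), mean(object$score, na.rm = TRUE)))
  invisible(object)
}

#' @export
plot.ceus_trajectory <- function(x, truth = NULL, ...) {
  cr <- x$row + x$height / 2 - 0.5
  cc <- x$col + x$width / 2 - 0.5
  graphics::plot(cc, cr, type = "o", pch = 16, cex = 0.5, col = "forestgreen",
                 xlab = "col (px)", ylab = "row (px)", ylim = rev(range(cr)),
                 main = "tracked center path", ...)
  if (!is.null(truth)) {
    truth <- as.data.frame(truth)
    graphics::lines(truth$center_col, truth$center_row, col = "gray40", lty = 2)
    graphics::legend("topleft", legend = c("tracked", "truth"),
                     col = c("forestgreen", "gray40"), lty = c(1, 2), bty = "n")
  }
  invisible(x)
}
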
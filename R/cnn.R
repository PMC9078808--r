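# Small convolutional classifier that scores candidate regions.
#
# Architecture: 3x3 conv (8 filters) -> ReLU -> 2x2 max-pool -> 3x3 conv
# (16 filters) -> ReLU -> 2x2 max-pool -> dense 64 (ReLU) -> dense 2 ->
# softmax. Trained per sequence on augmented crops of the annotated first
# frame and adapted online during tracking; small enough that full-batch
# gradient descent on a CPU converges in seconds. Forward and backward passes
# are written out explicitly and batched (im2col convolutions over the whole
# patch batch), which keeps the classifier dependency-free and bit-exactly
# reproducible under a fixed seed.

# ---- batched low-level layers ----------------------------------------------
# batch layout: (H, W, C, N)

# returns (H-2)(W-2)N x 9C matrix; rows ordered (i, j) within each sample n
im2col3 <- function(x) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  out <- matrix(0, (H - 2) * (W - 2) * N, 9 * C)
  k <- 1
  for (ch in seq_len(C)) {
    for (dj in 0:2) {
      for (di in 0:2) {
        out[, k] <- as.vector(x[(1 + di):(H - 2 + di), (1 + dj):(W - 2 + dj), ch, ])
        k <- k + 1
      }
    }
  }
  out
}

conv3_forward <- function(x, W, b) {
  d <- dim(x)
  cols <- im2col3(x)
  out <- sweep(cols %*% W, 2, b, "+")
  # (H-2, W-2, N, F) -> (H-2, W-2, F, N)
  out <- aperm(array(out, c(d[1] - 2, d[2] - 2, d[4], length(b))), c(1, 2, 4, 3))
  list(out = out, cols = cols)
}

conv3_backward <- function(dout, cols, W, x_dim) {
  H <- x_dim[1]; W_ <- x_dim[2]; C <- x_dim[3]; N <- x_dim[4]
  F_ <- dim(dout)[3]
  dm <- matrix(aperm(dout, c(1, 2, 4, 3)), (H - 2) * (W_ - 2) * N, F_)
  dW <- crossprod(cols, dm)
  db <- colSums(dm)
  dcols <- tcrossprod(dm, W)
  dx <- array(0, x_dim)
  k <- 1
  for (ch in seq_len(C)) {
    for (dj in 0:2) {
      for (di in 0:2) {
        dx[(1 + di):(H - 2 + di), (1 + dj):(W_ - 2 + dj), ch, ] <-
          dx[(1 + di):(H - 2 + di), (1 + dj):(W_ - 2 + dj), ch, ] +
          array(dcols[, k], c(H - 2, W_ - 2, N))
        k <- k + 1
      }
    }
  }
  list(dx = dx, dW = dW, db = db)
}

# 2x2 max pooling, stride 2; odd trailing row/col cropped
pool2_forward <- function(x) {
  d <- dim(x); H2 <- d[1] %/% 2; W2 <- d[2] %/% 2
  ro <- seq(1, 2 * H2, 2); co <- seq(1, 2 * W2, 2)
  a <- x[ro, co, , , drop = FALSE];      b <- x[ro + 1, co, , , drop = FALSE]
  cc <- x[ro, co + 1, , , drop = FALSE]; dd <- x[ro + 1, co + 1, , , drop = FALSE]
  mx <- pmax(a, b, cc, dd)
  m1 <- (a == mx); m2 <- (b == mx) & !m1
  m3 <- (cc == mx) & !m1 & !m2; m4 <- (dd == mx) & !m1 & !m2 & !m3
  list(out = mx, masks = list(m1, m2, m3, m4), x_dim = d)
}

pool2_backward <- function(dout, cache) {
  d <- cache$x_dim; H2 <- dim(dout)[1]; W2 <- dim(dout)[2]
  ro <- seq(1, 2 * H2, 2); co <- seq(1, 2 * W2, 2)
  dx <- array(0, d)
  dx[ro, co, , ] <- dout * cache$masks[[1]]
  dx[ro + 1, co, , ] <- dout * cache$masks[[2]]
  dx[ro, co + 1, , ] <- dout * cache$masks[[3]]
  dx[ro + 1, co + 1, , ] <- dout * cache$masks[[4]]
  dx
}

# ---- network ---------------------------------------------------------------

cnn_init <- function(patch_size = c(32, 32), f1 = 8, f2 = 16, hidden = 64,
                     seed = 1L) {
  set.seed(seed)
  p1 <- (patch_size - 2) %/% 2          # after conv1+pool
  p2 <- (p1 - 2) %/% 2                  # after conv2+pool
  nflat <- p2[1] * p2[2] * f2
  he <- function(nin, nr, nc) matrix(stats::rnorm(nr * nc, 0, sqrt(2 / nin)), nr, nc)
  list(W1 = he(9, 9, f1), b1 = numeric(f1),
       W2 = he(9 * f1, 9 * f1, f2), b2 = numeric(f2),
       W3 = he(nflat, hidden, nflat), b3 = numeric(hidden),
       W4 = he(hidden, 2, hidden), b4 = numeric(2),
       dims = list(patch_size = patch_size, f1 = f1, f2 = f2,
                   hidden = hidden, nflat = nflat))
}

# patches: list of H x W matrices -> (H, W, 1, N) batch
stack_patches <- function(patches) {
  d <- dim(patches[[1]])
  array(unlist(patches, use.names = FALSE), c(d[1], d[2], 1, length(patches)))
}

# per-patch input normalization applied before the network
norm_patches <- function(patches, input_norm) {
  if (input_norm == "none") return(patches)
  lapply(patches, function(p) (p - mean(p)) / (stats::sd(p) + 1e-3))
}

# forward pass over a batch; returns 2 x N probability matrix
cnn_forward <- function(params, batch, keep_cache = FALSE) {
  N <- dim(batch)[4]
  c1 <- conv3_forward(batch, params$W1, params$b1)
  a1 <- pmax(c1$out, 0)
  p1 <- pool2_forward(a1)
  c2 <- conv3_forward(p1$out, params$W2, params$b2)
  a2 <- pmax(c2$out, 0)
  p2 <- pool2_forward(a2)
  flat <- matrix(p2$out, ncol = N)          # nflat x N
  z3 <- params$W3 %*% flat + params$b3
  a3 <- pmax(z3, 0)
  z4 <- params$W4 %*% a3 + params$b4
  z4 <- sweep(z4, 2, apply(z4, 2, max), "-")
  e <- exp(z4)
  prob <- sweep(e, 2, colSums(e), "/")
  if (!keep_cache) return(list(prob = prob))
  list(prob = prob, batch = batch, c1 = c1, p1 = p1, c2 = c2, p2 = p2,
       flat = flat, a3 = a3)
}

# batched backward pass; labels in {1, 2}; returns mean gradients
cnn_backward <- function(params, cache, labels, label_smoothing = 0) {
  N <- length(labels)
  target <- matrix(label_smoothing, 2, N)
  target[cbind(labels, seq_len(N))] <- 1 - label_smoothing
  dz4 <- (cache$prob - target) / N
  dW4 <- tcrossprod(dz4, cache$a3); db4 <- rowSums(dz4)
  da3 <- crossprod(params$W4, dz4)
  dz3 <- da3 * (cache$a3 > 0)
  dW3 <- tcrossprod(dz3, cache$flat); db3 <- rowSums(dz3)
  dflat <- crossprod(params$W3, dz3)
  dp2 <- array(dflat, dim(cache$p2$out))
  da2 <- pool2_backward(dp2, cache$p2)
  dc2 <- da2 * (cache$c2$out > 0)
  g2 <- conv3_backward(dc2, cache$c2$cols, params$W2, dim(cache$p1$out))
  dp1 <- pool2_backward(g2$dx, cache$p1)
  dc1 <- dp1 * (cache$c1$out > 0)
  g1 <- conv3_backward(dc1, cache$c1$cols, params$W1, dim(cache$batch))
  list(W1 = g1$dW, b1 = g1$db, W2 = g2$dW, b2 = g2$db,
       W3 = dW3, b3 = db3, W4 = dW4, b4 = db4)
}

# gradient-descent-with-momentum loop shared by initial training and online
# adaptation; returns updated params and per-epoch mean losses
cnn_train_loop <- function(params, vel, patches, labels, epochs, lr, momentum,
                           label_smoothing, weight_decay) {
  batch <- stack_patches(patches)
  nms <- names(vel)
  loss_history <- numeric(epochs)
  idx <- cbind(labels, seq_along(labels))
  for (ep in seq_len(epochs)) {
    fw <- cnn_forward(params, batch, keep_cache = TRUE)
    loss_history[ep] <- -mean(log(pmax(t(fw$prob)[idx[, 2:1, drop = FALSE]], 1e-12)))
    g <- cnn_backward(params, fw, labels, label_smoothing)
    for (nm in nms) {
      vel[[nm]] <- momentum * vel[[nm]] - lr * (g[[nm]] + weight_decay * params[[nm]])
      params[[nm]] <- params[[nm]] + vel[[nm]]
    }
  }
  list(params = params, vel = vel, loss_history = loss_history)
}

# ---- user-facing operations ------------------------------------------------

#' Scale-normalize a candidate region to a fixed patch
#'
#' Crops the region from the frame and bilinearly resamples it to a common
#' patch size so candidates of any box size feed the same network; intensities
#' are rescaled from `[0, 255]` to `[0, 1]`. A region already at the target
#' size is cropped without resampling.
#'
#' @param frame image (matrix or RGB array; RGB is collapsed to its value
#'   channel).
#' @param region a `ceus_box` inside the frame.
#' @param out_size `c(rows, cols)` of the output patch.
#' @return `out_size` matrix in `[0, 1]`.
#' @export
normalize_patch <- function(frame, region, out_size = c(32, 32)) {
  if (region[3] < 1 || region[4] < 1) stop("degenerate (zero-area) region")
  g <- frame_gray(frame)
  if (!box_in_frame(region, dim(g))) stop("region outside frame")
  crop <- crop_box(g, region)
  if (all(dim(crop) == out_size)) return(crop / 255)
  EBImage::resize(crop, w = out_size[1], h = out_size[2], filter = "bilinear") / 255
}

# intersection-over-union of two ceus_box / c(row,col,h,w) vectors
box_iou <- function(a, b) {
  ih <- max(0, min(a[1] + a[3], b[1] + b[3]) - max(a[1], b[1]))
  iw <- max(0, min(a[2] + a[4], b[2] + b[4]) - max(a[2], b[2]))
  inter <- ih * iw
  inter / (a[3] * a[4] + b[3] * b[4] - inter)
}

#' Build a training set of lesion and background patches
#'
#' Positives are crops whose boxes are small random shifts of the annotated
#' target with IoU at least `pos_iou`; negatives are same-size background
#' crops with IoU at most `neg_iou`. Half the negatives (on average) are drawn
#' from the neighbourhood of the target (centers Gaussian around it), so the
#' classifier sees hard near-misses, the rest uniformly over the frame. The
#' unshifted target crop is always included as a positive.
#'
#' @param frame the annotated frame.
#' @param target the annotated `ceus_box`.
#' @param n_pos,n_neg number of positive/negative patches.
#' @param pos_iou,neg_iou IoU thresholds for the two classes.
#' @param max_shift largest positive jitter (px per axis); defaults to a
#'   quarter of the smaller box side. Tighter jitter makes the classifier's
#'   score peak more sharply at the true center.
#' @param out_size patch size fed to the network.
#' @param seed optional RNG seed.
#' @return list with `positives` and `negatives`, each a list of patches.
#' @export
training_patches <- function(frame, target, n_pos = 24, n_neg = 24,
                             pos_iou = 0.7, neg_iou = 0.3, max_shift = NULL,
                             out_size = c(32, 32), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- frame_gray(frame)
  fs <- dim(g)
  ctr <- box_center(target)
  diag <- sqrt(target[3]^2 + target[4]^2)
  pos_boxes <- list(target)
  if (is.null(max_shift))
    max_shift <- max(2, ceiling(min(target[3], target[4]) * 0.25))
  guard <- 0
  while (length(pos_boxes) < n_pos && guard < 10000) {
    guard <- guard + 1
    dr <- sample(-max_shift:max_shift, 1); dc <- sample(-max_shift:max_shift, 1)
    b <- ceus_box(target[1] + dr, target[2] + dc, target[3], target[4])
    if (box_in_frame(b, fs) && box_iou(target, b) >= pos_iou)
      pos_boxes[[length(pos_boxes) + 1]] <- b
  }
  neg_boxes <- list(); guard <- 0
  while (length(neg_boxes) < n_neg && guard < 20000) {
    guard <- guard + 1
    if (stats::runif(1) < 0.5) {        # hard negative near the target
      cand <- c(ctr[1] + stats::rnorm(1, 0, diag), ctr[2] + stats::rnorm(1, 0, diag))
      r <- round(cand[1] - target[3] / 2 + 0.5); c <- round(cand[2] - target[4] / 2 + 0.5)
    } else {                            # anywhere in the frame
      r <- sample(seq_len(fs[1] - target[3] + 1), 1)
      c <- sample(seq_len(fs[2] - target[4] + 1), 1)
    }
    if (r < 1 || c < 1 || r + target[3] - 1 > fs[1] || c + target[4] - 1 > fs[2]) next
    b <- ceus_box(r, c, target[3], target[4])
    if (box_iou(target, b) <= neg_iou) neg_boxes[[length(neg_boxes) + 1]] <- b
  }
  if (length(neg_boxes) == 0) stop("could not sample background (negative) boxes")
  list(positives = lapply(pos_boxes, function(b) normalize_patch(g, b, out_size)),
       negatives = lapply(neg_boxes, function(b) normalize_patch(g, b, out_size)))
}

#' Augment patches with speckle-like appearance perturbations
#'
#' Each augmented copy applies a random global gain and a smooth multiplicative
#' noise field (a blurred Gaussian field), emulating how the same lesion looks
#' over different speckle realizations; output clipped to `[0, 1]`.
#'
#' @param patches list of patches in `[0, 1]`.
#' @param times augmented copies per input patch.
#' @param gain_range range of the uniform global gain.
#' @param noise_sd relative amplitude of the multiplicative field.
#' @param grain blur sigma (px) of the noise field.
#' @return list of `length(patches) * times` augmented patches.
#' @export
augment_patches <- function(patches, times = 1, gain_range = c(0.8, 1.2),
                            noise_sd = 0.3, grain = 1.2) {
  out <- vector("list", length(patches) * times)
  k <- 1
  for (t in seq_len(times)) {
    for (p in patches) {
      g <- gaussian_blur(matrix(stats::rnorm(length(p)), nrow(p), ncol(p)), grain)
      g <- g / stats::sd(g)
      gain <- stats::runif(1, gain_range[1], gain_range[2])
      out[[k]] <- pmin(pmax(p * gain * (1 + noise_sd * g), 0), 1)
      k <- k + 1
    }
  }
  out
}

#' Train the candidate-region classifier
#'
#' Full-batch gradient descent with momentum on the softmax cross-entropy of
#' positive (lesion) vs negative (background) patches. Deterministic under a
#' fixed seed (initialization is the only random step).
#'
#' @param positives,negatives lists of patches (matrices in `[0, 1]`, all the
#'   same size), e.g. from [training_patches()].
#' @param epochs training epochs.
#' @param lr learning rate.
#' @param momentum momentum coefficient.
#' @param label_smoothing fraction of the one-hot target mass moved to the
#'   other class; keeps scores graded instead of saturating at 0/1, so that
#'   ranking candidates by score stays informative.
#' @param weight_decay L2 penalty coefficient.
#' @param input_norm `"none"` feeds raw `[0, 1]` patches; `"zscore"`
#'   standardizes each patch to zero mean / unit sd before the network, making
#'   scores invariant to local brightness and gain (the tracker's setting:
#'   on speckle backgrounds the lesion signature is its centered dark blob
#'   relative to its surround, not its absolute brightness).
#' @param seed seed for weight initialization.
#' @return object of class `dcnn_classifier`: network parameters, the patch
#'   size, and the per-epoch `loss_history`.
#' @export
train_classifier <- function(positives, negatives, epochs = 60, lr = 0.05,
                             momentum = 0.9, label_smoothing = 0.05,
                             weight_decay = 1e-4, input_norm = c("none", "zscore"),
                             seed = 1L) {
  if (length(positives) < 1 || length(negatives) < 1)
    stop("need at least one patch in each class")
  input_norm <- match.arg(input_norm)
  patches <- norm_patches(c(positives, negatives), input_norm)
  labels <- c(rep(1L, length(positives)), rep(2L, length(negatives)))
  psz <- dim(patches[[1]])
  params <- cnn_init(patch_size = psz, seed = seed)
  vel <- lapply(params[names(params) != "dims"], function(p) p * 0)
  fit <- cnn_train_loop(params, vel, patches, labels, epochs, lr, momentum,
                        label_smoothing, weight_decay)
  structure(list(params = fit$params, vel = fit$vel, patch_size = psz,
                 loss_history = fit$loss_history, input_norm = input_norm,
                 hyper = list(lr = lr, momentum = momentum,
                              label_smoothing = label_smoothing,
                              weight_decay = weight_decay),
                 n_pos = length(positives), n_neg = length(negatives)),
            class = "dcnn_classifier")
}

#' Adapt a trained classifier to new patches
#'
#' Continues gradient descent from the current weights for a few epochs on a
#' fresh patch set — the online (per-sequence) adaptation step of the tracker.
#' Momentum is reset; the other hyperparameters are carried over from
#' training.
#'
#' @param model a `dcnn_classifier`.
#' @param positives,negatives patch lists.
#' @param epochs adaptation epochs.
#' @param lr learning rate; defaults to the training rate.
#' @return the updated `dcnn_classifier` (loss history appended).
#' @export
update_classifier <- function(model, positives, negatives, epochs = 4,
                              lr = NULL) {
  stopifnot(inherits(model, "dcnn_classifier"))
  if (is.null(lr)) lr <- model$hyper$lr
  patches <- norm_patches(c(positives, negatives), model$input_norm)
  labels <- c(rep(1L, length(positives)), rep(2L, length(negatives)))
  vel <- lapply(model$vel, function(p) p * 0)
  fit <- cnn_train_loop(model$params, vel, patches, labels, epochs, lr,
                        model$hyper$momentum, model$hyper$label_smoothing,
                        model$hyper$weight_decay)
  model$params <- fit$params
  model$loss_history <- c(model$loss_history, fit$loss_history)
  model
}

#' @export
print.dcnn_classifier <- function(x, ...) {
  cat(sprintf(paste0("<dcnn_classifier: %dx%d patches, %d+%d training patches, ",
                     "final loss %.4f>\n"),
              x$patch_size[1], x$patch_size[2], x$n_pos, x$n_neg,
              x$loss_history[length(x$loss_history)]))
  invisible(x)
}

#' Score patches with the classifier
#'
#' @param model a `dcnn_classifier`.
#' @param patch a patch matrix in `[0, 1]` at the model's patch size, or a
#'   list of such patches.
#' @return probability (vector) in `[0, 1]` that each patch is the lesion
#'   (positive class).
#' @export
cnn_score <- function(model, patch) {
  if (is.matrix(patch)) patch <- list(patch)
  patch <- norm_patches(patch, model$input_norm)
  unname(cnn_forward(model$params, stack_patches(patch))$prob[1, ])
}

#' Classify candidate regions
#'
#' Scores every candidate region with the trained network (a pure function of
#' the pixels: identical regions get identical scores) and returns the set
#' sorted by descending score; score ties are broken by higher particle
#' weight, then by lower candidate index.
#'
#' @param model a `dcnn_classifier`.
#' @param cands a `candidate_set` from [candidates()].
#' @param frame the current frame.
#' @return the `candidate_set` reordered, with a `scores` field added.
#' @export
classify_candidates <- function(model, cands, frame) {
  if (length(cands$boxes) == 0) stop("empty candidate set")
  g <- frame_gray(frame)
  patches <- lapply(cands$boxes, function(b) normalize_patch(g, b, model$patch_size))
  scores <- cnn_score(model, patches)
  ord <- order(-scores, -cands$weights, seq_along(scores))
  structure(list(boxes = cands$boxes[ord],
                 centers = cands$centers[ord, , drop = FALSE],
                 weights = cands$weights[ord],
                 index = cands$index[ord],
                 scores = scores[ord]),
            class = "candidate_set")
}
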
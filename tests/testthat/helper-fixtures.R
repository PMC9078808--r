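# shared fixtures, all generated in code

# small default-style scene, cheap enough for unit tests
small_scene <- function(seed = 1, n_frames = 10, ...) {
  ceus_scene(frame_shape = c(64, 64), n_frames = n_frames,
             lesion_axes = c(7, 5),
             trajectory = list(type = "linear", start = c(26, 22),
                               velocity = c(0.3, 0.6)),
             seed = seed, ...)
}

# speckle-like textured pattern for flow oracles
textured_pattern <- function(n = 120, grain = 1.5, seed = 42) {
  set.seed(seed)
  g <- matrix(rnorm(n * n), n, n)
  sm <- ceustrack:::gaussian_blur(g, grain)
  130 * (0.5 + (sm - min(sm)) / diff(range(sm)))
}

# circular shift: content moves by (dr, dc) pixels (periodic boundary)
shift_image <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  m[((seq_len(nr) - 1 - dr) %% nr) + 1, ((seq_len(nc) - 1 - dc) %% nc) + 1]
}

# brute-force IoU by enumerating pixel sets
pixel_iou <- function(a, b) {
  pa <- outer((a[1]):(a[1] + a[3] - 1), (a[2]):(a[2] + a[4] - 1),
              function(r, c) paste(r, c))
  pb <- outer((b[1]):(b[1] + b[3] - 1), (b[2]):(b[2] + b[4] - 1),
              function(r, c) paste(r, c))
  inter <- length(intersect(pa, pb))
  inter / (length(pa) + length(pb) - inter)
}

random_box <- function(frame_shape = c(50, 50), max_size = 15) {
  h <- sample(1:max_size, 1); w <- sample(1:max_size, 1)
  r <- sample(1:(frame_shape[1] - h), 1); c <- sample(1:(frame_shape[2] - w), 1)
  ceus_box(r, c, h, w)
}

# separable toy patches: bright vs dark
toy_patches <- function(n_each = 6, size = 32, seed = 5) {
  set.seed(seed)
  list(positives = lapply(seq_len(n_each),
                          function(i) matrix(runif(size^2, 0.6, 1), size, size)),
       negatives = lapply(seq_len(n_each),
                          function(i) matrix(runif(size^2, 0, 0.4), size, size)))
}
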
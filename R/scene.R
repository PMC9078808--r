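#' Scene configuration for synthetic CEUS sequences
#'
#' Describes an ultrasound-like scene: a multiplicative-speckle background and
#' a hypoechoic (darker than background) elliptical lesion moving along a
#' parameterized trajectory, with an optional global gain curve emulating
#' contrast wash-in. The defaults define the package's standard synthetic
#' benchmark: a 96x96-pixel, 50-frame sequence with a 9x6-pixel (semi-axes)
#' lesion at 50% contrast translating at under a pixel per frame through
#' moderate speckle.
#'
#' @param frame_shape integer `c(rows, cols)` frame size in pixels.
#' @param n_frames number of frames.
#' @param lesion_axes numeric `c(semi_row, semi_col)` lesion semi-axes, pixels.
#' @param lesion_contrast fraction in `[0, 1)`: lesion interior mean intensity
#'   is `background mean * (1 - lesion_contrast)`.
#' @param trajectory a list with `$type` one of `"linear"`, `"sinusoidal"`,
#'   `"random_walk"`; `$start = c(row, col)` starting center; for linear,
#'   `$velocity = c(drow, dcol)` px/frame; for sinusoidal, additionally
#'   `$amplitude` (px) and `$period` (frames) of a transverse (row) oscillation
#'   superimposed on the linear drift; for random_walk, `$step_sd` px/frame.
#' @param speckle_scale dimensionless speckle strength in `[0, 1]`: 0 gives a
#'   noise-free background, 1 a fully developed squared-Gaussian speckle field.
#' @param speckle_grain correlation length (Gaussian blur sigma, px) of the
#'   speckle field; controls grain size.
#' @param base_intensity mean background gray level (8-bit scale).
#' @param wash_in `NULL`, or a numeric vector of length `n_frames` of global
#'   intensity gains (e.g. from [wash_in_curve()]).
#' @param edge_width fraction of the lesion radius over which the lesion edge
#'   rolls off (raised-cosine profile).
#' @param frame_noise_sd standard deviation (gray levels) of independent
#'   additive per-frame noise; 0 keeps the speckle pattern static, the
#'   behaviour of tissue speckle under a stationary probe.
#' @param channels 1 for grayscale frames (matrices), 3 to replicate the gray
#'   frame into an RGB array so color-pipeline code paths are exercisable.
#' @param seed RNG seed used by [generate_sequence()].
#' @return a list of class `ceus_scene_config`.
#' @seealso [generate_sequence()]
#' @export
ceus_scene <- function(frame_shape = c(96, 96),
                       n_frames = 50,
                       lesion_axes = c(9, 6),
                       lesion_contrast = 0.5,
                       trajectory = list(type = "linear",
                                         start = c(34, 28),
                                         velocity = c(0.35, 0.7)),
                       speckle_scale = 0.4,
                       speckle_grain = 1.2,
                       base_intensity = 130,
                       wash_in = NULL,
                       edge_width = 0.35,
                       frame_noise_sd = 0,
                       channels = 1,
                       seed = 1L) {
  stopifnot(length(frame_shape) == 2, all(frame_shape >= 8),
            n_frames >= 1, length(lesion_axes) == 2, all(lesion_axes > 0),
            lesion_contrast >= 0, lesion_contrast < 1,
            speckle_scale >= 0, speckle_scale <= 1,
            channels %in% c(1, 3))
  if (!is.list(trajectory) || is.null(trajectory$type))
    stop("trajectory must be a list with a $type field")
  if (!trajectory$type %in% c("linear", "sinusoidal", "random_walk"))
    stop("unknown trajectory type: ", trajectory$type)
  if (!is.null(wash_in) && length(wash_in) != n_frames)
    stop("wash_in must have one gain per frame")
  structure(list(frame_shape = as.integer(frame_shape), n_frames = as.integer(n_frames),
                 lesion_axes = lesion_axes, lesion_contrast = lesion_contrast,
                 trajectory = trajectory, speckle_scale = speckle_scale,
                 speckle_grain = speckle_grain, base_intensity = base_intensity,
                 wash_in = wash_in, edge_width = edge_width,
                 frame_noise_sd = frame_noise_sd, channels = channels,
                 seed = as.integer(seed)),
            class = "ceus_scene_config")
}

#' Contrast wash-in gain curve
#'
#' A saturating-exponential global gain emulating the intensity rise after
#' contrast-agent arrival: `gain(t) = 1 + amplitude * (1 - exp(-t / tau))`.
#'
#' @param n_frames number of frames.
#' @param amplitude peak fractional gain increase.
#' @param tau time constant in frames.
#' @return numeric vector of per-frame gains, length `n_frames`.
#' @export
wash_in_curve <- function(n_frames, amplitude = 0.3, tau = 10) {
  t <- seq_len(n_frames) - 1
  1 + amplitude * (1 - exp(-t / tau))
}

# analytic lesion-center trajectory; returns n_frames x 2 matrix (row, col).
# random_walk draws from the current RNG stream.
trajectory_centers <- function(config) {
  tr <- config$trajectory
  n <- config$n_frames
  t <- seq_len(n) - 1
  if (tr$type == "linear") {
    cbind(tr$start[1] + t * tr$velocity[1], tr$start[2] + t * tr$velocity[2])
  } else if (tr$type == "sinusoidal") {
    amp <- if (is.null(tr$amplitude)) 4 else tr$amplitude
    per <- if (is.null(tr$period)) 20 else tr$period
    vel <- if (is.null(tr$velocity)) c(0, 0.7) else tr$velocity
    cbind(tr$start[1] + t * vel[1] + amp * sin(2 * pi * t / per),
          tr$start[2] + t * vel[2])
  } else { # random_walk
    sd <- if (is.null(tr$step_sd)) 0.5 else tr$step_sd
    steps_r <- c(0, stats::rnorm(n - 1, 0, sd))
    steps_c <- c(0, stats::rnorm(n - 1, 0, sd))
    cbind(tr$start[1] + cumsum(steps_r), tr$start[2] + cumsum(steps_c))
  }
}

# unit-mean multiplicative speckle field: squared zero-mean Gaussian noise,
# low-pass filtered for grain, normalized to mean 1, then blended with the
# constant field 1 by speckle_scale (0 = none, 1 = fully developed).
speckle_field <- function(frame_shape, scale, grain) {
  if (scale <= 0) return(matrix(1, frame_shape[1], frame_shape[2]))
  g <- matrix(stats::rnorm(prod(frame_shape)), frame_shape[1], frame_shape[2])
  g <- gaussian_blur(g, grain)
  s <- g^2
  s <- s / mean(s)
  (1 - scale) + scale * s
}

# raised-cosine ellipse membership: 1 inside, cosine roll-off across the edge
lesion_mask <- function(frame_shape, center, axes, edge_width) {
  r <- matrix(seq_len(frame_shape[1]), frame_shape[1], frame_shape[2])
  c <- matrix(seq_len(frame_shape[2]), frame_shape[1], frame_shape[2], byrow = TRUE)
  rho <- sqrt(((r - center[1]) / axes[1])^2 + ((c - center[2]) / axes[2])^2)
  inner <- 1 - edge_width
  m <- matrix(0, frame_shape[1], frame_shape[2])
  m[rho <= inner] <- 1
  band <- rho > inner & rho < 1
  m[band] <- 0.5 * (1 + cos(pi * (rho[band] - inner) / edge_width))
  m
}

#' Generate a synthetic CEUS sequence with ground truth
#'
#' Renders `config$n_frames` frames: a static multiplicative speckle background
#' (tissue texture under a stationary probe) darkened by a moving hypoechoic
#' ellipse with a smooth raised-cosine edge, optionally rescaled per frame by a
#' wash-in gain and perturbed by additive frame noise. Intensities are clipped
#' to `[0, 255]` and quantized to 8-bit so that in-memory frames round-trip
#' exactly through PNG/TIFF files. The same seed and configuration always
#' reproduce a bit-identical sequence.
#'
#' @param config a [ceus_scene()] configuration.
#' @return a list of class `ceus_sequence` with elements
#'   \describe{
#'     \item{frames}{list of `rows x cols` matrices (or `rows x cols x 3`
#'       arrays when `channels = 3`), gray levels in `[0, 255]`.}
#'     \item{truth}{data.frame of class `ceus_truth`: columns `frame` (1-based),
#'       `row`, `col`, `height`, `width` (integer bounding box) and
#'       `center_row`, `center_col` (exact analytic center).}
#'     \item{config}{the input configuration.}
#'   }
#' @export
generate_sequence <- function(config) {
  stopifnot(inherits(config, "ceus_scene_config"))
  set.seed(config$seed)
  centers <- trajectory_centers(config)

  # box size fixed across frames (rigid lesion)
  h <- 2 * ceiling(config$lesion_axes[1])
  w <- 2 * ceiling(config$lesion_axes[2])
  boxes <- t(apply(centers, 1, function(ct) box_at(ct, c(h, w))))
  ok <- boxes[, 1] >= 1 & boxes[, 2] >= 1 &
    boxes[, 1] + h - 1 <= config$frame_shape[1] &
    boxes[, 2] + w - 1 <= config$frame_shape[2]
  if (!all(ok))
    stop(sprintf("lesion leaves the frame at frame %d (configuration error)",
                 which(!ok)[1]))

  speckle <- speckle_field(config$frame_shape, config$speckle_scale,
                           config$speckle_grain)
  background <- config$base_intensity * speckle

  frames <- vector("list", config$n_frames)
  for (s in seq_len(config$n_frames)) {
    m <- lesion_mask(config$frame_shape, centers[s, ], config$lesion_axes,
                     config$edge_width)
    img <- background * (1 - config$lesion_contrast * m)
    if (!is.null(config$wash_in)) img <- img * config$wash_in[s]
    if (config$frame_noise_sd > 0)
      img <- img + matrix(stats::rnorm(prod(config$frame_shape), 0,
                                       config$frame_noise_sd),
                          config$frame_shape[1], config$frame_shape[2])
    img <- round(pmin(pmax(img, 0), 255))
    if (config$channels == 3) img <- array(rep(img, 3), c(dim(img), 3))
    frames[[s]] <- img
  }

  truth <- data.frame(frame = seq_len(config$n_frames),
                      row = boxes[, 1], col = boxes[, 2],
                      height = h, width = w,
                      center_row = centers[, 1], center_col = centers[, 2])
  class(truth) <- c("ceus_truth", "data.frame")
  structure(list(frames = frames, truth = truth, config = config),
            class = "ceus_sequence")
}

#' @export
print.ceus_sequence <- function(x, ...) {
  cat(sprintf("<ceus_sequence: %d frames of %dx%d, %s trajectory, speckle %.2f>\n",
              x$config$n_frames, x$config$frame_shape[1], x$config$frame_shape[2],
              x$config$trajectory$type, x$config$speckle_scale))
  invisible(x)
}

#' @export
plot.ceus_sequence <- function(x, frame = 1, ...) {
  img <- frame_gray(x$frames[[frame]])
  graphics::image(t(img)[, nrow(img):1], col = grDevices::gray.colors(256, 0, 1),
                  axes = FALSE, asp = nrow(img) / ncol(img),
                  main = sprintf("frame %d", frame), ...)
  invisible(x)
}

#' Write a frame sequence to disk
#'
#' @param sequence a `ceus_sequence` (or plain list of frames).
#' @param path output directory (PNG mode) or `.tif` file (TIFF mode).
#' @param format `"png"` writes zero-padded `frame_0000.png` files (frame 0 is
#'   the first frame); `"tiff"` writes one multi-page TIFF.
#' @return invisibly, the written path.
#' @export
write_frames <- function(sequence, path, format = c("png", "tiff")) {
  format <- match.arg(format)
  frames <- if (inherits(sequence, "ceus_sequence")) sequence$frames else sequence
  norm <- lapply(frames, function(f) f / 255)
  if (format == "png") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_along(norm)) {
      png::writePNG(norm[[i]], file.path(path, sprintf("frame_%04d.png", i - 1)))
    }
  } else {
    tiff::writeTIFF(norm, path, bits.per.sample = 8L)
  }
  invisible(path)
}

#' Read a frame sequence from disk
#'
#' Accepts a directory of PNG frames (sorted by filename) or a multi-page TIFF
#' file. Intensities are returned on the `[0, 255]` scale used throughout the
#' package.
#'
#' @param path directory of `.png` frames or a `.tif`/`.tiff` file.
#' @return list of frame matrices/arrays.
#' @export
read_frames <- function(path) {
  to255 <- function(f) {
    if (length(dim(f)) == 3L && dim(f)[3] == 2L) f <- f[, , 1]       # gray+alpha
    if (length(dim(f)) == 3L && dim(f)[3] == 4L) f <- f[, , 1:3]     # rgba
    f * 255
  }
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
    if (length(files) == 0) stop("no PNG frames found in ", path)
    lapply(files, function(f) to255(png::readPNG(f)))
  } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    lapply(tiff::readTIFF(path, all = TRUE), to255)
  } else stop("path must be a directory of PNGs or a TIFF file")
}

#' Write / read ground-truth and trajectory CSVs
#'
#' The on-disk convention is 0-based row/col with half-open boxes, header
#' `frame,row,col,height,width` (plus extra columns when present, e.g.
#' `score` for tracker output or `center_row,center_col` for ground truth).
#' In-memory objects are 1-based.
#'
#' @param x a data.frame with at least `frame,row,col,height,width` (1-based).
#' @param path CSV path.
#' @return `write_boxes_csv`: invisibly, `path`. `read_boxes_csv`: a 1-based
#'   data.frame.
#' @export
write_boxes_csv <- function(x, path) {
  out <- as.data.frame(x)
  out$frame <- out$frame - 1
  out$row <- out$row - 1
  out$col <- out$col - 1
  if ("center_row" %in% names(out)) {
    out$center_row <- out$center_row - 1
    out$center_col <- out$center_col - 1
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_boxes_csv
#' @export
read_boxes_csv <- function(path) {
  x <- utils::read.csv(path)
  x$frame <- x$frame + 1
  x$row <- x$row + 1
  x$col <- x$col + 1
  if ("center_row" %in% names(x)) {
    x$center_row <- x$center_row + 1
    x$center_col <- x$center_col + 1
  }
  x
}
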
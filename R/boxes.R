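#' Construct an axis-aligned bounding box
#'
#' Boxes are stored as a named numeric vector `c(row, col, height, width)`
#' where `(row, col)` is the 1-based top-left pixel and the box covers the
#' half-open pixel ranges `row .. row + height - 1` and
#' `col .. col + width - 1`. On disk (CSV) the same box is written 0-based.
#'
#' @param row,col 1-based top-left pixel indices.
#' @param height,width box extent in pixels (positive integers).
#' @return a numeric vector of class `ceus_box`.
#' @export
ceus_box <- function(row, col, height, width) {
  b <- c(row = as.numeric(row), col = as.numeric(col),
         height = as.numeric(height), width = as.numeric(width))
  if (any(!is.finite(b))) stop("box fields must be finite")
  if (b["height"] <= 0 || b["width"] <= 0) stop("box height/width must be positive")
  class(b) <- "ceus_box"
  b
}

#' Center of a bounding box
#'
#' @param box a `ceus_box` (or plain `c(row, col, height, width)` vector).
#' @return numeric `c(row, col)` center, on the pixel-index grid (a 3-pixel-tall
#'   box starting at row 1 has center row 2).
#' @export
box_center <- function(box) {
  c(row = unname(box[1] + box[3] / 2 - 0.5),
    col = unname(box[2] + box[4] / 2 - 0.5))
}

#' Build a box of given size centered at a point
#'
#' The top-left corner is rounded to the pixel grid, so the realized center can
#' differ from `center` by up to half a pixel per axis.
#'
#' @param center numeric `c(row, col)`.
#' @param size numeric `c(height, width)`.
#' @return a `ceus_box`.
#' @export
box_at <- function(center, size) {
  ceus_box(round(center[1] - size[1] / 2 + 0.5),
           round(center[2] - size[2] / 2 + 0.5),
           size[1], size[2])
}

# clamp a box so it lies fully inside a frame of shape c(rows, cols)
clip_box <- function(box, frame_shape) {
  r <- min(max(box[1], 1), frame_shape[1] - box[3] + 1)
  c <- min(max(box[2], 1), frame_shape[2] - box[4] + 1)
  ceus_box(r, c, box[3], box[4])
}

box_in_frame <- function(box, frame_shape) {
  box[1] >= 1 && box[2] >= 1 &&
    box[1] + box[3] - 1 <= frame_shape[1] &&
    box[2] + box[4] - 1 <= frame_shape[2]
}

#' @export
print.ceus_box <- function(x, ...) {
  cat(sprintf("<box %gx%g at (row=%g, col=%g)>\n", x[3], x[4], x[1], x[2]))
  invisible(x)
}
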
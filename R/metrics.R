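#' Center location error (CLE)
#'
#' Per-frame Euclidean pixel distance between the predicted box center and the
#' true lesion center, averaged over the sequence. Lower is better.
#'
#' @param pred a `ceus_trajectory` or data.frame with `row,col,height,width`
#'   per frame.
#' @param truth a `ceus_truth` data.frame (uses its exact `center_row`,
#'   `center_col` when present, otherwise its box centers).
#' @return mean distance (px), with attribute `per_frame`.
#' @export
cle <- function(pred, truth) {
  pred <- as.data.frame(pred); truth <- as.data.frame(truth)
  if (nrow(pred) != nrow(truth)) stop("pred and truth must have equal lengths")
  pr <- pred$row + pred$height / 2 - 0.5
  pc <- pred$col + pred$width / 2 - 0.5
  if (all(c("center_row", "center_col") %in% names(truth))) {
    tr <- truth$center_row; tc <- truth$center_col
  } else {
    tr <- truth$row + truth$height / 2 - 0.5
    tc <- truth$col + truth$width / 2 - 0.5
  }
  d <- sqrt((pr - tr)^2 + (pc - tc)^2)
  structure(mean(d), per_frame = d)
}

#' Target overlap area ratio (TOAR)
#'
#' Intersection-over-union of two axis-aligned boxes: the overlap area divided
#' by the union area, in `[0, 1]`; 1 for identical boxes, 0 for disjoint ones.
#' Zero-area boxes yield 0 by convention (with a warning).
#'
#' @param box_a,box_b `ceus_box` vectors `c(row, col, height, width)`.
#' @return overlap ratio.
#' @export
toar <- function(box_a, box_b) {
  if (box_a[3] * box_a[4] == 0 || box_b[3] * box_b[4] == 0) {
    warning("zero-area box; TOAR defined as 0")
    return(0)
  }
  unname(box_iou(box_a, box_b))
}

#' Similarity index (SI) of two gray-value distributions
#'
#' One minus the Bhattacharyya coefficient of the two images' normalized
#' gray-level histograms: 0 for identical distributions, 1 for distributions
#' with disjoint support. Lower values mean the tracked region still looks
#' like the reference region. `literal = TRUE` instead computes
#' `1 - sum(H1*H2) / (sum(H1) * sum(H2))` on the normalized histograms — the
#' raw cross-correlation normalization, kept for comparison (its denominator
#' is identically 1 for normalized histograms, so it is not a bounded
#' similarity; the Bhattacharyya form is the default).
#'
#' @param img_a,img_b images (or image regions) of identical shape, gray
#'   levels in `[0, 255]`.
#' @param n_bins histogram bins over `[0, 255]` (default 64).
#' @param literal use the raw cross-correlation normalization instead of the
#'   Bhattacharyya coefficient.
#' @return dissimilarity in `[0, 1]` (Bhattacharyya form).
#' @export
si <- function(img_a, img_b, n_bins = 64, literal = FALSE) {
  a <- frame_gray(img_a); b <- frame_gray(img_b)
  if (length(a) == 0 || length(b) == 0) stop("empty image")
  if (!all(dim(a) == dim(b))) stop("images must have the same shape")
  h1 <- gray_hist(a, n_bins); h2 <- gray_hist(b, n_bins)
  if (literal) return(1 - sum(h1 * h2) / (sum(h1) * sum(h2)))
  1 - sum(sqrt(h1 * h2))
}

gray_hist <- function(img, n_bins) {
  idx <- pmin(pmax(floor(as.vector(img) / 256 * n_bins), 0), n_bins - 1) + 1
  h <- tabulate(idx, nbins = n_bins)
  h / sum(h)
}

#' Evaluate a trajectory against ground truth
#'
#' Computes the three tracking metrics over a sequence: mean and per-frame
#' CLE, TOAR between predicted and true boxes, and — when frames are supplied
#' — the SI between the first frame's tracked region and each later frame's
#' tracked region.
#'
#' @param pred predicted trajectory (`ceus_trajectory` or data.frame).
#' @param truth ground truth (`ceus_truth` data.frame).
#' @param frames optional list of frames for the SI component.
#' @param n_bins histogram bins for SI.
#' @return object of class `ceus_eval`: list with `cle`, `toar`, `si` (means)
#'   and `per_frame` data.frame.
#' @export
evaluate_tracking <- function(pred, truth, frames = NULL, n_bins = 64) {
  pred <- as.data.frame(pred); truth <- as.data.frame(truth)
  if (nrow(pred) != nrow(truth)) stop("pred and truth must have equal lengths")
  d <- cle(pred, truth)
  n <- nrow(pred)
  to <- vapply(seq_len(n), function(i)
    toar(unlist(pred[i, c("row", "col", "height", "width")]),
         unlist(truth[i, c("row", "col", "height", "width")])), numeric(1))
  si_pf <- rep(NA_real_, n)
  if (!is.null(frames)) {
    ref <- crop_box(frame_gray(frames[[1]]),
                    unlist(pred[1, c("row", "col", "height", "width")]))
    for (i in seq_len(n)) {
      cur <- crop_box(frame_gray(frames[[i]]),
                      unlist(pred[i, c("row", "col", "height", "width")]))
      si_pf[i] <- si(ref, cur, n_bins)
    }
  }
  structure(list(cle = as.numeric(d), toar = mean(to),
                 si = if (is.null(frames)) NA_real_ else mean(si_pf[-1]),
                 n_frames = n,
                 per_frame = data.frame(frame = seq_len(n),
                                        cle = attr(d, "per_frame"),
                                        toar = to, si = si_pf)),
            class = "ceus_eval")
}

#' @export
print.ceus_eval <- function(x, ...) {
  cat(sprintf("Tracking evaluation over %d frames\n", x$n_frames))
  cat(sprintf("  mean CLE : %6.3f px\n", x$cle))
  cat(sprintf("  mean TOAR: %6.3f\n", x$toar))
  if (!is.na(x$si)) cat(sprintf("  mean SI  : %6.3f\n", x$si))
  invisible(x)
}
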
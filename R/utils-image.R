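# Internal image helpers shared across modules.

# Gaussian blur via the frequency domain (periodic boundary). The transfer
# function is the sampled continuous Fourier transform of a Gaussian,
# exp(-2 pi^2 sigma^2 f^2), so arbitrarily large sigma costs the same as small
# sigma and no spatial kernel ever exceeds the image.
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  nr <- nrow(img); nc <- ncol(img)
  fr <- c(0:(floor(nr / 2)), -(ceiling(nr / 2) - 1):-1) / nr
  fc <- c(0:(floor(nc / 2)), -(ceiling(nc / 2) - 1):-1) / nc
  Hr <- exp(-2 * pi^2 * sigma^2 * fr^2)
  Hc <- exp(-2 * pi^2 * sigma^2 * fc^2)
  H <- outer(Hr, Hc)
  Re(stats::fft(stats::fft(img) * H, inverse = TRUE)) / (nr * nc)
}

# Summed-area table padded with a leading zero row/col so that
# rect_sum(ii, r1, r2, c1, c2) is O(1).
integral_image <- function(m) {
  ii <- apply(apply(m, 2, cumsum), 1, cumsum)  # t(cumsum both ways)
  ii <- t(ii)
  rbind(0, cbind(0, ii))
}

rect_sum <- function(ii, r1, r2, c1, c2) {
  ii[r2 + 1, c2 + 1] - ii[r1, c2 + 1] - ii[r2 + 1, c1] + ii[r1, c1]
}

# Box-filter (moving sum) of a matrix with a (2k+1)x(2k+1) window, zero-padded.
box_sum <- function(m, k) {
  nr <- nrow(m); nc <- ncol(m)
  ii <- integral_image(m)
  r1 <- pmax(seq_len(nr) - k, 1); r2 <- pmin(seq_len(nr) + k, nr)
  c1 <- pmax(seq_len(nc) - k, 1); c2 <- pmin(seq_len(nc) + k, nc)
  out <- matrix(0, nr, nc)
  for (j in seq_len(nc)) {
    out[, j] <- ii[r2 + 1, c2[j] + 1] - ii[r1, c2[j] + 1] -
      ii[r2 + 1, c1[j]] + ii[r1, c1[j]]
  }
  out
}

# central-difference spatial gradients; one-sided at the borders
spatial_gradients <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  gr <- matrix(0, nr, nc); gc <- matrix(0, nr, nc)
  gr[2:(nr - 1), ] <- (m[3:nr, ] - m[1:(nr - 2), ]) / 2
  gr[1, ] <- m[2, ] - m[1, ]; gr[nr, ] <- m[nr, ] - m[nr - 1, ]
  gc[, 2:(nc - 1)] <- (m[, 3:nc] - m[, 1:(nc - 2)]) / 2
  gc[, 1] <- m[, 2] - m[, 1]; gc[, nc] <- m[, nc] - m[, nc - 1]
  list(dr = gr, dc = gc)
}

# collapse a frame to the single-channel intensity used for flow/feature
# extraction: the HSV value channel (max over channels) for RGB input,
# the frame itself when already 2-D.
frame_gray <- function(frame) {
  if (is.matrix(frame)) return(frame)
  if (length(dim(frame)) == 3L && dim(frame)[3] == 3L) {
    return(pmax(frame[, , 1], frame[, , 2], frame[, , 3]))
  }
  stop("frame must be a matrix or a rows x cols x 3 array")
}

frame_shape <- function(frame) dim(frame)[1:2]

crop_box <- function(frame, box) {
  r <- box[1]; c <- box[2]
  frame[r:(r + box[3] - 1), c:(c + box[4] - 1), drop = FALSE]
}
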
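# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Bilinear sample an H x W x 3 array at 0-based (x, y) positions.
# Positions outside the image are sampled with edge clamping.
bilinear_sample <- function(pixels, xs, ys) {
  h <- dim(pixels)[1]; w <- dim(pixels)[2]
  xs <- clamp(xs, 0, w - 1)
  ys <- clamp(ys, 0, h - 1)
  x0 <- floor(xs); y0 <- floor(ys)
  x1 <- pmin(x0 + 1, w - 1); y1 <- pmin(y0 + 1, h - 1)
  fx <- xs - x0; fy <- ys - y0
  n <- length(xs)
  out <- matrix(0, n, 3)
  for (ch in 1:3) {
    pl <- pixels[, , ch]
    i00 <- y0 + 1 + h * x0; i10 <- y0 + 1 + h * x1
    i01 <- y1 + 1 + h * x0; i11 <- y1 + 1 + h * x1
    out[, ch] <- (1 - fy) * ((1 - fx) * pl[i00] + fx * pl[i10]) +
      fy * ((1 - fx) * pl[i01] + fx * pl[i11])
  }
  out
}

# Nearest-neighbour sample a logical matrix at 0-based positions.
nearest_sample <- function(mask, xs, ys) {
  h <- nrow(mask); w <- ncol(mask)
  xi <- clamp(round(xs), 0, w - 1)
  yi <- clamp(round(ys), 0, h - 1)
  mask[yi + 1 + h * xi]
}

# 2-D integral-image window sums of a numeric matrix, window of half-width r
# clipped at the borders. Returns a matrix of the same shape.
box_sum <- function(m, r) {
  h <- nrow(m); w <- ncol(m)
  cs <- matrix(0, h + 1, w + 1)
  cs[-1, -1] <- m
  cs <- apply(cs, 2, cumsum)
  cs <- t(apply(cs, 1, cumsum))
  y0 <- pmax(1, seq_len(h) - r); y1 <- pmin(h, seq_len(h) + r)
  x0 <- pmax(1, seq_len(w) - r); x1 <- pmin(w, seq_len(w) + r)
  cs[y1 + 1, x1 + 1, drop = FALSE] - cs[y0, x1 + 1, drop = FALSE] -
    cs[y1 + 1, x0, drop = FALSE] + cs[y0, x0, drop = FALSE]
}

# Number of pixels in the clipped (2r+1)^2 window around each pixel.
box_area <- function(h, w, r) {
  ny <- pmin(h, seq_len(h) + r) - pmax(1, seq_len(h) - r) + 1
  nx <- pmin(w, seq_len(w) + r) - pmax(1, seq_len(w) - r) + 1
  outer(ny, nx)
}
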
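# Small fixture constructors shared across test files.

tiny_spec <- function(seed = 1, n = 3, width = 64, height = 64, radius = 4) {
  pts <- list(A = c(16, 16), B = c(48, 20), C = c(32, 46),
              D = c(14, 50), E = c(50, 50))[seq_len(n)]
  fixture_spec(width = width, height = height, keypoints = pts,
               marker_radius = radius, seed = seed)
}

# The acceptance-scale restoration fixture: 128 x 128, 5 markers, radius 6.
suite_spec <- function(seed) {
  fixture_spec(width = 128, height = 128,
               keypoints = list(A = c(30, 30), B = c(90, 40), C = c(60, 64),
                                D = c(35, 95), E = c(95, 95)),
               marker_radius = 6, seed = seed)
}

# Brute-force SSD patch search over all fully-known candidate centers;
# independent of match_patch() internals. 0-based p; returns c(x, y).
brute_match <- function(image, remaining, p, radius) {
  h <- nrow(remaining); w <- ncol(remaining)
  known <- !remaining
  best <- NULL; best_key <- NULL
  for (qr in (radius + 1):(h - radius)) {
    for (qc in (radius + 1):(w - radius)) {
      if (any(remaining[(qr - radius):(qr + radius),
                        (qc - radius):(qc + radius)])) next
      ssd <- 0
      for (dr in -radius:radius) {
        for (dc in -radius:radius) {
          r0 <- p[2] + 1 + dr; c0 <- p[1] + 1 + dc
          if (r0 < 1 || r0 > h || c0 < 1 || c0 > w) next
          if (!known[r0, c0]) next
          d <- image[r0, c0, ] - image[qr + dr, qc + dc, ]
          ssd <- ssd + sum(d^2)
        }
      }
      d2 <- (qc - 1 - p[1])^2 + (qr - 1 - p[2])^2
      key <- c(ssd, d2, qr, qc)
      if (is.null(best_key) ||
          key[1] < best_key[1] - 1e-9 ||
          (abs(key[1] - best_key[1]) <= 1e-9 &&
           (key[2] < best_key[2] ||
            (key[2] == best_key[2] &&
             (key[3] < best_key[3] ||
              (key[3] == best_key[3] && key[4] < best_key[4])))))) {
        best_key <- key
        best <- c(qc - 1, qr - 1)
      }
    }
  }
  best
}
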
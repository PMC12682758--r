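#' Default acupoint layout for synthetic back images
#'
#' 34 named keypoints: M1-M6 down the spinal midline and seven mirrored
#' left/right pairs in two columns per side (L1-L14, R1-R14), laid out on a
#' grid over the central back area. The coordinates are fixture parameters,
#' not anatomical claims.
#'
#' @param width,height canvas size in pixels.
#' @return named list of length-2 numeric vectors (0-based pixel x, y).
#' @export
default_acupoint_layout <- function(width = 640, height = 480) {
  pos <- list()
  my <- seq(0.20, 0.78, length.out = 6) * (height - 1)
  for (i in 1:6) pos[[paste0("M", i)]] <- c(0.5 * (width - 1), my[i])
  ry <- seq(0.22, 0.76, length.out = 7) * (height - 1)
  xin <- 0.40; xout <- 0.31  # inner and outer paraspinal columns
  for (i in 1:7) {
    pos[[paste0("L", i)]] <- c(xin * (width - 1), ry[i])
    pos[[paste0("L", i + 7)]] <- c(xout * (width - 1), ry[i])
    pos[[paste0("R", i)]] <- c((1 - xin) * (width - 1), ry[i])
    pos[[paste0("R", i + 7)]] <- c((1 - xout) * (width - 1), ry[i])
  }
  pos
}

#' Specification for a synthetic marked back image
#'
#' Describes the stated world the fixture generator emulates: a smooth
#' skin-toned raster with mild low-frequency shading and sensor noise, plus
#' dark circular adhesive labels centered on the named acupoints. The same
#' spec also parameterizes the paired depth frame.
#'
#' @param width,height canvas size in pixels (default 640 x 480, the camera
#'   resolution of the recognition platform).
#' @param keypoints named list of 0-based `c(x, y)` pixel positions; default
#'   [default_acupoint_layout()] (34 points).
#' @param marker_radius adhesive-label radius in pixels (default 8).
#' @param base_tone length-3 RGB base skin tone in \[0,255\].
#' @param shading_amplitude amplitude (8-bit units) of the two-cosine
#'   low-frequency shading field.
#' @param noise_sd standard deviation (8-bit units) of per-pixel Gaussian
#'   sensor noise.
#' @param seed integer RNG seed; a fixed seed gives byte-identical output.
#' @return list of class `fixture_spec`.
#' @export
fixture_spec <- function(width = 640, height = 480,
                         keypoints = default_acupoint_layout(width, height),
                         marker_radius = 8,
                         base_tone = c(205, 170, 148),
                         shading_amplitude = 18,
                         noise_sd = 3,
                         seed = 1) {
  stopifnot(width > 0, height > 0, marker_radius >= 1,
            length(base_tone) == 3, all(base_tone >= 0 & base_tone <= 255),
            shading_amplitude >= 0, noise_sd >= 0)
  for (nm in names(keypoints)) {
    p <- keypoints[[nm]]
    if (p[1] < 0 || p[1] > width - 1 || p[2] < 0 || p[2] > height - 1) {
      stop("keypoint '", nm, "' lies outside the ", width, "x", height,
           " image")
    }
  }
  structure(list(width = as.integer(width), height = as.integer(height),
                 keypoints = keypoints, marker_radius = marker_radius,
                 base_tone = base_tone,
                 shading_amplitude = shading_amplitude,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Render a synthetic marked back image
#'
#' Produces the skin-toned raster (base tone + two low-frequency cosine
#' shading fields + seeded Gaussian noise) with an anti-aliased dark disc of
#' `marker_radius` at each keypoint. The returned marker mask is true exactly
#' on disc pixels (pixel centers within the radius), and each mask component
#' contains exactly one keypoint.
#'
#' @param spec a [fixture_spec()].
#' @return an [annotated_image()] whose `mask` marks the rendered discs.
#' @examples
#' img <- make_back_image(fixture_spec(width = 160, height = 120,
#'   keypoints = list(M1 = c(80, 60)), marker_radius = 5))
#' sum(img$mask)  # disc area ~ pi * 5^2
#' @export
make_back_image <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  w <- spec$width; h <- spec$height
  xs <- matrix(seq_len(w) - 1, h, w, byrow = TRUE)
  ys <- matrix(seq_len(h) - 1, h, w)
  # Two low-frequency cosines: broad vertical body shading plus a gentle
  # diagonal illumination gradient.
  shade <- spec$shading_amplitude *
    (0.6 * cos(2 * pi * (ys / h - 0.5)) +
     0.4 * cos(2 * pi * (0.7 * xs / w + 0.4 * ys / h)))
  noise <- with_seed(spec$seed,
                     matrix(stats::rnorm(h * w * 3, sd = spec$noise_sd),
                            h, w * 3))
  pixels <- array(0, c(h, w, 3))
  for (ch in 1:3) {
    pixels[, , ch] <- spec$base_tone[ch] + shade +
      noise[, ((ch - 1) * w + 1):(ch * w)]
  }
  mask <- matrix(FALSE, h, w)
  dark <- c(30, 30, 30)
  r <- spec$marker_radius
  for (nm in names(spec$keypoints)) {
    p <- spec$keypoints[[nm]]
    x0 <- max(0, floor(p[1] - r - 1)); x1 <- min(w - 1, ceiling(p[1] + r + 1))
    y0 <- max(0, floor(p[2] - r - 1)); y1 <- min(h - 1, ceiling(p[2] + r + 1))
    gx <- x0:x1; gy <- y0:y1
    d <- sqrt(outer((gy - p[2])^2, (gx - p[1])^2, `+`))
    # anti-aliased edge, confined to the disc so the mask covers every
    # altered pixel
    alpha <- clamp(r + 0.5 - d, 0, 1)
    alpha[d > r] <- 0
    rows <- gy + 1; cols <- gx + 1
    for (ch in 1:3) {
      blk <- pixels[rows, cols, ch]
      pixels[rows, cols, ch] <- (1 - alpha) * blk + alpha * dark[ch]
    }
    mask[rows, cols] <- mask[rows, cols] | (d <= r)
  }
  pixels <- round(clamp(pixels, 0, 255))
  kp <- keypoint_set(names(spec$keypoints),
                     vapply(spec$keypoints, `[`, numeric(1), 1),
                     vapply(spec$keypoints, `[`, numeric(1), 2))
  annotated_image(pixels, kp, mask)
}

#' Render the pristine (marker-free) version of a fixture
#'
#' Same raster as [make_back_image()] with no discs drawn: the ground truth
#' a de-labeling algorithm tries to restore.
#'
#' @param spec a [fixture_spec()].
#' @return an [annotated_image()] with `mask = NULL`.
#' @export
make_clean_image <- function(spec) {
  clean_spec <- spec
  clean_spec$keypoints <- list()
  out <- make_back_image(clean_spec)
  out$keypoints <- keypoint_set(names(spec$keypoints),
                                vapply(spec$keypoints, `[`, numeric(1), 1),
                                vapply(spec$keypoints, `[`, numeric(1), 2))
  out$mask <- NULL
  out
}

#' Synthesize a registered depth frame for a fixture
#'
#' A smooth surface — constant plane plus a single cosine bump that peaks at
#' the canvas center and falls to zero at the edges — rendered at the depth
#' camera's resolution. The width/height factors tie the depth raster to the
#' paired color image for registration.
#'
#' @param spec a [fixture_spec()] (supplies the color resolution).
#' @param color_to_depth_ratio length-2 `c(s_w, s_h)` resolution ratios
#'   (depth width = color width x s_w).
#' @param plane_depth base plane distance in millimeters (> 0).
#' @param bump_amplitude peak height of the body bump in millimeters
#'   (subtracted from the plane: the body bulges toward the camera).
#' @return list of class `depth_frame` with `depth` (H' x W' matrix, mm),
#'   `s_w`, `s_h`.
#' @export
make_depth_frame <- function(spec, color_to_depth_ratio = c(1, 1),
                             plane_depth = 800, bump_amplitude = 0) {
  stopifnot(inherits(spec, "fixture_spec"),
            length(color_to_depth_ratio) == 2,
            all(color_to_depth_ratio > 0))
  if (plane_depth <= 0) stop("plane_depth must be positive")
  s_w <- color_to_depth_ratio[1]; s_h <- color_to_depth_ratio[2]
  wd <- max(1L, as.integer(round(spec$width * s_w)))
  hd <- max(1L, as.integer(round(spec$height * s_h)))
  if (bump_amplitude == 0) {
    depth <- matrix(plane_depth, hd, wd)
  } else {
    rx <- if (wd > 1) (2 * (seq_len(wd) - 1) / (wd - 1) - 1) else 0
    ry <- if (hd > 1) (2 * (seq_len(hd) - 1) / (hd - 1) - 1) else 0
    bump <- bump_amplitude * outer(cos(pi * ry / 2), cos(pi * rx / 2))
    depth <- plane_depth - bump
  }
  structure(list(depth = depth, s_w = s_w, s_h = s_h),
            class = "depth_frame")
}

#' @export
print.depth_frame <- function(x, ...) {
  cat(sprintf("<depth_frame: %d x %d, s_w = %.3g, s_h = %.3g, range %.1f-%.1f mm>\n",
              ncol(x$depth), nrow(x$depth), x$s_w, x$s_h,
              min(x$depth), max(x$depth)))
  invisible(x)
}

#' Generate mock keypoint predictions with controlled error
#'
#' Displaces each visible ground-truth point by isotropic Gaussian noise of
#' standard deviation `sigma` per axis (radial displacement then follows a
#' Rayleigh law with mean `sigma * sqrt(pi/2)`), and independently marks
#' points invisible with probability `miss_rate` — a stand-in detector for
#' exercising the accuracy metrics.
#'
#' @param truth a [keypoint_set()] of ground-truth points.
#' @param sigma per-axis noise standard deviation in pixels (>= 0).
#' @param miss_rate probability in \[0,1\] that a point is reported missing.
#' @param seed integer RNG seed.
#' @return a [keypoint_set()] of mock predictions.
#' @export
mock_predictions <- function(truth, sigma, miss_rate = 0, seed = 1) {
  truth <- as_keypoint_set(truth)
  stopifnot(sigma >= 0, miss_rate >= 0, miss_rate <= 1)
  n <- nrow(truth)
  if (n == 0) return(truth)
  with_seed(seed, {
    dx <- stats::rnorm(n, sd = sigma)
    dy <- stats::rnorm(n, sd = sigma)
    miss <- stats::runif(n) < miss_rate
  })
  out <- truth
  vis <- out$visible
  out$x[vis] <- out$x[vis] + dx[vis]
  out$y[vis] <- out$y[vis] + dy[vis]
  out$visible <- vis & !miss
  out
}
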